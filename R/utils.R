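# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline derive their own seeds
#' deterministically from a single master seed, so that a run is reproducible
#' end to end while stages stay statistically independent.
#'
#' @param seed master seed (integer-like scalar).
#' @param index stage or repeat index (integer-like scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  # multiplicative congruential mix in double precision; values stay < 2^53
  as.integer((abs(as.double(seed)) * 48271 + as.double(index) * 104729) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# lower bound in years of a 5-year age band such as "20-24" or "95+"
age_band_lower <- function(band) {
  as.integer(sub("[-+].*$", "", as.character(band)))
}

age_to_band <- function(age) {
  lo <- pmin(5L * (as.integer(age) %/% 5L), 95L)
  ifelse(lo >= 95L, "95+", paste0(lo, "-", lo + 4L))
}
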