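#' Normalized time-varying elastance waveform
#'
#' Double-Hill activation function, the standard 0D idiom for the
#' ventricular elastance cycle: a rising Hill factor drives contraction and
#' a decaying one relaxation.  The waveform is periodic, starts at zero
#' activation (end-diastole) and is normalized so its maximum over one beat
#' equals 1 (to within 1e-6); the ventricular elastance is then
#' `e_min + (e_max - e_min) * e_norm(t)`.
#'
#' @param t time in seconds (vectorized).
#' @param period beat period in seconds.
#' @param shape list of shape parameters: exponents `n1`, `n2`, time
#'   constants `tau1`, `tau2` (fractions of the period) and
#'   `systolic_fraction` which rescales both time constants relative to the
#'   default 0.3 systole fraction.
#' @return normalized elastance values in \[0, 1\].
#' @export
#' @examples
#' normalized_elastance(c(0, 0.3, 0.9), period = 1)
normalized_elastance <- function(t, period,
                                 shape = list(systolic_fraction = 0.3,
                                              n1 = 1.32, n2 = 21.9,
                                              tau1 = 0.269, tau2 = 0.452)) {
  stopifnot(period > 0)
  scale <- shape$systolic_fraction / 0.3
  tau1 <- shape$tau1 * scale
  tau2 <- shape$tau2 * scale
  k <- .hill_norm_constant(shape$n1, shape$n2, tau1, tau2)
  x <- (t %% period) / period
  k * .hill_raw(x, shape$n1, shape$n2, tau1, tau2)
}

.hill_raw <- function(x, n1, n2, tau1, tau2) {
  a <- (x / tau1)^n1
  b <- (x / tau2)^n2
  (a / (1 + a)) / (1 + b)
}

# normalization constant cache: the raw double-Hill peak depends only on
# the four shape numbers, so memoise on them
.hill_cache <- new.env(parent = emptyenv())

.hill_norm_constant <- function(n1, n2, tau1, tau2) {
  key <- paste(format(c(n1, n2, tau1, tau2), digits = 15), collapse = "|")
  hit <- .hill_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- seq(0, 1, length.out = 20001)
  k <- 1 / max(.hill_raw(grid, n1, n2, tau1, tau2))
  # polish the peak on a finer local grid so the normalized max is 1 to 1e-8
  i <- which.max(.hill_raw(grid, n1, n2, tau1, tau2))
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  fine <- seq(lo, hi, length.out = 4001)
  k <- 1 / max(.hill_raw(fine, n1, n2, tau1, tau2))
  .hill_cache[[key]] <- k
  k
}
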