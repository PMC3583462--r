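#' Map functions: genetic distance to recombination fraction
#'
#' Convert between genetic distance (cM) and recombination fraction under
#' the Haldane model (independent crossovers, no interference).  The
#' forward function is \eqn{r = (1 - e^{-2d/100})/2}; its inverse is
#' \eqn{d = -50 \log(1 - 2r)}.
#'
#' @param d_cM genetic distance in centimorgans (vectorised, >= 0).
#'   `Inf` maps to r = 0.5 (unlinked).
#' @param r recombination fraction in [0, 0.5); values at or above 0.5 are
#'   mapped to `Inf`.
#' @return `haldane_r`: recombination fraction in [0, 0.5];
#'   `haldane_d`: distance in cM.
#' @examples
#' haldane_r(1.6)        # ~0.0157
#' haldane_d(haldane_r(10))
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0, na.rm = TRUE)) stop("distances must be >= 0")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' @rdname haldane_r
#' @export
haldane_d <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) stop("r must lie in [0, 0.5]")
  ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))
}
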