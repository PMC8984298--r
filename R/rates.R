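#' Nutrient-dependent per-capita rate laws
#'
#' The five per-capita event rates of the model as functions of the local
#' non-dimensional nutrient concentration `c`:
#'
#' * `rate_red_to_yellow()`: G1 to early-S commitment,
#'   `Rr_max * c^eta1 / (c_a^eta1 + c^eta1)` — an increasing Hill function
#'   with half-maximum at the arrest concentration `c_a`.
#' * `rate_yellow_to_green()`: constant `Ry`, nutrient-independent.
#' * `rate_green_to_red()`: constant `Rg`; this transition is mitosis.
#' * `rate_migration()`: `(m_max - m_min) * c^eta2 / (c_m^eta2 + c^eta2) +
#'   m_min`, increasing from `m_min` towards `m_max`.
#' * `rate_death()`: `(d_max - d_min) * (1 - c^eta3 / (c_d^eta3 + c^eta3)) +
#'   d_min`, decreasing from `d_max` at starvation to essentially `d_min`
#'   in well-nourished tissue.
#'
#' All rates are in events per hour. `c` is vectorized; values outside
#' \[0, 1\] are an error.
#'
#' @param c non-dimensional nutrient concentration(s) in \[0, 1\].
#' @param p a [spheroid_params()] object.
#' @return Numeric vector of rates (h^-1).
#' @examples
#' p <- default_params()
#' rate_red_to_yellow(p$c_a, p)  # half-maximum: Rr_max / 2
#' rate_death(0, p)              # starvation: d_max
#' @export
rate_red_to_yellow <- function(c, p) {
  check_conc(c)
  p$Rr_max * hill(c, p$c_a, p$eta1)
}

#' @rdname rate_red_to_yellow
#' @export
rate_yellow_to_green <- function(p) p$Ry

#' @rdname rate_red_to_yellow
#' @export
rate_green_to_red <- function(p) p$Rg

#' @rdname rate_red_to_yellow
#' @export
rate_migration <- function(c, p) {
  check_conc(c)
  (p$m_max - p$m_min) * hill(c, p$c_m, p$eta2) + p$m_min
}

#' @rdname rate_red_to_yellow
#' @export
rate_death <- function(c, p) {
  check_conc(c)
  (p$d_max - p$d_min) * (1 - hill(c, p$c_d, p$eta3)) + p$d_min
}

# Hill saturation c^eta / (K^eta + c^eta); exactly 0 at c = 0
hill <- function(c, K, eta) {
  cn <- ifelse(c > 0, c^eta, 0)
  cn / (K^eta + cn)
}

check_conc <- function(c) {
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1))
    stop("nutrient concentration must lie in [0, 1]", call. = FALSE)
  invisible(c)
}
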