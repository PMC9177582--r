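#' Gompertzian tumor growth parameters
#'
#' The primary tumor grows as
#' \deqn{V(t) = V(0)\, e^{(\alpha/\beta)(1 - e^{-\beta t})}}
#' with \eqn{V(0)} the volume of a single spherical cell of diameter
#' \code{d0_um}, \eqn{\alpha} the initial instantaneous growth rate and
#' \eqn{\beta} the exponential decay rate of growth (both per day). With the
#' defaults \eqn{\alpha = 0.0359}, \eqn{\beta = 0.0013} the asymptotic
#' diameter is just below the lethal 100 mm, and a 5 / 10 / 40 mm tumor is
#' 2.4 / 2.9 / 4.9 years old.
#'
#' @param alpha Initial instantaneous growth rate, per day.
#' @param beta Exponential decay rate of the growth rate, per day.
#' @param d0_um Initial (single-cell) diameter, micrometres.
#' @param d_lethal_mm Lethal tumor diameter, millimetres.
#' @return An object of class \code{gompertz_params}.
#' @examples
#' gompertz_params()
#' @export
gompertz_params <- function(alpha = 0.0359, beta = 0.0013,
                            d0_um = 10, d_lethal_mm = 100) {
  stopifnot(alpha > 0, beta > 0, d0_um > 0,
            d_lethal_mm > d0_um / 1000)
  structure(list(alpha = alpha, beta = beta, d0_um = d0_um,
                 d_lethal_mm = d_lethal_mm),
            class = "gompertz_params")
}

#' @exportS3Method base::print
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Gompertz growth: alpha = %g /day, beta = %g /day, d0 = %g um,\n  lethal diameter = %g mm (asymptote %.2f mm)\n",
    x$alpha, x$beta, x$d0_um, x$d_lethal_mm,
    x$d0_um / 1000 * exp(x$alpha / (3 * x$beta))))
  invisible(x)
}

DAYS_PER_YEAR <- 365

sphere_volume <- function(d) pi / 6 * d^3

#' Tumor volume at a given age
#'
#' @param t_days Time since tumor initiation, days (vectorized, >= 0).
#' @param p A [gompertz_params()] object.
#' @return Volume in cubic micrometres.
#' @export
volume_at_age <- function(t_days, p = gompertz_params()) {
  if (any(t_days < 0)) stop("tumor age must be non-negative")
  v0 <- sphere_volume(p$d0_um)
  v0 * exp(p$alpha / p$beta * (1 - exp(-p$beta * t_days)))
}

#' Tumor diameter at a given age
#'
#' @inheritParams volume_at_age
#' @return Diameter in millimetres.
#' @export
diameter_at_age <- function(t_days, p = gompertz_params()) {
  d0_mm <- p$d0_um / 1000
  d0_mm * exp(p$alpha / (3 * p$beta) * (1 - exp(-p$beta * t_days)))
}

#' Impute tumor age from diameter
#'
#' Inverts the Gompertz law: \eqn{t = -\ln(1 - (\beta/\alpha)\,3\ln(d/d_0)) /
#' \beta}, converted to years (365 days). Diameters at or above the Gompertz
#' asymptote (possible, since the asymptote with default parameters sits just
#' below the 100 mm inclusion cut) are clamped slightly below it, yielding a
#' large finite age, with a warning.
#'
#' @param d_mm Tumor diameter in millimetres (vectorized).
#' @param p A [gompertz_params()] object.
#' @return Tumor age in years.
#' @examples
#' diameter_to_age(c(5, 10, 40)) # 2.4, 2.9, 4.9 years
#' @export
diameter_to_age <- function(d_mm, p = gompertz_params()) {
  d0_mm <- p$d0_um / 1000
  if (any(!is.finite(d_mm)) || any(d_mm <= d0_mm))
    stop("diameter must exceed the initial cell diameter (",
         format(d0_mm), " mm)")
  x <- 3 * log(d_mm / d0_mm)          # = log(V/V0)
  cap <- p$alpha / p$beta
  clamped <- x >= cap
  if (any(clamped)) {
    warning(sum(clamped), " diameter(s) at or above the Gompertz asymptote (",
            sprintf("%.2f", d0_mm * exp(cap / 3)),
            " mm); age clamped to the near-asymptotic value")
    x[clamped] <- (1 - 1e-6) * cap
  }
  t_days <- -log(1 - x / cap) / p$beta
  t_days / DAYS_PER_YEAR
}

#' Tumor cell count at a given diameter
#'
#' Cells are counted as volume over single-cell volume at equal sphericity,
#' i.e. \eqn{(d/d_0)^3}; a 100 mm tumor of 10 um cells holds \eqn{10^{12}}
#' cells.
#'
#' @inheritParams diameter_to_age
#' @return Number of cells.
#' @examples
#' cell_count(100) # 1e12
#' @export
cell_count <- function(d_mm, p = gompertz_params()) {
  d0_mm <- p$d0_um / 1000
  if (any(d_mm < d0_mm)) stop("diameter below a single cell diameter")
  (d_mm / d0_mm)^3
}

#' Calibrate the initial growth rate from size anchors
#'
#' Chooses \eqn{\alpha} so that the Gompertz asymptotic diameter
#' \eqn{d_0 e^{\alpha/3\beta}} equals the lethal diameter:
#' \eqn{\alpha = 3 \beta \ln(d_\mathrm{lethal}/d_0)}.
#'
#' @param beta Decay rate, per day.
#' @param d0_um Initial cell diameter, micrometres.
#' @param d_lethal_mm Lethal diameter, millimetres.
#' @return Alpha, per day.
#' @examples
#' calibrate_alpha(0.0013, 10, 100) # 0.0359
#' @export
calibrate_alpha <- function(beta = 0.0013, d0_um = 10, d_lethal_mm = 100) {
  stopifnot(beta > 0, d0_um > 0, d_lethal_mm > 0)
  beta * 3 * log(d_lethal_mm / (d0_um / 1000))
}

#' Time to lethal size under constant doubling
#'
#' Reference calculation for a constant-doubling-time growth model: the time
#' for one cell to reach \code{n_lethal} cells at a fixed volume doubling
#' time. At the literature's 150-day doubling, reaching \eqn{10^{12}} cells
#' takes 16.4 years — the comparison motivating the decelerating Gompertz law.
#'
#' @param doubling_days Volume doubling time, days.
#' @param n_lethal Lethal cell count.
#' @return Years.
#' @examples
#' time_to_lethal_constant_doubling(150, 1e12) # 16.4
#' @export
time_to_lethal_constant_doubling <- function(doubling_days = 150,
                                             n_lethal = 1e12) {
  stopifnot(doubling_days > 0, n_lethal >= 1)
  log2(n_lethal) * doubling_days / DAYS_PER_YEAR
}
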