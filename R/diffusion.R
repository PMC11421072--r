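#' Construct a pulsed-gradient diffusion decay
#'
#' Signal attenuation versus gradient strength from a stimulated- or
#' spin-echo diffusion experiment, together with the pulse parameters
#' needed to form the Stejskal-Tanner b-values.
#'
#' @param gradients Gradient strengths g, T/m, non-negative, strictly
#'   increasing, at least 4 values with attenuation information.
#' @param intensities Peak intensities, arbitrary units.
#' @param delta_small Gradient pulse duration delta, s.
#' @param delta_big Diffusion time Delta (start-to-start of the encode and
#'   decode gradients), s; must exceed `delta_small`.
#' @param gamma Gyromagnetic ratio of the observed nucleus, rad s^-1 T^-1;
#'   defaults to 31P.
#' @return An object of class `diffusion_decay`.
#' @export
diffusion_decay <- function(gradients, intensities, delta_small, delta_big,
                            gamma = phos_constants()$gamma_31p) {
  gradients <- as.numeric(gradients)
  intensities <- as.numeric(intensities)
  if (length(gradients) != length(intensities)) {
    stop("gradients and intensities must have equal length", call. = FALSE)
  }
  if (length(gradients) < 4L) {
    stop("need at least 4 gradient points", call. = FALSE)
  }
  if (any(gradients < 0) || any(diff(gradients) <= 0)) {
    stop("gradients must be non-negative and strictly increasing", call. = FALSE)
  }
  if (max(gradients) == 0) {
    stop("all gradients are zero: no attenuation information", call. = FALSE)
  }
  if (!is.numeric(delta_small) || !is.numeric(delta_big) ||
      delta_small <= 0 || delta_big <= delta_small) {
    stop("require 0 < delta_small < delta_big (s)", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma <= 0) {
    stop("gamma must be positive (rad s^-1 T^-1)", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(list(gradients = gradients, intensities = intensities,
                 delta_small = delta_small, delta_big = delta_big,
                 gamma = gamma),
            class = "diffusion_decay")
}

#' @export
print.diffusion_decay <- function(x, ...) {
  cat(sprintf("<diffusion_decay> %d gradients up to %g T/m, delta = %g s, Delta = %g s\n",
              length(x$gradients), max(x$gradients), x$delta_small, x$delta_big))
  invisible(x)
}

#' Stejskal-Tanner b-values for a decay
#'
#' Rectangular-gradient convention: \eqn{b = \gamma^2 g^2 \delta^2 (\Delta
#' - \delta/3)}, in s/m^2.
#'
#' @param decay A [diffusion_decay()].
#' @return Numeric vector of b-values.
#' @export
stejskal_tanner_b <- function(decay) {
  stopifnot(inherits(decay, "diffusion_decay"))
  decay$gamma^2 * decay$gradients^2 * decay$delta_small^2 *
    (decay$delta_big - decay$delta_small / 3)
}

#' Fit the Stejskal-Tanner equation for the diffusion coefficient
#'
#' Fits \eqn{I = I_0 \exp(-D b)} with \eqn{b = \gamma^2 g^2 \delta^2
#' (\Delta - \delta/3)}. The primary estimate is a nonlinear
#' least-squares fit on the intensities; a log-linear regression of
#' \eqn{\log I} on \eqn{b} is computed as an independent cross-check and
#' the two estimates must agree within the fit uncertainty (a warning is
#' raised otherwise). Intensities that rise with gradient strength beyond
#' the noise level also trigger a warning.
#'
#' @param decay A [diffusion_decay()].
#' @return An object of class `diffusion_fit`: a list with `d_coeff`
#'   (m^2/s), `i0`, `residual_rms`, `d_se` (standard error of D from the
#'   nonlinear fit) and `d_loglin` (the cross-check estimate).
#' @export
fit_stejskal_tanner <- function(decay) {
  stopifnot(inherits(decay, "diffusion_decay"))
  b <- stejskal_tanner_b(decay)
  y <- decay$intensities
  if (stats::sd(y) == 0) {
    stop("fit error: constant intensities, D unidentifiable", call. = FALSE)
  }
  rises <- diff(y) > 0.05 * max(abs(y))
  if (any(rises)) {
    warning("non-monotone attenuation beyond noise tolerance at ",
            sum(rises), " step(s)", call. = FALSE)
  }
  pos <- y > 0
  if (sum(pos) < 3L) stop("fit error: too few positive intensities", call. = FALSE)
  lm0 <- stats::lm(log(y[pos]) ~ b[pos])
  d_loglin <- -unname(stats::coef(lm0)[2])
  i0_start <- exp(unname(stats::coef(lm0)[1]))
  d_start <- max(d_loglin, 1e-14)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i0 * exp(-d * b),
      start = list(i0 = i0_start, d = d_start),
      lower = c(i0 = 0, d = 1e-16),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("fit error (Stejskal-Tanner): ",
                             conditionMessage(e), call. = FALSE)
  )
  co <- stats::coef(fit)
  d_nls <- unname(co[["d"]])
  if (d_nls <= 0) stop("fit error: non-positive diffusion coefficient",
                       call. = FALSE)
  d_se <- tryCatch(summary(fit)$coefficients["d", "Std. Error"],
                   error = function(e) NA_real_)
  tol <- max(3 * d_se, 1e-6 * d_nls, na.rm = TRUE)
  if (is.finite(d_loglin) && abs(d_loglin - d_nls) > tol) {
    warning(sprintf("log-linear cross-check D = %.4g disagrees with nonlinear D = %.4g beyond uncertainty",
                    d_loglin, d_nls), call. = FALSE)
  }
  structure(
    list(d_coeff = d_nls, i0 = unname(co[["i0"]]),
         residual_rms = sqrt(mean(stats::resid(fit)^2)),
         d_se = d_se, d_loglin = d_loglin),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.6g m^2/s (log-linear check %.6g), I0 = %.4g\n",
              x$d_coeff, x$d_loglin, x$i0))
  invisible(x)
}

#' Translational hydrodynamic radius from a diffusion coefficient
#'
#' Stokes-Einstein relation for a sphere with stick boundary conditions:
#' \deqn{R_H = \frac{k T}{6 \pi \eta D}.}
#' The 6-pi friction factor is exposed so a slip-boundary (4-pi) variant
#' is a one-argument change.
#'
#' @param d_coeff Translational diffusion coefficient, m^2/s.
#' @param temperature K.
#' @param viscosity Pa s.
#' @param friction_factor Dimensionless boundary-condition factor
#'   multiplying pi eta R; default 6 (stick).
#' @return Hydrodynamic radius, m (vectorized over `d_coeff`).
#' @examples
#' translational_hydrodynamic_radius(2.3e-9, 298, 0.89e-3) # ~1.07 Angstrom
#' @export
translational_hydrodynamic_radius <- function(d_coeff,
                                              temperature = phos_constants()$temperature_default,
                                              viscosity = phos_constants()$water_viscosity_default,
                                              friction_factor = 6) {
  if (any(!is.finite(d_coeff)) || any(d_coeff <= 0) || temperature <= 0 ||
      viscosity <= 0 || friction_factor <= 0) {
    stop("d_coeff, temperature, viscosity and friction_factor must be positive",
         call. = FALSE)
  }
  k <- phos_constants()$boltzmann_k
  k * temperature / (friction_factor * pi * viscosity * d_coeff)
}
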