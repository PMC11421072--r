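#' Construct a relaxation decay/recovery curve
#'
#' @param delays Delay times, s, non-negative, strictly increasing.
#' @param intensities Signal intensities, arbitrary units.
#' @param kind `"inversion_recovery"` (T1) or `"echo_decay"` (T2).
#' @return An object of class `relaxation_curve`.
#' @export
relaxation_curve <- function(delays, intensities,
                             kind = c("inversion_recovery", "echo_decay")) {
  kind <- match.arg(kind)
  delays <- as.numeric(delays)
  intensities <- as.numeric(intensities)
  if (length(delays) != length(intensities)) {
    stop("delays and intensities must have equal length", call. = FALSE)
  }
  if (length(delays) < 4L) {
    stop("need at least 4 points to fit a relaxation curve", call. = FALSE)
  }
  if (any(delays < 0) || any(diff(delays) <= 0)) {
    stop("delays must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(list(delays = delays, intensities = intensities, kind = kind),
            class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("<relaxation_curve> %s, %d delays spanning %g-%g s\n",
              x$kind, length(x$delays), min(x$delays), max(x$delays)))
  invisible(x)
}

new_relaxation_fit <- function(rate, amplitude, inv_efficiency, residual_rms,
                               kind) {
  structure(list(rate = rate, amplitude = amplitude,
                 inv_efficiency = inv_efficiency,
                 residual_rms = residual_rms, kind = kind),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  rate_lbl <- if (x$kind == "inversion_recovery") "R1" else "R2"
  cat(sprintf("<relaxation_fit> %s = %.6g s^-1, I0 = %.4g, rms = %.3g\n",
              rate_lbl, x$rate, x$amplitude, x$residual_rms))
  invisible(x)
}

#' Fit an inversion-recovery curve for R1
#'
#' Nonlinear least-squares fit of
#' \deqn{I(t) = I_0 (1 - 2 a e^{-R_1 t})}
#' where `a` is the inversion efficiency (1 for a perfect 180-degree
#' pulse); it is fitted rather than fixed because imperfect inversion is
#' the norm.
#'
#' @param curve A [relaxation_curve()] of kind `inversion_recovery`.
#' @return A `relaxation_fit` with fields `rate` (R1, s^-1), `amplitude`
#'   (I0), `inv_efficiency` (a), `residual_rms`.
#' @export
fit_inversion_recovery <- function(curve) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (curve$kind != "inversion_recovery") {
    stop("curve is not an inversion-recovery acquisition", call. = FALSE)
  }
  t <- curve$delays; y <- curve$intensities
  if (stats::sd(y) == 0) {
    stop("fit error: constant intensities, rate unidentifiable", call. = FALSE)
  }
  i0_start <- max(abs(y))
  # crude R1 start: time at which the signal crosses zero, t_null = ln(2a)/R1
  crossing <- which(diff(sign(y)) != 0)
  r1_start <- if (length(crossing) > 0L) {
    log(2) / max(t[crossing[1] + 1L], t[2])
  } else {
    1 / max(t[t > 0][1], .Machine$double.eps)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i0 * (1 - 2 * a * exp(-r1 * t)),
      start = list(i0 = i0_start, a = 1, r1 = r1_start),
      lower = c(i0 = 0, a = 0, r1 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("fit error (inversion recovery): ",
                             conditionMessage(e), call. = FALSE)
  )
  co <- stats::coef(fit)
  if (co[["r1"]] <= 1e-10) {
    stop("fit error: recovered rate is not positive", call. = FALSE)
  }
  new_relaxation_fit(rate = unname(co[["r1"]]), amplitude = unname(co[["i0"]]),
                     inv_efficiency = unname(co[["a"]]),
                     residual_rms = sqrt(mean(stats::resid(fit)^2)),
                     kind = "inversion_recovery")
}

#' Fit a (CPMG/perfect-echo) decay curve for R2
#'
#' Nonlinear least-squares fit of \eqn{I(t) = I_0 e^{-R_2 t}}, started
#' from a log-linear regression on the positive intensities.
#'
#' @param curve A [relaxation_curve()] of kind `echo_decay`.
#' @return A `relaxation_fit` with `rate` = R2 (s^-1).
#' @export
fit_echo_decay <- function(curve) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (curve$kind != "echo_decay") {
    stop("curve is not an echo-decay acquisition", call. = FALSE)
  }
  t <- curve$delays; y <- curve$intensities
  pos <- y > 0
  if (sum(pos) < 3L || stats::sd(y) == 0) {
    stop("fit error: decay uninformative (constant or non-positive signal)",
         call. = FALSE)
  }
  lm0 <- stats::lm(log(y[pos]) ~ t[pos])
  r2_start <- max(-unname(stats::coef(lm0)[2]), 1e-9)
  i0_start <- exp(unname(stats::coef(lm0)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i0 * exp(-r2 * t),
      start = list(i0 = i0_start, r2 = r2_start),
      lower = c(i0 = 0, r2 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("fit error (echo decay): ",
                             conditionMessage(e), call. = FALSE)
  )
  co <- stats::coef(fit)
  if (co[["r2"]] <= 1e-10) {
    stop("fit error: recovered rate is not positive", call. = FALSE)
  }
  new_relaxation_fit(rate = unname(co[["r2"]]), amplitude = unname(co[["i0"]]),
                     inv_efficiency = NA_real_,
                     residual_rms = sqrt(mean(stats::resid(fit)^2)),
                     kind = "echo_decay")
}

#' Construct a CSA relaxation model
#'
#' Holds the inputs of the chemical-shift-anisotropy R1 model: Frobenius
#' norms of the symmetric and antisymmetric shielding-tensor parts (ppm),
#' the Larmor frequency, the rank-2 correlation time, and the spectral-
#' density prefactors. Under isotropic rotational diffusion the rank-1
#' correlation time is tied to the rank-2 one by tau1 = 3 tau2
#' (tau_l = 1 / (l (l + 1) D_r)).
#'
#' @param sigma_sym_F Frobenius norm of the symmetric CSA part, ppm.
#' @param sigma_anti_F Frobenius norm of the antisymmetric part, ppm;
#'   defaults to 0 (negligible for these phosphates).
#' @param nu0_mhz Larmor frequency, MHz.
#' @param tau2 Rank-2 rotational correlation time, s (may be `NULL` when
#'   the model is used as input to [invert_r1_for_tau2()]).
#' @param c_sym,c_anti Dimensionless spectral-density prefactors of the
#'   symmetric and antisymmetric terms; defaults 2/15 and 1/3
#'   (Frobenius-norm convention). Kept in one place so an alternative
#'   tensor convention is a one-argument change.
#' @return An object of class `csa_model`.
#' @export
csa_model <- function(sigma_sym_F, sigma_anti_F = 0,
                      nu0_mhz = phos_constants()$nu0_31p_mhz,
                      tau2 = NULL, c_sym = 2 / 15, c_anti = 1 / 3) {
  stopifnot(sigma_sym_F >= 0, sigma_anti_F >= 0, nu0_mhz > 0,
            c_sym > 0, c_anti > 0)
  if (sigma_sym_F == 0 && sigma_anti_F == 0) {
    stop("at least one CSA norm must be positive", call. = FALSE)
  }
  if (!is.null(tau2) && (!is.finite(tau2) || tau2 <= 0)) {
    stop("tau2 must be positive (s)", call. = FALSE)
  }
  structure(
    list(sigma_sym_F = sigma_sym_F, sigma_anti_F = sigma_anti_F,
         omega0 = larmor_omega0(nu0_mhz), nu0_mhz = nu0_mhz,
         tau2 = tau2, tau1 = if (is.null(tau2)) NULL else 3 * tau2,
         c_sym = c_sym, c_anti = c_anti),
    class = "csa_model"
  )
}

#' @export
print.csa_model <- function(x, ...) {
  cat(sprintf("<csa_model> |sigma_sym|_F = %g ppm, |sigma_anti|_F = %g ppm, nu0 = %g MHz",
              x$sigma_sym_F, x$sigma_anti_F, x$nu0_mhz))
  if (!is.null(x$tau2)) cat(sprintf(", tau2 = %.4g s", x$tau2))
  cat("\n")
  invisible(x)
}

# Lorentzian spectral density, tau / (1 + omega^2 tau^2)
lorentzian_j <- function(omega, tau) tau / (1 + (omega * tau)^2)

#' CSA-dominated spin-lattice relaxation rate
#'
#' At high field the 31P R1 of phosphates is dominated by chemical shift
#' anisotropy. With the tensor norms expressed in ppm and converted to
#' angular-frequency units through omega0, the model is
#' \deqn{R_1 = C_{sym}\,\omega_0^2 \|\sigma_{sym}\|_F^2\, J(\omega_0;\tau_2)
#'       + C_{anti}\,\omega_0^2 \|\sigma_{anti}\|_F^2\, J(\omega_0;\tau_1)}
#' with the Lorentzian spectral density \eqn{J(\omega;\tau) = \tau / (1 +
#' \omega^2\tau^2)} and \eqn{\tau_1 = 3\tau_2} (isotropic tumbling).
#'
#' @param model A [csa_model()] with `tau2` set, or with `tau2` supplied
#'   separately.
#' @param tau2 Optional rank-2 correlation time overriding the model's, s.
#' @return R1 in s^-1 (vectorized over `tau2`).
#' @export
csa_r1 <- function(model, tau2 = NULL) {
  stopifnot(inherits(model, "csa_model"))
  if (is.null(tau2)) tau2 <- model$tau2
  if (is.null(tau2)) stop("tau2 neither in model nor supplied", call. = FALSE)
  if (any(!is.finite(tau2)) || any(tau2 <= 0)) {
    stop("tau2 must be positive (s)", call. = FALSE)
  }
  w0 <- model$omega0
  dw_sym <- w0 * model$sigma_sym_F * 1e-6
  dw_anti <- w0 * model$sigma_anti_F * 1e-6
  model$c_sym * dw_sym^2 * lorentzian_j(w0, tau2) +
    model$c_anti * dw_anti^2 * lorentzian_j(w0, 3 * tau2)
}

#' Invert the CSA R1 model for the rank-2 correlation time
#'
#' `csa_r1` as a function of tau2 rises from 0, peaks near omega0 tau2 = 1
#' and falls again, so a measured R1 below the peak has two roots. Small
#' nucleotides at high field tumble well within omega0 tau2 < 1, so the
#' fast-motion branch is returned; the branch choice and the attainable
#' maximum are reported in the result. The root is located by bisection to
#' a relative width of `rel_tol`.
#'
#' @param r1 Measured R1, s^-1, positive.
#' @param model A [csa_model()] (its `tau2`, if any, is ignored).
#' @param rel_tol Relative bisection tolerance on tau2; default 1e-12.
#' @return A list with `tau2` (s), `tau1` (= 3 tau2), `branch`
#'   (`"fast"`), `r1_max` (the model's maximum attainable R1), and
#'   `near_maximum` (TRUE when r1 is within 1% of r1_max, where the two
#'   branches approach each other).
#' @export
invert_r1_for_tau2 <- function(r1, model, rel_tol = 1e-12) {
  stopifnot(inherits(model, "csa_model"))
  if (!is.numeric(r1) || length(r1) != 1L || !is.finite(r1) || r1 <= 0) {
    stop("r1 must be a positive scalar (s^-1)", call. = FALSE)
  }
  w0 <- model$omega0
  # the sym-only peak sits at w0 tau2 = 1; the anti term (tau1 = 3 tau2)
  # peaks at w0 tau2 = 1/3, so the combined peak lies in [1/(3 w0), 1/w0]
  opt <- stats::optimize(function(tau) csa_r1(model, tau),
                         interval = c(0.1 / w0, 10 / w0), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 / w0)
  tau_peak <- opt$maximum
  r1_max <- opt$objective
  if (r1 > r1_max * (1 + 1e-12)) {
    stop(sprintf("r1 = %g s^-1 exceeds the maximum attainable %g s^-1 for this CSA model",
                 r1, r1_max), call. = FALSE)
  }
  near_max <- r1 > 0.99 * r1_max
  if (near_max) {
    warning("r1 is within 1% of the model maximum; fast and slow branches are close",
            call. = FALSE)
  }
  lo <- 1e-30
  hi <- tau_peak
  f <- function(tau) csa_r1(model, tau) - r1
  if (f(hi) < 0) hi <- tau_peak # r1 == r1_max within tolerance
  for (i in 1:400) {
    mid <- sqrt(lo * hi) # geometric bisection: root can span many decades
    if (f(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < rel_tol) break
  }
  tau2 <- 0.5 * (lo + hi)
  list(tau2 = tau2, tau1 = 3 * tau2, branch = "fast",
       r1_max = r1_max, near_maximum = near_max)
}

#' Rotational hydrodynamic radius from the rank-2 correlation time
#'
#' Stokes-Einstein-Debye relation for a sphere under stick boundary
#' conditions: \eqn{\tau_2 = 4\pi\eta R_H^3 / (3 k T)}, inverted as
#' \deqn{R_H = \left(\frac{3 k T \tau_2}{4 \pi \eta}\right)^{1/3}.}
#'
#' @param tau2 Rank-2 rotational correlation time, s.
#' @param temperature K.
#' @param viscosity Solvent dynamic viscosity, Pa s.
#' @return Hydrodynamic radius in m (vectorized over `tau2`).
#' @examples
#' tau2_to_hydrodynamic_radius(5e-11, 298, 1.095e-3) # ~3.55 Angstrom
#' @export
tau2_to_hydrodynamic_radius <- function(tau2,
                                        temperature = phos_constants()$temperature_default,
                                        viscosity = phos_constants()$water_viscosity_default) {
  if (any(!is.finite(tau2)) || any(tau2 <= 0) || temperature <= 0 ||
      viscosity <= 0) {
    stop("tau2, temperature and viscosity must all be positive", call. = FALSE)
  }
  k <- phos_constants()$boltzmann_k
  (3 * k * temperature * tau2 / (4 * pi * viscosity))^(1 / 3)
}
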