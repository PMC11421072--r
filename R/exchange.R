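#' Two-state fast-exchange populations from observed chemical shifts
#'
#' Under fast exchange between a free and a Mg2+-bound state, the observed
#' shift is the population-weighted average of the two end-member shifts,
#' so the bound fraction at each titration point is
#' \deqn{p_b = (\delta_{obs} - \delta_f) / (\delta_b - \delta_f), \quad
#'       p_f = 1 - p_b.}
#'
#' By default the free-state shift is the observed shift at the lowest
#' (zero) Mg2+ equivalent and the bound-state shift is the shift at the
#' largest equivalent in the series, i.e. the largest shift change
#' observed at that concentration; both can be overridden. Populations
#' slightly outside [0, 1] (within `clip_tol`) are clipped with a warning;
#' larger violations are errors, since they indicate model failure rather
#' than noise.
#'
#' @param series A [titration_series()].
#' @param channel `"alpha"` or `"beta"`: which 31P shift column to model.
#' @param delta_f Free-state shift, ppm. Default: shift at the smallest eq.
#' @param delta_b Bound-state shift, ppm. Default: shift at the largest eq.
#' @param clip_tol Populations in (-clip_tol, 0) or (1, 1 + clip_tol) are
#'   clipped to [0, 1]; default 0.02.
#' @return An object of class `two_state_solution`: a data.frame with
#'   columns `mg_equiv`, `delta_obs`, `p_f`, `p_b`, `clipped`, plus
#'   `delta_f`, `delta_b`, `channel` attributes.
#' @examples
#' ser <- gen_titration(adp_conc = 10, deltas = list(alpha = c(f = 0, b = 0.89)))
#' two_state_populations(ser, "alpha")
#' @export
two_state_populations <- function(series, channel = c("alpha", "beta"),
                                  delta_f = NULL, delta_b = NULL,
                                  clip_tol = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  channel <- match.arg(channel)
  obs <- switch(channel, alpha = series$delta_alpha, beta = series$delta_beta)
  if (anyNA(obs)) stop("channel '", channel, "' has missing shifts", call. = FALSE)
  if (is.null(delta_f)) delta_f <- obs[which.min(series$mg_equiv)]
  if (is.null(delta_b)) delta_b <- obs[which.max(series$mg_equiv)]
  if (delta_b == delta_f) {
    stop("degenerate model: delta_b equals delta_f, populations unidentifiable",
         call. = FALSE)
  }
  p_b <- (obs - delta_f) / (delta_b - delta_f)
  clipped <- (p_b < 0 & p_b > -clip_tol) | (p_b > 1 & p_b < 1 + clip_tol)
  out_of_band <- p_b <= -clip_tol | p_b >= 1 + clip_tol
  if (any(out_of_band)) {
    stop("population outside [", -clip_tol, ", ", 1 + clip_tol, "] at eq ",
         paste(series$mg_equiv[out_of_band], collapse = ", "),
         "; the two-state model does not describe these data", call. = FALSE)
  }
  if (any(clipped)) {
    warning("clipped ", sum(clipped), " population(s) to [0, 1] at eq ",
            paste(series$mg_equiv[clipped], collapse = ", "), call. = FALSE)
    p_b <- pmin(pmax(p_b, 0), 1)
  }
  structure(
    data.frame(mg_equiv = series$mg_equiv, delta_obs = obs,
               p_f = 1 - p_b, p_b = p_b, clipped = clipped),
    delta_f = delta_f, delta_b = delta_b, channel = channel,
    adp_conc = attr(series, "adp_conc"),
    class = c("two_state_solution", "data.frame")
  )
}

#' @export
print.two_state_solution <- function(x, ...) {
  cat(sprintf("<two_state_solution> channel %s, delta_f = %.4g ppm, delta_b = %.4g ppm\n",
              attr(x, "channel"), attr(x, "delta_f"), attr(x, "delta_b")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Sequential three-state populations for the beta-phosphate shifts
#'
#' Models the beta-31P shift as a population-weighted average over free,
#' singly-bound (one Mg2+) and doubly-bound (two Mg2+) ADP:
#' \deqn{\delta_{obs,\beta} = p_f \delta_{f,\beta} + p_{b1} \delta_{b1,\beta}
#'       + p_{b2} \delta_{b2,\beta}, \qquad p_f + p_{b1} + p_{b2} = 1,}
#' with the free fractions `p_f` transferred from the alpha-channel
#' two-state fit (the second binding event is assumed to perturb only the
#' beta shift). Three further assumptions close the system:
#' \enumerate{
#'   \item No doubly-bound ADP at the anchor point (default 0.5 eq):
#'     `p_b2(anchor) = 0`, which fixes the singly-bound end-member shift
#'     `delta_b1_beta` from the anchor point alone.
#'   \item Stoichiometric cap: bound Mg2+ cannot exceed what was added,
#'     `p_b1 + 2 p_b2 <= chi_Mg` at every point.
#'   \item The doubly-bound shift `delta_b2_beta` takes the minimum
#'     possible separation from `delta_b1_beta` compatible with the cap
#'     (ties broken toward `delta_b1_beta`).
#' }
#' Given a candidate `delta_b2_beta`, each point's populations follow by
#' direct substitution; the minimal feasible separation is found by a
#' one-dimensional search over the separation `delta_b1_beta -
#' delta_b2_beta`, whose per-point feasibility bounds are monotone, so the
#' optimum is the largest per-point lower bound (resolved to `tol` ppm).
#'
#' @param series A [titration_series()] containing a 0-eq point and the
#'   anchor point.
#' @param p_f_alpha Numeric vector of free fractions, one per point of
#'   `series` (in `mg_equiv` order), normally from
#'   [two_state_populations()] on the alpha channel.
#' @param anchor_eq Equivalents at which `p_b2 = 0` is imposed; default 0.5.
#' @param tol Feasibility/separation tolerance, ppm; default 1e-9.
#' @param clip_tol Per-point populations in (-clip_tol, 0) are clipped to 0
#'   with a warning; default 0.02.
#' @return An object of class `three_state_solution`: a data.frame with
#'   columns `mg_equiv`, `delta_obs_beta`, `p_f`, `p_b1`, `p_b2`, plus
#'   attributes `delta_f_beta`, `delta_b1_beta`, `delta_b2_beta` and
#'   `p_f_discrepancy` (the absolute deviation of the supplied p_f from 1
#'   at 0 eq, reported rather than silently renormalized).
#' @export
three_state_populations <- function(series, p_f_alpha, anchor_eq = 0.5,
                                    tol = 1e-9, clip_tol = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  eq <- series$mg_equiv
  obs <- series$delta_beta
  if (anyNA(obs)) stop("beta channel has missing shifts", call. = FALSE)
  if (length(p_f_alpha) != length(eq)) {
    stop("p_f_alpha must supply one free fraction per titration point",
         call. = FALSE)
  }
  i0 <- which(eq == 0)
  if (length(i0) != 1L) stop("series must contain a 0-eq point", call. = FALSE)
  ia <- which(abs(eq - anchor_eq) < 1e-12)
  if (length(ia) != 1L) {
    stop("anchor eq ", anchor_eq, " absent from the series", call. = FALSE)
  }
  delta_f <- obs[i0]
  p_f <- p_f_alpha
  p_f_disc <- abs(p_f[i0] - 1)
  p_b <- 1 - p_f

  # anchor: p_b2 = 0 there, so delta_b1 follows from the two-term balance
  if (p_b[ia] <= tol) {
    stop("anchor point has no bound population; delta_b1_beta unidentifiable",
         call. = FALSE)
  }
  delta_b1 <- (obs[ia] - p_f[ia] * delta_f) / p_b[ia]

  # residual shift not explained by free + singly-bound at each point;
  # p_b2 = -numer / s with s = delta_b1 - delta_b2 > 0
  numer <- obs - p_f * delta_f - p_b * delta_b1
  numer[ia] <- 0 # exact by construction
  numer[i0] <- 0

  ppm_scale <- max(abs(delta_b1 - delta_f), tol)
  s_lo <- 0
  violations <- integer(0)
  for (i in seq_along(eq)) {
    if (numer[i] < -tol) {
      # point needs p_b2 > 0: separation bounded below by both the cap
      # (p_b + p_b2 <= chi) and p_b2 <= p_b
      room <- eq[i] - p_b[i]
      if (room <= tol) { violations <- c(violations, i); next }
      s_lo <- max(s_lo, -numer[i] / room, -numer[i] / p_b[i])
    } else if (numer[i] > clip_tol * ppm_scale) {
      # observed shift beyond the singly-bound end member: negative p_b2
      # too large to be noise
      violations <- c(violations, i)
    }
  }
  if (length(violations) > 0L) {
    stop("three-state model infeasible at eq ",
         paste(eq[violations], collapse = ", "),
         " (no delta_b2_beta satisfies the shift balance and the cap)",
         call. = FALSE)
  }
  if (s_lo >= delta_b1 - delta_f - tol && s_lo > 0) {
    stop("three-state model infeasible: required separation ", signif(s_lo, 6),
         " ppm would place delta_b2_beta at or below delta_f_beta",
         call. = FALSE)
  }
  delta_b2 <- delta_b1 - s_lo

  if (s_lo > 0) {
    p_b2 <- -numer / s_lo
  } else {
    p_b2 <- numeric(length(eq)) # degenerate two-state data: tie at delta_b1
  }
  clip <- p_b2 < 0
  if (any(p_b2 < -clip_tol)) {
    stop("negative doubly-bound population beyond clip tolerance at eq ",
         paste(eq[p_b2 < -clip_tol], collapse = ", "), call. = FALSE)
  }
  if (any(clip & p_b2 < -tol)) {
    warning("clipped small negative p_b2 to 0 at eq ",
            paste(eq[clip & p_b2 < -tol], collapse = ", "), call. = FALSE)
  }
  p_b2[clip] <- 0
  p_b2[ia] <- 0
  p_b1 <- p_b - p_b2
  cap_excess <- p_b1 + 2 * p_b2 - eq
  if (any(cap_excess > 1e-9)) {
    warning("transferred p_f implies more bound Mg2+ than was added at eq ",
            paste(eq[cap_excess > 1e-9], collapse = ", "),
            "; check the alpha-channel fit", call. = FALSE)
  }

  structure(
    data.frame(mg_equiv = eq, delta_obs_beta = obs,
               p_f = p_f, p_b1 = p_b1, p_b2 = p_b2),
    delta_f_beta = delta_f, delta_b1_beta = delta_b1, delta_b2_beta = delta_b2,
    anchor_eq = anchor_eq, p_f_discrepancy = p_f_disc,
    adp_conc = attr(series, "adp_conc"),
    class = c("three_state_solution", "data.frame")
  )
}

#' @export
print.three_state_solution <- function(x, ...) {
  cat(sprintf(paste0("<three_state_solution> delta_f = %.4f, delta_b1 = %.4f, ",
                     "delta_b2 = %.4f ppm (anchor %g eq)\n"),
              attr(x, "delta_f_beta"), attr(x, "delta_b1_beta"),
              attr(x, "delta_b2_beta"), attr(x, "anchor_eq")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Lower bound on the chemical exchange rate
#'
#' A single population-averaged peak per site places the system in the
#' fast-exchange regime, so the exchange rate must exceed the chemical
#' shift dispersion (in angular frequency units) by some margin:
#' \deqn{k_{ex} > f \cdot 2\pi \cdot \Delta\delta \cdot \nu_0}
#' with the dispersion in ppm and the Larmor frequency in MHz (the ppm and
#' MHz factors cancel to Hz).
#'
#' @param delta_shift Chemical-shift dispersion, ppm, non-negative.
#' @param larmor_freq Larmor frequency nu0, MHz, positive.
#' @param factor Dimensionless multiplier, default 5.
#' @return An object of class `exchange_rate_bound`: a list with fields
#'   `delta_shift`, `larmor_freq`, `factor`, `k_ex_min` (s^-1).
#' @examples
#' kex_lower_bound(0.89, 202.4) # > 5500 s^-1
#' @export
kex_lower_bound <- function(delta_shift, larmor_freq, factor = 5) {
  if (!is.numeric(delta_shift) || delta_shift < 0) {
    stop("delta_shift must be non-negative (ppm)", call. = FALSE)
  }
  if (!is.numeric(larmor_freq) || larmor_freq <= 0) {
    stop("larmor_freq must be positive (MHz)", call. = FALSE)
  }
  if (!is.numeric(factor) || factor < 0) {
    stop("factor must be non-negative", call. = FALSE)
  }
  structure(
    list(delta_shift = delta_shift, larmor_freq = larmor_freq,
         factor = factor,
         k_ex_min = factor * ppm_to_rad_s(delta_shift, larmor_freq)),
    class = "exchange_rate_bound"
  )
}

#' @export
print.exchange_rate_bound <- function(x, ...) {
  cat(sprintf("k_ex > %.4g s^-1 (%g x 2 pi x %g ppm at %g MHz)\n",
              x$k_ex_min, x$factor, x$delta_shift, x$larmor_freq))
  invisible(x)
}
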