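# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# exact 1:1 binding quadratic: bound complex fraction of total ligand
# A0, M0 in mM, kd in mM
binding_quadratic_pb <- function(adp_conc, mg_conc, kd) {
  s <- adp_conc + mg_conc + kd
  bound <- (s - sqrt(s^2 - 4 * adp_conc * mg_conc)) / 2
  bound / adp_conc
}

# stoichiometric sequential-binding populations at ratio chi:
# first equivalent fills the singly-bound pool, the second converts it to
# doubly-bound
stoichiometric_populations <- function(chi) {
  p_f <- pmax(1 - chi, 0)
  p_b2 <- pmin(pmax(chi - 1, 0), 1)
  p_b1 <- 1 - p_f - p_b2
  cbind(p_f = p_f, p_b1 = p_b1, p_b2 = p_b2)
}

#' Generate a synthetic chemical-shift titration
#'
#' Forward model of a fast-exchange Mg2+ titration: populations of free,
#' singly- and doubly-bound ADP are set either stoichiometrically (strong
#' binding: each added Mg2+ binds until saturation) or from the exact 1:1
#' equilibrium quadratic at the stated concentrations, and observed shifts
#' are the population-weighted averages of the end-member shifts, plus
#' optional i.i.d. Gaussian noise on the ppm values. The second binding
#' event perturbs only the beta shift, so the alpha channel sees a
#' two-state average with bound fraction `p_b1 + p_b2`.
#'
#' The generator mirrors the sample design it emulates: by default five
#' samples at Mg2+ equivalents 0, 0.5, 1, 1.5 and 2 of a 10 mM ADP
#' solution.
#'
#' @param adp_conc ADP concentration, mM.
#' @param eq_grid Mg2+ equivalents chi_Mg; default `c(0, 0.5, 1, 1.5, 2)`.
#' @param binding `"stoichiometric"` or `"equilibrium"`.
#' @param kd Dissociation constant, mM (equilibrium mode only).
#' @param deltas List of end-member shifts (ppm):
#'   `alpha = c(f = , b = )` and/or
#'   `beta = c(f = , b1 = , b2 = )` (three-state; must satisfy
#'   f < b2 <= b1) or `beta = c(f = , b = )` (two-state).
#' @param populations Optional explicit population matrix (columns `p_f`,
#'   `p_b1`, `p_b2`, one row per eq point) overriding the binding model.
#' @param noise_sd Gaussian noise sd on the shifts, ppm.
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @param nucleus_freq,temperature Passed to [titration_series()].
#' @return A [titration_series()] whose `ground_truth` attribute records
#'   the populations and end-member shifts used.
#' @examples
#' gen_titration(10, deltas = list(alpha = c(f = 0, b = 0.89)))
#' @export
gen_titration <- function(adp_conc = 10, eq_grid = c(0, 0.5, 1, 1.5, 2),
                          binding = c("stoichiometric", "equilibrium"),
                          kd = NULL,
                          deltas = list(alpha = c(f = 0, b = 0.89)),
                          populations = NULL, noise_sd = 0, seed = NULL,
                          nucleus_freq = phos_constants()$nu0_31p_mhz,
                          temperature = phos_constants()$temperature_default) {
  binding <- match.arg(binding)
  if (any(eq_grid < 0)) stop("eq_grid must be non-negative", call. = FALSE)
  if (is.null(populations)) {
    populations <- switch(binding,
      stoichiometric = stoichiometric_populations(eq_grid),
      equilibrium = {
        if (is.null(kd) || kd <= 0) stop("equilibrium mode needs kd > 0 (mM)",
                                         call. = FALSE)
        p_b <- binding_quadratic_pb(adp_conc, eq_grid * adp_conc, kd)
        cbind(p_f = 1 - p_b, p_b1 = p_b, p_b2 = 0)
      })
  } else {
    populations <- as.matrix(populations)
    if (nrow(populations) != length(eq_grid) || ncol(populations) != 3L) {
      stop("populations must be length(eq_grid) x 3", call. = FALSE)
    }
    if (any(abs(rowSums(populations) - 1) > 1e-9) || any(populations < -1e-12)) {
      stop("each population row must be non-negative and sum to 1", call. = FALSE)
    }
    colnames(populations) <- c("p_f", "p_b1", "p_b2")
  }
  p_f <- populations[, "p_f"]; p_b1 <- populations[, "p_b1"]
  p_b2 <- populations[, "p_b2"]

  d_alpha <- rep(NA_real_, length(eq_grid))
  if (!is.null(deltas$alpha)) {
    a <- deltas$alpha
    if (!all(c("f", "b") %in% names(a))) {
      stop("deltas$alpha must name f and b", call. = FALSE)
    }
    d_alpha <- p_f * a[["f"]] + (p_b1 + p_b2) * a[["b"]]
  }
  d_beta <- rep(NA_real_, length(eq_grid))
  if (!is.null(deltas$beta)) {
    bb <- deltas$beta
    if (all(c("f", "b1", "b2") %in% names(bb))) {
      if (!(bb[["f"]] < bb[["b2"]] && bb[["b2"]] <= bb[["b1"]])) {
        stop("beta end members must satisfy f < b2 <= b1 (ppm)", call. = FALSE)
      }
      d_beta <- p_f * bb[["f"]] + p_b1 * bb[["b1"]] + p_b2 * bb[["b2"]]
    } else if (all(c("f", "b") %in% names(bb))) {
      d_beta <- p_f * bb[["f"]] + (p_b1 + p_b2) * bb[["b"]]
    } else {
      stop("deltas$beta must name (f, b1, b2) or (f, b)", call. = FALSE)
    }
  }
  if (noise_sd > 0) {
    with_local_seed(seed, {
      if (!all(is.na(d_alpha))) d_alpha <- d_alpha + stats::rnorm(length(d_alpha), 0, noise_sd)
      if (!all(is.na(d_beta))) d_beta <- d_beta + stats::rnorm(length(d_beta), 0, noise_sd)
    })
  }
  ser <- titration_series(eq_grid, d_alpha, d_beta, adp_conc = adp_conc,
                          nucleus_freq = nucleus_freq,
                          temperature = temperature)
  attr(ser, "ground_truth") <- list(populations = populations,
                                    deltas = deltas, binding = binding,
                                    kd = kd, noise_sd = noise_sd, seed = seed)
  ser
}

#' Generate a synthetic relaxation curve
#'
#' Exact mono-exponential recovery or decay plus seeded Gaussian noise:
#' inversion recovery \eqn{I(t) = I_0 (1 - 2 a e^{-R t})}, echo decay
#' \eqn{I(t) = I_0 e^{-R t}}.
#'
#' @param kind `"inversion_recovery"` or `"echo_decay"`.
#' @param rate R1 or R2, s^-1, positive.
#' @param delays Delay times, s.
#' @param i0 Equilibrium/initial intensity.
#' @param inv_efficiency Inversion efficiency a (inversion recovery only).
#' @param noise_sd Gaussian noise sd as a fraction of `i0`.
#' @param seed Integer seed.
#' @return A [relaxation_curve()] with a `ground_truth` attribute.
#' @export
gen_relaxation_curve <- function(kind = c("inversion_recovery", "echo_decay"),
                                 rate, delays, i0 = 1, inv_efficiency = 1,
                                 noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive (s^-1)",
                                           call. = FALSE)
  y <- switch(kind,
    inversion_recovery = i0 * (1 - 2 * inv_efficiency * exp(-rate * delays)),
    echo_decay = i0 * exp(-rate * delays))
  if (noise_sd > 0) {
    y <- with_local_seed(seed, y + stats::rnorm(length(y), 0, noise_sd * i0))
  }
  curve <- relaxation_curve(delays, y, kind)
  attr(curve, "ground_truth") <- list(rate = rate, i0 = i0,
                                      inv_efficiency = inv_efficiency,
                                      noise_sd = noise_sd, seed = seed)
  curve
}

#' Generate a synthetic pulsed-gradient diffusion decay
#'
#' Evaluates the Stejskal-Tanner attenuation exactly and adds seeded
#' Gaussian noise on the intensities.
#'
#' @param d_coeff Diffusion coefficient, m^2/s.
#' @param gradients Gradient strengths, T/m.
#' @param delta_small,delta_big Gradient duration and diffusion time, s.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param i0 Unattenuated intensity.
#' @param noise_sd Gaussian noise sd as a fraction of `i0`.
#' @param seed Integer seed.
#' @return A [diffusion_decay()] with a `ground_truth` attribute.
#' @export
gen_diffusion_decay <- function(d_coeff, gradients = seq(0.005, 0.5, length.out = 16),
                                delta_small = 2e-3, delta_big = 0.1,
                                gamma = phos_constants()$gamma_31p,
                                i0 = 1, noise_sd = 0, seed = NULL) {
  if (!is.numeric(d_coeff) || d_coeff <= 0) {
    stop("d_coeff must be positive (m^2/s)", call. = FALSE)
  }
  decay <- diffusion_decay(gradients, rep(i0, length(gradients)),
                           delta_small, delta_big, gamma)
  b <- stejskal_tanner_b(decay)
  y <- i0 * exp(-d_coeff * b)
  if (noise_sd > 0) {
    y <- with_local_seed(seed, y + stats::rnorm(length(y), 0, noise_sd * i0))
  }
  decay$intensities <- y
  attr(decay, "ground_truth") <- list(d_coeff = d_coeff, i0 = i0,
                                      noise_sd = noise_sd, seed = seed)
  decay
}

#' Generate a synthetic ion-coordination trajectory
#'
#' Emulates the geometry of tight (Mg2+-like) versus diffuse (Na+-like)
#' ion-oxygen coordination: a reference ion is fixed at the box center;
#' each tight partner sits at a Gaussian-jittered radial distance with a
#' small sd (nearly constant ~1.9 Angstrom contact), while loose partners
#' get a large sd and, with probability `reposition_prob` per frame, are
#' repositioned uniformly in the box (unbinding excursions).
#'
#' @param n_frames Number of frames.
#' @param tight_pairs Data frame with columns `label`, `mean`, `sd`
#'   (Angstrom) for tightly coordinated partners; may be `NULL`.
#' @param loose_pairs Same, for loosely coordinated partners.
#' @param box Cubic box length or three lengths, Angstrom.
#' @param ref_label Label of the fixed reference ion.
#' @param reposition_prob Per-frame probability that a loose partner is
#'   repositioned uniformly in the box.
#' @param timestep ps between frames.
#' @param seed Integer seed.
#' @return A [phos_trajectory()] with a `ground_truth` attribute.
#' @export
gen_coordination_trajectory <- function(n_frames = 1000,
                                        tight_pairs = data.frame(
                                          label = c("O6", "O8", "O9"),
                                          mean = 1.9, sd = 0.05),
                                        loose_pairs = NULL,
                                        box = 35, ref_label = "MG",
                                        reposition_prob = 0.02,
                                        timestep = 1, seed = NULL) {
  box <- if (length(box) == 1L) rep(as.numeric(box), 3) else as.numeric(box)
  pairs <- rbind(
    if (!is.null(tight_pairs)) cbind(as.data.frame(tight_pairs), kind = "tight"),
    if (!is.null(loose_pairs)) cbind(as.data.frame(loose_pairs), kind = "loose")
  )
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("at least one partner atom is required", call. = FALSE)
  }
  if (any(pairs$mean + 4 * pairs$sd >= min(box) / 2)) {
    stop("coordination geometry infeasible: partner distances reach half the box",
         call. = FALSE)
  }
  labels <- c(ref_label, pairs$label)
  center <- box / 2
  coords <- array(NA_real_, c(n_frames, length(labels), 3L))
  with_local_seed(seed, {
    coords[, 1, ] <- matrix(center, n_frames, 3, byrow = TRUE)
    for (j in seq_len(nrow(pairs))) {
      r <- stats::rnorm(n_frames, pairs$mean[j], pairs$sd[j])
      r <- pmax(r, 0.1)
      # isotropic random directions
      u <- matrix(stats::rnorm(3 * n_frames), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pos <- matrix(center, n_frames, 3, byrow = TRUE) + u * r
      if (pairs$kind[j] == "loose" && reposition_prob > 0) {
        far <- stats::runif(n_frames) < reposition_prob
        if (any(far)) {
          pos[far, ] <- cbind(stats::runif(sum(far), 0, box[1]),
                              stats::runif(sum(far), 0, box[2]),
                              stats::runif(sum(far), 0, box[3]))
        }
      }
      coords[, j + 1L, ] <- pos
    }
  })
  traj <- phos_trajectory(labels, coords, box = box, timestep = timestep)
  attr(traj, "ground_truth") <- list(pairs = pairs, ref_label = ref_label,
                                     reposition_prob = reposition_prob,
                                     seed = seed)
  traj
}
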