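# Independent oracles kept deliberately naive; they must not share code
# paths with the implementation they check.

# brute-force RDF: double loop over frames, reference and target atoms
brute_rdf <- function(traj, ref, target, dr, r_max) {
  iref <- match(ref, traj$labels)
  itar <- match(target, traj$labels)
  n_frames <- dim(traj$coords)[1]
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1L)
  npairs <- 0L
  for (k in seq_len(n_frames)) {
    for (i in iref) {
      for (j in itar) {
        if (i == j) next
        if (k == 1L) npairs <- npairs + 1L
        d <- traj$coords[k, i, ] - traj$coords[k, j, ]
        if (!is.null(traj$box)) {
          d <- d - traj$box * round(d / traj$box)
        }
        r <- sqrt(sum(d^2))
        for (b in seq_along(counts)) {
          if (r >= edges[b] && r < edges[b + 1L]) counts[b] <- counts[b] + 1
        }
      }
    }
  }
  centers <- edges[-length(edges)] + dr / 2
  rho <- (npairs / length(iref)) / prod(traj$box)
  counts / (n_frames * length(iref) * rho * 4 * pi * centers^2 * dr)
}

# 1:1 binding bound fraction by bisection on the mass balance
# free_mg * free_adp / complex = kd, all in mM
brute_binding_pb <- function(adp_conc, mg_conc, kd) {
  f <- function(cplx) (mg_conc - cplx) * (adp_conc - cplx) / kd - cplx
  lo <- 0
  hi <- min(adp_conc, mg_conc)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / adp_conc
}

# random feasible three-state ground truth on the standard eq grid; the
# stoichiometric cap is exactly tight at the 2-eq point so the
# minimum-separation solution coincides with the truth
random_three_state_truth <- function() {
  delta_f <- -5.6
  delta_b1 <- stats::runif(1, -5.3, -4.9)
  sep_max <- delta_b1 - delta_f - 0.05
  sep <- stats::runif(1, 0.02, min(0.3, sep_max))
  delta_b2 <- delta_b1 - sep
  eq <- c(0, 0.5, 1, 1.5, 2)
  # the anchor's bound fraction may not exceed the 0.5 eq of Mg2+ added
  p_f <- c(1, stats::runif(1, 0.5, 0.7), stats::runif(1, 0, 0.05), 0, 0)
  p_b <- 1 - p_f
  p_b2 <- numeric(5)
  # interior points: p_b2 within both the cap (p_b + p_b2 <= chi) and p_b
  p_b2[4] <- stats::runif(1, 0, min(eq[4] - p_b[4], p_b[4]))
  p_b2[5] <- eq[5] - p_b[5] # cap tight: p_b1 + 2 p_b2 = chi
  p_b1 <- p_b - p_b2
  list(delta_f = delta_f, delta_b1 = delta_b1, delta_b2 = delta_b2,
       eq = eq,
       populations = cbind(p_f = p_f, p_b1 = p_b1, p_b2 = p_b2))
}

# forward beta shifts from a three-state truth
three_state_forward <- function(truth) {
  p <- truth$populations
  p[, "p_f"] * truth$delta_f + p[, "p_b1"] * truth$delta_b1 +
    p[, "p_b2"] * truth$delta_b2
}
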