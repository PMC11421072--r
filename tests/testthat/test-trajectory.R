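make_static_traj <- function(n_frames = 100, box = NULL) {
  coords <- array(0, c(n_frames, 2, 3))
  coords[, 2, 1] <- 1.9
  phos_trajectory(c("MG", "O6"), coords, box = box)
}

test_that("distance traces handle static geometry and minimum image", {
  tr <- distance_trace(make_static_traj(), "MG", "O6")
  expect_equal(tr$distance, rep(1.9, 100))
  expect_equal(stats::sd(tr$distance), 0)
  # an atom displaced by exactly one box length is at distance zero
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, ] <- c(10, 0, 0)
  traj <- phos_trajectory(c("A", "B"), coords, box = c(10, 10, 10))
  expect_equal(distance_trace(traj, "A", "B")$distance, 0)
  expect_error(distance_trace(traj, "A", "C"), "unknown atom label")
})

test_that("tight synthetic coordination reproduces its ground truth", {
  traj <- gen_coordination_trajectory(
    n_frames = 1000,
    tight_pairs = data.frame(label = c("O6", "O8", "O9"), mean = 1.9, sd = 0.05),
    seed = 5
  )
  tr <- distance_trace(traj, "MG", "O6")
  st <- coordination_stability(tr, cutoff = 2.5)
  expect_equal(st$mean, 1.9, tolerance = 0.02 / 1.9)
  expect_equal(st$sd, 0.05, tolerance = 0.15)
  expect_equal(st$fraction_within, 1)
})

test_that("coordination stability summarizes tight vs loose correctly", {
  tr <- distance_trace(make_static_traj(), "MG", "O6")
  expect_equal(coordination_stability(tr, 2.5),
               list(mean = 1.9, sd = 0, fraction_within = 1))
  # alternating bound/unbound trace: half the frames within cutoff
  coords <- array(0, c(10, 2, 3))
  coords[, 2, 1] <- rep(c(1.9, 5.0), 5)
  traj <- phos_trajectory(c("NA1", "O6"), coords)
  st <- coordination_stability(distance_trace(traj, "NA1", "O6"), 2.5)
  expect_equal(st$fraction_within, 0.5)
  # Mg-like tight traces are narrower than Na-like loose ones
  traj2 <- gen_coordination_trajectory(
    n_frames = 500,
    tight_pairs = data.frame(label = "O6", mean = 1.9, sd = 0.05),
    loose_pairs = data.frame(label = "O8", mean = 2.4, sd = 0.8),
    seed = 6
  )
  sd_tight <- coordination_stability(distance_trace(traj2, "MG", "O6"))$sd
  sd_loose <- coordination_stability(distance_trace(traj2, "MG", "O8"))$sd
  expect_lt(sd_tight, sd_loose)
})

test_that("RDF equals the brute-force pair-count oracle bin by bin", {
  set.seed(17)
  for (rep in 1:3) {
    n_atoms <- 8; n_frames <- 10
    coords <- array(runif(n_frames * n_atoms * 3, 0, 12),
                    c(n_frames, n_atoms, 3))
    labels <- paste0("A", seq_len(n_atoms))
    traj <- phos_trajectory(labels, coords, box = c(12, 12, 12))
    ref <- labels[1:2]
    target <- labels[3:8]
    got <- radial_distribution(traj, ref, target, dr = 0.25, r_max = 5)
    want <- brute_rdf(traj, ref, target, dr = 0.25, r_max = 5)
    expect_equal(got$g, want, tolerance = 1e-12)
  }
})

test_that("RDF of an ideal gas is 1 within counting noise", {
  set.seed(23)
  n_frames <- 200; n_target <- 64; box <- 20
  coords <- array(NA_real_, c(n_frames, n_target + 1L, 3))
  coords[, 1, ] <- box / 2
  coords[, -1, ] <- runif(n_frames * n_target * 3, 0, box)
  traj <- phos_trajectory(c("REF", paste0("T", seq_len(n_target))), coords,
                          box = rep(box, 3))
  rdf <- radial_distribution(traj, "REF", paste0("T", seq_len(n_target)),
                             dr = 0.25, r_max = 9)
  mid <- rdf$r_center >= 2 & rdf$r_center <= 8
  rho <- n_target / box^3
  n_expected <- n_frames * rho * 4 * pi * rdf$r_center[mid]^2 * 0.25
  sigma_g <- 1 / sqrt(n_expected)
  expect_true(all(abs(rdf$g[mid] - 1) < 4 * sigma_g))
  expect_equal(mean(rdf$g[mid]), 1, tolerance = 0.02)
})

test_that("a fixed pair puts all RDF mass in the bin containing its distance", {
  coords <- array(0, c(5, 2, 3))
  coords[, 1, ] <- 5
  coords[, 2, ] <- matrix(c(7, 5, 5), 5, 3, byrow = TRUE) # 2.0 A apart
  traj <- phos_trajectory(c("REF", "T1"), coords, box = c(10, 10, 10))
  rdf <- radial_distribution(traj, "REF", "T1", dr = 0.25, r_max = 5)
  hot <- which(rdf$g > 0)
  expect_length(hot, 1)
  expect_true(rdf$r_center[hot] - 0.125 <= 2 && 2 < rdf$r_center[hot] + 0.125)
})

test_that("RDF integrates to the mean neighbor count and is translation invariant", {
  set.seed(31)
  n_frames <- 20; n_target <- 30; box <- 15
  coords <- array(NA_real_, c(n_frames, n_target + 1L, 3))
  coords[, 1, ] <- box / 2
  coords[, -1, ] <- runif(n_frames * n_target * 3, 0, box)
  labels <- c("REF", paste0("T", seq_len(n_target)))
  traj <- phos_trajectory(labels, coords, box = rep(box, 3))
  dr <- 0.1; r_max <- 7
  rdf <- radial_distribution(traj, "REF", labels[-1], dr = dr, r_max = r_max)
  rho <- attr(rdf, "rho_target")
  integral <- sum(rdf$g * 4 * pi * rdf$r_center^2 * rho * dr)
  # direct mean count of targets within r_max per frame
  counts <- vapply(seq_len(n_frames), function(k) {
    d <- coords[k, -1, ] - matrix(coords[k, 1, ], n_target, 3, byrow = TRUE)
    d <- d - box * round(d / box)
    sum(sqrt(rowSums(d^2)) <= r_max)
  }, numeric(1))
  expect_equal(integral, mean(counts), tolerance = 0.05)
  # global translation leaves g(r) unchanged under periodic wrapping
  shifted <- traj
  shifted$coords <- traj$coords + 3.21
  rdf2 <- radial_distribution(shifted, "REF", labels[-1], dr = dr, r_max = r_max)
  expect_equal(rdf2$g, rdf$g, tolerance = 1e-12)
  # frame order is irrelevant
  perm <- traj
  perm$coords <- traj$coords[sample(n_frames), , ]
  rdf3 <- radial_distribution(perm, "REF", labels[-1], dr = dr, r_max = r_max)
  expect_equal(rdf3$g, rdf$g, tolerance = 1e-12)
})

test_that("RDF validates its geometric preconditions", {
  traj <- make_static_traj(box = c(10, 10, 10))
  expect_error(radial_distribution(traj, "MG", "O6", r_max = 6),
               "half the smallest box")
  expect_error(radial_distribution(make_static_traj(), "MG", "O6", r_max = 2),
               "periodic box")
})

test_that("XYZ trajectories round-trip through write and read", {
  traj <- gen_coordination_trajectory(
    n_frames = 5,
    tight_pairs = data.frame(label = c("O6", "O8"), mean = 1.9, sd = 0.05),
    seed = 8, timestep = 2
  )
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, path)
  back <- read_xyz_trajectory(path, timestep = 2)
  expect_identical(back$labels, traj$labels)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
  expect_equal(back$box, traj$box)
  expect_error(read_xyz_trajectory(withr::local_tempfile(lines = "")),
               "empty|bad atom count")
})
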