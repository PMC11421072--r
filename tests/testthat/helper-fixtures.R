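# Build a complete synthetic input set in `dir` and return a config list.
make_fixture_set <- function(dir, seed = 1) {
  ser <- gen_titration(
    adp_conc = 10,
    deltas = list(alpha = c(f = 0, b = 0.89),
                  beta = c(f = -5.60, b1 = -5.16, b2 = -5.30))
  )
  write_result_table(
    data.frame(mg_equiv = ser$mg_equiv, delta_alpha = ser$delta_alpha,
               delta_beta = ser$delta_beta),
    file.path(dir, "titration.csv")
  )
  m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
  relax_files <- lapply(c(0, 1), function(eq) {
    tau2 <- 1.5e-10 * (1 + eq)
    r1 <- csa_r1(m, tau2)
    delays <- seq(0.05, 5 / r1, length.out = 12)
    curve <- gen_relaxation_curve("inversion_recovery", r1, delays,
                                  noise_sd = 0.005, seed = seed + eq)
    fname <- sprintf("t1_%geq.csv", eq)
    write_result_table(data.frame(delay_s = curve$delays,
                                  intensity = curve$intensities),
                       file.path(dir, fname))
    list(path = fname, kind = "inversion_recovery", label = as.character(eq))
  })
  diff_files <- lapply(c(0, 1), function(eq) {
    d <- 2.0e-10 / (1 + 0.3 * eq)
    decay <- gen_diffusion_decay(d, gradients = seq(0.01, 0.6, length.out = 12),
                                 noise_sd = 0.005, seed = seed + 10 + eq)
    fname <- sprintf("dosy_%geq.csv", eq)
    write_result_table(data.frame(gradient_T_per_m = decay$gradients,
                                  intensity = decay$intensities),
                       file.path(dir, fname))
    list(path = fname, label = as.character(eq),
         delta_small = decay$delta_small, delta_big = decay$delta_big)
  })
  traj <- gen_coordination_trajectory(
    n_frames = 200,
    tight_pairs = data.frame(label = c("O6", "O8", "O9"), mean = 1.9, sd = 0.05),
    seed = seed + 20
  )
  write_xyz_trajectory(traj, file.path(dir, "traj.xyz"))
  list(
    seed = seed,
    constants = list(temperature = 298, viscosity = 1.095e-3,
                     nu0_mhz = 202.4, sigma_sym_F = 163),
    titration = list(path = file.path(dir, "titration.csv"), adp_conc = 10,
                     anchor_eq = 0.5),
    relaxation = list(files = lapply(relax_files, function(f) {
      f$path <- file.path(dir, f$path); f
    })),
    diffusion = list(files = lapply(diff_files, function(f) {
      f$path <- file.path(dir, f$path); f
    })),
    trajectory = list(path = file.path(dir, "traj.xyz"), ref = "MG",
                      partners = c("O6", "O8", "O9"), cutoff = 2.5,
                      rdf = list(dr = 0.1, r_max = 8))
  )
}
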