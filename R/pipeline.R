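#' Validate and normalize an analysis configuration
#'
#' The configuration is a nested list (or a YAML file with the same
#' structure) with sections `constants`, `titration`, `relaxation`,
#' `diffusion`, `trajectory` plus top-level `output_dir` and `seed`.
#' Only the sections whose inputs are supplied are run by
#' [run_full_analysis()]. All referenced files must exist at validation
#' time, and all constants must be positive.
#'
#' @param config A list, or path to a YAML config file.
#' @return The normalized config (constants filled from
#'   [phos_constants()], defaults applied), classed `analysis_config`.
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.base_dir <- base_dir
  }
  stopifnot(is.list(config))
  base_dir <- config$.base_dir %||% "."
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  cc <- config$constants %||% list()
  required <- c(temperature = "temperature", viscosity = "viscosity")
  defaults <- phos_constants()
  constants <- list(
    temperature = cc$temperature %||% defaults$temperature_default,
    viscosity = cc$viscosity %||% defaults$water_viscosity_default,
    nu0_mhz = cc$nu0_mhz %||% defaults$nu0_31p_mhz,
    gamma = cc$gamma %||% defaults$gamma_31p,
    sigma_sym_F = cc$sigma_sym_F %||% 163,
    sigma_anti_F = cc$sigma_anti_F %||% 0,
    boltzmann_k = defaults$boltzmann_k,
    kex_factor = cc$kex_factor %||% 5,
    friction_factor = cc$friction_factor %||% 6
  )
  for (nm in setdiff(names(constants), "sigma_anti_F")) {
    v <- constants[[nm]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v) || v <= 0) {
      stop("configuration error: constant '", nm,
           "' must be a positive number", call. = FALSE)
    }
  }
  for (section in c("titration", "trajectory")) {
    if (!is.null(config[[section]]$path)) {
      config[[section]]$path <- resolve(config[[section]]$path)
      if (!file.exists(config[[section]]$path)) {
        stop("configuration error: ", section, " input not found: ",
             config[[section]]$path, call. = FALSE)
      }
    }
  }
  for (section in c("relaxation", "diffusion")) {
    files <- config[[section]]$files
    if (!is.null(files)) {
      config[[section]]$files <- lapply(files, function(f) {
        f$path <- resolve(f$path)
        if (is.null(f$path) || !file.exists(f$path)) {
          stop("configuration error: ", section, " input not found: ",
               f$path %||% "<missing path>", call. = FALSE)
        }
        f
      })
    }
  }
  config$constants <- constants
  config$seed <- config$seed %||% 1L
  structure(config, class = c("analysis_config", "list"))
}

prov <- function(df, source, operation, parameters) {
  df$source <- source
  df$operation <- operation
  df$parameters <- parameters
  df
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s (partial outputs preserved in the output directory)",
                 name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full binding-analysis pipeline from one configuration
#'
#' Orchestrates the analysis flow end to end: titration table to
#' two-state (alpha) and three-state (beta) populations and the exchange
#' rate bound; relaxation decays to R1/R2, the rank-2 correlation time
#' and the rotational hydrodynamic radius; gradient decays to diffusion
#' coefficients and translational radii; trajectory to distance traces,
#' coordination summaries and RDFs. Each stage writes a CSV table with
#' per-row provenance (input file, operation, parameter string); a run
#' manifest records the package version, seed and every constant used.
#' Only stages whose inputs appear in the config are run. Reruns with the
#' same config and seed are byte-identical.
#'
#' @param config An [analysis_config()], a list, or a YAML path.
#' @param output_dir Output directory (created if needed); overrides the
#'   config's `output_dir`.
#' @return Invisibly, a list with `tables` (the data.frames), `paths`
#'   (the files written) and `log` (character vector, also written to the
#'   manifest). Errors abort with the failing stage's name; tables
#'   already written are preserved.
#' @export
run_full_analysis <- function(config, output_dir = NULL) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cst <- config$constants
  tables <- list()
  paths <- character(0)
  log <- c(
    sprintf("phosbind %s", as.character(utils::packageVersion("phosbind"))),
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("constants: %s",
            paste(sprintf("%s=%.10g", names(cst), unlist(cst)), collapse = " "))
  )
  emit <- function(df, fname, key) {
    p <- file.path(out_dir, fname)
    write_result_table(df, p)
    tables[[key]] <<- df
    paths <<- c(paths, p)
    log <<- c(log, sprintf("wrote %s (%d rows)", fname, nrow(df)))
  }

  if (!is.null(config$titration$path)) {
    run_stage("titration", {
      tc <- config$titration
      ser <- read_titration_table(tc$path, config = tc)
      two <- two_state_populations(ser, "alpha",
                                   delta_f = tc$delta_f, delta_b = tc$delta_b)
      pops <- prov(
        data.frame(model = "two_state", channel = "alpha",
                   mg_equiv = two$mg_equiv, delta_obs = two$delta_obs,
                   p_f = two$p_f, p_b1 = two$p_b, p_b2 = 0),
        basename(tc$path), "two_state_populations",
        sprintf("delta_f=%.10g;delta_b=%.10g",
                attr(two, "delta_f"), attr(two, "delta_b")))
      if (!anyNA(ser$delta_beta)) {
        anchor <- tc$anchor_eq %||% 0.5
        three <- three_state_populations(ser, two$p_f, anchor_eq = anchor)
        pops <- rbind(pops, prov(
          data.frame(model = "three_state", channel = "beta",
                     mg_equiv = three$mg_equiv,
                     delta_obs = three$delta_obs_beta,
                     p_f = three$p_f, p_b1 = three$p_b1, p_b2 = three$p_b2),
          basename(tc$path), "three_state_populations",
          sprintf("anchor_eq=%.10g;delta_f=%.10g;delta_b1=%.10g;delta_b2=%.10g",
                  anchor, attr(three, "delta_f_beta"),
                  attr(three, "delta_b1_beta"), attr(three, "delta_b2_beta"))))
      }
      emit(pops, "populations.csv", "populations")
      disp <- tc$kex_dispersion_ppm %||% diff(range(ser$delta_alpha))
      bound <- kex_lower_bound(disp, attr(ser, "nucleus_freq"),
                               factor = cst$kex_factor)
      log <- c(log, sprintf("exchange bound: k_ex > %.6g s^-1 (%.4g ppm at %.4g MHz, factor %g)",
                            bound$k_ex_min, disp, attr(ser, "nucleus_freq"),
                            cst$kex_factor))
    })
  }

  if (!is.null(config$relaxation$files)) {
    run_stage("relaxation", {
      rows <- lapply(config$relaxation$files, function(f) {
        tab <- read_result_table(f$path)
        kind <- f$kind %||% "inversion_recovery"
        curve <- relaxation_curve(tab$delay_s, tab$intensity, kind)
        fit <- if (kind == "inversion_recovery") fit_inversion_recovery(curve)
               else fit_echo_decay(curve)
        prov(data.frame(label = f$label %||% basename(f$path), kind = kind,
                        rate = fit$rate, amplitude = fit$amplitude,
                        inv_efficiency = fit$inv_efficiency,
                        residual_rms = fit$residual_rms),
             basename(f$path),
             if (kind == "inversion_recovery") "fit_inversion_recovery"
             else "fit_echo_decay", "")
      })
      rates <- do.call(rbind, rows)
      emit(rates, "relaxation_rates.csv", "relaxation_rates")

      r1_rows <- rates[rates$kind == "inversion_recovery", , drop = FALSE]
      if (nrow(r1_rows) > 0L) {
        model <- csa_model(cst$sigma_sym_F, cst$sigma_anti_F, cst$nu0_mhz)
        radii <- do.call(rbind, lapply(seq_len(nrow(r1_rows)), function(i) {
          inv <- invert_r1_for_tau2(r1_rows$rate[i], model)
          rh <- tau2_to_hydrodynamic_radius(inv$tau2, cst$temperature,
                                            cst$viscosity)
          prov(data.frame(label = r1_rows$label[i], r1 = r1_rows$rate[i],
                          tau2_s = inv$tau2, r_h_m = rh,
                          branch = inv$branch),
               r1_rows$source[i], "invert_r1_for_tau2;tau2_to_hydrodynamic_radius",
               sprintf("sigma_sym_F=%.10g;nu0_mhz=%.10g;T=%.10g;eta=%.10g",
                       cst$sigma_sym_F, cst$nu0_mhz, cst$temperature,
                       cst$viscosity))
        }))
        emit(radii, "rotational_radii.csv", "rotational_radii")
      }
    })
  }

  if (!is.null(config$diffusion$files)) {
    run_stage("diffusion", {
      dc <- config$diffusion
      rows <- lapply(dc$files, function(f) {
        tab <- read_result_table(f$path)
        decay <- diffusion_decay(tab$gradient_T_per_m, tab$intensity,
                                 delta_small = f$delta_small %||% dc$delta_small,
                                 delta_big = f$delta_big %||% dc$delta_big,
                                 gamma = cst$gamma)
        fit <- fit_stejskal_tanner(decay)
        rh <- translational_hydrodynamic_radius(fit$d_coeff, cst$temperature,
                                                cst$viscosity,
                                                cst$friction_factor)
        prov(data.frame(label = f$label %||% basename(f$path),
                        d_coeff = fit$d_coeff, d_loglin = fit$d_loglin,
                        r_h_m = rh),
             basename(f$path), "fit_stejskal_tanner;translational_hydrodynamic_radius",
             sprintf("delta=%.10g;Delta=%.10g;gamma=%.10g;T=%.10g;eta=%.10g;friction=%g",
                     f$delta_small %||% dc$delta_small,
                     f$delta_big %||% dc$delta_big, cst$gamma,
                     cst$temperature, cst$viscosity, cst$friction_factor))
      })
      emit(do.call(rbind, rows), "diffusion.csv", "diffusion")
    })
  }

  if (!is.null(config$trajectory$path)) {
    run_stage("trajectory", {
      tj <- config$trajectory
      traj <- read_xyz_trajectory(tj$path, timestep = tj$timestep %||% 1)
      ref <- tj$ref %||% traj$labels[1]
      partners <- tj$partners %||% setdiff(traj$labels, ref)
      cutoff <- tj$cutoff %||% 2.5
      summ <- do.call(rbind, lapply(partners, function(p) {
        tr <- distance_trace(traj, ref, p)
        st <- coordination_stability(tr, cutoff = cutoff)
        prov(data.frame(ref = ref, partner = p, mean_A = st$mean,
                        sd_A = st$sd, fraction_within = st$fraction_within),
             basename(tj$path), "distance_trace;coordination_stability",
             sprintf("cutoff=%.10g", cutoff))
      }))
      emit(summ, "trajectory_summary.csv", "trajectory_summary")
      if (!is.null(traj$box)) {
        rdf_cfg <- tj$rdf %||% list()
        rdf <- radial_distribution(traj, ref = ref,
                                   target = rdf_cfg$target %||% partners,
                                   dr = rdf_cfg$dr %||% 0.05,
                                   r_max = rdf_cfg$r_max %||%
                                     min(10, min(traj$box) / 2))
        emit(prov(as.data.frame(rdf), basename(tj$path), "radial_distribution",
                  sprintf("dr=%.10g;r_max=%.10g", attr(rdf, "dr"),
                          max(rdf$r_center) + attr(rdf, "dr") / 2)),
             "rdf.csv", "rdf")
      }
    })
  }

  manifest <- file.path(out_dir, "run_manifest.txt")
  writeLines(log, manifest)
  paths <- c(paths, manifest)
  invisible(list(tables = tables, paths = paths, log = log))
}
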