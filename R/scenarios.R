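# Study designs as runnable presets: time-step study, nano-silica content
# sweep, polymer ratio sweep, temperature sweep and shear-rate sweep, at
# full scale (box 15, 50,000 steps, as published) and at a reduced scale
# (box 9, 20,000 steps) sized for routine testing.

#' Scenario definition
#'
#' @param name identifier.
#' @param comp a \code{dpd_composition}.
#' @param temperature_K absolute temperature; default 298.
#' @param shear_rate reduced shear rate; default 0.
#' @param dt reduced time step; default 0.05.
#' @param n_steps total integration steps.
#' @param equilibration_steps steps discarded before computing equilibrium
#'   observables.
#' @param seeds integer vector of RNG seeds (one run per seed).
#' @param scale "full" or "reduced".
#' @param study study-group tag (free text).
#' @return object of class \code{dpd_scenario}.
#' @export
scenario <- function(name, comp, temperature_K = 298, shear_rate = 0,
                     dt = 0.05, n_steps = 50000L,
                     equilibration_steps = 30000L, seeds = 1L,
                     scale = c("full", "reduced"), study = "custom") {
  scale <- match.arg(scale)
  stopifnot(inherits(comp, "dpd_composition"),
            equilibration_steps <= n_steps)
  structure(list(name = name, composition = comp,
                 temperature_K = temperature_K, shear_rate = shear_rate,
                 dt = dt, n_steps = as.integer(n_steps),
                 equilibration_steps = as.integer(equilibration_steps),
                 seeds = as.integer(seeds), scale = scale, study = study),
            class = "dpd_scenario")
}

#' Published study designs as scenario presets
#'
#' Five study groups: the time-step study (dt 0.01/0.03/0.05/0.07 on the
#' 10\% PVA / 10\% PAM / 2\% silica system), the nano-silica content sweep
#' (0 to 2.5\% at 10/10 polymers), the polymer ratio sweep (20/0 to 0/20
#' at 1.5\% silica), the temperature sweep (298/328/358 K at 10/10/2) and
#' the shear sweep (0 to 0.16 at 10/10/1.5).  Full scale uses the
#' published box of edge 15 (10,125 beads), dt 0.05, 50,000 steps with
#' 30,000 equilibration, one realization each.  Reduced scale keeps the
#' same physics in a box of edge 9 (2,187 beads, still holding 50-bead
#' chains comfortably), 20,000 steps, five fixed seeds for stochastic
#' property checks.
#'
#' @param scale "full" (default) or "reduced".
#' @param study optionally restrict to one of "timestep", "content",
#'   "ratio", "temperature", "shear".
#' @return named list of \code{dpd_scenario}s.
#' @export
study_presets <- function(scale = c("full", "reduced"), study = NULL) {
  scale <- match.arg(scale)
  box <- if (scale == "full") 15 else 9
  n_steps <- if (scale == "full") 50000L else 20000L
  equil <- if (scale == "full") 30000L else 10000L
  seeds <- if (scale == "full") 1L else c(101L, 202L, 303L, 404L, 505L)
  mk <- function(name, study, PVA = 0.10, PAM = 0.10, SiO2 = 0,
                 temperature_K = 298, shear_rate = 0, dt = 0.05) {
    scenario(name, composition(box, 3, PVA = PVA, PAM = PAM, SiO2 = SiO2),
             temperature_K = temperature_K, shear_rate = shear_rate,
             dt = dt, n_steps = n_steps, equilibration_steps = equil,
             seeds = seeds, scale = scale, study = study)
  }
  out <- list()
  for (dt in c(0.01, 0.03, 0.05, 0.07))
    out[[sprintf("timestep_dt%.2f", dt)]] <-
      mk(sprintf("timestep_dt%.2f", dt), "timestep", SiO2 = 0.02, dt = dt)
  for (si in c(0, 0.005, 0.01, 0.015, 0.02, 0.025))
    out[[sprintf("content_si%.1f", 100 * si)]] <-
      mk(sprintf("content_si%.1f", 100 * si), "content", SiO2 = si)
  ratios <- list(c(0.20, 0), c(0.15, 0.05), c(0.10, 0.10), c(0.05, 0.15),
                 c(0, 0.20))
  for (r in ratios)
    out[[sprintf("ratio_pva%.0f_pam%.0f", 100 * r[1], 100 * r[2])]] <-
      mk(sprintf("ratio_pva%.0f_pam%.0f", 100 * r[1], 100 * r[2]),
         "ratio", PVA = r[1], PAM = r[2], SiO2 = 0.015)
  for (tk in c(298, 328, 358))
    out[[sprintf("temperature_%dK", tk)]] <-
      mk(sprintf("temperature_%dK", tk), "temperature", SiO2 = 0.02,
         temperature_K = tk)
  for (g in c(0, 0.04, 0.08, 0.12, 0.16))
    out[[sprintf("shear_g%.2f", g)]] <-
      mk(sprintf("shear_g%.2f", g), "shear", SiO2 = 0.015, shear_rate = g)
  if (!is.null(study)) out <- out[vapply(out, function(s) s$study,
                                         character(1)) == study]
  out
}

#' Execute a scenario and write its artifacts
#'
#' For each seed: builds the interaction table and initial configuration,
#' integrates, and writes the trajectory (extended XYZ), the
#' thermodynamic series, post-equilibration relative concentration
#' profiles for every non-water species, MSD curves and diffusion
#' coefficients, and silica cluster statistics, plus a manifest indexing
#' every artifact for exact reruns.
#'
#' @param scn a \code{dpd_scenario}.
#' @param output_dir directory for artifacts (created if needed).
#' @param chi_table Flory-Huggins table; default the packaged one.
#' @param overwrite allow replacing an existing manifest; default FALSE.
#' @param thermo_interval,trajectory_interval sampling intervals; defaults
#'   100 and \code{n_steps / 100}.
#' @return invisibly, the manifest data.frame (scenario, seed, role,
#'   path).
#' @export
run_scenario <- function(scn, output_dir, chi_table = default_chi_table(),
                         overwrite = FALSE, thermo_interval = 100L,
                         trajectory_interval = NULL) {
  stopifnot(inherits(scn, "dpd_scenario"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(output_dir, paste0(scn$name, "_manifest.tsv"))
  if (file.exists(man_path) && !overwrite)
    stop("manifest already exists (use overwrite = TRUE): ", man_path)
  if (is.null(trajectory_interval))
    trajectory_interval <- max(1L, scn$n_steps %/% 100L)
  params <- build_interaction_table(chi_table, scn$temperature_K)
  counts <- allocate_counts(scn$composition)
  rows <- list()
  add <- function(seed, role, path) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scn$name, seed = seed, role = role, path = path)
  }
  for (seed in scn$seeds) {
    tag <- file.path(output_dir, sprintf("%s_seed%d", scn$name, seed))
    cfg <- build_initial_configuration(counts, kBT = params$kBT,
                                       seed = seed)
    st <- dpd_settings(dt = scn$dt, shear_rate = scn$shear_rate,
                       seed = seed, thermo_interval = thermo_interval,
                       trajectory_interval = trajectory_interval)
    res <- dpd_run(cfg, params, st, scn$n_steps)
    traj <- res$trajectory
    p <- paste0(tag, "_trajectory.xyz")
    write_trajectory(p, traj)
    add(seed, "trajectory", p)
    p <- paste0(tag, "_thermo.tsv")
    write.table(res$thermo, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add(seed, "thermo", p)
    obs <- derive_observables(traj, scn$equilibration_steps)
    for (role in names(obs)) {
      p <- paste0(tag, "_", role, ".tsv")
      write.table(obs[[role]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      add(seed, role, p)
    }
  }
  man <- do.call(rbind, rows)
  stopifnot(all(file.exists(man$path)))
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  snap <- file.path(output_dir, paste0(scn$name, "_params.yml"))
  yaml::write_yaml(list(
    name = scn$name, study = scn$study, scale = scn$scale,
    box_edge = scn$composition$box_edge, rho = scn$composition$rho,
    fractions = as.list(scn$composition$fractions),
    temperature_K = scn$temperature_K, shear_rate = scn$shear_rate,
    dt = scn$dt, n_steps = scn$n_steps,
    equilibration_steps = scn$equilibration_steps,
    seeds = as.integer(scn$seeds),
    thermo_interval = as.integer(thermo_interval),
    trajectory_interval = as.integer(trajectory_interval),
    package_version = as.character(utils::packageVersion("dpdgel"))), snap)
  invisible(man)
}

#' Derive the standard observable tables from a trajectory
#'
#' Post-equilibration relative concentration profiles (30 slabs along Z)
#' for each non-water species, MSD and diffusion coefficient per species,
#' and silica cluster statistics on the final frame.  Used by
#' \code{\link{run_scenario}} and by the command-line \code{analyze}
#' subcommand, so that re-analysis of a stored trajectory reproduces the
#' original tables exactly.
#'
#' @param traj a \code{dpd_traj}.
#' @param equilibration_steps frames before this step are excluded from
#'   profiles.
#' @return named list of data.frames: \code{profile}, \code{msd},
#'   \code{diffusion}, \code{clusters}.
#' @export
derive_observables <- function(traj, equilibration_steps = 0) {
  present <- unique(traj$species_names[traj$species_id])
  sp_main <- setdiff(present, "H2O")
  if (!length(sp_main)) sp_main <- "H2O"
  prof <- list()
  for (s in sp_main) {
    pr <- average_profile(traj, s, axis = "Z", n_slabs = 30L,
                          from_step = equilibration_steps)
    prof[[s]] <- data.frame(species = s,
                            slab = seq_len(pr$n_slabs),
                            z_mid = (pr$slab_edges[-1] +
                                     pr$slab_edges[-length(pr$slab_edges)]) / 2,
                            rel_concentration = pr$rel_concentration)
  }
  msd_rows <- list()
  d_rows <- list()
  for (s in present) {
    m <- msd(traj, s)
    dc <- diffusion_coefficient(m)
    msd_rows[[s]] <- data.frame(species = s, lag_time = m$lag_times,
                                msd = m$msd)
    d_rows[[s]] <- data.frame(species = s, D = dc$D,
                              fit_from = dc$fit_window[1],
                              fit_to = dc$fit_window[2],
                              r_squared = dc$r_squared)
  }
  cl_tab <- data.frame(species = character(0), size = integer(0),
                       count = integer(0))
  if ("SiO2" %in% present) {
    cl <- cluster_stats(frame_config(traj, length(traj$positions)), "SiO2")
    h <- table(cl$sizes)
    cl_tab <- data.frame(species = "SiO2",
                         size = as.integer(names(h)),
                         count = as.integer(h))
  }
  list(profile = do.call(rbind, prof), msd = do.call(rbind, msd_rows),
       diffusion = do.call(rbind, d_rows), clusters = cl_tab)
}
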