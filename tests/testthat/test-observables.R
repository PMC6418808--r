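# Concentration profiles, maps, MSD/diffusion, clustering, equilibration.

test_that("relative concentration profile follows its defining ratio", {
  pos <- cbind(runif(10, 0, 5), runif(10, 0, 5), runif(10, 0, 0.9))
  cfg <- dpd_config(pos, rep("SiO2", 10), 5)
  pr <- relative_concentration_profile(cfg, "SiO2", "Z", 5)
  expect_equal(pr$rel_concentration, c(5, 0, 0, 0, 0))
  # homogeneous lattice: every slab near 1
  g <- seq(0.25, 4.75, by = 0.5)
  lat <- as.matrix(expand.grid(g, g, g))
  cfg <- dpd_config(lat, rep("H2O", nrow(lat)), 5)
  for (ax in c("X", "Y", "Z")) {
    pr <- relative_concentration_profile(cfg, "H2O", ax, 10)
    expect_true(all(abs(pr$rel_concentration - 1) < 1e-9))
  }
  expect_error(relative_concentration_profile(cfg, "SiO2"), "absent")
})

test_that("profile normalisation identity holds for arbitrary configurations", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:400, 1)
    cfg <- dpd_config(matrix(runif(3 * n, 0, 7), ncol = 3),
                      sample(c("H2O", "SiO2"), n, replace = TRUE,
                             prob = c(0.7, 0.3)),
                      7, species_names = c("H2O", "SiO2"))
    for (sp in unique(species_of(cfg))) {
      pr <- relative_concentration_profile(cfg, sp, "Y",
                                           sample(2:40, 1))
      expect_equal(mean(pr$rel_concentration), 1)
    }
  }
})

test_that("planar concentration maps localise a confined species", {
  set.seed(3)
  n <- 4000
  cfg <- dpd_config(matrix(runif(3 * n, 0, 6), ncol = 3), rep("PVA", n), 6)
  m <- concentration_map_2d(cfg, "PVA", "XY", n_bins = 6)
  expect_equal(mean(m), 1)
  expect_true(all(abs(m - 1) < 0.5))
  # confined to the x < 3 half: far half empty
  pos <- cbind(runif(500, 0, 3), runif(500, 0, 6), runif(500, 0, 6))
  cfg <- dpd_config(pos, rep("PAM", 500), 6)
  m <- concentration_map_2d(cfg, "PAM", "XY", n_bins = 6)
  expect_true(all(m[4:6, ] == 0))
  expect_equal(mean(m), 1)
  cfgz <- dpd_config(cbind(runif(50, 0, 6), runif(50, 0, 6),
                           runif(50, 0, 2)), rep("PAM", 50), 6)
  expect_error(concentration_map_2d(cfgz, "PAM", "XY",
                                    slab_thickness = 1, slab_center = 4.5),
               "slab")
  for (pl in c("YZ", "XZ"))
    expect_equal(mean(concentration_map_2d(cfg, "PAM", pl, 5)), 1)
})

make_traj <- function(frames, times, species = NULL, box = 10,
                      shear_rate = 0) {
  n <- nrow(frames[[1]])
  if (is.null(species)) species <- rep("SiO2", n)
  structure(list(steps = seq_along(times) - 1, times = times,
                 shear_offsets = rep(0, length(times)),
                 positions = lapply(frames, function(f) f %% box),
                 unwrapped = frames,
                 velocities = NULL,
                 species_id = match(species, unique(species)),
                 species_names = unique(species),
                 molecule_id = seq_len(n), box_edge = box,
                 shear_rate = shear_rate), class = "dpd_traj")
}

test_that("MSD recovers closed forms", {
  # static: identically zero
  f <- matrix(runif(30, 0, 5), ncol = 3)
  tr <- make_traj(list(f, f, f, f), times = 0:3)
  expect_equal(msd(tr, "SiO2")$msd, rep(0, 4))
  # ballistic: |v|^2 t^2, identical for single and multi origin
  v <- c(0.3, -0.2, 0.1)
  frames <- lapply(0:5, function(t) matrix(c(1, 1, 1) + v * t, 1, 3))
  tr <- make_traj(frames, times = 0:5)
  for (mode in c("multi", "single")) {
    m <- msd(tr, "SiO2", origin_mode = mode)
    expect_equal(m$msd, sum(v^2) * (0:5)^2, tolerance = 1e-12)
  }
  tr$unwrapped <- NULL
  expect_error(msd(tr, "SiO2"), "unwrapped")
})

test_that("diffusion coefficient is the MSD slope over six", {
  tr <- make_traj(lapply(0:10, function(t) matrix(0, 1, 3)), times = 0:10)
  m <- msd(tr, "SiO2")
  m$msd <- 6 * m$lag_times
  expect_equal(diffusion_coefficient(m)$D, 1)
  m$msd <- rep(0, 11)
  expect_equal(diffusion_coefficient(m)$D, 0)
  expect_error(diffusion_coefficient(m, fit_window = c(9.5, 9.9)),
               "fewer than 2")
})

test_that("free diffusion in the DPD solvent has a linear MSD", {
  cfg <- pure_fluid_config(5, seed = 12)
  st <- dpd_settings(dt = 0.05, seed = 13, thermo_interval = 0,
                     trajectory_interval = 40)
  res <- dpd_run(cfg, water_params(), st, 4000)
  dc <- diffusion_coefficient(msd(res$trajectory, "H2O"))
  expect_gt(dc$r_squared, 0.99)
  # literature range for the standard solvent bead
  expect_gt(dc$D, 0.1)
  expect_lt(dc$D, 0.5)
})

test_that("a reduced hydrogel run is detected as equilibrated", {
  res <- run_reduced_system(0.10, 0.10, 0.02, seed = 101L,
                            n_steps = 6000L, box = 6)
  # windowed D of the abundant species converges; silica's windowed D at
  # this scale is cluster-motion noise and is not a usable monitor
  for (sp in c("H2O", "PAM")) {
    ds <- diffusion_series(res$trajectory, sp, window_frames = 6L)
    expect_gte(nrow(ds), 4)
    chk <- equilibration_check(ds$D, tolerance = 0.25)
    expect_true(chk$converged, label = sp)
    expect_lte(ds$start_step[chk$first_window], 6000)
  }
})

test_that("cluster statistics equal the BFS oracle", {
  # all singletons
  g <- seq(0.75, 5.25, by = 1.5)
  lat <- as.matrix(expand.grid(g, g, g))
  cfg <- dpd_config(lat, rep("SiO2", nrow(lat)), 6)
  cl <- cluster_stats(cfg, "SiO2", 1)
  expect_equal(cl$n_clusters, nrow(lat))
  expect_true(all(cl$sizes == 1))
  # pair just inside the cutoff
  cfg <- dpd_config(rbind(c(1, 1, 1), c(1.9, 1, 1)), c("SiO2", "SiO2"), 6)
  cl <- cluster_stats(cfg, "SiO2", 1)
  expect_equal(cl$sizes, 2L)
  expect_equal(cl$n_clusters, 1L)
  # random instances vs brute-force BFS, including a sheared offset and a
  # box small enough to bypass the cell list
  set.seed(31)
  for (case in 1:6) {
    n <- sample(20:200, 1)
    L <- sample(c(2.5, 6), 1)
    off <- sample(c(0, 1.7), 1)
    cfg <- dpd_config(matrix(runif(3 * n, 0, L), ncol = 3),
                      rep("SiO2", n), L, shear_offset = off)
    cl <- cluster_stats(cfg, "SiO2", 1)
    ref <- bfs_clusters(cfg$positions, L, 1, off)
    expect_equal(sort(cl$sizes), sort(as.integer(table(ref))))
    expect_equal(sum(cl$sizes), n)
    # membership partitions agree up to labelling
    expect_equal(length(unique(paste(cl$membership, ref))),
                 cl$n_clusters)
  }
  # absent species: empty stats
  cl <- cluster_stats(cfg, "PVA", 1)
  expect_equal(cl$n_clusters, 0L)
  expect_equal(cl$largest, 0L)
})

test_that("equilibration detection reacts to convergence of windowed D", {
  expect_true(equilibration_check(rep(0.3, 6))$converged)
  expect_equal(equilibration_check(rep(0.3, 6))$first_window, 2L)
  growing <- 0.1 * 1.2^(0:5)
  expect_false(equilibration_check(growing)$converged)
  settle <- c(0.5, 0.3, 0.21, 0.2, 0.2, 0.2)
  chk <- equilibration_check(settle)
  expect_true(chk$converged)
  expect_equal(chk$first_window, 4L)
  two_sp <- cbind(rep(0.3, 5), c(0.5, 0.3, 0.3, 0.3, 0.3))
  expect_equal(equilibration_check(two_sp)$first_window, 3L)
  expect_error(equilibration_check(c(1, 2)), "3 windows")
})
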