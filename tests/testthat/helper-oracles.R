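# Shared fixtures and independent oracles.

# Published pairwise repulsion parameters (a_ij) at the three study
# temperatures, exactly as printed.  Two cells are internally inconsistent
# with the printed chi column and the mapping a_ij = a_ii + 3.27*chi:
# PAM-H2O at 298 K (printed 26.88; formula on printed chi 0.57 gives 26.86,
# i.e. the printed chi is rounded from ~0.575) and SiO2-SiO2 at 328 K
# (printed 26.82; formula gives 25.82 - off by exactly 1.00, a typo).
printed_a_table <- function() {
  tab <- rbind(
    c("PVA",  "PVA",  25.00, 27.52, 30.03),
    c("PVA",  "H2O",  25.75, 28.17, 30.61),
    c("PVA",  "PAM",  25.49, 27.98, 30.42),
    c("PVA",  "SiO2", 38.65, 39.35, 40.23),
    c("PAM",  "PAM",  25.00, 27.52, 30.03),
    c("PAM",  "H2O",  26.88, 29.12, 31.41),
    c("PAM",  "SiO2", 33.11, 34.88, 36.60),
    c("H2O",  "SiO2", 45.75, 45.15, 44.36),
    c("H2O",  "H2O",  25.00, 27.52, 30.03),
    c("SiO2", "SiO2", 23.55, 26.82, 28.04))
  data.frame(species_i = tab[, 1], species_j = tab[, 2],
             a298 = as.numeric(tab[, 3]), a328 = as.numeric(tab[, 4]),
             a358 = as.numeric(tab[, 5]))
}

# pairs of (pair, temperature) whose printed a_ij is inconsistent with the
# printed chi under the linear mapping, with the formula-derived value
print_inconsistencies <- function() {
  data.frame(species_i = c("PAM", "SiO2"), species_j = c("H2O", "SiO2"),
             temperature = c(298, 328), formula_value = c(26.86, 25.82))
}

# O(N^2) minimum-image pair scan (Lees-Edwards aware): the independent
# oracle for the cell-list neighbour search
brute_force_pairs <- function(pos, L, rcut, off = 0) {
  n <- nrow(pos)
  out <- matrix(integer(0), 0, 2)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    cy <- round(d[2] / L)
    d[2] <- d[2] - cy * L
    d[1] <- d[1] - cy * off
    d[1] <- d[1] - L * round(d[1] / L)
    d[3] <- d[3] - L * round(d[3] / L)
    if (sum(d^2) < rcut^2) out <- rbind(out, c(i, j))
  }
  out
}

pair_key <- function(i, j) sort(paste(pmin(i, j), pmax(i, j), sep = "-"))

# breadth-first-search connected components over the full minimum-image
# distance matrix: the independent oracle for cluster_stats
bfs_clusters <- function(pos, L, cutoff, off = 0) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    pr <- brute_force_pairs(pos, L, cutoff, off)
    if (nrow(pr))
      for (k in seq_len(nrow(pr))) {
        adj[pr[k, 1], pr[k, 2]] <- TRUE
        adj[pr[k, 2], pr[k, 1]] <- TRUE
      }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# small pure-solvent configuration at density 3
pure_fluid_config <- function(L, seed = 1, kBT = 1) {
  n <- round(3 * L^3)
  set.seed(seed)
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  v <- sweep(v, 2, colMeans(v))
  dpd_config(matrix(runif(3 * n, 0, L), ncol = 3), rep("H2O", n), L,
             velocities = v)
}

water_params <- function(temperature = 298, eta = 4.5) {
  build_interaction_table(matrix(0, 1, 1, dimnames = list("H2O", "H2O")),
                          temperature, eta = eta)
}

# reduced-scale hydrogel run used by the factor-effect and time-step suites
run_reduced_system <- function(PVA, PAM, SiO2, temperature_K = 298,
                               shear_rate = 0, seed = 101L, dt = 0.05,
                               n_steps = 20000L, box = 9) {
  params <- build_interaction_table(default_chi_table(), temperature_K)
  cts <- allocate_counts(composition(box, 3, PVA = PVA, PAM = PAM,
                                     SiO2 = SiO2))
  cfg <- build_initial_configuration(cts, kBT = params$kBT, seed = seed)
  st <- dpd_settings(dt = dt, shear_rate = shear_rate, seed = seed,
                     thermo_interval = 500L, trajectory_interval = 200L)
  dpd_run(cfg, params, st, n_steps)
}

subset_traj_frames <- function(traj, keep) {
  for (f in c("positions", "unwrapped", "velocities"))
    traj[[f]] <- traj[[f]][keep]
  for (f in c("times", "steps", "shear_offsets"))
    traj[[f]] <- traj[[f]][keep]
  traj
}

mean_largest_cluster <- function(res, from_step = 15000) {
  tr <- res$trajectory
  ks <- which(tr$steps >= from_step)
  mean(vapply(ks, function(k)
    cluster_stats(frame_config(tr, k), "SiO2")$largest, numeric(1)))
}

silica_diffusion <- function(res, from_step = 10000) {
  tr <- subset_traj_frames(res$trajectory,
                           which(res$trajectory$steps >= from_step))
  diffusion_coefficient(msd(tr, "SiO2"))$D
}

occupied_map_fraction <- function(res, species = "PAM",
                                  from_step = 15000, threshold = 0.5) {
  tr <- res$trajectory
  ks <- which(tr$steps >= from_step)
  mean(vapply(ks, function(k) {
    m <- concentration_map_2d(frame_config(tr, k), species, plane = "XY",
                              n_bins = 20L)
    mean(m > threshold)
  }, numeric(1)))
}
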