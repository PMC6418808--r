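# Engine surface: integrator settings, the run loop (compiled), reference
# implementations of the individual pair forces, neighbour search and
# thermodynamic diagnostics.

#' Integrator settings
#'
#' @param dt reduced time step.
#' @param lambda velocity-prediction factor of the modified velocity-Verlet
#'   scheme; default 0.65, the standard choice for soft DPD fluids at
#'   dt = 0.01-0.07.
#' @param shear_rate reduced shear rate applied along X with gradient along
#'   Y (Lees-Edwards boundaries); 0 for plain periodic boundaries.
#' @param seed integer seed driving the counter-based pair noise.
#' @param thermo_interval steps between thermodynamic samples.
#' @param trajectory_interval steps between stored frames.
#' @return object of class \code{dpd_settings}.
#' @export
dpd_settings <- function(dt = 0.05, lambda = 0.65, shear_rate = 0, seed = 1,
                         thermo_interval = 100L,
                         trajectory_interval = 200L) {
  stopifnot(dt > 0, lambda >= 0, lambda <= 1, shear_rate >= 0)
  structure(list(dt = dt, lambda = lambda, shear_rate = shear_rate,
                 seed = as.numeric(seed),
                 thermo_interval = as.integer(thermo_interval),
                 trajectory_interval = as.integer(trajectory_interval)),
            class = "dpd_settings")
}

species_a_matrix <- function(config, params) {
  sp <- config$species_names
  miss <- setdiff(sp[sort(unique(config$species_id))], params$species)
  if (length(miss))
    stop("interaction table has no parameters for species: ",
         paste(miss, collapse = ", "))
  idx <- match(sp, params$species)
  a <- matrix(0, length(sp), length(sp))
  ok <- !is.na(idx)
  a[ok, ok] <- params$a[idx[ok], idx[ok]]
  a
}

#' Integrate the equations of motion
#'
#' Runs \code{n_steps} of the lambda velocity-Verlet scheme: position
#' update, velocity prediction with \code{lambda}, one force evaluation
#' (conservative + dissipative + random + spring), velocity correction.
#' All pair forces are antisymmetric, so total momentum is conserved to
#' round-off; under shear, beads crossing the Y boundary are remapped by
#' the Lees-Edwards image offset and given the matching velocity change.
#'
#' @param config a \code{dpd_config}.
#' @param params a \code{dpd_params} interaction table covering every
#'   species present.
#' @param settings a \code{dpd_settings}.
#' @param n_steps number of steps to integrate.
#' @param record_frames store frames every \code{trajectory_interval}
#'   steps (including the initial state); default TRUE.
#' @param step0 global step counter at entry; offsets the keys of the
#'   counter-based noise so run segments draw non-overlapping noise
#'   streams.
#' @param fdt_scaling internal switch for the \eqn{\Delta t^{-1/2}} scaling
#'   of the random force; disabling it breaks temperature control and
#'   exists only to demonstrate that the fluctuation-dissipation relation
#'   is load-bearing.
#' @return list with elements \code{config} (advanced \code{dpd_config}),
#'   \code{thermo} (data.frame: step, time, temperature, pressure,
#'   momentum components) and \code{trajectory} (a \code{dpd_traj} or
#'   NULL).
#' @export
dpd_run <- function(config, params, settings, n_steps,
                    record_frames = TRUE, step0 = 0, fdt_scaling = TRUE) {
  stopifnot(inherits(config, "dpd_config"), inherits(params, "dpd_params"),
            inherits(settings, "dpd_settings"))
  a <- species_a_matrix(config, params)
  res <- cpp_run(config$positions, config$velocities, config$unwrapped,
                 config$species_id - 1L, a, config$bonds - 1L,
                 params$eta, params$sigma, params$spring_C,
                 config$box_edge, settings$dt, as.integer(n_steps),
                 settings$lambda, settings$shear_rate, config$shear_offset,
                 config$time, settings$seed, step0,
                 settings$thermo_interval, settings$trajectory_interval,
                 record_frames, fdt_scaling)
  out <- config
  out$positions <- res$positions
  out$velocities <- res$velocities
  out$unwrapped <- res$unwrapped
  out$shear_offset <- res$shear_offset
  out$time <- res$time
  traj <- NULL
  if (record_frames) {
    fr <- res$frames
    traj <- structure(list(steps = fr$step, times = fr$time,
                           shear_offsets = fr$shear_offset,
                           positions = fr$positions,
                           unwrapped = fr$unwrapped,
                           velocities = fr$velocities,
                           species_id = config$species_id,
                           species_names = config$species_names,
                           molecule_id = config$molecule_id,
                           box_edge = config$box_edge,
                           shear_rate = settings$shear_rate),
                      class = "dpd_traj")
  }
  list(config = out, thermo = as.data.frame(res$thermo), trajectory = traj)
}

#' Advance a configuration by a few steps
#'
#' Convenience wrapper around \code{\link{dpd_run}} returning only the
#' advanced configuration.
#'
#' @inheritParams dpd_run
#' @return the advanced \code{dpd_config}.
#' @export
dpd_step <- function(config, params, settings, n_steps = 1L, step0 = 0) {
  dpd_run(config, params, settings, n_steps, record_frames = FALSE,
          step0 = step0)$config
}

#' Within-cutoff neighbour pairs
#'
#' Cell-list search returning every unordered bead pair with minimum-image
#' distance below the cutoff, with the minimum-image displacement
#' \eqn{r_i - r_j}.  Under a Lees-Edwards offset, images across the Y
#' boundary are displaced accordingly.
#'
#' @param config a \code{dpd_config}.
#' @param r_cut cutoff radius (reduced); the box edge must be at least
#'   three times this.
#' @return data.frame with columns i, j, dx, dy, dz, r.
#' @export
neighbor_pairs <- function(config, r_cut = 1) {
  stopifnot(inherits(config, "dpd_config"), r_cut > 0)
  as.data.frame(cpp_pairs(config$positions, config$box_edge, r_cut,
                          config$shear_offset))
}

#' Conservative pair force (reference implementation)
#'
#' Soft linear repulsion \eqn{a_{ij} (1 - r) \hat e_{ij}} for \eqn{r < 1},
#' zero beyond the cutoff, acting on bead i; \code{r_vec} is the
#' minimum-image displacement \eqn{r_i - r_j}.
#'
#' @param a_ij repulsion parameter.
#' @param r_vec length-3 displacement vector.
#' @return force 3-vector on bead i.
#' @export
conservative_force <- function(a_ij, r_vec) {
  r <- sqrt(sum(r_vec^2))
  if (r >= 1) return(c(0, 0, 0))
  if (r == 0) {
    warning("coincident beads: conservative force set to zero")
    return(c(0, 0, 0))
  }
  a_ij * (1 - r) * r_vec / r
}

#' Dissipative plus random pair force (reference implementation)
#'
#' \eqn{F^D = -\eta (1-r)^2 (\hat e \cdot v_{ij}) \hat e} and
#' \eqn{F^R = \sigma (1-r) \xi \Delta t^{-1/2} \hat e}, the two halves of
#' the pairwise thermostat; both vanish continuously at the cutoff.  The
#' caller supplies \eqn{\xi} (zero mean, unit variance, symmetric in the
#' pair) so that determinism and Newton's third law rest with the caller's
#' noise scheme.
#'
#' @param eta dissipation strength.
#' @param sigma noise strength.
#' @param r_vec minimum-image displacement \eqn{r_i - r_j} (within cutoff).
#' @param v_vec relative velocity \eqn{v_i - v_j}.
#' @param dt time step (positive).
#' @param xi noise draw for the pair.
#' @return combined force 3-vector on bead i.
#' @export
dissipative_random_force <- function(eta, sigma, r_vec, v_vec, dt, xi) {
  if (dt <= 0) stop("dt must be positive")
  r <- sqrt(sum(r_vec^2))
  if (r >= 1 || r == 0) return(c(0, 0, 0))
  e <- r_vec / r
  w <- 1 - r
  fd <- -eta * w^2 * sum(e * v_vec) * e
  fr <- sigma * w * xi / sqrt(dt) * e
  fd + fr
}

#' Harmonic bond forces (reference implementation)
#'
#' Each bond contributes an attractive restoring force of magnitude
#' \eqn{C r} pulling the bonded beads together (minimum-image separation),
#' equal and opposite on the pair.
#'
#' @param spring_C spring constant.
#' @param bonds two-column matrix of bead indices (1-based).
#' @param positions N x 3 coordinate matrix.
#' @param box_edge periodic box edge.
#' @param shear_offset Lees-Edwards offset for the minimum image.
#' @return N x 3 matrix of per-bead bonded forces.
#' @export
spring_force <- function(spring_C, bonds, positions, box_edge,
                         shear_offset = 0) {
  f <- matrix(0, nrow(positions), 3)
  if (!nrow(bonds)) return(f)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    d <- positions[i, ] - positions[j, ]
    cy <- round(d[2] / box_edge)
    d[2] <- d[2] - cy * box_edge
    d[1] <- d[1] - cy * shear_offset
    d[1] <- d[1] - box_edge * round(d[1] / box_edge)
    d[3] <- d[3] - box_edge * round(d[3] / box_edge)
    f[i, ] <- f[i, ] - spring_C * d
    f[j, ] <- f[j, ] + spring_C * d
  }
  f
}

#' Advance the Lees-Edwards boundary state
#'
#' Moves the sliding-brick image offset forward by
#' \eqn{\dot\gamma L \Delta t} (wrapped modulo the box edge) and remaps
#' beads outside the Y range: a crossing bead is shifted by the offset in X
#' and its X velocity changes by \eqn{\mp \dot\gamma L}.  With
#' \code{shear_rate = 0} this reduces to plain periodic wrapping.
#'
#' @param config a \code{dpd_config}.
#' @param shear_rate reduced shear rate.
#' @param dt time increment over which the offset advances.
#' @return the remapped \code{dpd_config}.
#' @export
apply_shear <- function(config, shear_rate, dt) {
  stopifnot(shear_rate >= 0, dt >= 0)
  L <- config$box_edge
  off <- config$shear_offset + shear_rate * L * dt
  off <- off - L * floor(off / L)
  p <- config$positions
  v <- config$velocities
  u <- config$unwrapped
  le <- shear_rate != 0 || off != 0
  up <- p[, 2] >= L
  dn <- p[, 2] < 0
  ny <- floor(p[, 2] / L)            # crossing count (signed)
  if (any(up | dn) && le) {
    p[, 1] <- p[, 1] - ny * off
    u[, 1] <- u[, 1] - ny * off
    v[, 1] <- v[, 1] - ny * shear_rate * L
  }
  p[, 2] <- p[, 2] - ny * L
  p[, 1] <- p[, 1] - L * floor(p[, 1] / L)
  p[, 3] <- p[, 3] - L * floor(p[, 3] / L)
  config$positions <- p
  config$velocities <- v
  config$unwrapped <- u
  config$shear_offset <- off
  config
}

#' Thermodynamic diagnostics of a configuration
#'
#' Kinetic temperature \eqn{\sum m |v|^2 / (3N - 3)} (with the linear
#' streaming velocity removed under shear) and virial pressure
#' \eqn{\rho k_B T_{kin} + \frac{1}{3V} \sum_{pairs} r_{ij} \cdot F_{ij}},
#' with only conservative and spring forces entering the virial: the
#' dissipative and random contributions average to the thermostat's ideal
#' part and are excluded for a stable diagnostic.
#'
#' @param config a \code{dpd_config}.
#' @param params a \code{dpd_params}.
#' @param shear_rate shear rate used for the streaming correction.
#' @return list (class \code{dpd_thermo}): \code{kinetic_temperature},
#'   \code{virial_pressure}, \code{total_momentum} (3-vector),
#'   \code{time}.
#' @export
thermo_sample <- function(config, params, shear_rate = 0) {
  stopifnot(inherits(config, "dpd_config"))
  n <- nrow(config$positions)
  L <- config$box_edge
  v <- config$velocities
  vx <- v[, 1]
  if (shear_rate != 0)
    vx <- vx - shear_rate * (config$positions[, 2] - L / 2)
  temp <- sum(vx^2 + v[, 2]^2 + v[, 3]^2) / (3 * n - 3)
  a <- species_a_matrix(config, params)
  fr <- cpp_forces(config$positions, v, config$species_id - 1L, a,
                   config$bonds - 1L, 0, 0, params$spring_C, L,
                   config$shear_offset, shear_rate, 1, 0, 0, TRUE)
  vol <- L^3
  structure(list(kinetic_temperature = temp,
                 virial_pressure = n / vol * temp + fr$virial / (3 * vol),
                 total_momentum = colSums(v), time = config$time),
            class = "dpd_thermo")
}

#' Counter-based pair noise
#'
#' The deterministic noise draw \eqn{\xi} used for the random force of pair
#' (i, j) at a given step: zero mean, unit variance, symmetric in i and j,
#' and independent of pair iteration order.  Exposed so analyses and tests
#' can reproduce the engine's stochastic forces exactly.
#'
#' @param seed engine seed.
#' @param step global step counter.
#' @param i,j bead indices (1-based; order irrelevant).
#' @return the noise value.
#' @export
dpd_pair_noise <- function(seed, step, i, j) {
  cpp_pair_noise(as.numeric(seed), as.numeric(step),
                 as.integer(i) - 1L, as.integer(j) - 1L)
}
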