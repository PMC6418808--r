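# Analysis quantities: slab-resolved relative concentration profiles,
# planar concentration maps, mean squared displacement and Einstein
# diffusion coefficients, and distance-based cluster statistics for
# quantifying nano-silica aggregation.

axis_index <- function(axis) {
  i <- match(toupper(axis), c("X", "Y", "Z"))
  if (is.na(i)) stop("axis must be one of X, Y, Z")
  i
}

#' Relative concentration profile along an axis
#'
#' The box is cut into equal-width slabs along one axis; each slab's
#' species count per slab volume is divided by the species' overall number
#' density, so a homogeneous distribution gives a profile close to 1.0
#' everywhere, and the arithmetic mean over (equal) slabs is exactly 1
#' whenever the species is present.
#'
#' @param config a \code{dpd_config}.
#' @param species species name.
#' @param axis "X", "Y" or "Z"; default "Z".
#' @param n_slabs number of slabs; default 30.
#' @return object of class \code{dpd_profile}: \code{species},
#'   \code{axis}, \code{n_slabs}, \code{rel_concentration},
#'   \code{slab_edges}.
#' @export
relative_concentration_profile <- function(config, species, axis = "Z",
                                           n_slabs = 30L) {
  stopifnot(inherits(config, "dpd_config"), n_slabs >= 1)
  ax <- axis_index(axis)
  L <- config$box_edge
  sel <- species_of(config) == species
  if (!any(sel))
    stop("species ", species, " absent from the configuration")
  co <- config$positions[sel, ax]
  idx <- pmin(pmax(floor(co / L * n_slabs) + 1L, 1L), n_slabs)
  counts <- tabulate(idx, nbins = n_slabs)
  rel <- counts * n_slabs / sum(counts)
  structure(list(species = species, axis = toupper(axis),
                 n_slabs = as.integer(n_slabs), rel_concentration = rel,
                 slab_edges = seq(0, L, length.out = n_slabs + 1L)),
            class = "dpd_profile")
}

#' Mean relative concentration profile over trajectory frames
#'
#' @param traj a \code{dpd_traj}.
#' @param species species name.
#' @param axis profile axis.
#' @param n_slabs number of slabs.
#' @param from_step average only frames at or after this step (e.g. the
#'   equilibration length); default 0.
#' @return a \code{dpd_profile} whose values are the per-slab mean over
#'   frames.
#' @export
average_profile <- function(traj, species, axis = "Z", n_slabs = 30L,
                            from_step = 0) {
  stopifnot(inherits(traj, "dpd_traj"))
  keep <- which(traj$steps >= from_step)
  if (!length(keep)) stop("no frames at or after step ", from_step)
  acc <- NULL
  for (k in keep) {
    cf <- frame_config(traj, k)
    p <- relative_concentration_profile(cf, species, axis, n_slabs)
    acc <- if (is.null(acc)) p$rel_concentration
           else acc + p$rel_concentration
  }
  p$rel_concentration <- acc / length(keep)
  p
}

#' Materialise one trajectory frame as a configuration
#'
#' @param traj a \code{dpd_traj}.
#' @param k frame index (1-based).
#' @return a \code{dpd_config}.
#' @export
frame_config <- function(traj, k) {
  stopifnot(inherits(traj, "dpd_traj"), k >= 1, k <= length(traj$positions))
  vel <- if (!is.null(traj$velocities)) traj$velocities[[k]] else NULL
  dpd_config(traj$positions[[k]], traj$species_id, traj$box_edge,
             velocities = vel, molecule = traj$molecule_id,
             species_names = traj$species_names,
             shear_offset = traj$shear_offsets[[k]], time = traj$times[[k]],
             unwrapped = traj$unwrapped[[k]])
}

#' Planar relative concentration map
#'
#' Relative concentration of a species on an n x n grid in a coordinate
#' plane, averaged over a slab of the third axis.  Cell densities are
#' normalised by the species' mean density inside the slab, so the mean
#' over cells is 1 whenever the species occurs in the slab.
#'
#' @param config a \code{dpd_config}.
#' @param species species name.
#' @param plane "XY", "YZ" or "XZ".
#' @param n_bins grid resolution per side; default 20.
#' @param slab_thickness thickness of the averaged slab along the
#'   remaining axis; default the whole box.
#' @param slab_center centre of the slab; default mid-box.
#' @return n_bins x n_bins matrix (class \code{dpd_concmap}) with the two
#'   plane axes as dimnames attribute \code{plane}.
#' @export
concentration_map_2d <- function(config, species, plane = "XY",
                                 n_bins = 20L, slab_thickness = NULL,
                                 slab_center = NULL) {
  stopifnot(inherits(config, "dpd_config"))
  plane <- toupper(plane)
  axes <- switch(plane, XY = c(1L, 2L), YZ = c(2L, 3L), XZ = c(1L, 3L),
                 stop("plane must be XY, YZ or XZ"))
  perp <- setdiff(1:3, axes)
  L <- config$box_edge
  if (is.null(slab_thickness)) slab_thickness <- L
  if (is.null(slab_center)) slab_center <- L / 2
  sel <- species_of(config) == species
  if (!any(sel)) stop("species ", species, " absent from the configuration")
  p <- config$positions[sel, , drop = FALSE]
  d <- p[, perp] - slab_center
  d <- d - L * round(d / L)
  inslab <- abs(d) <= slab_thickness / 2
  if (!any(inslab)) stop("no ", species, " beads in the requested slab")
  p <- p[inslab, , drop = FALSE]
  i1 <- pmin(pmax(floor(p[, axes[1]] / L * n_bins) + 1L, 1L), n_bins)
  i2 <- pmin(pmax(floor(p[, axes[2]] / L * n_bins) + 1L, 1L), n_bins)
  counts <- matrix(0, n_bins, n_bins)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  rel <- counts * n_bins^2 / sum(counts)
  structure(rel, class = c("dpd_concmap", "matrix"), plane = plane,
            species = species, slab_thickness = slab_thickness,
            slab_center = slab_center)
}

#' Mean squared displacement of a species
#'
#' \eqn{MSD(t) = \langle |r_i(t) - r_i(0)|^2 \rangle} over the species'
#' beads, from unwrapped coordinates (periodic crossings accumulated by
#' the engine; post-hoc reconstruction from wrapped frames fails under
#' shear and is not attempted).  Under shear the affine streaming
#' displacement \eqn{\dot\gamma (y - L/2) t} is removed from the X
#' coordinate before accumulation.
#'
#' @param traj a \code{dpd_traj} with unwrapped frames.
#' @param species species name.
#' @param origin_mode "multi" (default) averages over all time origins at
#'   each lag for variance reduction; "single" uses the first frame as the
#'   only origin (the plain Einstein-relation form).
#' @return object of class \code{dpd_msd}: \code{species},
#'   \code{lag_times}, \code{msd}, \code{n_beads}.
#' @export
msd <- function(traj, species, origin_mode = c("multi", "single")) {
  stopifnot(inherits(traj, "dpd_traj"))
  origin_mode <- match.arg(origin_mode)
  if (is.null(traj$unwrapped) || !length(traj$unwrapped))
    stop("trajectory carries no unwrapped coordinates; ",
         "rerun with frame recording enabled")
  nf <- length(traj$unwrapped)
  if (nf < 2) stop("need at least two frames")
  sel <- which(traj$species_names[traj$species_id] == species)
  if (!length(sel)) stop("species ", species, " absent from the trajectory")
  L <- traj$box_edge
  g <- traj$shear_rate %||% 0
  coords <- lapply(seq_len(nf), function(k) {
    u <- traj$unwrapped[[k]][sel, , drop = FALSE]
    if (g != 0)
      u[, 1] <- u[, 1] - g * (u[, 2] - L / 2) * traj$times[[k]]
    u
  })
  t0 <- traj$times[[1]]
  lag_times <- vapply(seq_len(nf), function(k) traj$times[[k]] - t0,
                      numeric(1))
  m <- numeric(nf)
  if (origin_mode == "single") {
    for (k in 2:nf) {
      d <- coords[[k]] - coords[[1]]
      m[k] <- mean(rowSums(d^2))
    }
  } else {
    cnt <- integer(nf)
    for (o in 1:(nf - 1)) for (k in (o + 1):nf) {
      l <- k - o
      d <- coords[[k]] - coords[[o]]
      m[l + 1L] <- m[l + 1L] + mean(rowSums(d^2))
      cnt[l + 1L] <- cnt[l + 1L] + 1L
    }
    m[-1] <- m[-1] / pmax(cnt[-1], 1L)
  }
  structure(list(species = species, lag_times = lag_times, msd = m,
                 n_beads = length(sel)), class = "dpd_msd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Einstein diffusion coefficient from an MSD curve
#'
#' Least-squares slope of MSD over a lag window in the diffusive (linear)
#' regime, divided by 6.
#'
#' @param msd_result a \code{dpd_msd}.
#' @param fit_window length-2 numeric: lag-time range to fit; default the
#'   second half of the available lags.
#' @return object of class \code{dpd_diffusion}: \code{species}, \code{D},
#'   \code{slope}, \code{fit_window}, \code{r_squared}, plus the MSD data.
#' @export
diffusion_coefficient <- function(msd_result, fit_window = NULL) {
  stopifnot(inherits(msd_result, "dpd_msd"))
  lt <- msd_result$lag_times
  if (is.null(fit_window))
    fit_window <- c(max(lt) / 2, max(lt))
  keep <- lt >= fit_window[1] & lt <= fit_window[2]
  if (sum(keep) < 2) stop("fit window contains fewer than 2 points")
  fit <- lm(msd_result$msd[keep] ~ lt[keep])
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((msd_result$msd[keep] - mean(msd_result$msd[keep]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(species = msd_result$species, D = slope / 6,
                 slope = slope, fit_window = fit_window, r_squared = r2,
                 lag_times = lt, msd = msd_result$msd,
                 n_beads = msd_result$n_beads), class = "dpd_diffusion")
}

#' Windowed diffusion-coefficient series
#'
#' Splits a trajectory into consecutive blocks of frames and computes the
#' diffusion coefficient within each, the series whose convergence signals
#' equilibration.
#'
#' @param traj a \code{dpd_traj}.
#' @param species species name.
#' @param window_frames frames per window; default splits into 5 windows.
#' @return data.frame (window, start_step, D).
#' @export
diffusion_series <- function(traj, species, window_frames = NULL) {
  nf <- length(traj$unwrapped)
  if (is.null(window_frames)) window_frames <- max(3L, nf %/% 5L)
  starts <- seq(1L, nf - window_frames + 1L, by = window_frames)
  out <- data.frame(window = seq_along(starts),
                    start_step = traj$steps[starts], D = NA_real_)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + window_frames - 1L)
    sub <- traj
    sub$positions <- traj$positions[idx]
    sub$unwrapped <- traj$unwrapped[idx]
    sub$times <- traj$times[idx]
    sub$steps <- traj$steps[idx]
    sub$shear_offsets <- traj$shear_offsets[idx]
    out$D[w] <- diffusion_coefficient(msd(sub, species))$D
  }
  out
}

#' Equilibration check on windowed diffusion coefficients
#'
#' The system is considered equilibrated once successive windowed
#' diffusion-coefficient estimates agree to a relative tolerance for all
#' species, from some window onward.
#'
#' @param diffusion_series numeric vector of windowed D values for one
#'   species, or a matrix with one column per species (rows = windows).
#' @param tolerance relative tolerance; default 0.1.
#' @return list: \code{converged} (logical) and \code{first_window} (index
#'   of the first window from which all successive changes stay inside
#'   tolerance; NA when not converged).
#' @export
equilibration_check <- function(diffusion_series, tolerance = 0.1) {
  d <- as.matrix(diffusion_series)
  if (nrow(d) < 3) stop("need at least 3 windows")
  rel <- abs(d[-1, , drop = FALSE] - d[-nrow(d), , drop = FALSE]) /
    pmax(abs(d[-nrow(d), , drop = FALSE]), 1e-12)
  ok <- apply(rel < tolerance, 1, all)   # ok[k]: window k+1 vs window k
  conv_from <- NA_integer_
  for (k in rev(seq_along(ok))) {
    if (!ok[k]) break
    conv_from <- k + 1L
  }
  list(converged = !is.na(conv_from), first_window = conv_from)
}

#' Distance-based cluster statistics of a species
#'
#' Single-linkage aggregates: beads of the species are vertices and edges
#' join minimum-image pairs within the cutoff; connected components are
#' the clusters.  The cluster-size distribution is the quantitative face
#' of "aggregation" that the relative-concentration peaks display
#' visually.
#'
#' @param config a \code{dpd_config}.
#' @param species species name.
#' @param cutoff clustering distance (reduced); default 1.0, the
#'   interaction cutoff.
#' @return object of class \code{dpd_clusters}: \code{species},
#'   \code{cutoff}, \code{sizes} (descending), \code{n_clusters},
#'   \code{largest}, \code{mean_size}, \code{membership}.
#' @export
cluster_stats <- function(config, species, cutoff = 1) {
  stopifnot(inherits(config, "dpd_config"), cutoff > 0)
  sel <- which(species_of(config) == species)
  n <- length(sel)
  if (n == 0L)
    return(structure(list(species = species, cutoff = cutoff,
                          sizes = integer(0), n_clusters = 0L,
                          largest = 0L, mean_size = NaN,
                          membership = integer(0)),
                     class = "dpd_clusters"))
  p <- config$positions[sel, , drop = FALSE]
  L <- config$box_edge
  off <- config$shear_offset
  if (L >= 3 * cutoff) {
    pr <- cpp_pairs(p, L, cutoff, off)
    edges <- pr[, 1:2, drop = FALSE]
  } else {
    # small boxes: direct minimum-image scan
    edges <- NULL
    if (n > 1) {
      cmb <- utils::combn(n, 2)
      d <- p[cmb[1, ], , drop = FALSE] - p[cmb[2, ], , drop = FALSE]
      cy <- round(d[, 2] / L)
      d[, 2] <- d[, 2] - cy * L
      d[, 1] <- d[, 1] - cy * off
      d[, 1] <- d[, 1] - L * round(d[, 1] / L)
      d[, 3] <- d[, 3] - L * round(d[, 3] / L)
      hit <- rowSums(d^2) < cutoff^2
      edges <- t(cmb)[hit, , drop = FALSE]
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  structure(list(species = species, cutoff = cutoff, sizes = sizes,
                 n_clusters = comp$no, largest = sizes[1],
                 mean_size = mean(sizes),
                 membership = as.integer(comp$membership)),
            class = "dpd_clusters")
}

#' @export
print.dpd_clusters <- function(x, ...) {
  cat(sprintf("%s clusters at cutoff %g: %d clusters, largest %d, mean %.2f\n",
              x$species, x$cutoff, x$n_clusters, x$largest, x$mean_size))
  invisible(x)
}
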