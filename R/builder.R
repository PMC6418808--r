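# Initial-state construction: bead species, chain topologies, bead counts
# from composition percentages, uniform placement, Maxwell-Boltzmann
# velocities.  This is the pipeline's synthetic-data generator: its defaults
# are the published model conditions (rho = 3, 20% polymer volume, 50-mer
# PVA and 31-mer PAM chains, beads uniformly distributed in the box).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Molecule template
#'
#' @param species character vector: species of each bead in the molecule.
#' @param bonds integer matrix with two columns of within-molecule bead
#'   indices (1-based), or NULL for an unbonded molecule.
#' @return object of class \code{mol_template}.
#' @export
mol_template <- function(species, bonds = NULL) {
  n <- length(species)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > n))
    stop("bond indices outside the molecule")
  structure(list(species = as.character(species), bonds = bonds),
            class = "mol_template")
}

linear_chain <- function(species, n) {
  b <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L) else NULL
  mol_template(rep(species, n), b)
}

#' Coarse-grained molecule templates of the hydrogel model
#'
#' PVA as a 50-bead linear chain, PAM as a 31-bead linear chain, water
#' (three molecules per bead) and nano-silica (one molecule per bead) as
#' single unbonded beads.
#'
#' @return named list of \code{mol_template}s (PVA, PAM, H2O, SiO2).
#' @export
standard_templates <- function() {
  list(PVA = linear_chain("PVA", 50L),
       PAM = linear_chain("PAM", 31L),
       H2O = linear_chain("H2O", 1L),
       SiO2 = linear_chain("SiO2", 1L))
}

#' System composition
#'
#' Component percentages are bead-number fractions; because all beads have
#' the same volume these equal volume fractions.  Water fills the
#' remainder.
#'
#' @param box_edge cubic box edge in reduced length.
#' @param rho bead number density; default 3.
#' @param PVA,PAM,SiO2 number fractions in [0, 1].
#' @return object of class \code{dpd_composition}.
#' @export
composition <- function(box_edge, rho = 3, PVA = 0, PAM = 0, SiO2 = 0) {
  fr <- c(PVA = PVA, PAM = PAM, SiO2 = SiO2)
  if (any(fr < 0)) stop("fractions must be non-negative")
  if (sum(fr) > 1 + 1e-12) stop("fractions sum to more than 1")
  if (box_edge <= 0 || rho <= 0) stop("box_edge and rho must be positive")
  structure(list(box_edge = box_edge, rho = rho, fractions = fr),
            class = "dpd_composition")
}

#' Allocate molecule counts from a composition
#'
#' Polymer chain counts are rounded to whole chains
#' (\code{round(fraction * N / chain_length)}); silica bead count is
#' rounded directly and water absorbs the remainder, so the total bead
#' count equals \code{round(rho * box_edge^3)} exactly and the bead density
#' is preserved at the cost of a sub-percent composition shift.  Both the
#' requested and the realized fractions are reported.
#'
#' @param comp a \code{dpd_composition}.
#' @param templates named list of \code{mol_template}s covering PVA, PAM,
#'   H2O, SiO2; default \code{\link{standard_templates}()}.
#' @return object of class \code{dpd_counts}: \code{n_total},
#'   \code{molecules} (named molecule counts), \code{beads} (named bead
#'   counts), \code{requested}, \code{realized} (named fractions).
#' @export
allocate_counts <- function(comp, templates = standard_templates()) {
  stopifnot(inherits(comp, "dpd_composition"))
  n_total <- round(comp$rho * comp$box_edge^3)
  fr <- comp$fractions
  mols <- c(PVA = 0L, PAM = 0L, SiO2 = 0L, H2O = 0L)
  beads <- mols
  for (s in c("PVA", "PAM")) {
    len <- length(templates[[s]]$species)
    m <- as.integer(round(fr[[s]] * n_total / len))
    if (fr[[s]] > 0 && m == 0L)
      stop("composition infeasible: ", s, " fraction smaller than one chain")
    mols[s] <- m
    beads[s] <- m * len
  }
  mols["SiO2"] <- beads["SiO2"] <- as.integer(round(fr[["SiO2"]] * n_total))
  rest <- n_total - sum(beads[c("PVA", "PAM", "SiO2")])
  if (rest < 0)
    stop("composition infeasible: components exceed the total bead count")
  mols["H2O"] <- beads["H2O"] <- as.integer(rest)
  structure(list(n_total = as.integer(n_total), molecules = mols,
                 beads = beads, requested = fr,
                 realized = beads[c("PVA", "PAM", "SiO2")] / n_total,
                 box_edge = comp$box_edge, rho = comp$rho,
                 templates = templates[c("PVA", "PAM", "SiO2", "H2O")]),
            class = "dpd_counts")
}

#' Simulation state container
#'
#' Low-level constructor for a bead configuration; most users will obtain
#' one from \code{\link{build_initial_configuration}}.
#'
#' @param positions N x 3 matrix, reduced coordinates (wrapped into the box
#'   by the constructor).
#' @param species character vector of per-bead species names, or an integer
#'   id vector if \code{species_names} is given.
#' @param box_edge cubic box edge (reduced).
#' @param velocities N x 3 matrix; default zero.
#' @param molecule per-bead molecule id; default each bead its own.
#' @param bonds global bead-index pairs (1-based, 2 columns); default none.
#' @param species_names species name per id, when \code{species} is integer.
#' @param shear_offset accumulated Lees-Edwards image displacement.
#' @param time reduced simulation time.
#' @param unwrapped N x 3 matrix of unwrapped coordinates; defaults to
#'   \code{positions}.
#' @return object of class \code{dpd_config}.
#' @export
dpd_config <- function(positions, species, box_edge, velocities = NULL,
                       molecule = NULL, bonds = NULL, species_names = NULL,
                       shear_offset = 0, time = 0, unwrapped = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, box_edge > 0)
  if (is.character(species) || is.factor(species)) {
    species <- as.character(species)
    if (is.null(species_names)) {
      std <- hydrogel_species()
      u <- unique(species)
      species_names <- if (all(u %in% std)) std[std %in% u] else u
    }
    species_id <- match(species, species_names)
    if (anyNA(species_id)) stop("species not covered by species_names")
  } else {
    species_id <- as.integer(species)
    if (is.null(species_names)) stop("integer species need species_names")
  }
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(molecule)) molecule <- seq_len(n)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (min(bonds) < 1L || max(bonds) > n) stop("bond indices out of range")
    if (any(molecule[bonds[, 1]] != molecule[bonds[, 2]]))
      stop("bonded beads must belong to the same molecule")
  }
  if (is.null(unwrapped)) unwrapped <- positions
  wrapped <- positions - box_edge * floor(positions / box_edge)
  structure(list(positions = wrapped, velocities = as.matrix(velocities),
                 species_id = as.integer(species_id),
                 species_names = species_names,
                 molecule_id = as.integer(molecule), bonds = bonds,
                 box_edge = box_edge, shear_offset = shear_offset,
                 time = time, unwrapped = as.matrix(unwrapped)),
            class = "dpd_config")
}

#' Per-bead species names of a configuration
#' @param config a \code{dpd_config}.
#' @return character vector of length N.
#' @export
species_of <- function(config) config$species_names[config$species_id]

#' @export
print.dpd_config <- function(x, ...) {
  cat(sprintf("DPD configuration: %d beads in box %g^3, t = %g\n",
              nrow(x$positions), x$box_edge, x$time))
  print(table(species_of(x)))
  invisible(x)
}

#' Build a random initial configuration
#'
#' Single beads are placed uniformly at random in the box; polymer chains
#' are grown as free random walks with a fixed bond step, then wrapped
#' periodically (soft DPD potentials tolerate the resulting overlaps).
#' Velocities are drawn from the Maxwell-Boltzmann distribution at the
#' target temperature and shifted to zero net momentum.  Fully reproducible
#' from \code{seed}.
#'
#' @param counts a \code{dpd_counts} allocation.
#' @param kBT target reduced temperature for the initial velocities.
#' @param seed integer RNG seed (the caller's RNG state is preserved).
#' @param bond_step initial bond length of the chain random walk, reduced
#'   units; default 0.7, near the equilibrium bond length of the C = 4
#'   spring in a rho = 3 soft fluid.
#' @return a \code{dpd_config}.
#' @export
build_initial_configuration <- function(counts, kBT = 1, seed = NULL,
                                        bond_step = 0.7) {
  stopifnot(inherits(counts, "dpd_counts"))
  with_seed(seed, {
    L <- counts$box_edge
    n <- counts$n_total
    pos <- matrix(0, n, 3)
    spn <- hydrogel_species()
    sp_id <- integer(n)
    mol_id <- integer(n)
    bond_list <- list()
    at <- 0L
    mol <- 0L
    for (s in c("PVA", "PAM", "SiO2", "H2O")) {
      tpl <- counts$templates[[s]]
      len <- length(tpl$species)
      for (k in seq_len(counts$molecules[[s]])) {
        mol <- mol + 1L
        idx <- at + seq_len(len)
        start <- runif(3, 0, L)
        if (len > 1L) {
          dirs <- matrix(rnorm(3 * (len - 1L)), ncol = 3)
          dirs <- dirs / sqrt(rowSums(dirs^2))
          steps <- rbind(start, bond_step * dirs)
          pos[idx, ] <- apply(steps, 2, cumsum)
        } else {
          pos[idx, ] <- matrix(start, 1, 3)
        }
        sp_id[idx] <- match(tpl$species, spn)
        mol_id[idx] <- mol
        if (nrow(tpl$bonds))
          bond_list[[length(bond_list) + 1L]] <- tpl$bonds + at
        at <- at + len
      }
    }
    bonds <- if (length(bond_list)) do.call(rbind, bond_list)
             else matrix(integer(0), 0, 2)
    vel <- matrix(rnorm(3L * n, sd = sqrt(kBT)), n, 3)
    vel <- sweep(vel, 2, colMeans(vel))   # zero net momentum (m = 1)
    dpd_config(pos, sp_id, L, velocities = vel, molecule = mol_id,
               bonds = bonds, species_names = spn, unwrapped = pos)
  })
}
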