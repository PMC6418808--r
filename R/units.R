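#' @useDynLib dpdgel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd var coef lm median
#' @importFrom utils read.delim write.table
NULL

#' Reduced thermal energy from an absolute temperature
#'
#' The DPD unit of energy is the thermal energy at the reference
#' temperature (298 K), so the reduced \eqn{k_B T} of a state point is the
#' exact temperature ratio \eqn{T / T_{ref}}.  The exact ratio, rather than a
#' value rounded to one decimal, is what reproduces the published repulsion
#' parameters at 328 K and 358 K to the printed precision (27.52 and 30.03;
#' the rounded ratios 1.1 and 1.2 would give 27.50 and 30.00).
#'
#' @param T_kelvin absolute temperature in Kelvin (vectorised).
#' @param T_ref reference temperature in Kelvin; default 298.
#' @return reduced thermal energy (dimensionless), \code{T_kelvin / T_ref}.
#' @examples
#' reduced_kBT(298)            # 1
#' reduced_kBT(c(328, 358))    # exact ratios, ~1.1007 and ~1.2013
#' @export
reduced_kBT <- function(T_kelvin, T_ref = 298) {
  if (any(!is.finite(T_kelvin)) || any(T_kelvin <= 0))
    stop("temperature must be positive and finite")
  if (T_ref <= 0) stop("reference temperature must be positive")
  T_kelvin / T_ref
}

#' Like-species repulsion parameter from the compressibility route
#'
#' For beads of the same species the maximum conservative repulsion is set
#' by matching the compressibility of water, giving
#' \eqn{a_{ii} = 75 k_B T / \rho} at bead number density \eqn{\rho}.
#'
#' @param kBT reduced thermal energy.
#' @param rho bead number density in reduced units (typically 3).
#' @return repulsion parameter \eqn{a_{ii}} in reduced energy/length.
#' @examples
#' compute_aii(1, 3)                    # 25
#' compute_aii(reduced_kBT(358), 3)     # 30.03 at 2 dp
#' @export
compute_aii <- function(kBT, rho) {
  if (any(kBT <= 0)) stop("kBT must be positive")
  if (any(rho <= 0)) stop("rho must be positive (division by zero otherwise)")
  75 * kBT / rho
}

#' Unlike-species repulsion from the Flory-Huggins parameter
#'
#' Linear mapping \eqn{a_{ij} = a_{ii} + 3.27 \chi_{ij}} between the
#' Flory-Huggins interaction parameter of a bead pair and its DPD repulsion
#' at density 3.
#'
#' @param aii like-species repulsion (baseline).
#' @param chi Flory-Huggins parameter of the pair (dimensionless).
#' @return repulsion parameter \eqn{a_{ij}}.
#' @examples
#' compute_aij(25, 2.48)   # PAM-SiO2 at 298 K: 33.11
#' @export
compute_aij <- function(aii, chi) {
  if (any(!is.finite(aii)) || any(!is.finite(chi)))
    stop("aii and chi must be finite")
  aii + 3.27 * chi
}

#' Noise strength from the fluctuation-dissipation theorem
#'
#' The random and dissipative pair forces thermostat the system only when
#' \eqn{\sigma^2 = 2 \eta k_B T}.  Given the dissipation strength and target
#' reduced temperature this returns the matching noise strength.
#'
#' @param eta dissipation strength (reduced), non-negative.
#' @param kBT reduced thermal energy, positive.
#' @return noise strength \eqn{\sigma} (reduced).
#' @examples
#' sigma_from_fdt(4.5, 1)                    # 3
#' sigma_from_fdt(4.5, reduced_kBT(328))     # 3.15 at 2 dp
#' @export
sigma_from_fdt <- function(eta, kBT) {
  if (any(eta < 0)) stop("eta must be non-negative")
  if (any(kBT <= 0)) stop("kBT must be positive")
  sqrt(2 * eta * kBT)
}

#' Physical duration of a number of DPD steps
#'
#' @param n_steps number of integration steps.
#' @param dt_reduced reduced time step.
#' @param tau_ps physical length of one DPD time unit in picoseconds
#'   (default 93.1 ps for three water molecules per bead).
#' @return duration in picoseconds.
#' @examples
#' physical_time(1, 0.05)   # 4.655 ps
#' @export
physical_time <- function(n_steps, dt_reduced, tau_ps = 93.1) {
  if (any(n_steps < 0) || any(dt_reduced < 0) || any(tau_ps < 0))
    stop("inputs must be non-negative")
  n_steps * dt_reduced * tau_ps
}

#' Physical cutoff radius from the coarse-graining degree
#'
#' The cutoff (= bead diameter) follows from packing \code{Nm} water
#' molecules of volume \code{v_molecule} per bead at bead density \code{rho}:
#' \eqn{r_c = (\rho N_m v)^{1/3}}.  With \eqn{\rho = 3}, \eqn{N_m = 3} and
#' the 30 A^3 water molecule this gives 6.46 Angstrom.
#'
#' @param rho bead number density (reduced).
#' @param Nm water molecules per bead.
#' @param v_molecule molecular volume in cubic Angstrom.
#' @return physical cutoff in Angstrom.
#' @export
rc_from_coarse_graining <- function(rho, Nm, v_molecule) {
  if (any(rho <= 0) || any(Nm <= 0) || any(v_molecule <= 0))
    stop("inputs must be positive")
  (rho * Nm * v_molecule)^(1 / 3)
}

#' Reduced/physical unit system of the hydrogel model
#'
#' @param rc_physical physical cutoff in Angstrom.
#' @param tau_ps physical time unit in picoseconds.
#' @param Nm water molecules per bead.
#' @param T_ref reference temperature in Kelvin.
#' @return an object of class \code{dpd_units}.
#' @export
unit_system <- function(rc_physical = 6.46, tau_ps = 93.1, Nm = 3,
                        T_ref = 298) {
  stopifnot(rc_physical > 0, tau_ps > 0, Nm >= 1, T_ref > 0)
  structure(list(rc_physical = rc_physical, bead_mass = 1, energy_ref = 1,
                 tau_physical = tau_ps, Nm = as.integer(Nm), T_ref = T_ref),
            class = "dpd_units")
}

#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention for parameter tables (2.505 -> 2.51), as opposed to
#' R's round-half-even.  Internal computation keeps full precision; this is
#' applied to displayed values only.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a Flory-Huggins parameter table
#'
#' Plain-text tab-separated file with columns \code{species_i},
#' \code{species_j}, \code{temperature_K}, \code{chi}; one row per
#' pair-temperature.  Pairs are unordered (a row for i-j covers j-i).
#'
#' @param path file path.
#' @return data.frame with the four columns.
#' @export
read_chi_table <- function(path) {
  if (!file.exists(path)) stop("chi table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_i", "species_j", "temperature_K", "chi")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("chi table is missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Packaged Flory-Huggins table for the PVA/PAM/water/silica system
#'
#' The published interaction parameters of the four bead species at 298,
#' 328 and 358 K, as shipped in \code{inst/extdata/chi_table.tsv}.
#'
#' @return data.frame (species_i, species_j, temperature_K, chi).
#' @export
default_chi_table <- function() {
  read_chi_table(system.file("extdata", "chi_table.tsv", package = "dpdgel",
                             mustWork = TRUE))
}

#' Species names of the hydrogel model
#' @return character vector PVA, PAM, H2O, SiO2.
#' @export
hydrogel_species <- function() c("PVA", "PAM", "H2O", "SiO2")

#' Build the DPD interaction parameter set at a temperature
#'
#' Combines the compressibility route for like pairs, the Flory-Huggins
#' mapping for pairs with nonzero \eqn{\chi} (including the silica-silica
#' pair, whose published \eqn{\chi} is negative), and the
#' fluctuation-dissipation relation for the noise strength, into one
#' force-field parameter object.
#'
#' @param chi_table data.frame as returned by \code{\link{read_chi_table}},
#'   or a symmetric numeric matrix of \eqn{\chi} values with dimnames.
#' @param T_kelvin absolute temperature in Kelvin.
#' @param eta dissipation strength; default 4.5.
#' @param spring_C bond spring constant; default 4.
#' @param rho bead number density used in the compressibility route;
#'   default 3.
#' @param species species to include, in order; default: all species in the
#'   table (or \code{\link{hydrogel_species}} order where applicable).
#' @return an object of class \code{dpd_params} with elements
#'   \code{species}, \code{chi} (matrix), \code{a} (matrix), \code{eta},
#'   \code{sigma}, \code{spring_C}, \code{r_cut}, \code{kBT},
#'   \code{temperature_K}, \code{rho}.
#' @examples
#' p <- build_interaction_table(default_chi_table(), 298)
#' p$a["PAM", "SiO2"]   # 33.11 at 2 dp
#' @export
build_interaction_table <- function(chi_table, T_kelvin, eta = 4.5,
                                    spring_C = 4, rho = 3, species = NULL) {
  kBT <- reduced_kBT(T_kelvin)
  if (is.matrix(chi_table)) {
    if (is.null(dimnames(chi_table)[[1]]))
      stop("chi matrix must carry species dimnames")
    if (!isTRUE(all.equal(chi_table, t(chi_table))))
      stop("chi matrix must be symmetric")
    sp <- if (is.null(species)) rownames(chi_table) else species
    chi <- chi_table[sp, sp, drop = FALSE]
  } else {
    tab <- chi_table[chi_table$temperature_K == T_kelvin, , drop = FALSE]
    if (nrow(tab) == 0L)
      stop("chi table has no rows at temperature ", T_kelvin, " K")
    sp <- if (is.null(species)) {
      found <- unique(c(tab$species_i, tab$species_j))
      std <- hydrogel_species()
      if (all(found %in% std)) std[std %in% found] else found
    } else species
    n <- length(sp)
    chi <- matrix(NA_real_, n, n, dimnames = list(sp, sp))
    for (k in seq_len(nrow(tab))) {
      i <- tab$species_i[k]; j <- tab$species_j[k]
      if (i %in% sp && j %in% sp)
        chi[i, j] <- chi[j, i] <- tab$chi[k]
    }
    if (anyNA(chi)) {
      idx <- which(is.na(chi) & upper.tri(chi, diag = TRUE), arr.ind = TRUE)
      pairs <- apply(idx, 1L, function(r) paste(sp[r[1]], sp[r[2]], sep = "-"))
      stop("chi table is missing pair(s) at ", T_kelvin, " K: ",
           paste(unique(pairs), collapse = ", "))
    }
  }
  if (any(!is.finite(chi))) stop("chi values must be finite")
  aii <- compute_aii(kBT, rho)
  a <- compute_aij(aii, chi)   # like pairs have chi = 0 unless published
  structure(list(species = rownames(chi), chi = chi, a = a,
                 eta = eta, sigma = sigma_from_fdt(eta, kBT),
                 spring_C = spring_C, r_cut = 1, kBT = kBT,
                 temperature_K = T_kelvin, rho = rho),
            class = "dpd_params")
}

#' Pairwise parameter table in publication layout
#'
#' Flattens a \code{dpd_params} object into one row per unordered species
#' pair with \eqn{\chi} and \eqn{a} rounded half-up to two decimals, the
#' layout used for regression against the published table.
#'
#' @param params a \code{dpd_params} object.
#' @return data.frame (pair, chi, a).
#' @export
param_table <- function(params) {
  stopifnot(inherits(params, "dpd_params"))
  sp <- params$species
  rows <- list()
  for (i in seq_along(sp)) for (j in i:length(sp)) {
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(sp[i], sp[j], sep = "-"),
      chi = round_half_up(params$chi[i, j], 2),
      a = round_half_up(params$a[i, j], 2))
  }
  do.call(rbind, rows)
}

#' Write a parameter table to a tab-separated file
#' @param params a \code{dpd_params} object.
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
export_param_table <- function(params, path) {
  tab <- param_table(params)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @export
print.dpd_params <- function(x, ...) {
  cat(sprintf("DPD interaction table: %d species at %g K (kBT = %.4f)\n",
              length(x$species), x$temperature_K, x$kBT))
  cat(sprintf("eta = %g, sigma = %.4f, spring C = %g, r_cut = %g\n",
              x$eta, x$sigma, x$spring_C, x$r_cut))
  print(round_half_up(x$a, 2))
  invisible(x)
}
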