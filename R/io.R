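# Extended-XYZ trajectory I/O, scenario configuration files and the
# command-line entry point.
#
# Frames are self-describing: the comment line carries the box as a
# Lattice string plus Time, Step and ShearOffset key=value tokens, and the
# per-bead columns are species, wrapped position, velocity, unwrapped
# position and molecule id.  Numeric output uses full round-trip precision
# (%.17g), so write -> read is bit-exact.

xyz_properties <-
  "Properties=species:S:1:pos:R:3:vel:R:3:unwrapped:R:3:molecule:I:1"

format_xyz_frame <- function(positions, velocities, unwrapped, species,
                             molecule, box_edge, time, shear_offset,
                             step = NA) {
  n <- nrow(positions)
  head <- sprintf(
    'Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" %s Time=%.17g ShearOffset=%.17g%s',
    box_edge, box_edge, box_edge, xyz_properties, time, shear_offset,
    if (is.na(step)) "" else sprintf(" Step=%.17g", step))
  body <- sprintf(
    "%s %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %d",
    species, positions[, 1], positions[, 2], positions[, 3],
    velocities[, 1], velocities[, 2], velocities[, 3],
    unwrapped[, 1], unwrapped[, 2], unwrapped[, 3], molecule)
  c(as.character(n), head, body)
}

#' Write a configuration as a single extended-XYZ frame
#'
#' @param path output file.
#' @param config a \code{dpd_config}.
#' @return invisibly, \code{path}.
#' @export
write_configuration <- function(path, config) {
  stopifnot(inherits(config, "dpd_config"))
  writeLines(format_xyz_frame(config$positions, config$velocities,
                              config$unwrapped, species_of(config),
                              config$molecule_id, config$box_edge,
                              config$time, config$shear_offset), path)
  invisible(path)
}

#' Write a trajectory as concatenated extended-XYZ frames
#'
#' @param path output file.
#' @param traj a \code{dpd_traj}.
#' @return invisibly, \code{path}.
#' @export
write_trajectory <- function(path, traj) {
  stopifnot(inherits(traj, "dpd_traj"))
  sp <- traj$species_names[traj$species_id]
  out <- vector("list", length(traj$positions))
  for (k in seq_along(traj$positions)) {
    vel <- if (!is.null(traj$velocities)) traj$velocities[[k]]
           else matrix(0, nrow(traj$positions[[k]]), 3)
    out[[k]] <- format_xyz_frame(traj$positions[[k]], vel,
                                 traj$unwrapped[[k]], sp,
                                 traj$molecule_id, traj$box_edge,
                                 traj$times[[k]], traj$shear_offsets[[k]],
                                 traj$steps[[k]])
  }
  writeLines(unlist(out), path)
  invisible(path)
}

xyz_header_value <- function(header, key, line_no, required = TRUE) {
  m <- regmatches(header,
                  regexec(paste0(key, '="?([^" ]+)"?'), header))[[1]]
  if (length(m) < 2) {
    if (required)
      stop("line ", line_no, ": missing ", key, " in frame header")
    return(NA_real_)
  }
  as.numeric(m[2])
}

parse_xyz <- function(lines) {
  frames <- list()
  i <- 1L
  nl <- length(lines)
  while (i <= nl) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n < 1)
      stop("line ", i, ": expected a bead count")
    if (i + 1L + n > nl)
      stop("line ", i, ": frame declares ", n,
           " beads but the file ends early")
    header <- lines[i + 1L]
    lat <- regmatches(header, regexec('Lattice="([^"]+)"', header))[[1]]
    if (length(lat) < 2) stop("line ", i + 1L, ": missing Lattice")
    lat_v <- as.numeric(strsplit(lat[2], "[ ]+")[[1]])
    box <- lat_v[1]
    time <- xyz_header_value(header, "Time", i + 1L)
    off <- xyz_header_value(header, "ShearOffset", i + 1L)
    step <- xyz_header_value(header, "Step", i + 1L, required = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[ \t]+")
    nfield <- lengths(parts)
    if (any(nfield != 11L))
      stop("line ", i + 1L + which(nfield != 11L)[1],
           ": expected 11 fields per bead line")
    flat <- unlist(parts)
    dim(flat) <- c(11L, n)
    num <- suppressWarnings(matrix(as.numeric(flat[2:10, ]), nrow = 9L))
    if (anyNA(num))
      stop("line ", i + 1L + which(colSums(is.na(num)) > 0)[1],
           ": malformed numeric field")
    frames[[length(frames) + 1L]] <- list(
      species = flat[1, ], positions = t(num[1:3, , drop = FALSE]),
      velocities = t(num[4:6, , drop = FALSE]),
      unwrapped = t(num[7:9, , drop = FALSE]),
      molecule = as.integer(flat[11, ]), box_edge = box, time = time,
      shear_offset = off, step = step)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found")
  frames
}

linear_bonds_from_molecules <- function(molecule) {
  same <- which(molecule[-1] == molecule[-length(molecule)])
  cbind(same, same + 1L)
}

#' Read a single-frame extended-XYZ configuration
#'
#' Bonds are not stored in the XYZ format; consecutive beads sharing a
#' molecule id are re-bonded as linear chains (the only topology the model
#' builder produces) when \code{rebuild_bonds = TRUE}.
#'
#' @param path input file.
#' @param rebuild_bonds reconstruct linear-chain bonds; default TRUE.
#' @return a \code{dpd_config}.
#' @export
read_configuration <- function(path, rebuild_bonds = TRUE) {
  fr <- parse_xyz(readLines(path))[[1]]
  bonds <- if (rebuild_bonds) linear_bonds_from_molecules(fr$molecule)
           else NULL
  dpd_config(fr$positions, fr$species, fr$box_edge,
             velocities = fr$velocities, molecule = fr$molecule,
             bonds = bonds, shear_offset = fr$shear_offset,
             time = fr$time, unwrapped = fr$unwrapped)
}

#' Read a multi-frame extended-XYZ trajectory
#'
#' @param path input file.
#' @param shear_rate shear rate the trajectory was generated under (used
#'   by MSD streaming correction); default 0.
#' @return a \code{dpd_traj}.
#' @export
read_trajectory <- function(path, shear_rate = 0) {
  frames <- parse_xyz(readLines(path))
  f1 <- frames[[1]]
  std <- hydrogel_species()
  u <- unique(f1$species)
  spn <- if (all(u %in% std)) std[std %in% u] else u
  structure(list(
    steps = vapply(frames, function(f) f$step, numeric(1)),
    times = vapply(frames, function(f) f$time, numeric(1)),
    shear_offsets = vapply(frames, function(f) f$shear_offset, numeric(1)),
    positions = lapply(frames, function(f) f$positions),
    unwrapped = lapply(frames, function(f) f$unwrapped),
    velocities = lapply(frames, function(f) f$velocities),
    species_id = match(f1$species, spn),
    species_names = spn,
    molecule_id = f1$molecule,
    box_edge = f1$box_edge,
    shear_rate = shear_rate), class = "dpd_traj")
}

# ---------------------------------------------------------------- CLI ----

cli_parse_flags <- function(args) {
  flags <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (key %in% c("force")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        if (i == length(args)) stop("flag --", key, " needs a value")
        flags[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("name", "box_edge", "rho", "PVA", "PAM", "SiO2",
               "temperature_K", "dt", "n_steps", "equilibration_steps",
               "shear_rate", "seeds", "chi_table", "scale")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (key in c("box_edge", "n_steps"))
    if (is.null(cfg[[key]])) stop("configuration key missing: ", key)
  cfg
}

scenario_from_config <- function(cfg) {
  comp <- composition(cfg$box_edge, cfg$rho %||% 3,
                      PVA = cfg$PVA %||% 0, PAM = cfg$PAM %||% 0,
                      SiO2 = cfg$SiO2 %||% 0)
  scenario(cfg$name %||% "run", comp,
           temperature_K = cfg$temperature_K %||% 298,
           shear_rate = cfg$shear_rate %||% 0,
           dt = cfg$dt %||% 0.05, n_steps = cfg$n_steps,
           equilibration_steps = cfg$equilibration_steps %||%
             min(cfg$n_steps, as.integer(0.6 * cfg$n_steps)),
           seeds = cfg$seeds %||% 1L,
           scale = cfg$scale %||% "full")
}

#' Command-line entry point
#'
#' Subcommands: \code{params} (print the pairwise interaction-parameter
#' matrix for a temperature), \code{run} (execute a scenario from a YAML
#' configuration file), \code{sweep} (run every preset of a named study)
#' and \code{analyze} (re-derive the observable tables from a stored
#' trajectory).  Designed to be driven by the \code{exec/dpdgel} script;
#' returns the process exit status instead of quitting so it can be
#' called programmatically.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: dpdgel <params|run|sweep|analyze> ...")
    cmd <- args[1]
    p <- cli_parse_flags(args[-1])
    fl <- p$flags
    if (cmd == "params") {
      tk <- as.numeric(fl$temperature %||% 298)
      chi <- if (!is.null(fl$chi)) read_chi_table(fl$chi)
             else default_chi_table()
      tab <- build_interaction_table(chi, tk)
      cat(sprintf("Interaction parameters at %g K (kBT = %.4f, sigma = %.2f)\n",
                  tk, tab$kBT, round_half_up(tab$sigma, 2)))
      out <- param_table(tab)
      write.table(format(out, nsmall = 2), row.names = FALSE,
                  quote = FALSE, sep = "\t")
    } else if (cmd == "run") {
      if (is.null(fl$config)) stop("run needs --config <file>")
      if (is.null(fl$out)) stop("run needs --out <dir>")
      cfg <- read_scenario_config(fl$config)
      if (!is.null(fl$seed)) cfg$seeds <- as.integer(fl$seed)
      if (!is.null(fl$steps)) cfg$n_steps <- as.integer(fl$steps)
      if (!is.null(fl$dt)) cfg$dt <- as.numeric(fl$dt)
      if (!is.null(fl$shear)) cfg$shear_rate <- as.numeric(fl$shear)
      if (!is.null(fl$scale)) cfg$scale <- fl$scale
      scn <- scenario_from_config(cfg)
      chi <- if (!is.null(cfg$chi_table)) read_chi_table(cfg$chi_table)
             else default_chi_table()
      run_scenario(scn, fl$out, chi_table = chi,
                   overwrite = isTRUE(fl$force))
      cat("wrote", file.path(fl$out, paste0(scn$name, "_manifest.tsv")),
          "\n")
    } else if (cmd == "sweep") {
      if (is.null(fl$study)) stop("sweep needs --study <name>")
      if (is.null(fl$out)) stop("sweep needs --out <dir>")
      scns <- study_presets(scale = fl$scale %||% "full",
                            study = fl$study)
      if (!length(scns)) stop("unknown study: ", fl$study)
      for (scn in scns)
        run_scenario(scn, fl$out, overwrite = isTRUE(fl$force))
    } else if (cmd == "analyze") {
      if (is.null(fl$trajectory)) stop("analyze needs --trajectory <file>")
      if (is.null(fl$out)) stop("analyze needs --out <dir>")
      traj <- read_trajectory(fl$trajectory,
                              shear_rate = as.numeric(fl$shear %||% 0))
      equil <- as.numeric(fl$equilibration %||% 0)
      obs <- derive_observables(traj, equil)
      dir.create(fl$out, showWarnings = FALSE, recursive = TRUE)
      base <- tools::file_path_sans_ext(basename(fl$trajectory))
      for (role in names(obs)) {
        path <- file.path(fl$out, paste0(base, "_", role, ".tsv"))
        if (file.exists(path) && !isTRUE(fl$force))
          stop("output exists (use --force): ", path)
        write.table(obs[[role]], path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("dpdgel: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
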