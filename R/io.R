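# Trajectory, curve and configuration I/O. Extended-XYZ is the native
# trajectory format (human-readable, site-typed S/P/B); LAMMPS dump files are
# read-only support for consuming MD engine output. Curves travel as CSV,
# fit reports and matrices as JSON, junction definitions as YAML.

.SPECIES <- c(sugar = "S", phosphate = "P", base = "B")

# FNV-1a 32-bit hash of a character scalar, for provenance stamps
.fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: site count, a comment line of `key=value` metadata
#' (including `Properties=species:S:1:pos:R:3`, frame time and provenance),
#' then one `TAG x y z` line per site with species tags S (sugar),
#' P (phosphate), B (base). Coordinates are written with six decimals.
#'
#' @param traj a `trajectory`
#' @param path output file
#' @param topology a `junction_topology` supplying the site tags
#' @export
write_trajectory <- function(traj, path, topology) {
  stopifnot(inherits(traj, "trajectory"), inherits(topology, "junction_topology"))
  tags <- .SPECIES[topology$sites$kind]
  n <- dim(traj$coords)[1L]
  con <- file(path, "w")
  on.exit(close(con))
  md <- traj$metadata
  for (f in seq_len(dim(traj$coords)[3L])) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Properties=species:S:1:pos:R:3 time=%g state=%s temperature=%g salt=%g seed=%s member=%s',
      traj$times[f],
      if (!is.null(traj$states)) traj$states[f] else "NA",
      md$temperature, md$salt, md$seed, md$member), con)
    fr <- traj$coords[, , f]
    writeLines(sprintf("%s %.6f %.6f %.6f", tags, fr[, 1L], fr[, 2L], fr[, 3L]), con)
  }
  invisible(path)
}

#' Read a trajectory from extended XYZ or LAMMPS dump
#'
#' The dialect is sniffed from the first line unless declared: a bare integer
#' starts an XYZ block, `ITEM: TIMESTEP` a LAMMPS dump. LAMMPS frames are
#' re-sorted by atom id; coordinates are multiplied by `scale` (unit
#' conversion to Angstrom). A truncated final frame is dropped with a
#' warning; a site count differing from the declared topology is an error
#' naming the frame.
#'
#' @param path input file
#' @param dialect `"auto"`, `"xyz"` or `"lammps"`
#' @param topology optional `junction_topology` to validate site counts
#' @param scale coordinate scale factor (LAMMPS unit conversion)
#' @param column_map optional named integer vector mapping `id`, `x`, `y`,
#'   `z` to LAMMPS ATOMS columns (default: read from the ATOMS header)
#' @return a `trajectory`
#' @export
read_trajectory <- function(path, dialect = c("auto", "xyz", "lammps"),
                            topology = NULL, scale = 1, column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("^ITEM: TIMESTEP", lines[1L])) "lammps" else "xyz"
  }
  if (dialect == "xyz") .read_xyz(lines, topology)
  else .read_lammps(lines, topology, scale, column_map)
}

.read_xyz <- function(lines, topology) {
  frames <- list(); times <- numeric(); states <- character()
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) stop("malformed XYZ at line ", i)
    n <- as.integer(lines[i])
    f <- f + 1L
    if (i + 1L + n > length(lines)) {
      warning("dropping truncated final frame ", f)
      break
    }
    if (!is.null(topology) && n != topology$n_sites)
      stop(sprintf("frame %d has %d sites but topology declares %d",
                   f, n, topology$n_sites))
    comment <- lines[i + 1L]
    kv <- regmatches(comment, gregexpr("[A-Za-z_]+=[^ ]+", comment))[[1L]]
    kv <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    mat <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3L,
                  byrow = TRUE)
    frames[[f]] <- mat
    times <- c(times, suppressWarnings(as.numeric(kv["time"])))
    states <- c(states, if ("state" %in% names(kv)) kv[["state"]] else NA_character_)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no complete frames in file")
  coords <- array(unlist(frames), dim = c(nrow(frames[[1L]]), 3L, length(frames)))
  # unlist concatenates column-major per frame; rebuild properly
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  structure(list(coords = coords,
                 times = if (anyNA(times)) seq_along(frames) - 1 else times,
                 states = if (all(is.na(states))) NULL else states,
                 metadata = list(temperature = NA_real_, salt = NA_real_,
                                 seed = NA_integer_, member = NA_integer_)),
            class = "trajectory")
}

.read_lammps <- function(lines, topology, scale, column_map) {
  starts <- which(lines == "ITEM: TIMESTEP")
  if (!length(starts)) stop("no TIMESTEP records found")
  frames <- list(); times <- numeric(); f <- 0L
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    f <- f + 1L
    natoms_i <- which(grepl("^ITEM: NUMBER OF ATOMS", block)) + 1L
    atoms_i <- which(grepl("^ITEM: ATOMS", block))
    if (!length(natoms_i) || !length(atoms_i)) stop("malformed dump frame ", f)
    n <- as.integer(block[natoms_i])
    if (atoms_i + n > length(block)) {
      warning("dropping truncated final frame ", f)
      break
    }
    if (!is.null(topology) && n != topology$n_sites)
      stop(sprintf("frame %d has %d sites but topology declares %d",
                   f, n, topology$n_sites))
    cmap <- column_map
    if (is.null(cmap)) {
      cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", block[atoms_i]), "\\s+")[[1L]]
      cmap <- stats::setNames(match(c("id", "x", "y", "z"), cols),
                              c("id", "x", "y", "z"))
      if (anyNA(cmap)) stop("cannot locate id/x/y/z columns in ATOMS header")
    }
    body <- block[(atoms_i + 1L):(atoms_i + n)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    ids <- as.integer(parts[, cmap[["id"]]])
    mat <- matrix(as.numeric(parts[, cmap[c("x", "y", "z")]]), ncol = 3L)
    frames[[f]] <- mat[order(ids), , drop = FALSE] * scale
    times <- c(times, as.numeric(block[2L]))
  }
  if (!length(frames)) stop("no complete frames in file")
  coords <- array(0, dim = c(nrow(frames[[1L]]), 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  structure(list(coords = coords, times = times, states = NULL,
                 metadata = list(temperature = NA_real_, salt = NA_real_,
                                 seed = NA_integer_, member = NA_integer_)),
            class = "trajectory")
}

#' Read a junction definition from YAML
#'
#' Expected fields: `arm_length`, `strands` (map of label to sequence for X,
#' R, H, B), and optionally `core_markers` (list of records with `strand`,
#' `nt`, `role`).
#'
#' @param path YAML file
#' @return a `junction_topology`
#' @export
read_junction_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$strands) || is.null(cfg$arm_length))
    stop("junction YAML must declare strands and arm_length")
  seqs <- unlist(cfg$strands)
  cm <- NULL
  if (!is.null(cfg$core_markers)) {
    cm <- do.call(rbind, lapply(cfg$core_markers, function(m)
      data.frame(strand = m$strand, nt = as.integer(m$nt), role = m$role,
                 stringsAsFactors = FALSE)))
  }
  build_topology(seqs, cfg$arm_length, core_markers = cm)
}

#' Write / read a melting curve as CSV
#'
#' Columns `temperature_K`, `alpha` and optionally `n_frames`; the strand
#' concentration is carried in a `# C_mol_per_L=` header comment.
#'
#' @param curve a `melting_curve`
#' @param path file path
#' @export
write_melting_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# C_mol_per_L=%.10g", attr(curve, "C")), con)
  df <- data.frame(temperature_K = curve$temperature, alpha = curve$alpha)
  if (!is.null(curve$n_frames)) df$n_frames <- curve$n_frames
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melting_csv
#' @param C strand concentration, mol/L; overrides any header value
#' @export
read_melting_csv <- function(path, C = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(C) && grepl("^# C_mol_per_L=", first))
    C <- as.numeric(sub("^# C_mol_per_L=", "", first))
  if (is.null(C)) stop("strand concentration not found; pass C explicitly")
  df <- utils::read.csv(path, comment.char = "#")
  melting_curve(df$temperature_K, df$alpha, C = C, n_frames = df$n_frames)
}

#' Read an absorbance melting curve from CSV
#'
#' Columns: `temperature_K` (or `temperature_C`, auto-converted) and `A260`.
#'
#' @param path CSV file
#' @param lower_window,upper_window baseline windows in K (defaults: outer
#'   15% of the grid span)
#' @return an `absorbance_curve`
#' @export
read_absorbance_csv <- function(path, lower_window = NULL, upper_window = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  if ("temperature_C" %in% names(df)) {
    tk <- df$temperature_C + 273.15
  } else if ("temperature_K" %in% names(df)) {
    tk <- df$temperature_K
  } else stop("need a temperature_K or temperature_C column")
  span <- diff(range(tk))
  n <- length(tk)
  if (is.null(lower_window))
    lower_window <- c(min(tk), max(min(tk) + 0.15 * span, tk[min(3L, n)]))
  if (is.null(upper_window))
    upper_window <- c(min(max(tk) - 0.15 * span, tk[max(1L, n - 2L)]), max(tk))
  absorbance_curve(tk, df$A260, lower_window, upper_window)
}

#' Write a state series as CSV (time_ns, state)
#' @param series a `state_series`
#' @param path file path
#' @export
write_states_csv <- function(series, path) {
  utils::write.csv(data.frame(time_ns = series$times, state = series$states),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dt <- if (nrow(df) > 1L) df$time_ns[2L] - df$time_ns[1L] else NA_real_
  structure(list(times = df$time_ns, states = df$state, dt = dt,
                 initial = df$state[1L], member = NA_integer_,
                 seed = NA_integer_, jumps = NULL),
            class = "state_series")
}

#' Write an analysis result as JSON with a provenance stamp
#'
#' Adds `provenance` (package version, seed if supplied, and an FNV-1a hash
#' of the serialized parameters) alongside the payload.
#'
#' @param x a list (e.g. a `vant_hoff_fit`, `transition_matrix` or
#'   `population_estimate`, unclassed)
#' @param path output file
#' @param seed seed used to produce the result, if any
#' @export
write_result_json <- function(x, path, seed = NULL) {
  payload <- unclass(x)
  payload$provenance <- list(
    package = "fourway",
    version = as.character(utils::packageVersion("fourway")),
    seed = seed,
    param_hash = .fnv1a(paste(utils::capture.output(utils::str(payload)),
                              collapse = "\n")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
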