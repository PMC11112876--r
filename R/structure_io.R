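#' @importFrom stats sd median quantile rnorm runif kruskal.test setNames
#' @importFrom utils write.table packageVersion
NULL

# Residue names recognised as water (case-insensitive). TIP3 covers
# CHARMM-style topologies; SOL/WAT cover GROMACS/AMBER writers.
.water_resnames <- c("HOH", "TIP3", "SOL", "WAT")

# Standard atomic masses (u). Keyed by upper-case element symbol.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  `NA` = 22.990, K = 39.098, CL = 35.45, MN = 54.938, CU = 63.546
)

#' Infer element symbols from PDB atom names
#'
#' Used when the element column of a PDB file is blank. The first
#' alphabetic character of the atom name is taken as the element, which is
#' correct for the heavy atoms of standard residues and waters ("CA" is
#' carbon alpha, not calcium, in a protein chain).
#'
#' @param atom_names character vector of PDB atom names.
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(atom_names) {
  stripped <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atom_names)))
  substr(stripped, 1L, 1L)
}

#' Look up atomic masses
#'
#' @param element character vector of element symbols (may contain blanks).
#' @param atom_name character vector of atom names, used as fallback when
#'   the element is blank or unknown.
#' @return numeric vector of masses in atomic mass units.
#' @keywords internal
atom_mass <- function(element, atom_name) {
  el <- toupper(trimws(element))
  missing <- is.na(el) | el == "" | !(el %in% names(.atomic_masses))
  if (any(missing)) el[missing] <- infer_element(atom_name[missing])
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    bad <- unique(atom_name[is.na(m)])
    stop("cannot assign a mass to atom(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Construct a trajectory object
#'
#' A `trajectory` couples a constant atom table with per-frame coordinates,
#' the representation used throughout the package. All frames share one
#' atom identity ordering; waters are flagged in the atom table.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_number`, `element`, `mass`,
#'   `is_water`.
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns
#'   in x1,y1,z1,x2,... order (the bio3d convention).
#' @param dt_ps frame spacing in picoseconds (`NA` when unknown).
#' @param source free-text provenance string.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, dt_ps = NA_real_, source = "") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(atoms) == 0L) stop("trajectory must contain at least one atom")
  stopifnot(ncol(xyz) == 3L * nrow(atoms), nrow(xyz) >= 1L)
  if (!all(is.finite(xyz))) stop("trajectory coordinates must be finite")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) identity within a frame: ",
         key[anyDuplicated(key)])
  }
  structure(
    list(atoms = atoms, xyz = xyz, dt_ps = as.numeric(dt_ps), source = source),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frame(s), %d atoms (%d waters), dt = %s ps\n",
              n_frames(x), nrow(x$atoms), sum(x$atoms$is_water),
              ifelse(is.na(x$dt_ps), "?", format(x$dt_ps))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Frame times in picoseconds
#' @param traj a `trajectory`.
#' @return numeric vector, `k`-th frame at `(k-1) * dt_ps` (0-based times);
#'   `NA` when `dt_ps` is unset.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1L) * traj$dt_ps

#' Coordinates of one frame as an n x 3 matrix
#' @param traj a `trajectory`.
#' @param frame 1-based frame index.
#' @param idx optional integer atom indices to extract.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
frame_coords <- function(traj, frame = 1L, idx = NULL) {
  if (frame < 1L || frame > n_frames(traj)) {
    stop("frame index ", frame, " out of range [1, ", n_frames(traj), "]")
  }
  m <- matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Subset the frames of a trajectory
#' @param traj a `trajectory`.
#' @param frames integer vector of 1-based frame indices to keep.
#' @return a `trajectory` with the selected frames.
#' @export
subset_frames <- function(traj, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(traj))) {
    stop("frame range outside [1, ", n_frames(traj), "]")
  }
  trajectory(traj$atoms, traj$xyz[frames, , drop = FALSE],
             dt_ps = traj$dt_ps, source = traj$source)
}

# Pre-scan a PDB file: locate MODEL blocks, check coordinate fields are
# numeric (error names the offending line), check all models carry the
# same number of coordinate records.
.scan_pdb_lines <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  is_coord <- rec %in% c("ATOM  ", "HETATM")
  coord_lines <- which(is_coord)
  for (i in coord_lines) {
    for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      field <- substr(lines[i], cols[1L], cols[2L])
      if (is.na(suppressWarnings(as.numeric(field)))) {
        stop("malformed coordinate field at line ", i, ": '", field, "'")
      }
    }
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    return(list(n_models = 1L, counts = length(coord_lines)))
  }
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records")
  }
  counts <- vapply(seq_along(model_starts), function(k) {
    sum(coord_lines > model_starts[k] & coord_lines < ends[k])
  }, integer(1))
  if (length(unique(counts)) != 1L) {
    stop("frames have mismatched atom sets: counts ",
         paste(counts, collapse = ", "))
  }
  list(n_models = length(model_starts), counts = counts[1L])
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses fixed-column PDB (v3.3) via bio3d, treating each MODEL as one
#' trajectory frame. ATOM and HETATM records are both read; water residues
#' (HOH/TIP3/SOL/WAT, case-insensitive) are retained and flagged. Alternate
#' locations other than `' '`/`'A'` are dropped with a warning. A file with
#' no MODEL records is a single-frame trajectory. Frames are assumed to be
#' whole-molecule imaged: no periodic-boundary correction is applied.
#'
#' @param path path to a PDB file.
#' @param dt_ps frame spacing in picoseconds (not inferred from the file).
#' @return a [trajectory].
#' @examples
#' tr <- build_hexamer(synthesis_params(n_frames = 2, seed = 1))$trajectory
#' f <- tempfile(fileext = ".pdb")
#' write_pdb_models(tr, f)
#' tr2 <- read_pdb_models(f)
#' n_frames(tr2)
#' @export
read_pdb_models <- function(path, dt_ps = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  scan <- .scan_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = scan$n_models > 1L, verbose = FALSE)
  at <- pdb$atom
  alt <- at$alt
  keep_alt <- is.na(alt) | alt %in% c("", " ", "A")
  if (!all(keep_alt)) {
    warning(sum(!keep_alt), " atom(s) with altloc other than ' '/'A' dropped")
  }
  keep <- which(keep_alt)
  elesy <- at$elesy[keep]
  elesy[is.na(elesy)] <- ""
  atoms <- data.frame(
    serial = at$eleno[keep],
    atom_name = at$elety[keep],
    residue_name = at$resid[keep],
    chain_id = ifelse(is.na(at$chain[keep]), " ", at$chain[keep]),
    residue_number = at$resno[keep],
    element = elesy,
    mass = atom_mass(elesy, at$elety[keep]),
    is_water = toupper(at$resid[keep]) %in% .water_resnames,
    stringsAsFactors = FALSE
  )
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  xyz_idx <- as.vector(t(outer(keep, 1:3, function(i, j) 3L * (i - 1L) + j)))
  xyz <- xyz[, xyz_idx, drop = FALSE]
  trajectory(atoms, xyz, dt_ps = dt_ps, source = path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-column v3.3 layout (coordinates
#' at 3 decimals). Round-trips through [read_pdb_models] on the semantic
#' atom table: names, residues, chains, numbering and coordinates at PDB
#' precision.
#'
#' @param traj a [trajectory] with at least one frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1L || nrow(traj$atoms) == 0L) {
    stop("cannot write an empty trajectory")
  }
  if (any(abs(traj$xyz) >= 10000)) {
    stop("coordinate exceeds fixed-column width (|x| >= 10000 Å)")
  }
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frame_coords(traj, k)
    rec <- ifelse(a$is_water, "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(a$atom_name) < 4L,
                    sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
    writeLines(sprintf(
      "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000L, name4, a$residue_name, a$chain_id,
      a$residue_number, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by chain, residue, atom name or water flag
#'
#' Filters are combined by conjunction; omitted filters match everything.
#' An empty selection is a legal result. The returned indices follow file
#' order and index both the atom table and [frame_coords].
#'
#' @param traj a [trajectory] (the atom table is shared by all frames).
#' @param chain optional chain IDs to keep.
#' @param residue_numbers optional residue numbers to keep.
#' @param atom_names optional atom names to keep.
#' @param water `NA` (default) keeps both; `TRUE` waters only; `FALSE`
#'   non-waters only.
#' @return integer vector of atom indices.
#' @examples
#' b <- build_hexamer(synthesis_params(n_frames = 1, seed = 1))
#' length(select_atoms(b$trajectory, chain = "A", atom_names = "CA"))
#' @export
select_atoms <- function(traj, chain = NULL, residue_numbers = NULL,
                         atom_names = NULL, water = NA) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(residue_numbers)) keep <- keep & a$residue_number %in% residue_numbers
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  if (!is.na(water)) keep <- keep & (a$is_water == water)
  which(keep)
}

#' Number of frames recorded by a production run
#'
#' Bookkeeping helper: a run of `duration_ns` nanoseconds sampled every
#' `interval_ps` picoseconds yields `duration_ns * 1000 / interval_ps`
#' records (e.g. 100 ns at 1 ps gives 100,000).
#'
#' @param duration_ns run length in nanoseconds.
#' @param interval_ps recording interval in picoseconds.
#' @return integer number of recorded frames.
#' @export
frames_recorded <- function(duration_ns, interval_ps) {
  stopifnot(duration_ns > 0, interval_ps > 0)
  n <- duration_ns * 1000 / interval_ps
  if (abs(n - round(n)) > 1e-9) {
    stop("recording interval does not divide the run length")
  }
  as.integer(round(n))
}
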