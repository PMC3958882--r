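#' @title Coordinate trajectories
#'
#' @description
#' A `trajectory` holds an ordered set of frames of 3-D coordinates in
#' Angstrom for a fixed set of atoms, with a time stamp (ps) per frame.
#' Internally coordinates are stored as an array of dimension
#' `c(n_atoms, 3, n_frames)`.
#'
#' @param coords numeric array `c(n_atoms, 3, n_frames)` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param times numeric vector of frame times in ps, strictly increasing;
#'   defaults to `0:(n_frames-1)`.
#' @return an object of class `trajectory` with elements `coords`, `times`,
#'   `n_frames`, `n_atoms`.
#' @export
trajectory <- function(coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (!all(is.finite(coords))) stop("trajectory: coordinates must be finite")
  n_frames <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames) {
    stop("trajectory: times length must equal frame count")
  }
  if (n_frames > 1L && any(diff(times) <= 0)) {
    stop("trajectory: times must be strictly increasing")
  }
  structure(list(coords = coords, times = as.numeric(times),
                 n_frames = n_frames, n_atoms = dim(coords)[1]),
            class = "trajectory")
}

#' Extract one frame as an n_atoms x 3 matrix
#'
#' @param traj a [trajectory].
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > traj$n_frames) stop("frame index out of range: ", i)
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.6g..%.6g ps\n",
              x$n_frames, x$n_atoms, x$times[1], x$times[x$n_frames]))
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' Parses ATOM records delimited by MODEL/ENDMDL into a [trajectory] plus a
#' topology skeleton (atom names, elements, residues, chains -- no force-field
#' parameters). A file without MODEL records is read as a single frame.
#' Frame times are recovered from `REMARK   6 TIME_PS <t>` records when
#' present (the writer emits them), otherwise default to 1 ps spacing.
#'
#' All models must contain the same atoms in the same order; a model with a
#' deviating atom count is a hard error naming the model index.
#'
#' @param path path to a PDB file.
#' @return list with elements `trajectory` ([trajectory]) and `skeleton`
#'   (data frame: `atom_id`, `name`, `residue_index`, `residue_name`,
#'   `chain_id`, `element`).
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(rec == "MODEL ")

  if (length(model_starts) == 0L) {
    frame_id <- rep(1L, sum(is_atom))
    atom_lines <- lines[is_atom]
  } else {
    # assign each ATOM line to the most recent MODEL record
    model_of_line <- findInterval(seq_along(lines), model_starts)
    keep <- is_atom & model_of_line >= 1L
    frame_id <- model_of_line[keep]
    atom_lines <- lines[keep]
  }
  if (length(atom_lines) == 0L) stop("no ATOM records in ", path)

  n_models <- max(frame_id)
  counts <- tabulate(frame_id, nbins = n_models)
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("model %d: expected %d atoms, found %d",
                 bad, counts[1], counts[bad]))
  }
  n_atoms <- counts[1]

  x <- suppressWarnings(as.numeric(substr(atom_lines, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 47L, 54L)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    all_idx <- which(is_atom)
    bad_local <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("unparseable ATOM line at file line ",
         which(lines == atom_lines[bad_local])[1])
  }

  first <- frame_id == 1L
  serial <- suppressWarnings(as.integer(substr(atom_lines[first], 7L, 11L)))
  name <- trimws(substr(atom_lines[first], 13L, 16L))
  res_name <- trimws(substr(atom_lines[first], 18L, 20L))
  chain <- trimws(substr(atom_lines[first], 22L, 22L))
  res_seq <- suppressWarnings(as.integer(substr(atom_lines[first], 23L, 26L)))
  element <- trimws(substr(atom_lines[first], 77L, 78L))
  no_el <- element == ""
  element[no_el] <- substr(gsub("[^A-Za-z].*$", "", name[no_el]), 1L, 1L)
  if (anyNA(serial) || anyNA(res_seq)) {
    stop("unparseable ATOM numbering in first model of ", path)
  }

  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_models))
  ord <- order(frame_id, seq_along(frame_id))  # stable; lines already ordered
  coords[, 1L, ] <- x[ord]
  coords[, 2L, ] <- y[ord]
  coords[, 3L, ] <- z[ord]

  times <- NULL
  tm_lines <- grep("^REMARK   6 TIME_PS ", lines, value = TRUE)
  if (length(tm_lines) == n_models) {
    times <- as.numeric(sub("^REMARK   6 TIME_PS +", "", tm_lines))
    if (anyNA(times)) times <- NULL
  }

  skeleton <- data.frame(atom_id = serial, name = name,
                         residue_index = res_seq, residue_name = res_name,
                         chain_id = chain, element = element,
                         stringsAsFactors = FALSE)
  list(trajectory = trajectory(coords, times), skeleton = skeleton)
}

#' Write a multi-model PDB trajectory
#'
#' Emits MODEL/ENDMDL-delimited ATOM records with `%8.3f` coordinates (the
#' round-trip precision is therefore 1e-3 Angstrom) and per-model
#' `REMARK   6 TIME_PS` records carrying the frame times.
#'
#' @param traj a [trajectory].
#' @param top a [topology] or topology skeleton providing `atom_id`, `name`,
#'   `residue_name`, `chain_id`, `residue_index`, `element`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, top, path) {
  if (nrow(top) != traj$n_atoms) {
    stop("topology/trajectory atom count mismatch")
  }
  el <- if ("element" %in% names(top)) top$element else ""
  name4 <- ifelse(nchar(top$name) < 4L, sprintf(" %-3s", top$name),
                  substr(top$name, 1L, 4L))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    writeLines(sprintf("REMARK   6 TIME_PS %.6f", traj$times[f]), con)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      top$atom_id, name4, substr(top$residue_name, 1L, 3L), top$chain_id,
      top$residue_index, xyz[, 1], xyz[, 2], xyz[, 3], el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
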