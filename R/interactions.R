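#' Geometric hydrogen-bond test for one frame
#'
#' A hydrogen bond is present when the donor-acceptor distance is at most
#' `dist_cutoff` (default 3.5 Angstrom) AND the D-H...A angle (at the
#' hydrogen) is at least `angle_cutoff` (default 120 degrees).
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param donor,hydrogen,acceptor atom indices (three distinct atoms; the
#'   hydrogen must be covalently attached to the donor).
#' @param dist_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff D-H...A angle cutoff (degrees).
#' @return list: `present` (logical), `distance` (Angstrom, D..A),
#'   `angle` (degrees).
#' @export
detect_hbond <- function(frame, donor, hydrogen, acceptor,
                         dist_cutoff = 3.5, angle_cutoff = 120) {
  idx <- c(donor, hydrogen, acceptor)
  if (anyNA(idx) || length(unique(idx)) != 3L) {
    stop("detect_hbond: donor, hydrogen and acceptor must be 3 distinct atoms")
  }
  D <- frame[donor, ]; H <- frame[hydrogen, ]; A <- frame[acceptor, ]
  dist <- sqrt(sum((D - A)^2))
  v1 <- D - H; v2 <- A - H
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("detect_hbond: coincident atoms")
  cosang <- sum(v1 * v2) / (n1 * n2)
  angle <- acos(min(1, max(-1, cosang))) * 180 / pi
  list(present = (dist <= dist_cutoff) && (angle >= angle_cutoff),
       distance = dist, angle = angle)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' @inheritParams detect_hbond
#' @param traj a [trajectory].
#' @return list of class `hbond_record`: `donor`, `hydrogen`, `acceptor`,
#'   `present` (logical per frame), `occupancy` (percent of frames, reported
#'   to 0.01), `mean_distance` (Angstrom), `mean_angle` (degrees).
#' @export
hbond_occupancy <- function(traj, donor, hydrogen, acceptor,
                            dist_cutoff = 3.5, angle_cutoff = 120) {
  if (traj$n_frames < 1L) stop("hbond_occupancy: empty trajectory")
  res <- lapply(seq_len(traj$n_frames), function(i) {
    detect_hbond(get_frame(traj, i), donor, hydrogen, acceptor,
                 dist_cutoff, angle_cutoff)
  })
  present <- vapply(res, `[[`, logical(1), "present")
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 present = present,
                 occupancy = round(100 * mean(present), 2),
                 mean_distance = mean(vapply(res, `[[`, numeric(1),
                                             "distance")),
                 mean_angle = mean(vapply(res, `[[`, numeric(1), "angle"))),
            class = "hbond_record")
}

#' @export
print.hbond_record <- function(x, ...) {
  cat(sprintf(
    "hbond %d-%d...%d: occupancy %.2f%% (mean d %.2f A, mean angle %.1f deg)\n",
    x$donor, x$hydrogen, x$acceptor, x$occupancy, x$mean_distance,
    x$mean_angle))
  invisible(x)
}

# internal: heavy nonpolar atom rows of a selection
nonpolar_heavy <- function(top, selection) {
  selection[top$polarity_class[selection] == "nonpolar" &
              toupper(top$element[selection]) != "H"]
}

#' Hydrophobic contacts between two selections in one frame
#'
#' A residue pair is in hydrophobic contact when any pair of nonpolar heavy
#' atoms (one from each selection; polarity from the topology) is within the
#' cutoff (default 3.9 Angstrom, the LigPlot+ convention).
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param selection_1,selection_2 disjoint integer atom index vectors.
#' @param top a [topology].
#' @param cutoff contact distance cutoff (Angstrom).
#' @return data frame, one row per contacting residue pair: `residue_1`,
#'   `residue_2`, `atom_1`, `atom_2` (closest nonpolar heavy pair),
#'   `min_distance`.
#' @export
hydrophobic_contacts <- function(frame, selection_1, selection_2, top,
                                 cutoff = 3.9) {
  if (length(intersect(selection_1, selection_2)) > 0L) {
    stop("hydrophobic_contacts: selections overlap")
  }
  a1 <- nonpolar_heavy(top, selection_1)
  a2 <- nonpolar_heavy(top, selection_2)
  empty <- data.frame(residue_1 = integer(0), residue_2 = integer(0),
                      atom_1 = integer(0), atom_2 = integer(0),
                      min_distance = numeric(0))
  if (length(a1) == 0L || length(a2) == 0L) return(empty)
  d <- pair_distance_matrix(frame, a1, a2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  res1 <- top$residue_index[a1[hit[, 1]]]
  res2 <- top$residue_index[a2[hit[, 2]]]
  dist <- d[hit]
  key <- paste(res1, res2)
  best <- tapply(seq_along(key), key, function(ii) ii[which.min(dist[ii])])
  best <- unlist(best, use.names = FALSE)
  out <- data.frame(residue_1 = res1[best], residue_2 = res2[best],
                    atom_1 = top$atom_id[a1[hit[best, 1]]],
                    atom_2 = top$atom_id[a2[hit[best, 2]]],
                    min_distance = dist[best])
  out[order(out$residue_1, out$residue_2), , drop = FALSE]
}

# internal: cross distance matrix between two atom index sets
pair_distance_matrix <- function(frame, idx1, idx2) {
  p1 <- frame[idx1, , drop = FALSE]
  p2 <- frame[idx2, , drop = FALSE]
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * tcrossprod(p1, p2)
  sqrt(pmax(d2, 0))
}

#' Contact populations of listed residue pairs over a trajectory
#'
#' @param traj a [trajectory].
#' @param selection_1,selection_2 disjoint atom index vectors.
#' @param top a [topology].
#' @param pair_list data frame (or 2-column matrix) of residue index pairs
#'   to track.
#' @param cutoff contact cutoff (Angstrom).
#' @return data frame: `residue_1`, `residue_2`, `population` (percent of
#'   frames in contact, to 0.01).
#' @export
contact_population <- function(traj, selection_1, selection_2, top,
                               pair_list, cutoff = 3.9) {
  pair_list <- as.data.frame(pair_list)
  if (nrow(pair_list) == 0L) {
    return(data.frame(residue_1 = integer(0), residue_2 = integer(0),
                      population = numeric(0)))
  }
  names(pair_list)[1:2] <- c("residue_1", "residue_2")
  hits <- matrix(0L, nrow = nrow(pair_list), ncol = traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    cc <- hydrophobic_contacts(get_frame(traj, f), selection_1, selection_2,
                               top, cutoff)
    key_now <- paste(cc$residue_1, cc$residue_2)
    key_want <- paste(pair_list$residue_1, pair_list$residue_2)
    hits[, f] <- as.integer(key_want %in% key_now)
  }
  data.frame(residue_1 = pair_list$residue_1,
             residue_2 = pair_list$residue_2,
             population = round(100 * rowMeans(hits), 2))
}

#' Minimum side-chain distance series between two residues
#'
#' Side-chain heavy atoms are all atoms of the residue not named N, CA, C or
#' O and not hydrogen. The per-frame minimum over all cross pairs is
#' reported together with the fraction of frames at or below `cutoff`
#' (default 3.5 Angstrom, the hydrogen-bond distance criterion).
#'
#' @param traj a [trajectory].
#' @param residue_1,residue_2 residue indices.
#' @param top a [topology].
#' @param cutoff summary cutoff (Angstrom).
#' @return list: `distance` (numeric per frame), `fraction_below` (percent
#'   of frames with minimum distance <= cutoff, to 0.01).
#' @export
min_sidechain_distance_series <- function(traj, residue_1, residue_2, top,
                                          cutoff = 3.5) {
  side_atoms <- function(res) {
    idx <- which(top$residue_index == res &
                   !(top$name %in% c("N", "CA", "C", "O")) &
                   toupper(top$element) != "H")
    if (length(idx) == 0L) {
      stop("min_sidechain_distance_series: residue ", res,
           " has no side-chain heavy atoms")
    }
    idx
  }
  s1 <- side_atoms(residue_1); s2 <- side_atoms(residue_2)
  d <- vapply(seq_len(traj$n_frames), function(f) {
    min(pair_distance_matrix(get_frame(traj, f), s1, s2))
  }, numeric(1))
  list(distance = d, fraction_below = round(100 * mean(d <= cutoff), 2))
}
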