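#' @title Open/closed conformational-state metric
#'
#' @description
#' The dimer state metric is the distance between the mass center of the
#' dimerization base (helices A-D of BOTH monomers jointly) and the mass
#' center of one monomer's top helices (G-I). A monomer is called closed
#' when that distance is below `d_closed` (default 35 Angstrom) and open
#' when above `d_open` (default 37 Angstrom); the band in between is labeled
#' intermediate. Mass centers are mass-weighted over all atoms of the helix
#' residues.
#'
#' @name state_metric
NULL

#' Default analysis constants
#'
#' One block holding every tunable constant of the analyses: state
#' thresholds (35/37 Angstrom), hydrogen-bond criteria (3.5 Angstrom,
#' 120 degrees), hydrophobic-contact cutoff (3.9 Angstrom), non-polar
#' model (gamma 0.005 kcal/(mol A^2), beta 0), solvent dielectric (78.5),
#' temperature (300 K) and SASA sampling (probe 1.4 Angstrom, 960 points).
#'
#' @return named list of defaults.
#' @export
dimermd_defaults <- function() {
  list(d_closed = 35, d_open = 37,
       hbond_dist_cutoff = 3.5, hbond_angle_cutoff = 120,
       contact_cutoff = 3.9,
       gamma = 0.005, beta = 0, eps_solvent = 78.5,
       temperature = 300, sasa_probe = 1.4, sasa_n_points = 960)
}

#' Base-to-top mass-center distance per monomer
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param hmap a [helix_map] defining segments A-D and G-I on both chains.
#' @param top a [topology].
#' @return named numeric vector `c(A = d_A, B = d_B)` (Angstrom): for each
#'   monomer, the distance from the joint A-D base mass center (both chains)
#'   to that monomer's G-I top mass center.
#' @export
state_distance <- function(frame, hmap, top) {
  chains <- names(hmap$chains)
  base_idx <- unlist(lapply(chains, function(ch) {
    helix_atoms(hmap, top, ch, c("A", "B", "C", "D"))
  }))
  base_com <- center_of_mass(frame, base_idx, top)
  d <- vapply(chains, function(ch) {
    top_idx <- helix_atoms(hmap, top, ch, c("G", "H", "I"))
    sqrt(sum((center_of_mass(frame, top_idx, top) - base_com)^2))
  }, numeric(1))
  names(d) <- chains
  d
}

#' Classify a base-to-top distance as closed/open/intermediate
#'
#' @param distance distance(s) in Angstrom, non-negative.
#' @param d_closed closed-state threshold (default 35 Angstrom): strictly
#'   below is closed.
#' @param d_open open-state threshold (default 37 Angstrom): strictly above
#'   is open.
#' @return character vector of labels in
#'   `c("closed", "intermediate", "open")`.
#' @export
classify_state <- function(distance, d_closed = 35, d_open = 37) {
  if (d_closed >= d_open) stop("classify_state: d_closed must be < d_open")
  if (any(distance < 0)) stop("classify_state: negative distance")
  ifelse(distance < d_closed, "closed",
         ifelse(distance > d_open, "open", "intermediate"))
}

#' Distance between the two monomers' top-helix mass centers
#'
#' @inheritParams state_distance
#' @return numeric scalar (Angstrom): distance between COM(G-I of chain 1)
#'   and COM(G-I of chain 2).
#' @export
top_top_distance <- function(frame, hmap, top) {
  chains <- names(hmap$chains)
  if (length(chains) != 2L) stop("top_top_distance: need exactly 2 chains")
  coms <- lapply(chains, function(ch) {
    center_of_mass(frame, helix_atoms(hmap, top, ch, c("G", "H", "I")), top)
  })
  sqrt(sum((coms[[1]] - coms[[2]])^2))
}

#' Per-frame state series for a whole trajectory
#'
#' Computes, for every frame, the per-monomer base-to-top distances with
#' their open/closed labels, the top-top distance, and (optionally) the
#' backbone RMSD from a reference frame.
#'
#' @param traj a [trajectory].
#' @param hmap a [helix_map].
#' @param top a [topology].
#' @param d_closed,d_open classification thresholds (Angstrom).
#' @param reference optional reference frame matrix for an RMSD column; the
#'   backbone selection (atoms named N, CA, C, O) is used.
#' @return data frame, one row per frame: `time_ps`, `d_A`, `d_B`,
#'   `label_A`, `label_B`, `top_top_distance` and, with a reference, `rmsd`.
#'   (Columns are named after the actual chain ids.)
#' @export
state_series <- function(traj, hmap, top, d_closed = 35, d_open = 37,
                         reference = NULL) {
  chains <- names(hmap$chains)
  dmat <- t(vapply(seq_len(traj$n_frames), function(i) {
    state_distance(get_frame(traj, i), hmap, top)
  }, numeric(length(chains))))
  tt <- vapply(seq_len(traj$n_frames), function(i) {
    top_top_distance(get_frame(traj, i), hmap, top)
  }, numeric(1))
  out <- data.frame(time_ps = traj$times)
  for (k in seq_along(chains)) {
    out[[paste0("d_", chains[k])]] <- dmat[, k]
    out[[paste0("label_", chains[k])]] <-
      classify_state(dmat[, k], d_closed, d_open)
  }
  out$top_top_distance <- tt
  if (!is.null(reference)) {
    bb <- which(top$name %in% c("N", "CA", "C", "O"))
    out$rmsd <- rmsd_series(traj, reference, bb)
  }
  out
}
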