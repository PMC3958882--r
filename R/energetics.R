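## MM-GBSA energetics: gas-phase nonbonded terms, HCT generalized-Born polar
## solvation, Shrake-Rupley SASA non-polar term, monomer-monomer binding
## energies and per-residue decomposition.
##
## Model summary (all energies kcal/mol, per snapshot):
##   G_total     = H_gas + G_solvation
##   H_gas       = E_vdW + E_ele
##   G_solvation = G_pol + G_nonpol
##   G_nonpol    = gamma * SASA + beta        (gamma 0.005 kcal/(mol A^2),
##                                             beta 0 by default)
## Binding uses the single-trajectory scheme: monomer terms are evaluated on
## the complex geometry, so internal bonded energies cancel and only
## nonbonded + solvation terms are ever computed.

KE_COULOMB <- 332.0636   # kcal A / (mol e^2)
GB_OFFSET <- 0.09        # A, intrinsic-radius offset of the HCT scheme

#' Lennard-Jones 12-6 energy over a pair set
#'
#' Uses the Rmin/epsilon convention with combination rules
#' `Rmin_ij = rmin_half_i + rmin_half_j` and `eps_ij = sqrt(eps_i eps_j)`:
#' `E = sum eps_ij ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)`.
#'
#' The caller is responsible for excluding bonded (1-2/1-3) pairs when
#' intra-chain pairs are requested; see [nonbonded_pairs()].
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param top a [topology].
#' @param pair_set 2-column integer matrix of atom row indices.
#' @return total energy, kcal/mol.
#' @export
lj_energy <- function(frame, top, pair_set) {
  if (nrow(pair_set) == 0L) return(0)
  i <- pair_set[, 1]; j <- pair_set[, 2]
  r <- sqrt(rowSums((frame[i, , drop = FALSE] -
                       frame[j, , drop = FALSE])^2))
  if (any(r == 0)) stop("lj_energy: zero interatomic distance")
  rmin <- top$lj_rmin_half[i] + top$lj_rmin_half[j]
  eps <- sqrt(top$lj_epsilon[i] * top$lj_epsilon[j])
  s6 <- (rmin / r)^6
  sum(eps * (s6^2 - 2 * s6))
}

#' Coulomb energy over a pair set
#'
#' `E = sum k_e q_i q_j / (eps r_ij)` with
#' `k_e = 332.0636 kcal A / (mol e^2)`.
#'
#' @inheritParams lj_energy
#' @param dielectric relative dielectric constant (default 1).
#' @return total energy, kcal/mol.
#' @export
coulomb_energy <- function(frame, top, pair_set, dielectric = 1) {
  if (nrow(pair_set) == 0L) return(0)
  i <- pair_set[, 1]; j <- pair_set[, 2]
  r <- sqrt(rowSums((frame[i, , drop = FALSE] -
                       frame[j, , drop = FALSE])^2))
  if (any(r == 0)) stop("coulomb_energy: zero interatomic distance")
  sum(KE_COULOMB * top$charge[i] * top$charge[j] / (dielectric * r))
}

#' Nonbonded intra/inter-chain pair sets
#'
#' Enumerates atom pairs within a selection, excluding pairs inside the same
#' residue or in adjacent residues of the same chain (the tabular topology
#' carries no bond list, so the 1-2/1-3 exclusion is applied at residue
#' granularity). Pairs across chains are always included.
#'
#' @param top a [topology].
#' @param selection atom row indices (default all).
#' @return 2-column integer matrix of atom row indices (i < j).
#' @export
nonbonded_pairs <- function(top, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(top))
  n <- length(selection)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cmb <- t(utils::combn(selection, 2L))
  same_chain <- top$chain_id[cmb[, 1]] == top$chain_id[cmb[, 2]]
  close_res <- abs(top$residue_index[cmb[, 1]] -
                     top$residue_index[cmb[, 2]]) <= 1L
  cmb[!(same_chain & close_res), , drop = FALSE]
}

#' All pairs between two chains
#'
#' @param top a [topology].
#' @return 2-column integer matrix (atom rows of chain 1 x chain 2).
#' @export
inter_chain_pairs <- function(top) {
  chains <- unique(top$chain_id)
  if (length(chains) != 2L) stop("inter_chain_pairs: need exactly 2 chains")
  i <- which(top$chain_id == chains[1])
  j <- which(top$chain_id == chains[2])
  cbind(rep(i, times = length(j)), rep(j, each = length(i)))
}

#' HCT effective Born radii
#'
#' Pairwise-descreening effective radii (Hawkins-Cramer-Truhlar scheme, the
#' sander igb=1 flavor). The intrinsic radius of each atom is its topology
#' `born_radius` minus the standard 0.09 A offset; an isolated atom's
#' effective radius equals that offset-corrected intrinsic radius, and
#' descreening by neighbors can only enlarge it.
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param top a [topology].
#' @param selection atom row indices (default all); descreening sums run
#'   over the selection only.
#' @return numeric vector of effective radii (Angstrom), one per selected
#'   atom.
#' @export
effective_born_radii <- function(frame, top, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(top))
  n <- length(selection)
  rho <- top$born_radius[selection] - GB_OFFSET
  if (any(rho <= 0)) {
    stop("effective_born_radii: born_radius must exceed the ",
         GB_OFFSET, " A offset")
  }
  if (n == 1L) return(rho)
  xyz <- frame[selection, , drop = FALSE]
  r2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  r <- sqrt(pmax(r2, 0))
  diag(r) <- NA_real_
  if (any(r == 0, na.rm = TRUE)) {
    stop("effective_born_radii: overlapping identical centers")
  }
  sr <- top$screen_factor[selection] * rho     # scaled descreening radii
  srj <- matrix(sr, n, n, byrow = TRUE)        # column atom j descreens row i
  rhoi <- matrix(rho, n, n)
  U <- r + srj
  active <- !is.na(r) & (rhoi < U)
  L <- pmax(rhoi, abs(r - srj))
  term <- 0.5 * (1 / L - 1 / U +
                   0.25 * (r - srj^2 / r) * (1 / U^2 - 1 / L^2) +
                   0.5 * log(L / U) / r)
  inside <- active & (rhoi < srj - r)          # atom i inside j's scaled sphere
  term[inside] <- term[inside] + (1 / rhoi[inside] - 1 / L[inside])
  term[!active] <- 0
  I <- rowSums(term)
  inv <- 1 / rho - I
  alpha <- ifelse(inv > 1e-3, 1 / inv, 1000)   # clamp runaway radii at 1000 A
  pmax(alpha, rho)
}

#' Generalized-Born polar solvation energy
#'
#' Still's pairwise expression with the canonical interpolation function
#' `f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j)))`:
#' `G_pol = -1/2 k_e (1 - 1/eps_w) sum_{i,j} q_i q_j / f_GB`, where the
#' double sum includes the i = j Born self terms (`f_GB = a_i`).
#'
#' @inheritParams effective_born_radii
#' @param eps_solvent exterior (solvent) dielectric, default 78.5; the
#'   interior dielectric is 1.
#' @param radii optional precomputed effective radii for the selection.
#' @param per_atom if `TRUE`, also return the per-atom contributions (pair
#'   terms split evenly between partners); they sum exactly to the total.
#' @return energy in kcal/mol, or (with `per_atom`) a list
#'   `list(energy, per_atom)`.
#' @export
gb_polar_energy <- function(frame, top, selection = NULL, eps_solvent = 78.5,
                            radii = NULL, per_atom = FALSE) {
  if (is.null(selection)) selection <- seq_len(nrow(top))
  if (is.null(radii)) radii <- effective_born_radii(frame, top, selection)
  q <- top$charge[selection]
  n <- length(selection)
  xyz <- frame[selection, , drop = FALSE]
  r2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  r2 <- pmax(r2, 0)
  aa <- tcrossprod(radii)
  fgb <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
  pref <- -0.5 * KE_COULOMB * (1 - 1 / eps_solvent)
  contrib <- pref * outer(q, q) / fgb   # contrib[i, j] = pref q_i q_j / f_GB
  g_atom <- rowSums(contrib)
  energy <- sum(g_atom)
  if (per_atom) list(energy = energy, per_atom = g_atom) else energy
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic point-sampling SASA: each atom's sphere of radius
#' (vdW radius + probe) carries a fixed Fibonacci point lattice; points
#' buried inside any neighbor's expanded sphere are discarded and the
#' accessible fraction is converted to area. The vdW radius is the
#' topology's `lj_rmin_half`.
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param top a [topology].
#' @param selection atom row indices (default all); occlusion is computed
#'   within the selection only.
#' @param probe probe radius (Angstrom), default 1.4.
#' @param n_points points per sphere, default 960.
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
sasa <- function(frame, top, selection = NULL, probe = 1.4, n_points = 960) {
  if (is.null(selection)) selection <- seq_len(nrow(top))
  radius <- top$lj_rmin_half[selection] + probe
  if (anyNA(radius)) stop("sasa: missing vdW radius (lj_rmin_half)")
  n <- length(selection)
  xyz <- frame[selection, , drop = FALSE]
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  # neighbor lists from expanded-sphere overlap
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  rsum <- outer(radius, radius, "+")
  for (k in seq_len(n)) {
    nb <- which(d2[k, ] < rsum[k, ]^2)
    nb <- nb[nb != k]
    if (length(nb) == 0L) {
      out[k] <- 4 * pi * radius[k]^2
      next
    }
    p <- sweep(pts * radius[k], 2L, xyz[k, ], "+")     # n_points x 3
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | (dj2 < radius[j]^2)
      if (all(buried)) break
    }
    out[k] <- 4 * pi * radius[k]^2 * mean(!buried)
  }
  out
}

# deterministic Fibonacci sphere lattice (unit vectors)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Non-polar solvation energy from SASA
#'
#' `G_nonpol = gamma * SASA + beta` with the empirical constants
#' gamma = 0.005 kcal/(mol A^2) and beta = 0 by default.
#'
#' @param sasa_total total SASA (Angstrom^2).
#' @param gamma surface-tension coefficient, kcal/(mol A^2).
#' @param beta offset, kcal/mol.
#' @return energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa_total, gamma = 0.005, beta = 0) {
  gamma * sasa_total + beta
}

#' Full MM-GBSA energy breakdown of one frame
#'
#' Assembles the four components over the nonbonded pairs of a selection
#' (see [nonbonded_pairs()] for the intra-chain exclusion policy) and the
#' GB/SASA solvation terms, and returns them with the composite sums. The
#' defining identities `H_gas = E_vdW + E_ele`,
#' `G_solvation = G_pol + G_nonpol` and `G_total = H_gas + G_solvation`
#' hold exactly by construction.
#'
#' Because no internal bonded terms are included, whole-system totals are
#' comparable across frames (trends) but not to force-field absolute
#' energies.
#'
#' @inheritParams sasa
#' @param gamma,beta non-polar model constants.
#' @param eps_solvent solvent dielectric.
#' @param n_points SASA points per sphere.
#' @return one-row data frame: `E_vdW`, `E_ele`, `G_pol`, `G_nonpol`,
#'   `H_gas`, `G_solvation`, `G_total`, `SASA`.
#' @export
frame_energy <- function(frame, top, selection = NULL, gamma = 0.005,
                         beta = 0, eps_solvent = 78.5, probe = 1.4,
                         n_points = 960) {
  if (is.null(selection)) selection <- seq_len(nrow(top))
  pairs <- nonbonded_pairs(top, selection)
  e_vdw <- lj_energy(frame, top, pairs)
  e_ele <- coulomb_energy(frame, top, pairs)
  g_pol <- gb_polar_energy(frame, top, selection, eps_solvent)
  s <- sum(sasa(frame, top, selection, probe, n_points))
  g_np <- nonpolar_energy(s, gamma, beta)
  data.frame(E_vdW = e_vdw, E_ele = e_ele, G_pol = g_pol, G_nonpol = g_np,
             H_gas = e_vdw + e_ele, G_solvation = g_pol + g_np,
             G_total = e_vdw + e_ele + g_pol + g_np, SASA = s)
}

# internal engine shared by binding_energy and per_residue_decomposition.
# Single-trajectory scheme: monomer quantities are evaluated on the complex
# geometry, so intra-chain gas-phase terms cancel and only inter-chain LJ and
# Coulomb energies plus the change in GB and SASA terms remain.
mmgbsa_engine <- function(traj, top, frames = NULL, gamma = 0.005, beta = 0,
                          eps_solvent = 78.5, probe = 1.4, n_points = 960,
                          per_atom = FALSE) {
  chains <- unique(top$chain_id)
  if (length(chains) != 2L) stop("binding energy needs exactly 2 chains")
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  ia <- which(top$chain_id == chains[1])
  ib <- which(top$chain_id == chains[2])
  n_all <- nrow(top)
  qa <- top$charge[ia]; qb <- top$charge[ib]
  rha <- top$lj_rmin_half[ia]; rhb <- top$lj_rmin_half[ib]
  epa <- top$lj_epsilon[ia]; epb <- top$lj_epsilon[ib]
  rmin <- outer(rha, rhb, "+")
  epsij <- sqrt(outer(epa, epb))
  qq <- KE_COULOMB * outer(qa, qb)

  comp <- matrix(NA_real_, nrow = length(frames), ncol = 4L,
                 dimnames = list(NULL, c("E_vdW", "E_ele", "G_pol",
                                         "G_nonpol")))
  atom_acc <- if (per_atom) {
    matrix(0, nrow = n_all, ncol = 4L,
           dimnames = list(NULL, c("E_vdW", "E_ele", "G_pol", "G_nonpol")))
  } else NULL

  for (fk in seq_along(frames)) {
    fr <- get_frame(traj, frames[fk])
    pa <- fr[ia, , drop = FALSE]; pb <- fr[ib, , drop = FALSE]
    r2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    r <- sqrt(pmax(r2, 0))
    if (any(r == 0)) stop("mmgbsa: coincident inter-chain atoms")
    s6 <- (rmin / r)^6
    e_vdw_mat <- epsij * (s6^2 - 2 * s6)
    e_ele_mat <- qq / r
    d_vdw <- sum(e_vdw_mat)
    d_ele <- sum(e_ele_mat)

    gb_c <- gb_polar_energy(fr, top, NULL, eps_solvent, per_atom = TRUE)
    gb_a <- gb_polar_energy(fr, top, ia, eps_solvent, per_atom = TRUE)
    gb_b <- gb_polar_energy(fr, top, ib, eps_solvent, per_atom = TRUE)
    d_pol <- gb_c$energy - gb_a$energy - gb_b$energy

    sa_c <- sasa(fr, top, NULL, probe, n_points)
    sa_a <- sasa(fr, top, ia, probe, n_points)
    sa_b <- sasa(fr, top, ib, probe, n_points)
    d_sasa_atom <- sa_c
    d_sasa_atom[ia] <- d_sasa_atom[ia] - sa_a
    d_sasa_atom[ib] <- d_sasa_atom[ib] - sa_b
    d_np <- gamma * sum(d_sasa_atom) - beta

    comp[fk, ] <- c(d_vdw, d_ele, d_pol, d_np)

    if (per_atom) {
      # split each inter-chain pair term evenly between the two atoms
      atom_acc[ia, "E_vdW"] <- atom_acc[ia, "E_vdW"] + rowSums(e_vdw_mat) / 2
      atom_acc[ib, "E_vdW"] <- atom_acc[ib, "E_vdW"] + colSums(e_vdw_mat) / 2
      atom_acc[ia, "E_ele"] <- atom_acc[ia, "E_ele"] + rowSums(e_ele_mat) / 2
      atom_acc[ib, "E_ele"] <- atom_acc[ib, "E_ele"] + colSums(e_ele_mat) / 2
      d_gb_atom <- gb_c$per_atom
      d_gb_atom[ia] <- d_gb_atom[ia] - gb_a$per_atom
      d_gb_atom[ib] <- d_gb_atom[ib] - gb_b$per_atom
      atom_acc[, "G_pol"] <- atom_acc[, "G_pol"] + d_gb_atom
      atom_acc[, "G_nonpol"] <- atom_acc[, "G_nonpol"] +
        gamma * d_sasa_atom - beta / n_all
    }
  }
  list(components = comp, frames = frames,
       per_atom_mean = if (per_atom) atom_acc / length(frames) else NULL)
}

#' Monomer-monomer MM-GBSA binding energy
#'
#' Single-trajectory scheme: for each frame,
#' `dG = G(complex) - G(chain 1) - G(chain 2)` with the monomer geometries
#' taken from the complex frame, so internal bonded terms cancel by
#' construction. The enthalpic/solvation part is reported (no entropy; see
#' [quasiharmonic_entropy()]).
#'
#' @param traj a [trajectory] of the dimer.
#' @param top a [topology] with exactly two chains.
#' @param frames frame indices to evaluate (default all).
#' @param gamma,beta,eps_solvent,probe,n_points model constants as in
#'   [frame_energy()].
#' @return list of class `binding_energy`: `per_frame` (data frame with
#'   `time_ps`, `dE_vdW`, `dE_ele`, `dG_pol`, `dG_nonpol`, `dH_gas`,
#'   `dG_solvation`, `dG_total`) and `mean` (named numeric of the same
#'   components averaged over frames).
#' @export
binding_energy <- function(traj, top, frames = NULL, gamma = 0.005,
                           beta = 0, eps_solvent = 78.5, probe = 1.4,
                           n_points = 960) {
  check_topology_trajectory(top, traj)
  eng <- mmgbsa_engine(traj, top, frames, gamma, beta, eps_solvent, probe,
                       n_points)
  comp <- eng$components
  pf <- data.frame(time_ps = traj$times[eng$frames],
                   dE_vdW = comp[, "E_vdW"], dE_ele = comp[, "E_ele"],
                   dG_pol = comp[, "G_pol"], dG_nonpol = comp[, "G_nonpol"])
  pf$dH_gas <- pf$dE_vdW + pf$dE_ele
  pf$dG_solvation <- pf$dG_pol + pf$dG_nonpol
  pf$dG_total <- pf$dH_gas + pf$dG_solvation
  structure(list(per_frame = pf,
                 mean = colMeans(pf[, -1, drop = FALSE])),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  m <- x$mean
  cat(sprintf(
    "MM-GBSA binding energy over %d frames (kcal/mol):\n", nrow(x$per_frame)))
  cat(sprintf("  dE_vdW %8.3f  dE_ele %8.3f  dG_pol %8.3f  dG_nonpol %8.3f\n",
              m["dE_vdW"], m["dE_ele"], m["dG_pol"], m["dG_nonpol"]))
  cat(sprintf("  dG_total %8.3f\n", m["dG_total"]))
  invisible(x)
}

#' Per-residue decomposition of the binding energy
#'
#' Inter-chain pair energies are split half to each partner atom's residue;
#' GB terms are the difference of the per-atom complex and monomer
#' contributions; buried SASA is attributed to the atom owning the area.
#' Component sums over residues therefore reproduce the corresponding mean
#' binding-energy components exactly.
#'
#' @inheritParams binding_energy
#' @return data frame of class `residue_decomposition`, one row per residue:
#'   `residue_index`, `chain_id`, `dE_vdW`, `dE_ele`, `dG_pol`,
#'   `dG_nonpol`, `dG_total`, `hydrophobic_part`
#'   (`= dE_vdW + dG_nonpol`). The matching mean binding components are
#'   attached as attribute `totals`.
#' @export
per_residue_decomposition <- function(traj, top, frames = NULL,
                                      gamma = 0.005, beta = 0,
                                      eps_solvent = 78.5, probe = 1.4,
                                      n_points = 960) {
  check_topology_trajectory(top, traj)
  eng <- mmgbsa_engine(traj, top, frames, gamma, beta, eps_solvent, probe,
                       n_points, per_atom = TRUE)
  pa <- eng$per_atom_mean
  res <- top$residue_index
  agg <- rowsum(pa, group = res, reorder = TRUE)
  residue_index <- as.integer(rownames(agg))
  chain <- top$chain_id[match(residue_index, top$residue_index)]
  out <- data.frame(residue_index = residue_index, chain_id = chain,
                    dE_vdW = agg[, "E_vdW"], dE_ele = agg[, "E_ele"],
                    dG_pol = agg[, "G_pol"], dG_nonpol = agg[, "G_nonpol"])
  out$dG_total <- out$dE_vdW + out$dE_ele + out$dG_pol + out$dG_nonpol
  out$hydrophobic_part <- out$dE_vdW + out$dG_nonpol
  rownames(out) <- NULL
  attr(out, "totals") <- colMeans(eng$components)
  class(out) <- c("residue_decomposition", "data.frame")
  out
}

#' Interaction-spectrum summary statistics
#'
#' Counts residues whose total contribution passes +-`threshold` kcal/mol
#' (favorable below `-threshold`, unfavorable above `+threshold`) in each
#' decomposition table, and the Pearson correlation of the hydrophobic
#' parts (`dE_vdW + dG_nonpol`) across residues common to both tables.
#'
#' @param table_1,table_2 [per_residue_decomposition()] tables.
#' @param threshold contribution threshold, kcal/mol (default 1).
#' @return list: `favorable_1`, `unfavorable_1`, `favorable_2`,
#'   `unfavorable_2`, `correlation`.
#' @export
interaction_spectrum_stats <- function(table_1, table_2, threshold = 1) {
  common <- intersect(table_1$residue_index, table_2$residue_index)
  h1 <- table_1$hydrophobic_part[match(common, table_1$residue_index)]
  h2 <- table_2$hydrophobic_part[match(common, table_2$residue_index)]
  list(favorable_1 = sum(table_1$dG_total < -threshold),
       unfavorable_1 = sum(table_1$dG_total > threshold),
       favorable_2 = sum(table_2$dG_total < -threshold),
       unfavorable_2 = sum(table_2$dG_total > threshold),
       correlation = stats::cor(h1, h2))
}
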