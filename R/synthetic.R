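## Synthetic dimeric helical trajectories with planted ground truth.
##
## The generator emulates the statistical structure of open/closed dimer MD
## trajectories: two C2-symmetric monomers of ideal alpha-helices (a base
## group mapped to segments A-D, a hinge group E-F, a top group G-I), whose
## top groups hinge rigidly between a closed and an open base-to-top
## mass-center distance following a per-frame schedule, plus Gaussian
## coordinate noise and planted hydrogen bonds / hydrophobic contacts with
## known Bernoulli occupancies. No physical dynamics is claimed.

# cylindrical backbone parameters of an ideal alpha-helix: radius (A),
# phase offset (deg) and axial offset (A) per atom relative to the CA of the
# same residue, frozen from a standard phi=-57/psi=-47 internal-coordinate
# construction and re-gridded to an exact 1.5 A rise and 100 deg twist.
HELIX_ATOM_PARAMS <- data.frame(
  name = c("N", "CA", "C", "O", "H", "CB"),
  element = c("N", "C", "C", "O", "H", "C"),
  r = c(1.5207, 2.3099, 1.7600, 1.9998, 1.5192, 3.3961),
  dphi = c(-24.9199, 0, 26.9979, 20.2843, -17.1736, 15.4192),
  dz = c(-0.9213, 0, 1.0664, 2.2515, -1.9102, -0.7723),
  stringsAsFactors = FALSE)
HELIX_RISE <- 1.5     # A per residue
HELIX_TWIST <- 100    # deg per residue

#' Build an ideal alpha-helix
#'
#' Parametric helix with a 1.5 Angstrom rise and 100 degree rotation per
#' residue about the axis; backbone N, CA, C, O and the amide H are placed
#' per residue with standard local geometry (frozen cylindrical offsets from
#' an ideal phi/psi construction).
#'
#' @param n_res number of residues.
#' @param origin position of the first residue's axial reference point.
#' @param axis helix axis direction (normalized internally).
#' @param atoms atom names to place per residue; any subset of
#'   `N, CA, C, O, H, CB` (default the 5 backbone atoms).
#' @return list: `coords` (`(n_res * n_atoms) x 3` matrix), `atoms` (data
#'   frame with `name`, `element`, `residue` 1-based within the helix).
#' @export
build_ideal_helix <- function(n_res, origin = c(0, 0, 0),
                              axis = c(0, 0, 1),
                              atoms = c("N", "CA", "C", "O", "H")) {
  stopifnot(n_res >= 1L)
  par <- HELIX_ATOM_PARAMS[match(atoms, HELIX_ATOM_PARAMS$name), ]
  if (anyNA(par$name)) stop("build_ideal_helix: unknown atom name")
  na <- nrow(par)
  res <- rep(seq_len(n_res), each = na)
  ang <- ((res - 1L) * HELIX_TWIST + par$dphi[rep(seq_len(na), n_res)]) *
    pi / 180
  rr <- par$r[rep(seq_len(na), n_res)]
  zz <- (res - 1L) * HELIX_RISE + par$dz[rep(seq_len(na), n_res)]
  local <- cbind(rr * cos(ang), rr * sin(ang), zz)
  R <- rotation_to_axis(axis)
  coords <- sweep(local %*% t(R), 2L, origin, "+")
  list(coords = coords,
       atoms = data.frame(name = rep(par$name, n_res),
                          element = rep(par$element, n_res),
                          residue = res, stringsAsFactors = FALSE))
}

# rotation matrix taking (0,0,1) to the given axis
rotation_to_axis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  c_ <- sum(z * a)
  if (sum(v^2) < 1e-12) {
    if (c_ > 0) return(diag(3)) else return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Scenario configuration for the synthetic generator
#'
#' @param n_frames number of frames.
#' @param n_res_per_helix residues per helix (default 8).
#' @param helices integer vector `c(base, hinge, top)` helix counts per
#'   monomer, mapped onto segment names A-D / E-F / G-I (defaults 4, 2, 3;
#'   may be reduced, e.g. `c(2, 1, 1)`, for fast small systems).
#' @param d_closed,d_open target base-to-top mass-center distances
#'   (Angstrom) of the fully closed / fully open geometry (defaults 33 and
#'   41, both at least 2 Angstrom outside the 35-37 classification band).
#' @param schedule per-frame open fraction theta in `[0, 1]` (length
#'   `n_frames`); default all 0 (closed). The realized base-to-top distance
#'   at zero noise is `(1 - theta) d_closed + theta d_open`.
#' @param noise_sigma Gaussian noise s.d. per coordinate (Angstrom),
#'   default 0.1.
#' @param planted_hbonds data frame `donor_res`, `acceptor_res`,
#'   `occupancy` (0..1): residues that receive explicit donor/H/acceptor
#'   side-chain atoms toggled per frame with Bernoulli(occupancy).
#' @param planted_contacts data frame `res_1`, `res_2`, `population`
#'   (0..1): residue pairs with nonpolar side-chain atoms toggled in/out of
#'   contact range.
#' @param charge_scheme one of `"neutral"`, `"polar"`, `"ion_pair"`; see
#'   [assign_toy_parameters()].
#' @param dt_ps frame spacing in ps (default 1, one saved frame per ps).
#' @param seed RNG seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_frames, n_res_per_helix = 8,
                            helices = c(4, 2, 3),
                            d_closed = 33, d_open = 41,
                            schedule = NULL, noise_sigma = 0.1,
                            planted_hbonds = NULL, planted_contacts = NULL,
                            charge_scheme = "neutral", dt_ps = 1,
                            seed = 1L) {
  if (d_open <= d_closed) stop("scenario_config: d_open must exceed d_closed")
  if (is.null(schedule)) schedule <- rep(0, n_frames)
  if (length(schedule) != n_frames) {
    stop("scenario_config: schedule length must equal n_frames")
  }
  if (any(schedule < 0 | schedule > 1)) {
    stop("scenario_config: schedule values must be in [0, 1]")
  }
  if (length(helices) != 3L || helices[1] < 1L || helices[1] > 4L ||
      helices[2] < 0L || helices[2] > 2L || helices[3] < 1L ||
      helices[3] > 3L) {
    stop("scenario_config: helices must be c(base <= 4, hinge <= 2, top <= 3)")
  }
  for (df in list(planted_hbonds, planted_contacts)) {
    if (!is.null(df) && any(df[[3]] < 0 | df[[3]] > 1)) {
      stop("scenario_config: planted probabilities must be in [0, 1]")
    }
  }
  structure(list(n_frames = as.integer(n_frames),
                 n_res_per_helix = as.integer(n_res_per_helix),
                 helices = as.integer(helices),
                 d_closed = d_closed, d_open = d_open,
                 schedule = schedule, noise_sigma = noise_sigma,
                 planted_hbonds = planted_hbonds,
                 planted_contacts = planted_contacts,
                 charge_scheme = charge_scheme, dt_ps = dt_ps,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# internal: static dimer scaffold (topology skeleton, template coordinates,
# helix map, per-chain top-group info). Chain B is chain A rotated 180
# degrees about z (proper rotation; preserves helix handedness and gives an
# exactly C2-symmetric dimer).
build_dimer_scaffold <- function(config) {
  nb <- config$helices[1]; nh <- config$helices[2]; nt <- config$helices[3]
  nres <- config$n_res_per_helix
  base_xy <- list(c(-14, -5), c(-14, 5), c(-7, -5), c(-7, 5))[seq_len(nb)]
  hinge_xy <- list(c(-19, 1), c(-11, 11))[seq_len(nh)]
  top_xy <- list(c(-14, -4), c(-14, 4), c(-7, 0))[seq_len(nt)]
  segs <- list(base = LETTERS[seq_len(nb)],
               hinge = if (nh > 0) c("E", "F")[seq_len(nh)] else character(0),
               top = c("G", "H", "I")[seq_len(nt)])
  coords <- NULL
  at <- NULL
  seg_of_helix <- c(segs$base, segs$hinge, segs$top)
  xy <- c(base_xy, hinge_xy, top_xy)
  zoff <- c(rep(0, nb), rep(8, nh), rep(26, nt))
  res_counter <- 0L
  seg_ranges <- list()
  for (h in seq_along(seg_of_helix)) {
    hx <- build_ideal_helix(nres, origin = c(xy[[h]][1], xy[[h]][2], zoff[h]),
                            atoms = c("N", "CA", "C", "O", "H", "CB"))
    hx$atoms$residue <- hx$atoms$residue + res_counter
    seg_ranges[[seg_of_helix[h]]] <- c(res_counter + 1L, res_counter + nres)
    res_counter <- res_counter + nres
    coords <- rbind(coords, hx$coords)
    at <- rbind(at, hx$atoms)
  }
  n_mono_atoms <- nrow(at)
  n_mono_res <- res_counter
  # chain B: 180 degree rotation about z
  R2 <- diag(c(-1, -1, 1))
  coords_b <- coords %*% R2
  at_b <- at
  at_b$residue <- at_b$residue + n_mono_res
  skeleton <- data.frame(
    atom_id = seq_len(2L * n_mono_atoms),
    name = c(at$name, at_b$name),
    element = c(at$element, at_b$element),
    residue_index = c(at$residue, at_b$residue),
    residue_name = "ALA",
    chain_id = rep(c("A", "B"), each = n_mono_atoms),
    stringsAsFactors = FALSE)
  hm_a <- lapply(seg_ranges, identity)
  hm_b <- lapply(seg_ranges, function(r) r + n_mono_res)
  list(skeleton = skeleton,
       template = rbind(coords, coords_b),
       helix_map_chains = list(A = hm_a, B = hm_b),
       segs = segs, n_mono_res = n_mono_res, n_mono_atoms = n_mono_atoms)
}

#' Assign toy force-field parameters to a topology skeleton
#'
#' Fills masses, Lennard-Jones parameters, partial charges, intrinsic Born
#' radii, HCT screening factors and polarity classes from a small internal
#' per-element table (H, C, N, O). Charge schemes: `"neutral"` (all
#' charges 0), `"polar"` (backbone amide/carbonyl partial charges summing
#' to zero per residue), `"ion_pair"` (neutral plus +1 e / -1 e planted on
#' `ion_atoms`).
#'
#' @param skeleton data frame with at least `atom_id`, `name`, `element`,
#'   `residue_index`, `residue_name`, `chain_id`.
#' @param charge_scheme `"neutral"`, `"polar"` or `"ion_pair"`.
#' @param ion_atoms length-2 integer: row indices receiving +1 and -1 e
#'   under `"ion_pair"`.
#' @return a validated [topology]; the net charge is attached as attribute
#'   `net_charge`.
#' @export
assign_toy_parameters <- function(skeleton,
                                  charge_scheme = c("neutral", "polar",
                                                    "ion_pair"),
                                  ion_atoms = NULL) {
  charge_scheme <- match.arg(charge_scheme)
  elem <- data.frame(
    element = c("H", "C", "N", "O"),
    mass = c(1.008, 12.011, 14.007, 15.999),
    lj_rmin_half = c(0.6, 1.908, 1.824, 1.661),
    lj_epsilon = c(0.0157, 0.1094, 0.17, 0.21),
    born_radius = c(1.3, 1.7, 1.55, 1.5),
    screen_factor = c(0.85, 0.72, 0.79, 0.85),
    polarity_class = c("nonpolar", "nonpolar", "polar", "polar"),
    stringsAsFactors = FALSE)
  m <- match(toupper(skeleton$element), elem$element)
  if (anyNA(m)) {
    stop("assign_toy_parameters: element not in toy table: ",
         paste(unique(skeleton$element[is.na(m)]), collapse = ", "))
  }
  df <- skeleton
  df$mass <- elem$mass[m]
  df$lj_rmin_half <- elem$lj_rmin_half[m]
  df$lj_epsilon <- elem$lj_epsilon[m]
  df$born_radius <- elem$born_radius[m]
  df$screen_factor <- elem$screen_factor[m]
  df$polarity_class <- elem$polarity_class[m]
  df$charge <- 0
  if (charge_scheme == "polar") {
    bb <- c(N = -0.416, H = 0.272, C = 0.597, O = -0.567, CA = 0.114,
            CB = 0)
    known <- df$name %in% names(bb)
    df$charge[known] <- unname(bb[df$name[known]])
  } else if (charge_scheme == "ion_pair") {
    if (is.null(ion_atoms) || length(ion_atoms) != 2L) {
      stop("assign_toy_parameters: ion_pair scheme needs 2 ion_atoms")
    }
    df$charge[ion_atoms[1]] <- 1
    df$charge[ion_atoms[2]] <- -1
  }
  out <- topology(df)
  attr(out, "net_charge") <- sum(df$charge)
  out
}

#' Build one dimer frame at a given open fraction
#'
#' Base and hinge helices stay at the scaffold template; each monomer's top
#' helix group is rigidly translated along its base-to-top direction so that
#' [state_distance()] returns `(1 - theta) d_closed + theta d_open` for both
#' monomers (exact at zero noise).
#'
#' @param config a [scenario_config()].
#' @param theta open fraction in `[0, 1]`.
#' @return list: `frame` (coordinate matrix), `topology`, `helix_map`,
#'   `target_distance`.
#' @export
build_dimer_frame <- function(config, theta) {
  sc <- build_dimer_scaffold(config)
  top <- assign_toy_parameters(sc$skeleton, "neutral")
  hmap <- helix_map(sc$helix_map_chains, top = top)
  fr <- place_top_groups(sc$template, sc, top, hmap, config, theta)
  list(frame = fr, topology = top, helix_map = hmap,
       target_distance = (1 - theta) * config$d_closed +
         theta * config$d_open)
}

# internal: translate both top groups to hit the target state distance
place_top_groups <- function(frame, sc, top, hmap, config, theta) {
  d_target <- (1 - theta) * config$d_closed + theta * config$d_open
  base_idx <- unlist(lapply(c("A", "B"), function(ch) {
    helix_atoms(hmap, top, ch, sc$segs$base)
  }))
  base_com <- center_of_mass(frame, base_idx, top)
  for (ch in c("A", "B")) {
    top_idx <- helix_atoms(hmap, top, ch, sc$segs$top)
    tc <- center_of_mass(frame, top_idx, top)
    u <- tc - base_com
    d0 <- sqrt(sum(u^2))
    u <- u / d0
    shift <- (d_target - d0) * u
    frame[top_idx, ] <- sweep(frame[top_idx, , drop = FALSE], 2L, shift, "+")
  }
  frame
}

#' Generate a synthetic dimer trajectory with ground truth
#'
#' Per frame: the open fraction comes from the schedule; the top groups are
#' placed to realize the scheduled base-to-top distance; i.i.d. Gaussian
#' noise of s.d. `noise_sigma` is added to every scaffold coordinate; then
#' every planted hydrogen bond / hydrophobic contact is toggled with its
#' Bernoulli probability and its interaction-site atoms are positioned with
#' exact bond geometry relative to their (noisy) anchor residues, so the
#' planted occupancies are recovered at any noise level up to binomial
#' sampling error. Fully deterministic for a fixed seed.
#'
#' Planted hydrogen-bond residues get side-chain atoms `ND` (donor N),
#' `HD` (hydrogen) and the acceptor residue an `OA` oxygen; donor-acceptor
#' distance is 2.9 Angstrom (collinear, angle 180 degrees) when formed and
#' 6.0 when broken. Planted contact residues get nonpolar `CG` carbons at
#' 3.4 / 6.5 Angstrom.
#'
#' @param config a [scenario_config()].
#' @return list: `trajectory`, `topology`, `helix_map`, `ground_truth`
#'   (list: `frames` data frame with per-frame `theta`, `d_target`,
#'   `label_A`, `label_B`; `hbonds` / `contacts` data frames with planted
#'   probabilities, atom rows and per-frame presence matrices), `config`.
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sc <- build_dimer_scaffold(config)
  skeleton <- sc$skeleton
  n_scaffold <- nrow(skeleton)

  hb <- config$planted_hbonds
  ct <- config$planted_contacts
  extra <- list()
  if (!is.null(hb)) {
    for (k in seq_len(nrow(hb))) {
      extra[[length(extra) + 1L]] <- data.frame(
        name = c("ND", "HD", "OA"), element = c("N", "H", "O"),
        residue_index = c(hb$donor_res[k], hb$donor_res[k],
                          hb$acceptor_res[k]), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ct)) {
    for (k in seq_len(nrow(ct))) {
      extra[[length(extra) + 1L]] <- data.frame(
        name = c("CG", "CG"), element = c("C", "C"),
        residue_index = c(ct$res_1[k], ct$res_2[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(extra) > 0L) {
    ex <- do.call(rbind, extra)
    res_chain <- skeleton$chain_id[match(ex$residue_index,
                                         skeleton$residue_index)]
    if (anyNA(res_chain)) {
      stop("generate_trajectory: planted residue outside the dimer")
    }
    ex_full <- data.frame(atom_id = NA_integer_, name = ex$name,
                          element = ex$element,
                          residue_index = ex$residue_index,
                          residue_name = "ALA", chain_id = res_chain,
                          stringsAsFactors = FALSE)
    skeleton <- rbind(skeleton, ex_full)
    # keep residues contiguous and atom_ids increasing
    ord <- order(match(skeleton$chain_id, c("A", "B")),
                 skeleton$residue_index)
    skeleton <- skeleton[ord, ]
    skeleton$atom_id <- seq_len(nrow(skeleton))
    rownames(skeleton) <- NULL
  }
  ion_atoms <- NULL
  if (config$charge_scheme == "ion_pair") {
    # CB of the first residue of each chain (C2-related pair across chains)
    ion_atoms <- c(which(skeleton$chain_id == "A" & skeleton$name == "CB")[1],
                   which(skeleton$chain_id == "B" & skeleton$name == "CB")[1])
  }
  top <- assign_toy_parameters(skeleton, config$charge_scheme,
                               ion_atoms = ion_atoms)
  hmap <- helix_map(sc$helix_map_chains, top = top)

  scaffold_rows <- which(!(top$name %in% c("ND", "HD", "OA", "CG")))
  # map template rows (scaffold order) onto reordered topology rows
  tmpl_of_row <- match(paste(top$chain_id, top$residue_index, top$name)[scaffold_rows],
                       paste(sc$skeleton$chain_id, sc$skeleton$residue_index,
                             sc$skeleton$name))
  ca_row <- function(res) {
    which(top$residue_index == res & top$name == "CA")[1]
  }

  n_atoms <- nrow(top)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, config$n_frames))
  hb_present <- if (!is.null(hb)) {
    matrix(NA, nrow = nrow(hb), ncol = config$n_frames)
  } else NULL
  ct_present <- if (!is.null(ct)) {
    matrix(NA, nrow = nrow(ct), ncol = config$n_frames)
  } else NULL

  labels <- character(config$n_frames)
  d_target <- (1 - config$schedule) * config$d_closed +
    config$schedule * config$d_open

  tmpl_top <- assign_toy_parameters(sc$skeleton, "neutral")
  tmpl_hmap <- helix_map(sc$helix_map_chains)
  for (f in seq_len(config$n_frames)) {
    fr_tmpl <- place_top_groups(sc$template, sc, tmpl_top, tmpl_hmap,
                                config, config$schedule[f])
    frame <- matrix(NA_real_, n_atoms, 3L)
    frame[scaffold_rows, ] <- fr_tmpl[tmpl_of_row, ]
    if (config$noise_sigma > 0) {
      frame[scaffold_rows, ] <- frame[scaffold_rows, ] +
        matrix(stats::rnorm(length(scaffold_rows) * 3L,
                            sd = config$noise_sigma),
               ncol = 3L)
    }
    if (!is.null(hb)) {
      for (k in seq_len(nrow(hb))) {
        on <- stats::runif(1) < hb$occupancy[k]
        hb_present[k, f] <- on
        dres <- hb$donor_res[k]; ares <- hb$acceptor_res[k]
        a1 <- frame[ca_row(dres), ]; a2 <- frame[ca_row(ares), ]
        u <- a2 - a1; u <- u / sqrt(sum(u^2))
        nd <- which(top$residue_index == dres & top$name == "ND")
        hd <- which(top$residue_index == dres & top$name == "HD")
        oa <- which(top$residue_index == ares & top$name == "OA")
        dda <- if (on) 2.9 else 6.0
        frame[nd, ] <- a1 + 1.5 * u
        frame[hd, ] <- a1 + 2.5 * u
        frame[oa, ] <- a1 + (1.5 + dda) * u
      }
    }
    if (!is.null(ct)) {
      for (k in seq_len(nrow(ct))) {
        on <- stats::runif(1) < ct$population[k]
        ct_present[k, f] <- on
        r1 <- ct$res_1[k]; r2 <- ct$res_2[k]
        a1 <- frame[ca_row(r1), ]; a2 <- frame[ca_row(r2), ]
        u <- a2 - a1; u <- u / sqrt(sum(u^2))
        cg1 <- which(top$residue_index == r1 & top$name == "CG")
        cg2 <- which(top$residue_index == r2 & top$name == "CG")
        dc <- if (on) 3.4 else 6.5
        frame[cg1, ] <- a1 + 1.5 * u
        frame[cg2, ] <- a1 + (1.5 + dc) * u
      }
    }
    coords[, , f] <- frame
    labels[f] <- classify_state(d_target[f])
  }

  traj <- trajectory(coords, times = (seq_len(config$n_frames) - 1L) *
                       config$dt_ps)
  gt_frames <- data.frame(frame = seq_len(config$n_frames),
                          theta = config$schedule, d_target = d_target,
                          label_A = labels, label_B = labels,
                          stringsAsFactors = FALSE)
  gt <- list(frames = gt_frames)
  if (!is.null(hb)) {
    gt$hbonds <- data.frame(
      donor_res = hb$donor_res, acceptor_res = hb$acceptor_res,
      occupancy = hb$occupancy,
      donor_atom = vapply(hb$donor_res, function(r) {
        which(top$residue_index == r & top$name == "ND")
      }, integer(1)),
      hydrogen_atom = vapply(hb$donor_res, function(r) {
        which(top$residue_index == r & top$name == "HD")
      }, integer(1)),
      acceptor_atom = vapply(hb$acceptor_res, function(r) {
        which(top$residue_index == r & top$name == "OA")
      }, integer(1)))
    gt$hbond_present <- hb_present
  }
  if (!is.null(ct)) {
    gt$contacts <- data.frame(res_1 = ct$res_1, res_2 = ct$res_2,
                              population = ct$population)
    gt$contact_present <- ct_present
  }
  list(trajectory = traj, topology = top, helix_map = hmap,
       ground_truth = gt, config = config)
}
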