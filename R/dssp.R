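#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model of the backbone C=O...H-N interaction used by the
#' DSSP assignment: partial charges +-0.42 e on C/O and +-0.20 e on N/H give
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A backbone hydrogen bond is assigned when `E < -0.5` kcal/mol.
#'
#' @param C_pos,O_pos,N_pos,H_pos length-3 coordinate vectors (Angstrom) of
#'   the acceptor carbonyl C and O and the donor amide N and H.
#' @return energy in kcal/mol.
#' @export
ks_hbond_energy <- function(C_pos, O_pos, N_pos, H_pos) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  r_ON <- d(O_pos, N_pos); r_CH <- d(C_pos, H_pos)
  r_OH <- d(O_pos, H_pos); r_CN <- d(C_pos, N_pos)
  if (min(r_ON, r_CH, r_OH, r_CN) <= 0) {
    stop("ks_hbond_energy: coincident atoms")
  }
  0.084 * 332 * (1 / r_ON + 1 / r_CH - 1 / r_OH - 1 / r_CN)
}

# internal: per-chain backbone index table (residues in order)
backbone_table <- function(top) {
  keep <- top$name %in% c("N", "CA", "C", "O", "H")
  bt <- data.frame(row = which(keep),
                   name = top$name[keep],
                   residue = top$residue_index[keep],
                   chain = top$chain_id[keep],
                   stringsAsFactors = FALSE)
  bt
}

#' DSSP-style secondary-structure assignment for one frame
#'
#' Implements the helix/turn subset of the Kabsch-Sander algorithm: backbone
#' i->i+4 hydrogen bonds (energy below -0.5 kcal/mol) define 4-turns; two
#' consecutive 4-turns starting at i-1 and i mark residues i..i+3 as H
#' (alpha-helix); 3-turns (i->i+3) analogously mark G (3-10 helix) where not
#' already H; residues in isolated turns get T; everything else C. Strand
#' classes are not assigned (intended for all-alpha proteins). Chains
#' shorter than 5 residues are all C.
#'
#' The amide hydrogen must be present in the topology (atom name `H`);
#' assignment is purely geometric, so it is invariant under rigid motion.
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param top a [topology] (or topology skeleton) with backbone N, CA, C, O
#'   and amide H atoms.
#' @return data frame: `residue_index`, `chain_id`, `code` (one of
#'   `"H"`, `"G"`, `"T"`, `"C"`).
#' @export
assign_dssp <- function(frame, top) {
  bt <- backbone_table(top)
  out_res <- integer(0); out_chain <- character(0); out_code <- character(0)
  for (ch in unique(top$chain_id)) {
    cb <- bt[bt$chain == ch, ]
    residues <- sort(unique(top$residue_index[top$chain_id == ch]))
    n <- length(residues)
    code <- rep("C", n)
    if (n >= 5L) {
      pos <- function(res, nm) {
        r <- cb$row[cb$residue == res & cb$name == nm]
        if (length(r) != 1L) return(NULL)
        frame[r, ]
      }
      has_H <- any(cb$name == "H")
      if (!has_H) {
        stop("assign_dssp: amide H atoms absent for chain ", ch)
      }
      hbond <- function(i_acc, j_don) {
        # bond from CO of residues[i_acc] to NH of residues[j_don]
        Cp <- pos(residues[i_acc], "C"); Op <- pos(residues[i_acc], "O")
        Np <- pos(residues[j_don], "N"); Hp <- pos(residues[j_don], "H")
        if (is.null(Cp) || is.null(Op) || is.null(Np) || is.null(Hp)) {
          return(FALSE)
        }
        ks_hbond_energy(Cp, Op, Np, Hp) < -0.5
      }
      turn4 <- vapply(seq_len(n), function(i) {
        i + 4L <= n && hbond(i, i + 4L)
      }, logical(1))
      turn3 <- vapply(seq_len(n), function(i) {
        i + 3L <= n && hbond(i, i + 3L)
      }, logical(1))
      # alpha helix: consecutive 4-turns at i-1 and i -> H for i..i+3
      for (i in 2:n) {
        if (turn4[i - 1L] && turn4[i]) {
          code[i:min(i + 3L, n)] <- "H"
        }
      }
      # 3-10 helix: consecutive 3-turns, not overriding H
      for (i in 2:n) {
        if (turn3[i - 1L] && turn3[i]) {
          span <- i:min(i + 2L, n)
          code[span][code[span] == "C"] <- "G"
        }
      }
      # isolated turns
      for (i in which(turn4)) {
        span <- i:min(i + 4L, n)
        code[span][code[span] == "C"] <- "T"
      }
      for (i in which(turn3)) {
        span <- i:min(i + 3L, n)
        code[span][code[span] == "C"] <- "T"
      }
    }
    out_res <- c(out_res, residues)
    out_chain <- c(out_chain, rep(ch, n))
    out_code <- c(out_code, code)
  }
  data.frame(residue_index = out_res, chain_id = out_chain, code = out_code,
             stringsAsFactors = FALSE)
}

#' Helical fraction time series
#'
#' Fraction of residues in a range assigned H or G, per frame.
#'
#' @param traj a [trajectory].
#' @param top a [topology].
#' @param residue_range integer vector of residue indices to score.
#' @return numeric vector, one fraction in `[0, 1]` per frame.
#' @export
helix_fraction_series <- function(traj, top, residue_range) {
  residue_range <- intersect(residue_range, unique(top$residue_index))
  if (length(residue_range) == 0L) {
    stop("helix_fraction_series: empty residue range")
  }
  vapply(seq_len(traj$n_frames), function(i) {
    sse <- assign_dssp(get_frame(traj, i), top)
    sub <- sse[sse$residue_index %in% residue_range, ]
    mean(sub$code %in% c("H", "G"))
  }, numeric(1))
}

#' Per-frame x per-residue secondary-structure matrix
#'
#' @param traj a [trajectory].
#' @param top a [topology].
#' @return character matrix `n_frames x n_residues`, one code per cell;
#'   columns named by residue index.
#' @export
dssp_matrix <- function(traj, top) {
  first <- assign_dssp(get_frame(traj, 1L), top)
  m <- matrix("C", nrow = traj$n_frames, ncol = nrow(first),
              dimnames = list(NULL, first$residue_index))
  m[1L, ] <- first$code
  if (traj$n_frames > 1L) {
    for (i in 2:traj$n_frames) {
      m[i, ] <- assign_dssp(get_frame(traj, i), top)$code
    }
  }
  m
}
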