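# shared fixtures built in code

# minimal point-particle topology: one atom per residue, one residue per
# chain entry; element C unless overridden
point_topology <- function(n, chain = rep("A", n), element = rep("C", n),
                           name = paste0("X", seq_len(n)),
                           mass = rep(12, n), charge = rep(0, n),
                           rmin_half = rep(1.908, n), eps = rep(0.1094, n),
                           born = rep(1.7, n), screen = rep(0.72, n),
                           polarity = rep("nonpolar", n),
                           residue = seq_len(n)) {
  topology(data.frame(
    atom_id = seq_len(n), name = name, element = element,
    residue_index = residue, residue_name = "ALA", chain_id = chain,
    mass = mass, charge = charge, lj_rmin_half = rmin_half,
    lj_epsilon = eps, born_radius = born, screen_factor = screen,
    polarity_class = polarity, stringsAsFactors = FALSE))
}

# ideal-helix topology skeleton -> toy topology
helix_topology <- function(hx, chain = "A", scheme = "neutral") {
  sk <- data.frame(atom_id = seq_len(nrow(hx$coords)), name = hx$atoms$name,
                   element = hx$atoms$element,
                   residue_index = hx$atoms$residue, residue_name = "ALA",
                   chain_id = chain, stringsAsFactors = FALSE)
  assign_toy_parameters(sk, scheme)
}

# random rigid motion (proper rotation + translation)
random_rigid_motion <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(frame, rm) {
  sweep(frame %*% t(rm$R), 2L, rm$t, "+")
}

# uniform random rotations (quaternion method), n x 9 row-major matrices
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  cbind(1 - 2 * (q[, 3]^2 + q[, 4]^2),
        2 * (q[, 2] * q[, 3] - q[, 1] * q[, 4]),
        2 * (q[, 2] * q[, 4] + q[, 1] * q[, 3]),
        2 * (q[, 2] * q[, 3] + q[, 1] * q[, 4]),
        1 - 2 * (q[, 2]^2 + q[, 4]^2),
        2 * (q[, 3] * q[, 4] - q[, 1] * q[, 2]),
        2 * (q[, 2] * q[, 4] - q[, 1] * q[, 3]),
        2 * (q[, 3] * q[, 4] + q[, 1] * q[, 2]),
        1 - 2 * (q[, 2]^2 + q[, 3]^2))
}

# brute-force RMSD oracle: min over sampled rotations after centroid
# alignment; rmsd^2 = (|P0|^2 + |Q0|^2 - 2 tr(R M)) / n, and tr(R M) is a
# dot product of the row-major rotation with the column-major vec(M)
brute_force_rmsd <- function(P, Q, rotations) {
  P0 <- sweep(P, 2L, colMeans(P))
  Q0 <- sweep(Q, 2L, colMeans(Q))
  M <- crossprod(P0, Q0)
  tr <- rotations %*% as.numeric(M)
  sqrt(max(0, (sum(P0^2) + sum(Q0^2) - 2 * max(tr)) / nrow(P)))
}
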