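#' All-pairs RMSD matrix
#'
#' Computes the Kabsch-minimal RMSD between every pair of frames over an
#' atom selection. The computation is fully vectorized: per-frame centered
#' coordinate blocks give the 3x3 cross-covariance of every pair through
#' nine frame-by-frame matrix products, and the singular values needed by
#' the Kabsch formula come from a closed-form symmetric 3x3
#' eigendecomposition evaluated elementwise over all pairs.
#'
#' @param traj a [trajectory].
#' @param selection atom row indices (default all).
#' @return symmetric `n_frames x n_frames` matrix (Angstrom) with zero
#'   diagonal.
#' @export
pairwise_rmsd_matrix <- function(traj, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(traj$n_atoms)
  n_sel <- length(selection)
  if (n_sel < 3L) stop("pairwise_rmsd_matrix: need at least 3 atoms")
  f <- traj$n_frames
  # centered coordinate blocks, one F x n matrix per axis
  Xa <- vector("list", 3L)
  for (a in 1:3) {
    m <- t(traj$coords[selection, a, , drop = TRUE])
    if (f == 1L) m <- matrix(traj$coords[selection, a, 1], nrow = 1L)
    Xa[[a]] <- m - rowMeans(m)
  }
  ssq <- Xa[[1]]^2 %*% rep(1, n_sel) + Xa[[2]]^2 %*% rep(1, n_sel) +
    Xa[[3]]^2 %*% rep(1, n_sel)
  ssq <- as.numeric(ssq)
  # M[a,b] for every frame pair: M_ab[i,j] = sum_k X_a[i,k] X_b[j,k]
  M <- vector("list", 9L)
  dim(M) <- c(3L, 3L)
  for (a in 1:3) for (b in 1:3) M[[a, b]] <- tcrossprod(Xa[[a]], Xa[[b]])
  # A = M^T M (symmetric PSD); unique entries
  A11 <- M[[1, 1]]^2 + M[[2, 1]]^2 + M[[3, 1]]^2
  A22 <- M[[1, 2]]^2 + M[[2, 2]]^2 + M[[3, 2]]^2
  A33 <- M[[1, 3]]^2 + M[[2, 3]]^2 + M[[3, 3]]^2
  A12 <- M[[1, 1]] * M[[1, 2]] + M[[2, 1]] * M[[2, 2]] + M[[3, 1]] * M[[3, 2]]
  A13 <- M[[1, 1]] * M[[1, 3]] + M[[2, 1]] * M[[2, 3]] + M[[3, 1]] * M[[3, 3]]
  A23 <- M[[1, 2]] * M[[1, 3]] + M[[2, 2]] * M[[2, 3]] + M[[3, 2]] * M[[3, 3]]
  detM <- M[[1, 1]] * (M[[2, 2]] * M[[3, 3]] - M[[2, 3]] * M[[3, 2]]) -
    M[[1, 2]] * (M[[2, 1]] * M[[3, 3]] - M[[2, 3]] * M[[3, 1]]) +
    M[[1, 3]] * (M[[2, 1]] * M[[3, 2]] - M[[2, 2]] * M[[3, 1]])
  rm(M)
  # closed-form eigenvalues of symmetric 3x3 (trigonometric method)
  q <- (A11 + A22 + A33) / 3
  p2 <- (A11 - q)^2 + (A22 - q)^2 + (A33 - q)^2 +
    2 * (A12^2 + A13^2 + A23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  B11 <- A11 - q; B22 <- A22 - q; B33 <- A33 - q
  detB <- B11 * (B22 * B33 - A23^2) - A12 * (A12 * B33 - A23 * A13) +
    A13 * (A12 * A23 - B22 * A13)
  safe_p <- ifelse(p > 0, p, 1)
  rr <- pmin(pmax(detB / (2 * safe_p^3), -1), 1)
  phi <- acos(rr) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  s1 <- sqrt(pmax(e1, 0)); s2 <- sqrt(pmax(e2, 0)); s3 <- sqrt(pmax(e3, 0))
  tr_opt <- s1 + s2 + sign(detM) * s3
  d2 <- (outer(ssq, ssq, "+") - 2 * tr_opt) / n_sel
  out <- sqrt(pmax(d2, 0))
  out <- (out + t(out)) / 2
  diag(out) <- 0
  out
}

#' Average-linkage agglomerative clustering of an RMSD matrix
#'
#' Runs `stats::hclust(method = "average")` on the distance matrix and cuts
#' the tree either at a fixed cluster count or at a merge-distance cutoff.
#' Output is deterministic for a fixed input; cluster labels are assigned in
#' order of first appearance along the frame sequence.
#'
#' @param matrix symmetric pairwise RMSD matrix (Angstrom).
#' @param n_clusters number of clusters to cut at (exclusive with
#'   `merge_cutoff`).
#' @param merge_cutoff merge height cutoff in Angstrom (exclusive with
#'   `n_clusters`).
#' @return list of class `cluster_result`: `labels` (integer per frame),
#'   `populations` (percent per cluster, summing to 100), `representatives`
#'   (frame index per cluster, see [representative_frame()]), `n_clusters`,
#'   `hclust` (the tree).
#' @export
average_linkage_cluster <- function(matrix, n_clusters = NULL,
                                    merge_cutoff = NULL) {
  if (is.null(n_clusters) == is.null(merge_cutoff)) {
    stop("give exactly one of n_clusters or merge_cutoff")
  }
  if (!isSymmetric(unname(matrix), tol = 1e-8)) {
    stop("average_linkage_cluster: matrix must be symmetric")
  }
  hc <- stats::hclust(stats::as.dist(matrix), method = "average")
  labels <- if (!is.null(n_clusters)) {
    stats::cutree(hc, k = n_clusters)
  } else {
    stats::cutree(hc, h = merge_cutoff)
  }
  # relabel in order of first appearance for reproducible numbering
  first_seen <- unique(labels)
  labels <- match(labels, first_seen)
  k <- max(labels)
  populations <- as.numeric(round(100 * tabulate(labels, k) / length(labels),
                                  2))
  reps <- vapply(seq_len(k), function(cl) {
    representative_frame(matrix, which(labels == cl))
  }, integer(1))
  structure(list(labels = labels, populations = populations,
                 representatives = reps, n_clusters = k, hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%d clusters over %d frames\n", x$n_clusters,
              length(x$labels)))
  for (cl in seq_len(x$n_clusters)) {
    cat(sprintf("  cluster %d: %5.2f%%  representative frame %d\n",
                cl, x$populations[cl], x$representatives[cl]))
  }
  invisible(x)
}

#' Representative (nearest-to-center) frame of a cluster
#'
#' The member minimizing the mean RMSD to the other members; ties break to
#' the lowest frame index.
#'
#' @param matrix pairwise RMSD matrix.
#' @param member_indices frame indices of the cluster members.
#' @return a single frame index.
#' @export
representative_frame <- function(matrix, member_indices) {
  member_indices <- sort(as.integer(member_indices))
  if (length(member_indices) == 0L) {
    stop("representative_frame: empty cluster")
  }
  if (length(member_indices) == 1L) return(member_indices)
  sub <- matrix[member_indices, member_indices, drop = FALSE]
  mean_d <- rowSums(sub) / (length(member_indices) - 1L)
  member_indices[which.min(mean_d)]
}
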