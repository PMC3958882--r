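#' Mass-weighted center of a selection
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param selection integer atom indices.
#' @param top a [topology] supplying masses.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(frame, selection, top) {
  if (length(selection) == 0L) stop("center_of_mass: empty selection")
  m <- top$mass[selection]
  xyz <- frame[selection, , drop = FALSE]
  colSums(xyz * m) / sum(m)
}

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms of `mobile` onto `reference` (SVD-based Kabsch algorithm,
#' with the determinant sign correction that forbids reflections).
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices.
#' @param selection integer atom indices used for the fit (default all).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that aligned = mobile %*% t(rotation) + translation, and `rmsd`
#'   (Angstrom) over the selection after alignment.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) {
    if (nrow(mobile) != nrow(reference)) {
      stop("kabsch_superpose: atom count mismatch")
    }
    selection <- seq_len(nrow(mobile))
  }
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference)) {
    stop("kabsch_superpose: selection exceeds atom count")
  }
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("kabsch_superpose: selection count mismatch")
  if (nrow(P) < 3L) stop("kabsch_superpose: need at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  # degenerate (collinear) selections leave the rotation under-determined
  if (sum(svd(P0, nu = 0, nv = 0)$d > 1e-8) < 2L ||
      sum(svd(Q0, nu = 0, nv = 0)$d > 1e-8) < 2L) {
    stop("kabsch_superpose: degenerate (collinear) selection")
  }
  M <- crossprod(P0, Q0)           # 3x3 covariance
  sv <- svd(M)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)      # rotation: aligned = P0 %*% t(R)
  ssd <- sum(P0^2) + sum(Q0^2) - 2 * sum(sv$d * c(1, 1, d))
  rmsd <- sqrt(max(ssd, 0) / nrow(P))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' Apply a superposition to a full frame
#'
#' @param frame `n x 3` matrix.
#' @param fit result of [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(frame, fit) {
  sweep(frame %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' RMSD time series against a reference frame
#'
#' Each frame is optimally superposed (Kabsch) onto the reference over the
#' selection, and the post-fit RMSD is reported.
#'
#' @param traj a [trajectory].
#' @param reference `n_atoms x 3` reference coordinates.
#' @param selection integer atom indices (default all).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  vapply(seq_len(traj$n_frames), function(i) {
    kabsch_superpose(get_frame(traj, i), reference, selection)$rmsd
  }, numeric(1))
}

#' Root-mean-square fluctuation about the aligned mean structure
#'
#' Frames are iteratively superposed onto their running average structure
#' until the average moves by less than `tol` (max atom displacement),
#' then `RMSF_i = sqrt(mean_f |x_i(f) - xbar_i|^2)` is reported per selected
#' atom.
#'
#' @param traj a [trajectory] with at least 2 frames.
#' @param selection integer atom indices (default all); both the fit and the
#'   report use this selection.
#' @param tol convergence threshold on the mean structure (Angstrom).
#' @param max_iter iteration cap.
#' @return numeric vector of per-atom RMSF (Angstrom), one per selected atom.
#' @export
rmsf <- function(traj, selection = NULL, tol = 1e-6, max_iter = 50L) {
  if (traj$n_frames < 2L) stop("rmsf: need at least 2 frames")
  if (is.null(selection)) selection <- seq_len(traj$n_atoms)
  frames <- lapply(seq_len(traj$n_frames), function(i) {
    get_frame(traj, i)[selection, , drop = FALSE]
  })
  ref <- frames[[1L]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(frames, function(fr) {
      fit <- kabsch_superpose(fr, ref)
      apply_superposition(fr, fit)
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    shift <- max(abs(new_mean - ref))
    ref <- new_mean
    frames <- aligned
    if (shift < tol) break
  }
  dev2 <- Reduce(`+`, lapply(frames, function(fr) rowSums((fr - ref)^2)))
  sqrt(dev2 / length(frames))
}

#' Ordinary least-squares trend of a time series window
#'
#' @param times numeric vector (ps).
#' @param values numeric vector, same length.
#' @param window optional length-2 vector `c(t_min, t_max)` restricting the
#'   fit (inclusive); default uses all points.
#' @return list of class `trend_fit`: `slope` (units of values per ps),
#'   `intercept`, `mean` (mean of the fitted values window), `n`.
#' @export
linear_trend <- function(times, values, window = NULL) {
  stopifnot(length(times) == length(values))
  keep <- if (is.null(window)) rep(TRUE, length(times)) else {
    times >= window[1] & times <= window[2]
  }
  t <- times[keep]; y <- values[keep]
  if (length(t) < 2L) stop("linear_trend: need at least 2 points in window")
  if (diff(range(t)) == 0) stop("linear_trend: all times identical")
  fit <- stats::lm.fit(cbind(1, t), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 mean = mean(y), n = length(y)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: slope %.6g /ps, intercept %.6g, mean %.6g (n=%d)\n",
              x$slope, x$intercept, x$mean, x$n))
  invisible(x)
}
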