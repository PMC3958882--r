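## Quasi-harmonic configurational entropy from the mass-weighted coordinate
## covariance of a trajectory. This estimator stands in for force-field
## normal-mode (Hessian) analysis: each covariance eigenvalue lambda
## (amu A^2) defines an effective oscillator frequency
## omega = sqrt(kB T / lambda), scored with the quantum harmonic-oscillator
## entropy. Rigid-body modes are removed by superposition and appear as
## near-zero eigenvalues, which are discarded.

KB_KCAL <- 0.0019872041       # kcal/(mol K)
HBAR_KCAL_PS <- 0.01517873    # kcal ps / mol  (hbar * N_A)
KCAL_TO_AMU_A2_PS2 <- 418.4   # 1 kcal/mol in amu A^2/ps^2

#' Quasi-harmonic configurational entropy
#'
#' @param traj a [trajectory] (>= 2 frames; at least `3 n_atoms + 1` frames
#'   are needed for a full mode set, otherwise the spectrum is truncated at
#'   the covariance rank with a warning).
#' @param top a [topology] supplying masses.
#' @param T temperature in K (default 300).
#' @param selection atom row indices (default all).
#' @param align superpose frames onto their iteratively refined mean
#'   structure before the covariance (default `TRUE`). Set `FALSE` only for
#'   inputs that are already aligned or for controlled tests.
#' @param eig_tol eigenvalues (amu A^2) at or below this are treated as
#'   unpopulated (rigid-body or numerical) and discarded.
#' @return list of class `entropy_estimate`: `T` (K), `minus_T_S`
#'   (kcal/mol, `-T * S`), `S` (kcal/(mol K)), `n_modes` used.
#' @export
quasiharmonic_entropy <- function(traj, top, T = 300, selection = NULL,
                                  align = TRUE, eig_tol = 1e-6) {
  if (traj$n_frames < 2L) stop("quasiharmonic_entropy: need >= 2 frames")
  if (is.null(selection)) selection <- seq_len(traj$n_atoms)
  frames <- lapply(seq_len(traj$n_frames), function(i) {
    get_frame(traj, i)[selection, , drop = FALSE]
  })
  if (align) {
    ref <- frames[[1L]]
    for (it in seq_len(50L)) {
      frames <- lapply(frames, function(fr) {
        apply_superposition(fr, kabsch_superpose(fr, ref))
      })
      new_mean <- Reduce(`+`, frames) / length(frames)
      conv <- max(abs(new_mean - ref)) < 1e-6
      ref <- new_mean
      if (conv) break
    }
  }
  sq_m <- sqrt(rep(top$mass[selection], each = 1L))
  X <- t(vapply(frames, function(fr) as.numeric(fr * sq_m),
                numeric(3L * length(selection))))
  n_dof <- ncol(X)
  if (nrow(X) - 1L < n_dof) {
    warning("quasiharmonic_entropy: fewer frames than degrees of freedom; ",
            "mode set truncated at the covariance rank")
  }
  C <- stats::cov(X)
  lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > eig_tol]
  if (length(lambda) == 0L) {
    out <- list(T = T, minus_T_S = 0, S = 0, n_modes = 0L)
    class(out) <- "entropy_estimate"
    return(out)
  }
  omega <- sqrt(KB_KCAL * T * KCAL_TO_AMU_A2_PS2 / lambda)  # 1/ps
  a <- HBAR_KCAL_PS * omega / (KB_KCAL * T)
  S <- KB_KCAL * sum(a / (exp(a) - 1) - log(1 - exp(-a)))
  out <- list(T = T, minus_T_S = -T * S, S = S, n_modes = length(lambda))
  class(out) <- "entropy_estimate"
  out
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf(
    "quasi-harmonic entropy at %g K: -T*S = %.4f kcal/mol (%d modes)\n",
    x$T, x$minus_T_S, x$n_modes))
  invisible(x)
}
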