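#' Optimal rigid superposition of two paired point sets
#'
#' Computes the proper rotation and translation minimizing the root mean
#' square deviation between two conformations of the same point set
#' (rows are points, columns x/y/z), by SVD of the cross-covariance matrix.
#' The SVD sign is corrected so the returned rotation is always proper
#' (determinant +1, never a reflection).
#'
#' The convention is row-vector: the aligned copy of `P` is
#' `sweep(P, 2, cp) %*% rotation + matrix(cq, ...)`, i.e. `P` is moved onto
#' `Q`. For degenerate input (all points coincident) the rotation is the
#' identity by convention and the RMSD is still reported.
#'
#' @param P Numeric n x 3 matrix, the mobile point set.
#' @param Q Numeric n x 3 matrix, the reference point set.
#' @return A list with elements `rotation` (3 x 3, det +1), `translation`
#'   (length-3; `aligned = P %*% rotation + translation` rowwise), `rmsd`
#'   (minimal RMSD) and `aligned` (the superposed copy of `P`).
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- kabsch_superpose(P %*% R + 2, P)
#' fit$rmsd  # ~0: a rigid transform is fully removed
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be n x 3 matrices with equal row counts (",
         nrow(P), " vs ", nrow(Q), ")")
  if (nrow(P) < 1L) stop("need at least one point")
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stop("coordinates must be finite")

  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)                       # 3x3 cross-covariance

  if (sum(H * H) < .Machine$double.eps) {
    R <- diag(3)                               # coincident points: identity
  } else {
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v) # row-convention rotation
  }
  aligned <- Pc %*% R + matrix(cq, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(rotation = R,
       translation = as.numeric(cq - cp %*% R),
       rmsd = rmsd,
       aligned = aligned)
}

#' Coordinate-prediction (CRD) loss
#'
#' Mean squared per-coordinate error between a predicted C-alpha trace and
#' the ground-truth structure after optimal rigid superposition of the
#' prediction onto the target. Because the superposition is itself the
#' minimizer, the loss can never exceed the plain MSE, and any rigid motion
#' of the prediction leaves it unchanged.
#'
#' @param predicted Numeric n x 3 matrix of predicted coordinates.
#' @param target Numeric n x 3 matrix of ground-truth coordinates.
#' @param gradient If `TRUE`, also return the gradient of the loss with
#'   respect to `predicted` (exact at the optimum by the envelope theorem).
#' @return The loss (nonnegative scalar); with `gradient = TRUE`, a list
#'   with elements `loss` and `gradient`.
#' @export
crd_loss <- function(predicted, target, gradient = FALSE) {
  predicted <- as.matrix(predicted); target <- as.matrix(target)
  if (nrow(predicted) != nrow(target))
    stop("shape mismatch: prediction has ", nrow(predicted),
         " residues, target has ", nrow(target))
  fit <- kabsch_superpose(predicted, target)
  resid <- fit$aligned - target
  loss <- mean(resid^2)
  if (!gradient) return(loss)
  # holding the optimal (R, t) fixed is exact: both are inner minimizers
  g <- (2 / length(resid)) * resid %*% t(fit$rotation)
  list(loss = loss, gradient = g)
}
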