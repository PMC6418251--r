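#' Kabsch superposition of two point sets
#'
#' Least-squares rigid-body fit of \code{mobile} onto \code{reference} via
#' the SVD of the cross-covariance matrix, with the reflection excluded by
#' sign-correcting the smallest singular vector so the returned rotation is
#' proper (det = +1). The transform maps mobile rows as
#' \code{mobile \%*\% rotation + translation}.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, non-collinear
#' @param weights optional non-negative per-point weights
#' @return a \linkS4class{SuperpositionResult}
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    .stopf("mobile and reference must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) .stopf("superposition needs at least 3 points, got %d", n)
  w <- if (is.null(weights)) rep(1, n) else {
    if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
      .stopf("weights must be %d non-negative values with positive sum", n)
    weights
  }
  w <- w / sum(w)
  cmM <- colSums(mobile * w)
  cmR <- colSums(reference * w)
  A <- sweep(mobile, 2, cmM)
  B <- sweep(reference, 2, cmR)
  H <- crossprod(A * w, B)           # 3x3 weighted cross-covariance
  s <- svd(H)
  # collinear/degenerate configurations have rank < 2
  sv <- svd(A)$d
  if (sv[2] <= 1e-8 * max(sv[1], 1e-12))
    .stopf("degenerate (collinear) point configuration; cannot superpose")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cmR - cmM %*% R), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param coordMatrix n x 3 matrix
#' @param fit a \linkS4class{SuperpositionResult}
#' @return transformed n x 3 matrix
#' @export
applySuperposition <- function(coordMatrix, fit) {
  sweep(as.matrix(coordMatrix) %*% fit@rotation, 2, -fit@translation)
}
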