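#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the root-mean-square
#' deviation between two paired point sets.
#'
#' @param ref N x 3 matrix of reference coordinates (Angstrom).
#' @param mov N x 3 matrix of mobile coordinates, paired with `ref` by row.
#' @return A list with elements `rotation` (3 x 3 proper rotation matrix,
#'   determinant +1), `translation` (length-3 vector) and `rmsd` (Angstrom).
#'   The fitted coordinates are `mov %*% t(rotation)` plus the translation,
#'   row-wise; see [applyTransform()].
#' @details The closed-form SVD solution is used. For degenerate (collinear)
#'   point sets the returned rotation is still a valid minimizer of the RMSD,
#'   but it is no longer unique; no error is raised.
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit <- superpose(ref, ref + 5)
#' fit$rmsd   # 0
#' @export
superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!is.numeric(ref) || !is.numeric(mov))
    stop("coordinates must be numeric")
  if (ncol(ref) != 3L || ncol(mov) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(ref) != nrow(mov))
    stop("point sets must be paired: ", nrow(ref), " vs ", nrow(mov), " rows")
  if (nrow(ref) < 3L)
    stop("at least 3 paired points are required, got ", nrow(ref))
  if (any(!is.finite(ref)) || any(!is.finite(mov)))
    stop("coordinates must be finite")

  cref <- colMeans(ref)
  cmov <- colMeans(mov)
  P <- sweep(mov, 2L, cmov)     # mobile, centered
  Q <- sweep(ref, 2L, cref)     # reference, centered

  C <- crossprod(P, Q)          # 3 x 3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)

  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  translation <- as.numeric(cref - R %*% cmov)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 coordinate matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return Transformed N x 3 matrix: each row `x` becomes `rotation %*% x +
#'   translation`.
#' @export
applyTransform <- function(coords, rotation, translation) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(rotation), 2L, translation, "+")
}

## angle between two 3-vectors, degrees
vec_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cosang <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

## rotation matrix from ZYZ Euler angles (radians)
euler_rotation <- function(a, b, g) {
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry  <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

## all pairwise Euclidean distances between rows of a and rows of b
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## evaluate expr with a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
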