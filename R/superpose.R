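# Rigid-body transforms are lists with a 3x3 rotation `R` (det +1) and a
# length-3 translation `t`, acting as x -> R x + t (coordinates as rows are
# transformed with tcrossprod).

#' Create a rigid transform
#'
#' @param R 3x3 orthonormal rotation matrix with determinant +1.
#' @param t Length-3 translation vector (Angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- unname(as.matrix(R))
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$R) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.1f deg, |t| = %.2f A\n",
              ang, sqrt(sum(x$t^2))))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tf A [rigid_transform()].
#' @param xyz An n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
transform_coords <- function(tf, xyz) {
  xyz <- rbind(xyz)
  sweep(tcrossprod(xyz, tf$R), 2, -tf$t)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#'
#' @param tf A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.vector(-t(tf$R) %*% tf$t))
}

#' Rotation about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle Rotation angle in radians.
#' @param t Optional translation.
#' @return A [rigid_transform()].
#' @export
axis_rotation <- function(axis = c("z", "x", "y"), angle, t = c(0, 0, 0)) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  R <- switch(axis,
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE)
  )
  rigid_transform(R, t)
}

#' @keywords internal
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

#' @keywords internal
rotation_axis <- function(R) {
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  ax <- Re(e$vectors[, i])
  ax / sqrt(sum(ax^2))
}

#' Least-squares (Kabsch) superposition of two point sets
#'
#' Finds the rigid transform minimizing the RMSD between `transform(mobile)`
#' and `target`, points matched by row.
#'
#' @param mobile,target n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return A list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (post-superposition RMSD in Angstrom).
#' @export
#' @examples
#' pts <- matrix(rnorm(30), ncol = 3)
#' superpose(pts, pts)$rmsd # 0
superpose <- function(mobile, target) {
  mobile <- rbind(mobile); target <- rbind(target)
  if (nrow(mobile) != nrow(target)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  sv_a <- svd(A)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1)) {
    stop("points are collinear; superposition is degenerate")
  }
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ct - as.vector(R %*% cm)
  tf <- rigid_transform(R, t_vec)
  moved <- transform_coords(tf, mobile)
  list(transform = tf, rmsd = sqrt(mean(rowSums((moved - target)^2))))
}
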