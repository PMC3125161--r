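#' Rigid-body transformation
#'
#' Constructs a proper rigid transformation (rotation + translation) acting
#' on row-wise 3D coordinates as `x -> R x + t`.  An *undefined* transform
#' (returned by [kabsch()] when fewer than three point pairs are available)
#' carries `defined = FALSE`; callers must fall back rather than error.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 translation vector, in Angstrom.
#' @param defined logical; `FALSE` marks the "not defined" sentinel.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            defined = TRUE) {
  if (defined) {
    stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
              length(translation) == 3L)
  }
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 defined = isTRUE(defined)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
undefined_transform <- function() {
  rigid_transform(NULL, NULL, defined = FALSE)
}

#' @param x object to test / print.
#' @rdname rigid_transform
#' @export
is_defined <- function(x) {
  inherits(x, "rigid_transform") && isTRUE(x$defined)
}

#' @param ... ignored.
#' @rdname rigid_transform
#' @export
print.rigid_transform <- function(x, ...) {
  if (!is_defined(x)) {
    cat("<rigid_transform: undefined>\n")
  } else {
    cat("<rigid_transform>\nrotation:\n")
    print(round(x$rotation, 6))
    cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  }
  invisible(x)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum_i ||R p_i + t - q_i||^2` over paired points, via SVD of the
#' cross-covariance matrix with the usual determinant sign correction so
#' that reflections are never returned.  With fewer than three point pairs
#' the transformation is declared *not defined* and an undefined sentinel
#' is returned (not an error: alignment code must fall back to a coarser
#' transform).
#'
#' Degenerate (e.g. collinear) point sets still return the SVD solution;
#' the minimiser may then be non-unique, but the returned rotation is
#' always proper.
#'
#' @param P,Q n x 3 coordinate matrices of corresponding points (P is
#'   mapped onto Q).
#' @return A [rigid_transform()]; undefined when `nrow(P) < 3`.
#' @export
#' @examples
#' P <- matrix(rnorm(18), 6, 3)
#' tr <- kabsch(P, P)
#' max(abs(tr$rotation - diag(3)))  # ~0
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3L) return(undefined_transform())
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)            # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                # fully degenerate cross-covariance
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  rigid_transform(R, t)
}

#' Apply a rigid transformation to coordinates
#'
#' @param tr a defined [rigid_transform()].
#' @param pts k x 3 coordinate matrix (a bare length-3 vector is accepted).
#' @return k x 3 matrix of transformed coordinates.
#' @export
transform_coords <- function(tr, pts) {
  stopifnot(is_defined(tr))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  sweep(pts %*% t(tr$rotation), 2L, tr$translation, "+")
}

#' Invert a rigid transformation
#'
#' @param tr a defined [rigid_transform()].
#' @return The analytic inverse `x -> R^T (x - t)`.
#' @export
invert_transform <- function(tr) {
  stopifnot(is_defined(tr))
  rigid_transform(t(tr$rotation), -as.numeric(t(tr$rotation) %*% tr$translation))
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param P,Q n x 3 coordinate matrices.
#' @return RMSD in Angstrom (non-negative; 0 iff identical).
#' @export
rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(all(dim(P) == dim(Q)))
  sqrt(mean(rowSums((P - Q)^2)))
}

#' RMSD after optimal superposition
#'
#' Convenience wrapper: Kabsch-fit P onto Q, then measure the residual RMSD.
#'
#' @inheritParams rmsd
#' @return Superposed RMSD in Angstrom, or `NA` when the fit is undefined.
#' @export
kabsch_rmsd <- function(P, Q) {
  tr <- kabsch(P, Q)
  if (!is_defined(tr)) return(NA_real_)
  rmsd(transform_coords(tr, P), Q)
}

#' Uniformly random proper rotation matrix
#'
#' Quaternion method: a unit quaternion drawn uniformly on S^3 is mapped to
#' SO(3).  Uses the current RNG stream.
#'
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

# unit quaternion (w,x,y,z) -> rotation matrix
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

# rotation about an arbitrary unit axis by angle (radians), Rodrigues form
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
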