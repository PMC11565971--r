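# Homogeneous affine transforms on (ap, dv, ml) coordinates.
#
# Coordinate frame used throughout the package: columns (ap, dv, ml), all in
# micrometers. AP increases posteriorly, DV increases ventrally, ML is signed
# with the midline at 0. Section index k corresponds to AP = k * section_um.

#' Identity affine transform
#'
#' Affine transforms are represented as 4x4 homogeneous matrices acting on
#' column vectors c(ap, dv, ml, 1).
#'
#' @return A 4x4 identity matrix.
#' @export
aff_identity <- function() diag(4)

#' Translation transform
#'
#' @param t Numeric length-3 translation c(ap, dv, ml) in micrometers.
#' @return A 4x4 affine matrix.
#' @export
aff_translation <- function(t) {
  stopifnot(length(t) == 3, all(is.finite(t)))
  m <- diag(4)
  m[1:3, 4] <- as.numeric(t)
  m
}

#' Axis-aligned scaling transform
#'
#' @param ap,dv,ml Scale factors per axis (must be positive).
#' @return A 4x4 affine matrix.
#' @export
aff_scale <- function(ap = 1, dv = 1, ml = 1) {
  if (any(c(ap, dv, ml) <= 0)) stop("scale factors must be positive")
  diag(c(ap, dv, ml, 1))
}

#' Shear of the AP axis by the ML coordinate
#'
#' Implements ap' = ap + s * ml, the left/right asymmetry compensation used
#' in coronal-section registration.
#'
#' @param s Shear coefficient (dimensionless, AP micrometers per ML micrometer).
#' @return A 4x4 affine matrix.
#' @export
aff_shear_ap_ml <- function(s) {
  stopifnot(is.finite(s))
  m <- diag(4)
  m[1, 3] <- s
  m
}

#' Apply an affine transform to a point matrix
#'
#' @param m A 4x4 affine matrix.
#' @param pts An n x 3 matrix (or length-3 vector) of (ap, dv, ml) coordinates.
#' @return An n x 3 matrix of transformed coordinates.
#' @export
apply_affine <- function(m, pts) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  out <- cbind(pts, 1) %*% t(m)
  out[, 1:3, drop = FALSE]
}

#' Invert an affine transform
#'
#' @param m A 4x4 affine matrix.
#' @return The inverse 4x4 matrix.
#' @export
aff_invert <- function(m) {
  d <- det(m[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) {
    stop("affine transform is not invertible (singular linear part)")
  }
  solve(m)
}

# Internal: compose transforms left-to-right in application order:
# aff_compose(a, b) applies a first, then b.
aff_compose <- function(...) {
  ms <- list(...)
  out <- diag(4)
  for (m in ms) out <- m %*% out
  out
}

# Internal: points data.frame/matrix coercion, columns ap_um, dv_um, ml_um.
as_points <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("ap_um", "dv_um", "ml_um") %in% names(x)))
    x <- cbind(x$ap_um, x$dv_um, x$ml_um)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- as.matrix(x)
  colnames(out) <- c("ap_um", "dv_um", "ml_um")
  out
}
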