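# Geometry kernels: rigid superposition, RMSD, plane fitting, dihedrals.
# All coordinates in Angstrom, all angles in degrees.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimize the RMSD between
#' the selected atoms of a mobile and a reference coordinate set.  The
#' closed-form SVD solution is used; reflections are excluded by forcing the
#' rotation determinant to +1.
#'
#' @param mobile N x 3 coordinate matrix to be moved.
#' @param reference N x 3 coordinate matrix held fixed.
#' @param selection integer vector of row indices used for the fit
#'   (defaults to all rows).
#' @return A list with components `rotation` (3 x 3 proper rotation),
#'   `translation` (length-3 vector) and `rmsd` (Angstrom, over the
#'   selection after superposition).  The transform maps a mobile point `x`
#'   to `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) == 0) stop("empty selection")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selection lengths differ between sets")
  check_noncollinear(Q)
  cm <- colMeans(P)
  cr <- colMeans(Q)
  Pc <- sweep(P, 2, cm)
  Qc <- sweep(Q, 2, cr)
  H <- crossprod(Pc, Qc)               # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                   # degenerate spectrum: keep +1 branch
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(sum((moved - Qc)^2) / nrow(P))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param transform list with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as_coord_matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

#' RMSD over one selection after fitting on another
#'
#' Superposes `frame` onto `reference` using only `fit_selection`, then
#' reports the RMSD over `measure_selection` with no further fitting.  This
#' is the two-step ligand-RMSD convention: align on the receptor backbone,
#' measure the ligand.
#'
#' @param frame,reference N x 3 coordinate matrices (same atom order).
#' @param fit_selection indices used for the superposition.
#' @param measure_selection indices over which the RMSD is reported
#'   (defaults to `fit_selection`).
#' @return RMSD in Angstrom.
#' @export
rmsd_after_fit <- function(frame, reference, fit_selection,
                           measure_selection = fit_selection) {
  frame <- as_coord_matrix(frame)
  reference <- as_coord_matrix(reference)
  tf <- kabsch_superpose(frame, reference, fit_selection)
  moved <- apply_transform(frame[measure_selection, , drop = FALSE], tf)
  ref <- reference[measure_selection, , drop = FALSE]
  sqrt(sum((moved - ref)^2) / length(measure_selection))
}

#' Total-least-squares plane through a point set
#'
#' Fits the plane minimizing the sum of squared orthogonal distances (SVD of
#' the centered coordinates; the normal is the singular direction of
#' smallest singular value).
#'
#' @param points N x 3 matrix, N >= 3, not collinear.
#' @param orient optional 3-vector; the returned normal is flipped, if
#'   needed, to have a positive component along it (e.g. the 5'->3'
#'   tetrad-stack axis).
#' @return list with `normal` (unit 3-vector) and `centroid`.
#' @export
fit_plane <- function(points, orient = NULL) {
  points <- as_coord_matrix(points)
  if (nrow(points) < 3) stop("degenerate geometry: need >= 3 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate geometry: points are collinear")
  n <- sv$v[, 3]
  n <- n / sqrt(sum(n^2))
  if (!is.null(orient) && sum(n * orient) < 0) n <- -n
  list(normal = n, centroid = ctr)
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from p2 to p3, the angle is positive when
#' the far bond (p3-p4) is rotated clockwise relative to the near bond
#' (p2-p1).  Cis is 0, trans is 180.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-16 || sum(b2^2) < 1e-16 || sum(b3^2) < 1e-16)
    stop("zero-length bond vector in dihedral")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Angle between two planes
#'
#' The orientation-free plane-plane angle, folded to [0, 90] degrees.
#'
#' @param normal_a,normal_b plane normals (need not be unit length, but must
#'   be nonzero).
#' @return angle in degrees in [0, 90].
#' @export
interplane_angle <- function(normal_a, normal_b) {
  na <- sqrt(sum(normal_a^2)); nb <- sqrt(sum(normal_b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length plane normal")
  c_ang <- abs(sum(normal_a * normal_b)) / (na * nb)
  acos(min(1, c_ang)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must be an N x 3 matrix")
  storage.mode(x) <- "double"
  x
}

check_noncollinear <- function(pts) {
  if (nrow(pts) < 3) stop("degenerate geometry: need >= 3 points")
  X <- sweep(pts, 2, colMeans(pts))
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[2] < 1e-8 * max(d[1], 1e-12))
    stop("degenerate geometry: selected points are collinear")
  invisible(TRUE)
}
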