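#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `moving` mapped onto `fixed` (`x -> R x + t`), via singular value
#' decomposition of the cross-covariance matrix with the determinant
#' correction that excludes reflections.
#'
#' @param fixed,moving numeric matrices (n x 3) of paired points, n >= 3.
#' @return list of class `rigid_transform` with elements `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length 3) and `rmsd` (Angstrom).
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch(p, p)$rmsd
#' @export
kabsch <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (!all(dim(fixed) == dim(moving)) || ncol(fixed) != 3)
    stop("kabsch: point sets must be equal-size n x 3 matrices")
  n <- nrow(fixed)
  if (n < 3L) stop("kabsch: need at least 3 points")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  P <- sweep(fixed, 2, cf)    # target
  Q <- sweep(moving, 2, cm)   # source
  # collinearity check: rank of either centred set < 2 is ill-posed
  dP <- svd(P, nu = 0, nv = 0)$d
  dQ <- svd(Q, nu = 0, nv = 0)$d
  if (dP[2] < 1e-8 * max(1, dP[1]) || dQ[2] < 1e-8 * max(1, dQ[1]))
    stop("kabsch: degenerate (collinear) point set")
  H <- crossprod(Q, P)        # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cf - as.vector(R %*% cm)
  moved <- Q %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - P)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_axis_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, |t| = %.3f A, rmsd %.4g A\n",
              aa$angle_deg, sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (or a `chain_model`, transformed in
#'   place).
#' @return transformed coordinates (or chain model).
#' @export
apply_transform <- function(transform, xyz) {
  if (inherits(xyz, "chain_model")) {
    xyz$xyz <- apply_transform(transform, xyz$xyz)
    return(xyz)
  }
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation,
        "+")
}

#' Axis-angle decomposition of a rotation matrix
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return list with `angle_deg` in `[0, 180]` and `axis`, a unit 3-vector
#'   (arbitrary for angle 0; sign convention follows the right-hand rule).
#' @export
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cs <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cs)
  if (angle < 1e-12) {
    return(list(angle_deg = 0, axis = c(0, 0, 1)))
  }
  if (abs(pi - angle) < 1e-6) {
    # near 180 deg: axis from the symmetric part, largest diagonal of R + I
    B <- (R + diag(3)) / 2
    k <- which.max(diag(B))
    axis <- B[, k] / sqrt(B[k, k])
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  }
  list(angle_deg = angle * 180 / pi, axis = axis / sqrt(sum(axis^2)))
}

# Paired coordinates of two chains over the intersection of their resolved
# residue numbers restricted to `resnos` (NULL = all shared residues).
paired_coords <- function(ref, mob, resnos = NULL, what = "range") {
  shared <- intersect(ref$resno, mob$resno)
  if (!is.null(resnos)) shared <- intersect(shared, resnos)
  if (length(shared) == 0L)
    stop("superpose_range: no shared residues in ", what)
  shared <- sort(shared)
  list(ref = ref$xyz[match(shared, ref$resno), , drop = FALSE],
       mob = mob$xyz[match(shared, mob$resno), , drop = FALSE],
       resno = shared)
}

#' Superpose one conformer onto another over a residue range
#'
#' Fits the rigid transform on the C-alpha pairs shared within
#' `align_range` (author numbering intersection of resolved residues), then
#' reports the RMSD both on the alignment range and, after applying that
#' same transform, on `measure_range`. This is the operation behind
#' "superpose the C-lobe, measure the whole molecule" comparisons of
#' open/closed kinase conformers.
#'
#' @param ref,mob `chain_model`s of the same protein.
#' @param align_range integer vector of residue numbers to fit on (default
#'   all shared residues).
#' @param measure_range residue numbers to measure on (default all shared).
#' @return list with `transform` (a `rigid_transform`), `rmsd_align`,
#'   `rmsd_measure` (Angstrom), and the residue counts used (`n_align`,
#'   `n_measure`).
#' @export
superpose_range <- function(ref, mob, align_range = NULL,
                            measure_range = NULL) {
  pa <- paired_coords(ref, mob, align_range, "align_range")
  if (nrow(pa$ref) < 3L)
    stop("superpose_range: fewer than 3 shared residues in align_range")
  tr <- kabsch(pa$ref, pa$mob)
  pm <- paired_coords(ref, mob, measure_range, "measure_range")
  moved <- apply_transform(tr, pm$mob)
  rmsd_measure <- sqrt(mean(rowSums((moved - pm$ref)^2)))
  list(transform = tr, rmsd_align = tr$rmsd, rmsd_measure = rmsd_measure,
       n_align = nrow(pa$ref), n_measure = nrow(pm$ref))
}
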