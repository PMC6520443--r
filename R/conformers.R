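#' Build a conformer ensemble
#'
#' Collects two or more conformers of the same protein into an ensemble
#' over the intersection of their resolved residue numbers. Crystal
#' structures routinely miss flexible residues, so all ensemble analyses
#' (pairwise RMSD, PCA, hinge angles) operate on this common residue set.
#'
#' @param chains list of `chain_model`s (>= 2) of the same protein.
#' @param scheme a [subdomain_scheme()].
#' @param labels optional member labels; defaults to
#'   `source_id:chain_id`.
#' @return object of class `conformer_ensemble` with `members`,
#'   `common_resnos`, `scheme`, `labels`.
#' @export
build_ensemble <- function(chains, scheme = subdomain_scheme(),
                           labels = NULL) {
  if (length(chains) < 2L) stop("build_ensemble: need >= 2 chains")
  common <- Reduce(intersect, lapply(chains, `[[`, "resno"))
  if (length(common) < 10L)
    stop("build_ensemble: common residue set too small (",
         length(common), " < 10)")
  common <- sort(common)
  if (is.null(labels)) {
    labels <- vapply(chains, function(ch) {
      if (nzchar(ch$source_id)) paste0(ch$source_id, ":", ch$chain_id)
      else ch$chain_id
    }, character(1))
    labels <- make.unique(labels, sep = "#")
  }
  structure(list(members = chains, common_resnos = common, scheme = scheme,
                 labels = labels),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d members, %d common residues (%d-%d)\n",
              length(x$members), length(x$common_resnos),
              min(x$common_resnos), max(x$common_resnos)))
  invisible(x)
}

# Coordinates of one member restricted to resnos (must all be present).
member_coords <- function(chain, resnos) {
  idx <- match(resnos, chain$resno)
  if (anyNA(idx)) stop("member lacks residues: ",
                       paste(resnos[is.na(idx)][1:3], collapse = ","))
  chain$xyz[idx, , drop = FALSE]
}

#' Interlobe distance of one conformer
#'
#' Euclidean distance between the C-alpha atoms of two reporter residues,
#' one in each lobe. The defaults (residues 15 and 416) are the reporter
#' pair used to order SjGlcNK conformers from open (about 31.7 Angstrom)
#' to closed (about 20.6 Angstrom).
#'
#' @param chain a `chain_model`.
#' @param res_a,res_b author residue numbers of the two reporters.
#' @return distance in Angstrom.
#' @export
interlobe_distance <- function(chain, res_a = 15L, res_b = 416L) {
  ia <- match(res_a, chain$resno); ib <- match(res_b, chain$resno)
  if (is.na(ia)) stop("interlobe_distance: residue ", res_a, " not resolved")
  if (is.na(ib)) stop("interlobe_distance: residue ", res_b, " not resolved")
  sqrt(sum((chain$xyz[ia, ] - chain$xyz[ib, ])^2))
}

#' Openness table of an ensemble
#'
#' Computes the interlobe reporter distance for every member and assigns
#' conformational state labels I, II, ... by decreasing distance (state I
#' is the most open).
#'
#' @param ens a `conformer_ensemble`.
#' @inheritParams interlobe_distance
#' @return data frame with `member`, `interlobe_A`, `state` (Roman
#'   numeral), ordered as the ensemble.
#' @export
openness_table <- function(ens, res_a = 15L, res_b = 416L) {
  d <- vapply(ens$members, interlobe_distance, numeric(1),
              res_a = res_a, res_b = res_b)
  state <- as.character(utils::as.roman(rank(-d, ties.method = "first")))
  data.frame(member = ens$labels, interlobe_A = d, state = state,
             stringsAsFactors = FALSE)
}

#' Pairwise RMSD matrix of an ensemble
#'
#' For every member pair, superposes on `align_range` and measures RMSD on
#' `measure_range` (see [superpose_range()]). With a C-lobe alignment range
#' and a whole-molecule measure range this quantifies interlobe
#' rearrangement while the individual lobes stay rigid.
#'
#' @param ens a `conformer_ensemble`.
#' @param align_range,measure_range residue-number vectors (default: all
#'   common residues).
#' @return symmetric matrix (Angstrom) with zero diagonal, dimnames from
#'   member labels.
#' @export
rmsd_matrix <- function(ens, align_range = NULL, measure_range = NULL) {
  m <- length(ens$members)
  M <- matrix(0, m, m, dimnames = list(ens$labels, ens$labels))
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    sp <- superpose_range(ens$members[[i]], ens$members[[j]],
                          align_range, measure_range)
    M[i, j] <- M[j, i] <- sp$rmsd_measure
  }
  M
}

#' Principal-component analysis of a conformer ensemble
#'
#' Members are first superposed onto the first member over `align_range`
#' (by default the C-lobe of the ensemble's subdomain scheme), then PCA is
#' performed on the flattened common-residue C-alpha coordinates. Modes are
#' returned as per-residue 3-vector displacements ("porcupine" vectors);
#' for a hinge-bending ensemble PC1 is the opening-closure motion.
#'
#' @param ens a `conformer_ensemble` with >= 3 members for a nontrivial
#'   decomposition (2 members give a single mode).
#' @param align_range residue numbers to superpose on (default: the
#'   scheme's C-lobe).
#' @return object of class `ensemble_pca`: `eigenvalues` (descending),
#'   `variance_fractions`, `modes` (list of n x 3 matrices),
#'   `projections` (members x modes score matrix), `mean_xyz` (n x 3),
#'   `resnos`, `zero_variance` flag.
#' @export
ensemble_pca <- function(ens, align_range = NULL) {
  if (is.null(align_range))
    align_range <- seq.int(ens$scheme$c_lobe[1], ens$scheme$c_lobe[2])
  m <- length(ens$members)
  resnos <- ens$common_resnos
  ref <- ens$members[[1]]
  X <- matrix(0, m, 3L * length(resnos))
  X[1, ] <- as.vector(t(member_coords(ref, resnos)))
  for (k in seq.int(2L, m)) {
    sp <- superpose_range(ref, ens$members[[k]], align_range)
    moved <- apply_transform(sp$transform, member_coords(ens$members[[k]],
                                                         resnos))
    X[k, ] <- as.vector(t(moved))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / (m - 1)
  zero <- total_var < 1e-12
  if (zero) {
    warning("ensemble_pca: ensemble has no conformational variance")
    ev <- rep(0, m - 1L)
    vf <- rep(NA_real_, m - 1L)
    modes <- replicate(m - 1L,
                       matrix(0, length(resnos), 3L), simplify = FALSE)
    proj <- matrix(0, m, m - 1L)
  } else {
    # m << 3n: eigendecompose the m x m Gram matrix
    G <- tcrossprod(Xc) / (m - 1)
    eg <- eigen(G, symmetric = TRUE)
    keep <- seq_len(max(1L, sum(eg$values > 1e-12 * eg$values[1])))
    ev <- pmax(eg$values[keep], 0)
    V <- crossprod(Xc, eg$vectors[, keep, drop = FALSE])   # 3n x k modes
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    vf <- ev / sum(pmax(eg$values, 0))
    modes <- lapply(seq_along(keep), function(k)
      matrix(V[, k], ncol = 3L, byrow = TRUE))
    proj <- Xc %*% V
  }
  structure(list(eigenvalues = ev, variance_fractions = vf, modes = modes,
                 projections = proj, mean_xyz = matrix(mu, ncol = 3L,
                                                       byrow = TRUE),
                 resnos = resnos, zero_variance = zero,
                 labels = ens$labels),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  cat("<ensemble_pca>", length(x$eigenvalues), "modes;")
  if (x$zero_variance) cat(" zero variance\n") else
    cat(sprintf(" PC1 %.1f%% of total variance\n",
                100 * x$variance_fractions[1]))
  invisible(x)
}

#' Hinge-bending angle between two conformers
#'
#' Two-stage rigid-fit decomposition: the mobile conformer is first
#' superposed on the fixed (reference) domain; the residual rigid
#' transform that then maps its mobile domain onto the reference's mobile
#' domain is decomposed into a rotation angle, hinge axis, and screw
#' translation along the axis. For a two-lobed kinase with the C-lobe as
#' the fixed domain and the N-lobe mobile, this is the interlobe
#' hinge-bending angle (23.8 degrees between the most-open and most-closed
#' SjGlcNK conformers).
#'
#' @param open_chain,closed_chain `chain_model`s of the two states.
#' @param fixed_range residue numbers of the reference (fixed) domain.
#' @param mobile_range residue numbers of the mobile domain.
#' @return object of class `hinge_result`: `angle_deg` in `[0, 180]`,
#'   `axis` (unit 3-vector), `screw_translation_A` (translation component
#'   along the axis), `rmsd_fixed_A`.
#' @export
hinge_angle <- function(open_chain, closed_chain, fixed_range,
                        mobile_range) {
  sp1 <- superpose_range(open_chain, closed_chain, fixed_range)
  moved <- apply_transform(sp1$transform, closed_chain)
  pm <- paired_coords(open_chain, moved, mobile_range, "mobile_range")
  if (nrow(pm$ref) < 3L)
    stop("hinge_angle: fewer than 3 shared residues in mobile_range")
  tr2 <- kabsch(pm$ref, pm$mob)
  aa <- rotation_axis_angle(tr2$rotation)
  screw <- sum(tr2$translation * aa$axis)
  structure(list(angle_deg = aa$angle_deg, axis = aa$axis,
                 screw_translation_A = screw,
                 rmsd_fixed_A = sp1$rmsd_align),
            class = "hinge_result")
}

#' @export
print.hinge_result <- function(x, ...) {
  cat(sprintf(
    "<hinge_result> %.2f deg about (%.3f, %.3f, %.3f); screw %.2f A\n",
    x$angle_deg, x$axis[1], x$axis[2], x$axis[3], x$screw_translation_A))
  invisible(x)
}
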