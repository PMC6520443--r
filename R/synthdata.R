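# Run code under a fixed RNG seed without disturbing the caller's RNG
# state. Every generator draws all of its randomness through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniform random unit vector.
runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Rotation matrix for angle (degrees) about a unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Self-avoiding random walk of n points with a fixed step length,
# rejecting steps that clash with earlier points or leave a compact
# bounding sphere. Returns an n x 3 matrix centred on `center`.
saw_cloud <- function(n, center = c(0, 0, 0), step = 3.8,
                      min_sep = 3.0, max_tries = 200L) {
  # protein-like density: ~130 A^3 per residue -> radius ~ 3.2 n^(1/3)
  r_max <- max(2 * step, 3.2 * n^(1 / 3))
  for (attempt in seq_len(20L)) {
    xyz <- matrix(0, n, 3)
    ok <- TRUE
    for (i in seq.int(2L, n)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        cand <- xyz[i - 1L, ] + step * runif_sphere()
        if (sqrt(sum(cand^2)) > r_max) next
        d2 <- rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE], 2,
                            cand)^2)
        # the previous residue sits at exactly one step; only non-bonded
        # neighbours are checked for clashes
        if (i > 2L && any(d2[seq_len(i - 2L)] < min_sep^2)) next
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      return(sweep(xyz, 2, colMeans(xyz) - center))
    }
  }
  stop("saw_cloud: failed to place a self-avoiding walk of ", n, " points")
}

#' Generate a synthetic hinge-bending conformer ensemble
#'
#' Builds a two-domain C-alpha decoy related by pure hinge rotations of
#' known angle, emulating an open-to-closed crystallographic conformer
#' series. The fixed domain (the C-lobe analogue) is a seeded self-avoiding
#' walk with 3.8 Angstrom steps; the mobile domain (N-lobe analogue) is a
#' second walk rigidly rotated about the given hinge axis by each requested
#' angle. Author numbering mirrors the real protein: mobile residues start
#' at 1, fixed residues at `n_residues_mobile + 8` (a seven-residue
#' unmodelled linker), and two reporter residues (one per domain) play the
#' interlobe-distance roles. Configurations with interdomain clashes or a
#' non-monotone reporter distance across the angle series are regenerated
#' (bounded retries), so the emitted ensemble is always a clean one-mode
#' hinge system.
#'
#' The defaults emulate the study conditions: six conformers spanning a
#' 23.8-degree hinge rotation, domain sizes matching an N-lobe of 186 and a
#' C-lobe of 245 residues.
#'
#' @param n_residues_fixed,n_residues_mobile residues per domain (>= 20).
#' @param angles_deg hinge angles (degrees, in `[0, 180)`); angle 0 is the
#'   reference (most open) conformer.
#' @param axis hinge axis direction (unit-normalised internally).
#' @param seed RNG seed; identical arguments give identical output.
#' @return list with `chains` (list of `chain_model`, one per angle) and
#'   `truth`: `angles_deg`, `axis`, `hinge_point`, `reporter_a`,
#'   `reporter_b` (residue numbers), `reporter_distance_A` per conformer,
#'   `mobile_resnos`, `fixed_resnos`, `seed`.
#' @export
make_hinge_ensemble <- function(n_residues_fixed = 245L,
                                n_residues_mobile = 186L,
                                angles_deg = seq(0, 23.8,
                                                 length.out = 6L),
                                axis = c(0, 0, 1),
                                seed = 1L) {
  if (n_residues_fixed < 20L || n_residues_mobile < 20L)
    stop("make_hinge_ensemble: need >= 20 residues per domain")
  if (any(angles_deg < 0 | angles_deg >= 180))
    stop("make_hinge_ensemble: angles must lie in [0, 180)")
  axis <- axis / sqrt(sum(axis^2))
  hinge_point <- c(0, 0, 0)
  # centre separation: both domain radii plus an interface gap, so the
  # reference conformer is clash-free by construction. The mobile domain
  # sits at a 45-degree kink from the fixed domain relative to the hinge
  # axis, so that hinge rotation swings it toward the fixed domain: the
  # closed states are more compact than the open ones, as in the real
  # two-lobed enzyme where closure shortens the interlobe distance and
  # the radius of gyration.
  sep <- 3.2 * (n_residues_fixed^(1 / 3) + n_residues_mobile^(1 / 3)) + 8
  kink <- 45 * pi / 180
  with_seed(seed, {
    out <- NULL
    for (try in seq_len(50L)) {
      fixed_xyz <- saw_cloud(n_residues_fixed, center = c(-sep / 2, 0, 0))
      mobile_xyz <- saw_cloud(n_residues_mobile,
                              center = sep / 2 * c(cos(kink), sin(kink), 0))
      mobile_resnos <- seq_len(n_residues_mobile)
      fixed_start <- n_residues_mobile + 8L
      fixed_resnos <- seq.int(fixed_start,
                              fixed_start + n_residues_fixed - 1L)
      rep_a <- mobile_resnos[min(15L, n_residues_mobile)]
      rep_b <- fixed_resnos[min(223L, n_residues_fixed)]
      chains <- vector("list", length(angles_deg))
      dists <- numeric(length(angles_deg))
      clash <- FALSE
      for (k in seq_along(angles_deg)) {
        R <- rotation_about_axis(axis, angles_deg[k])
        mob_k <- sweep(sweep(mobile_xyz, 2, hinge_point) %*% t(R), 2,
                       hinge_point, "+")
        dmin <- min(pracma::pdist2(mob_k, fixed_xyz))
        if (dmin < 3.0) { clash <- TRUE; break }
        xyz <- rbind(mob_k, fixed_xyz)
        chains[[k]] <- chain_model(
          chain_id = LETTERS[((k - 1L) %% 26L) + 1L],
          resno = c(mobile_resnos, fixed_resnos),
          resid = rep("ALA", length(mobile_resnos) + length(fixed_resnos)),
          xyz = xyz,
          source_id = sprintf("synthetic_hinge_%05.1fdeg", angles_deg[k]))
        dists[k] <- interlobe_distance(chains[[k]], rep_a, rep_b)
      }
      if (clash) next
      ord <- order(angles_deg)
      dd <- diff(dists[ord])
      if (length(dd) > 0 && !(all(dd > 0) || all(dd < 0))) next
      out <- list(
        chains = chains,
        truth = list(angles_deg = angles_deg, axis = axis,
                     hinge_point = hinge_point,
                     reporter_a = rep_a, reporter_b = rep_b,
                     reporter_distance_A = dists,
                     mobile_resnos = mobile_resnos,
                     fixed_resnos = fixed_resnos, seed = seed))
      break
    }
    if (is.null(out))
      stop("make_hinge_ensemble: could not generate a clash-free, ",
           "monotone hinge series in 50 attempts")
    out
  })
}

#' Generate a synthetic two-state scattering mixture
#'
#' Computes Debye profiles for an open and a closed conformer, mixes them
#' as `w_open * I_open + (1 - w_open) * I_closed`, and applies
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#' The sigma column of the emitted profile is the generating standard
#' deviation (`noise_cv * I_mix`), as a real error column would be; with
#' `noise_cv = 0` no sigma column is attached.
#'
#' @param open_chain,closed_chain `chain_model`s (or coordinate matrices)
#'   of the two states.
#' @param w_open open-state fraction in `[0, 1]`.
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param q_grid momentum-transfer grid.
#' @param seed RNG seed.
#' @return list with `profile` (the noisy mixture), `open_profile`,
#'   `closed_profile` (the noiseless bases) and `truth` (`w_open`,
#'   `noise_cv`, `seed`).
#' @export
make_saxs_mixture <- function(open_chain, closed_chain, w_open = 0.7,
                              noise_cv = 0.01,
                              q_grid = default_q_grid(), seed = 1L) {
  if (w_open < 0 || w_open > 1)
    stop("make_saxs_mixture: w_open must be in [0, 1]")
  if (noise_cv < 0) stop("make_saxs_mixture: negative noise_cv")
  open_p <- debye_profile(open_chain, q_grid)
  closed_p <- debye_profile(closed_chain, q_grid)
  mix <- w_open * open_p$intensity + (1 - w_open) * closed_p$intensity
  if (noise_cv == 0) {
    prof <- scattering_profile(q_grid, mix, label = "synthetic mixture")
  } else {
    noisy <- with_seed(seed,
                       mix * (1 + stats::rnorm(length(mix), 0, noise_cv)))
    prof <- scattering_profile(q_grid, noisy, sigma = noise_cv * mix,
                               label = "synthetic mixture")
  }
  list(profile = prof, open_profile = open_p, closed_profile = closed_p,
       truth = list(w_open = w_open, noise_cv = noise_cv, seed = seed))
}

#' Generate a sequence set with planted motif occurrences
#'
#' Emits `n_seqs` i.i.d.-uniform random amino acid sequences and overwrites
#' selected windows with a motif: literal positions receive the pattern's
#' residues, wildcard positions keep their background letters, and for a
#' degraded plant the requested number of randomly chosen literal positions
#' are replaced by a different residue (so the planted window has exactly
#' that many mismatches).
#'
#' @param n_seqs number of sequences.
#' @param length sequence length.
#' @param planted data frame with columns `seq` (1-based sequence index),
#'   `position` (1-based window start) and `mismatches` (degraded literal
#'   count); windows must fit and must not overlap within a sequence.
#' @param pattern `motif_pattern` to plant
#'   (default [glcnk_signature_pattern()]).
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector) and `truth`: the
#'   `planted` table augmented with the realised `end` and window string,
#'   plus `pattern` (string form) and `seed`.
#' @export
make_motif_set <- function(n_seqs = 50L, length = 200L,
                           planted = data.frame(seq = integer(0),
                                                position = integer(0),
                                                mismatches = integer(0)),
                           pattern = glcnk_signature_pattern(),
                           seed = 1L) {
  stopifnot(all(c("seq", "position", "mismatches") %in% names(planted)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  span <- pattern$span
  if (nrow(planted)) {
    if (any(planted$seq < 1L | planted$seq > n_seqs))
      stop("make_motif_set: planted seq index out of range")
    if (any(planted$position < 1L | planted$position + span - 1L > length))
      stop("make_motif_set: planted window does not fit")
    if (any(planted$mismatches < 0L |
              planted$mismatches > length(pattern$literal_pos)))
      stop("make_motif_set: invalid mismatch count")
    for (s in unique(planted$seq)) {
      p <- sort(planted$position[planted$seq == s])
      if (any(diff(p) < span))
        stop("make_motif_set: overlapping planted windows in sequence ", s)
    }
  }
  with_seed(seed, {
    mat <- matrix(sample(aa, n_seqs * length, replace = TRUE),
                  nrow = n_seqs)
    realised <- character(nrow(planted))
    for (r in seq_len(nrow(planted))) {
      i <- planted$seq[r]; p0 <- planted$position[r]
      win <- mat[i, p0:(p0 + span - 1L)]
      win[pattern$literal_pos] <- pattern$template[pattern$literal_pos]
      if (planted$mismatches[r] > 0L) {
        hit_pos <- sample(pattern$literal_pos, planted$mismatches[r])
        for (h in hit_pos)
          win[h] <- sample(setdiff(aa, pattern$template[h]), 1L)
      }
      mat[i, p0:(p0 + span - 1L)] <- win
      realised[r] <- paste(win, collapse = "")
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- sprintf("synth_%03d", seq_len(n_seqs))
    truth <- planted
    truth$end <- truth$position + span - 1L
    truth$window <- realised
    list(seqs = seqs,
         truth = list(planted = truth, pattern = pattern$source,
                      seed = seed))
  })
}

#' Generate synthetic saturation-kinetics data
#'
#' Draws rates from the Michaelis-Menten law with multiplicative Gaussian
#' noise, `v = Vmax * S / (Km + S) * (1 + e)`, `e ~ N(0, cv^2)`, per
#' replicate. Defaults use the glucosamine Km of 8 mM with eight
#' log-spaced concentrations spanning 0.25x to 16x Km.
#'
#' @param km_mM,vmax generating parameters.
#' @param s_grid substrate concentrations (mM).
#' @param cv noise coefficient of variation (>= 0).
#' @param replicates replicate measurements per concentration.
#' @param seed RNG seed.
#' @return list with `data` (a `rate_dataset`, replicates stacked) and
#'   `truth` (`km_mM`, `vmax`, `cv`, `replicates`, `seed`).
#' @export
make_kinetics_set <- function(km_mM = 8, vmax = 100,
                              s_grid = km_mM * 2^seq(-2, 4,
                                                     length.out = 8L),
                              cv = 0.05, replicates = 1L, seed = 1L) {
  if (km_mM <= 0 || vmax <= 0)
    stop("make_kinetics_set: km_mM and vmax must be positive")
  if (cv < 0) stop("make_kinetics_set: negative cv")
  S <- rep(s_grid, times = replicates)
  v0 <- vmax * S / (km_mM + S)
  v <- if (cv == 0) v0 else
    with_seed(seed, v0 * (1 + stats::rnorm(length(v0), 0, cv)))
  list(data = rate_dataset(S, v, substrate_name = "GlcN",
                           enzyme_name = "synthetic"),
       truth = list(km_mM = km_mM, vmax = vmax, cv = cv,
                    replicates = replicates, seed = seed))
}
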