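# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, direct formulas) so they share no code path
# with the implementation they check.

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rotation by angle (deg) about a unit axis, Rodrigues formula written out
# independently of the package internals.
oracle_rotation <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
  matrix(c(
    c_ + u[1]^2 * C, u[1] * u[2] * C + u[3] * s_, u[1] * u[3] * C - u[2] * s_,
    u[1] * u[2] * C - u[3] * s_, c_ + u[2]^2 * C, u[2] * u[3] * C + u[1] * s_,
    u[1] * u[3] * C + u[2] * s_, u[2] * u[3] * C - u[1] * s_, c_ + u[3]^2 * C),
    3, 3)
}

# Best RMSD of moving onto fixed over n_trials random orientations with
# optimal translation (centroid matching): a brute-force lower-bound
# certificate for the Kabsch minimum.
oracle_best_rmsd <- function(fixed, moving, n_trials = 10000L) {
  P <- sweep(fixed, 2, colMeans(fixed))
  Q <- sweep(moving, 2, colMeans(moving))
  best <- Inf
  for (k in seq_len(n_trials)) {
    R <- random_rotation()
    r <- sqrt(mean(rowSums((Q %*% t(R) - P)^2)))
    if (r < best) best <- r
  }
  best
}

# Per-window, per-position motif mismatch counts: the naive double loop.
oracle_window_mismatches <- function(sequence, template) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  span <- length(template)
  n_win <- length(chars) - span + 1L
  if (n_win < 1L) return(integer(0))
  mm <- integer(n_win)
  for (w in seq_len(n_win)) {
    cnt <- 0L
    for (p in seq_len(span)) {
      if (!is.na(template[p]) && chars[w + p - 1L] != template[p])
        cnt <- cnt + 1L
    }
    mm[w] <- cnt
  }
  mm
}

# Uniform points inside a sphere of radius R (rejection-free radial draw).
sample_sphere_points <- function(n, R) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- R * runif(n)^(1 / 3)
  u * r
}

# Analytic solid-sphere form factor P(q) = I(q)/I(0).
sphere_form_factor <- function(q, R) {
  x <- q * R
  ifelse(x < 1e-8, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# A toy two-domain chain pair related by a known hinge rotation of the
# second half about an axis through a given point.
toy_hinge_pair <- function(n_fixed = 30L, n_mobile = 30L, angle_deg = 20,
                           axis = c(0, 1, 0), point = c(0, 0, 0)) {
  fixed <- matrix(rnorm(3 * n_fixed, sd = 6), n_fixed, 3)
  mobile <- sweep(matrix(rnorm(3 * n_mobile, sd = 6), n_mobile, 3), 2,
                  c(25, 0, 0), "+")
  R <- oracle_rotation(axis, angle_deg)
  mobile_rot <- sweep(sweep(mobile, 2, point) %*% t(R), 2, point, "+")
  resno <- seq_len(n_fixed + n_mobile)
  a <- chain_model("A", resno, rep("GLY", length(resno)),
                   rbind(fixed, mobile))
  b <- chain_model("B", resno, rep("GLY", length(resno)),
                   rbind(fixed, mobile_rot))
  list(a = a, b = b, fixed_range = seq_len(n_fixed),
       mobile_range = seq.int(n_fixed + 1L, n_fixed + n_mobile),
       angle_deg = angle_deg, axis = axis)
}
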