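#' Construct a scattering profile
#'
#' A 1-D small-angle scattering curve: momentum transfer `q` (inverse
#' Angstrom, strictly ascending), intensity (arbitrary units), and optional
#' per-point uncertainties.
#'
#' @param q numeric vector, strictly ascending, `q >= 0`.
#' @param intensity numeric vector, finite, same length.
#' @param sigma optional positive uncertainties, same length.
#' @param label curve label.
#' @return object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  stopifnot(length(q) == length(intensity))
  if (any(q < 0) || any(diff(q) <= 0))
    stop("scattering_profile: q must be non-negative and strictly ascending")
  if (!all(is.finite(intensity)))
    stop("scattering_profile: non-finite intensities")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    stopifnot(length(sigma) == length(q))
    if (any(!is.finite(sigma) | sigma <= 0))
      stop("scattering_profile: sigma must be positive and finite")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label)),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile>%s %d points, q %.4g-%.4g 1/A%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' Default SAXS momentum-transfer grid
#' @param qmin,qmax grid limits (1/Angstrom).
#' @param n number of points (linear spacing).
#' @return numeric vector.
#' @export
default_q_grid <- function(qmin = 0.005, qmax = 0.35, n = 150L) {
  seq(qmin, qmax, length.out = n)
}

#' Theoretical scattering profile from coordinates (Debye formula)
#'
#' Computes the orientationally averaged intensity
#' `I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij)` over one scattering centre
#' per residue placed at the C-alpha position, with a uniform dummy form
#' factor `f`. This shape-level (coarse-grained) profile discriminates open
#' from closed conformers; it does not model atomic form factors or the
#' hydration layer. `I(0) = (n f)^2`.
#'
#' @param chain a `chain_model` (or bare n x 3 coordinate matrix); a
#'   single point gives the constant `I(q) = f^2`.
#' @param q_grid momentum-transfer grid (default [default_q_grid()]).
#' @param f uniform per-residue scattering factor.
#' @return a `scattering_profile`.
#' @export
debye_profile <- function(chain, q_grid = default_q_grid(), f = 1) {
  xyz <- if (inherits(chain, "chain_model")) chain$xyz else as.matrix(chain)
  n <- nrow(xyz)
  if (n < 1L) stop("debye_profile: need >= 1 scattering centre")
  if (any(q_grid < 0)) stop("debye_profile: negative q")
  d <- as.numeric(stats::dist(xyz))
  I <- .debye_sum(as.numeric(q_grid), d, n, f)
  lab <- if (inherits(chain, "chain_model") && nzchar(chain$source_id))
    paste0("debye:", chain$source_id) else "debye"
  scattering_profile(q_grid, I, label = lab)
}

#' Guinier analysis of a scattering profile
#'
#' Iterated linear fit of `ln I` versus `q^2` at low angle: starting from
#' all points, the window is repeatedly truncated to `q <= qrg_limit / Rg`
#' (the standard `q_max * Rg` rule for globular particles) and refitted
#' until the point set is stable. `Rg = sqrt(-3 * slope)`, `I0 = exp of the
#' intercept`.
#'
#' @param profile a `scattering_profile`.
#' @param qrg_limit upper bound on `q_max * Rg` (default 1.3).
#' @param min_points minimum points in the fit window (default 5).
#' @param max_iter iteration cap (default 50).
#' @return object of class `guinier_fit`: `rg`, `rg_se`, `i0`,
#'   `q_range_used`, `n_points`, `iterations`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5L,
                        max_iter = 50L) {
  q <- profile$q; I <- profile$intensity
  use <- seq_along(q)
  prev <- integer(0)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter)
      stop("guinier_fit: window did not converge in ", max_iter,
           " iterations")
    if (length(use) < min_points)
      stop("guinier_fit: fewer than ", min_points,
           " points in the Guinier window")
    if (any(I[use] <= 0))
      stop("guinier_fit: non-positive intensity in the Guinier window")
    fit <- stats::lm(log(I[use]) ~ I(q[use]^2))
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0)
      stop("guinier_fit: non-negative Guinier slope (no decay at low q)")
    rg <- sqrt(-3 * slope)
    new_use <- which(q * rg <= qrg_limit & q <= max(q[use]))
    if (identical(new_use, use) || identical(new_use, prev)) break
    prev <- use
    use <- new_use
  }
  # exact synthetic profiles trip lm's perfect-fit warning in summary()
  cf <- suppressWarnings(summary(fit)$coefficients)
  rg_se <- if (nrow(cf) == 2 && !is.na(cf[2, 2]))
    3 * cf[2, 2] / (2 * rg) else NA_real_
  structure(list(rg = rg, rg_se = rg_se, i0 = exp(stats::coef(fit)[[1]]),
                 q_range_used = range(q[use]), n_points = length(use),
                 iterations = it),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.2f A, I(0) = %.4g (%d pts, q %.4g-%.4g, qmax*Rg = %.2f)\n",
    x$rg, x$i0, x$n_points, x$q_range_used[1], x$q_range_used[2],
    x$q_range_used[2] * x$rg))
  invisible(x)
}

# Linear interpolation of a profile onto a q grid; errors if the grid
# extends beyond the profile's support.
interpolate_profile <- function(profile, q) {
  if (min(q) < min(profile$q) - 1e-12 || max(q) > max(profile$q) + 1e-12)
    stop("two_state_fit: profile '", profile$label,
         "' does not cover the experimental q range")
  stats::approx(profile$q, profile$intensity, xout = q)$y
}

#' Two-state (open/closed) mixture fit of a scattering curve
#'
#' Expresses an experimental profile as a non-negative combination
#' `c_open * I_open(q) + c_closed * I_closed(q) + background` by
#' sigma-weighted non-negative least squares (the free-sign background is
#' handled as the difference of two non-negative columns, which solves the
#' same convex problem exactly). The reported volume fractions are
#' `w = c / (c_open + c_closed)`; with basis curves computed from open and
#' closed conformers of the same molecule these are the conformational
#' population fractions in solution.
#'
#' @param experimental a `scattering_profile` (weights `1/sigma^2` when
#'   sigma is present, unweighted otherwise).
#' @param open_p,closed_p basis profiles, interpolable onto the
#'   experimental grid.
#' @param background include a constant background term? (default TRUE)
#' @return object of class `mixture_fit`: `w_open`, `w_closed`, `scale`
#'   (`c_open + c_closed`), `background`, `chi2_reduced`, `n_points`.
#' @export
two_state_fit <- function(experimental, open_p, closed_p,
                          background = TRUE) {
  q <- experimental$q
  y <- experimental$intensity
  io <- interpolate_profile(open_p, q)
  ic <- interpolate_profile(closed_p, q)
  rel <- max(abs(io - ic)) / max(abs(io), abs(ic), 1e-300)
  if (rel < 1e-9)
    stop("two_state_fit: open and closed basis profiles are identical; ",
         "the mixture weights are unidentifiable")
  w <- if (!is.null(experimental$sigma)) 1 / experimental$sigma else
    rep(1, length(q))
  A <- cbind(open = io, closed = ic)
  if (background) A <- cbind(A, bg_pos = 1, bg_neg = -1)
  fit <- pracma::lsqnonneg(A * w, y * w)
  cf <- fit$x
  c_open <- cf[1]; c_closed <- cf[2]
  bg <- if (background) cf[3] - cf[4] else 0
  total <- c_open + c_closed
  if (total <= 0)
    stop("two_state_fit: degenerate fit with zero total state weight")
  resid <- y - (c_open * io + c_closed * ic + bg)
  dof <- length(q) - (2L + as.integer(background))
  chi2 <- sum((resid * w)^2) / max(dof, 1L)
  structure(list(w_open = c_open / total, w_closed = c_closed / total,
                 scale = total, background = bg, chi2_reduced = chi2,
                 n_points = length(q)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> open %.1f%% / closed %.1f%% (scale %.4g, bg %.4g, red. chi2 %.3g)\n",
    100 * x$w_open, 100 * x$w_closed, x$scale, x$background,
    x$chi2_reduced))
  invisible(x)
}

#' Read a 1-D scattering curve from whitespace-delimited text
#'
#' Accepts the common SAS data dialect: 2 or 3 numeric columns
#' (`q`, `I`[, `sigma`]), `#`-prefixed comment lines and blank lines
#' ignored; any non-numeric header lines before the data block are
#' skipped.
#'
#' @param path file path.
#' @param label curve label (default: file name).
#' @return a `scattering_profile`.
#' @export
read_dat_profile <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rows <- lapply(strsplit(lines, "[ \t,]+"), function(f)
    suppressWarnings(as.numeric(f)))
  ok <- vapply(rows, function(r) length(r) >= 2 && !anyNA(r[1:2]),
               logical(1))
  rows <- rows[ok]
  if (length(rows) == 0L) stop("read_dat_profile: no numeric data in ", path)
  ncol <- min(vapply(rows, length, integer(1)), 3L)
  m <- t(vapply(rows, function(r) r[seq_len(ncol)], numeric(ncol)))
  sigma <- if (ncol >= 3L && all(is.finite(m[, 3])) && all(m[, 3] > 0))
    m[, 3] else NULL
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (!is.null(sigma)) sigma <- sigma[ord]
  keep <- !duplicated(m[, 1])
  scattering_profile(m[keep, 1], m[keep, 2],
                     sigma = if (is.null(sigma)) NULL else sigma[keep],
                     label = label)
}

#' Write a scattering profile as whitespace-delimited text
#' @param profile a `scattering_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dat_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", profile$label), con)
  writeLines("# q(1/A) I(a.u.) sigma", con)
  s <- if (is.null(profile$sigma)) rep(NA_real_, length(profile$q)) else
    profile$sigma
  writeLines(sprintf("%.8g %.10g %s", profile$q, profile$intensity,
                     ifelse(is.na(s), "", sprintf("%.10g", s))), con)
  invisible(path)
}
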