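#' Construct a rate dataset
#'
#' Substrate-concentration / initial-rate pairs for saturation-kinetics
#' fitting, e.g. luminescence-derived ADP-release rates at a series of
#' sugar concentrations.
#'
#' @param substrate_mM non-negative substrate concentrations (mM).
#' @param rate rates (arbitrary units), finite, same length.
#' @param sd optional per-point rate standard deviations (> 0).
#' @param substrate_name,enzyme_name labels.
#' @return object of class `rate_dataset`.
#' @export
rate_dataset <- function(substrate_mM, rate, sd = NULL,
                         substrate_name = "substrate",
                         enzyme_name = "enzyme") {
  substrate_mM <- as.numeric(substrate_mM); rate <- as.numeric(rate)
  stopifnot(length(substrate_mM) == length(rate))
  if (any(substrate_mM < 0)) stop("rate_dataset: negative concentrations")
  if (!all(is.finite(rate))) stop("rate_dataset: non-finite rates")
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    stopifnot(length(sd) == length(rate))
    if (any(!is.finite(sd) | sd <= 0)) stop("rate_dataset: invalid sd")
  }
  structure(list(substrate_mM = substrate_mM, rate = rate, sd = sd,
                 substrate_name = substrate_name,
                 enzyme_name = enzyme_name),
            class = "rate_dataset")
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat(sprintf("<rate_dataset> %s / %s: %d points, S %.3g-%.3g mM\n",
              x$enzyme_name, x$substrate_name, length(x$rate),
              min(x$substrate_mM), max(x$substrate_mM)))
  invisible(x)
}

# Average replicate measurements at identical concentrations; propagate
# the replicate SD for weighting.
average_replicates <- function(data) {
  s <- data$substrate_mM
  if (!anyDuplicated(s)) return(data)
  grp <- split(seq_along(s), s)
  s_u <- as.numeric(names(grp))
  v_u <- vapply(grp, function(i) mean(data$rate[i]), numeric(1))
  sd_u <- vapply(grp, function(i) {
    if (length(i) > 1L) stats::sd(data$rate[i]) else NA_real_
  }, numeric(1))
  if (anyNA(sd_u) || any(sd_u <= 0)) sd_u <- NULL
  ord <- order(s_u)
  rate_dataset(s_u[ord], v_u[ord],
               sd = if (is.null(sd_u)) NULL else sd_u[ord],
               substrate_name = data$substrate_name,
               enzyme_name = data$enzyme_name)
}

#' Michaelis-Menten fit
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` by
#' Levenberg-Marquardt, initialised from the data (`Vmax0` = maximum rate,
#' `Km0` = concentration at half-maximal rate by linear interpolation).
#' Replicate measurements at the same concentration are averaged first and
#' their standard deviations used as `1/sd^2` weights when available.
#' Standard errors come from the local curvature of the fit. A warning is
#' issued when the fitted `Km` exceeds the sampled concentration range
#' (the regime of the glucose activity of glucosamine kinases, Km above
#' 100 mM), where `Km` and `Vmax` are only bounded, not determined.
#'
#' @param data a `rate_dataset` with >= 4 distinct concentrations.
#' @return object of class `mm_fit`: `km_mM`, `vmax`, `km_se`, `vmax_se`,
#'   `converged`, `km_above_range`, `n_points`, `fitted` (function of S),
#'   `data` (the averaged dataset).
#' @examples
#' S <- c(1, 2, 4, 8, 16, 32, 64, 128)
#' fit <- mm_fit(rate_dataset(S, 100 * S / (8 + S)))
#' c(fit$km_mM, fit$vmax)
#' @export
mm_fit <- function(data) {
  stopifnot(inherits(data, "rate_dataset"))
  data <- average_replicates(data)
  S <- data$substrate_mM; v <- data$rate
  if (length(unique(S)) < 4L)
    stop("mm_fit: need >= 4 distinct substrate concentrations")
  if (all(v == 0)) stop("mm_fit: all rates are zero")
  vmax0 <- max(v)
  half <- vmax0 / 2
  ord <- order(S)
  km0 <- tryCatch(stats::approx(v[ord], S[ord], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S[S > 0])
  w <- if (!is.null(data$sd)) 1 / data$sd^2 else rep(1, length(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      weights = w,
                      lower = c(Vmax = 0, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(km_mM = NA_real_, vmax = NA_real_,
                          km_se = NA_real_, vmax_se = NA_real_,
                          converged = FALSE,
                          km_above_range = NA,
                          n_points = length(v),
                          diagnostics = conditionMessage(fit),
                          data = data),
                     class = "mm_fit"))
  }
  cf <- summary(fit)$coefficients
  km <- cf["Km", "Estimate"]; vmax <- cf["Vmax", "Estimate"]
  above <- km > max(S)
  if (above)
    warning("mm_fit: fitted Km (", signif(km, 3),
            " mM) exceeds the sampled concentration range (max ",
            max(S), " mM); Km and Vmax are poorly determined")
  structure(list(km_mM = km, vmax = vmax,
                 km_se = cf["Km", "Std. Error"],
                 vmax_se = cf["Vmax", "Std. Error"],
                 converged = TRUE, km_above_range = above,
                 n_points = length(v),
                 fitted = function(S) vmax * S / (km + S),
                 data = data),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mm_fit> did not converge:", x$diagnostics, "\n")
  } else {
    cat(sprintf("<mm_fit> Km = %.3g +/- %.2g mM, Vmax = %.4g +/- %.2g%s\n",
                x$km_mM, x$km_se, x$vmax, x$vmax_se,
                if (isTRUE(x$km_above_range))
                  " [Km above sampled range]" else ""))
  }
  invisible(x)
}

#' Relative activity normalisation
#'
#' Divides raw activity signals (e.g. luminescence counts from an ADP
#' release assay) by the signal of a reference substrate, so that the
#' preferred substrate maps to 1.0 and the rest to fractions of it.
#'
#' @param raw_signals named numeric vector of signals per substrate.
#' @param reference_substrate name of the reference; must be present with
#'   a nonzero signal.
#' @return named numeric vector of fractions; the reference maps to 1.
#' @examples
#' relative_activity(c(GlcN = 1000, glucose = 120, maltose = 5), "GlcN")
#' @export
relative_activity <- function(raw_signals, reference_substrate) {
  if (is.null(names(raw_signals)) || any(!nzchar(names(raw_signals))))
    stop("relative_activity: signals must be named by substrate")
  if (!reference_substrate %in% names(raw_signals))
    stop("relative_activity: reference substrate '", reference_substrate,
         "' not present")
  ref <- raw_signals[[reference_substrate]]
  if (!is.finite(ref) || ref == 0)
    stop("relative_activity: reference signal is zero or non-finite")
  raw_signals / ref
}

#' Read a rate table from TSV
#'
#' Expects a header line and columns `substrate_mM`, `rate` and optionally
#' `sd`.
#'
#' @param path TSV file.
#' @param substrate_name,enzyme_name labels for the dataset.
#' @return a `rate_dataset`.
#' @export
read_rate_tsv <- function(path, substrate_name = "substrate",
                          enzyme_name = "enzyme") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  if (!all(c("substrate_mM", "rate") %in% names(df)))
    stop("read_rate_tsv: need columns 'substrate_mM' and 'rate' in ", path)
  rate_dataset(df$substrate_mM, df$rate,
               sd = if ("sd" %in% names(df)) df$sd else NULL,
               substrate_name = substrate_name, enzyme_name = enzyme_name)
}
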