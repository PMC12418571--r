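#' Constrained calibration of STS_VVO against conventional STS
#'
#' Fits the line `overlap = 100 - a * STS`, constrained so that zero motion
#' corresponds to 100% overlap. Under that constraint the unique
#' least-squares solution is regression through the origin of the overlap
#' deficit `100 - y` on `x`: `a = sum(x * (100 - y)) / sum(x^2)`. Only pairs
#' with STS inside the clinically realistic window (default 0 to 1.5 mm) are
#' used, and a session yields a coefficient only if more than `min_fraction`
#' (default 25%) of its datapoints survive the windowing.
#'
#' @param sts Per-timepoint conventional scan-to-scan displacement (mm), or
#'   a data frame containing columns `sts` and `sts_vvo`.
#' @param sts_vvo Per-timepoint STS_VVO (percent); ignored when `sts` is a
#'   data frame.
#' @param window Inclusion window on STS, mm.
#' @param min_fraction Minimum surviving fraction for the fit to count.
#' @return A `vvo_calibration` object with elements `a` (slope magnitude,
#'   percent per mm; `NA` when not included), `se` (through-origin standard
#'   error), `sigma`, `n_total`, `n_used`, `included`, `window`, `data`
#'   (the kept pairs). Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' s <- calibration_session(a_true = 40, noise_sd = 0, n = 50, seed = 1)
#' fit_constrained(s)$a  # 40
#' @export
fit_constrained <- function(sts, sts_vvo = NULL, window = c(0, 1.5),
                            min_fraction = 0.25) {
  if (is.data.frame(sts)) {
    stopifnot(all(c("sts", "sts_vvo") %in% names(sts)))
    sts_vvo <- sts$sts_vvo
    sts <- sts$sts
  }
  sts <- as.numeric(sts)
  sts_vvo <- as.numeric(sts_vvo)
  if (length(sts) != length(sts_vvo)) {
    abort("`sts` and `sts_vvo` must have the same length.")
  }
  if (length(sts) < 2L) abort("Need at least 2 paired observations.")
  stopifnot(length(window) == 2L, window[1] < window[2])

  keep <- is.finite(sts) & is.finite(sts_vvo) &
    sts >= window[1] & sts <= window[2]
  n_total <- length(sts)
  n_used <- sum(keep)
  x <- sts[keep]
  y <- sts_vvo[keep]
  included <- n_used / n_total > min_fraction && sum(x^2) > 0
  a <- se <- sigma <- NA_real_
  if (included) {
    sxx <- sum(x^2)
    a <- sum(x * (100 - y)) / sxx
    resid <- (100 - y) - a * x
    sigma <- sqrt(sum(resid^2) / max(1L, n_used - 1L))
    se <- sigma / sqrt(sxx)
    a <- abs(a)
  }
  structure(
    list(a = a, se = se, sigma = sigma,
         n_total = n_total, n_used = n_used,
         included = included, window = window,
         min_fraction = min_fraction,
         data = tibble::tibble(sts = x, sts_vvo = y)),
    class = "vvo_calibration"
  )
}

#' @export
print.vvo_calibration <- function(x, ...) {
  cat("Constrained VVO calibration: overlap = 100 - a * STS\n")
  if (x$included) {
    cat(sprintf("  a = %.4f %% per mm (SE %.4f)\n", x$a, x$se))
  } else {
    cat("  no fit: window-survival rule not met\n")
  }
  cat(sprintf("  n = %d of %d within [%g, %g] mm (%.1f%%)\n",
              x$n_used, x$n_total, x$window[1], x$window[2],
              100 * x$n_used / x$n_total))
  invisible(x)
}

#' @rdname fit_constrained
#' @param x,object A `vvo_calibration` object.
#' @param ... Unused.
#' @method tidy vvo_calibration
#' @export
tidy.vvo_calibration <- function(x, ...) {
  tibble::tibble(
    term = "sts_slope",
    estimate = x$a,
    std.error = x$se
  )
}

#' @rdname fit_constrained
#' @method glance vvo_calibration
#' @export
glance.vvo_calibration <- function(x, ...) {
  tibble::tibble(
    a = x$a, sigma = x$sigma, n_total = x$n_total, n_used = x$n_used,
    fraction_used = x$n_used / x$n_total, included = x$included
  )
}

#' Mean calibration slope over sessions
#'
#' Aggregates per-session constrained fits: the mean of `a` over sessions
#' that met the window-survival rule.
#'
#' @param fits A list of `vvo_calibration` objects.
#' @return A list with `a` (mean slope; `NA` when no session was included),
#'   `sd`, `n_sessions`, `n_included`.
#' @export
mean_calibration <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "vvo_calibration")))
  a <- vapply(fits, function(f) f$a, numeric(1))
  inc <- vapply(fits, function(f) f$included, logical(1))
  list(
    a = if (any(inc)) mean(a[inc]) else NA_real_,
    sd = if (sum(inc) > 1L) stats::sd(a[inc]) else NA_real_,
    n_sessions = length(fits),
    n_included = sum(inc)
  )
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' STS to STS_VVO lookup table
#'
#' Tabulates the calibrated correspondence `STS_VVO = 100 - a * STS` over a
#' grid of STS thresholds, rounded at the second decimal place
#' (half away from zero) and clamped below at 0. With the cross-session mean
#' slope this translates conventional displacement cutoffs into
#' voxel-size-independent overlap cutoffs.
#'
#' @param a Slope (percent per mm), >= 0.
#' @param sts_grid STS grid in mm; default 0 to 1.5 in steps of 0.05.
#' @return A tibble with columns `sts` (mm) and `sts_vvo` (percent).
#' @examples
#' lookup_table(43.2422)[c(1, 6, 31), ]
#' @export
lookup_table <- function(a, sts_grid = seq(0, 1.5, by = 0.05)) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0) {
    abort("`a` must be a single non-negative slope.")
  }
  tibble::tibble(
    sts = as.numeric(sts_grid),
    sts_vvo = pmax(0, round_half_away(100 - a * as.numeric(sts_grid), 2L))
  )
}

#' Quality classification of STS_VVO values
#'
#' Maps overlap percentages onto the default quality bands: >= 90 very high,
#' >= 80 high, >= 55 potentially acceptable, below 55 questionable (35 marks
#' the very lenient cutoff in the lookup table). Boundaries are inclusive
#' upward.
#'
#' @param sts_vvo Numeric percent values in [0, 100].
#' @param thresholds Decreasing cut points, default `c(90, 80, 55)`.
#' @return An ordered factor with levels questionable <
#'   potentially_acceptable < high < very_high.
#' @examples
#' classify_quality(c(92, 83, 60, 40))
#' @export
classify_quality <- function(sts_vvo, thresholds = c(90, 80, 55)) {
  sts_vvo <- as.numeric(sts_vvo)
  if (any(!is.finite(sts_vvo)) || any(sts_vvo < 0 | sts_vvo > 100)) {
    abort("`sts_vvo` values must lie in [0, 100].")
  }
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) < 0))
  lv <- c("questionable", "potentially_acceptable", "high", "very_high")
  idx <- 1L + (sts_vvo >= thresholds[3]) + (sts_vvo >= thresholds[2]) +
    (sts_vvo >= thresholds[1])
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Censoring (scrubbing) regressor from overlap values
#'
#' Flags volumes whose median overlap falls strictly below a threshold and
#' builds the corresponding one-hot spike-regressor matrix (one column per
#' flagged volume) for use as censoring covariates in a GLM.
#'
#' @param vvo A `vvo_series` from [compute_vvo()].
#' @param measure `"sts_vvo"` (default) or `"td_vvo"`.
#' @param threshold Percent threshold in [0, 100]; default 55.
#' @return A list with `indicator` (0/1 integer vector, one per volume) and
#'   `spikes` (n x k 0/1 matrix, k = number of flagged volumes).
#' @export
censor_regressor <- function(vvo, measure = c("sts_vvo", "td_vvo"),
                             threshold = 55) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 100)
  vals <- vvo[[paste0(measure, "_median")]]
  stopifnot(!is.null(vals))
  indicator <- as.integer(vals < threshold)
  flagged <- which(indicator == 1L)
  spikes <- matrix(0L, length(vals), length(flagged))
  if (length(flagged) > 0L) {
    spikes[cbind(flagged, seq_along(flagged))] <- 1L
    colnames(spikes) <- paste0("censor_", flagged)
  }
  list(indicator = indicator, spikes = spikes)
}

#' Rank association between overlap and conventional displacement
#'
#' Rank correlation (Spearman by default, Kendall selectable) between the
#' per-timepoint median overlap and the matching conventional displacement
#' series. For motion-containing series the expected sign is negative: more
#' displacement, less overlap. Constant inputs make the correlation
#' undefined, which is flagged rather than errored.
#'
#' @param vvo A `vvo_series` from [compute_vvo()].
#' @param disp A displacement tibble from [displacement_series()]; its
#'   `mode` attribute selects the matching overlap column.
#' @param method `"spearman"` or `"kendall"`.
#' @return A one-row tibble: `measure`, `method`, `estimate`, `p.value`,
#'   `defined`.
#' @export
association_report <- function(vvo, disp, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  mode <- attr(disp, "mode") %||% "STS"
  col <- if (mode == "TD") "td_vvo_median" else "sts_vvo_median"
  x <- disp$displacement
  y <- vvo[[col]]
  if (length(x) != length(y)) abort("Series lengths differ.")
  if (length(x) < 3L) abort("Need at least 3 paired timepoints.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(measure = col, method = method,
                          estimate = NA_real_, p.value = NA_real_,
                          defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(measure = col, method = method,
                 estimate = unname(ct$estimate), p.value = ct$p.value,
                 defined = TRUE)
}
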