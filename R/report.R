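#' Assemble a full motion-QC report
#'
#' Runs the whole pipeline on one motion-parameter series: conventional TD
#' and STS displacement, the six-location overlap series, the out-of-plane
#' decomposition, quality classification of the median STS_VVO, the
#' censoring indicator, and rank-correlation summaries relating overlap to
#' displacement.
#'
#' @inheritParams compute_vvo
#' @param plane Acquisition plane for the out-of-plane decomposition.
#' @param censor_threshold Percent threshold for the censoring indicator
#'   (strictly below flags a volume); default 55.
#' @param thresholds Quality cut points passed to [classify_quality()].
#' @param meta Named list of extra metadata to carry (e.g. input path).
#' @return A `vvo_qc_report`: a list with `meta` (parameters used),
#'   `per_timepoint` (one row per volume: displacement, per-location and
#'   median overlaps, out-of-plane percent, quality label, censor flag) and
#'   `summary` (medians over time, percent flagged, correlations).
#' @examples
#' rep <- qc_report(pure_shift_series(c(0.5, 1)), dims = 3)
#' rep$summary$sts_vvo_median
#' @export
qc_report <- function(motion, dims, plane = "axial", radius = 65,
                      censor_threshold = 55, thresholds = c(90, 80, 55),
                      label = "acquired", meta = list()) {
  dims <- check_dims(dims)
  vvo <- compute_vvo(motion, dims, radius = radius, label = label)
  td <- displacement_series(motion, "TD", radius = radius)
  sts <- displacement_series(motion, "STS", radius = radius)
  oop <- out_of_plane(motion, dims, plane = plane, radius = radius)
  cens <- censor_regressor(vvo, "sts_vvo", censor_threshold)

  per_timepoint <- dplyr::bind_cols(
    tibble::tibble(volume = vvo$volume,
                   td = td$displacement, sts = sts$displacement),
    vvo[setdiff(names(vvo), "volume")],
    tibble::tibble(out_of_plane = oop$out_of_plane,
                   quality = as.character(
                     classify_quality(vvo$sts_vvo_median, thresholds)),
                   censor = cens$indicator)
  )

  assoc <- if (nrow(per_timepoint) >= 3L) {
    dplyr::bind_rows(association_report(vvo, td),
                     association_report(vvo, sts))
  } else {
    NULL
  }
  summary <- list(
    n_volumes = nrow(per_timepoint),
    td_vvo_median = median(per_timepoint$td_vvo_median),
    sts_vvo_median = median(per_timepoint$sts_vvo_median),
    td_median = median(per_timepoint$td),
    sts_median = median(per_timepoint$sts),
    pct_censored = 100 * mean(per_timepoint$censor),
    association = assoc
  )
  structure(
    list(
      meta = c(list(dims = dims, label = label, plane = plane,
                    radius = radius, censor_threshold = censor_threshold,
                    thresholds = thresholds,
                    version = as.character(utils::packageVersion("vvoqc"))),
               meta),
      per_timepoint = per_timepoint,
      summary = summary
    ),
    class = "vvo_qc_report"
  )
}

#' @export
print.vvo_qc_report <- function(x, ...) {
  cat(sprintf("VVO motion-QC report: %d volumes, voxel %s mm (%s), %s plane\n",
              x$summary$n_volumes,
              paste(format(x$meta$dims, trim = TRUE), collapse = "x"),
              x$meta$label, x$meta$plane))
  cat(sprintf("  median TD_VVO %.2f%%, median STS_VVO %.2f%%, %.1f%% censored (<%g%%)\n",
              x$summary$td_vvo_median, x$summary$sts_vvo_median,
              x$summary$pct_censored, x$meta$censor_threshold))
  invisible(x)
}

#' Write / read a QC report
#'
#' JSON output nests `meta`, `per_timepoint` and `summary` and round-trips
#' losslessly through [read_report()]; CSV output is the flat per-timepoint
#' table, one row per volume, written in full precision.
#'
#' @param report A `vvo_qc_report`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "vvo_qc_report"))
  if (format == "json") {
    jsonlite::write_json(
      list(meta = report$meta,
           per_timepoint = report$per_timepoint,
           summary = report$summary),
      path, auto_unbox = TRUE, digits = NA, na = "null", null = "null"
    )
  } else {
    readr::write_csv(report$per_timepoint, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_timepoint <- tibble::as_tibble(obj$per_timepoint)
  if (!is.null(obj$summary$association)) {
    obj$summary$association <- tibble::as_tibble(obj$summary$association)
  }
  structure(obj, class = "vvo_qc_report")
}
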