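# Motion-parameter file dialects. Canonical internal order is SPM's
# (trans_x trans_y trans_z rot_x rot_y rot_z), rotations in radians.

motion_cols <- c("trans_x", "trans_y", "trans_z",
                 "rot_x", "rot_y", "rot_z")

#' Read rigid-body realignment parameters
#'
#' Reads per-volume motion parameters in the common dialects:
#' * `spm_rp` — SPM `rp_*.txt`: whitespace-separated, 6 numbers per line in
#'   order tx ty tz rx ry rz, rotations in radians;
#' * `fsl_par` — FSL MCFLIRT `.par`: 6 numbers per line in order
#'   rx ry rz tx ty tz, rotations in radians (re-ordered on read);
#' * `bids_tsv` — BIDS confounds TSV with named columns
#'   `trans_x..trans_z`, `rot_x..rot_z` (radians per BIDS convention).
#'
#' `dialect = "auto"` resolves by extension (`.tsv` with a header line →
#' bids_tsv, `.par` → fsl_par, otherwise spm_rp). The first row is the
#' reference volume's parameters as given (typically zeros); it is not
#' forced to zero.
#'
#' @param path Path to the parameter file.
#' @param dialect One of `"auto"`, `"spm_rp"`, `"fsl_par"`, `"bids_tsv"`.
#' @param degrees If `TRUE`, rotations in the file are degrees and are
#'   converted to radians (override for nonconforming files).
#' @return A tibble with one row per volume and columns
#'   `trans_x, trans_y, trans_z` (mm) and `rot_x, rot_y, rot_z` (radians).
#' @export
read_motion <- function(path, dialect = c("auto", "spm_rp", "fsl_par", "bids_tsv"),
                        degrees = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "tsv") "bids_tsv"
               else if (ext == "par") "fsl_par"
               else "spm_rp"
  }
  out <- switch(dialect,
    spm_rp = read_six_columns(path, order = 1:6),
    fsl_par = read_six_columns(path, order = c(4:6, 1:3)),
    bids_tsv = read_bids_confounds(path)
  )
  if (nrow(out) < 1L) abort(paste0("Empty motion file: ", path))
  if (degrees) {
    out[4:6] <- out[4:6] * pi / 180
  }
  out
}

# headerless whitespace-separated 6-column reader with line-numbered errors;
# `order` maps file columns onto canonical positions
read_six_columns <- function(path, order) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("Empty motion file: ", path))
  rows <- lapply(seq_along(lines), function(i) {
    tokens <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(tokens) != 6L) {
      abort(sprintf("%s line %d: expected 6 values, found %d.",
                    path, i, length(tokens)))
    }
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals)) {
      abort(sprintf("%s line %d: non-numeric token '%s'.",
                    path, i, tokens[which(is.na(vals))[1]]))
    }
    vals
  })
  m <- do.call(rbind, rows)[, order, drop = FALSE]
  colnames(m) <- motion_cols
  tibble::as_tibble(m)
}

read_bids_confounds <- function(path) {
  df <- utils::read.delim(path, na.strings = c("", "n/a", "NA"),
                          check.names = FALSE)
  missing_cols <- setdiff(motion_cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0(path, ": missing confounds column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- df[motion_cols]
  bad <- which(!stats::complete.cases(out))
  if (length(bad) > 0L) {
    abort(sprintf("%s line %d: missing or non-numeric motion value.",
                  path, bad[1] + 1L))
  }
  tibble::as_tibble(out)
}

#' Write motion parameters in a given dialect
#'
#' Inverse of [read_motion()]; used for fixtures and interoperability.
#' Values are written in full precision so that a write/read round trip
#' reproduces the series exactly.
#'
#' @param motion Motion-parameter data frame (canonical columns).
#' @param path Output path.
#' @param dialect `"spm_rp"`, `"fsl_par"` or `"bids_tsv"`.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path, dialect = c("spm_rp", "fsl_par", "bids_tsv")) {
  dialect <- match.arg(dialect)
  m <- motion_params_matrix(motion)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  if (dialect == "bids_tsv") {
    writeLines(c(paste(colnames(m), collapse = "\t"),
                 apply(m, 1L, function(r) paste(fmt(r), collapse = "\t"))),
               path)
  } else {
    ord <- if (dialect == "spm_rp") 1:6 else c(4:6, 1:3)
    writeLines(apply(m[, ord, drop = FALSE], 1L,
                     function(r) paste(fmt(r), collapse = " ")), path)
  }
  invisible(path)
}

#' Voxel dimensions from a NIfTI header
#'
#' Reads the three spatial grid spacings from a NIfTI-1/2 header and returns
#' their absolute values (sign conventions in the header are ignored). The
#' fourth (time) dimension is ignored. No image data is read.
#'
#' @param path Path to a NIfTI file.
#' @return Numeric `(dx, dy, dz)` in mm.
#' @export
read_voxel_dims <- function(path) {
  hdr <- RNifti::niftiHeader(path)
  dims <- abs(as.numeric(hdr$pixdim[2:4]))
  if (length(dims) != 3L || anyNA(dims) || any(!is.finite(dims)) ||
      any(dims == 0)) {
    abort(paste0(path, ": missing or zero voxel spacing in NIfTI header."))
  }
  dims
}
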