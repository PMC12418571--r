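# Synthetic motion traces with known structure, so every stage of the
# pipeline is testable without any imaging dataset.

#' Pure-shift ground-truth series
#'
#' A reference volume (all zeros) followed by one volume per requested shift
#' magnitude along a single axis, with zero rotations — the ground-truth
#' simulation used to validate the overlap computation against closed-form
#' expectations. Default magnitudes are 0.5, 1, 1.5, 2, 2.5 and 3 mm.
#'
#' @param magnitudes Shift magnitudes in mm (may be empty: reference only).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A motion-parameter tibble (see [read_motion()]).
#' @examples
#' pure_shift_series()               # 7 volumes
#' pure_shift_series(1, axis = "y")  # reference + one 1 mm y-shift
#' @export
pure_shift_series <- function(magnitudes = c(0.5, 1, 1.5, 2, 2.5, 3),
                              axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  magnitudes <- as.numeric(magnitudes)
  stopifnot(all(is.finite(magnitudes)))
  n <- length(magnitudes) + 1L
  m <- matrix(0, n, 6L, dimnames = list(NULL, motion_cols))
  m[-1L, match(axis, c("x", "y", "z"))] <- magnitudes
  tibble::as_tibble(m)
}

#' Random motion trace
#'
#' Generates a realistic realignment-parameter series: cumulative Gaussian
#' drift per translation axis plus transient Bernoulli motion spikes, with
#' analogous (scaled-down) drift and spikes on the rotation axes. The first
#' volume is all zeros. Identical seeds produce bit-identical series. The
#' defaults are tuned to land mean scan-to-scan displacement in the range
#' typical of adult fMRI sessions (roughly 0.07-0.26 mm).
#'
#' @param n_volumes Number of volumes (>= 1).
#' @param drift_sd Per-volume translation drift SD, mm.
#' @param spike_rate Per-volume probability of a motion spike.
#' @param spike_sd Translation spike SD, mm.
#' @param rot_scale Per-volume rotation drift SD, radians; rotation spikes
#'   use `5 * rot_scale`.
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @return A motion-parameter tibble.
#' @export
random_motion <- function(n_volumes, drift_sd = 0.02, spike_rate = 0.05,
                          spike_sd = 0.5, rot_scale = 0.002, seed = 1L) {
  stopifnot(n_volumes >= 1, drift_sd >= 0, spike_rate >= 0, spike_rate <= 1,
            spike_sd >= 0, rot_scale >= 0)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- as.integer(n_volumes)
  m <- matrix(0, n, 6L, dimnames = list(NULL, motion_cols))
  if (n > 1L) {
    steps <- n - 1L
    spikes <- rbinom(steps, 1L, spike_rate)
    for (j in 1:3) {
      m[-1L, j] <- cumsum(rnorm(steps, 0, drift_sd)) +
        spikes * rnorm(steps, 0, spike_sd)
    }
    for (j in 4:6) {
      m[-1L, j] <- cumsum(rnorm(steps, 0, rot_scale)) +
        spikes * rnorm(steps, 0, 5 * rot_scale)
    }
  }
  tibble::as_tibble(m)
}

#' Synthetic calibration session
#'
#' Draws a paired (STS, STS_VVO) session from a known generative line for
#' testing the constrained calibration fit: STS values follow a half-normal
#' distribution (scale 0.5 mm) truncated to [0, 1.5] mm, and overlap values
#' are `100 - a_true * STS` plus Gaussian noise, clamped to [0, 100].
#'
#' @param a_true Generative slope (percent overlap lost per mm), >= 0.
#' @param noise_sd Gaussian noise SD on the overlap percent.
#' @param n Number of timepoints.
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @return A tibble with columns `sts` (mm) and `sts_vvo` (percent).
#' @export
calibration_session <- function(a_true = 43.2422, noise_sd = 2, n = 300,
                                seed = 1L) {
  stopifnot(a_true >= 0, noise_sd >= 0, n >= 2)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sts <- numeric(0)
  while (length(sts) < n) {
    draw <- abs(rnorm(n, 0, 0.5))
    sts <- c(sts, draw[draw <= 1.5])
  }
  sts <- sts[seq_len(n)]
  sts_vvo <- pmin(100, pmax(0, 100 - a_true * sts + rnorm(n, 0, noise_sd)))
  tibble::tibble(sts = sts, sts_vvo = sts_vvo)
}
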