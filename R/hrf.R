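#' Canonical double-gamma hemodynamic response function
#'
#' Standard two-gamma kernel (positive peak near 5 s, late undershoot),
#' sampled on a fine grid. The kernel is stored together with its
#' cumulative integral; regressors built from it are normalized so that a
#' sustained (long-duration) block response plateaus at 1, the
#' duration-modulated ("dmBLOCK-style") convention.
#'
#' @param dt Sampling step of the kernel grid, seconds (default 0.02).
#' @param peak_delay,peak_disp Shape/scale of the positive gamma (defaults
#'   6 and 1: mode at 5 s).
#' @param undershoot_delay,undershoot_disp Shape/scale of the undershoot
#'   gamma (defaults 16 and 1).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param duration Kernel support in seconds (default 32, must be >= 30).
#' @return Object of class `hrf`: list with `t`, `kernel`, `cumulative`,
#'   `dt`, `peak_response` (max block response, the normalization constant).
#' @export
build_hrf <- function(dt = 0.02, peak_delay = 6, peak_disp = 1,
                      undershoot_delay = 16, undershoot_disp = 1,
                      undershoot_ratio = 1 / 6, duration = 32) {
  if (dt <= 0 || peak_delay <= 0 || peak_disp <= 0 || undershoot_delay <= 0 ||
      undershoot_disp <= 0 || undershoot_ratio < 0)
    stop("invalid HRF shape parameters")
  if (duration < 30) stop("HRF kernel support must be at least 30 s")
  t <- seq(0, duration, by = dt)
  kernel <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      dgamma(t, shape = undershoot_delay / undershoot_disp,
             scale = undershoot_disp)
  if (sum(kernel) * dt <= 0) stop("invalid HRF: kernel integral not positive")
  cumulative <- cumsum(kernel) * dt
  structure(list(t = t, kernel = kernel, cumulative = cumulative, dt = dt,
                 peak_response = max(cumulative)),
            class = "hrf")
}

# Block response at times `tt` for an event starting at 0 with the given
# duration: C(t) - C(t - duration), C the kernel's cumulative integral
# (0 for t < 0, constant past the kernel support).
hrf_block_response <- function(hrf, tt, duration) {
  cum_at <- function(x) {
    y <- numeric(length(x))
    pos <- x > 0
    y[pos] <- approx(hrf$t, hrf$cumulative, xout = pmin(x[pos], max(hrf$t)),
                     rule = 2)$y
    y
  }
  (cum_at(tt) - cum_at(tt - duration)) / hrf$peak_response
}

#' Duration-modulated trial regressor
#'
#' Unit-height boxcar of the event's duration convolved with the canonical
#' HRF and normalized so that a long block plateaus at 1, evaluated at the
#' volume acquisition times of one run.
#'
#' @param onset Event onset, seconds from run start.
#' @param duration Event duration, seconds (> 0).
#' @param hrf Kernel from [build_hrf()].
#' @param n_volumes Volumes in the run.
#' @param tr Repetition time, seconds.
#' @param sample_times Optional explicit sample times (overrides the
#'   `(0:(n_volumes-1)) * tr` volume grid); used for fine-grid checks.
#' @return Numeric regressor, one value per sample time.
#' @export
make_trial_regressor <- function(onset, duration, hrf, n_volumes, tr,
                                 sample_times = NULL) {
  if (is.na(duration) || duration <= 0)
    stop("degenerate event: non-positive duration yields a zero regressor")
  tt <- sample_times %||% ((seq_len(n_volumes) - 1) * tr)
  if (onset < 0 || onset > max(tt)) stop("event outside run bounds")
  hrf_block_response(hrf, tt - onset, duration)
}
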