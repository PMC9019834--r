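#' Default rigid-body motion noise parameters
#'
#' Slow drift (random walk), fast white jitter, and sparse large spikes.
#' Magnitudes are chosen so that typical framewise displacement in a
#' simulated child cohort averages about 0.2 mm.
#'
#' @return Named list of motion parameters.
#' @export
motion_parameters <- function() {
  list(
    drift_sd_trans = 0.002,   # mm per volume (random-walk step)
    drift_sd_rot   = 0.00002, # rad per volume
    jitter_sd_trans = 0.04,   # mm
    jitter_sd_rot   = 0.0004, # rad
    spike_prob = 0.008,       # per volume
    spike_mag_trans = 0.6,    # mm (y translation)
    spike_mag_rot   = 0.004   # rad (pitch)
  )
}

#' Simulate 6-parameter rigid-body head motion
#'
#' Columns are x/y/z translations (mm) then pitch/roll/yaw rotations
#' (radians). Each parameter is a random-walk drift plus white jitter;
#' Bernoulli spikes add a transient offset (one volume) to the y
#' translation and pitch rotation.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param motion_params See [motion_parameters()].
#' @param seed Optional integer seed.
#' @return Numeric matrix `n_volumes x 6` with an attribute `spikes`
#'   (volume indices of planted spikes).
#' @export
generate_motion <- function(n_volumes, motion_params = motion_parameters(),
                            seed = NULL) {
  stopifnot(n_volumes >= 2)
  if (!is.null(seed)) set.seed(seed)
  p <- motion_params
  m <- matrix(0, n_volumes, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  for (j in 1:3)
    m[, j] <- cumsum(rnorm(n_volumes, 0, p$drift_sd_trans)) +
      rnorm(n_volumes, 0, p$jitter_sd_trans)
  for (j in 4:6)
    m[, j] <- cumsum(rnorm(n_volumes, 0, p$drift_sd_rot)) +
      rnorm(n_volumes, 0, p$jitter_sd_rot)
  spikes <- integer(0)
  if (p$spike_prob > 0) {
    spikes <- which(runif(n_volumes) < p$spike_prob)
    if (length(spikes)) {
      sign <- sample(c(-1, 1), length(spikes), replace = TRUE)
      m[spikes, "trans_y"] <- m[spikes, "trans_y"] + sign * p$spike_mag_trans
      m[spikes, "rot_x"] <- m[spikes, "rot_x"] + sign * p$spike_mag_rot
    }
  }
  attr(m, "spikes") <- spikes
  m
}
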