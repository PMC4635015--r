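#' Measured behavioral parameter presets
#'
#' The wigwag parameters measured for the three experimental groups:
#' intact animals, regenerating head fragments and headless fragments.
#' Turn angles are Normal(mean, sd) in radians; intervals are lognormal
#' with the quoted log-space location and scale in log-seconds (e.g. the
#' intact median interval is `exp(0.14) ~ 1.15` s). `reference_n` records
#' the sample sizes behind the measurements (angles pooled over animals).
#'
#' @param group `"intact"`, `"head_fragment"` or `"headless"`.
#' @return Object of class `group_preset`: `group`, `params`
#'   ([wigwag_params()]) and `reference_n` (`angles`, `animals`).
#' @examples
#' preset_params("intact")$params
#' @export
preset_params <- function(group = c("intact", "head_fragment", "headless")) {
  group <- match.arg(group)
  spec <- switch(group,
    intact        = list(a = c(-0.01, 0.34), i = c(0.14, 0.48), n = c(196L, 15L)),
    head_fragment = list(a = c(-0.07, 0.36), i = c(0.45, 0.40), n = c(69L, 11L)),
    headless      = list(a = c(0.01, 0.32),  i = c(1.0, 0.59),  n = c(101L, 14L)))
  structure(list(
    group = group,
    params = wigwag_params(angle_mean = spec$a[1], angle_sd = spec$a[2],
                           interval_logmean = spec$i[1],
                           interval_logsd = spec$i[2]),
    reference_n = c(angles = spec$n[1], animals = spec$n[2])),
    class = "group_preset")
}

#' @export
print.group_preset <- function(x, ...) {
  cat("<group_preset>", x$group,
      sprintf("(reference n: %d angles from %d animals)\n",
              x$reference_n[["angles"]], x$reference_n[["animals"]]))
  print(x$params)
  invisible(x)
}

#' Draw raw wigwag samples from the generators
#'
#' Seeded draws of turn angles (normal) and turn intervals (lognormal)
#' directly from the configured distributions, for testing the fitting
#' pipeline against known truth.
#'
#' @param params A [wigwag_params()] object.
#' @param n_angles,n_intervals Numbers of draws.
#' @param seed Optional seed.
#' @return List with `angles` (radians) and `intervals` (seconds, > 0).
#' @export
sample_wigwag <- function(params, n_angles, n_intervals, seed = NULL) {
  stopifnot(inherits(params, "wigwag_params"))
  with_seed(seed, list(
    angles = stats::rnorm(n_angles, params$angle_mean, params$angle_sd),
    intervals = stats::rlnorm(n_intervals, params$interval_logmean,
                              params$interval_logsd)))
}

#' Emulate a video-tracked trajectory
#'
#' Simulates a trajectory and overlays independent isotropic Gaussian
#' positional jitter of `noise_sd_mm` per frame, then strips the
#' simulator's event log and contact flags — mimicking what a tracking
#' pipeline would deliver from a recording.
#'
#' @inheritParams simulate_planarian
#' @param noise_sd_mm Tracking noise SD per coordinate, mm (>= 0).
#' @return A `wigwag_traj` without event log or contact flags.
#' @export
synth_tracked_trajectory <- function(params, field, duration_s,
                                     noise_sd_mm = 0, seed = NULL,
                                     start = NULL, start_theta = NULL) {
  if (noise_sd_mm < 0) stop_wigwag("noise_sd_mm must be >= 0")
  with_seed(seed, {
    tr <- simulate_planarian(params, field, duration_s, seed = NULL,
                             start = start, start_theta = start_theta)
    if (noise_sd_mm > 0) {
      sdu <- mm_to_units(noise_sd_mm)
      n <- nrow(tr)
      tr$x <- tr$x + stats::rnorm(n, 0, sdu)
      tr$y <- tr$y + stats::rnorm(n, 0, sdu)
    }
    new_wigwag_traj(data.frame(t = tr$t, x = tr$x, y = tr$y),
                    field = field, dt = params$dt, seed = seed)
  })
}
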