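# Shared fixtures, all built in code.

toy_traj <- function(x, y, dt = 0.1) {
  wigwag:::new_wigwag_traj(
    data.frame(t = (seq_along(x) - 1) * dt, x = x, y = y),
    field = NULL, dt = dt)
}

intact_params <- function() preset_params("intact")$params

# Zero-wigwag parameter set: the agent never turns spontaneously.
straight_params <- function() {
  wigwag_params(angle_mean = 0, angle_sd = 0,
                interval_logmean = 0.14, interval_logsd = 0.48)
}

UNITS_PER_MM <- 14 / 3
MM_PER_UNIT <- 3 / 14
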