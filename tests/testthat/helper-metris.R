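# Shared fixtures: everything is generated in code at test time.

short_protocol <- function(n_cycles = 2, tau = 5, off_period = 5, omega = 1,
                           first_direction = "CW") {
  actuation_protocol(omega = omega, tau = tau, off_period = off_period,
                     n_cycles = n_cycles, first_direction = first_direction)
}

# one noise-free roller through the full trajectory pipeline
noise_free_rp <- function(true_rp, n_cycles = 2, diameter = 10, tau = 5,
                          omega = 1, mode = "magnitude") {
  pr <- short_protocol(n_cycles, tau = tau, omega = omega)
  r <- roller_spec(1, diameter = diameter, true_rp = true_rp,
                   start_position = c(500, 50))
  tr <- generate_trajectories(r, pr, noise_model(), condition = "nf")
  suppressWarnings(rp_from_tracks(tr, pr, diameter = diameter, mode = mode))
}

# small straight-line calibration fixture in log10 space
line_points <- function(log_rp, a = -15, b = -10, family = "fam",
                        jitter = 0) {
  calibration_points(label = paste0("p", seq_along(log_rp)),
                     rp = 10^log_rp, kd = 10^(a + b * log_rp + jitter),
                     family = family)
}
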