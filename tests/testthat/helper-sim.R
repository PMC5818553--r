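# shared builders for simulation-based tests

# preset with linear-regime indicator: dF/F proportional to Ca - ca_rest,
# so fluorescence kinetics track clearance kinetics
linear_preset <- function(k_leak = 1.386, delta = 5, pump_vmax = 0,
                          noise_sigma_dff = 0, frame_rate = 25,
                          pump_km = 150, pump_scale = NULL) {
  structure(list(
    calcium = calcium_model(k_leak = k_leak, delta_ca_per_ap = delta,
                            pump_vmax = pump_vmax, pump_km = pump_km,
                            pump_scale_schedule = pump_scale),
    excitability = excitability_profile(),
    indicator = indicator_preset("linear"),
    noise_sigma_dff = noise_sigma_dff, frame_rate = frame_rate,
    type = "Ib", scenario = "test"), class = "nmj_preset")
}

# single centered bouton on a small frame
one_bouton_imaging <- function(noise_sigma = 0, rng_seed = 1L,
                               frame_shape = c(48L, 48L), radius = 4,
                               f0 = 100, background = 10) {
  ctr <- floor((frame_shape - 1) / 2)
  imaging_model(frame_rate = 25, frame_shape = frame_shape,
                bouton_specs = data.frame(x = ctr[2], y = ctr[1],
                                          radius = radius,
                                          f0 = f0, type = "Ib"),
                background_level = background, noise_sigma = noise_sigma,
                rng_seed = rng_seed)
}

# grid of n boutons on a frame large enough to keep footprints + background
# regions disjoint
grid_imaging <- function(n, radius = 3, spacing = 16L, f0 = 100,
                         noise_sigma = 0, rng_seed = 1L, types = "Ib") {
  per_row <- ceiling(sqrt(n))
  xy <- expand.grid(col = seq_len(per_row), row = seq_len(per_row))[seq_len(n), ]
  side <- as.integer(spacing * (per_row + 1L))
  imaging_model(frame_rate = 25, frame_shape = c(side, side),
                bouton_specs = data.frame(x = xy$col * spacing,
                                          y = xy$row * spacing,
                                          radius = radius, f0 = f0,
                                          type = rep_len(types, n)),
                background_level = 10, noise_sigma = noise_sigma,
                rng_seed = rng_seed)
}

# independent fine-step explicit-Euler integrator of the clearance ODE,
# used as oracle for simulate_calcium
euler_oracle <- function(ap_times, model, time_grid, refine = 10L) {
  dt <- diff(time_grid[1:2]) / refine
  tt <- seq(time_grid[1], time_grid[length(time_grid)], by = dt)
  u <- numeric(length(tt))
  s <- model$pump_scale_schedule
  ev <- sort(ap_times)
  j <- 1L
  u[1] <- sum(ev <= tt[1]) * model$delta_ca_per_ap
  while (j <= length(ev) && ev[j] <= tt[1]) j <- j + 1L
  for (i in 2:length(tt)) {
    du <- -model$k_leak * u[i - 1] -
      s(tt[i - 1]) * model$pump_vmax * u[i - 1] / (u[i - 1] + model$pump_km)
    u[i] <- u[i - 1] + dt * du
    while (j <= length(ev) && ev[j] <= tt[i]) {
      u[i] <- u[i] + model$delta_ca_per_ap
      j <- j + 1L
    }
  }
  model$ca_rest + stats::approx(tt, u, xout = time_grid)$y
}
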