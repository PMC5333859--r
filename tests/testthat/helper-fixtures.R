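# Shared fixtures built in code.

# A manually constructed normalized thermogram following the proximate program,
# passing through the given (temperature, mass) control points on the ramp and
# the given masses at the end of the N2 hold and at the end of the run.
toy_proximate_thermogram <- function(ramp_points, n2_end_mass, final_mass,
                                     sample_id = "toy") {
  program <- program_proximate()
  t_dry <- dry_point_time(program)           # 8.75 min
  t_ramp_end <- t_dry + (800 - 105) / 50     # 22.65 min
  t_n2_end <- nitrogen_end_time(program)     # 29.65 min
  t_final <- program_duration(program)       # 39.65 min
  ramp_times <- t_dry + (ramp_points$temperature - 105) / 50
  knot_t <- c(ramp_times, t_n2_end, t_final)
  knot_m <- c(ramp_points$mass, n2_end_mass, final_mass)
  time <- seq(t_dry, t_final, by = 0.05)
  mass <- approx(knot_t, knot_m, xout = time, rule = 2)$y
  thermogram(
    sample_id = sample_id,
    time = time,
    temperature = program_temperature(program, time),
    mass = mass,
    program = program,
    normalized = abs(mass[1] - 100) < 1e-8
  )
}

# A normalized pyrolysis-program (N2-only) thermogram through ramp control points.
toy_pyrolysis_thermogram <- function(ramp_points, sample_id = "toy") {
  program <- program_pyrolysis()
  t_dry <- dry_point_time(program)           # 3.75 min
  time <- seq(t_dry, program_duration(program), by = 0.05)
  temperature <- program_temperature(program, time)
  mass <- approx(ramp_points$temperature, ramp_points$mass,
                 xout = temperature, rule = 2)$y
  thermogram(
    sample_id = sample_id,
    time = time,
    temperature = temperature,
    mass = mass,
    program = program,
    normalized = abs(mass[1] - 100) < 1e-8
  )
}

# Seeded random regression problem.
random_problem <- function(n, p, seed, noise_sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, beta = beta)
}

# Small generator config for fast tests.
small_config <- function(seed = 11, noise_sd = 0.5, n_per_group = 3, ...) {
  generator_config(seed = seed, noise_sd = noise_sd, n_per_group = n_per_group,
                   sample_interval = 0.1, ...)
}
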