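# Acousto-electric conversion chain, drive waveforms, and safety indices.

test_that("particle speed and pressure follow the plane-wave relations", {
  # oracle: w = sqrt(2 * Gamma[W/m^2] / (rho * c0)), evaluated by hand
  expect_equal(particle_speed_amplitude(3), sqrt(2 * 3e4 / (1120 * 1540)),
               tolerance = 1e-12)
  expect_equal(particle_speed_amplitude(3), 0.1865, tolerance = 1e-3)
  expect_equal(particle_speed_amplitude(0.73), 0.0920, tolerance = 1e-3)
  # w -> 0 as gamma -> 0+
  expect_lt(particle_speed_amplitude(1e-12), 1e-6)

  expect_equal(pressure_amplitude(3), 1120 * 1540 * particle_speed_amplitude(3),
               tolerance = 1e-12)
  expect_equal(pressure_amplitude(3), 3.217e5, tolerance = 1e-3)
  # square-root law: doubling intensity scales pressure by sqrt(2)
  expect_equal(pressure_amplitude(6) / pressure_amplitude(3), sqrt(2),
               tolerance = 1e-12)

  expect_error(particle_speed_amplitude(0), "gamma")
  expect_error(pressure_amplitude(-1), "gamma")
})

test_that("current density amplitude is sigma*B*w with a single unit constant", {
  sp <- cw_drive(gamma = 3, b_field = 3)
  j <- current_density_amplitude(sp)
  # brute-force recomputation chaining the acoustic relations
  w <- sqrt(2 * 3 * 1e4 / (1120 * 1540))
  expect_equal(j$a_per_m2, 0.5 * 3 * w, tolerance = 1e-15)
  expect_equal(j$ua_per_cm2, j$a_per_m2 * 100, tolerance = 1e-15)
  expect_equal(j$ua_per_cm2, 27.98, tolerance = 1e-3)

  # linear in B, square-root in gamma
  j2 <- current_density_amplitude(cw_drive(gamma = 3, b_field = 6))
  expect_equal(j2$a_per_m2 / j$a_per_m2, 2, tolerance = 1e-12)
  j4 <- current_density_amplitude(cw_drive(gamma = 12, b_field = 3))
  expect_equal(j4$a_per_m2 / j$a_per_m2, 2, tolerance = 1e-12)

  expect_error(drive_spec(gamma = -3, b_field = 3, freq = 5e5), "gamma")
  expect_error(drive_spec(gamma = 3, b_field = 0, freq = 5e5), "b_field")
})

test_that("continuous offset-sine drive is non-negative, periodic, mean J0", {
  sp <- cw_drive(gamma = 3, b_field = 3, freq = 5e5)
  j0 <- current_density_amplitude(sp)$ua_per_cm2
  period_ms <- 1000 / sp$freq

  # extrema of the offset sine
  expect_equal(continuous_drive(period_ms / 4, sp), 2 * j0, tolerance = 1e-9)
  expect_equal(continuous_drive(3 * period_ms / 4, sp), 0, tolerance = 1e-9 * j0)

  tt <- seq(0, 10 * period_ms, by = period_ms / 200)
  jt <- continuous_drive(tt, sp)
  expect_true(all(jt >= -1e-12 * j0))
  # time-average over whole periods equals J0 (trapezoid over uniform grid
  # double-counts nothing because endpoints coincide up to one sample)
  expect_equal(mean(jt[-length(jt)]), j0, tolerance = 1e-6)
  # periodicity to near machine precision
  expect_lt(max(abs(continuous_drive(tt, sp) -
                      continuous_drive(tt + period_ms, sp))), 1e-9 * j0)

  expect_error(continuous_drive(-1, sp), "t")
})

test_that("pulse gate honours the right-closed window convention", {
  # RF = 10 Hz, DC = 50%: on-window is (0, 0.05] s within the first period
  expect_equal(pulse_gate(0.02, 10, 0.5), 1)
  expect_equal(pulse_gate(0.05, 10, 0.5), 1)   # right endpoint included
  expect_equal(pulse_gate(0.07, 10, 0.5), 0)
  expect_equal(pulse_gate(0, 10, 0.5), 0)      # gate is 0 at t = 0
  expect_equal(pulse_gate(0.1, 10, 0.5), 0)    # boundary closes period 1
  expect_equal(pulse_gate(0.12, 10, 0.5), 1)   # second period on-window

  # degenerate duty cycle: gate identically 1 for t > 0
  tt <- seq(1e-4, 0.5, by = 1e-3)
  expect_true(all(pulse_gate(tt, 10, 1) == 1))

  # on-fraction over integer periods equals DC within one sample width
  # per repetition period (sample width 1e-5 s, period 0.1 s)
  tt <- seq(0, 1, by = 1e-5)[-1]
  for (dc in c(0.05, 0.3, 0.8)) {
    expect_lt(abs(mean(pulse_gate(tt, 10, dc)) - dc), 1e-4)
  }

  expect_error(pulse_gate(0.1, 10, 1.5), "duty_cycle")
  expect_error(pulse_gate(0.1, 10, 0), "duty_cycle")
})

test_that("pulsed drive gates the full offset-sine carrier", {
  sp <- pulsed_drive_spec(duty_cycle = 0.05, rep_freq = 10)
  j0 <- current_density_amplitude(sp)$ua_per_cm2

  # exactly one 5 ms on-burst per 100 ms repetition period
  tt <- seq(0.05, 100, by = 0.05)
  on <- pulsed_drive(tt, sp) > 0
  sin_pos <- continuous_drive(tt, sp) > 0
  expect_true(all(tt[on] <= 5))
  expect_true(!any(on[tt > 5]))
  expect_true(all(on[tt <= 5 & sin_pos]))

  # mean over one repetition period ~ DC * J0
  tfine <- seq(0, 100, by = 1e-4)[-1]
  expect_equal(mean(pulsed_drive(tfine, sp)), sp$duty_cycle * j0,
               tolerance = 1e-3)

  # DC = 1 reproduces the continuous drive exactly (for t > 0)
  sp1 <- pulsed_drive_spec(duty_cycle = 1, rep_freq = 10)
  tt <- seq(0.001, 10, by = 0.01)
  expect_identical(pulsed_drive(tt, sp1), continuous_drive(tt, sp1))

  expect_error(pulsed_drive(1, cw_drive()), "pulsed")
})

test_that("drive validation rejects inconsistent pulsed settings", {
  expect_error(drive_spec(3, 3, 5e5, mode = "pulsed"), "duty_cycle")
  expect_error(drive_spec(3, 3, 5e5, mode = "pulsed", duty_cycle = 1.2,
                          rep_freq = 10), "duty_cycle")
  expect_error(drive_spec(3, 3, 5e5, mode = "pulsed", duty_cycle = 0.5,
                          rep_freq = 1e5), "rep_freq")
})

test_that("safety indices match their one-line arithmetic oracles", {
  expect_equal(mechanical_index(0.2275, 0.5), 0.2275 / sqrt(0.5),
               tolerance = 1e-15)
  expect_equal(mechanical_index(1, 1), 1)
  # linear in pr3
  expect_equal(mechanical_index(0.6, 0.25) / mechanical_index(0.2, 0.25), 3,
               tolerance = 1e-12)

  expect_equal(thermal_index(212, 0.5), 212 * 0.5 / 210, tolerance = 1e-15)
  expect_equal(thermal_index(420, 0.5), 1, tolerance = 1e-12)
  expect_equal(thermal_index(210, 1), 1, tolerance = 1e-12)

  pw <- acoustic_power(3, 3)
  expect_equal(pw$spot_area_cm2, pi * 0.15^2, tolerance = 1e-15)
  expect_equal(pw$power_mw, 3 * pi * 0.15^2 * 1000, tolerance = 1e-15)
  # linear in gamma at fixed diameter
  expect_equal(acoustic_power(6, 3)$power_mw / pw$power_mw, 2,
               tolerance = 1e-12)

  expect_error(mechanical_index(0, 1), "pr3")
  expect_error(thermal_index(100, -1), "freq_mhz")
  expect_error(acoustic_power(3, 0), "spot_diameter")

  s <- safety_summary(0.2275, 0.5, 3, 3)
  expect_equal(s$mi, mechanical_index(0.2275, 0.5))
  expect_equal(s$ti, thermal_index(s$power_mw, 0.5))
})
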