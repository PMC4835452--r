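# Sweep mechanics, presets, waveform comparison, and config loading.
# Scientific trend assertions over the full smoke grids live in
# test-acceptance.R; here the sweeps use short custom windows.

short_sim <- sim_config(150)

test_that("sweep rows are ordered and re-derivable from a direct simulation", {
  spec <- sweep_spec("b_field", c(7, 4), fixed = cw_drive(), sim = short_sim)
  tab <- run_sweep(spec)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$b_field_T, c(4, 7))  # sorted ascending
  expect_equal(tab$mode, rep("continuous", 2))

  # independent recomputation of the second row
  sim <- simulate_hh(cw_drive(b_field = 7), short_sim)
  s <- summarize_firing(sim)
  expect_equal(tab$amp_mV[2], s$amp_mV)
  expect_equal(tab$isi_ms[2], s$isi_ms)
  expect_equal(tab$n_spikes[2], s$n_spikes)
})

test_that("pulsed sweeps carry FR and gate columns", {
  spec <- sweep_spec("rep_freq", c(20, 50),
                     fixed = pulsed_drive_spec(), sim = sim_config(300))
  tab <- run_sweep(spec)
  expect_equal(tab$rep_freq_Hz, c(20, 50))
  expect_true(all(is.finite(tab$fr_per_cycle)))
  expect_true(all(tab$duty_cycle == 0.5))
})

test_that("presets encode the stated grids and fixed parameters", {
  full <- tmas_preset("b_field", smoke = FALSE)
  expect_equal(full$values, seq(0.5, 7, by = 0.5))
  expect_length(full$values, 14)
  expect_equal(full$fixed$gamma, 3)
  expect_equal(full$fixed$freq, 5e5)

  expect_length(tmas_preset("duty_cycle", smoke = FALSE)$values, 19)
  expect_equal(range(tmas_preset("duty_cycle", smoke = FALSE)$values),
               c(0.05, 0.95))
  expect_equal(tmas_preset("gamma_pulsed")$fixed$rep_freq, 10)
  expect_equal(tmas_preset("rep_freq")$fixed$duty_cycle, 0.5)

  smoke <- tmas_preset("freq")
  expect_lte(length(smoke$values), 4)
  expect_error(tmas_preset("nope"), "arg")
})

test_that("sweep validation catches out-of-range and inconsistent requests", {
  expect_error(sweep_spec("duty_cycle", c(0.5), fixed = cw_drive()),
               "pulsed")
  expect_error(sweep_spec("b_field", c(1, 12), fixed = cw_drive()),
               "standard range")
  expect_s3_class(sweep_spec("b_field", c(1, 12), fixed = cw_drive(),
                             allow_extrapolation = TRUE), "sweep_spec")
  expect_error(sweep_spec("gamma", numeric(0), fixed = cw_drive()),
               "non-empty")
})

test_that("carrier comparison: pure sine silent, offset sine fires", {
  tab <- compare_carrier_waveforms(duration = 100)
  expect_equal(tab$waveform, c("sine", "offset_sine"))
  expect_equal(tab$n_spikes[1], 0)
  expect_gte(tab$n_spikes[2], 1)
  # the sine carrier barely gates sodium channels open
  expect_lt(tab$peak_na_uA_cm2[1], tab$peak_na_uA_cm2[2] / 50)

  # composition identity with a direct simulate + detect call
  sim <- simulate_hh(cw_drive(), sim_config(100))
  expect_equal(tab$n_spikes[2], length(detect_spikes(sim)$times))
})

test_that("subthreshold intensity leaves both carriers silent", {
  tab <- compare_carrier_waveforms(gamma = 0.05, b_field = 0.5,
                                   duration = 60)
  expect_equal(tab$n_spikes, c(0, 0))
})

test_that("config loading validates schema and honours defaults", {
  path <- withr::local_tempfile(fileext = ".yml")

  writeLines(c("sweep:", "  preset: gamma_cw"), path)
  spec <- load_config(path)
  expect_s3_class(spec, "sweep_spec")
  expect_equal(spec$parameter, "gamma")

  writeLines(c("sweep:",
               "  parameter: duty_cycle",
               "  values: [0.1, 0.5]",
               "  fixed:",
               "    gamma: 3",
               "    b_field: 3",
               "    freq: 5.0e+5",
               "    mode: pulsed",
               "    duty_cycle: 0.5",
               "    rep_freq: 10",
               "  sim:",
               "    duration: 200",
               "  output_path: out.csv"), path)
  spec <- load_config(path)
  expect_equal(spec$values, c(0.1, 0.5))
  expect_equal(spec$sim$duration, 200)
  expect_equal(attr(spec, "output_path"), "out.csv")

  # out-of-range duty cycle is named in the error
  writeLines(c("sweep:",
               "  parameter: duty_cycle",
               "  values: [1.5]",
               "  fixed:",
               "    gamma: 3",
               "    b_field: 3",
               "    freq: 5.0e+5",
               "    mode: pulsed",
               "    duty_cycle: 0.5",
               "    rep_freq: 10"), path)
  expect_error(load_config(path), "duty_cycle")

  # unknown keys are rejected with their path
  writeLines(c("sweep:", "  preset: freq", "  bogus_key: 1"), path)
  expect_error(load_config(path), "bogus_key")

  writeLines(c("simulate:",
               "  drive: {gamma: 3, b_field: 3, freq: 5.0e+5}",
               "  sim: {duration: 20, dt: 0.001}"), path)
  expect_error(load_config(path), NA)

  expect_error(load_config("no/such/file.yml"), "not found")
})
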