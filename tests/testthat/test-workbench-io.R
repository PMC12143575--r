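test_that("configurations round-trip through YAML with defaults filled and keys validated", {
  tmp <- tempfile(fileext = ".yaml")
  # minimal config: defaults applied
  writeLines("integration:\n  duration: 10", tmp)
  p <- load_config(tmp)
  expect_equal(p$integration$duration, 10)
  expect_equal(p$sigmoid$e0, default_params()$sigmoid$e0)
  expect_false(is.null(attr(p, "provenance")$md5))
  # unknown key rejected with its name
  writeLines("integration:\n  dtx: 1", tmp)
  expect_error(load_config(tmp), "dtx")
  # invalid value rejected
  writeLines("stp:\n  ACd:\n    tau_f: -0.5", tmp)
  expect_error(load_config(tmp), "tau_f")
  expect_error(load_config(tempfile()), "not found")
})

test_that("the fixture generator matches its specification and is reproducible", {
  sp <- fixture_spec(duration = 60, rate = 3.5, seed = 8)
  fx <- generate_fixture_seeg(sp)
  expect_length(fx$times, 210) # rate x duration
  expect_length(fx$ncx, 60 * sp$fs)
  # suppression interval contains no events
  sp2 <- fixture_spec(duration = 60, rate = 3.5, suppression = c(6.5, 22.9),
                      seed = 8)
  fx2 <- generate_fixture_seeg(sp2)
  expect_false(any(fx2$times > 6.5 & fx2$times < 22.9))
  # reproducibility
  expect_identical(generate_fixture_seeg(sp)$ncx, fx$ncx)
  # event rate within 1% over a long horizon
  long <- generate_fixture_seeg(fixture_spec(duration = 600, rate = 3.5, seed = 1))
  expect_equal(length(long$times) / 600, 3.5, tolerance = 0.01)
  # thalamic channel: negative peaks time-locked to neocortical events
  i <- round(fx$times[5] * fx$fs) + 1
  expect_lt(fx$thal[i], mean(fx$thal) - 3 * sd(fx$thal))
})

test_that("simulation results round-trip losslessly and corruption is detected", {
  p <- short_params(duration = 2, warmup = 1)
  sim <- run_protocol(p, stim_protocol(100, onset = 0.5, duration = 1,
                                       gabab_enabled = FALSE), seed = 4)
  base <- tempfile()
  write_result(sim, base)
  back <- read_result(base)
  expect_equal(back$traces, sim$traces, tolerance = 1e-12)
  expect_equal(back$time, sim$time, tolerance = 1e-12)
  expect_equal(back$proto$frequency, 100)
  expect_equal(back$seed, sim$seed)
  # CSV row count equals trace length
  expect_equal(nrow(utils::read.csv(paste0(base, ".csv"))), nrow(sim$traces))
  # truncation is an error, not silent corruption
  lines <- readLines(paste0(base, ".csv"))
  writeLines(lines[1:(length(lines) - 10)], paste0(base, ".csv"))
  expect_error(read_result(base), "corrupt|truncated")
  # version mismatch is explicit
  meta <- jsonlite::read_json(paste0(base, ".json"))
  meta$version <- "999"
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
  expect_error(read_result(base), "version")
})

test_that("parameter validation enforces the physical invariants", {
  p <- default_params()
  expect_silent(validate_params(p))
  q <- p; q$subpopulations$RtN1$w <- 10
  expect_error(validate_params(q), "RtN1")
  q <- p; q$couplings$PV_PV <- 5
  expect_error(validate_params(q), "PV_PV")
  q <- p; q$stp$BTh$ue <- 1.5
  expect_error(validate_params(q), "ue")
  q <- p; q$stim_coupling$TC <- 0.1
  expect_error(validate_params(q), "stim_coupling")
})
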