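test_that("identical configuration and seed give bit-identical trajectories", {
  p <- short_params(duration = 3, warmup = 2)
  s1 <- run_protocol(p, stim_protocol(100, onset = 1, duration = 1,
                                      gabab_enabled = FALSE), seed = 7)
  s2 <- run_protocol(p, stim_protocol(100, onset = 1, duration = 1,
                                      gabab_enabled = FALSE), seed = 7)
  expect_identical(s1$traces, s2$traces)
})

test_that("changing only the output rate does not change the trajectory", {
  p <- short_params(duration = 3, warmup = 2)
  p2 <- p; p2$integration$fs_out <- 250
  s1 <- run_protocol(p, stim_protocol(0), seed = 3)
  s2 <- run_protocol(p2, stim_protocol(0), seed = 3)
  # the coarser grid is a subset of the finer one
  idx <- match(round(s2$time, 9), round(s1$time, 9))
  expect_false(any(is.na(idx)))
  expect_identical(s2$traces[, "y_PYR1"], s1$traces[idx, "y_PYR1"])
})

test_that("with zero gains, noise and stimulation, rest is preserved exactly", {
  p <- quiet_params(duration = 1, warmup = 0.5)
  for (nm in subpop_names()) p$subpopulations[[nm]]$W <- 0
  p$noise$PYR2$mean <- 0; p$noise$TC$mean <- 0
  s <- run_protocol(p, stim_protocol(0), seed = 1)
  expect_true(all(s$traces[, paste0("y_", subpop_names())] == 0))
})

test_that("the trajectory error shrinks roughly linearly in the step size", {
  p <- quiet_params(duration = 1, warmup = 0)
  run_dt <- function(dt) {
    q <- p; q$integration$dt <- dt; q$integration$fs_out <- 500
    run_protocol(q, stim_protocol(0), seed = 1, clamp_drive = 0.18)$traces[, "y_PYR1"]
  }
  y_ref <- run_dt(2.5e-5)
  e1 <- max(abs(run_dt(2e-4) - y_ref))
  e2 <- max(abs(run_dt(1e-4) - y_ref))
  expect_gt(e1, e2)
  expect_gt(e1 / e2, 1.4)
  expect_lt(e1 / e2, 3.5)
})

test_that("all traces stay within sanity bounds over a full-length run", {
  p <- default_params()
  s <- run_protocol(p, stim_protocol(100, gabab_enabled = FALSE), seed = 5)
  expect_true(all(abs(s$traces[, paste0("y_", subpop_names())]) < 500))
  expect_true(all(is.finite(s$traces)))
})

test_that("the battery shares one noise path and is keyed by frequency", {
  p <- short_params(duration = 8, warmup = 2)
  bat <- run_frequency_battery(p, seed = 2, gate_from = Inf)
  expect_named(bat, c("50", "70", "100", "150"))
  # pre-stimulus segments are identical across frequencies
  pre <- lapply(bat, function(b) b$traces[b$time < 5, "lfp"])
  for (f in c("70", "100", "150"))
    expect_identical(pre[[f]], pre[["50"]])
})

test_that("the GABA-B gate engages only at 150 Hz during the train", {
  p <- short_params(duration = 15, warmup = 3)
  bat <- run_frequency_battery(p, seed = 1)
  expect_false(bat[["100"]]$gate$enabled)
  expect_true(bat[["150"]]$gate$enabled)
  expect_true(bat[["150"]]$gate$engaged)
  expect_gte(bat[["150"]]$gate$engage_time, 5)
  expect_lt(bat[["150"]]$gate$engage_time, 10)
  # threshold equals the accumulation maximum of the 100 Hz reference
  expect_equal(bat[["150"]]$gate$threshold, max(bat[["100"]]$traces[, "y26"]),
               tolerance = 1e-6)
})

test_that("thalamic PSPs carry the interictal rhythm and the stimulation frequency", {
  p <- default_params()
  p$integration$duration <- 20; p$integration$warmup <- 10
  s <- run_protocol(p, stim_protocol(100, gabab_enabled = FALSE), seed = 1)
  # pre-stimulus: the reticular PSPs are driven by the ~3-4 Hz cortical rhythm
  pre <- s$time < 5
  f_low <- dominant_frequency(s$traces[pre, "y_RtN2"], s$fs, c(1, 20))
  expect_gte(f_low, 2.5); expect_lte(f_low, 4.5)
  # during the train: a spectral component at the stimulation frequency
  stim_sel <- s$time >= 5 & s$time < 10
  x <- s$traces[stim_sel, "y_RtN1"]
  f_hi <- dominant_frequency(x, s$fs, c(80, 130))
  expect_equal(f_hi, 100, tolerance = 0.03)
})
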