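test_that("the detector recovers injected spike-wave complexes and rejects noise", {
  fx <- generate_fixture_seeg(fixture_spec(duration = 12, rate = 1,
                                           noise_sd = 0.1, seed = 11))
  expect_length(fx$times, 12)
  ev <- detect_interictal_spikes(fx$ncx, fx$fs)
  expect_length(ev$times, 12)
  expect_lt(max(abs(ev$times - fx$times)), 0.05)
  # pure noise at the fixture's noise level: no events
  set.seed(1)
  noise <- rnorm(12 * fx$fs, sd = 0.1)
  expect_length(detect_interictal_spikes(noise, fx$fs)$times, 0)
})

test_that("detection is invariant under amplitude scaling and DC offset", {
  fx <- generate_fixture_seeg(fixture_spec(duration = 20, rate = 2, seed = 3))
  t0 <- detect_interictal_spikes(fx$ncx, fx$fs)$times
  expect_identical(detect_interictal_spikes(10 * fx$ncx, fx$fs)$times, t0)
  expect_identical(detect_interictal_spikes(fx$ncx + 5, fx$fs)$times, t0)
  expect_error(detect_interictal_spikes(fx$ncx[1:10], fx$fs), "shorter")
  # event times strictly increasing with refractory spacing
  expect_true(all(diff(t0) >= 0.15))
})

test_that("suppression windows are found when gaps overlap the train and only then", {
  proto <- stim_protocol(100)
  # constructed gap 6.5-22.9 s
  times <- c(seq(0.5, 6.5, by = 0.3), seq(22.9, 59, by = 0.3))
  w <- suppression_window(times, proto)
  expect_equal(w$start, 6.5)
  expect_equal(w$end, 22.9)
  expect_equal(w$post, 12.9)
  # uniform spiking: none
  expect_null(suppression_window(seq(0.2, 59.8, by = 0.3), proto))
  # gap entirely before stimulation onset: none
  times2 <- c(seq(4.8, 59.8, by = 0.3))
  expect_null(suppression_window(times2, proto))
  # windows are computed per run: concatenating two runs cannot span the boundary
  run1 <- seq(0.2, 59.8, by = 0.3)
  run2 <- run1
  w1 <- suppression_window(run1, proto)
  w2 <- suppression_window(run2, proto)
  expect_null(w1); expect_null(w2)
})

test_that("binned counts use half-open 5 s bins over 60 s", {
  b0 <- binned_spike_counts(numeric(0))
  expect_identical(b0$counts, rep(0L, 12))
  b1 <- binned_spike_counts(5.0)
  expect_identical(which(b1$counts == 1L), 2L)
  mids <- seq(2.5, 57.5, by = 5)
  expect_identical(binned_spike_counts(mids)$counts, rep(1L, 12))
  # total is preserved
  set.seed(2); tt <- runif(100, 0, 60)
  expect_equal(sum(binned_spike_counts(tt)$counts), sum(tt < 60))
})

test_that("DTW similarity is 1 for identical inputs, symmetric and in [0, 1]", {
  set.seed(4)
  fx <- generate_fixture_seeg(fixture_spec(duration = 4, rate = 3.5, seed = 5))
  a <- fx$ncx[1:1000]
  b <- a + rnorm(1000, sd = 0.05)
  expect_equal(dtw_similarity(a, a)$score, 1)
  expect_equal(dtw_similarity(a, b)$score, dtw_similarity(b, a)$score)
  expect_true(dtw_similarity(a, -a)$score >= 0)
  expect_error(dtw_similarity(numeric(0), a), "empty")
  # structured alignment beats shuffled surrogates
  s_true <- dtw_similarity(a, b)$score
  worse <- replicate(30, dtw_similarity(a, sample(b))$score)
  expect_gt(s_true, max(worse))
})

test_that("the banded dynamic program matches brute-force enumeration on tiny series", {
  # recursive enumeration of all monotone warping paths
  brute <- function(a, b) {
    rec <- function(i, j) {
      cost <- abs(a[i] - b[j])
      if (i == 1 && j == 1) return(cost)
      best <- Inf
      if (i > 1) best <- min(best, rec(i - 1, j))
      if (j > 1) best <- min(best, rec(i, j - 1))
      if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
      cost + best
    }
    rec(length(a), length(b))
  }
  set.seed(9)
  for (rep in 1:5) {
    a <- round(rnorm(sample(3:6, 1)), 2)
    b <- round(rnorm(sample(3:6, 1)), 2)
    expect_equal(dtw_cost_cpp(a, b, 10L), brute(a, b))
  }
})

test_that("the ablation API validates mechanisms and returns paired per-bin statistics", {
  expect_error(mechanism_ablation(default_params(), "nonsense"), "unknown mechanism")
  ab <- mechanism_ablation(default_params(), "ET", levels = c(0, 100),
                           n_seeds = 2, seed = 1)
  expect_equal(dim(ab$mean), c(2L, 12L))
  expect_equal(dim(ab$counts), c(2L, 2L, 12L))
  expect_identical(ab$seeds, 1:2)
})
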