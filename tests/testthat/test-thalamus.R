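test_that("STP baseline is a fixed point and steady states match the closed forms", {
  s <- stp_state(ue = 0.3, tau_f = 0.5, tau_d = 0.2)
  d <- stp_derivatives(s, fr = 40, stim = 0)
  expect_identical(c(d$du, d$dk), c(0, 0))
  expect_error(stp_derivatives(s, fr = -1, stim = 1), "negative")
  # constant drive: integrate for 20 * max(tau_f, tau_d) and compare
  fr <- 12
  f <- function(x) {
    st <- s; st$u <- x[1]; st$k <- x[2]
    d <- stp_derivatives(st, fr, 1)
    c(d$du, d$dk)
  }
  x <- euler(f, c(s$ue, 1), 1e-4, round(20 * max(s$tau_f, s$tau_d) / 1e-4))
  ss <- stp_steady_state(s, fr)
  expect_equal(x[1], ss$u_star, tolerance = 1e-3)
  expect_equal(x[2], ss$k_star, tolerance = 1e-3)
})

test_that("effective gain is (u/ue) k x0 with exact cancellation", {
  s <- stp_state(ue = 0.25, tau_f = 0.1, tau_d = 0.1, x0 = 7)
  expect_equal(effective_gain(s), 7)
  s$u <- 0.5; s$k <- 0.5
  expect_equal(effective_gain(s), 7)
})

test_that("a pure-depression synapse has a non-increasing gain under sustained drive", {
  # tau_f -> 0 pins u at its baseline; only the resource variable evolves
  s <- stp_state(ue = 0.5, tau_f = 1e-6, tau_d = 0.5, x0 = 1)
  gains <- numeric(200)
  k <- 1
  for (i in 1:200) {
    st <- s; st$u <- s$ue; st$k <- k
    d <- stp_derivatives(st, fr = 20, stim = 1)
    k <- k + 5e-3 * d$dk
    gains[i] <- (s$ue / s$ue) * k
  }
  expect_true(all(diff(gains) <= 1e-9))
})

test_that("STP variables stay in their admissible boxes along random drives", {
  set.seed(42)
  for (rep in 1:5) {
    s <- stp_state(ue = runif(1, 0.02, 0.6), tau_f = runif(1, 0.05, 2),
                   tau_d = runif(1, 0.05, 1))
    x <- c(s$ue, 1)
    for (i in 1:2000) {
      st <- s; st$u <- x[1]; st$k <- x[2]
      d <- stp_derivatives(st, fr = runif(1, 0, 5), stim = rbinom(1, 1, 0.5))
      x <- x + 1e-3 * c(d$du, d$dk)
      expect_true(x[1] >= s$ue - 1e-6 && x[1] <= 1 + 1e-6)
      expect_true(x[2] >= -1e-6 && x[2] <= 1 + 1e-6)
    }
  }
})

test_that("after the drive stops, u and k relax monotonically to baseline", {
  s <- stp_state(ue = 0.2, tau_f = 0.5, tau_d = 0.3)
  x <- c(0.8, 0.4) # displaced state, as after a train
  us <- ks <- numeric(1500)
  for (i in 1:1500) {
    st <- s; st$u <- x[1]; st$k <- x[2]
    d <- stp_derivatives(st, fr = 3, stim = 0) # stim off: fr term inactive
    x <- x + 5e-3 * c(d$du, d$dk)
    us[i] <- x[1]; ks[i] <- x[2]
  }
  expect_true(all(diff(us) < 0))
  expect_true(all(diff(ks) > 0))
  expect_equal(x[1], s$ue, tolerance = 1e-2)
  expect_equal(x[2], 1, tolerance = 1e-2)
})

test_that("combined reticular firing is a linear weighted sum", {
  expect_equal(rtn_combined_firing(0, 0, 1, 2), 0)
  expect_equal(rtn_combined_firing(2, 3, 0.5, 2), 7)
  expect_equal(rtn_combined_firing(4, 6, 0.5, 2), 14)
  expect_equal(rtn_combined_firing(5, 3, 0, 2), 6)
  expect_error(rtn_combined_firing(-1, 0, 1, 1), "negative")
})

test_that("GABA accumulation decays exponentially without CMS and saturates at phi*tau with CMS", {
  tn <- tonic_state(y26 = 2, tau_IE = 4)
  at <- function(y) { t <- tn; t$y26 <- y; t }
  # analytic solution of the linear decay law
  dt <- 1e-4
  y <- 2
  for (i in 1:40000) y <- y + dt * gaba_accumulation_derivative(at(y), 0, FALSE)
  expect_equal(y, 2 * exp(-1), tolerance = 1e-3) # t = tau_IE
  # with CMS on and constant phi the steady state is phi * tau_IE
  phi <- 0.3
  y <- 0
  for (i in 1:600000) y <- y + dt * gaba_accumulation_derivative(at(y), phi, TRUE)
  expect_equal(y, phi * tn$tau_IE, tolerance = 1e-3)
  # phi = 0 with CMS on equals the CMS-off law
  expect_equal(gaba_accumulation_derivative(tn, 0, TRUE),
               gaba_accumulation_derivative(tn, 0.5, FALSE))
})

test_that("the tonic IPSP filter is critically damped with steady state ET c / eT", {
  tn <- tonic_state(ET = 0.125, eT = 1.5)
  d0 <- tonic_psp_derivatives(tn)
  expect_identical(c(d0$dy11, d0$dy24), c(0, 0))
  # step in y26: approach without oscillation
  tn$y26 <- 1
  x <- c(0, 0) # y11, y24
  tr <- numeric(8000)
  for (i in 1:8000) {
    st <- tn; st$y11 <- x[1]; st$y24 <- x[2]
    d <- tonic_psp_derivatives(st)
    x <- x + 1e-3 * c(d$dy11, d$dy24)
    tr[i] <- x[1]
  }
  yss <- tn$ET * tn$y26 / tn$eT
  expect_equal(x[1], yss, tolerance = 1e-3)
  expect_true(max(tr) <= yss * (1 + 1e-6)) # no overshoot: double real pole
})

test_that("the GABA-B gate engages once, multiplies ue by 50 and divides tau_IE", {
  g <- gabab_gate(threshold = 1, ue_multiplier = 50, tau_reduction = 3.5)
  r1 <- stp_state(ue = 0.01, tau_f = 0.02, tau_d = 0.02)
  r2 <- stp_state(ue = 0.015, tau_f = 4, tau_d = 0.4)
  tn <- tonic_state(tau_IE = 12)
  # below threshold: unchanged
  out <- gabab_gate_update(g, 0.5, TRUE, r1, r2, tn)
  expect_false(out$gate$engaged)
  expect_equal(out$rtn1$ue, 0.01)
  # stimulation off: unchanged even above threshold
  out <- gabab_gate_update(g, 2, FALSE, r1, r2, tn)
  expect_false(out$gate$engaged)
  # engage
  out <- gabab_gate_update(g, 2, TRUE, r1, r2, tn)
  expect_true(out$gate$engaged)
  expect_equal(out$rtn1$ue, 0.5)   # 50 x 0.01
  expect_equal(out$rtn2$ue, 0.75)  # 50 x 0.015
  expect_equal(out$tonic$tau_IE, 12 / 3.5)
  # idempotent once engaged
  out2 <- gabab_gate_update(out$gate, 5, TRUE, out$rtn1, out$rtn2, out$tonic)
  expect_equal(out2$rtn1$ue, 0.5)
  expect_equal(out2$tonic$tau_IE, 12 / 3.5)
  # the multiplied release fraction is clipped at 1
  big <- stp_state(ue = 0.2, tau_f = 1, tau_d = 1)
  out3 <- gabab_gate_update(g, 2, TRUE, big, big, tn)
  expect_equal(out3$rtn1$ue, 1)
  expect_error(gabab_gate(1, ue_multiplier = -1), "positive")
})

test_that("simulated GABA accumulation decays at exactly 1/tau_IE after the train", {
  p <- short_params(duration = 25, warmup = 3)
  sim <- run_protocol(p, stim_protocol(100, gabab_enabled = FALSE), seed = 2)
  sel <- sim$time >= 12 & sim$time <= 22
  y26 <- sim$traces[sel, "y26"]
  fit <- stats::lm(log(y26) ~ sim$time[sel])
  rate <- -unname(coef(fit)[2])
  expect_equal(rate, 1 / p$tonic$tau_IE, tolerance = 0.01)
})
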