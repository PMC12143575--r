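sig <- list(e0 = 2.5, v0 = 6, r = 0.56)

test_that("wave-to-pulse sigmoid has the correct midpoint, bounds and monotonicity", {
  expect_equal(wave_to_pulse(sig$v0, sig), sig$e0)
  expect_lt(abs(wave_to_pulse(1e3, sig) - 2 * sig$e0), 1e-10)
  expect_lt(wave_to_pulse(-1e3, sig), 1e-10)
  v <- seq(-50, 50, by = 0.25)
  s <- wave_to_pulse(v, sig)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 2 * sig$e0))
  expect_error(wave_to_pulse(NaN, sig), "non-finite")
})

test_that("sigmoid derivative matches a numerical derivative", {
  v <- seq(-10, 15, by = 0.5)
  h <- 1e-6
  num <- (wave_to_pulse(v + h, sig) - wave_to_pulse(v - h, sig)) / (2 * h)
  expect_equal(wave_to_pulse_deriv(v, sig), num, tolerance = 1e-6)
})

test_that("pulse-to-wave kinetics match the closed-form impulse and step responses", {
  k <- list(W = 3.25, w = 100)
  # rest is a fixed point
  d0 <- pulse_to_wave_derivatives(0, 0, 0, k)
  expect_identical(c(d0$dy, d0$dydot), c(0, 0))
  # integrate the filter at dt = 1e-5 and compare with the closed forms
  dt <- 1e-5
  f_step <- function(x) {
    d <- pulse_to_wave_derivatives(x[1], x[2], 1, k)
    c(d$dy, d$dydot)
  }
  tt <- c(1 / k$w, 2 / k$w, 5 / k$w)
  for (t_end in tt) {
    x <- rk4(f_step, c(0, 0), dt, round(t_end / dt))
    expect_equal(x[1], psp_step_response(t_end, k, 1), tolerance = 1e-6)
  }
  # impulse response: initial condition ydot = W*w (unit rate impulse)
  f_free <- function(x) {
    d <- pulse_to_wave_derivatives(x[1], x[2], 0, k)
    c(d$dy, d$dydot)
  }
  x <- rk4(f_free, c(0, k$W * k$w), dt, round((1 / k$w) / dt))
  expect_equal(x[1], psp_impulse_response(1 / k$w, k), tolerance = 1e-6)
  # closed-form peak of the impulse response is W/e at t = 1/w
  expect_equal(psp_impulse_response(1 / k$w, k), k$W / exp(1), tolerance = 1e-12)
})

test_that("constant drive reaches the steady state W*fr/w and stays bounded", {
  k <- list(W = 22, w = 50)
  fr0 <- 5 # maximal rate: BIBO check at the largest admissible input
  f <- function(x) {
    d <- pulse_to_wave_derivatives(x[1], x[2], fr0, k)
    c(d$dy, d$dydot)
  }
  x <- euler(f, c(0, 0), 1e-4, 20000) # 2 s >> 1/w
  expect_equal(x[1], k$W * fr0 / k$w, tolerance = 1e-6)
})

test_that("total synaptic input is linear and permutation-invariant over edges", {
  p <- default_params()
  g <- connectivity_graph(p)
  psps <- setNames(runif(10, 0, 0.2), subpop_names())
  v1 <- total_input("PYR1", psps, g)
  # permutation invariance
  v2 <- total_input("PYR1", psps, g[sample(nrow(g)), ])
  expect_equal(v1, v2)
  # doubling every coupling doubles the input
  g2 <- g; g2$C <- 2 * g2$C
  expect_equal(total_input("PYR1", psps, g2), 2 * v1)
  # single-edge case
  g1 <- data.frame(source = "TC", target = "X", C = 1, sign = 1, delay = 0,
                   plasticity = "none")
  expect_equal(total_input("X", c(TC = 3), g1), 3)
  expect_error(total_input("nonsense", psps, g), "unknown target")
})

test_that("the default connectivity carries exactly three plastic edges with correct tags", {
  g <- connectivity_graph(default_params())
  pl <- g[g$plasticity != "none", ]
  expect_equal(nrow(pl), 3L)
  expect_setequal(paste(pl$source, pl$target, pl$plasticity),
                  c("TC PYR1 STD", "RtN1 TC STD", "RtN2 TC STF"))
  expect_true(all(g$delay >= 0))
  expect_equal(g$C[g$source == "PV" & g$target == "PV"], 0)
})
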