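# short-horizon parameter set for fast unit tests
short_params <- function(duration = 5, warmup = 3) {
  p <- default_params()
  p$integration$duration <- duration
  p$integration$warmup <- warmup
  p
}

# noise-free variant
quiet_params <- function(...) {
  p <- short_params(...)
  p$noise$PYR1$sd <- 0; p$noise$PYR2$sd <- 0; p$noise$TC$sd <- 0
  p
}

# forward-Euler integrator used as a simple independent reference
euler <- function(deriv, x0, dt, n) {
  x <- x0
  for (i in seq_len(n)) x <- x + dt * deriv(x)
  x
}

# classical RK4 for smooth reference integrations in oracle tests
rk4 <- function(deriv, x0, dt, n) {
  x <- x0
  for (i in seq_len(n)) {
    k1 <- deriv(x)
    k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2)
    k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
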