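#' Synthetic SEEG fixture specification
#'
#' Parameters of the synthetic interictal SEEG generator used to exercise
#' the analysis layer without any recording: sampling rate, duration, the
#' spike-wave complex rate (the interictal rhythm sits in the 3-4 Hz band),
#' the amplitude ratio between the fast spike and the slow wave, additive
#' noise level, an optional suppression interval with no events, and a seed.
#'
#' @param fs sampling rate (Hz). @param duration length (s).
#' @param rate complex rate (Hz). @param amp_ratio spike/wave amplitude
#'   ratio. @param noise_sd additive Gaussian noise SD (signal units).
#' @param suppression optional `c(start, end)` (s) interval without events.
#' @param seed integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(fs = 512, duration = 60, rate = 3.5, amp_ratio = 2,
                         noise_sd = 0.1, suppression = NULL, seed = 1) {
  stopifnot(fs > 100, duration > 0, rate > 0, amp_ratio > 0, noise_sd >= 0)
  if (!is.null(suppression)) stopifnot(length(suppression) == 2,
                                       suppression[1] < suppression[2])
  structure(list(fs = fs, duration = duration, rate = rate,
                 amp_ratio = amp_ratio, noise_sd = noise_sd,
                 suppression = suppression, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic interictal SEEG fixture
#'
#' Builds a neocortical channel as a periodic train of spike-wave templates
#' (a sharp positive spike followed by a slower wave of opposite sign) plus
#' Gaussian noise, and a thalamic channel with a negative peak time-locked
#' to each neocortical spike, mimicking the relationship between dysplastic
#' premotor cortex and centromedian-nucleus recordings. Events inside the
#' suppression interval are deleted. Fully reproducible from the seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `ncx` and `thal` (numeric traces), `times`
#'   (ground-truth event times, s), `fs`, `spec`.
#' @export
#' @examples
#' fx <- generate_fixture_seeg(fixture_spec(duration = 10))
#' length(fx$times) # rate * duration
generate_fixture_seeg <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(as.integer(spec$seed))
  period <- 1 / spec$rate
  times <- seq(period / 2, spec$duration - 1e-9, by = period)
  if (!is.null(spec$suppression))
    times <- times[times < spec$suppression[1] | times > spec$suppression[2]]
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  ncx <- numeric(n); thal <- numeric(n)
  spike_sd <- 0.012; wave_sd <- 0.060; wave_lag <- 0.12; thal_sd <- 0.010
  for (t0 in times) {
    ncx <- ncx + exp(-(tt - t0)^2 / (2 * spike_sd^2)) -
      (1 / spec$amp_ratio) * exp(-(tt - t0 - wave_lag)^2 / (2 * wave_sd^2))
    thal <- thal - 0.8 * exp(-(tt - t0)^2 / (2 * thal_sd^2))
  }
  ncx <- ncx + stats::rnorm(n, 0, spec$noise_sd)
  thal <- thal + stats::rnorm(n, 0, spec$noise_sd)
  list(ncx = ncx, thal = thal, times = times, fs = spec$fs, spec = spec)
}
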