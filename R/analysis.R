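#' Detect interictal spikes in a field-potential trace
#'
#' Band-passes the signal (Butterworth, zero-phase), estimates a robust
#' baseline (median and MAD) over a baseline window, and marks events where
#' the deviation from the baseline median exceeds `c` robust standard
#' deviations, with a refractory spacing between events. The threshold is
#' relative, so detection is invariant under amplitude scaling and DC offset
#' of the input.
#'
#' @param lfp numeric trace. @param fs sampling rate (Hz, > 100).
#' @param band band-pass edges (Hz). @param c threshold in robust SDs.
#' @param refractory minimum event spacing (s).
#' @param baseline window (s) used for the baseline statistics; defaults to
#'   the first 2 s (the pre-stimulus interictal segment).
#' @param polarity `"auto"` (side with the larger extreme deviation),
#'   `"positive"` or `"negative"`.
#' @return object of class `spike_events`: `times` (s, strictly increasing,
#'   spaced >= `refractory`), `amplitudes` (band-passed deviation at each
#'   event), `params`.
#' @export
detect_interictal_spikes <- function(lfp, fs, band = c(1, 40), c = 4,
                                     refractory = 0.15, baseline = c(0, 2),
                                     polarity = "auto") {
  if (fs <= 100) stop("sampling rate must exceed 100 Hz", call. = FALSE)
  if (!all(is.finite(lfp))) stop("non-finite values in the trace", call. = FALSE)
  if (length(lfp) < round(fs * diff(baseline)))
    stop("series shorter than the baseline-estimation window", call. = FALSE)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, lfp - mean(lfp))
  idx_base <- seq(max(1, floor(baseline[1] * fs) + 1),
                  min(length(bp), ceiling(baseline[2] * fs)))
  med <- stats::median(bp[idx_base])
  rsd <- stats::mad(bp[idx_base])
  if (rsd <= 0) rsd <- stats::sd(bp[idx_base])
  dev <- bp - med
  if (polarity == "auto")
    polarity <- if (abs(max(dev)) >= abs(min(dev))) "positive" else "negative"
  if (polarity == "negative") dev <- -dev
  thr <- c * rsd
  above <- dev > thr
  times <- numeric(0); amps <- numeric(0)
  ref_n <- round(refractory * fs)
  i <- 1L
  n <- length(dev)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      pk <- i - 1L + which.max(dev[i:j])
      # extend the refractory lockout past the group
      if (!length(times) || (pk - 1) / fs - times[length(times)] >= refractory) {
        times <- c(times, (pk - 1) / fs)
        amps <- c(amps, dev[pk])
      }
      i <- max(j + 1L, pk + ref_n)
    } else i <- i + 1L
  }
  structure(list(times = times, amplitudes = amps,
                 params = list(band = band, c = c, refractory = refractory,
                               baseline = baseline, polarity = polarity,
                               fs = fs)),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events, polarity %s, threshold %g robust SD\n",
              length(x$times), x$params$polarity, x$params$c))
  invisible(x)
}

#' Suppression window of interictal activity
#'
#' The longest inter-event gap that overlaps the stimulation window and
#' exceeds `min_gap`, reported as the interval from the last spike before
#' the gap to the first spike after it (or the end of the recording if
#' activity never resumes). Returns `NULL` when no gap qualifies.
#'
#' @param ev a `spike_events` object (or numeric event times).
#' @param proto a [stim_protocol()]. @param min_gap minimum gap (s); the
#'   default 2 s corresponds to six to eight missed interictal periods at
#'   3-4 Hz. @param horizon recording length (s).
#' @param grace attribution margin (s): a gap is attributed to the train if
#'   it begins no later than `grace` after train end, so that a single
#'   straggler discharge at the train boundary does not sever the window.
#' @return list with `start`, `end`, `duration`, `post` (suppression beyond
#'   train end, s), or `NULL`.
#' @export
suppression_window <- function(ev, proto, min_gap = 2, horizon = 60,
                               grace = 0.5) {
  times <- if (inherits(ev, "spike_events")) ev$times else sort(ev)
  stim_lo <- proto$onset
  stim_hi <- proto$onset + proto$duration + grace
  if (!length(times)) {
    gaps <- data.frame(lo = 0, hi = horizon)
  } else {
    gaps <- data.frame(lo = c(0, times), hi = c(times, horizon))
  }
  gaps$len <- gaps$hi - gaps$lo
  ok <- gaps$len > min_gap & gaps$lo < stim_hi & gaps$hi > stim_lo
  if (!any(ok)) return(NULL)
  g <- gaps[ok, , drop = FALSE]
  g <- g[which.max(g$len), ]
  list(start = g$lo, end = g$hi, duration = g$len,
       post = max(0, g$hi - (proto$onset + proto$duration)))
}

#' Binned interictal spike counts
#'
#' Counts events in half-open bins `[k w, (k+1) w)` over the horizon
#' (default: twelve 5 s bins over 60 s).
#'
#' @param ev a `spike_events` object or numeric event times.
#' @param horizon recording length (s). @param width bin width (s).
#' @return list of class `binned_counts` with `edges` and `counts`.
#' @export
binned_spike_counts <- function(ev, horizon = 60, width = 5) {
  times <- if (inherits(ev, "spike_events")) ev$times else ev
  edges <- seq(0, horizon, by = width)
  idx <- floor(times[times >= 0 & times < horizon] / width) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, counts = counts), class = "binned_counts")
}

#' Dynamic time warping similarity
#'
#' Classic DTW (symmetric step pattern, absolute-difference local cost)
#' inside a Sakoe-Chiba band, on z-scored inputs. The score is
#' `1 - cost / worst`, clipped to `[0, 1]`, where the worst-case bound is
#' the mean DTW cost of aligning each series against its own sign-flipped
#' copy — a data-driven upper bound attained by maximally anti-correlated
#' signals. Identical inputs score 1; the measure is symmetric.
#'
#' @param a,b numeric series. @param window Sakoe-Chiba half-width in
#'   samples (default 10\% of the longer series).
#' @return list of class `dtw_score`: `score`, `cost`, `worst`, `window`.
#' @export
dtw_similarity <- function(a, b, window = NULL) {
  if (!length(a) || !length(b)) stop("empty series", call. = FALSE)
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) x - mean(x) else (x - mean(x)) / s
  }
  az <- zs(a); bz <- zs(b)
  if (is.null(window)) window <- max(10L, ceiling(0.1 * max(length(a), length(b))))
  cost <- dtw_cost_cpp(az, bz, as.integer(window))
  worst <- 0.5 * (dtw_cost_cpp(az, -az, as.integer(window)) +
                  dtw_cost_cpp(bz, -bz, as.integer(window)))
  score <- if (worst > 0) 1 - cost / worst else as.numeric(cost == 0)
  structure(list(score = max(0, min(1, score)), cost = cost, worst = worst,
                 window = window), class = "dtw_score")
}

#' @export
print.dtw_score <- function(x, ...) {
  cat(sprintf("<dtw_score> %.4f (cost %.3g / worst %.3g, band %d)\n",
              x$score, x$cost, x$worst, x$window))
  invisible(x)
}

ablation_mechanisms <- function() {
  c("ET", "STD_TC_PYR", "STF_RtN2_TC", "STD_RtN1_TC")
}

#' Mechanism-ablation experiment
#'
#' Quantifies the contribution of one mechanism — extrasynaptic tonic
#' inhibition (`ET`), STD of the TC->PYR connection (`STD_TC_PYR`), STF of
#' RtN2->TC (`STF_RtN2_TC`) or STD of RtN1->TC (`STD_RtN1_TC`) — to the
#' suppression of interictal spikes under 100 Hz stimulation. The selected
#' mechanism is varied individually, the rest of the model left intact: for
#' `ET` the tonic gain is scaled from 0 to its full value; for the STP
#' mechanisms the baseline release fraction `ue` is scaled (0 disables that
#' mechanism entirely). Spike counts in 5 s bins over 60 s are averaged over
#' a shared list of noise seeds, the same seeds at every level, so level
#' effects are paired.
#'
#' @param params model parameters. @param mechanism one of
#'   `ablation_mechanisms()`. @param levels percentages in `[0, 100]`.
#' @param n_seeds number of noise realisations. @param freq stimulation
#'   frequency (Hz). @param seed base seed: the seed list is
#'   `seed + 0:(n_seeds-1)`.
#' @param detector_args list of overrides for
#'   [detect_interictal_spikes()].
#' @return list of class `ablation_result`: `mechanism`, `levels`, `mean`
#'   and `sd` (level x bin matrices), `counts` (level x seed x bin array),
#'   `edges`, `seeds`.
#' @export
mechanism_ablation <- function(params = default_params(), mechanism,
                               levels = seq(0, 100, by = 20), n_seeds = 30,
                               freq = 100, seed = 1, detector_args = list()) {
  if (!mechanism %in% ablation_mechanisms())
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  stopifnot(all(levels >= 0), all(levels <= 100))
  seeds <- as.integer(seed) + seq_len(n_seeds) - 1L
  stp_key <- switch(mechanism, STD_TC_PYR = "ACd", STF_RtN2_TC = "BTh",
                    STD_RtN1_TC = "GTh", NULL)
  edges <- seq(0, 60, by = 5)
  counts <- array(NA_real_, dim = c(length(levels), n_seeds,
                                    length(edges) - 1L))
  for (li in seq_along(levels)) {
    p <- params
    lev <- levels[li] / 100
    if (mechanism == "ET") {
      p$tonic$ET <- lev * params$tonic$ET
    } else if (lev > 0) {
      p$stp[[stp_key]]$ue <- lev * params$stp[[stp_key]]$ue
    } else {
      p$stp[[stp_key]]$enabled <- FALSE
    }
    proto <- stim_protocol(freq, gabab_enabled = FALSE)
    for (si in seq_along(seeds)) {
      sim <- run_protocol(p, proto, seed = seeds[si])
      ev <- do.call(detect_interictal_spikes,
                    c(list(lfp = sim$traces[, "lfp"], fs = sim$fs),
                      detector_args))
      counts[li, si, ] <- binned_spike_counts(ev)$counts
    }
  }
  mu <- apply(counts, c(1, 3), mean)
  sdv <- apply(counts, c(1, 3), stats::sd)
  dimnames(mu) <- dimnames(sdv) <-
    list(paste0(levels, "%"), paste0("bin", seq_len(ncol(mu))))
  structure(list(mechanism = mechanism, levels = levels, mean = mu, sd = sdv,
                 counts = counts, edges = edges, seeds = seeds),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result> %s, %d levels x %d seeds\n", x$mechanism,
              length(x$levels), length(x$seeds)))
  print(round(x$mean, 2))
  invisible(x)
}

#' Dominant spectral frequency
#'
#' Frequency (Hz) of the largest periodogram peak of a detrended trace
#' within a search band. Used to verify the ~3-4 Hz interictal rhythm.
#'
#' @param x numeric trace. @param fs sampling rate (Hz).
#' @param band search band (Hz).
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, band = c(0.5, 30)) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / n))))^2
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq >= band[1] & freq <= band[2]
  freq[sel][which.max(sp[sel])]
}
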