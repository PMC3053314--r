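#' Stationary moments and exponential ACF fit of an open-fraction series
#'
#' Computes the sample mean, the (unbiased) sample variance, and the
#' autocovariance function of a stationary series, then fits a single
#' decaying exponential `amplitude * exp(-lag/tau)` to the ACF by profiled
#' least squares on lags up to five times the dominant time constant (the
#' dominant scale is estimated from the 1/e crossing and the fit is
#' iterated once). The ACF is scaled so that its value at lag 0 equals the
#' reported variance exactly.
#'
#' @param z numeric series (e.g. open fractions at fixed sampling step).
#' @param dt sampling step of `z` (ms).
#' @param burn_in initial stretch to discard (ms).
#' @param max_lag_ms maximal ACF lag retained (ms); default chooses
#'   `min(500 * dt, span/10)`.
#' @return list with `mean`, `variance`, and `acf` (list with `lags_ms`,
#'   `values`, and `fit = list(amplitude, tau)`; `fit` is `NULL` for a
#'   degenerate, zero-variance series).
#' @export
stationary_stats <- function(z, dt, burn_in = 0, max_lag_ms = NULL) {
  stopifnot(is.numeric(z), dt > 0)
  if (burn_in > 0) z <- z[-seq_len(min(length(z) - 1L, floor(burn_in / dt)))]
  n <- length(z)
  if (n < 16L) stop("series too short for stationary statistics",
                    call. = FALSE)
  m <- mean(z)
  v <- var(z)
  if (is.null(max_lag_ms)) max_lag_ms <- min(500 * dt, n * dt / 10)
  nlag <- max(2L, min(n - 2L, floor(max_lag_ms / dt)))
  ac <- as.numeric(acf(z, lag.max = nlag, type = "covariance",
                       plot = FALSE, demean = TRUE)$acf)
  if (ac[1] > 0) ac <- ac * (v / ac[1]) # lag-0 value == reported variance
  lags <- seq.int(0L, nlag) * dt
  fit <- NULL
  if (v > 0 && any(ac[-1] > 0)) {
    # dominant scale from the 1/e crossing, then refit on 5 tau
    idx <- which(ac < ac[1] / exp(1))[1]
    tau0 <- if (is.na(idx)) lags[length(lags)] / 2 else lags[idx]
    tau0 <- max(tau0, dt)
    for (pass in 1:2) {
      keep <- lags <= 5 * tau0
      if (sum(keep) < 3L) keep <- seq_len(min(8L, length(lags)))
      f <- fit_single_exp_curve(lags[keep], ac[keep],
                                tau_range = c(dt / 2, max(lags) * 2))
      tau0 <- f$tau
    }
    fit <- list(amplitude = f$amplitude, tau = f$tau)
  }
  list(mean = m, variance = v,
       acf = list(lags_ms = lags, values = ac, fit = fit))
}

#' Detect spikes as threshold crossings
#'
#' Upward crossings of `threshold`, with at most one spike per refractory
#' window.
#'
#' @param v voltage trace (mV) on a uniform grid.
#' @param dt sampling step (ms).
#' @param threshold detection threshold (mV); default 0, unambiguous for
#'   full-height action potentials.
#' @param refractory_ms minimal separation of detected spikes (ms).
#' @return numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory_ms = 2) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  up <- which(v[-1L] >= threshold & v[-n] < threshold)
  if (!length(up)) return(numeric(0))
  times <- up * dt
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory_ms) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Firing rate and ISI coefficient of variation
#'
#' @param spikes spike times (ms).
#' @param duration_ms observation window (ms).
#' @return list with `rate_hz`, `cv` (`NA` with `cv_defined = FALSE` when
#'   fewer than three spikes, i.e. fewer than two ISIs), `n_spikes`.
#' @export
isi_statistics <- function(spikes, duration_ms) {
  stopifnot(duration_ms > 0)
  n <- length(spikes)
  rate <- n / duration_ms * 1000
  if (n < 3L) {
    return(list(rate_hz = rate, cv = NA_real_, cv_defined = FALSE,
                n_spikes = n))
  }
  isi <- diff(spikes)
  list(rate_hz = rate, cv = sd(isi) / mean(isi), cv_defined = TRUE,
       n_spikes = n)
}

#' Per-trial spike trains under a common stimulus
#'
#' @param trials list of numeric spike-time vectors (ms), one per trial.
#' @param duration_ms trial length (ms).
#' @param stimulus optional [stimulus] metadata.
#' @param seeds optional per-trial seeds.
#' @return object of class `spike_train_set`.
#' @export
spike_train_set <- function(trials, duration_ms, stimulus = NULL,
                            seeds = NULL) {
  stopifnot(is.list(trials),
            all(vapply(trials, function(s) {
              !is.unsorted(s, strictly = TRUE)
            }, logical(1))))
  structure(list(trials = trials, duration_ms = duration_ms,
                 stimulus = stimulus, seeds = seeds),
            class = "spike_train_set")
}

#' Firing efficacy, latency and jitter of pulse responses
#'
#' @param trains a [spike_train_set()].
#' @param stim_onset_ms stimulus onset (ms).
#' @param window_ms response window after onset (ms).
#' @return list with `efficacy` (fraction of trials with >= 1 spike in the
#'   window), `latency_ms` and `jitter_ms` (mean and SD of first-spike
#'   latencies over responding trials; `NA` when no trial responds).
#' @export
efficacy_latency_jitter <- function(trains, stim_onset_ms, window_ms) {
  stopifnot(inherits(trains, "spike_train_set"), window_ms > 0)
  first <- vapply(trains$trials, function(s) {
    s <- s[s >= stim_onset_ms & s <= stim_onset_ms + window_ms]
    if (length(s)) s[1] - stim_onset_ms else NA_real_
  }, numeric(1))
  responding <- !is.na(first)
  eff <- mean(responding)
  if (!any(responding)) {
    return(list(efficacy = 0, latency_ms = NA_real_, jitter_ms = NA_real_))
  }
  list(efficacy = eff, latency_ms = mean(first[responding]),
       jitter_ms = if (sum(responding) > 1L) sd(first[responding])
                   else NA_real_)
}

#' Event-based spike-timing reliability and precision
#'
#' The across-trial peristimulus time histogram is smoothed with a Gaussian
#' kernel; *events* are contiguous stretches where the smoothed rate
#' exceeds a threshold (default: twice the trial-average mean rate, the
#' shuffled-baseline surrogate). Reliability is the mean over events of the
#' fraction of trials contributing at least one spike to the event;
#' precision is the mean within-event standard deviation of each trial's
#' first spike.
#'
#' @param trains a [spike_train_set()] with at least two trials.
#' @param kernel_sd_ms Gaussian smoothing SD (ms).
#' @param threshold event threshold (spikes/s); default twice the mean
#'   rate.
#' @param bin_ms PSTH bin width (ms).
#' @return list with `reliability` in `[0, 1]`, `precision_ms` (`NA` when
#'   no events), and `n_events`.
#' @export
reliability_precision <- function(trains, kernel_sd_ms = 2,
                                  threshold = NULL, bin_ms = 0.5) {
  stopifnot(inherits(trains, "spike_train_set"),
            length(trains$trials) >= 2L)
  ntr <- length(trains$trials)
  dur <- trains$duration_ms
  edges <- seq(0, dur + bin_ms, by = bin_ms)
  counts <- rep(0, length(edges) - 1L)
  for (s in trains$trials) {
    if (length(s)) {
      h <- tabulate(findInterval(s, edges), nbins = length(counts))
      counts <- counts + h
    }
  }
  rate <- counts / (ntr * bin_ms) * 1000 # spikes/s
  half <- ceiling(4 * kernel_sd_ms / bin_ms)
  kt <- seq(-half, half) * bin_ms
  kern <- exp(-kt^2 / (2 * kernel_sd_ms^2))
  kern <- kern / sum(kern)
  sm <- as.numeric(stats::filter(c(rep(0, half), rate, rep(0, half)), kern,
                                 sides = 2))
  sm <- sm[half + seq_along(rate)]
  if (is.null(threshold)) threshold <- 2 * mean(rate)
  above <- !is.na(sm) & sm > threshold
  if (!any(above)) {
    return(list(reliability = 0, precision_ms = NA_real_, n_events = 0L))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- which(runs$values)
  rel <- numeric(0)
  prec <- numeric(0)
  mids <- (edges[-length(edges)] + edges[-1L]) / 2
  for (e in ev) {
    lo <- edges[starts[e]]
    hi <- edges[ends[e] + 1L]
    firsts <- vapply(trains$trials, function(s) {
      s <- s[s >= lo & s < hi]
      if (length(s)) s[1] else NA_real_
    }, numeric(1))
    hit <- !is.na(firsts)
    rel <- c(rel, mean(hit))
    if (sum(hit) > 1L) prec <- c(prec, sd(firsts[hit]))
  }
  list(reliability = mean(rel),
       precision_ms = if (length(prec)) mean(prec) else NA_real_,
       n_events = length(ev))
}

#' Welch power spectral density with spike blanking
#'
#' Averaged modified periodograms over Hann-windowed segments with the
#' given overlap. Segments overlapping a blanked interval around any spike
#' are excluded entirely. The one-sided PSD is normalised so that
#' `sum(power) * df` equals the variance of the (globally demeaned) trace
#' for a stationary signal (Parseval).
#'
#' @param x signal on a uniform grid (e.g. membrane potential, mV).
#' @param dt sampling step (ms).
#' @param window_ms segment length (ms).
#' @param overlap fractional overlap of consecutive segments (default
#'   0.5).
#' @param spike_times optional spike times (ms) for blanking.
#' @param blank_ms `c(pre, post)` exclusion window around each spike (ms).
#' @return list with `freq_hz`, `power` (units of `x^2` per Hz),
#'   `n_segments`.
#' @export
welch_psd <- function(x, dt, window_ms, overlap = 0.5, spike_times = NULL,
                      blank_ms = c(2, 8)) {
  stopifnot(dt > 0, window_ms > 0, overlap >= 0, overlap < 1)
  n <- length(x)
  nper <- floor(window_ms / dt)
  if (nper < 8L || n < 2L * nper) {
    stop("trace too short: need at least two analysis windows",
         call. = FALSE)
  }
  x <- x - mean(x)
  hop <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = hop)
  if (!is.null(spike_times) && length(spike_times)) {
    bad_lo <- (spike_times - blank_ms[1]) / dt
    bad_hi <- (spike_times + blank_ms[2]) / dt
    ok <- vapply(starts, function(s) {
      e <- s + nper - 1L
      !any(bad_lo <= e & bad_hi >= s)
    }, logical(1))
    starts <- starts[ok]
  }
  if (!length(starts)) {
    stop("all analysis windows overlap blanked spike regions",
         call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) # Hann
  u <- sum(w^2)
  fs <- 1000 / dt # Hz
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    p <- abs(fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  pow <- acc / length(starts)
  # fold negative frequencies into the one-sided spectrum
  if (nper %% 2 == 0) {
    pow[2:(nf - 1L)] <- 2 * pow[2:(nf - 1L)]
  } else {
    pow[2:nf] <- 2 * pow[2:nf]
  }
  list(freq_hz = (seq_len(nf) - 1L) * fs / nper, power = pow,
       n_segments = length(starts))
}
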