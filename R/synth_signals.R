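# Synthetic multi-site photometry and behavior streams with known ground
# truth. SNr and DCN source signals are Poisson event trains convolved with
# a 1 s decay kernel (autocorrelation is what makes the time-shift shuffle
# null informative); the thalamus ideal trace is an exact linear mixture
# plus Gaussian noise. Raw channels carry a shared multiplicative
# exponential bleach and an additive background; the 410 nm isosbestic
# channel carries the shared artifacts but no calcium transients.

#' Ground truth for a synthetic photometry mixture
#'
#' @param A,B,C Mixing coefficients of thal = A*snr + B*dcn + C.
#' @param noise_sd Gaussian noise SD added to the thalamus ideal trace
#'   (trace units, >= 0).
#' @param bleach_tau Photobleaching time constant in seconds (> 0); set to
#'   \code{Inf} to disable bleaching.
#' @param event_rate_hz Poisson rate of source transients (default 0.2).
#' @param seed Integer seed.
#' @return A list of class \code{synth_signal_truth}.
#' @export
signal_truth <- function(A = 0.5, B = 0.3, C = 0.1, noise_sd = 0.05,
                         bleach_tau = 600, event_rate_hz = 0.2, seed = 1) {
  stopifnot(noise_sd >= 0, bleach_tau > 0, event_rate_hz >= 0)
  structure(list(A = A, B = B, C = C, noise_sd = noise_sd,
                 bleach_tau = bleach_tau, event_rate_hz = event_rate_hz,
                 seed = seed), class = "synth_signal_truth")
}

# Internal: autocorrelated source trace - Poisson events convolved with an
# exponential kernel (1 s decay, fast 50 ms rise), amplitudes Exp(1).
event_trace <- function(n, fs, rate_hz, decay_s = 1, rise_s = 0.05) {
  spikes <- numeric(n)
  k <- stats::rpois(1, rate_hz * n / fs)
  if (k > 0) {
    at <- sample.int(n, k, replace = TRUE)
    amp <- stats::rexp(k)
    for (i in seq_len(k)) spikes[at[i]] <- spikes[at[i]] + amp[i]
  }
  tk <- seq(0, 5 * decay_s, by = 1 / fs)
  kern <- (1 - exp(-tk / rise_s)) * exp(-tk / decay_s)
  out <- stats::convolve(spikes, rev(kern), type = "open")[seq_len(n)]
  list(trace = out, event_times = sort(which(spikes > 0) - 1) / fs)
}

#' Generate a synchronized multi-site photometry bundle
#'
#' Produces 470 nm signal and 410 nm isosbestic channels for SNr, DCN and
#' thalamus at \code{fs} Hz, plus a background channel. The thalamus ideal
#' trace is exactly \code{A*snr + B*dcn + C} plus Gaussian noise of SD
#' \code{noise_sd}; all raw channels are multiplied by a shared exponential
#' bleach and offset by the background level.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (default 30).
#' @param truth A \code{\link{signal_truth}} object.
#' @param noise_frac If non-NULL, overrides \code{truth$noise_sd} with
#'   \code{noise_frac * sd(A*snr + B*dcn)} so noise is stated relative to
#'   the mixed signal.
#' @param f0 Baseline fluorescence of the 470 channel (a.u.).
#' @param f0_iso Baseline of the isosbestic channel.
#' @param background Background light level added to every channel.
#' @param gain Fluorescence units per unit of source activity.
#' @return A list of class \code{photometry_bundle}: \code{fs},
#'   \code{duration_s}, \code{regions} (snr/dcn/thal, each with
#'   \code{sig470} and \code{iso410}), \code{background} (trace),
#'   \code{ideal} (bleach- and noise-free source/mixture traces),
#'   \code{truth} (including the realized \code{noise_sd} and event times).
#' @export
gen_photometry <- function(duration_s = 900, fs = 30, truth = signal_truth(),
                           noise_frac = NULL, f0 = 100, f0_iso = 80,
                           background = 10, gain = 20) {
  stopifnot(duration_s > 0, fs > 0)
  set.seed(truth$seed)
  n <- round(duration_s * fs)
  snr <- event_trace(n, fs, truth$event_rate_hz)
  dcn <- event_trace(n, fs, truth$event_rate_hz)
  mix <- truth$A * snr$trace + truth$B * dcn$trace + truth$C
  noise_sd <- if (!is.null(noise_frac)) noise_frac * stats::sd(mix) else truth$noise_sd
  thal <- mix + stats::rnorm(n, 0, noise_sd)
  bleach <- if (is.finite(truth$bleach_tau)) {
    exp(-(seq_len(n) - 1) / fs / truth$bleach_tau)
  } else rep(1, n)
  raw <- function(x) list(sig470 = (f0 + gain * x) * bleach + background,
                          iso410 = f0_iso * bleach + background)
  truth$noise_sd <- noise_sd
  truth$event_times <- list(snr = snr$event_times, dcn = dcn$event_times)
  structure(list(
    fs = fs, duration_s = duration_s,
    regions = list(snr = raw(snr$trace), dcn = raw(dcn$trace), thal = raw(thal)),
    background = rep(background, n),
    ideal = list(snr = snr$trace, dcn = dcn$trace, thal = thal, mixture = mix),
    truth = truth
  ), class = "photometry_bundle")
}

#' Generate a behavior stream with known events
#'
#' Lever streams are position traces (mm) containing half-sine push pulses
#' of the requested amplitudes; wheel streams are velocity traces with
#' trapezoidal running bouts. Events must not overlap.
#'
#' @param kind \code{"lever"} or \code{"wheel"}.
#' @param events Data.frame with \code{time_s}, \code{amplitude} (mm for
#'   lever, velocity units for wheel) and optionally \code{duration_s}
#'   (default 0.5 s lever, 2 s wheel).
#' @param fs Sampling rate (Hz).
#' @param duration_s Total stream length (s).
#' @return Numeric trace with attributes \code{fs}, \code{kind} and
#'   \code{events} (the realized onset times and amplitudes).
#' @export
gen_behavior <- function(kind = c("lever", "wheel"), events, fs = 30,
                         duration_s = 60) {
  kind <- match.arg(kind)
  n <- round(duration_s * fs)
  x <- numeric(n)
  if (is.null(events) || nrow(events) == 0) {
    return(structure(x, fs = fs, kind = kind,
                     events = data.frame(time_s = numeric(0), amplitude = numeric(0))))
  }
  if (is.null(events$duration_s)) {
    events$duration_s <- if (kind == "lever") 0.5 else 2
  }
  if (kind == "lever" && any(events$amplitude < 0 | events$amplitude > 8)) {
    stop("lever amplitudes must lie within 0-8 mm")
  }
  ev <- events[order(events$time_s), ]
  ends <- ev$time_s + ev$duration_s
  if (any(ev$time_s[-1] < ends[-nrow(ev)])) stop("overlapping events")
  if (any(ev$time_s < 0) || any(ends > duration_s)) stop("events outside the stream")
  onset_real <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    i0 <- round(ev$time_s[i] * fs) + 1
    onset_real[i] <- (i0 - 1) / fs    # realized on-grid onset
    len <- max(2, round(ev$duration_s[i] * fs))
    shape <- if (kind == "lever") {
      sin(pi * seq(0, 1, length.out = len))
    } else {
      # trapezoid: 20% rise, 60% hold, 20% fall
      r <- ceiling(0.2 * len)
      c(seq(0, 1, length.out = r), rep(1, len - 2 * r), seq(1, 0, length.out = r))
    }
    idx <- i0:min(n, i0 + len - 1)
    x[idx] <- x[idx] + ev$amplitude[i] * shape[seq_along(idx)]
  }
  structure(x, fs = fs, kind = kind,
            events = data.frame(time_s = ev$time_s, onset_s = onset_real,
                                amplitude = ev$amplitude,
                                duration_s = ev$duration_s))
}
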