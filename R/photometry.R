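# Photometry preprocessing: background subtraction, zero-phase low-pass
# filtering, isosbestic least-squares correction to dF/F, trial
# segmentation around movement onset, baseline z-scoring, and early/late
# session grouping.

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward 4th-order Butterworth filtering (no group delay, which
#' onset-aligned analyses at 30 Hz cannot tolerate), with reflection
#' padding to tame edge transients.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz Critical frequency (default 2 Hz); must be below fs/2.
#' @param order Filter order (default 4).
#' @return The filtered trace, same length as \code{x}.
#' @export
lowpass <- function(x, fs, cutoff_hz = 2, order = 4) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  n <- length(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  mu <- mean(x)          # center so constant traces pass through exactly
  x <- x - mu
  p <- min(n - 1, round(3 * fs))
  xp <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[(p + 1):(p + n)] + mu
}

#' Isosbestic-corrected dF/F
#'
#' Order of operations: subtract the background estimate from both
#' channels, low-pass both with a 4th-order Butterworth at 2 Hz, fit
#' a + b * iso410 to sig470 by least squares, and return
#' (sig470 - fit) / fit. The session mean of the dedicated background
#' channel is used as the background estimate.
#'
#' @param signal_470 Calcium-dependent channel.
#' @param isosbestic_410 Isosbestic control channel (same length).
#' @param background Background channel trace, or a scalar level (default 0).
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz,order Low-pass parameters (defaults 2 Hz, 4th order).
#' @return The dF/F trace, with attribute \code{iso_fit} = c(intercept, slope).
#' @export
dff <- function(signal_470, isosbestic_410, background = 0, fs,
                cutoff_hz = 2, order = 4) {
  n <- length(signal_470)
  stopifnot(length(isosbestic_410) == n, n >= 10 * fs)
  bg <- mean(background)
  s470 <- lowpass(signal_470 - bg, fs, cutoff_hz, order)
  s410 <- lowpass(isosbestic_410 - bg, fs, cutoff_hz, order)
  beta <- stats::lm.fit(cbind(1, s410), s470)$coefficients
  beta[is.na(beta)] <- 0   # constant isosbestic channel: intercept-only fit
  fit <- beta[1] + beta[2] * s410
  if (any(fit == 0) || any(fit > 0) && any(fit < 0)) {
    stop("fitted isosbestic trace crosses zero; dF/F undefined")
  }
  out <- (s470 - fit) / fit
  attr(out, "iso_fit") <- unname(beta)
  out
}

#' Segment a recording into per-trial windows around movement onsets
#'
#' Cuts raw-channel segments of \code{window_s} seconds centered on each
#' onset and applies the full preprocessing (filtering and isosbestic
#' normalization) independently within each trial window. Onsets too close
#' to the recording edges are dropped and counted.
#'
#' @param signal_470,isosbestic_410 Raw session traces.
#' @param background Background channel or scalar (session-level estimate).
#' @param onsets_s Movement onset times in seconds.
#' @param fs Sampling rate (Hz).
#' @param window_s Trial window length (default 10 s, centered on onset).
#' @param cutoff_hz,order Low-pass parameters.
#' @return Matrix trials x samples of per-trial dF/F, with attributes
#'   \code{onset_sample} (column index of onset), \code{onsets_s} (kept)
#'   and \code{n_dropped}.
#' @export
segment_trials <- function(signal_470, isosbestic_410, background = 0,
                           onsets_s, fs, window_s = 10, cutoff_hz = 2, order = 4) {
  n <- length(signal_470)
  half <- round(window_s / 2 * fs)
  len <- 2 * half
  on_idx <- round(onsets_s * fs) + 1
  ok <- on_idx - half >= 1 & on_idx + half - 1 <= n
  if (!any(ok)) stop("no onsets with a full trial window inside the recording")
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " onset(s) dropped: trial window exceeds the recording")
  }
  on_idx <- on_idx[ok]
  bg <- mean(background)
  out <- t(vapply(on_idx, function(i) {
    idx <- (i - half):(i + half - 1)
    as.numeric(dff(signal_470[idx], isosbestic_410[idx], bg, fs, cutoff_hz, order))
  }, numeric(len)))
  attr(out, "onset_sample") <- half + 1
  attr(out, "onsets_s") <- onsets_s[ok]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Z-score trial segments against a pre-movement baseline
#'
#' Each trial is z-scored with the mean and SD of a \code{baseline_ms}
#' (default 700 ms) window ending at movement onset; for the locomotion
#' task the window is shifted \code{baseline_shift_ms} = 500 ms earlier to
#' account for pre-onset calcium changes. Trials with zero baseline SD are
#' excluded and flagged.
#'
#' @param segments Trials x samples matrix from \code{\link{segment_trials}}
#'   (or any matrix with an \code{onset_sample} attribute; defaults to the
#'   window midpoint).
#' @param fs Sampling rate (Hz).
#' @param baseline_ms Baseline duration (default 700).
#' @param baseline_shift_ms Gap between baseline end and onset (0 for the
#'   lever task, 500 for locomotion).
#' @return Z-scored matrix with attributes \code{baseline_cols},
#'   \code{excluded} (row indices dropped for zero baseline SD) and the
#'   baseline spec.
#' @export
zscore_trials <- function(segments, fs, baseline_ms = 700, baseline_shift_ms = 0) {
  onset <- attr(segments, "onset_sample")
  if (is.null(onset)) onset <- ncol(segments) / 2 + 1
  nb <- round(baseline_ms / 1000 * fs)
  shift <- round(baseline_shift_ms / 1000 * fs)
  bl_end <- onset - 1 - shift
  bl_cols <- (bl_end - nb + 1):bl_end
  if (bl_cols[1] < 1) stop("baseline window extends before the trial segment")
  mu <- rowMeans(segments[, bl_cols, drop = FALSE])
  sd_ <- apply(segments[, bl_cols, drop = FALSE], 1, stats::sd)
  excluded <- which(sd_ == 0)
  if (length(excluded) > 0) {
    message(length(excluded), " trial(s) excluded for zero baseline SD")
  }
  keep <- sd_ > 0
  z <- (segments[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  attr(z, "onset_sample") <- onset
  attr(z, "baseline_cols") <- bl_cols
  attr(z, "baseline_ms") <- baseline_ms
  attr(z, "baseline_shift_ms") <- baseline_shift_ms
  attr(z, "excluded") <- excluded
  z
}

#' Day windows defining early and late learning phases
#'
#' @param task \code{"lever"} (early days 1-3, late 8-10) or
#'   \code{"locomotion"} (early 1-2, late 4-5).
#' @return List with \code{early} and \code{late} integer day vectors.
#' @export
learning_phases <- function(task = c("lever", "locomotion")) {
  task <- match.arg(task)
  if (task == "lever") list(early = 1:3, late = 8:10) else list(early = 1:2, late = 4:5)
}

#' Average trials into early/late learning phases per subject
#'
#' Pools all trials from the task-specific early and late day windows and
#' averages them per subject and phase.
#'
#' @param trials List of entries, each a list with \code{subject},
#'   \code{day} and \code{z} (trials x samples matrix).
#' @param task Passed to \code{\link{learning_phases}}; ignored when
#'   \code{phases} is given.
#' @param phases Optional custom list(early =, late =) day vectors.
#' @return Named list per subject, each with \code{early} and \code{late}
#'   mean traces and trial counts.
#' @export
group_sessions <- function(trials, task = "lever", phases = NULL) {
  if (is.null(phases)) phases <- learning_phases(task)
  subjects <- unique(vapply(trials, `[[`, "", "subject"))
  out <- list()
  for (s in subjects) {
    res <- list()
    for (ph in c("early", "late")) {
      mats <- lapply(trials, function(tr) {
        if (tr$subject == s && tr$day %in% phases[[ph]]) tr$z else NULL
      })
      mats <- Filter(Negate(is.null), mats)
      if (length(mats) == 0) {
        stop("no trials for subject '", s, "' in the ", ph, " phase")
      }
      stacked <- do.call(rbind, mats)
      res[[ph]] <- colMeans(stacked)
      res[[paste0("n_", ph)]] <- nrow(stacked)
    }
    out[[s]] <- res
  }
  out
}
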