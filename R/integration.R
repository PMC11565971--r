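# Linear integration model: does thalamic activity follow
# A * snr + B * dcn + C? Random 135 s intervals are sampled per subject,
# ordinary least squares gives (A, B, C) and an R^2 per interval, and a
# matched control refits after shifting the SNr and DCN windows by
# independent random lags of up to +/-67.5 s, destroying temporal
# correspondence while preserving the marginal signal statistics.

#' Sample random analysis intervals across recording sessions
#'
#' Draws \code{n_intervals} start times uniformly, each contained in a
#' single session. Sessions shorter than the interval are excluded (and
#' counted); if none is long enough an error is raised.
#'
#' @param session_lengths_s Named numeric vector of session durations (s).
#' @param interval_s Interval length (default 135 s).
#' @param n_intervals Number of intervals to draw (default 20).
#' @param seed Integer seed.
#' @return Data.frame \code{session, start_s}; attribute
#'   \code{n_sessions_excluded}.
#' @export
sample_intervals <- function(session_lengths_s, interval_s = 135,
                             n_intervals = 20, seed = 1) {
  stopifnot(interval_s > 0, n_intervals >= 1)
  if (is.null(names(session_lengths_s))) {
    names(session_lengths_s) <- paste0("session", seq_along(session_lengths_s))
  }
  eligible <- session_lengths_s >= interval_s
  if (!any(eligible)) stop("no session is at least ", interval_s, " s long")
  n_excl <- sum(!eligible)
  if (n_excl > 0) message(n_excl, " session(s) shorter than the interval excluded")
  lens <- session_lengths_s[eligible]
  set.seed(seed)
  ses <- sample(names(lens), n_intervals, replace = TRUE)
  start <- stats::runif(n_intervals, 0, lens[ses] - interval_s)
  out <- data.frame(session = ses, start_s = start, stringsAsFactors = FALSE)
  attr(out, "n_sessions_excluded") <- n_excl
  out
}

#' Fit the linear integration model on one interval
#'
#' Ordinary least squares for thal = A * snr + B * dcn + C, with the
#' goodness of fit R^2 = 1 - SS_res / SS_tot of the predicted trace.
#'
#' @param thal,snr,dcn Equal-length traces (length >= 3).
#' @return List with \code{A, B, C}, \code{r2} and \code{predicted}.
#' @export
fit_integration <- function(thal, snr, dcn) {
  n <- length(thal)
  stopifnot(length(snr) == n, length(dcn) == n, n >= 3)
  x <- cbind(snr, dcn, 1)
  if (qr(x)$rank < 3) {
    stop("snr and dcn are collinear over this interval; model not identifiable")
  }
  beta <- stats::lm.fit(x, thal)$coefficients
  pred <- drop(x %*% beta)
  ss_tot <- sum((thal - mean(thal))^2)
  r2 <- 1 - sum((thal - pred)^2) / ss_tot
  list(A = unname(beta[1]), B = unname(beta[2]), C = unname(beta[3]),
       r2 = r2, predicted = pred)
}

# Internal: draw a sample shift keeping [start, start+len) inside [1, n];
# redraw up to `retries`, then clamp into range.
draw_shift <- function(start, len, n, max_shift, retries = 100) {
  for (i in seq_len(retries)) {
    s <- round(stats::runif(1, -max_shift, max_shift))
    if (start + s >= 1 && start + s + len - 1 <= n) return(list(shift = s, clamped = FALSE))
  }
  s <- round(stats::runif(1, -max_shift, max_shift))
  s <- min(max(s, 1 - start), n - len + 1 - start)
  list(shift = s, clamped = TRUE)
}

#' Shuffled control for the integration model
#'
#' For each interval, independent uniform time shifts in
#' \code{[-max_shift_s, +max_shift_s]} are drawn for the SNr and for the
#' DCN signal (separately), the shifted windows are read from the parent
#' session traces, and the regression and R^2 are recomputed against the
#' unshifted thalamus window. Shifted windows that would leave the session
#' are redrawn (bounded retries) and finally clamped.
#'
#' @param thal,snr,dcn Full parent session traces.
#' @param starts_idx Integer vector of interval start samples (1-based).
#' @param len Interval length in samples.
#' @param fs Sampling rate (Hz).
#' @param max_shift_s Maximum absolute shift (default 67.5 s).
#' @param seed Integer seed.
#' @return Data.frame \code{r2_shuffled, shift_snr_s, shift_dcn_s} per
#'   interval.
#' @export
shuffled_control <- function(thal, snr, dcn, starts_idx, len, fs,
                             max_shift_s = 67.5, seed = 1) {
  n <- length(thal)
  stopifnot(all(starts_idx >= 1), all(starts_idx + len - 1 <= n))
  set.seed(seed)
  max_shift <- max_shift_s * fs
  out <- data.frame(r2_shuffled = numeric(length(starts_idx)),
                    shift_snr_s = numeric(length(starts_idx)),
                    shift_dcn_s = numeric(length(starts_idx)))
  for (i in seq_along(starts_idx)) {
    st <- starts_idx[i]
    ds <- draw_shift(st, len, n, max_shift)
    dd <- draw_shift(st, len, n, max_shift)
    w0 <- st:(st + len - 1)
    fit <- fit_integration(thal[w0], snr[w0 + ds$shift], dcn[w0 + dd$shift])
    out$r2_shuffled[i] <- fit$r2
    out$shift_snr_s[i] <- ds$shift / fs
    out$shift_dcn_s[i] <- dd$shift / fs
  }
  out
}

#' Run the full interval-sampled integration analysis for one subject
#'
#' Samples intervals across the subject's sessions, fits the observed
#' regression per interval, and computes the matched shuffled control.
#'
#' @param sessions Named list of sessions, each a list with equal-length
#'   \code{thal}, \code{snr}, \code{dcn} traces.
#' @param fs Sampling rate (Hz).
#' @param interval_s Interval length (default 135 s).
#' @param n_intervals Number of intervals (default 20).
#' @param max_shift_s Shuffle shift bound (default 67.5 s).
#' @param seed Integer seed.
#' @param subject Subject label carried into the output.
#' @return Data.frame with one row per interval: \code{subject, session,
#'   start_s, A, B, C, r2_observed, r2_shuffled, shift_snr_s, shift_dcn_s}.
#' @export
run_integration <- function(sessions, fs, interval_s = 135, n_intervals = 20,
                            max_shift_s = 67.5, seed = 1, subject = "subject1") {
  lens <- vapply(sessions, function(s) length(s$thal) / fs, 0)
  iv <- sample_intervals(lens, interval_s, n_intervals, seed = seed)
  len <- round(interval_s * fs)
  rows <- vector("list", nrow(iv))
  for (s in unique(iv$session)) {
    ses <- sessions[[s]]
    sel <- which(iv$session == s)
    starts <- round(iv$start_s[sel] * fs) + 1
    starts <- pmin(starts, length(ses$thal) - len + 1)
    shuf <- shuffled_control(ses$thal, ses$snr, ses$dcn, starts, len, fs,
                             max_shift_s, seed = seed + 1)
    for (j in seq_along(sel)) {
      w <- starts[j]:(starts[j] + len - 1)
      fit <- fit_integration(ses$thal[w], ses$snr[w], ses$dcn[w])
      rows[[sel[j]]] <- data.frame(
        subject = subject, session = s, start_s = (starts[j] - 1) / fs,
        A = fit$A, B = fit$B, C = fit$C, r2_observed = fit$r2,
        r2_shuffled = shuf$r2_shuffled[j],
        shift_snr_s = shuf$shift_snr_s[j], shift_dcn_s = shuf$shift_dcn_s[j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-subject summary of the integration analysis
#'
#' Averages observed and shuffled R^2 over all intervals per subject and
#' tabulates the paired differences, ready for external significance
#' testing.
#'
#' @param results Data.frame from \code{\link{run_integration}} (possibly
#'   row-bound over subjects).
#' @return Data.frame \code{subject, n_intervals, mean_r2_observed,
#'   mean_r2_shuffled, paired_diff}.
#' @export
summarize_integration <- function(results) {
  stopifnot(nrow(results) >= 1)
  sp <- split(results, results$subject)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(subject = d$subject[1], n_intervals = nrow(d),
               mean_r2_observed = mean(d$r2_observed),
               mean_r2_shuffled = mean(d$r2_shuffled),
               paired_diff = mean(d$r2_observed) - mean(d$r2_shuffled),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
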