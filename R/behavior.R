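# Behavioral event quantification: lever-push detection against the
# 1 mm / 5 mm thresholds, velocity-based movement onsets, running-bout
# detection, optogenetic analysis windows, and session inclusion rules.

#' Detect lever pushes and successes in a position trace
#'
#' Candidate movements are maximal epochs where the lever position exceeds
#' half the push threshold (noise-immune), merged across gaps shorter than
#' \code{min_quiet_s}. A movement counts as a push only when its peak
#' exceeds \code{push_mm} (strictly greater than 1 mm by default) and as
#' successful when the peak reaches the \code{success_mm} reward threshold
#' (5 mm). The onset is refined by walking back from the epoch start to the
#' last sample at or below 10\% of \code{push_mm} (bounded backtrack).
#'
#' @param position Lever position trace in mm.
#' @param fs Sampling rate (Hz).
#' @param push_mm Push-counting threshold (default 1; strict inequality).
#' @param success_mm Reward threshold (default 5).
#' @param start_frac Movement-start criterion as a fraction of
#'   \code{push_mm} (default 0.1).
#' @param min_quiet_s Minimum quiet gap separating movements (default 0.2 s).
#' @param max_backtrack_s Onset backtrack bound (default 0.5 s).
#' @return Data.frame of pushes: \code{onset_idx, onset_s, peak_mm,
#'   success}; attribute \code{n_movements} counts all candidate movements.
#' @export
detect_pushes <- function(position, fs, push_mm = 1, success_mm = 5,
                          start_frac = 0.1, min_quiet_s = 0.2,
                          max_backtrack_s = 0.5) {
  if (any(!is.finite(position))) stop("non-finite samples in position trace")
  stopifnot(push_mm < success_mm)
  hi <- 0.5 * push_mm
  lo <- start_frac * push_mm
  runs <- contiguous_runs(position >= hi)
  runs <- merge_runs(runs, round(min_quiet_s * fs))
  if (nrow(runs) == 0) {
    out <- data.frame(onset_idx = integer(0), onset_s = numeric(0),
                      peak_mm = numeric(0), success = logical(0))
    attr(out, "n_movements") <- 0L
    return(out)
  }
  back <- round(max_backtrack_s * fs)
  onset <- vapply(runs$start, function(i) {
    j <- i
    while (j > 1 && i - j < back && position[j - 1] > lo) j <- j - 1
    as.integer(j)
  }, integer(1))
  peak <- vapply(seq_len(nrow(runs)), function(k) {
    max(position[runs$start[k]:runs$end[k]])
  }, 0)
  keep <- peak > push_mm
  out <- data.frame(onset_idx = onset[keep],
                    onset_s = (onset[keep] - 1) / fs,
                    peak_mm = peak[keep],
                    success = peak[keep] >= success_mm)
  attr(out, "n_movements") <- nrow(runs)
  out
}

# Internal: maximal TRUE runs of a logical vector.
contiguous_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Internal: merge runs separated by gaps shorter than `gap` samples.
merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1 < gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

#' Movement onsets from a velocity trace
#'
#' Onsets are threshold crossings of the forward movement velocity that
#' follow at least \code{min_quiet_s} of sub-threshold velocity; used to
#' align photometry trials for both the lever and the locomotion task.
#'
#' @param velocity Velocity trace (consistent units).
#' @param fs Sampling rate (Hz).
#' @param threshold Crossing threshold.
#' @param min_quiet_s Required quiet period before an onset (default 0.5 s).
#' @return Numeric vector of onset times in seconds.
#' @export
movement_onset_from_velocity <- function(velocity, fs, threshold,
                                         min_quiet_s = 0.5) {
  above <- velocity >= threshold
  runs <- contiguous_runs(above)
  if (nrow(runs) == 0) return(numeric(0))
  quiet <- round(min_quiet_s * fs)
  ok <- vapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]
    s > quiet && !any(above[(s - quiet):(s - 1)])
  }, TRUE)
  (runs$start[ok] - 1) / fs
}

#' Detect running bouts on the wheel
#'
#' Maximal epochs of supra-threshold wheel velocity, with epochs separated
#' by gaps at or below \code{merge_gap_s} joined, kept when they last at
#' least \code{min_duration_s}. The threshold and duration criteria are
#' explicit configuration.
#'
#' @param velocity Wheel velocity trace (cm/s).
#' @param fs Sampling rate (Hz).
#' @param threshold Velocity threshold (default 1 cm/s).
#' @param min_duration_s Minimum bout duration (default 1 s).
#' @param merge_gap_s Sub-threshold gaps up to this length are bridged
#'   (default 0.5 s).
#' @return Data.frame \code{start_s, end_s, duration_s}.
#' @export
detect_running_bouts <- function(velocity, fs, threshold = 1,
                                 min_duration_s = 1, merge_gap_s = 0.5) {
  runs <- contiguous_runs(velocity > threshold)
  runs <- merge_runs(runs, round(merge_gap_s * fs) + 1)
  if (nrow(runs) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  }
  dur <- (runs$end - runs$start + 1) / fs
  keep <- dur >= min_duration_s
  data.frame(start_s = (runs$start[keep] - 1) / fs,
             end_s = (runs$end[keep] - 1) / fs,
             duration_s = dur[keep])
}

#' Optogenetic silencing analysis windows
#'
#' Pure function of the laser onset and offset: baseline is the 2 min
#' before laser onset, the inhibition window is the 2 min starting 1 min
#' after onset, and the post-stim washout is the 2 min starting 1 min
#' after the laser turned off.
#'
#' @param laser_on_s,laser_off_s Laser onset/offset in seconds
#'   (\code{laser_off_s > laser_on_s}; onset must allow a full baseline).
#' @return List of length-2 windows (s): \code{baseline}, \code{inhibition},
#'   \code{post}.
#' @export
opto_windows <- function(laser_on_s, laser_off_s) {
  stopifnot(laser_off_s > laser_on_s)
  if (laser_on_s < 120) stop("laser onset before 120 s: no full baseline window")
  list(baseline = c(laser_on_s - 120, laser_on_s),
       inhibition = c(laser_on_s + 60, laser_on_s + 180),
       post = c(laser_off_s + 60, laser_off_s + 180))
}

#' Apply session/subject inclusion rules
#'
#' \code{mode = "photometry"} keeps subjects whose session-average push
#' count is at least 10. \code{mode = "opto"} keeps sessions with a
#' baseline push rate of at least 2 per minute and then, of a subject's
#' remaining silencing sessions, selects the one with the higher baseline
#' push count.
#'
#' @param sessions Data.frame with \code{subject, session} and either
#'   \code{n_pushes} (photometry mode) or \code{baseline_pushes} plus
#'   \code{baseline_min} (opto mode; baseline duration in minutes,
#'   default 2).
#' @param mode \code{"photometry"} or \code{"opto"}.
#' @param min_avg_pushes Photometry threshold (default 10).
#' @param min_rate_per_min Opto baseline rate threshold (default 2).
#' @return The filtered sessions data.frame.
#' @export
apply_inclusion <- function(sessions, mode = c("photometry", "opto"),
                            min_avg_pushes = 10, min_rate_per_min = 2) {
  mode <- match.arg(mode)
  if (mode == "photometry") {
    avg <- tapply(sessions$n_pushes, sessions$subject, mean)
    keep <- names(avg)[avg >= min_avg_pushes]
    return(sessions[sessions$subject %in% keep, , drop = FALSE])
  }
  if (is.null(sessions$baseline_min)) sessions$baseline_min <- 2
  rate <- sessions$baseline_pushes / sessions$baseline_min
  s <- sessions[rate >= min_rate_per_min, , drop = FALSE]
  if (nrow(s) == 0) return(s)
  picked <- do.call(rbind, lapply(split(s, s$subject), function(d) {
    d[which.max(d$baseline_pushes), , drop = FALSE]
  }))
  rownames(picked) <- NULL
  picked
}
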