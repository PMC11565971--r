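# Evoked synaptic current quantification and input classification.
# Convention: inward currents are negative pA, outward positive.

#' Amplitude of an optogenetically evoked current
#'
#' Subtracts the mean baseline current over the \code{baseline_ms} before
#' laser onset (default 50 ms) from the peak (largest-deviation) current in
#' the \code{search_ms} after onset; the sign of the deviation is
#' preserved, so the result is invariant to constant offsets of the whole
#' trace.
#'
#' @param time_s Sample times (s).
#' @param current_pA Current trace (pA).
#' @param onset_s Laser onset time (s).
#' @param baseline_ms Baseline duration before onset (default 50).
#' @param search_ms Peak search window after onset (default 100; the pulse
#'   lengths are known but the search window is a package choice).
#' @return Signed amplitude in pA.
#' @export
evoked_amplitude <- function(time_s, current_pA, onset_s, baseline_ms = 50,
                             search_ms = 100) {
  if (time_s[1] > onset_s - baseline_ms / 1000 + 1e-12) {
    stop("insufficient pre-onset data for the baseline window")
  }
  bl <- time_s >= onset_s - baseline_ms / 1000 & time_s < onset_s
  if (!any(bl)) stop("insufficient pre-onset data for the baseline window")
  sw <- time_s >= onset_s & time_s <= onset_s + search_ms / 1000
  if (!any(sw)) stop("no samples in the peak search window")
  base <- mean(current_pA[bl])
  dev <- current_pA[sw] - base
  dev[which.max(abs(dev))]
}

#' Classify a neuron's synaptic inputs from evoked amplitudes
#'
#' A cell receives DCN input when the inward (negative) current evoked by
#' DCN stimulation is at least 25 pA in magnitude, and SNr input when the
#' outward (positive) current evoked by SNr stimulation is at least
#' 100 pA. The two booleans define four exhaustive, mutually exclusive
#' classes.
#'
#' @param dcn_amp_pA,snr_amp_pA Signed evoked amplitudes (vectors allowed).
#' @param dcn_thresh Inward magnitude threshold for DCN input (default 25).
#' @param snr_thresh Outward threshold for SNr input (default 100).
#' @return Character vector in \code{c("dual", "snr_only", "dcn_only",
#'   "none")}.
#' @export
classify_input <- function(dcn_amp_pA, snr_amp_pA, dcn_thresh = 25,
                           snr_thresh = 100) {
  stopifnot(length(dcn_amp_pA) == length(snr_amp_pA))
  dcn_in <- dcn_amp_pA <= -dcn_thresh
  snr_in <- snr_amp_pA >= snr_thresh
  ifelse(dcn_in & snr_in, "dual",
         ifelse(snr_in, "snr_only", ifelse(dcn_in, "dcn_only", "none")))
}

#' Cross-activation check for blue-light evoked inward currents
#'
#' When opsins for both pathways are co-expressed, 450 nm stimulation can
#' cross-activate the red-shifted opsin on GABAergic terminals, producing
#' an inward current at -70 mV that is not a genuine oEPSC. Comparing the
#' response at -70 mV and +10 mV to the same 450 nm stimulus: an inward
#' current at -70 mV accompanied by an outward current at +10 mV above the
#' outward threshold carries the GABAergic signature and is flagged as
#' cross-activation; otherwise it is genuine. A missing +10 mV measurement
#' leaves the call unverified.
#'
#' @param amp_at_minus70 Signed amplitude at -70 mV holding (pA).
#' @param amp_at_plus10 Signed amplitude at +10 mV holding, or NA.
#' @param outward_thresh Outward threshold at +10 mV (default 100 pA, the
#'   same criterion used for SNr input).
#' @return One of \code{"genuine"}, \code{"cross_activation"},
#'   \code{"unverified"}.
#' @export
cross_activation_check <- function(amp_at_minus70, amp_at_plus10,
                                   outward_thresh = 100) {
  if (is.na(amp_at_plus10)) return("unverified")
  if (amp_at_minus70 < 0 && amp_at_plus10 >= outward_thresh) "cross_activation"
  else "genuine"
}
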