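#' Remove the DC offset from a record
#'
#' Subtracts the arithmetic mean of the samples, the first conditioning
#' step applied to a raw recording.
#'
#' @param record An [emg_record()].
#' @return The record with zero-mean samples.
#' @examples
#' remove_dc(emg_record(c(1, 2, 3, 4), fs = 10))$samples
#' @export
remove_dc <- function(record) {
  stopifnot(inherits(record, "emg_record"))
  record$samples <- record$samples - mean(record$samples)
  record
}

#' Condition a raw sEMG record
#'
#' Standard conditioning chain for a raw single-channel sEMG recording:
#' DC-offset removal, a Butterworth band-pass retaining the informative
#' 25-350 Hz EMG band, and a Butterworth band-stop at 47-53 Hz suppressing
#' 50 Hz power-line interference. Both filters use design order 2 and are
#' applied zero-phase (forward-backward) by default so that envelope
#' timing is preserved across later sub-band comparisons; a causal
#' single-pass mode is available via `zero_phase = FALSE`.
#'
#' @param record An [emg_record()] with `fs > 700` Hz (so the 350 Hz
#'   corner stays below Nyquist).
#' @param config A [classifier_config()] supplying the filter corners and
#'   orders.
#' @param zero_phase Override the config's zero-phase flag.
#' @return The conditioned [emg_record()].
#' @export
preprocess <- function(record, config = classifier_config(),
                       zero_phase = NULL) {
  stopifnot(inherits(record, "emg_record"))
  if (record$fs <= 2 * config$bp_high)
    stop("sampling rate ", record$fs, " Hz too low: band-pass corner ",
         config$bp_high, " Hz must lie below Nyquist", call. = FALSE)
  zp <- if (is.null(zero_phase)) config$zero_phase else isTRUE(zero_phase)
  bp <- filter_spec("band-pass", config$bp_order, config$bp_low,
                    config$bp_high, zero_phase = zp)
  bs <- filter_spec("band-stop", config$bs_order, config$bs_low,
                    config$bs_high, zero_phase = zp)
  rec <- remove_dc(record)
  rec <- apply_filter(rec, bp)
  apply_filter(rec, bs)
}
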