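#' Configuration for the double-step fatigue classifier
#'
#' Bundles every tunable of the analysis pipeline. The defaults are the
#' algorithm as published: 3 s windows with 1.5 s overlap, conditioning
#' band-pass 25-350 Hz (order 2) and power-line band-stop 47-53 Hz
#' (order 2), and sub-band decomposition into a low-frequency component
#' band (LFC, 25-79 Hz) and a high-frequency component band (HFC,
#' 80-350 Hz) with order-4 Butterworth band-passes. The 79/80 Hz boundary
#' is kept exactly as published even though the two Butterworth roll-offs
#' overlap near 80 Hz; no guard band is inserted.
#'
#' @param window_s,overlap_s Segmentation window and overlap, seconds.
#' @param bp_low,bp_high,bp_order Conditioning band-pass corners (Hz) and
#'   design order.
#' @param bs_low,bs_high,bs_order Power-line band-stop corners (Hz) and
#'   design order.
#' @param lfc_low,lfc_high Low-frequency component band corners (Hz).
#' @param hfc_low,hfc_high High-frequency component band corners (Hz).
#' @param subband_order Design order of the two sub-band band-passes.
#' @param zero_phase Apply all filters forward-backward (default); set
#'   `FALSE` for causal single-pass filtering.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(window_s = 3, overlap_s = 1.5,
                              bp_low = 25, bp_high = 350, bp_order = 2,
                              bs_low = 47, bs_high = 53, bs_order = 2,
                              lfc_low = 25, lfc_high = 79,
                              hfc_low = 80, hfc_high = 350,
                              subband_order = 4, zero_phase = TRUE) {
  cfg <- list(window_s = window_s, overlap_s = overlap_s,
              bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
              bs_low = bs_low, bs_high = bs_high, bs_order = bs_order,
              lfc_low = lfc_low, lfc_high = lfc_high,
              hfc_low = hfc_low, hfc_high = hfc_high,
              subband_order = subband_order,
              zero_phase = isTRUE(zero_phase))
  if (!(cfg$lfc_high < cfg$hfc_low))
    stop("low band must end below the high band (lfc_high < hfc_low)",
         call. = FALSE)
  if (!(cfg$overlap_s >= 0 && cfg$overlap_s < cfg$window_s))
    stop("need 0 <= overlap_s < window_s", call. = FALSE)
  structure(cfg, class = "classifier_config")
}

#' Extract a band-limited sub-signal from a segment
#'
#' Band-pass-filters a segment to one of the two component bands,
#' producing the low-frequency sub-signal (LFSS) or high-frequency
#' sub-signal (HFSS). Filtering is per-segment, after segmentation.
#'
#' @param seg An `emg_segment` (or [emg_record()]).
#' @param low,high Band corners in Hz.
#' @param order Butterworth design order (default 4).
#' @param zero_phase Forward-backward application (default `TRUE`).
#' @return The band-limited segment, same length and metadata.
#' @export
extract_subband <- function(seg, low, high, order = 4, zero_phase = TRUE) {
  spec <- filter_spec("band-pass", order, low, high,
                      zero_phase = zero_phase)
  apply_filter(seg, spec)
}

#' Instantaneous mean amplitude of a segment
#'
#' Mean magnitude of the full two-sided discrete Fourier transform of the
#' segment, `(1/N) * sum(|X_n|)` over all `N` bins. Applied to the LFSS
#' and HFSS of a window, the two IMA values summarize how much signal
#' amplitude each component band carries.
#'
#' @param seg An `emg_segment`, [emg_record()] or numeric vector.
#' @return Nonnegative scalar.
#' @examples
#' ima(c(1, 0, 0, 0))  # impulse: flat unit spectrum, IMA = 1
#' @export
ima <- function(seg) {
  x <- .samples_of(seg)
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  mean(Mod(stats::fft(x)))
}

#' Sub-band analysis and fatigue index of a segment
#'
#' Decomposes a (conditioned) segment into its low- and high-frequency
#' sub-signals, computes the IMA of each, and returns the fatigue index
#' `IMA(LFSS) - IMA(HFSS)`. During progressing fatigue spectral mass
#' migrates downward, so the index rises from negative toward zero and
#' beyond; a nonnegative index marks the fatigue state (see
#' [fatigue_decision()]).
#'
#' @param seg A conditioned `emg_segment`.
#' @param config A [classifier_config()].
#' @return A `subband_analysis`: list with `ima_lfss`, `ima_hfss`,
#'   `fatigue_index`.
#' @export
fatigue_index <- function(seg, config = classifier_config()) {
  lf <- extract_subband(seg, config$lfc_low, config$lfc_high,
                        config$subband_order, config$zero_phase)
  hf <- extract_subband(seg, config$hfc_low, config$hfc_high,
                        config$subband_order, config$zero_phase)
  il <- ima(lf)
  ih <- ima(hf)
  structure(list(ima_lfss = il, ima_hfss = ih, fatigue_index = il - ih),
            class = "subband_analysis")
}

#' Decision rule on a fatigue-index value
#'
#' Maps an index value to a label: `"fatigue"` when the index is greater
#' than or equal to zero (the low band carries at least as much mean
#' amplitude as the high band), `"non-fatigue"` otherwise.
#'
#' @param index Numeric fatigue-index value(s).
#' @return Character vector of labels.
#' @export
fatigue_decision <- function(index) {
  ifelse(index >= 0, "fatigue", "non-fatigue")
}

#' Classify one segment with the double-step rule
#'
#' Step 1 gates on contraction: the segment's IEMG must strictly exceed
#' the session's baseline IEMG (`iemg_initial`, the first segment's
#' value). If the gate fails the segment is labeled non-fatigue and no
#' sub-band analysis is performed. If it passes, step 2 computes the
#' fatigue index and applies [fatigue_decision()]. The gate is evaluated
#' independently for every segment (no latching).
#'
#' @param seg A conditioned `emg_segment`.
#' @param iemg_initial Baseline IEMG (>= 0).
#' @param config A [classifier_config()].
#' @param gate Set `FALSE` to skip step 1 and label purely by the index
#'   sign (used to demonstrate why the gate is necessary).
#' @return A `segment_classification`: list with `segment_index`,
#'   `t_start`, `iemg`, `gate_passed`, `subband` (or `NULL`), `label`.
#' @export
classify_segment <- function(seg, iemg_initial,
                             config = classifier_config(), gate = TRUE) {
  stopifnot(inherits(seg, "emg_segment"))
  if (!is.numeric(iemg_initial) || iemg_initial < 0)
    stop("`iemg_initial` must be a nonnegative number", call. = FALSE)
  iemg_v <- iemg(seg)
  gate_passed <- iemg_v > iemg_initial
  if (gate && !gate_passed) {
    sb <- NULL
    label <- "non-fatigue"
  } else {
    sb <- fatigue_index(seg, config)
    label <- fatigue_decision(sb$fatigue_index)
  }
  structure(list(segment_index = seg$index, t_start = seg$t_start,
                 iemg = iemg_v, gate_passed = gate_passed,
                 subband = sb, label = label),
            class = "segment_classification")
}

#' Detect muscle fatigue in an sEMG record
#'
#' Runs the full double-step pipeline on a record: conditioning
#' ([preprocess()]), overlapping segmentation ([segment_record()]), then
#' per-segment classification ([classify_segment()]) against the first
#' segment's IEMG baseline. The first segment always comes out
#' non-fatigue: it cannot strictly exceed its own baseline. The fatigue
#' report collects every per-segment outcome in order, together with the
#' onset time, defined as the start time of the first fatigue-labeled
#' segment.
#'
#' @param record An [emg_record()] long enough for at least two windows.
#' @param config A [classifier_config()].
#' @param gate Set `FALSE` for the step-2-only variant (no IEMG gate).
#' @param preprocessed Set `TRUE` if `record` is already conditioned.
#' @return A `fatigue_report`: list with `segments` (data frame:
#'   `segment_index`, `t_start_s`, `iemg`, `gate_passed`, `ima_lfss`,
#'   `ima_hfss`, `fatigue_index`, `label`), `iemg_initial`, `onset_time`
#'   (seconds, `NA` if no segment is labeled fatigue), `config`, `gate`.
#' @examples
#' \donttest{
#' sim <- simulate_semg(duration_s = 30, crossover_s = 15, seed = 1)
#' rep <- detect_fatigue(sim$record)
#' summary(rep)
#' }
#' @export
detect_fatigue <- function(record, config = classifier_config(),
                           gate = TRUE, preprocessed = FALSE) {
  stopifnot(inherits(record, "emg_record"))
  if (!preprocessed) record <- preprocess(record, config)
  segs <- segment_record(record, config$window_s, config$overlap_s)
  if (length(segs) < 2L)
    stop("record too short: at least two windows are required",
         call. = FALSE)
  iemg_initial <- iemg(segs[[1L]])
  cls <- lapply(segs, classify_segment, iemg_initial = iemg_initial,
                config = config, gate = gate)
  seg_df <- do.call(rbind, lapply(cls, function(cc) {
    data.frame(
      segment_index = cc$segment_index,
      t_start_s = cc$t_start,
      iemg = cc$iemg,
      gate_passed = cc$gate_passed,
      ima_lfss = if (is.null(cc$subband)) NA_real_ else cc$subband$ima_lfss,
      ima_hfss = if (is.null(cc$subband)) NA_real_ else cc$subband$ima_hfss,
      fatigue_index = if (is.null(cc$subband)) NA_real_
                      else cc$subband$fatigue_index,
      label = cc$label,
      stringsAsFactors = FALSE)
  }))
  fat <- which(seg_df$label == "fatigue")
  structure(list(segments = seg_df,
                 iemg_initial = iemg_initial,
                 onset_time = if (length(fat) > 0L)
                   seg_df$t_start_s[fat[1L]] else NA_real_,
                 config = config, gate = gate,
                 call = match.call()),
            class = "fatigue_report")
}

#' @export
print.fatigue_report <- function(x, ...) {
  n <- nrow(x$segments)
  nf <- sum(x$segments$label == "fatigue")
  cat(sprintf("Double-step sEMG fatigue report: %d segments, %d fatigue\n",
              n, nf))
  if (is.na(x$onset_time)) cat("No fatigue detected.\n")
  else cat(sprintf("Fatigue onset at %.1f s (segment %d).\n", x$onset_time,
                   x$segments$segment_index[
                     which(x$segments$label == "fatigue")[1L]]))
  invisible(x)
}

#' @export
summary.fatigue_report <- function(object, ...) {
  seg <- object$segments
  out <- list(
    n_segments = nrow(seg),
    n_fatigue = sum(seg$label == "fatigue"),
    n_gate_passed = sum(seg$gate_passed),
    iemg_initial = object$iemg_initial,
    iemg_slope = iemg_slope(seg$iemg),
    onset_time = object$onset_time,
    final_index = utils::tail(seg$fatigue_index[!is.na(seg$fatigue_index)],
                              1L)
  )
  class(out) <- "summary.fatigue_report"
  out
}

#' @export
print.summary.fatigue_report <- function(x, ...) {
  cat("Double-step sEMG fatigue report\n")
  cat(sprintf("  segments:            %d (%d fatigue, %d passed the gate)\n",
              x$n_segments, x$n_fatigue, x$n_gate_passed))
  cat(sprintf("  IEMG baseline:       %.6g\n", x$iemg_initial))
  cat(sprintf("  IEMG slope/segment:  %.6g\n", x$iemg_slope))
  if (length(x$final_index) == 1L)
    cat(sprintf("  final fatigue index: %.6g\n", x$final_index))
  if (is.na(x$onset_time)) cat("  onset:               no fatigue detected\n")
  else cat(sprintf("  onset:               %.1f s\n", x$onset_time))
  invisible(x)
}

#' @export
as.data.frame.fatigue_report <- function(x, ...) x$segments

#' Plot a fatigue report
#'
#' Two stacked panels: the per-segment IMA of the low- and high-frequency
#' sub-signals (whose crossing marks the onset), and the fatigue index
#' with the zero decision threshold. Segments that failed the IEMG gate
#' have no sub-band analysis and appear as gaps.
#'
#' @param x A `fatigue_report`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fatigue_report <- function(x, ...) {
  seg <- x$segments
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(c(seg$ima_lfss, seg$ima_hfss), na.rm = TRUE)
  graphics::plot(seg$t_start_s, seg$ima_hfss, type = "l", col = "red",
                 xlab = "time (s)", ylab = "IMA", ylim = ylim,
                 main = "Sub-band instantaneous mean amplitude", ...)
  graphics::lines(seg$t_start_s, seg$ima_lfss, col = "blue")
  graphics::legend("topright", c("HFSS", "LFSS"), col = c("red", "blue"),
                   lty = 1, bty = "n")
  graphics::plot(seg$t_start_s, seg$fatigue_index, type = "b", pch = 16,
                 cex = 0.6, xlab = "time (s)", ylab = "fatigue index",
                 main = "Fatigue index", ...)
  graphics::abline(h = 0, lty = 2)
  if (!is.na(x$onset_time)) graphics::abline(v = x$onset_time, col = "grey")
  invisible(x)
}
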