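#' Integrated EMG of a segment
#'
#' The integrated EMG (IEMG) of a window is the sum of absolute sample
#' amplitudes, `sum(|x_n|)` over the window. It rises with sustained
#' contraction and progressing fatigue, and is the quantity the
#' classifier's first step gates on.
#'
#' @param seg An `emg_segment`, [emg_record()] or numeric vector.
#' @return Nonnegative scalar.
#' @examples
#' iemg(c(0.3, -0.5, 0.2, -0.1, 0.4, -0.2))  # 1.7
#' @export
iemg <- function(seg) {
  x <- .samples_of(seg)
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  sum(abs(x))
}

#' One-sided periodogram of a segment
#'
#' Raw single-window periodogram of the untapered segment: `P_k = |X_k|^2`
#' from the discrete Fourier transform, retained for bins
#' `k = 0..floor(N/2)` at frequencies `k * fs / N`. No averaging or taper
#' is applied: the segmentation windows are rectangular by construction.
#'
#' @param seg An `emg_segment`, or a numeric vector with `fs` supplied.
#' @param fs Sampling rate in Hz (ignored when `seg` carries one).
#' @return A `power_spectrum`: list with `freqs` (Hz), `power`,
#'   and the segment length `n`. An all-zero input is flagged with
#'   attribute `degenerate = TRUE`.
#' @export
power_spectrum <- function(seg, fs = NULL) {
  x <- .samples_of(seg)
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  if (is.null(fs)) {
    if (inherits(seg, c("emg_record", "emg_segment"))) fs <- seg$fs
    else stop("`fs` required for a bare numeric vector", call. = FALSE)
  }
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n %/% 2)
  ps <- structure(
    list(freqs = k * fs / n, power = Mod(X[k + 1L])^2, n = n),
    class = "power_spectrum")
  if (all(x == 0)) attr(ps, "degenerate") <- TRUE
  ps
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%g Hz, total power %.4g\n",
              length(x$freqs), max(x$freqs), sum(x$power)))
  invisible(x)
}

# shared validation for spectral moments; drops the DC bin (the offset is
# removed upstream and the moment sums index from k = 1)
.spectral_bins <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  keep <- ps$freqs > 0
  f <- ps$freqs[keep]
  p <- ps$power[keep]
  if (sum(p) <= 0)
    stop("degenerate spectrum: total power is zero", call. = FALSE)
  list(f = f, p = p)
}

#' Mean frequency of a power spectrum
#'
#' Power-weighted mean frequency, `sum(f_k P_k) / sum(P_k)` over the
#' one-sided bins (DC excluded). Together with [mdf()] it locates the
#' spectral centre of an EMG window, which is how the 80 Hz boundary
#' between the low- and high-frequency component bands is justified.
#'
#' @param ps A [power_spectrum()].
#' @return Mean frequency in Hz.
#' @export
mnf <- function(ps) {
  b <- .spectral_bins(ps)
  sum(b$f * b$p) / sum(b$p)
}

#' Median frequency of a power spectrum
#'
#' The frequency splitting the spectrum into two halves of equal power.
#' On discrete bins exact equality rarely holds, so the smallest bin
#' frequency at which the cumulative power reaches half the total is
#' returned (DC excluded).
#'
#' @param ps A [power_spectrum()].
#' @return Median frequency in Hz.
#' @export
mdf <- function(ps) {
  b <- .spectral_bins(ps)
  cum <- cumsum(b$p)
  b$f[which(cum >= sum(b$p) / 2)[1L]]
}

#' Per-segment feature summary
#'
#' Convenience wrapper computing IEMG, MNF and MDF for every segment of a
#' record (after conditioning, if requested).
#'
#' @param record An [emg_record()].
#' @param config A [classifier_config()].
#' @param preprocessed Set `TRUE` if `record` is already conditioned.
#' @return A data frame with one row per segment: `segment_index`,
#'   `t_start_s`, `iemg`, `mnf_hz`, `mdf_hz`.
#' @export
segment_features <- function(record, config = classifier_config(),
                             preprocessed = FALSE) {
  if (!preprocessed) record <- preprocess(record, config)
  segs <- segment_record(record, config$window_s, config$overlap_s)
  do.call(rbind, lapply(segs, function(s) {
    ps <- power_spectrum(s)
    data.frame(segment_index = s$index, t_start_s = s$t_start,
               iemg = iemg(s), mnf_hz = mnf(ps), mdf_hz = mdf(ps))
  }))
}
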