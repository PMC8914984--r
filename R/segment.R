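#' Split a record into overlapping rectangular windows
#'
#' Segments a record into fixed-length rectangular windows (default 3 s
#' with 1.5 s overlap). Windows are half-open sample ranges
#' `[start, start + N)` with `start = round(i * hop * fs)` for hop
#' `window_s - overlap_s`, so no sample is assigned by a rounding
#' accident. A trailing stretch shorter than a full window is discarded:
#' all downstream features normalize by the fixed window length `N`.
#' "Rectangular" means no taper is applied before any FFT.
#'
#' @param record An [emg_record()] at least one window long.
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds,
#'   `0 <= overlap_s < window_s`.
#' @return A list of `emg_segment` objects, each a list with `samples`,
#'   `index` (1-based segment number), `t_start` (seconds) and `fs`.
#' @examples
#' rec <- emg_record(rnorm(9 * 100), fs = 100)
#' length(segment_record(rec))  # floor((9 - 3) / 1.5) + 1 = 5
#' @export
segment_record <- function(record, window_s = 3, overlap_s = 1.5) {
  stopifnot(inherits(record, "emg_record"))
  if (!(overlap_s >= 0 && overlap_s < window_s))
    stop("need 0 <= overlap_s < window_s", call. = FALSE)
  fs <- record$fs
  n <- length(record$samples)
  nw <- as.integer(round(window_s * fs))
  if (n < nw)
    stop(sprintf("record (%.3f s) shorter than one %g s window",
                 n / fs, window_s), call. = FALSE)
  hop <- window_s - overlap_s
  segs <- list()
  i <- 0L
  repeat {
    start <- as.integer(round(i * hop * fs))  # 0-based start sample
    if (start + nw > n) break
    segs[[i + 1L]] <- structure(
      list(samples = record$samples[(start + 1L):(start + nw)],
           index = i + 1L, t_start = i * hop, fs = fs),
      class = "emg_segment")
    i <- i + 1L
  }
  segs
}

#' @export
print.emg_segment <- function(x, ...) {
  cat(sprintf("<emg_segment> #%d: %d samples @ %g Hz, t = %.3f s\n",
              x$index, length(x$samples), x$fs, x$t_start))
  invisible(x)
}
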