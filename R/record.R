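#' Construct a single-channel sEMG record
#'
#' An `emg_record` is the container every stage of the pipeline transforms:
#' a uniformly sampled sequence of amplitudes together with its sampling
#' rate. Amplitudes are in volts or arbitrary sensor units; the classifier
#' is scale-invariant so the unit never matters.
#'
#' @param samples Numeric vector of amplitudes. Must be non-empty and all
#'   finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Optional free-text channel/muscle identifier.
#'
#' @return An object of class `emg_record`: a list with elements
#'   `samples`, `fs` and `label`.
#' @examples
#' rec <- emg_record(sin(2 * pi * 100 * seq(0, 1, by = 1 / 2000)), fs = 2000)
#' rec
#' @export
emg_record <- function(samples, fs, label = "") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` contains non-finite values (first at index ",
         which(!is.finite(samples))[1L], ")", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         label = as.character(label)[1L]),
    class = "emg_record"
  )
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.emg_record <- function(x) length(x$samples)

#' Duration of a record in seconds
#' @param record An [emg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "emg_record"))
  length(record$samples) / record$fs
}

# coerce segment-or-record-or-numeric to a bare numeric vector
.samples_of <- function(x) {
  if (inherits(x, c("emg_record", "emg_segment"))) x$samples
  else if (is.numeric(x)) x
  else stop("expected an emg_record, emg_segment or numeric vector",
            call. = FALSE)
}
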