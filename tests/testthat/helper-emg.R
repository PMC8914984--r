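# Shared test helpers: tone/segment builders and independent oracles.

fs_default <- 2000

make_tone <- function(f, fs = fs_default, dur = 3, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs + phase)
}

make_segment <- function(samples, fs = fs_default, index = 1L, t_start = 0) {
  structure(list(samples = samples, index = index, t_start = t_start,
                 fs = fs), class = "emg_segment")
}

rms <- function(x) sqrt(mean(x^2))

# drop 0.25 s from each end before steady-state RMS comparisons
edge_trim <- function(x, fs = fs_default, trim_s = 0.25) {
  k <- round(trim_s * fs)
  x[(k + 1):(length(x) - k)]
}

# O(N^2) DFT oracle, independent of stats::fft
dft_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

# single-pass Butterworth gain oracle via signal::butter + polynomial
# evaluation on the unit circle (independent of filter_gain())
butter_gain_oracle <- function(order, low, high, f, fs,
                               type = "pass", zero_phase = TRUE) {
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = type)
  z <- exp(-1i * 2 * pi * f / fs)
  g <- abs(sum(filt$b * z^(0:(length(filt$b) - 1))) /
           sum(filt$a * z^(0:(length(filt$a) - 1))))
  if (zero_phase) g^2 else g
}

# write a label-table CSV from a matrix of labels
write_label_csv <- function(labels, path = tempfile(fileext = ".csv")) {
  df <- data.frame(subject = seq_len(nrow(labels)), muscle = "left",
                   labels, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "emgfatigue", mustWork = TRUE)
}
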