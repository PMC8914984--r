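# Synthetic sEMG generation.
#
# The surrogate for each component band is a stationary Gaussian-like
# process built as a mixture of (a) a dense random-phase harmonic series
# at every integer frequency in the band, which pins the spectral
# envelope, and (b) band-pass-filtered white Gaussian noise, which
# supplies realistic spectral variability. Each band surrogate is then
# rescaled so that one unit of band weight produces one unit of measured
# sub-band IMA through the full analysis pipeline; this makes the
# designed weight-crossover time coincide with the fatigue-index zero
# crossing, i.e. a well-defined ground truth for onset recovery.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# random-phase harmonic series at every integer Hz in [low, high],
# unit variance; synthesized by inverse FFT when the tones fall on the
# record's frequency grid, otherwise by direct summation
.band_comb <- function(n, fs, low, high) {
  freqs <- seq(ceiling(low), floor(high))
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  bins <- freqs * n / fs
  if (all(abs(bins - round(bins)) < 1e-9) && all(round(bins) < n / 2)) {
    Z <- complex(n)
    k <- round(bins)
    Z[k + 1L] <- (n / 2) * exp(1i * phases)
    Z[n - k + 1L] <- Conj(Z[k + 1L])
    x <- Re(stats::fft(Z, inverse = TRUE)) / n
  } else {
    t <- (seq_len(n) - 1L) / fs
    x <- numeric(n)
    for (j in seq_along(freqs))
      x <- x + cos(2 * pi * freqs[j] * t + phases[j])
  }
  x / stats::sd(x)
}

# band-limited white Gaussian noise, unit variance
.band_noise <- function(n, fs, low, high, order = 4) {
  spec <- filter_spec("band-pass", order, low, high, zero_phase = TRUE)
  x <- apply_filter(stats::rnorm(n), spec, fs = fs)
  x / stats::sd(x)
}

# mean LFSS and HFSS IMA of a surrogate through the full analysis
# pipeline (conditioning + per-segment sub-band extraction)
.pipeline_band_imas <- function(x, fs, config) {
  rec <- preprocess(emg_record(x, fs), config)
  segs <- segment_record(rec, config$window_s, config$overlap_s)
  vals <- vapply(segs, function(s) c(
    ima(extract_subband(s, config$lfc_low, config$lfc_high,
                        config$subband_order, config$zero_phase)),
    ima(extract_subband(s, config$hfc_low, config$hfc_high,
                        config$subband_order, config$zero_phase))),
    numeric(2))
  rowMeans(vals)
}

# Band surrogate (harmonic comb + filtered noise), calibrated so that one
# unit of band weight contributes one unit to the measured fatigue index
# net of cross-band filter leakage: the two order-4 sub-band filters
# adjoin at 79/80 Hz, so a surrogate raises the other band's IMA a
# little, and calibrating the difference (own-band minus other-band IMA)
# makes the designed weight crossover the exact index zero crossing.
.band_surrogate <- function(n, fs, low, high, noise_mix, config) {
  x <- if (noise_mix < 1)
    sqrt(1 - noise_mix) * .band_comb(n, fs, low, high) else 0
  if (noise_mix > 0)
    x <- x + sqrt(noise_mix) * .band_noise(n, fs, low, high)
  g <- .pipeline_band_imas(x, fs, config)
  own_low <- low < config$hfc_low
  net <- if (own_low) g[1L] - g[2L] else g[2L] - g[1L]
  x / net
}

# Joint refinement: rescale the low surrogate so that an equal-weight
# mixture measures a zero fatigue index through the pipeline. Per-band
# calibration cannot see the small phasor interaction between the two
# sub-signals in the shared roll-off bins near the 79/80 Hz boundary;
# zeroing the equal-weight mixture pins the crossover exactly, since at
# the designed crossover the mixture *is* equal-weight (overall amplitude
# scales out). Newton steps with unit slope: the net index gain of the
# low surrogate is ~1 after .band_surrogate calibration.
.joint_calibrate <- function(s_l, s_h, fs, config) {
  rho <- 1
  for (k in 1:3) {
    g <- .pipeline_band_imas(rho * s_l + s_h, fs, config)
    delta <- g[1L] - g[2L]
    if (abs(delta) < 1e-4) break
    rho <- rho - delta
  }
  rho * s_l
}

# broadband (conditioning-band) noise, calibrated to unit full-band IMA
# so `noise_floor` shares the band weights' units
.broadband_surrogate <- function(n, fs, config) {
  x <- .band_noise(n, fs, config$bp_low, config$bp_high)
  rec <- preprocess(emg_record(x, fs), config)
  segs <- segment_record(rec, config$window_s, config$overlap_s)
  x / mean(vapply(segs, ima, numeric(1)))
}

.check_sim_common <- function(fs, duration_s, config) {
  if (fs < 800)
    stop("`fs` must be at least 800 Hz (EMG extends to ~400 Hz)",
         call. = FALSE)
  if (duration_s < 2 * config$window_s)
    stop("`duration_s` must cover at least two windows", call. = FALSE)
}

#' Simulate an sEMG record with controllable fatigue structure
#'
#' Generates a synthetic single-channel sEMG record as an
#' amplitude-modulated mixture of two band-limited surrogates - one in
#' the low-frequency component band (25-79 Hz), one in the high-frequency
#' band (80-350 Hz) - plus a broadband noise floor:
#' `x(t) = amp(t) * (w_l(t) * s_L(t) + w_h(t) * s_H(t)) + floor * s_0(t)`.
#'
#' In fatigue mode the high-band weight falls and the low-band weight
#' rises linearly so that they cross at `crossover_s`; because each
#' surrogate is calibrated to unit sub-band IMA per unit weight (see the
#' package vignette), the crossover time is the designed ground-truth
#' fatigue onset. The overall amplitude grows linearly
#' (`amp(t) = amp0 * (1 + amp_growth * t)`), driving the rising IEMG that
#' the classifier's first step gates on. With `crossover_s = NULL` the
#' weights stay constant (high band dominant): a stationary non-fatigue
#' signal.
#'
#' @param duration_s Record length in seconds (default 80).
#' @param fs Sampling rate in Hz (default 2000; must be >= 800).
#' @param seed Integer seed; the output is bit-identical for a given
#'   seed.
#' @param amp0 Baseline amplitude (arbitrary sensor units).
#' @param amp_growth Fractional amplitude increase per second.
#' @param w_l0,w_h0 Initial low-/high-band weights (fatigue mode needs
#'   `w_h0 > w_l0`).
#' @param w_cross Common weight value at the crossover; sets the two
#'   linear rates independently (`NULL` for the symmetric midpoint).
#' @param crossover_s Designed crossover time in seconds, or `NULL` for
#'   non-fatigue mode.
#' @param noise_floor Broadband (25-350 Hz) noise weight relative to
#'   `amp0`.
#' @param noise_mix Fraction of each band surrogate's power carried by
#'   filtered white noise rather than the harmonic series (0-1).
#' @param config A [classifier_config()]; supplies the band corners and
#'   the calibration pipeline settings.
#' @return An `semg_simulation`: list with `record` (an [emg_record()]),
#'   `truth` (mode, `crossover_s`, and the per-segment-grid weight
#'   trajectories) and `params`.
#' @examples
#' \donttest{
#' sim <- simulate_semg(duration_s = 30, crossover_s = 15, seed = 42)
#' plot(detect_fatigue(sim$record))
#' }
#' @export
simulate_semg <- function(duration_s = 80, fs = 2000, seed = 1,
                          amp0 = 0.1, amp_growth = 0.06,
                          w_l0 = 0.1, w_h0 = 2.2, w_cross = 0.25,
                          crossover_s = 50, noise_floor = 0.02,
                          noise_mix = 0.2,
                          config = classifier_config()) {
  .check_sim_common(fs, duration_s, config)
  if (w_l0 < 0 || w_h0 < 0) stop("weights must be >= 0", call. = FALSE)
  if (!(noise_mix >= 0 && noise_mix <= 1))
    stop("`noise_mix` must lie in [0, 1]", call. = FALSE)
  fatigue_mode <- !is.null(crossover_s)
  if (fatigue_mode) {
    if (crossover_s <= 0) stop("`crossover_s` must be > 0", call. = FALSE)
    if (!(w_h0 > w_l0))
      stop("fatigue mode needs w_h0 > w_l0", call. = FALSE)
    if (is.null(w_cross)) w_cross <- (w_l0 + w_h0) / 2
    if (!(w_cross > w_l0 && w_cross < w_h0))
      stop("`w_cross` must lie strictly between w_l0 and w_h0",
           call. = FALSE)
    if (crossover_s > duration_s - config$window_s)
      warning("crossover_s lies beyond the analyzed record; ",
              "no onset will fall within it", call. = FALSE)
  }

  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs

  .with_seed(seed, {
    s_l <- .band_surrogate(n, fs, config$lfc_low, config$lfc_high,
                           noise_mix, config)
    s_h <- .band_surrogate(n, fs, config$hfc_low, config$hfc_high,
                           noise_mix, config)
    s_l <- .joint_calibrate(s_l, s_h, fs, config)
    s_0 <- .broadband_surrogate(n, fs, config)
  })

  if (fatigue_mode) {
    # The classifier judges a window by its mean content but reports its
    # start time, so the crossover is defined as the start of the first
    # window whose mean spectral balance favours the low band: the
    # trajectories run on window-start time, i.e. delayed by half a
    # window relative to wall-clock time.
    rate_l <- (w_cross - w_l0) / crossover_s
    rate_h <- (w_h0 - w_cross) / crossover_s
    ts <- pmax(0, t - config$window_s / 2)
    w_l <- w_l0 + rate_l * ts
    w_h <- pmax(0, w_h0 - rate_h * ts)
  } else {
    w_l <- rep(w_l0, n)
    w_h <- rep(w_h0, n)
  }
  amp <- amp0 * pmax(0, 1 + amp_growth * t)
  x <- amp * (w_l * s_l + w_h * s_h) + amp0 * noise_floor * s_0

  hop <- config$window_s - config$overlap_s
  grid <- seq(0, duration_s - config$window_s, by = hop)
  truth <- list(
    mode = if (fatigue_mode) "fatigue" else "non-fatigue",
    crossover_s = if (fatigue_mode) crossover_s else NA_real_,
    grid = data.frame(
      t_start_s = grid,
      w_l_mid = if (fatigue_mode) w_l0 + rate_l * grid
                else rep(w_l0, length(grid)),
      w_h_mid = if (fatigue_mode) pmax(0, w_h0 - rate_h * grid)
                else rep(w_h0, length(grid))))

  structure(list(
    record = emg_record(x, fs, label = paste0("synthetic-",
                                              truth$mode)),
    truth = truth,
    params = list(duration_s = duration_s, fs = fs, seed = seed,
                  amp0 = amp0, amp_growth = amp_growth, w_l0 = w_l0,
                  w_h0 = w_h0, w_cross = if (fatigue_mode) w_cross else NA,
                  crossover_s = if (fatigue_mode) crossover_s else NA,
                  noise_floor = noise_floor, noise_mix = noise_mix)),
    class = "semg_simulation")
}

#' @export
print.semg_simulation <- function(x, ...) {
  cat(sprintf("<semg_simulation> %s mode, %g s @ %g Hz, seed %d\n",
              x$truth$mode, x$params$duration_s, x$params$fs,
              x$params$seed))
  if (x$truth$mode == "fatigue")
    cat(sprintf("  designed crossover at %g s\n", x$truth$crossover_s))
  invisible(x)
}

#' Simulate a relaxed (virtually silent) muscle recording
#'
#' Generates the counter-example that motivates the classifier's first
#' step: a low-amplitude recording with the two component bands in
#' balance, as produced by a muscle at rest. The spectral balance makes
#' the fatigue index hover around zero, so the index sign fluctuates and
#' step 2 alone raises false positives; the gentle exponential amplitude
#' settling (`amp(t) = amp0 * exp(-decay * t)`) emulates residual
#' activity dying away after the posture is assumed, so the IEMG never
#' exceeds its initial value and the full two-step classifier stays
#' silent.
#'
#' @param duration_s Record length in seconds; the default 31.5 s yields
#'   20 analysis windows.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed (deterministic output).
#' @param amp0 Baseline amplitude; an order of magnitude below a
#'   contracted muscle.
#' @param decay Exponential amplitude settling rate per second.
#' @param noise_floor Broadband noise weight relative to `amp0`.
#' @param config A [classifier_config()].
#' @return An `semg_simulation` (mode `"relaxed"`).
#' @export
relaxed_semg <- function(duration_s = 31.5, fs = 2000, seed = 1,
                         amp0 = 0.01, decay = 0.05, noise_floor = 0.02,
                         config = classifier_config()) {
  .check_sim_common(fs, duration_s, config)
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  .with_seed(seed, {
    s_l <- .band_surrogate(n, fs, config$lfc_low, config$lfc_high,
                           1, config)
    s_h <- .band_surrogate(n, fs, config$hfc_low, config$hfc_high,
                           1, config)
    s_l <- .joint_calibrate(s_l, s_h, fs, config)
    s_0 <- .broadband_surrogate(n, fs, config)
  })
  amp <- amp0 * exp(-decay * t)
  x <- amp * (s_l + s_h) + amp0 * noise_floor * s_0
  structure(list(
    record = emg_record(x, fs, label = "synthetic-relaxed"),
    truth = list(mode = "relaxed", crossover_s = NA_real_),
    params = list(duration_s = duration_s, fs = fs, seed = seed,
                  amp0 = amp0, decay = decay,
                  noise_floor = noise_floor)),
    class = "semg_simulation")
}
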