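# Seeded generators for EEG background, double-blink events, common-mode
# motion artifacts, and gyroscope pursuit traces, with ground truth.
#
# Every generator is a pure function of its parameters and seed. The
# default scene mirrors the evaluation protocol: 91 s at 128 Hz, 10 double
# blinks at random non-overlapping cue times, head-movement artifact
# throughout (the worst case: moving the head while double blinking), and a
# pursuit gyro trace with jitter.

EMOTIV_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                     "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

derive_seed <- function(seed, k) {
  as.integer((abs(seed) * 7919 + k * 104729) %% .Machine$integer.max)
}

#' Synthetic EEG background noise
#'
#' Independent AR(2) noise per channel (coefficients 0.8, 0.05), a cheap
#' stand-in for the 1/f-shaped EEG background, scaled to a target RMS via
#' the stationary variance of the process. The coefficients are chosen so
#' the DC-to-Nyquist power ratio is ~128, i.e. approximately 1/f power
#' across the seven octaves of a 128 Hz band — much flatter than a random
#' walk, as real EEG is.
#'
#' @param channels channel labels; default the 14-electrode consumer montage.
#' @param duration_s length in seconds, default 91.
#' @param rate_hz sampling rate, default 128.
#' @param rms target per-channel RMS amplitude (microvolt-scale units),
#'   default 10.
#' @param seed RNG seed.
#' @return an [eeg_recording()].
#' @export
make_background <- function(channels = EMOTIV_CHANNELS, duration_s = 91,
                            rate_hz = 128, rms = 10, seed = 1L) {
  stopifnot(duration_s > 0, rms >= 0)
  n <- round(duration_s * rate_hz)
  a1 <- 0.8; a2 <- 0.05
  # stationary variance of AR(2): sigma_e^2 (1 - a2) / ((1 + a2)((1 - a2)^2 - a1^2))
  gain2 <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  sd_e <- rms / sqrt(gain2)
  burn <- 512L
  data <- with_seed(seed, {
    vapply(seq_along(channels), function(i) {
      e <- stats::rnorm(n + burn, sd = sd_e)
      x <- stats::filter(e, c(a1, a2), method = "recursive")
      as.numeric(x[(burn + 1):(burn + n)])
    }, numeric(n))
  })
  eeg_recording(data, rate_hz, channels)
}

# Shared head-sway process shaper: 1/f amplitude tilt (flat below knee_hz)
# with a raised-cosine cap at max_hz and drift removal below 0.1 Hz.
pink_lowpass <- function(x, max_hz, rate, knee_hz = 0.3) {
  n <- length(x)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f)
  gain <- knee_hz / pmax(f, knee_hz)
  gain[f > max_hz] <- 0
  roll <- f > max_hz * 0.8 & f <= max_hz
  gain[roll] <- gain[roll] * (1 + cos(pi * (f[roll] - max_hz * 0.8) /
                                        (max_hz * 0.2))) / 2
  gain[f < 0.1] <- 0
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Biphasic EOG-like pulse: difference of Gaussians, unit peak, ~0.2 s.
blink_template <- function(rate_hz, width_s = 0.2) {
  t <- seq(0, width_s, by = 1 / rate_hz)
  p <- exp(-(t - 0.35 * width_s)^2 / (2 * (0.12 * width_s)^2)) -
    0.5 * exp(-(t - 0.7 * width_s)^2 / (2 * (0.18 * width_s)^2))
  p / max(p)
}

#' Add double-blink events to a recording
#'
#' Each event places two biphasic pulse templates (~0.2 s each) starting
#' `intra_pair_gap_s` apart, so the two maxima fall well inside 0.5 s, on
#' the frontal channels at full amplitude and on every other channel as an
#' attenuated copy. Event amplitudes get a small multiplicative jitter.
#'
#' @param rec an [eeg_recording()].
#' @param times event onset times in seconds.
#' @param channels frontal channels carrying the full pulse, default
#'   AF3/AF4.
#' @param amplitude peak amplitude on the frontal channels, default 100
#'   (microvolt scale: the corneo-retinal potential puts typical blink
#'   deflections at 0.4-1.0 mV at the eye, of which a consumer headset's
#'   frontal electrodes retain on the order of a hundred microvolts —
#'   roughly ten times the background RMS).
#' @param intra_pair_gap_s start-to-start gap between the two pulses,
#'   default 0.3 (must stay below 0.5).
#' @param other_gain attenuation of the copies on non-frontal channels,
#'   default 0.1.
#' @param amp_jitter relative s.d. of per-event amplitude jitter, default
#'   0.1.
#' @param width_s single-pulse width, default 0.2.
#' @param seed RNG seed.
#' @return list with `recording` (markers set at event onsets), `truth`
#'   (`blink_times`, `peak_times`) and `component` (the added samples x
#'   channels matrix).
#' @export
add_double_blinks <- function(rec, times, channels = c("AF3", "AF4"),
                              amplitude = 100, intra_pair_gap_s = 0.3,
                              other_gain = 0.1, amp_jitter = 0.1,
                              width_s = 0.2, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"), all(channels %in% rec$channels))
  stopifnot(intra_pair_gap_s > 0, intra_pair_gap_s < 0.5)
  n <- nrow(rec$data)
  span_s <- intra_pair_gap_s + width_s
  times <- sort(times)
  if (length(times) > 1L && any(diff(times) < span_s)) {
    stop("overlapping double-blink events", call. = FALSE)
  }
  if (any(times < 0) || any((times + span_s) * rec$rate > n)) {
    stop("event outside the recording span", call. = FALSE)
  }
  tmpl <- blink_template(rec$rate, width_s)
  comp <- matrix(0, n, ncol(rec$data), dimnames = list(NULL, rec$channels))
  amps <- with_seed(seed, amplitude * pmax(0.2, stats::rnorm(length(times), 1, amp_jitter)))
  peak_offset <- (which.max(tmpl) - 1) / rec$rate
  for (i in seq_along(times)) {
    for (pulse_t in c(times[i], times[i] + intra_pair_gap_s)) {
      s0 <- round(pulse_t * rec$rate) + 1L
      idx <- s0:(s0 + length(tmpl) - 1L)
      keep <- idx <= n
      comp[idx[keep], channels] <- comp[idx[keep], channels] +
        amps[i] * tmpl[keep]
      othr <- setdiff(rec$channels, channels)
      comp[idx[keep], othr] <- comp[idx[keep], othr] +
        other_gain * amps[i] * tmpl[keep]
    }
  }
  markers <- data.frame(sample = round(times * rec$rate) + 1L,
                        label = "blink_cue")
  peak_times <- as.vector(vapply(times, function(t0) {
    c(t0, t0 + intra_pair_gap_s) + peak_offset
  }, numeric(2)))
  list(
    recording = eeg_recording(rec$data + comp, rec$rate, rec$channels,
                              markers),
    truth = list(blink_times = times, peak_times = peak_times,
                 amplitudes = amps),
    component = comp
  )
}

#' Add a common-mode motion artifact
#'
#' One shared low-frequency (< `max_hz`) random process is added to every
#' channel with per-channel gains and a small per-channel sample shift
#' (phase jitter) — the head/body-movement signature that appears on all
#' electrodes with small variations.
#'
#' The shared process models the experimental protocol, in which the
#' subject deliberately follows an oscillating on-screen target with
#' increasing speed: a quasi-periodic head sway (a slow chirp, 0.25 rising
#' to ~1.2 Hz, with a mild random amplitude envelope) plus a 1/f-tilted
#' broadband residue capped at `max_hz`. A narrowband sway is what
#' deliberate head oscillation produces, and it keeps the artifact
#' spectrally below the ~2.5-5 Hz band of the 0.2 s blink pulses. Segment
#' edges are softened with 0.5 s raised-cosine ramps.
#'
#' @param rec an [eeg_recording()].
#' @param segments list of `c(start_s, end_s)` pairs; default the full span.
#' @param rms RMS amplitude of the shared process inside segments, default
#'   35 (peaks then reach the default blink amplitude: the stated worst
#'   case of head movement during a double blink).
#' @param max_hz upper band edge of the artifact, default 3.
#' @param gain_range per-channel gain range, default `c(0.8, 1.2)`.
#' @param phase_jitter_samples maximum per-channel shift, default 2.
#' @param seed RNG seed.
#' @return list with `recording`, `truth` (`artifact_segments`) and
#'   `component` (samples x channels matrix actually added).
#' @export
add_motion_artifact <- function(rec, segments = NULL, rms = 35, max_hz = 3,
                                gain_range = c(0.8, 1.2),
                                phase_jitter_samples = 2L, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"), rms >= 0)
  n <- nrow(rec$data)
  dur <- n / rec$rate
  if (is.null(segments)) segments <- list(c(0, dur))
  for (seg in segments) {
    stopifnot(length(seg) == 2L, seg[1] >= 0, seg[2] <= dur + 1e-9,
              seg[1] < seg[2])
  }
  nch <- ncol(rec$data)
  out <- with_seed(seed, {
    t <- (seq_len(n) - 1) / rec$rate
    f0 <- 0.25
    f1 <- min(1.2, 0.4 * max_hz)
    phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
    env_raw <- pink_lowpass(stats::rnorm(n), 0.15, rec$rate)
    env_sd <- stats::sd(env_raw)
    # short segments may hold no FFT bin below the envelope cap
    env <- if (env_sd > 0) 1 + 0.3 * env_raw / env_sd else rep(1, n)
    sway <- pmax(0.2, env) * sin(phase)
    residue <- pink_lowpass(stats::rnorm(n), max_hz, rec$rate)
    shared <- sway / stats::sd(sway) +
      0.5 * residue / stats::sd(residue)
    shared <- shared / sqrt(mean(shared^2))
    gains <- stats::runif(nch, gain_range[1], gain_range[2])
    shifts <- sample(seq(-phase_jitter_samples, phase_jitter_samples), nch,
                     replace = TRUE)
    list(shared = shared, gains = gains, shifts = shifts)
  })
  env <- numeric(n)
  ramp_n <- round(0.5 * rec$rate)
  for (seg in segments) {
    i0 <- max(1L, floor(seg[1] * rec$rate) + 1L)
    i1 <- min(n, ceiling(seg[2] * rec$rate))
    env[i0:i1] <- 1
    up <- i0:min(i1, i0 + ramp_n - 1L)
    env[up] <- pmin(env[up], (1 - cos(pi * seq_along(up) / length(up))) / 2)
    dn <- max(i0, i1 - ramp_n + 1L):i1
    env[dn] <- pmin(env[dn], (1 - cos(pi * rev(seq_along(dn)) / length(dn))) / 2)
  }
  comp <- matrix(0, n, nch, dimnames = list(NULL, rec$channels))
  for (j in seq_len(nch)) {
    sh <- out$shifts[j]
    shifted <- if (sh == 0) out$shared else if (sh > 0) {
      c(rep(out$shared[1], sh), out$shared[seq_len(n - sh)])
    } else {
      c(out$shared[(1 - sh):n], rep(out$shared[n], -sh))
    }
    comp[, j] <- rms * out$gains[j] * shifted * env
  }
  list(
    recording = eeg_recording(rec$data + comp, rec$rate, rec$channels,
                              rec$markers),
    truth = list(artifact_segments = segments),
    component = comp
  )
}

#' Synthetic gyroscope pursuit trace
#'
#' Emulates a subject following an oscillating on-screen target with
#' increasing speed: the target yaw velocity is an amplitude-ramped chirp
#' (pitch a scaled copy at lower amplitude), and the measured rates add
#' jitter noise. The jitter models physiological head tremor plus sensor
#' noise: band-limited 4-12 Hz rate noise (shakiness), which integrates to
#' a bounded high-frequency wobble of the cursor rather than an unbounded
#' random walk. For the `"steps"` profile the target velocity is piecewise
#' constant.
#'
#' @param duration_s length in seconds, default 91.
#' @param rate_hz sampling rate, default 128.
#' @param target_profile `"sine_sweep"` (default) or `"steps"`.
#' @param jitter_sd white-noise s.d. in deg/s, default 5.
#' @param peak_dps peak target speed at the end of the sweep, default 60.
#' @param seed RNG seed.
#' @return list with `trace` (a [gyro_trace()]), `target_rates`
#'   (noise-free samples x 2) and `true_path` (noise-free integrated
#'   positions in degrees, samples x 2).
#' @export
make_pursuit_gyro <- function(duration_s = 91, rate_hz = 128,
                              target_profile = c("sine_sweep", "steps"),
                              jitter_sd = 5, peak_dps = 60, seed = 1L) {
  target_profile <- match.arg(target_profile)
  stopifnot(duration_s > 0, jitter_sd >= 0)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  if (target_profile == "sine_sweep") {
    f0 <- 0.1; f1 <- 0.4
    phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * duration_s))
    amp <- peak_dps * t / duration_s
    yaw <- amp * sin(phase)
    pitch <- 0.4 * amp * sin(phase / 2)
  } else {
    steps <- c(0, 10, -20, 35, -45, 55, -60, 30, 0)
    idx <- pmin(length(steps), 1L + floor(t / duration_s * length(steps)))
    yaw <- steps[idx] * peak_dps / 60
    pitch <- 0.4 * yaw
  }
  target <- cbind(yaw, pitch)
  jitter <- with_seed(seed, {
    j <- matrix(stats::rnorm(2 * n), n, 2)
    if (jitter_sd > 0) {
      j <- apply(j, 2, function(v) {
        b <- bandpass_filter(v, 4, min(12, 0.45 * rate_hz), rate_hz)
        jitter_sd * b / stats::sd(b)
      })
    } else {
      j[] <- 0
    }
    j
  })
  noisy <- target + jitter
  dt <- 1 / rate_hz
  true_path <- cbind(cumtrapz(target[, 1], dt), cumtrapz(target[, 2], dt))
  list(trace = gyro_trace(noisy, rate_hz),
       target_rates = target, true_path = true_path)
}

# Random non-overlapping event times: draw uniform points in the slack
# interval and re-insert the minimum gaps (uniform over valid placements).
draw_event_times <- function(n_events, duration_s, span_s, min_gap_s, seed,
                             margin_s = 2) {
  avail <- duration_s - 2 * margin_s - span_s
  slack <- avail - (n_events - 1) * min_gap_s
  if (slack <= 0) stop("could not place non-overlapping events", call. = FALSE)
  with_seed(seed, {
    u <- sort(stats::runif(n_events, 0, slack))
    margin_s + u + (seq_len(n_events) - 1L) * min_gap_s
  })
}

#' Generate a full synthetic test scene
#'
#' The `"paper91s"` preset assembles the complete stated world: 91 s of
#' 14-channel background EEG at 128 Hz, 10 double-blink cues at random
#' non-overlapping times (cue markers attached), a common-mode motion
#' artifact active throughout at blink-comparable amplitude, and a pursuit
#' gyroscope trace with jitter.
#'
#' @param preset currently `"paper91s"`.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_blinks number of double-blink events, default 10.
#' @param duration_s,rate_hz scene geometry, defaults 91 s / 128 Hz.
#' @param background_rms,blink_amplitude,artifact_rms,jitter_sd noise /
#'   signal levels, defaults 10 / 100 / 35 / 5 (microvolt-scale units; see
#'   the generator docs for the physiological grounding).
#' @param artifact whether the motion artifact is added, default `TRUE`.
#' @return object of class `synthetic_scene`: `recording`, `gyro` (list
#'   from [make_pursuit_gyro()]), `truth` (blink times, artifact segments,
#'   true path), `components` (background / blinks / artifact matrices) and
#'   `seed`.
#' @export
make_scene <- function(preset = "paper91s", seed = 1L, n_blinks = 10L,
                       duration_s = 91, rate_hz = 128, background_rms = 10,
                       blink_amplitude = 100, artifact_rms = 35,
                       jitter_sd = 5, artifact = TRUE) {
  stopifnot(identical(preset, "paper91s"))
  bg <- make_background(duration_s = duration_s, rate_hz = rate_hz,
                        rms = background_rms, seed = derive_seed(seed, 1L))
  times <- draw_event_times(n_blinks, duration_s, span_s = 0.5,
                            min_gap_s = 5, seed = derive_seed(seed, 2L))
  bl <- add_double_blinks(bg, times, amplitude = blink_amplitude,
                          seed = derive_seed(seed, 3L))
  if (artifact) {
    ar <- add_motion_artifact(bl$recording, rms = artifact_rms,
                              seed = derive_seed(seed, 4L))
    rec <- ar$recording
    art_comp <- ar$component
    art_truth <- ar$truth$artifact_segments
  } else {
    rec <- bl$recording
    art_comp <- matrix(0, nrow(bg$data), ncol(bg$data),
                       dimnames = list(NULL, bg$channels))
    art_truth <- list()
  }
  gyro <- make_pursuit_gyro(duration_s, rate_hz, jitter_sd = jitter_sd,
                            seed = derive_seed(seed, 5L))
  structure(
    list(
      recording = rec,
      gyro = gyro,
      truth = list(blink_times = bl$truth$blink_times,
                   peak_times = bl$truth$peak_times,
                   artifact_segments = art_truth,
                   true_path = gyro$true_path),
      components = list(background = bg$data, blinks = bl$component,
                        artifact = art_comp),
      seed = seed
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene (seed %d): %.0f s @ %g Hz, %d channels, %d double blinks\n",
              x$seed, nrow(x$recording$data) / x$recording$rate,
              x$recording$rate, length(x$recording$channels),
              length(x$truth$blink_times)))
  cat(sprintf("  blink times: %s\n",
              paste(sprintf("%.1f", x$truth$blink_times), collapse = ", ")))
  invisible(x)
}

#' Write / read a scene to a directory
#'
#' Writes `recording.csv` (+ JSON sidecar), `gyro.csv` (+ sidecar) and
#' `truth.json`; `read_scene` parses them back. The round trip is lossless
#' (doubles serialized with 17 significant digits). Ground-truth component
#' matrices stay in memory only.
#'
#' @param scene a [make_scene()] result.
#' @param dir output directory (created if missing).
#' @return `write_scene` returns `dir` invisibly; `read_scene` a list with
#'   `recording`, `gyro`, `truth`.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_recording(scene$recording, file.path(dir, "recording.csv"))
  write_gyro(scene$gyro$trace, file.path(dir, "gyro.csv"))
  jsonlite::write_json(
    list(seed = scene$seed,
         blink_times = scene$truth$blink_times,
         peak_times = scene$truth$peak_times,
         artifact_segments = scene$truth$artifact_segments,
         true_path = scene$truth$true_path),
    file.path(dir, "truth.json"), digits = NA
  )
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(
    recording = read_recording(file.path(dir, "recording.csv")),
    gyro = read_gyro(file.path(dir, "gyro.csv")),
    truth = truth
  )
}
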