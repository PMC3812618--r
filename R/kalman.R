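# Gyroscope-to-cursor tracking: integration, quantization, dead-band
# baseline, and a constant-velocity Kalman filter.
#
# The state model is a particle moving in the plane at constant velocity
# subject to random perturbations: state (x1, x2, x1dot, x2dot), transition
#   F = [[1,0,Ts,0],[0,1,0,Ts],[0,0,1,0],[0,0,0,1]],
# observation z = (x1, x2) + v. The gain follows the Riccati recursion
#   M = F P F' + Q;  K = M H' (H M H' + R)^{-1};  P = (I - K H) M.

#' Two-axis gyroscope trace
#'
#' @param rates numeric matrix, samples x 2 (yaw, pitch) in degrees/second.
#' @param rate_hz sampling frequency, default 128 Hz (the device never
#'   states the gyro rate; configurable).
#' @param adc_range device quantization description
#'   `c(min_deg_s, max_deg_s, integer_span)`. The headset reports 0-600
#'   deg/s onto 0-4000 integer steps (~0.15 deg/s per step); the signed
#'   default here, `c(-600, 600, 8000)`, keeps that step size.
#' @return object of class `gyro_trace`.
#' @export
gyro_trace <- function(rates, rate_hz = 128, adc_range = c(-600, 600, 8000)) {
  rates <- as.matrix(rates)
  stopifnot(ncol(rates) == 2L, rate_hz > 0, length(adc_range) == 3L,
            adc_range[1] < adc_range[2], adc_range[3] >= 1)
  stop_if_not_finite(rates, "gyro rates")
  colnames(rates) <- c("yaw_dps", "pitch_dps")
  structure(list(rates = rates, rate_hz = rate_hz, adc_range = adc_range),
            class = "gyro_trace")
}

#' @export
print.gyro_trace <- function(x, ...) {
  cat(sprintf("gyro_trace: %d samples @ %g Hz (%.1f s), ADC %g..%g deg/s over %d steps\n",
              nrow(x$rates), x$rate_hz, nrow(x$rates) / x$rate_hz,
              x$adc_range[1], x$adc_range[2], x$adc_range[3]))
  invisible(x)
}

#' Quantize / dequantize gyroscope rates
#'
#' Affine map of the physical rate range onto the ADC integer span with
#' rounding (`quantize_rates`), and its inverse (`dequantize_rates`). The
#' round trip errs by at most half an ADC step.
#'
#' @param trace a [gyro_trace()].
#' @return integer matrix of ADC steps.
#' @export
quantize_rates <- function(trace) {
  stopifnot(inherits(trace, "gyro_trace"))
  r <- trace$adc_range
  q <- round((trace$rates - r[1]) / (r[2] - r[1]) * r[3])
  q[] <- pmin(pmax(q, 0), r[3])
  storage.mode(q) <- "integer"
  q
}

#' @rdname quantize_rates
#' @param q integer matrix from `quantize_rates`.
#' @param adc_range quantization description as in [gyro_trace()].
#' @return numeric matrix of rates in degrees/second.
#' @export
dequantize_rates <- function(q, adc_range) {
  adc_range[1] + q / adc_range[3] * (adc_range[2] - adc_range[1])
}

#' Dead-band baseline
#'
#' The simple jitter-suppression baseline: rates whose quantized ADC value
#' lies within `threshold_steps` of the zero-rate step are zeroed; all other
#' samples pass unchanged. About 10 steps suppress resting shakiness, but
#' fast movements need nearly 30, i.e. the dead band trades away 1.4-4.2
#' deg/s of resolution — the comparison point for the Kalman estimator.
#'
#' @param trace a [gyro_trace()].
#' @param threshold_steps dead-band half width in ADC steps (>= 0).
#' @return a [gyro_trace()] with small rates zeroed.
#' @export
dead_band <- function(trace, threshold_steps = 10L) {
  stopifnot(inherits(trace, "gyro_trace"), threshold_steps >= 0)
  if (threshold_steps == 0) return(trace)
  r <- trace$adc_range
  q <- quantize_rates(trace)
  q0 <- round((0 - r[1]) / (r[2] - r[1]) * r[3])
  rates <- trace$rates
  rates[abs(q - q0) <= threshold_steps] <- 0
  gyro_trace(rates, trace$rate_hz, trace$adc_range)
}

#' Integrate gyroscope rates into a cursor path
#'
#' Cumulative trapezoidal integration of the rate signals, scaled from
#' degrees to pixels, starting at the screen center. Optionally clips to
#' the screen bounds.
#'
#' @param trace a [gyro_trace()].
#' @param scale pixels per degree, default 3.
#' @param screen `c(width, height)` in pixels, default `c(1920, 1080)`.
#' @param clip clip positions to the screen, default `FALSE`.
#' @return object of class `cursor_path`: list with `positions`
#'   (samples x 2, pixels), `scale`, `screen`, `rate_hz`.
#' @export
integrate_rates <- function(trace, scale = 3, screen = c(1920, 1080),
                            clip = FALSE) {
  stopifnot(inherits(trace, "gyro_trace"), scale > 0)
  dt <- 1 / trace$rate_hz
  pos <- cbind(cumtrapz(trace$rates[, 1], dt),
               cumtrapz(trace$rates[, 2], dt)) * scale
  pos[, 1] <- pos[, 1] + screen[1] / 2
  pos[, 2] <- pos[, 2] + screen[2] / 2
  if (clip) {
    pos[, 1] <- pmin(pmax(pos[, 1], 0), screen[1])
    pos[, 2] <- pmin(pmax(pos[, 2], 0), screen[2])
  }
  structure(list(positions = pos, scale = scale, screen = screen,
                 rate_hz = trace$rate_hz),
            class = "cursor_path")
}

#' @export
print.cursor_path <- function(x, ...) {
  cat(sprintf("cursor_path: %d samples @ %g Hz, %g px/deg, screen %dx%d\n",
              nrow(x$positions), x$rate_hz, x$scale, x$screen[1], x$screen[2]))
  invisible(x)
}

#' Constant-velocity Kalman model
#'
#' Builds the 4-state tracking model. `Q` may be given as a full 4x4
#' matrix, or as a length-2 vector of per-axis white-acceleration
#' intensities q (the rest-measurement convention of [estimate_noise()]:
#' the resting rate variance in (deg/s)^2, scaled to px if the states are
#' in px). A scalar/vector `Q` is discretized per axis as
#' `q * [[Ts^3/3, Ts^2/2], [Ts^2/2, Ts]]` over the (position, velocity)
#' pair — noise enters through the velocity states and leaks into position
#' across the step. `R` likewise as a 2-vector of measurement variances or
#' a 2x2 matrix.
#'
#' @param Ts sampling period in seconds.
#' @param Q process noise (see above).
#' @param R measurement noise (see above).
#' @param x0 initial state, default zero position and velocity (callers
#'   usually set position to the screen center).
#' @param P0 initial error covariance, default a diffuse `1e3 * I`.
#' @return object of class `kalman_model` with elements
#'   `x, F, H, Q, R, P, M, K, Ts`.
#' @export
kalman_model <- function(Ts, Q, R, x0 = c(0, 0, 0, 0), P0 = diag(1e3, 4)) {
  stopifnot(Ts > 0)
  Phi <- diag(4)
  Phi[1, 3] <- Ts
  Phi[2, 4] <- Ts
  H <- matrix(0, 2, 4)
  H[1, 1] <- 1
  H[2, 2] <- 1
  if (!is.matrix(Q)) {
    stopifnot(length(Q) %in% c(1L, 2L), all(Q >= 0))
    q <- rep(Q, length.out = 2L)
    Q <- matrix(0, 4, 4)
    for (ax in 1:2) {
      pos <- ax; vel <- ax + 2L
      Q[pos, pos] <- q[ax] * Ts^3 / 3
      Q[pos, vel] <- Q[vel, pos] <- q[ax] * Ts^2 / 2
      Q[vel, vel] <- q[ax] * Ts
    }
  }
  if (!is.matrix(R)) {
    stopifnot(length(R) %in% c(1L, 2L), all(R >= 0))
    R <- diag(rep(R, length.out = 2L), 2)
  }
  stopifnot(all(dim(Q) == c(4L, 4L)), all(dim(R) == c(2L, 2L)),
            length(x0) == 4L, all(dim(P0) == c(4L, 4L)))
  structure(
    list(x = as.numeric(x0), F = Phi, H = H, Q = Q, R = R,
         P = P0, M = P0, K = matrix(0, 4, 2), Ts = Ts),
    class = "kalman_model"
  )
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("kalman_model: constant-velocity tracker, Ts = %g s\n", x$Ts))
  cat(sprintf("  state: pos (%.2f, %.2f), vel (%.2f, %.2f)\n",
              x$x[1], x$x[2], x$x[3], x$x[4]))
  cat(sprintf("  Q vel diag: %s; R diag: %s\n",
              paste(signif(diag(x$Q)[3:4], 4), collapse = ", "),
              paste(signif(diag(x$R), 4), collapse = ", ")))
  invisible(x)
}

#' One Kalman predict/correct step
#'
#' Riccati recursion plus state update: `M = F P F' + Q`,
#' `K = M H' (H M H' + R)^{-1}`, `P = (I - K H) M`; the state is propagated
#' through `F` and corrected with the innovation `z - H x_pred`.
#'
#' @param model a [kalman_model()].
#' @param z measurement pair (observed position).
#' @return the updated `kalman_model`.
#' @export
kalman_step <- function(model, z) {
  stopifnot(inherits(model, "kalman_model"), length(z) == nrow(model$H))
  Phi <- model$F; H <- model$H
  M <- Phi %*% model$P %*% t(Phi) + model$Q
  S <- H %*% M %*% t(H) + model$R
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("innovation covariance is not invertible", call. = FALSE)
  })
  K <- M %*% t(H) %*% Sinv
  P <- (diag(nrow(M)) - K %*% H) %*% M
  P <- (P + t(P)) / 2 # keep symmetric against rounding
  x_pred <- drop(Phi %*% model$x)
  model$x <- x_pred + drop(K %*% (z - drop(H %*% x_pred)))
  model$M <- M
  model$K <- K
  model$P <- P
  model
}

#' Filter a measured cursor path
#'
#' Runs [kalman_step()] over every row of a measurement matrix.
#'
#' @param model a [kalman_model()].
#' @param z numeric matrix, samples x 2 of measured positions.
#' @return list with `states` (samples x 4) and the final `model`.
#' @export
kalman_filter <- function(model, z) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == 2L)
  states <- matrix(0, nrow(z), 4L)
  for (i in seq_len(nrow(z))) {
    model <- kalman_step(model, z[i, ])
    states[i, ] <- model$x
  }
  list(states = states, model = model)
}

#' Estimate process and measurement noise from data
#'
#' `Q` is taken from the gyroscope at rest: the per-axis variance of the
#' resting rate signal becomes the velocity-state process noise (diagonal;
#' noise enters the velocity states only in the constant-velocity model).
#' `R` comes from a moving segment: the integrated position is compared to a
#' zero-phase 5 Hz low-pass reference ("true" movement), and the per-axis
#' residual variance becomes the measurement noise.
#'
#' @param trace_rest a [gyro_trace()] recorded at rest, >= 2 s.
#' @param trace_moving a [gyro_trace()] recorded during movement.
#' @param lowpass_hz reference cutoff for the moving segment, default 5.
#' @return list with `Q` (length-2 velocity variances, deg^2/s^2) and `R`
#'   (length-2 position residual variances, deg^2).
#' @export
estimate_noise <- function(trace_rest, trace_moving, lowpass_hz = 5) {
  stopifnot(inherits(trace_rest, "gyro_trace"),
            inherits(trace_moving, "gyro_trace"))
  if (nrow(trace_rest$rates) < 2 * trace_rest$rate_hz) {
    stop("rest segment must cover at least 2 s", call. = FALSE)
  }
  if (nrow(trace_moving$rates) < 2L) {
    stop("moving segment is empty", call. = FALSE)
  }
  # population variance about the mean: a constant bias is not noise
  Q <- apply(trace_rest$rates, 2, function(v) mean((v - mean(v))^2))
  dt <- 1 / trace_moving$rate_hz
  pos <- cbind(cumtrapz(trace_moving$rates[, 1], dt),
               cumtrapz(trace_moving$rates[, 2], dt))
  R <- apply(pos, 2, function(p) {
    ref <- lowpass_filter(p, lowpass_hz, trace_moving$rate_hz)
    mean((p - ref)^2)
  })
  list(Q = unname(Q), R = unname(R))
}

#' Track a cursor from gyroscope rates
#'
#' Convenience wrapper: integrate the rates to a measured path, then either
#' return it unfiltered, smooth it with the constant-velocity Kalman filter,
#' or apply the dead-band baseline before integration.
#'
#' @inheritParams integrate_rates
#' @param filter `"kalman"`, `"deadband"`, or `"none"`.
#' @param Q,R noise settings for the Kalman model, in trace units (deg^2/s^2
#'   and deg^2); scaled internally to pixels. Defaults `Q = 25` (5 deg/s
#'   tremor sd) and `R = 0.1`, which place the closed-loop bandwidth around
#'   1-2 Hz: flat over the <=0.5 Hz pursuit movement, strongly attenuating
#'   the 4-12 Hz tremor band.
#' @param deadband_steps dead-band width for the baseline, default 10.
#' @return a `cursor_path`.
#' @export
track_cursor <- function(trace, scale = 3, screen = c(1920, 1080),
                         filter = c("kalman", "deadband", "none"),
                         Q = 25, R = 0.1, deadband_steps = 10L, clip = FALSE) {
  filter <- match.arg(filter)
  if (filter == "deadband") {
    return(integrate_rates(dead_band(trace, deadband_steps), scale, screen,
                           clip))
  }
  path <- integrate_rates(trace, scale, screen, clip)
  if (filter == "none") return(path)
  model <- kalman_model(
    Ts = 1 / trace$rate_hz,
    Q = rep(Q, length.out = 2L) * scale^2,
    R = rep(R, length.out = 2L) * scale^2,
    x0 = c(path$positions[1, ], 0, 0)
  )
  out <- kalman_filter(model, path$positions)
  path$positions <- out$states[, 1:2]
  if (clip) {
    path$positions[, 1] <- pmin(pmax(path$positions[, 1], 0), screen[1])
    path$positions[, 2] <- pmin(pmax(path$positions[, 2], 0), screen[2])
  }
  path
}

#' Read / write gyroscope traces and cursor paths as CSV
#'
#' Gyro CSV columns: `t, yaw_dps, pitch_dps`; path CSV columns:
#' `t, x_px, y_px`. A JSON sidecar `<path>.json` stores `rate_hz` and
#' `adc_range` for traces.
#'
#' @param trace a [gyro_trace()].
#' @param path file path.
#' @return `write_gyro` returns `path` invisibly; `read_gyro` a
#'   [gyro_trace()].
#' @export
write_gyro <- function(trace, path) {
  stopifnot(inherits(trace, "gyro_trace"))
  t <- (seq_len(nrow(trace$rates)) - 1) / trace$rate_hz
  df <- data.frame(t = sprintf("%.17g", t),
                   yaw_dps = sprintf("%.17g", trace$rates[, 1]),
                   pitch_dps = sprintf("%.17g", trace$rates[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rate_hz = trace$rate_hz,
                            adc_range = trace$adc_range),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gyro
#' @export
read_gyro <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gyro_trace(cbind(df$yaw_dps, df$pitch_dps),
             rate_hz = as.numeric(side$rate_hz),
             adc_range = as.numeric(side$adc_range))
}

#' @rdname write_gyro
#' @param cursor a `cursor_path`.
#' @export
write_cursor_path <- function(cursor, path) {
  stopifnot(inherits(cursor, "cursor_path"))
  t <- (seq_len(nrow(cursor$positions)) - 1) / cursor$rate_hz
  df <- data.frame(t = sprintf("%.17g", t),
                   x_px = sprintf("%.17g", cursor$positions[, 1]),
                   y_px = sprintf("%.17g", cursor$positions[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
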