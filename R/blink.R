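# Double-blink detection: preprocessing, windowing, candidate peak scan,
# IMF-energy and wavelet-energy features, Mahalanobis classification, ROC.

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with raised-cosine band edges: unity gain between
#' `low_hz` and `high_hz`, rolling off to zero over `transition_hz` on either
#' side, applied by FFT and inverse FFT (hence exactly zero phase). Removes
#' DC and mains components ahead of the spectral analysis; the pipeline
#' default band is 0.5-10 Hz.
#'
#' @param x numeric vector or an [eeg_recording()] (filtered per channel).
#' @param low_hz,high_hz band edges, `0 < low < high < rate/2`.
#' @param rate sampling rate in Hz (ignored for recordings).
#' @param transition_hz roll-off widths `c(low_side, high_side)`; default
#'   `c(low_hz/2, 1)`.
#' @return same type as `x`.
#' @export
bandpass_filter <- function(x, low_hz = 0.5, high_hz = 10, rate = NULL,
                            transition_hz = NULL) {
  if (inherits(x, "eeg_recording")) {
    filt <- apply(x$data, 2, bandpass_filter, low_hz = low_hz,
                  high_hz = high_hz, rate = x$rate,
                  transition_hz = transition_hz)
    return(eeg_recording(filt, x$rate, x$channels, x$markers))
  }
  stopifnot(!is.null(rate), low_hz > 0, low_hz < high_hz, high_hz < rate / 2)
  if (is.null(transition_hz)) transition_hz <- c(low_hz / 2, 1)
  tw <- rep(transition_hz, length.out = 2L)
  n <- length(x)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f) # folded (two-sided) frequency axis
  gain <- rep(0, n)
  gain[f >= low_hz & f <= high_hz] <- 1
  lo <- f < low_hz & f > low_hz - tw[1]
  gain[lo] <- (1 + cos(pi * (low_hz - f[lo]) / tw[1])) / 2
  hi <- f > high_hz & f < high_hz + tw[2]
  gain[hi] <- (1 + cos(pi * (f[hi] - high_hz) / tw[2])) / 2
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Zero-phase low-pass filter
#'
#' Companion to [bandpass_filter()]: unity gain up to `high_hz`, raised-cosine
#' roll-off of `transition_hz`. Used e.g. to define the smooth movement
#' reference when estimating measurement noise.
#'
#' @inheritParams bandpass_filter
#' @param high_hz cutoff frequency.
#' @param transition_hz roll-off width, default 1 Hz.
#' @return numeric vector.
#' @export
lowpass_filter <- function(x, high_hz, rate, transition_hz = 1) {
  stopifnot(high_hz > 0, high_hz < rate / 2)
  n <- length(x)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f)
  gain <- rep(0, n)
  gain[f <= high_hz] <- 1
  hi <- f > high_hz & f < high_hz + transition_hz
  gain[hi] <- (1 + cos(pi * (f[hi] - high_hz) / transition_hz)) / 2
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Sliding analysis windows
#'
#' Start indices (1-based) of windows of `window` samples advancing by
#' `stride`; the count follows the closed form
#' `floor((n_samples - window) / stride) + 1`. A 91 s recording at 128 Hz
#' (11648 samples) with 256-sample windows sliding 128 gives 90 windows.
#'
#' @param n_samples total samples available.
#' @param window window length in samples.
#' @param stride hop in samples (>= 1).
#' @return list with `count` and `starts`; `window > n_samples` yields zero
#'   windows.
#' @export
sliding_windows <- function(n_samples, window, stride) {
  stopifnot(stride >= 1, window >= 1)
  if (window > n_samples) return(list(count = 0L, starts = integer(0)))
  count <- (n_samples - window) %/% stride + 1L
  list(count = as.integer(count),
       starts = 1L + stride * (seq_len(count) - 1L))
}

# 5-point quadratic Savitzky-Golay smoother; edges keep the raw samples.
sg5_smooth <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  co <- c(-3, 12, 17, 12, -3) / 35
  s <- x
  s[3:(n - 2)] <- co[1] * x[1:(n - 4)] + co[2] * x[2:(n - 3)] +
    co[3] * x[3:(n - 2)] + co[4] * x[4:(n - 1)] + co[5] * x[5:n]
  s
}

#' Scan a window for a double-peak (candidate double blink)
#'
#' Smooths the window (5-sample Savitzky-Golay), takes the discrete second
#' derivative (central differences) to label critical points, and keeps local
#' maxima whose amplitude exceeds an adaptive prominence floor of
#' `median + 3 * MAD` of the absolute smoothed signal. Returns `TRUE` when at
#' least two such maxima fall within `pair_span_s` of each other — the
#' two-maxima-in-0.5-s signature of a double blink.
#'
#' @param x numeric vector (band-passed, denoised window).
#' @param rate sampling rate in Hz.
#' @param pair_span_s maximum peak separation in seconds, default 0.5.
#' @return logical flag.
#' @export
double_peak_scan <- function(x, rate, pair_span_s = 0.5) {
  n <- length(x)
  if (n < 5L) return(FALSE)
  s <- sg5_smooth(x)
  d2 <- c(0, diff(s, differences = 2), 0)
  e <- local_extrema(s)
  peaks <- e$maxima[d2[e$maxima] < 0]
  floor_level <- stats::median(abs(s)) + 3 * stats::mad(abs(s))
  peaks <- peaks[s[peaks] > floor_level]
  if (length(peaks) < 2L) return(FALSE)
  any(diff(peaks) <= pair_span_s * rate)
}

#' IMF-energy feature vector
#'
#' Decomposes the window by EMD and returns the energies (sums of squares)
#' of the first `k_imfs` IMFs plus the residual — the double-blink signature
#' concentrates in IMFs 1-3 and the residual of a 2 s window. Missing IMFs
#' contribute zero, so the dimension is always `k_imfs + 1`.
#'
#' @param x numeric window (length >= 64).
#' @param k_imfs number of leading IMFs, default 3.
#' @param config a [sift_config()].
#' @return named numeric vector `imf1..imfK, residual`.
#' @export
emd_features <- function(x, k_imfs = 3L, config = sift_config()) {
  stopifnot(length(x) >= 64L)
  out <- numeric(k_imfs + 1L)
  names(out) <- c(paste0("imf", seq_len(k_imfs)), "residual")
  if (all(x == 0)) return(out)
  fit <- emd(x, config)
  k <- min(k_imfs, ncol(fit$imfs))
  if (k > 0) out[seq_len(k)] <- colSums(fit$imfs[, seq_len(k), drop = FALSE]^2)
  out[k_imfs + 1L] <- signal_energy(fit$residual)
  out
}

# Periodized Daubechies-2 analysis filters (orthonormal).
db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)) # low-pass
  g <- c(h[4], -h[3], h[2], -h[1])                       # high-pass (QMF)
  list(h = h, g = g)
}

#' Multilevel discrete wavelet transform (periodized)
#'
#' Mallat pyramid with Daubechies-2 filters and periodic boundary handling,
#' so the transform is orthonormal and total energy is conserved exactly
#' (Parseval). Used as the comparison feature extractor against EMD.
#'
#' @param x numeric vector; `length(x)` must be divisible by `2^levels`.
#' @param levels decomposition depth, default 5.
#' @return list with `details` (list of detail coefficient vectors, level 1 =
#'   finest, band `rate/4`-`rate/2`) and `approx` (final approximation).
#' @export
dwt_db2 <- function(x, levels = 5L) {
  stopifnot(levels >= 1L, length(x) >= 2^levels,
            length(x) %% 2^levels == 0L)
  filt <- db2_filters()
  a <- x
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    n <- length(a)
    idx <- outer(2L * (seq_len(n %/% 2L) - 1L), 0:3, "+") %% n + 1L
    am <- matrix(a[idx], ncol = 4L)
    details[[lev]] <- drop(am %*% filt$g)
    a <- drop(am %*% filt$h)
  }
  list(details = details, approx = a)
}

#' Wavelet-energy feature vector
#'
#' Energies of the detail coefficients at `detail_levels` of a Daubechies-2
#' decomposition. At 128 Hz levels 2-5 cover roughly 2-32 Hz dyadic bands,
#' with blink energy concentrated around 1-8 Hz (levels 4-5).
#'
#' @param x numeric window; length divisible by `2^levels`.
#' @param levels decomposition depth, default 5.
#' @param detail_levels levels whose detail energies form the feature vector,
#'   default `2:5`.
#' @return named numeric vector of energies.
#' @export
dwt_features <- function(x, levels = 5L, detail_levels = 2:5) {
  stopifnot(all(detail_levels >= 1L), all(detail_levels <= levels))
  out <- numeric(length(detail_levels))
  names(out) <- paste0("d", detail_levels)
  if (all(x == 0)) return(out)
  dec <- dwt_db2(x, levels)
  for (i in seq_along(detail_levels)) {
    out[i] <- signal_energy(dec$details[[detail_levels[i]]])
  }
  out
}

#' Fit a Mahalanobis-distance blink classifier
#'
#' Estimates the mean vector and sample covariance of blink feature vectors
#' and stores the decision distance: a window is classified as a double
#' blink when its Mahalanobis distance from the blink mean falls below the
#' decision distance (default 0.95, the value found experimentally to
#' enclose double-blink events). The covariance is regularized with a ridge
#' `epsilon * I`, `epsilon = 1e-6 * trace(S) / d` by default, so that
#' 10-vector training folds remain invertible.
#'
#' @param features numeric matrix, one feature vector per row (at least
#'   `ncol + 1` rows).
#' @param decision_distance classification threshold on the distance,
#'   default 0.95.
#' @param ridge ridge size; `NULL` uses the trace rule above.
#' @return an object of class `blink_classifier` with elements `mu`,
#'   `sigma`, `decision_distance`, `n`, `ridge`.
#' @seealso [mahalanobis_distance()], [predict.blink_classifier()]
#' @export
blink_classifier <- function(features, decision_distance = 0.95,
                             ridge = NULL) {
  features <- as.matrix(features)
  d <- ncol(features)
  stopifnot(decision_distance > 0)
  if (nrow(features) < d + 1L) {
    stop("need at least dimension + 1 training vectors", call. = FALSE)
  }
  mu <- colMeans(features)
  S <- stats::cov(features)
  if (is.null(ridge)) {
    tr <- sum(diag(S))
    ridge <- if (tr > 0) 1e-6 * tr / d else 1e-12
  }
  sigma <- S + diag(ridge, d)
  structure(
    list(mu = mu, sigma = sigma, decision_distance = decision_distance,
         n = nrow(features), ridge = ridge),
    class = "blink_classifier"
  )
}

#' @export
print.blink_classifier <- function(x, ...) {
  cat(sprintf("blink_classifier: %d-dim Mahalanobis model, n = %d, decision distance %g\n",
              length(x$mu), x$n, x$decision_distance))
  cat("  mu:", paste(signif(x$mu, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mahalanobis distance to the blink class
#'
#' `D_m = sqrt((x - mu)^T Sigma^{-1} (x - mu))`, evaluated through a Cholesky
#' factorization of the (regularized) covariance.
#'
#' @param x numeric vector, or matrix with one feature vector per row.
#' @param model a [blink_classifier()].
#' @return numeric vector of distances.
#' @export
mahalanobis_distance <- function(x, model) {
  stopifnot(inherits(model, "blink_classifier"))
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  stopifnot(ncol(xm) == length(model$mu))
  L <- tryCatch(chol(model$sigma), error = function(e) {
    stop("covariance is singular even after regularization", call. = FALSE)
  })
  z <- forwardsolve(t(L), t(xm) - model$mu)
  sqrt(colSums(z^2))
}

#' @param object a [blink_classifier()].
#' @param newdata feature matrix (rows = windows) or single vector.
#' @param ... unused.
#' @return data frame with `distance` and logical `blink`.
#' @rdname blink_classifier
#' @export
predict.blink_classifier <- function(object, newdata, ...) {
  d <- mahalanobis_distance(newdata, object)
  data.frame(distance = d, blink = d < object$decision_distance)
}

#' Random disjoint folds
#'
#' Seeded random split of `n` items into `k` equal groups — the 2 x 10
#' fold-validation design used to train and test the classifier.
#'
#' @param n number of items.
#' @param k number of folds (must divide `n`), default 2.
#' @param seed RNG seed.
#' @return list of `k` disjoint index vectors.
#' @export
split_folds <- function(n, k = 2L, seed = 1L) {
  stopifnot(n %% k == 0L)
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep(seq_len(k), each = n %/% k))
}

#' ROC curve from classifier distances
#'
#' Sweeps a threshold across the decision range (default 0 to 1.91 in steps
#' of 0.01) and computes, at each threshold, the true-positive rate over
#' `scores_positive` and false-positive rate over `scores_negative`, where a
#' score below the threshold predicts "blink" (distances: smaller = more
#' blink-like). The AUC is the trapezoidal area under the curve extended to
#' its (0,0) and (1,1) endpoints.
#'
#' @param scores_positive distances of true-event windows.
#' @param scores_negative distances of non-event windows.
#' @param thresholds sweep grid, default `seq(0, 1.91, by = 0.01)`.
#' @return object of class `roc_curve` with `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_curve <- function(scores_positive, scores_negative,
                      thresholds = seq(0, 1.91, by = 0.01)) {
  stopifnot(length(scores_positive) > 0, length(scores_negative) > 0)
  tpr <- vapply(thresholds, function(th) mean(scores_positive < th), numeric(1))
  fpr <- vapply(thresholds, function(th) mean(scores_negative < th), numeric(1))
  fx <- c(0, fpr, 1)
  fy <- c(0, tpr, 1)
  ord <- order(fx, fy)
  auc <- sum(diff(fx[ord]) * (fy[ord][-1] + fy[ord][-length(fy)]) / 2)
  structure(
    list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds in [%g, %g], AUC = %.4f\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$auc))
  invisible(x)
}

#' @param x a `roc_curve`.
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::plot()] / [graphics::lines()].
#' @rdname roc_curve
#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  fx <- c(0, x$fpr, 1)
  fy <- c(0, x$tpr, 1)
  if (add) {
    graphics::lines(fx, fy, ...)
  } else {
    graphics::plot(fx, fy, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate", ylab = "True positive rate",
                   ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Per-window classifier distances over a channel
#'
#' Slides the detection window along a (denoised, band-passed) channel and
#' returns each window's feature-space Mahalanobis distance; the raw
#' material for ROC sweeps and for [detect_blinks()].
#'
#' @param x numeric vector, one channel.
#' @param model a [blink_classifier()].
#' @param rate sampling rate in Hz.
#' @param window window length in samples, default 256 (2 s at 128 Hz).
#' @param stride hop in samples, default 128.
#' @param features `"emd"` or `"dwt"`.
#' @param k_imfs leading IMFs for EMD features, default 3.
#' @param config a [sift_config()].
#' @return data frame with `start` (1-based), `time_s`, `distance`.
#' @export
window_distances <- function(x, model, rate, window = 256L, stride = 128L,
                             features = c("emd", "dwt"), k_imfs = 3L,
                             config = sift_config()) {
  features <- match.arg(features)
  sw <- sliding_windows(length(x), window, stride)
  feat_fun <- if (features == "emd") {
    function(v) emd_features(v, k_imfs, config)
  } else {
    function(v) dwt_features(v)
  }
  dist <- vapply(sw$starts, function(s) {
    mahalanobis_distance(feat_fun(x[s:(s + window - 1L)]), model)
  }, numeric(1))
  data.frame(start = sw$starts, time_s = (sw$starts - 1) / rate,
             distance = dist)
}

#' Detect double blinks on a channel
#'
#' Full per-channel detection: sliding windows, optional double-peak
#' candidate gating, Mahalanobis distance against the blink model, threshold
#' decision, and a refractory debounce (no two detections closer than
#' `debounce_s`).
#'
#' @inheritParams window_distances
#' @param threshold decision distance; defaults to the model's.
#' @param debounce_s refractory period in seconds, default 1.
#' @param require_double_peak require the two-maxima-in-0.5-s candidate scan
#'   to pass as well, default `TRUE`.
#' @return data frame with `start`, `time_s`, `distance` of accepted
#'   detections.
#' @export
detect_blinks <- function(x, model, rate, window = 256L, stride = 128L,
                          features = c("emd", "dwt"), threshold = NULL,
                          debounce_s = 1, require_double_peak = TRUE,
                          k_imfs = 3L, config = sift_config()) {
  features <- match.arg(features)
  if (is.null(threshold)) threshold <- model$decision_distance
  wd <- window_distances(x, model, rate, window, stride, features, k_imfs,
                         config)
  cand <- wd$distance < threshold
  if (require_double_peak && any(cand)) {
    dp <- vapply(wd$start[cand], function(s) {
      double_peak_scan(x[s:(s + window - 1L)], rate)
    }, logical(1))
    cand[cand] <- dp
  }
  hits <- wd[cand, , drop = FALSE]
  if (nrow(hits) > 1L) {
    keep <- logical(nrow(hits))
    last <- -Inf
    for (i in seq_len(nrow(hits))) {
      if (hits$time_s[i] - last >= debounce_s) {
        keep[i] <- TRUE
        last <- hits$time_s[i]
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}
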