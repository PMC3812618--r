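# Cross-electrode artifact suppression.
#
# Head or body movement disturbs every electrode near-identically, while
# blink/EMG activity is confined to the frontal channels. Each channel is
# decomposed by EMD over 10 s windows; IMFs whose Pearson correlation with
# the corresponding IMF of a reference electrode is significant on most
# electrodes are treated as common-mode artifact and withheld from the
# reconstruction ("integration") stage.

#' Pearson correlation coefficient
#'
#' Direct implementation of `E[(X - muX)(Y - muY)] / (sigmaX sigmaY)`, the
#' population-moment form, clamped to \[-1, 1\] against rounding.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return scalar correlation.
#' @export
pearson_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  cx <- x - mean(x)
  cy <- y - mean(y)
  sx <- sqrt(mean(cx^2))
  sy <- sqrt(mean(cy^2))
  if (sx == 0 || sy == 0) {
    stop("correlation undefined for a constant sequence", call. = FALSE)
  }
  max(-1, min(1, mean(cx * cy) / (sx * sy)))
}

#' Two-sided p-value for a correlation coefficient
#'
#' Transforms rho into `t = rho * sqrt((n - 2) / (1 - rho^2))` and evaluates
#' a two-sided tail of the Student-t distribution with n - 2 degrees of
#' freedom. `n` is whatever the caller deems the number of observations; see
#' [correlate_imfs()] for the two conventions used in IMF gating.
#'
#' @param rho correlation in \[-1, 1\].
#' @param n number of observations (>= 3).
#' @return p-value in \[0, 1\]; |rho| = 1 returns 0.
#' @export
correlation_p_value <- function(rho, n) {
  stopifnot(n >= 3L, abs(rho) <= 1)
  if (abs(rho) == 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Correlate corresponding IMFs against a reference electrode
#'
#' For one aligned set of per-channel decompositions, computes the Pearson
#' correlation and p-value of each channel's IMF k against the reference
#' channel's IMF k. IMF indices are aligned by extraction order; when
#' channels yield different IMF counts the shorter list bounds the
#' comparison and the missing pairs are reported as `NA` (unavailable, not
#' an error).
#'
#' The p-value convention is a deliberate choice. `p_n = "channels"` (the
#' default) takes n as the number of electrodes — the rows of the electrode
#' correlation matrix — so that with 12 electrodes p < 0.05 demands
#' |rho| > ~0.58: only strongly correlated, genuinely common-mode IMFs gate.
#' `p_n = "samples"` takes n as the window sample count, the textbook
#' convention for time-series correlation (far more sensitive: at n = 1280
#' even |rho| ~ 0.055 is "significant", which would also flag the faint
#' frontal-blink residue found on distant electrodes).
#'
#' IMF index alignment is `"exact"` by default: reference IMF k against each
#' channel's IMF k, extraction order. `"adjacent"` alignment instead matches
#' reference IMF k against the channel's best-correlated IMF among
#' k-1, k, k+1 (reported in `matched_imf`). EMD's dyadic mode boundaries on
#' noisy channels are unstable — a few samples more can shift a mode's index
#' by one — so the artifact-gating path uses adjacent alignment to keep the
#' vote from being scrambled by off-by-one mode splits.
#'
#' @param decompositions named list of [emd()] results, one per channel, all
#'   from the same time window.
#' @param reference_channel label of the reference electrode (default
#'   `"AF4"`).
#' @param p_n `"channels"` or `"samples"` (see Details).
#' @param alignment `"exact"` or `"adjacent"` (see Details).
#' @return data frame with columns `imf`, `channel`, `matched_imf`, `rho`,
#'   `p_value`, `n`. A single-channel input yields an empty report.
#' @export
correlate_imfs <- function(decompositions, reference_channel = "AF4",
                           p_n = c("channels", "samples"),
                           alignment = c("exact", "adjacent")) {
  p_n <- match.arg(p_n)
  alignment <- match.arg(alignment)
  stopifnot(is.list(decompositions), !is.null(names(decompositions)))
  if (!reference_channel %in% names(decompositions)) {
    stop(sprintf("reference channel %s not decomposed", reference_channel),
         call. = FALSE)
  }
  others <- setdiff(names(decompositions), reference_channel)
  ref <- decompositions[[reference_channel]]
  n_imfs_all <- vapply(decompositions, function(d) ncol(d$imfs), integer(1))
  max_imf <- max(c(0L, n_imfs_all))
  if (length(others) == 0L || max_imf == 0L) {
    return(data.frame(imf = integer(0), channel = character(0),
                      matched_imf = integer(0), rho = numeric(0),
                      p_value = numeric(0), n = integer(0)))
  }
  if (length(unique(n_imfs_all)) > 1L) {
    message(sprintf("channels yield different IMF counts (%d-%d); shorter list bounds each pair",
                    min(n_imfs_all), max(n_imfs_all)))
  }
  n_eff_channels <- length(decompositions)
  rows <- vector("list", max_imf * length(others))
  i <- 0L
  for (k in seq_len(max_imf)) {
    ref_imf <- if (k <= ncol(ref$imfs)) ref$imfs[, k] else NULL
    for (ch in others) {
      i <- i + 1L
      d <- decompositions[[ch]]
      cand <- if (alignment == "adjacent") {
        intersect((k - 1L):(k + 1L), seq_len(ncol(d$imfs)))
      } else {
        intersect(k, seq_len(ncol(d$imfs)))
      }
      if (is.null(ref_imf) || length(cand) == 0L) {
        rows[[i]] <- data.frame(imf = k, channel = ch,
                                matched_imf = NA_integer_, rho = NA_real_,
                                p_value = NA_real_, n = NA_integer_)
        next
      }
      n_obs <- if (p_n == "channels") n_eff_channels else length(ref_imf)
      rhos <- vapply(cand, function(j) {
        tryCatch(pearson_rho(ref_imf, d$imfs[, j]),
                 error = function(e) NA_real_)
      }, numeric(1))
      if (all(is.na(rhos))) {
        rows[[i]] <- data.frame(imf = k, channel = ch,
                                matched_imf = NA_integer_, rho = NA_real_,
                                p_value = NA_real_, n = n_obs)
        next
      }
      best <- which.max(abs(rhos))
      rho <- rhos[best]
      rows[[i]] <- data.frame(imf = k, channel = ch,
                              matched_imf = cand[best], rho = rho,
                              p_value = correlation_p_value(rho, n_obs),
                              n = n_obs)
    }
  }
  do.call(rbind, rows)
}

#' Decide which IMFs to gate out
#'
#' An IMF index is gated (suppressed) when the fraction of non-reference
#' channels with `p_value < alpha` strictly exceeds `majority_fraction` —
#' the "correlation in most of the electrodes" rule. Unavailable pairs
#' (`NA`) count as not significant.
#'
#' @param report a [correlate_imfs()] data frame (optionally with a `window`
#'   column; gating is then per window).
#' @param alpha significance level, default 0.05.
#' @param majority_fraction strictly-exceeded fraction in (0, 1\], default
#'   0.5.
#' @return logical vector indexed by IMF (or a logical matrix IMF x window
#'   when the report has a `window` column); `TRUE` = suppressed.
#' @export
build_gate_mask <- function(report, alpha = 0.05, majority_fraction = 0.5) {
  stopifnot(alpha > 0, alpha < 1,
            majority_fraction > 0, majority_fraction <= 1)
  gate_one <- function(rep) {
    if (!nrow(rep)) return(logical(0))
    ks <- sort(unique(rep$imf))
    out <- vapply(ks, function(k) {
      p <- rep$p_value[rep$imf == k]
      frac <- sum(!is.na(p) & p < alpha) / length(p)
      frac > majority_fraction
    }, logical(1))
    names(out) <- ks
    out
  }
  if (!is.null(report$window)) {
    wins <- sort(unique(report$window))
    masks <- lapply(wins, function(w) gate_one(report[report$window == w, ]))
    k_max <- max(c(0L, vapply(masks, length, integer(1))))
    m <- matrix(FALSE, nrow = k_max, ncol = length(wins),
                dimnames = list(NULL, wins))
    for (j in seq_along(masks)) m[seq_along(masks[[j]]), j] <- masks[[j]]
    m
  } else {
    gate_one(report)
  }
}

#' Reconstruct a channel from its non-gated IMFs
#'
#' The "integration module": sums the IMFs whose gate entry is `FALSE`, plus
#' the residual. An empty mask reproduces the input exactly (completeness);
#' gating every IMF returns the residual alone.
#'
#' @param imfset an [emd()] result.
#' @param gate logical vector, one entry per IMF (`TRUE` = suppressed).
#'   Shorter masks are padded with `FALSE`.
#' @return numeric vector, same length as the decomposed segment.
#' @export
reconstruct_gated <- function(imfset, gate = logical(0)) {
  stopifnot(inherits(imfset, "imfset"))
  k <- ncol(imfset$imfs)
  g <- rep(FALSE, k)
  g[seq_len(min(k, length(gate)))] <- gate[seq_len(min(k, length(gate)))]
  if (k == 0L || all(g)) {
    if (k == 0L) return(imfset$residual)
  }
  keep <- which(!g)
  if (length(keep)) {
    rowSums(imfset$imfs[, keep, drop = FALSE]) + imfset$residual
  } else {
    imfset$residual
  }
}

#' Suppress common-mode movement artifacts in a multichannel recording
#'
#' Runs the full preprocessing chain per correlation window: EMD of every
#' channel, correlation of corresponding IMFs against the reference
#' electrode, majority-rule gating, and reconstruction from the surviving
#' IMFs. Windows are non-overlapping (hop = window length); each window is
#' decomposed with a small pad on either side and adjacent reconstructions
#' are joined with a linear cross-fade to avoid seams.
#'
#' @param rec an [eeg_recording()].
#' @param reference_channel reference electrode label, default `"AF4"`.
#' @param window_s correlation window length in seconds, default 10.
#' @param alpha,majority_fraction gating rule parameters, see
#'   [build_gate_mask()].
#' @param p_n p-value convention, see [correlate_imfs()].
#' @param alignment IMF matching rule, see [correlate_imfs()]; the default
#'   `"adjacent"` tolerates the off-by-one mode splits EMD produces on
#'   noisy channels. Once the majority vote gates a reference index, every
#'   channel's matched IMF for that index is suppressed — the index is
#'   "prevented from passing to the integration module" across the montage,
#'   with no per-channel re-test.
#' @param crossfade_s cross-fade length in seconds at window joins,
#'   default 0.25.
#' @param config a [sift_config()].
#' @return an object of class `denoise_result`: list with `recording` (the
#'   denoised [eeg_recording()]), `report` (all per-window correlations) and
#'   `mask` (IMF x window gate matrix).
#' @export
denoise_recording <- function(rec, reference_channel = "AF4", window_s = 10,
                              alpha = 0.05, majority_fraction = 0.5,
                              p_n = c("channels", "samples"),
                              alignment = c("adjacent", "exact"),
                              crossfade_s = 0.25, config = sift_config()) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  p_n <- match.arg(p_n)
  alignment <- match.arg(alignment)
  n <- nrow(rec$data)
  w <- round(window_s * rec$rate)
  pad <- round(crossfade_s * rec$rate)
  starts <- seq(1L, max(1L, n - w + 1L), by = w)
  # fold a short tail (< one window) into the final window
  ends <- pmin(starts + w - 1L, n)
  if (length(starts) > 1L && (n - starts[length(starts)] + 1L) < w / 2) {
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  ends[length(ends)] <- n

  out <- matrix(0, nrow = n, ncol = ncol(rec$data),
                dimnames = list(NULL, rec$channels))
  weight <- matrix(0, nrow = n, ncol = 1L)
  reports <- vector("list", length(starts))

  for (j in seq_along(starts)) {
    s0 <- max(1L, starts[j] - pad)
    s1 <- min(n, ends[j] + pad)
    decomps <- lapply(rec$channels, function(ch) {
      emd(rec$data[s0:s1, ch], config)
    })
    names(decomps) <- rec$channels
    rep_j <- suppressMessages(
      correlate_imfs(decomps, reference_channel, p_n = p_n,
                     alignment = alignment)
    )
    if (nrow(rep_j)) {
      rep_j$window <- j
      rep_j$window_start <- starts[j]
      rep_j$window_end <- ends[j]
    }
    reports[[j]] <- rep_j
    gate <- build_gate_mask(rep_j[, setdiff(names(rep_j), "window"), drop = FALSE],
                            alpha, majority_fraction)
    gated_k <- if (length(gate)) as.integer(names(gate)[gate]) else integer(0)
    n_crit <- if (p_n == "channels") length(rec$channels) else (s1 - s0 + 1L)
    seg_w <- seq(0, 1, length.out = s1 - s0 + 1L)
    ramp <- pmin(1, pmin(seq_len(s1 - s0 + 1L),
                         rev(seq_len(s1 - s0 + 1L))) / max(1L, pad))
    if (j == 1L) ramp[seq_len(min(pad, length(ramp)))] <- 1
    if (j == length(starts)) {
      ramp[seq(length(ramp) - min(pad, length(ramp)) + 1L, length(ramp))] <- 1
    }
    for (ch in rec$channels) {
      if (ch == reference_channel) {
        ch_gate <- seq_len(ncol(decomps[[ch]]$imfs)) %in% gated_k
      } else {
        sel <- rep_j$channel == ch & rep_j$imf %in% gated_k
        gate_js <- rep_j$matched_imf[sel]
        # a split mode leaves a second shard of the common process in a
        # neighbouring IMF: also gate any adjacent candidate individually
        # exceeding the significance cut
        kc <- ncol(decomps[[ch]]$imfs)
        for (k in gated_k) {
          if (k > ncol(decomps[[reference_channel]]$imfs)) next
          ref_imf <- decomps[[reference_channel]]$imfs[, k]
          for (jj in intersect((k - 1L):(k + 1L), seq_len(kc))) {
            r_jj <- tryCatch(pearson_rho(ref_imf, decomps[[ch]]$imfs[, jj]),
                             error = function(e) NA_real_)
            if (!is.na(r_jj) &&
                correlation_p_value(r_jj, n_crit) < alpha) {
              gate_js <- c(gate_js, jj)
            }
          }
        }
        ch_gate <- seq_len(kc) %in% gate_js
      }
      recon <- reconstruct_gated(decomps[[ch]], ch_gate)
      out[s0:s1, ch] <- out[s0:s1, ch] + recon * ramp
    }
    weight[s0:s1, 1L] <- weight[s0:s1, 1L] + ramp
  }
  out <- out / as.vector(weight)

  report <- do.call(rbind, reports)
  mask <- if (!is.null(report) && nrow(report)) build_gate_mask(report, alpha, majority_fraction)
          else matrix(FALSE, 0, 0)
  structure(
    list(
      recording = eeg_recording(out, rec$rate, rec$channels, rec$markers),
      report = report,
      mask = mask,
      reference_channel = reference_channel,
      alpha = alpha, majority_fraction = majority_fraction, p_n = p_n
    ),
    class = "denoise_result"
  )
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("denoise_result: reference %s, alpha %g, majority > %g (p_n = %s)\n",
              x$reference_channel, x$alpha, x$majority_fraction, x$p_n))
  if (length(x$mask)) {
    cat(sprintf("  windows: %d; gated IMF-window cells: %d of %d\n",
                ncol(x$mask), sum(x$mask), length(x$mask)))
  }
  invisible(x)
}
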