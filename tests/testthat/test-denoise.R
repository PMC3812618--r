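# Cross-electrode artifact suppression: correlation, gating, reconstruction.

test_that("Pearson coefficient matches the direct moment formula", {
  set.seed(2)
  x <- rnorm(50)
  expect_identical(pearson_rho(x, x), 1)
  expect_identical(pearson_rho(x, -x), -1)

  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  expect_lt(abs(pearson_rho(a, b) - pearson_brute_force(a, b)), 1e-12)
  expect_lt(abs(pearson_rho(a, b) - cor(a, b)), 1e-12) # independent cross-check

  expect_error(pearson_rho(rep(1, 5), 1:5), "constant")
  expect_error(pearson_rho(1:2, 1:2), "length")
})

test_that("correlation p-values match an independent t-distribution oracle", {
  expect_equal(correlation_p_value(0, 30), 1)
  expect_equal(correlation_p_value(1, 30), 0)
  expect_equal(correlation_p_value(-1, 10), 0)
  for (case in list(c(0.5, 30), c(0.2, 12), c(-0.8, 100))) {
    expect_lt(abs(correlation_p_value(case[1], case[2]) -
                    p_value_by_integration(case[1], case[2])), 1e-9)
  }
  expect_error(correlation_p_value(0.5, 2))
})

test_that("a shared tone drives all IMF pairs significant; single channel gives an empty report", {
  decs <- shared_tone_decompositions(n_channels = 4, seed = 5)
  rep_df <- correlate_imfs(decs, "CH1", p_n = "samples")
  # the tone-bearing IMF index: largest mean |rho| across pairs
  by_imf <- tapply(abs(rep_df$rho), rep_df$imf, mean, na.rm = TRUE)
  k <- as.integer(names(which.max(by_imf)))
  sig <- rep_df[rep_df$imf == k, ]
  expect_true(all(sig$p_value < 0.05, na.rm = TRUE))

  one <- correlate_imfs(decs["CH1"], "CH1")
  expect_equal(nrow(one), 0L)
})

test_that("pairs missing an IMF are reported unavailable, not an error", {
  decs <- shared_tone_decompositions(n_channels = 3, seed = 6)
  # truncate one channel's decomposition to fewer IMFs
  k2 <- ncol(decs[["CH2"]]$imfs)
  decs[["CH2"]]$imfs <- decs[["CH2"]]$imfs[, 1, drop = FALSE]
  decs[["CH2"]]$sift_counts <- decs[["CH2"]]$sift_counts[1]
  expect_message(rep_df <- correlate_imfs(decs, "CH1", alignment = "exact"),
                 "IMF counts")
  tail_rows <- rep_df[rep_df$imf > 2 & rep_df$channel == "CH2", ]
  expect_true(all(is.na(tail_rows$rho)))
})

test_that("majority gating follows the p < alpha vote", {
  mk <- function(p) data.frame(imf = 1L, channel = paste0("E", seq_along(p)),
                               matched_imf = 1L, rho = 0.5, p_value = p,
                               n = length(p) + 1L)
  expect_true(build_gate_mask(mk(rep(0.001, 12))))
  expect_false(build_gate_mask(mk(rep(0.5, 12))))
  # the 12-electrode case: p near 0 everywhere except one electrode (0.639)
  expect_true(build_gate_mask(mk(c(rep(1e-6, 11), 0.639))))
  # exactly half significant does not strictly exceed the majority
  expect_false(build_gate_mask(mk(c(rep(0.001, 6), rep(0.5, 6)))))
})

test_that("reconstruction without gates is exact; full gating leaves the residual", {
  set.seed(9)
  x <- rnorm(512) + 4 * sin(2 * pi * 3 * (1:512) / 128)
  fit <- emd(x)
  expect_lt(max(abs(reconstruct_gated(fit) - x)), 1e-9 * max(abs(x)))
  expect_identical(reconstruct_gated(fit, rep(TRUE, ncol(fit$imfs))),
                   fit$residual)
})

test_that("sample-n p-values are calibrated on independent white sequences", {
  # null calibration of the t transform at n = 1280 observations per
  # window: for WHITE sequences the 5% level is honest. (For IMF pairs it
  # is not: IMFs are narrowband, their effective sample size is far below
  # n, and independent channels show |rho| >> 1/sqrt(n) — which is why
  # gating defaults to the channel-count convention.)
  set.seed(31)
  n_sig <- 0L; n_tot <- 0L
  for (rep in 1:400) {
    x <- rnorm(1280); y <- rnorm(1280)
    p <- correlation_p_value(pearson_rho(x, y), 1280)
    n_sig <- n_sig + (p < 0.05)
    n_tot <- n_tot + 1L
  }
  frac <- n_sig / n_tot
  expect_lt(abs(frac - 0.05), 0.03 + 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("denoising only removes energy and leaves no anomalous seams", {
  sc <- make_scene(seed = 77, duration_s = 40, n_blinks = 4)
  den <- denoise_recording(sc$recording)
  for (ch in c("AF3", "P8")) {
    e_in <- sum(channel_samples(sc$recording, ch)^2)
    e_out <- sum(channel_samples(den$recording, ch)^2)
    expect_lte(e_out, e_in * 1.02) # crossfade tolerance
  }
  # seam continuity: jumps at window joins are not anomalous relative to
  # the signal's own sample-to-sample steps
  x <- channel_samples(den$recording, "AF3")
  w <- round(10 * 128)
  seams <- seq(w, length(x) - 1, by = w)
  expect_lte(max(abs(x[seams + 1] - x[seams])), max(abs(diff(x))))
  expect_output(print(den), "denoise_result")
})

test_that("the gate suppresses a common-mode artifact but keeps frontal blinks", {
  sc <- make_scene(seed = 88)
  den <- denoise_recording(sc$recording)
  rate <- sc$recording$rate
  for (ch in c("AF3", "AF4")) {
    att <- artifact_attenuation(channel_samples(den$recording, ch),
                                channel_samples(sc$recording, ch),
                                sc$components$artifact[, ch],
                                0.5, 3, rate)
    expect_lt(att, 0.2) # >= 80% of the artifact component removed
    ret <- blink_retention(
      bandpass_filter(channel_samples(den$recording, ch), 0.5, 10, rate),
      sc$components$blinks[, ch], sc$truth$peak_times, rate
    )
    expect_gte(median(ret), 0.7)
  }
})
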