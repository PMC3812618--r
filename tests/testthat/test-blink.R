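# Blink detection: preprocessing, windowing, features, classifier, ROC.

test_that("the zero-phase band-pass removes DC, passes the band, kills mains", {
  rate <- 128
  t <- (0:1279) / rate
  expect_lt(max(abs(bandpass_filter(rep(5, 1280), 0.5, 10, rate))), 5e-6)

  tone5 <- sin(2 * pi * 5 * t)
  out5 <- bandpass_filter(tone5, 0.5, 10, rate)
  gain <- sd(out5[320:960]) / sd(tone5[320:960])
  expect_gt(gain, 0.9); expect_lt(gain, 1.1)

  tone50 <- sin(2 * pi * 50 * t)
  out50 <- bandpass_filter(tone50, 0.5, 10, rate)
  expect_lt(sd(out50[320:960]) / sd(tone50[320:960]), 0.1) # >= 20 dB

  expect_error(bandpass_filter(tone5, 0.5, 70, rate))
})

test_that("sliding window counts follow the closed form", {
  sw <- sliding_windows(11648, 256, 128)
  expect_identical(sw$count, 90L) # 91 s at 128 Hz
  expect_identical(sliding_windows(256, 256, 128)$count, 1L)
  expect_identical(sliding_windows(500, 256, 128)$count, 2L)
  expect_identical(sliding_windows(100, 256, 128)$count, 0L)

  # closed form vs direct enumeration on random geometries
  set.seed(14)
  for (i in 1:100) {
    n <- sample(50:5000, 1); w <- sample(10:300, 1); s <- sample(1:200, 1)
    starts <- seq(1L, n, by = s)
    starts <- starts[starts + w - 1L <= n]
    sw <- sliding_windows(n, w, s)
    expect_identical(sw$count, length(starts))
    expect_identical(sw$starts, starts)
  }
})

test_that("the double-peak scan flags two maxima within the pair span", {
  rate <- 128
  tmpl <- emdmouse:::blink_template(rate)
  win <- rep(0, 256)
  put <- function(w, t0) {
    idx <- round(t0 * rate) + seq_along(tmpl)
    w[idx] <- w[idx] + tmpl
    w
  }
  two <- put(put(win, 0.4), 0.7) # peaks ~0.3 s apart
  set.seed(3)
  noise <- rnorm(256, sd = 0.02)
  expect_true(double_peak_scan(two + noise, rate))
  expect_false(double_peak_scan(put(win, 0.6) + noise, rate))
  expect_false(double_peak_scan(noise, rate))
  # two pulses too far apart are not a double blink
  far <- put(put(win, 0.2), 1.4)
  expect_false(double_peak_scan(far + noise, rate, pair_span_s = 0.5))
})

test_that("IMF-energy features are homogeneous of degree 2 and near-complete", {
  expect_identical(unname(emd_features(rep(0, 256))), rep(0, 4))

  set.seed(8)
  x <- sin(2 * pi * 3 * (1:256) / 128) + rnorm(256, sd = 0.3)
  f1 <- emd_features(x, 3)
  f2 <- emd_features(2.5 * x, 3)
  expect_equal(f2, 2.5^2 * f1, tolerance = 1e-10)

  # with k covering every IMF, energies account for the signal energy up
  # to orthogonality leakage
  fit <- emd(x)
  io <- orthogonality_index(fit, x)
  fall <- emd_features(x, max(3, ncol(fit$imfs)))
  expect_lt(abs(sum(fall) - sum(x^2)) / sum(x^2), abs(io) + 0.05)
})

test_that("the db2 pyramid conserves energy and sorts tones into dyadic bands", {
  expect_identical(unname(dwt_features(rep(0, 256))), rep(0, 4))

  set.seed(12)
  x <- rnorm(256)
  dec <- dwt_db2(x, 5)
  total <- sum(vapply(dec$details, function(d) sum(d^2), numeric(1))) +
    sum(dec$approx^2)
  expect_lt(abs(total - sum(x^2)), 1e-9) # Parseval, orthonormal periodized

  rate <- 128
  t <- (0:255) / rate
  # level j detail covers rate/2^(j+1) .. rate/2^j: 3 Hz -> level 5, 6 Hz -> 4
  f3 <- dwt_features(sin(2 * pi * 3 * t), detail_levels = 1:5)
  expect_identical(names(which.max(f3)), "d5")
  f6 <- dwt_features(sin(2 * pi * 6 * t), detail_levels = 1:5)
  expect_identical(names(which.max(f6)), "d4")
})

test_that("Mahalanobis distances behave like Eq.-defined covariance distances", {
  mu <- c(1, 2, 3, 4)
  model <- structure(
    list(mu = mu, sigma = diag(4), decision_distance = 0.95, n = 10,
         ridge = 0),
    class = "blink_classifier"
  )
  expect_equal(mahalanobis_distance(mu, model), 0)
  expect_equal(mahalanobis_distance(mu + c(3, 4, 0, 0), model), 5)

  # agreement with the reference implementation on a random covariance
  set.seed(19)
  A <- matrix(rnorm(16), 4)
  S <- crossprod(A) + diag(4)
  m2 <- structure(list(mu = mu, sigma = S, decision_distance = 0.95,
                       n = 10, ridge = 0), class = "blink_classifier")
  xs <- matrix(rnorm(40), 10)
  expect_equal(mahalanobis_distance(xs, m2),
               sqrt(stats::mahalanobis(xs, mu, S)), tolerance = 1e-10)

  # classification at the 0.95 decision distance
  p <- predict(model, rbind(mu + 0.5 * c(1, 0, 0, 0), mu + c(1.2, 0, 0, 0)))
  expect_identical(p$blink, c(TRUE, FALSE))
})

test_that("Mahalanobis distance is affine invariant", {
  set.seed(23)
  feats <- matrix(rnorm(200, mean = 5), 50, 4)
  model <- blink_classifier(feats, ridge = 0)
  A <- matrix(rnorm(16), 4); A <- A + 4 * diag(4) # well-conditioned
  b <- rnorm(4)
  mapped <- feats %*% t(A) + matrix(b, 50, 4, byrow = TRUE)
  model_t <- structure(
    list(mu = drop(A %*% model$mu + b), sigma = A %*% model$sigma %*% t(A),
         decision_distance = 0.95, n = model$n, ridge = 0),
    class = "blink_classifier"
  )
  x <- rnorm(4, mean = 5)
  d1 <- mahalanobis_distance(x, model)
  d2 <- mahalanobis_distance(drop(A %*% x + b), model_t)
  expect_lt(abs(d1 - d2), 1e-9)
})

test_that("classifier fitting: ridge, folds, and parameter recovery", {
  same <- matrix(rep(c(1, 2, 3, 4), 10), 10, 4, byrow = TRUE)
  clf <- blink_classifier(same)
  expect_equal(unname(clf$mu), c(1, 2, 3, 4))
  expect_equal(clf$sigma, diag(clf$ridge, 4), ignore_attr = TRUE) # epsilon * I

  expect_error(blink_classifier(same[1:3, ]), "training vectors")

  folds <- split_folds(20, 2, seed = 7)
  expect_identical(sort(unname(unlist(folds))), 1:20)
  expect_length(folds[[1]], 10)
  expect_length(intersect(folds[[1]], folds[[2]]), 0)
  expect_identical(split_folds(20, 2, seed = 7), folds) # seeded

  # mean recovery from a known generator, n = 500
  set.seed(41)
  mu_true <- c(10, 20, 5, 1)
  draws <- matrix(rnorm(2000, mean = rep(mu_true, each = 500), sd = 2),
                  500, 4)
  fit <- blink_classifier(draws)
  se <- 2 / sqrt(500)
  expect_true(all(abs(fit$mu - mu_true) < 3 * se))
})

test_that("ROC sweeps have correct endpoints, separation and null behavior", {
  pos <- c(0.1, 0.2, 0.3); neg <- c(5, 6, 7)
  roc <- roc_curve(pos, neg)
  expect_equal(roc$auc, 1.0)
  expect_true(all(roc$tpr[roc$thresholds <= 0.1] == 0))
  expect_true(all(diff(roc$tpr) >= 0), all(diff(roc$fpr) >= 0))

  # threshold below all scores: FPR = TPR = 0; above all: both 1
  wide <- roc_curve(c(1, 2), c(1.5, 2.5), thresholds = c(0, 10))
  expect_equal(wide$tpr, c(0, 1)); expect_equal(wide$fpr, c(0, 1))

  set.seed(50)
  a <- runif(1e4, 0, 1.91); b <- runif(1e4, 0, 1.91)
  expect_lt(abs(roc_curve(a, b)$auc - 0.5), 0.02)
})

test_that("detection respects the refractory debounce", {
  rate <- 128
  set.seed(60)
  x <- rnorm(128 * 20, sd = 2)
  tmpl <- emdmouse:::blink_template(rate)
  for (t0 in c(3, 6.5, 7.2, 12)) {
    for (pt in c(t0, t0 + 0.3)) {
      idx <- round(pt * rate) + seq_along(tmpl)
      x[idx] <- x[idx] + 60 * tmpl
    }
  }
  clf <- blink_classifier(rbind(
    t(sapply(c(3, 6.5, 12), function(t0) {
      emd_features(x[(round(t0 * rate) + 1):(round(t0 * rate) + 256)], 3)
    })),
    t(sapply(c(3, 6.5, 12), function(t0) {
      emd_features(x[(round(t0 * rate) - 63):(round(t0 * rate) + 192)], 3)
    }))
  ), decision_distance = 10)
  hits <- detect_blinks(x, clf, rate, threshold = 10, debounce_s = 1)
  if (nrow(hits) > 1) {
    expect_true(all(diff(hits$time_s) >= 1))
  }
  expect_gt(nrow(hits), 0)
})
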