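# Empirical mode decomposition: envelopes, sifting, stopping, diagnostics.

test_that("envelope mean is near zero for a sinusoid and near c for c + sin", {
  rate <- 128
  t <- seq(0, 4, by = 1 / rate)
  s <- sin(2 * pi * 3 * t)
  central <- round(length(s) * 0.25):round(length(s) * 0.75)

  m <- envelope_mean(s)
  expect_lt(max(abs(m[central])), 0.05) # < 5% of unit amplitude

  m2 <- envelope_mean(2.5 + s)
  expect_lt(max(abs(m2[central] - 2.5)), 0.05)

  expect_error(envelope_mean(seq(0, 1, length.out = 100)), "extrema")
  expect_error(envelope_mean(c(1, 2, NA, 4, 3)), "non-finite")
})

test_that("pchip envelopes are an accepted alternative interpolation", {
  t <- seq(0, 4, by = 1 / 128)
  s <- sin(2 * pi * 3 * t)
  central <- round(length(s) * 0.25):round(length(s) * 0.75)
  m <- envelope_mean(s, sift_config(interpolation = "pchip"))
  expect_lt(max(abs(m[central])), 0.1)
})

test_that("one sifting step subtracts the (weighted) envelope mean", {
  set.seed(4)
  x <- sin(2 * pi * 3 * seq(0, 4, by = 1 / 128)) + rnorm(513, sd = 0.2)

  d_plain <- sift_once(x)
  d_ones <- sift_once(x, weight = rep(1, length(x)))
  expect_identical(d_plain, d_ones) # w(t) = 1 reduces weighted to plain

  expect_identical(sift_once(x, weight = rep(0, length(x))), x)

  s <- sin(2 * pi * 3 * seq(0, 4, by = 1 / 128))
  central <- round(length(s) * 0.25):round(length(s) * 0.75)
  expect_lt(max(abs(sift_once(s)[central] - s[central])), 0.05)
})

test_that("local weights are a raised-cosine taper in [0, 1] with soft decay", {
  w <- local_weight(200, active_start = 80, active_end = 120, taper = 30)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(w[80:120] == 1))
  expect_true(all(w[1:40] == 0))
  # soft decay: no jump exceeds the raised-cosine step bound
  expect_lt(max(abs(diff(w))), pi / (2 * 30))
})

test_that("decomposition handles degenerate inputs", {
  expect_error(emd(c(1, 2, 3)), "short")
  expect_error(emd(c(rep(1, 10), NA, rep(1, 10))), "non-finite")

  fit <- emd(rep(3, 64))
  expect_equal(ncol(fit$imfs), 0L)
  expect_identical(fit$residual, rep(3, 64))
})

test_that("a two-tone signal separates: IMF1 recovers the fast component", {
  rate <- 128
  t <- seq(1 / rate, 10, by = 1 / rate)
  fast <- sin(2 * pi * 20 * t)
  x <- sin(2 * pi * 2 * t) + fast
  fit <- emd(x)
  central <- round(length(x) * 0.25):round(length(x) * 0.75)
  expect_gt(abs(cor(fit$imfs[central, 1], fast[central])), 0.95)
})

test_that("decomposition satisfies completeness, the IMF criterion and determinism", {
  set.seed(11)
  rate <- 128
  for (rep in 1:10) {
    n <- sample(c(256, 512, 1280), 1)
    t <- (seq_len(n) - 1) / rate
    x <- rnorm(n) + 3 * sin(2 * pi * runif(1, 1, 8) * t) +
      2 * sin(2 * pi * runif(1, 10, 30) * t)
    fit <- emd(x)
    recon <- rowSums(fit$imfs) + fit$residual
    expect_lt(max(abs(recon - x)), 1e-9 * max(abs(x)))
    for (k in seq_len(ncol(fit$imfs))) {
      imf <- fit$imfs[, k]
      expect_lte(abs(emdmouse:::n_extrema(imf) -
                       emdmouse:::n_zero_crossings(imf)), 1L)
    }
  }
  x <- rnorm(512)
  expect_identical(emd(x), emd(x)) # bit-identical rerun
})

test_that("orthogonality index matches a brute-force double sum", {
  # residual-only decomposition: empty sum
  fit0 <- emd(rep(1, 64))
  expect_identical(orthogonality_index(fit0, rep(1, 64)), 0)

  # two exactly orthogonal sinusoids planted as components
  rate <- 128
  t <- (0:255) / rate
  c1 <- sin(2 * pi * 8 * t)
  c2 <- sin(2 * pi * 16 * t)
  x <- c1 + c2
  planted <- structure(
    list(imfs = cbind(c1), residual = c2, sift_counts = 1L,
         source_length = length(x)),
    class = "imfset"
  )
  expect_lt(abs(orthogonality_index(planted, x) -
                  io_brute_force(cbind(c1, c2), x)), 1e-12)

  # typical EMD of a two-tone signal: small leakage, exact vs oracle
  x2 <- sin(2 * pi * 2 * (1:1280) / rate) + sin(2 * pi * 20 * (1:1280) / rate)
  fit <- emd(x2)
  io <- orthogonality_index(fit, x2)
  expect_lt(abs(io), 0.1)
  expect_lt(abs(io - io_brute_force(cbind(fit$imfs, fit$residual), x2)),
            1e-12)

  expect_error(orthogonality_index(fit0, rep(0, 64)), "zero-energy")
})

test_that("component energies do not exceed input energy beyond the leakage bound", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(512) + 2 * sin(2 * pi * 5 * (1:512) / 128)
    fit <- emd(x)
    io <- orthogonality_index(fit, x)
    comp_energy <- sum(fit$imfs^2) + sum(fit$residual^2)
    expect_lte(comp_energy, (1 + abs(io) * 1.5) * sum(x^2) + 1e-9)
  }
})

test_that("an IMF set exports to a data frame with imf_k and residual columns", {
  fit <- emd(sin(2 * pi * 4 * (1:256) / 128) + rnorm(256, sd = 0.1))
  df <- as.data.frame(fit)
  expect_true(all(c("imf_1", "residual") %in% names(df)))
  expect_equal(nrow(df), 256)
  expect_output(print(fit), "Empirical mode decomposition")
})
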