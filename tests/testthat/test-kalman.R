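# Cursor tracking: quantization, dead band, integration, Kalman recursion.

test_that("quantization maps range endpoints and round-trips within half a step", {
  tr <- gyro_trace(rbind(c(0, 600), c(600, 0), c(300, 150)),
                   adc_range = c(0, 600, 4000))
  q <- quantize_rates(tr)
  expect_equal(q[1, 1], 0L, ignore_attr = TRUE)    # min of range -> 0
  expect_equal(q[2, 1], 4000L, ignore_attr = TRUE) # max -> integer span
  back <- dequantize_rates(q, c(0, 600, 4000))
  step <- 600 / 4000
  expect_lte(max(abs(back - tr$rates)), step / 2 + 1e-12)
})

test_that("the dead band zeroes only sub-threshold rates", {
  set.seed(70)
  tr <- gyro_trace(matrix(rnorm(200, sd = 3), ncol = 2))
  expect_identical(dead_band(tr, 0L)$rates, tr$rates)

  small <- gyro_trace(matrix(runif(200, -1, 1), ncol = 2)) # < 1.5 deg/s
  expect_true(all(dead_band(small, 10L)$rates == 0))

  mixed <- dead_band(tr, 10L)
  thresh <- 10 * 1200 / 8000
  kept <- tr$rates[mixed$rates != 0]
  expect_true(all(abs(kept) > thresh - 0.15)) # half-step rounding slack
})

test_that("rate integration matches closed-form displacements", {
  rate <- 128
  zero <- gyro_trace(matrix(0, 256, 2), rate)
  p0 <- integrate_rates(zero, scale = 3, screen = c(1920, 1080))
  expect_true(all(p0$positions[, 1] == 960), all(p0$positions[, 2] == 540))

  const <- gyro_trace(matrix(10, 257, 2), rate) # 2 s at 10 deg/s
  p1 <- integrate_rates(const, scale = 3)
  expect_equal(unname(p1$positions[257, 1] - p1$positions[1, 1]), 60,
               tolerance = 1e-9)

  t <- (0:2559) / rate
  sine <- gyro_trace(cbind(30 * sin(2 * pi * 0.5 * t), 0 * t), rate)
  p2 <- integrate_rates(sine, scale = 1, screen = c(0, 0))
  analytic <- 30 / (2 * pi * 0.5) * (1 - cos(2 * pi * 0.5 * t))
  expect_lt(max(abs(p2$positions[, 1] - analytic)) / max(analytic), 0.005)
})

test_that("the filter converges on noise-free constant-velocity motion", {
  Ts <- 1 / 128
  truth <- function(k) c(10 + 3 * k * Ts, 20 - 2 * k * Ts)
  model <- kalman_model(Ts, Q = c(0, 0), R = c(1e-10, 1e-10),
                        x0 = c(0, 0, 0, 0))
  for (k in 1:50) model <- kalman_step(model, truth(k))
  expect_lt(sqrt(sum((model$x[1:2] - truth(50))^2)) /
              sqrt(sum(truth(50)^2)), 1e-6)
  expect_lt(abs(model$x[3] - 3), 1e-4)
  expect_lt(abs(model$x[4] + 2), 1e-4)
})

test_that("filtering a static target reduces measurement variance", {
  set.seed(81)
  z <- matrix(rnorm(2 * 10000, mean = 50, sd = 1), ncol = 2)
  model <- kalman_model(1 / 128, Q = c(0.01, 0.01), R = c(1, 1),
                        x0 = c(50, 50, 0, 0))
  out <- kalman_filter(model, z)
  drop_in <- apply(out$states[1001:10000, 1:2], 2, var)
  expect_true(all(drop_in < apply(z[1001:10000, ], 2, var)))
})

test_that("steady-state covariance matches the scalar Riccati fixed point", {
  # 1-D position-only model run through the same step routine
  Q <- 0.3; R <- 2
  model <- structure(
    list(x = 0, F = matrix(1), H = matrix(1), Q = matrix(Q), R = matrix(R),
         P = matrix(100), M = matrix(100), K = matrix(0), Ts = 1),
    class = "kalman_model"
  )
  for (k in 1:200) model <- kalman_step(model, 0)
  # fixed point of P = (P + Q) R / (P + Q + R): P^2 + QP - QR = 0
  p_star <- (-Q + sqrt(Q^2 + 4 * Q * R)) / 2
  expect_lt(abs(model$P[1, 1] - p_star), 1e-8)
})

test_that("the error covariance stays symmetric positive semi-definite", {
  # 2e4 random steps (scaled down from 1e5 for runtime), eigenvalues
  # checked every 100 steps
  set.seed(90)
  model <- kalman_model(1 / 128, Q = c(25, 25), R = c(0.5, 0.5))
  for (k in 1:20000) {
    model <- kalman_step(model, rnorm(2, sd = 3))
    if (k %% 100 == 0) {
      expect_lt(max(abs(model$P - t(model$P))), 1e-10)
      expect_gte(min(eigen(model$P, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("measurement trust is monotone in R", {
  set.seed(91)
  n <- 512
  z <- matrix(rnorm(2 * n, sd = 5), ncol = 2)
  dev_from_z <- sapply(c(1e-8, 1, 1e8), function(R) {
    m <- kalman_model(1 / 128, Q = c(1, 1), R = c(R, R))
    out <- kalman_filter(m, z)
    mean((out$states[, 1:2] - z)^2)
  })
  expect_true(all(diff(dev_from_z) > 0)) # larger R, less following
  # R -> 0 follows the measurements; R -> infinity ignores them
  expect_lt(dev_from_z[1], 0.05 * var(as.vector(z)))
  expect_gt(dev_from_z[3], 0.8 * var(as.vector(z)))
})

test_that("noise estimation recovers known generators and scales quadratically", {
  rest0 <- gyro_trace(matrix(0, 512, 2))
  moving <- make_pursuit_gyro(duration_s = 20, seed = 3)$trace
  est0 <- estimate_noise(rest0, moving)
  expect_equal(est0$Q, c(0, 0))

  set.seed(92)
  w <- matrix(rnorm(2 * 10000, sd = 2), ncol = 2)
  est <- estimate_noise(gyro_trace(w), moving)
  expect_true(all(abs(est$Q - 4) / 4 < 0.1))

  est2 <- estimate_noise(gyro_trace(2 * w), moving)
  expect_equal(est2$Q, 4 * est$Q, tolerance = 1e-12)

  expect_error(estimate_noise(gyro_trace(w[1:100, ]), moving), "2 s")
})

test_that("Kalman tracking beats the dead-band baseline on the pursuit scene", {
  g <- make_pursuit_gyro(seed = 64)
  scale <- 3
  truth_px <- cbind(g$true_path[, 1] * scale + 960,
                    g$true_path[, 2] * scale + 540)
  rmse <- function(p) sqrt(mean((p$positions - truth_px)^2))
  pk <- track_cursor(g$trace, filter = "kalman")
  # fast-movement scene: the dead band needs ~30 ADC steps there
  pd <- track_cursor(g$trace, filter = "deadband", deadband_steps = 30L)
  pn <- track_cursor(g$trace, filter = "none")
  expect_lt(rmse(pk), rmse(pd))

  # jitter removal: > 5 Hz energy of the filtered path <= 25% of raw
  expect_lte(highfreq_energy(pk$positions[, 1], 5, 128) /
               highfreq_energy(pn$positions[, 1], 5, 128), 0.25)
})

test_that("a noise-free pursuit trace reproduces its target exactly", {
  g <- make_pursuit_gyro(duration_s = 10, jitter_sd = 0, seed = 1)
  expect_equal(unname(g$trace$rates), unname(g$target_rates))
  g2 <- make_pursuit_gyro(duration_s = 10, jitter_sd = 2, seed = 5)
  g3 <- make_pursuit_gyro(duration_s = 10, jitter_sd = 2, seed = 5)
  expect_identical(g2, g3)
})
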