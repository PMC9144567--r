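test_that("epoching slices whole epochs and drops the remainder", {
  set.seed(20)
  rec <- raw_recording(matrix(rnorm(2 * 9000), 2, 9000), 100, c("A", "B"))
  er <- epoch_signal(rec)                      # 90 s at 100 Hz
  expect_equal(dim(er$epochs), c(2L, 3000L, 3L))

  rec2 <- raw_recording(matrix(rnorm(6000), 1, 6000), 200, "A")
  expect_equal(dim(epoch_signal(rec2)$epochs), c(1L, 6000L, 1L))

  rec3 <- raw_recording(matrix(rnorm(2900), 1, 2900), 100, "A")
  expect_error(epoch_signal(rec3), "shorter than one epoch")

  # 95 s -> 3 epochs, 5 s dropped
  rec4 <- raw_recording(matrix(rnorm(9500), 1, 9500), 100, "A")
  expect_equal(dim(epoch_signal(rec4)$epochs)[3], 3L)
})

test_that("band-pass filter preserves in-band and rejects out-of-band tones", {
  rate <- 100
  t <- seq_len(30 * rate) / rate
  tone <- function(f) sin(2 * pi * f * t)
  rms <- function(x) sqrt(mean(x^2))
  in_band <- band_filter(tone(10), c(8, 13), rate)
  expect_lt(abs(rms(in_band) / rms(tone(10)) - 1), 0.05)
  out_band <- band_filter(tone(2), c(8, 13), rate)
  expect_lt(rms(out_band) / rms(tone(2)), 0.10)
  expect_equal(band_filter(numeric(3000), c(8, 13), rate), numeric(3000))
  expect_length(in_band, length(t))
  expect_error(band_filter(tone(10), c(8, 60), rate), "Nyquist")
})

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(21)
  # unit variance: 0.5 * log(2*pi*e) = 1.41894
  x <- rnorm(50000)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-9)
  expect_equal(0.5 * log(2 * pi * exp(1)), 1.41894, tolerance = 1e-5)

  # variance 1/(2*pi*e) gives exactly zero
  x0 <- x / sqrt(2 * pi * exp(1))
  expect_equal(differential_entropy(x0), 0, tolerance = 1e-9)

  # dense sinusoid of amplitude 2 has variance 2: DE = 0.5*log(4*pi*e)
  s <- 2 * sin(seq(0, 2 * pi, length.out = 100001)[-1])
  expect_equal(differential_entropy(s), 0.5 * log(4 * pi * exp(1)),
               tolerance = 1e-3)
  expect_equal(0.5 * log(4 * pi * exp(1)), 1.7655, tolerance = 1e-3)

  expect_warning(fl <- differential_entropy(rep(1, 10)), "zero-variance")
  expect_equal(fl, -20)
})

test_that("differential entropy is shift-invariant and log-scales", {
  set.seed(22)
  x <- rnorm(2000, sd = 3)
  expect_equal(differential_entropy(x + 100), differential_entropy(x),
               tolerance = 1e-9)
  for (a in c(0.5, 2, 7))
    expect_equal(differential_entropy(a * x),
                 differential_entropy(x) + log(a), tolerance = 1e-9)
})

test_that("feature matrix has the right shape and band-splitting behavior", {
  set.seed(23)
  rate <- 100
  epoch <- matrix(rnorm(2 * 3000), 2, 3000)
  fm <- feature_matrix(epoch, rate)
  expect_equal(dim(fm), c(2L, 5L))
  expect_true(all(is.finite(fm)))

  # identical channels give identical rows, deterministically
  ep2 <- rbind(epoch[1, ], epoch[1, ])
  fm2 <- feature_matrix(ep2, rate)
  expect_identical(fm2[1, ], fm2[2, ])
  expect_identical(fm2, feature_matrix(ep2, rate))

  # each band captures only part of a white signal's power, so per-band
  # DE (log variance) sits below the full-band DE
  full <- differential_entropy(epoch[1, ])
  expect_true(all(fm[1, ] < full))
})

test_that("context assembly stacks k+1 stride-d epochs labelled by the last", {
  set.seed(24)
  n_ep <- 10
  feats <- array(rnorm(2 * 3 * n_ep), c(2, 3, n_ep))
  labels <- sample(stage_levels(), n_ep, replace = TRUE)
  fc <- assemble_contexts(feats, labels, k = 4, d = 1)
  expect_equal(dim(fc$x), c(2L, 3L, 5L, 6L))
  expect_identical(fc$y, labels[5:10])
  # the last frame of each context is the labelled epoch itself
  for (j in seq_len(6))
    expect_equal(fc$x[, , 5, j], feats[, , j + 4])
  # first context stacks epochs 1..5 in order
  expect_equal(fc$x[, , , 1], feats[, , 1:5])

  fc0 <- assemble_contexts(feats, labels, k = 0)
  expect_equal(dim(fc0$x)[3:4], c(1L, 10L))
  expect_identical(fc0$y, labels)

  feats3 <- feats[, , 1:3, drop = FALSE]
  expect_warning(fce <- assemble_contexts(feats3, labels[1:3], k = 4),
                 "no contexts")
  expect_equal(dim(fce$x)[4], 0L)

  # stride 2: epochs t-8, t-6, ..., t
  fc2 <- assemble_contexts(feats, labels, k = 4, d = 2)
  expect_equal(dim(fc2$x)[4], max(0, n_ep - 8))
  expect_equal(fc2$x[, , , 1], feats[, , c(1, 3, 5, 7, 9)])
})
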