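test_that("feature sets have exactly 50 / 26 / 26 named features", {
  expect_length(feature_names("combined"), 50)
  expect_length(feature_names("accel_only"), 26)
  expect_length(feature_names("gyro_only"), 26)
  # the two step-level temporal features belong to every set
  for (m in c("combined", "accel_only", "gyro_only"))
    expect_true(all(c("step_length", "step_duration") %in% feature_names(m)))
  expect_false(any(grepl("^G", feature_names("accel_only"))))
  expect_false(any(grepl("^A", feature_names("gyro_only"))))

  step <- random_step(64, seed = 1)
  fv <- extract_features(step)
  expect_true(all(feature_names("combined") %in% names(fv)))
  expect_equal(sum(names(fv) %in% feature_names("combined")), 50)
})

test_that("step duration and length follow from the frame span", {
  step <- random_step(128, seed = 2)   # 128 frames at 128 Hz
  fv <- extract_features(step)
  expect_equal(fv$step_length, 128)
  expect_equal(fv$step_duration, 1.0)
  expect_error(extract_features(random_step(1, seed = 3)), "at least 2")
})

test_that("toy step matches the hand-computed oracle table", {
  other <- c(0, 1, 0, -1)
  samples <- stats::setNames(
    c(list(c(1, 2, 3, 2)), replicate(5, other, simplify = FALSE)),
    imu_channels())
  fv <- extract_features(make_step(samples, sampling_rate = 128))

  # Ax = [1,2,3,2]: p = (1/8, 1/4, 3/8, 1/4)
  expect_equal(fv$Ax_mean, 2)
  expect_equal(fv$Ax_sd, sd(c(1, 2, 3, 2)))
  expect_equal(fv$Ax_min, 1)
  expect_equal(fv$Ax_max, 3)
  expect_equal(fv$Ax_rms, sqrt(18 / 4))
  expect_equal(fv$Ax_energy, 1 + 4 + 9 + 4)
  expect_equal(fv$Ax_entropy,
               -(1 / 8 * log2(1 / 8) + 2 * (1 / 4 * log2(1 / 4)) +
                   3 / 8 * log2(3 / 8)))
  # DFT of [1,2,3,2]: X1 = -2, X2 = 0, X3 = -2 -> max non-DC magnitude 2
  expect_equal(fv$Ax_amplitude, 2)

  # Gz = [0,1,0,-1] is a pure sine at bin 1: amplitude N/2 * 1 = 2
  expect_equal(fv$Gz_amplitude, 2)
  expect_equal(fv$Gz_energy, 2)
  expect_equal(fv$Gz_rms, sqrt(0.5))
  # magnitudes (0,1,0,1): p = (0, 1/2, 0, 1/2) -> 1 bit
  expect_equal(fv$Gz_entropy, 1)

  # full-vector agreement with the naive oracle
  want <- oracle_features(samples, 128)
  for (nm in names(want)) expect_equal(fv[[nm]], unname(want[nm]))
})

test_that("entropy: uniform maximum, scale invariance, degenerate inputs", {
  expect_equal(channel_entropy(rep(5, 4)), 2)           # log2(4)
  expect_equal(channel_entropy(7), 0)                   # single sample
  expect_warning(z <- channel_entropy(c(0, 0, 0)), "all-zero")
  expect_equal(z, 0)
  set.seed(11)
  for (rep in 1:20) {
    s <- rnorm(sample(2:50, 1))
    h <- channel_entropy(s)
    expect_gte(h, 0)
    expect_lte(h, log2(length(s)) + 1e-12)
    expect_equal(channel_entropy(3.7 * s), h, tolerance = 1e-12)
    expect_lte(h, channel_entropy(rep(1, length(s))) + 1e-12)  # uniform max
  }
})

test_that("energy, rms and spectral amplitude identities", {
  expect_equal(channel_energy(rep(1, 4)), 4)
  expect_equal(channel_energy(numeric(3)), 0)
  expect_equal(channel_amplitude(rep(2.5, 16)), 0)      # constant: only DC
  # cosine of amplitude a at an exact bin -> N/2 * a
  n <- 64; a <- 1.7
  x <- a * cos(2 * pi * 5 * (0:(n - 1)) / n)
  expect_equal(channel_amplitude(x), n / 2 * a, tolerance = 1e-9)
  # alternating signal: Nyquist bin, magnitude N * 1
  alt <- rep(c(1, -1), 8)
  expect_equal(channel_amplitude(alt), oracle_amplitude(alt),
               tolerance = 1e-9)
  expect_equal(channel_amplitude(alt), 16)

  set.seed(12)
  for (rep in 1:25) {
    s <- rnorm(50)
    expect_equal(channel_energy(s), 50 * oracle_rms(s)^2, tolerance = 1e-9)
  }
})

test_that("per-channel statistics satisfy their structural invariants", {
  set.seed(13)
  for (rep in 1:30) {
    step <- random_step(sample(4:128, 1), seed = 1000 + rep)
    fv <- extract_features(step)
    for (ch in imu_channels()) {
      g <- function(stat) fv[[paste0(ch, "_", stat)]]
      expect_lte(g("min"), g("mean"))
      expect_lte(g("mean"), g("max"))
      expect_gte(g("sd"), 0)
      expect_gte(g("energy"), 0)
      n <- fv$step_length
      # rms^2 = mean^2 + population variance
      expect_equal(g("rms")^2, g("mean")^2 + g("sd")^2 * (n - 1) / n,
                   tolerance = 1e-9)
      expect_equal(g("energy"), n * g("rms")^2, tolerance = 1e-9)
    }
  }
})

test_that("select_features keeps identity columns and the contracted order", {
  steps <- lapply(1:3, function(i) random_step(20, seed = i))
  ft <- extract_feature_table(steps)
  expect_equal(ft$step_index, 1:3)
  acc <- select_features(ft, "accel_only")
  expect_true(all(feature_names("accel_only") %in% names(acc)))
  expect_false("Gx_mean" %in% names(acc))
  expect_true("subject_id" %in% names(acc))
})
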