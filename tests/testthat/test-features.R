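# Brute-force loop oracles, independent of the package implementations.
oracle <- list(
  MAV = function(x) { s <- 0; for (v in x) s <- s + abs(v); s / length(x) },
  RMS = function(x) { s <- 0; for (v in x) s <- s + v^2; sqrt(s / length(x)) },
  VAR = function(x) {
    m <- sum(x) / length(x); s <- 0
    for (v in x) s <- s + (v - m)^2
    s / (length(x) - 1)
  },
  WL = function(x) {
    s <- 0
    for (i in 1:(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
    s
  },
  ZC = function(x) {
    s <- 0
    for (i in 1:(length(x) - 1)) if (x[i] * x[i + 1] < 0) s <- s + 1
    s
  },
  SSC = function(x) {
    m <- sum(x) / length(x)
    om <- 0.05 * sqrt(sum((x - m)^2) / (length(x) - 1))
    s <- 0
    for (i in 2:(length(x) - 1)) {
      if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= om) s <- s + 1
    }
    s
  }
)

test_that("every feature matches its brute-force oracle on 1000 random windows", {
  set.seed(101)
  fns <- list(MAV = mav, RMS = rms, VAR = variance, WL = waveform_length,
              ZC = zero_crossings, SSC = slope_sign_change)
  for (i in 1:1000) {
    x <- switch(1 + i %% 4,
                rnorm(150), rnorm(150, sd = 0.01),
                rt(150, df = 3), rnorm(150, mean = 2))
    for (f in names(fns)) {
      expect_equal(fns[[f]](x), oracle[[f]](x), tolerance = 1e-10,
                   label = sprintf("%s on window %d", f, i))
    }
  }
})

test_that("frozen hand-computed examples hold", {
  expect_equal(mav(c(1, -2, 3, -4)), 2.5)
  expect_equal(mav(rep(2.5, 10)), 2.5)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-3, 5)), 3)
  expect_equal(variance(c(1, 2, 3)), 1)
  expect_equal(variance(c(0, 2)), 2)
  expect_equal(waveform_length(c(1, -2, 3, -4)), 15)      # 3 + 5 + 7
  expect_equal(waveform_length(seq(0, 9, by = 1)), 9)     # (N-1)|d|
  expect_equal(zero_crossings(c(1, -1, 2, 3, -5)), 3)
  expect_equal(zero_crossings(rep(c(1, -1), 10)), 19)
  expect_equal(zero_crossings(1:10), 0)
  expect_equal(slope_sign_change(c(0, 1, 0, 1, 0)), 3)
  # thresholding: tiny oscillation products fall below omega = 0.05 * sd
  expect_equal(slope_sign_change(c(0, 0.001, 0, 0.001, 0)), 0)
  expect_equal(slope_sign_change(1:50), 0)                # monotone ramp
  for (z in list(mav, rms, waveform_length)) expect_equal(z(rep(0, 150)), 0)
})

test_that("feature errors and degenerate inputs follow the contracts", {
  expect_error(mav(numeric(0)), "empty")
  expect_error(rms(numeric(0)), "empty")
  expect_error(variance(1), "2 samples")
  expect_error(waveform_length(1), "2 samples")
  expect_error(zero_crossings(1), "2 samples")
  expect_error(slope_sign_change(c(1, 2)), "3 samples")
  expect_error(ar4_coefficient(1:4), "longer than")
  expect_warning(a <- ar4_coefficient(rep(3, 150)), "constant")
  expect_equal(a, 0)
})

test_that("AR(4) fit recovers known processes and vanishes on white noise", {
  # oracle: Levinson-Durbin on the *theoretical* autocovariances recovers
  # the generating coefficients exactly
  phi <- c(0.5, -0.3, 0.2, -0.1)
  rho <- stats::ARMAacf(ar = phi, lag.max = 4)
  phi_hat <- solve(toeplitz(rho[1:4]), rho[2:5])
  expect_equal(unname(phi_hat), phi, tolerance = 1e-10)
  # long simulated series: estimate within +/- 0.05 of the generating value,
  # under the sign convention x_i = -sum a_k x_{i-k} + e_i (a4 = -phi4)
  set.seed(7)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n = 10000))
  expect_lt(abs(ar4_coefficient(x) - (-phi[4])), 0.05)
  # cross-check against the established Yule-Walker implementation
  ref <- stats::ar(x, aic = FALSE, order.max = 4, method = "yule-walker")
  expect_equal(ar4_coefficient(x), -ref$ar[4], tolerance = 1e-8)
  # white noise: theoretical coefficients all zero
  set.seed(8)
  expect_lt(abs(ar4_coefficient(rnorm(10000))), 0.05)
})

test_that("algebraic identities hold on random windows", {
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(150, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    n <- length(x)
    expect_equal(rms(x)^2, (n - 1) / n * variance(x) + mean(x)^2,
                 tolerance = 1e-9)
    expect_lte(mav(x), rms(x) + 1e-12)
    expect_true(zero_crossings(x) >= 0 && zero_crossings(x) <= n - 1)
    expect_true(slope_sign_change(x) >= 0 && slope_sign_change(x) <= n - 2)
    expect_gte(waveform_length(x), 0)
    expect_gte(variance(x), 0)
  }
})

test_that("features obey their scaling laws under x -> a * x", {
  set.seed(12)
  x <- rnorm(150)
  a <- 3.7
  expect_equal(mav(a * x), a * mav(x))
  expect_equal(rms(a * x), a * rms(x))
  expect_equal(waveform_length(a * x), a * waveform_length(x))
  expect_equal(variance(a * x), a^2 * variance(x))
  expect_equal(zero_crossings(a * x), zero_crossings(x))
  expect_equal(ar4_coefficient(a * x), ar4_coefficient(x), tolerance = 1e-9)
  # SSC is *not* scale-invariant: the product scales by a^2 but the
  # threshold only by a. Assert the formula as written: for a shrinking
  # signal the threshold bites and the count can only drop or persist.
  y <- c(0, 0.5, 0.1, 0.6, 0.05, 0.55, 0) + rnorm(7, sd = 0.01)
  big <- slope_sign_change(1000 * y)
  small <- slope_sign_change(y / 1000)
  expect_gte(big, small)
})

test_that("window extraction is channel-major and matches scalar paths", {
  set.seed(13)
  w <- matrix(rnorm(150 * 8), 150, 8)
  fv <- extract_window(w)
  expect_length(fv, 56)
  expect_identical(names(fv)[1:7],
                   paste0("ch1_", c("MAV", "RMS", "VAR", "ARC", "WL", "ZC", "SSC")))
  for (ch in c(1, 4, 8)) {
    expect_equal(unname(fv[sprintf("ch%d_MAV", ch)]), mav(w[, ch]))
    expect_equal(unname(fv[sprintf("ch%d_RMS", ch)]), rms(w[, ch]))
    expect_equal(unname(fv[sprintf("ch%d_VAR", ch)]), variance(w[, ch]))
    expect_equal(unname(fv[sprintf("ch%d_ARC", ch)]), ar4_coefficient(w[, ch]),
                 tolerance = 1e-10)
    expect_equal(unname(fv[sprintf("ch%d_WL", ch)]), waveform_length(w[, ch]))
    expect_equal(unname(fv[sprintf("ch%d_ZC", ch)]), zero_crossings(w[, ch]))
    expect_equal(unname(fv[sprintf("ch%d_SSC", ch)]), slope_sign_change(w[, ch]))
  }
  # single-feature spec -> 8 dimensions
  expect_length(extract_window(w, feature_spec("MAV")), 8)
  # zero window: amplitude features 0, counts 0, ARC degenerates to 0
  expect_warning(fz <- extract_window(matrix(0, 150, 8)), "constant")
  expect_true(all(fz == 0))
})

test_that("feature specs are canonicalized and validated", {
  expect_identical(feature_spec(c("ZC", "MAV"))$selected, c("MAV", "ZC"))
  expect_error(feature_spec(character(0)), "at least one")
  expect_error(feature_spec(c("MAV", "MAV")), "duplicate")
  expect_error(feature_spec("MAW"), "unknown")
})

test_that("dataset extraction preserves counts and schema", {
  feats <- small_subject_features()      # 1 subject, 3 s trials
  expect_equal(nrow(feats), 60 * 20)     # 20 windows per 3 s trial
  expect_length(feature_columns(feats), 56)
  expect_true(all(c("subject_id", "compound_id", "gesture", "wrist",
                    "strength_g", "trial_position") %in% names(feats)))
  w <- slice_windows(tiny_recording(duration = 0.6, id = 33, seed = 2))
  sp <- chronological_split(w, 0.5, shuffle_seed = 1)
  tab <- extract_dataset(sp)
  expect_equal(nrow(tab), 4)
  expect_identical(sort(unique(tab$split)), c("test", "train"))
  expect_equal(sum(tab$split == "train"), 2)
})
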