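make_rec <- function(data, rate = 100, label = "HEALTHY") {
  colnames(data) <- sprintf("ch%02d", seq_len(ncol(data)))
  gait_recording("S1", label, rate, data)
}

test_that("resampling lengths, constants, and sinusoid fidelity", {
  rec <- make_rec(matrix(rnorm(2000), 1000, 2), rate = 100)
  out <- resample_recording(rec, 25)
  expect_equal(nrow(out$data), 250)
  expect_equal(out$sample_rate_hz, 25)

  const <- make_rec(matrix(3.5, 400, 1), rate = 100)
  expect_true(all(resample_recording(const, 25)$data == 3.5))

  # 1 Hz unit sinusoid, 100 -> 25 Hz: compare against the closed form on
  # the new grid
  tt <- (0:999) / 100
  sine <- make_rec(matrix(sin(2 * pi * tt), ncol = 1), rate = 100)
  res <- resample_recording(sine, 25)
  t_new <- (0:249) / 25
  expect_lt(max(abs(res$data[, 1] - sin(2 * pi * t_new))), 0.01)
  expect_lt(abs(max(res$data[, 1]) - 1), 0.01)

  ev <- gait_recording("S1", "PD", 100, matrix(rnorm(100), ncol = 1),
                       channel_names = "c1", event_log = c(0.1, 0.9))
  expect_identical(resample_recording(ev, 25)$event_log, c(0.1, 0.9))
  expect_warning(resample_recording(rec, 500), "upsampling")
})

test_that("Savitzky-Golay reproduces low-degree polynomials and smooths noise", {
  cfg <- preprocess_config(sg_window = 11, sg_polyorder = 3)
  s <- seq(0, 1, length.out = 200)
  poly2 <- 2 + 3 * s - 5 * s^2
  rec <- make_rec(matrix(poly2, ncol = 1))
  out <- savitzky_golay(rec, cfg)
  expect_lt(max(abs(out$data[, 1] - poly2)), 1e-8)

  const <- make_rec(matrix(7, 100, 1))
  expect_lt(max(abs(savitzky_golay(const, cfg)$data - 7)), 1e-10)

  set.seed(1)
  noise <- rnorm(1000)
  sm <- savitzky_golay(make_rec(matrix(noise, ncol = 1)), cfg)$data[, 1]
  expect_lt(var(sm), var(noise))
  # interior samples agree with a direct sliding least-squares fit
  oracle <- sliding_ls_fit(noise, 11, 3)
  interior <- 6:995
  expect_lt(max(abs(sm[interior] - oracle[interior])), 1e-8)

  expect_error(savitzky_golay(make_rec(matrix(1:5, ncol = 1)),
                              preprocess_config(sg_window = 11)),
               "longer than")
  expect_error(preprocess_config(sg_window = 10), "odd")
})

test_that("Butterworth gain matches the analytic magnitude response", {
  cfg <- preprocess_config(butter_order = 4, butter_cutoff_hz = 6)
  rate <- 25
  n <- 2000
  tt <- (0:(n - 1)) / rate
  mid <- 500:1500
  amp_after <- function(f_hz, zero_phase = TRUE) {
    c2 <- cfg
    c2$zero_phase <- zero_phase
    rec <- make_rec(matrix(sin(2 * pi * f_hz * tt), ncol = 1), rate = rate)
    out <- butterworth_lowpass(rec, c2)
    max(abs(out$data[mid, 1]))
  }
  # at the cutoff, one pass gives 1/sqrt(2); forward-backward squares it
  expect_lt(abs(amp_after(6) - 0.5), 0.02)
  # at twice the cutoff the order-4 analytic gain is (1/sqrt(1+2^8))^2
  expect_lt(amp_after(12), 0.01)
  # well below the cutoff the signal passes
  expect_gt(amp_after(1), 0.98)

  const <- make_rec(matrix(-2.5, 300, 1), rate = rate)
  expect_lt(max(abs(butterworth_lowpass(const, cfg)$data + 2.5)), 1e-9)

  bad <- preprocess_config(butter_cutoff_hz = 6)
  slow <- make_rec(matrix(rnorm(100), ncol = 1), rate = 10)
  expect_error(butterworth_lowpass(slow, bad), "Nyquist")
})

test_that("z-normalization yields mean 0 / sd 1, handles constants, idempotent", {
  rec <- make_rec(matrix(rnorm(600, 5, 3), 200, 3))
  out <- znormalize(rec)
  for (j in 1:3) {
    expect_lt(abs(mean(out$data[, j])), 1e-9)
    expect_lt(abs(sd(out$data[, j]) - 1), 1e-9)
  }
  twice <- znormalize(out)
  expect_lt(max(abs(twice$data - out$data)), 1e-9)

  cdata <- cbind(rnorm(50), rep(4, 50))
  expect_warning(zc <- znormalize(make_rec(cdata)), "zero-variance")
  expect_true(all(zc$data[, 2] == 0))
})

test_that("segmentation counts, exclusion of corrupted windows, label inheritance", {
  rec <- make_rec(matrix(rnorm(600), 300, 2), label = "PD")
  segs <- segment_recording(rec, 125)
  expect_length(segs, 2)
  expect_identical(unique(vapply(segs, `[[`, "", "label")), "PD")
  expect_identical(unique(vapply(segs, `[[`, "", "provenance")), "ORIGINAL")
  expect_equal(segs[[1]]$data, rec$data[1:125, ], ignore_attr = TRUE)
  # sample conservation: kept windows * L + dropped tail = T
  expect_equal(2 * 125 + 50, 300)

  expect_length(segment_recording(make_rec(matrix(0, 124, 1)), 125), 0)

  d <- matrix(rnorm(375), 375, 1)
  d[131, 1] <- NaN
  segs2 <- segment_recording(make_rec(d), 125)
  expect_length(segs2, 2)
  expect_identical(vapply(segs2, `[[`, 0L, "segment_index"), c(1L, 3L))
})

test_that("the preprocessing chain is a pure function of recording and config", {
  rec <- simulate_recording(simulator_config(duration_s = 20, seed = 1),
                            "HEALTHY", 3)
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$data, b$data)
  expect_equal(nrow(a$data), 20 * 25)
})
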