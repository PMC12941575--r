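test_that("zero perturbation yields the identity warp", {
  for (s in 1:5) {
    w <- make_warp(125, warp_config(sigma = 0), draw_seed = s)
    expect_lt(max(abs(w$w - 0:124)), 1e-9)
  }
})

test_that("warp invariants: endpoints, strict monotonicity, range", {
  for (s in 1:500) {
    w <- make_warp(125, warp_config(sigma = 0.2), draw_seed = s)
    expect_identical(w$w[1], 0)
    expect_identical(w$w[125], 124)
    expect_true(all(diff(w$w) > 0))
    expect_true(all(w$w >= 0 & w$w <= 124))
  }
  # also at a harsher sigma and a short segment
  for (s in 1:100) {
    w <- make_warp(20, warp_config(sigma = 1.0), draw_seed = s)
    expect_true(all(diff(w$w) > 0))
  }
  expect_error(make_warp(3, warp_config()), "at least 4")
  expect_error(warp_config(sigma = -0.1), "non-negative")
})

test_that("the mean warp is close to the identity (Monte Carlo)", {
  L <- 125
  acc <- numeric(L)
  n_draws <- 2000
  for (s in seq_len(n_draws)) {
    acc <- acc + make_warp(L, warp_config(sigma = 0.2), draw_seed = s)$w
  }
  expect_lt(max(abs(acc / n_draws - 0:(L - 1))), 2)
})

test_that("warping a segment preserves shape, constants, and couplings", {
  seg <- make_segment(matrix(rnorm(125 * 3), 125, 3), "PD", "P1")
  idw <- make_warp(125, warp_config(sigma = 0), draw_seed = 1)
  same <- warp_segment(seg, idw)
  expect_lt(max(abs(same$data - seg$data)), 1e-12)
  expect_identical(same$provenance, "SYNTHETIC")
  expect_identical(same$parent_id, seg$id)
  expect_identical(same$label, "PD")

  w <- make_warp(125, warp_config(sigma = 0.3), draw_seed = 9)
  cseg <- make_segment(matrix(2.5, 125, 2), "PD", "P1")
  expect_lt(max(abs(warp_segment(cseg, w)$data - 2.5)), 1e-12)

  warped <- warp_segment(seg, w)
  expect_equal(dim(warped$data), c(125, 3))
  expect_identical(colnames(warped$data), colnames(seg$data))
  # all channels share one warp: warping a duplicated channel gives
  # identical columns
  dup <- make_segment(cbind(seg$data[, 1], seg$data[, 1]), "PD", "P2")
  wd <- warp_segment(dup, w)
  expect_identical(wd$data[, 1], wd$data[, 2])

  short <- make_segment(matrix(0, 64, 3), "PD", "P3")
  expect_error(warp_segment(short, w), "does not match")
})

test_that("selective augmentation multiplies only the targeted class", {
  segs <- c(
    lapply(1:10, function(i) make_segment(matrix(rnorm(125), 125, 1), "PD",
                                          sprintf("P%02d", i))),
    lapply(1:20, function(i) make_segment(matrix(rnorm(125), 125, 1),
                                          "HEALTHY", sprintf("H%02d", i))))
  pol <- augmentation_policy("PD_ONLY", warp_config(n_variants = 5, seed = 3))
  out <- augment_dataset(segs, pol)
  labs <- vapply(out, `[[`, "", "label")
  prov <- vapply(out, `[[`, "", "provenance")
  expect_equal(sum(labs == "PD"), 60)
  expect_equal(sum(labs == "PD" & prov == "ORIGINAL"), 10)
  expect_equal(sum(labs == "HEALTHY"), 20)
  expect_true(all(prov[labs == "HEALTHY"] == "ORIGINAL"))

  none <- augment_dataset(segs, augmentation_policy("NONE"))
  expect_identical(none, segs)

  full <- augment_dataset(segs, augmentation_policy("FULL",
                                                    warp_config(n_variants = 5,
                                                                seed = 3)))
  labs_f <- vapply(full, `[[`, "", "label")
  expect_equal(sum(labs_f == "PD"), 60)
  expect_equal(sum(labs_f == "HEALTHY"), 120)

  ho <- augment_dataset(segs, augmentation_policy("HEALTHY_ONLY",
                                                  warp_config(n_variants = 2,
                                                              seed = 3)))
  expect_length(ho, 30 + 40)

  # augmentation is a pure function of (segments, policy)
  out2 <- augment_dataset(segs, pol)
  expect_identical(lapply(out, `[[`, "data"), lapply(out2, `[[`, "data"))

  # synthetic inputs are refused (no compounding)
  expect_error(augment_dataset(out, pol), "ORIGINAL")
})

test_that("warping reorders time without shifting per-channel means", {
  set.seed(7)
  base <- make_segment(matrix(rnorm(125 * 2), 125, 2), "PD", "P1")
  sds <- apply(base$data, 2, sd)
  dev <- replicate(300, {
    w <- make_warp(125, warp_config(sigma = 0.2),
                   draw_seed = sample.int(1e6, 1))
    max(abs(colMeans(warp_segment(base, w)$data) -
              colMeans(base$data)) / sds)
  })
  expect_gte(mean(dev < 0.2), 0.99)
})

test_that("variant dissimilarity grows with warp intensity", {
  set.seed(11)
  tt <- 0:124
  base <- make_segment(matrix(sin(2 * pi * tt / 25), 125, 1), "PD", "P1")
  rms_at <- function(sigma) {
    mean(replicate(200, {
      w <- make_warp(125, warp_config(sigma = sigma),
                     draw_seed = sample.int(1e6, 1))
      sqrt(mean((warp_segment(base, w)$data - base$data)^2))
    }))
  }
  d <- vapply(c(0.05, 0.2, 0.5), rms_at, numeric(1))
  expect_true(all(diff(d) > 0))
})
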