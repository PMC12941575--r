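test_that("confusion-derived metrics match hand-computed tables", {
  # TP=15, FN=1, TN=33, FP=2 at threshold 0.5
  labels <- rep(c("PD", "HEALTHY"), c(16, 35))
  scores <- c(rep(0.9, 15), 0.1,          # 15 TP, 1 FN
              rep(0.8, 2), rep(0.2, 33))  # 2 FP, 33 TN
  rep0 <- compute_metrics(labels, scores)
  expect_identical(rep0$confusion, list(tp = 15L, fp = 2L, tn = 33L,
                                        fn = 1L))
  expect_equal(rep0$sensitivity, 15 / 16)
  expect_equal(rep0$specificity, 33 / 35)
  expect_equal(rep0$accuracy, 48 / 51)

  perfect <- compute_metrics(rep(c("PD", "HEALTHY"), c(5, 5)),
                             c(runif(5, 0.6, 1), runif(5, 0, 0.4)))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$confusion$fp + perfect$confusion$fn, 0L)

  expect_error(compute_metrics(rep("PD", 4), runif(4)), "single-class")
  expect_error(compute_metrics(c("PD", "HEALTHY"), runif(3)), "equal length")
})

test_that("trapezoidal AUC equals the ordered-pair statistic with ties", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    labels <- ifelse(runif(n) < runif(1, 0.2, 0.8), "PD", "HEALTHY")
    if (length(unique(labels)) < 2) labels[1:2] <- c("PD", "HEALTHY")
    # coarse scores so ties occur often
    scores <- round(runif(n), sample(c(1, 2), 1))
    auc <- compute_metrics(labels, scores)$auc
    expect_equal(auc, pair_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("ROC points are monotone and span the unit square", {
  set.seed(3)
  labels <- ifelse(runif(300) < 0.3, "PD", "HEALTHY")
  scores <- runif(300)
  r <- compute_metrics(labels, scores)
  expect_true(!is.unsorted(r$roc_points$fpr))
  expect_true(!is.unsorted(r$roc_points$tpr))
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
               c(fpr = 1, tpr = 1))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- ifelse(runif(150) < 0.4, "PD", "HEALTHY")
  scores <- round(runif(150), 2)
  ours <- compute_metrics(labels, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, levels = c("HEALTHY", "PD")),
    predictor = scores, levels = c("HEALTHY", "PD"), direction = "<",
    quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("sample entropy: constants, ordering, and exact oracle agreement", {
  expect_equal(sample_entropy(rep(3, 50)), 0)

  set.seed(8)
  noise <- runif(1000)
  sine <- sin(2 * pi * (0:999) / 50)
  expect_gt(sample_entropy(noise), sample_entropy(sine))

  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(200) + sin(2 * pi * (0:199) / 25)
    expect_identical(sample_entropy(x), naive_sampen(x))
  }

  flat <- c(rep(0, 20), 5, rep(0, 20))
  expect_error(sample_entropy(1:5), "at least 10")
  expect_warning(se <- sample_entropy(seq_len(200) * 1000, r_factor = 1e-9),
                 "Inf")
  expect_identical(se, Inf)
})

test_that("stride-interval CV formula and simulator ordering", {
  expect_equal(stride_interval_cv(seq(0, 10, by = 1)), 0)
  iv <- c(1.0, 1.1, 0.9)
  ev <- cumsum(c(0, iv))
  expect_equal(stride_interval_cv(ev), sd(iv) / mean(iv))
  expect_error(stride_interval_cv(c(0, 1)), "at least 3")
})

test_that("with zero variants all policies collapse to the baseline", {
  cfg <- simulator_config(n_healthy_subjects = 4, n_pd_subjects = 4,
                          duration_s = 30, seed = 77)
  cohort <- simulate_cohort(cfg)
  mc <- model_config(conv_filters = c(4, 8), kernel_sizes = c(3, 3),
                     lstm_units = 8, epochs = 3, seed = 1)
  res <- compare_strategies(cohort, model = mc, seeds = 1:2,
                            warp = warp_config(n_variants = 0),
                            retained_k = 8, rf_trees = 100)
  # identical reports per seed across policies
  for (si in 1:2) {
    base <- res$reports[["NONE"]][[si]]
    for (p in c("HEALTHY_ONLY", "FULL", "PD_ONLY")) {
      expect_identical(res$reports[[p]][[si]]$accuracy, base$accuracy)
      expect_identical(res$reports[[p]][[si]]$auc, base$auc)
      expect_identical(res$reports[[p]][[si]]$confusion, base$confusion)
    }
  }
  # the comparison table mirrors the four-policy layout
  expect_equal(nrow(res$summary), 4)
  expect_true(all(c("mean_accuracy", "mean_auc", "mean_sensitivity",
                    "mean_specificity") %in% names(res$summary)))
})
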