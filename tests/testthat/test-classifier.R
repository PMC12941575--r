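test_that("stratified split preserves ratios, reproduces, and blocks leakage", {
  segs <- c(
    lapply(1:80, function(i) make_segment(matrix(rnorm(50), 25, 2), "HEALTHY",
                                          sprintf("H%03d", i))),
    lapply(1:20, function(i) make_segment(matrix(rnorm(50), 25, 2), "PD",
                                          sprintf("P%03d", i))))
  sp <- split_dataset(segs, val_fraction = 0.2, seed = 3)
  expect_length(sp$train, 80)
  expect_length(sp$validation, 20)
  val_labs <- vapply(sp$validation, `[[`, "", "label")
  expect_equal(sum(val_labs == "PD"), 4)
  expect_length(intersect(vapply(sp$train, `[[`, "", "id"),
                          vapply(sp$validation, `[[`, "", "id")), 0)

  sp2 <- split_dataset(segs, val_fraction = 0.2, seed = 3)
  expect_identical(vapply(sp2$validation, `[[`, "", "id"),
                   vapply(sp$validation, `[[`, "", "id"))

  # after augmenting the training side, no validation segment has a parent
  # or child in train
  aug <- augment_dataset(sp$train,
                         augmentation_policy("FULL",
                                             warp_config(n_variants = 2,
                                                         seed = 1)))
  parents <- unlist(lapply(aug, `[[`, "parent_id"))
  val_ids <- vapply(sp$validation, `[[`, "", "id")
  expect_length(intersect(parents, val_ids), 0)

  expect_error(split_dataset(segs[1:80], seed = 1), "both classes")
  expect_error(split_dataset(aug, seed = 1), "ORIGINAL")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  L <- 16; C <- 3; N <- 6
  X <- array(rnorm(L * C * N), dim = c(L, C, N))
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  arch <- list(filters = c(4L, 5L), kernels = c(3L, 3L), pool = 2L,
               lstm_units = 4L, use_bn = TRUE)
  glx <- function(r, c) matrix(runif(r * c, -1, 1) * sqrt(6 / (r + c)), r, c)
  params <- list(
    conv = list(
      list(W = glx(3 * C, 4), b = rnorm(4) * 0.1,
           gamma = runif(4, 0.5, 1.5), beta = rnorm(4) * 0.1),
      list(W = glx(3 * 4, 5), b = rnorm(5) * 0.1,
           gamma = runif(5, 0.5, 1.5), beta = rnorm(5) * 0.1)),
    lstm = list(Wx = glx(16, 5), Wh = glx(16, 4), b = rnorm(16) * 0.1),
    dense = list(W = glx(2, 4), b = rnorm(2) * 0.1))
  bn <- list(list(mean = rep(0, 4), var = rep(1, 4)),
             list(mean = rep(0, 5), var = rep(1, 5)))
  lg <- gaitwarp:::cpp_cnnlstm_loss_grads(params, bn, arch, X, y)
  expect_true(is.finite(lg$loss))

  modp <- function(p, path, f) {
    if (length(path) == 0) return(f(p))
    p[[path[[1]]]] <- modp(p[[path[[1]]]], path[-1], f)
    p
  }
  eps <- 1e-6
  check_path <- function(path, n_el = 8) {
    A <- params; G <- lg$grads
    for (k in path) { A <- A[[k]]; G <- G[[k]] }
    rel <- vapply(seq_len(min(n_el, length(A))), function(i) {
      lp <- gaitwarp:::cpp_cnnlstm_loss_grads(
        modp(params, path, function(m) { m[i] <- m[i] + eps; m }),
        bn, arch, X, y)$loss
      lm <- gaitwarp:::cpp_cnnlstm_loss_grads(
        modp(params, path, function(m) { m[i] <- m[i] - eps; m }),
        bn, arch, X, y)$loss
      gn <- (lp - lm) / (2 * eps)
      if (abs(gn) < 1e-10 && abs(G[i]) < 1e-10) 0 else
        abs(gn - G[i]) / max(abs(gn), abs(G[i]), 1e-8)
    }, numeric(1))
    max(rel)
  }
  paths <- list(list("conv", 1, "W"), list("conv", 1, "gamma"),
                list("conv", 1, "beta"), list("conv", 2, "W"),
                list("lstm", "Wx"), list("lstm", "Wh"), list("lstm", "b"),
                list("dense", "W"), list("dense", "b"))
  for (p in paths) expect_lt(check_path(p), 1e-4)
})

test_that("the classifier solves a linearly separable toy task", {
  wins <- 0
  for (s in 1:5) {
    segs <- toy_separable_segments(500, seed = 100 + s)
    fit <- train_classifier(
      segs, list(),
      model_config(conv_filters = c(4, 8), kernel_sizes = c(3, 3),
                   lstm_units = 8, epochs = 15, seed = s))
    if (max(fit$history$train_accuracy) >= 0.99) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("prediction is calibrated softmax and deterministic", {
  segs <- toy_separable_segments(200, seed = 7)
  sp <- split_dataset(segs, 0.25, seed = 1)
  mc <- model_config(conv_filters = c(4, 8), kernel_sizes = c(3, 3),
                     lstm_units = 8, epochs = 10, seed = 2)
  fit <- train_classifier(sp$train, sp$validation, mc)
  expect_equal(nrow(fit$history), 10)
  expect_true(all(fit$history$train_loss >= 0))
  expect_true(all(fit$history$val_accuracy >= 0 &
                    fit$history$val_accuracy <= 1))

  P <- predict(fit$model, sp$validation)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
  expect_identical(P, predict(fit$model, sp$validation))

  # held-out accuracy on the separable task is near-perfect
  pred_lab <- colnames(P)[max.col(P)]
  truth <- vapply(sp$validation, `[[`, "", "label")
  expect_gte(mean(pred_lab == truth), 0.95)

  # same seeds and data reproduce the fit exactly
  fit2 <- train_classifier(sp$train, sp$validation, mc)
  expect_identical(fit$history, fit2$history)
  expect_identical(predict(fit2$model, sp$validation), P)

  short <- toy_separable_segments(4, len = 20, seed = 1)
  expect_error(predict(fit$model, short), "does not match")
})

test_that("randomly permuted labels give chance-level validation accuracy", {
  accs <- vapply(1:5, function(s) {
    segs <- toy_separable_segments(240, seed = 200 + s)
    set.seed(s)
    labs <- sample(vapply(segs, `[[`, "", "label"))
    segs <- Map(function(seg, l) { seg$label <- l; seg }, segs, labs)
    sp <- split_dataset(segs, 0.25, seed = s)
    fit <- train_classifier(
      sp$train, sp$validation,
      model_config(conv_filters = c(4, 8), kernel_sizes = c(3, 3),
                   lstm_units = 8, epochs = 10, seed = s))
    fit$history$val_accuracy[10]
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})
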