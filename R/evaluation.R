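#' Segment-level classification metrics with ROC/AUC
#'
#' The Parkinsonian class is the positive class: sensitivity is the true
#' positive rate for PD detection, specificity the true negative rate for
#' healthy controls. The ROC curve is traced by sweeping all distinct scores
#' as thresholds; the AUC is its trapezoidal integral, which equals the
#' fraction of correctly ordered positive-negative score pairs with ties
#' counted one half.
#'
#' @param true_labels character vector of `"HEALTHY"`/`"PD"`.
#' @param scores numeric vector of predicted PD probabilities (or a matrix
#'   with a `"PD"` column, as returned by [predict.cnn_lstm_model()]).
#' @param threshold decision threshold for the confusion matrix.
#' @param history optional per-epoch training history to attach.
#' @param config_fingerprint,seeds optional provenance to attach.
#' @return An object of class `evaluation_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `confusion` (tp/fp/tn/fn),
#'   `roc_points`, and `threshold`.
#' @examples
#' compute_metrics(c("PD", "PD", "HEALTHY"), c(0.9, 0.6, 0.2))
#' @export
compute_metrics <- function(true_labels, scores, threshold = 0.5,
                            history = NULL, config_fingerprint = NULL,
                            seeds = NULL) {
  if (is.matrix(scores)) scores <- scores[, "PD"]
  if (length(true_labels) != length(scores)) {
    stop("true_labels and scores must have equal length", call. = FALSE)
  }
  y <- true_labels == "PD"
  if (all(y) || !any(y)) {
    stop("AUC is undefined with a single-class truth vector", call. = FALSE)
  }
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)

  # ROC: cumulative TP/FP over descending distinct scores.
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  distinct <- c(diff(ss) != 0, TRUE)
  cum_tp <- cumsum(ys)[distinct]
  cum_fp <- cumsum(!ys)[distinct]
  tpr <- c(0, cum_tp / sum(y))
  fpr <- c(0, cum_fp / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)

  structure(
    list(accuracy = (tp + tn) / length(y), sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp), auc = auc,
         confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
         roc_points = data.frame(fpr = fpr, tpr = tpr),
         threshold = threshold, history = history,
         config_fingerprint = config_fingerprint, seeds = seeds),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> acc %.3f | auc %.3f | sens %.3f | spec %.3f\n",
    x$accuracy, x$auc, x$sensitivity, x$specificity))
  cat(sprintf("  confusion (PD positive): TP %d FP %d TN %d FN %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn))
  invisible(x)
}

#' Sample entropy of a univariate series
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of m-length templates whose
#' Chebyshev distance is at most `r` and A the corresponding (m+1)-length
#' counts, with self-matches excluded and both template sets anchored at the
#' same positions. Lower values indicate more regular, less complex signals;
#' simulated Parkinsonian channels score below healthy ones.
#'
#' @param series numeric vector (length >= 10).
#' @param m template length (default 2).
#' @param r_factor tolerance as a fraction of the series SD (default 0.2).
#' @return Non-negative value; `+Inf` with a warning when no (m+1)-length
#'   template matches exist.
#' @export
sample_entropy <- function(series, m = 2, r_factor = 0.2) {
  if (length(series) < 10) {
    stop("sample_entropy needs at least 10 points", call. = FALSE)
  }
  r <- r_factor * sd(series)
  counts <- cpp_sampen_counts(as.numeric(series), as.integer(m), r)
  if (counts[2] == 0 || counts[1] == 0) {
    warning("no template matches at length m+1; returning +Inf")
    return(Inf)
  }
  -log(counts[1] / counts[2])
}

#' Coefficient of variation of stride intervals
#'
#' sd/mean of successive differences of stride-onset times. Applied to the
#' simulator's ground-truth event logs it recovers the class-differential
#' stride-timing variability exactly, without any signal processing.
#'
#' @param event_log numeric vector of stride-onset times (>= 3 events).
#' @return Dimensionless fraction.
#' @export
stride_interval_cv <- function(event_log) {
  if (length(event_log) < 3) {
    stop("stride_interval_cv needs at least 3 events", call. = FALSE)
  }
  d <- diff(event_log)
  sd(d) / mean(d)
}

# One policy-seed pipeline run on a prepared split: augment the training
# side, project both sides onto the ranked channels, train, and score the
# untouched validation originals.
run_policy_once <- function(split, ranking, k, policy, mc, master_seed) {
  aug_train <- augment_dataset(split$train, policy)
  train_sel <- select_channels(aug_train, ranking, k)
  val_sel <- select_channels(split$validation, ranking, k)
  mc$seed <- derive_seed(master_seed, "model")
  fit <- train_classifier(train_sel, val_sel, mc)
  probs <- predict(fit$model, val_sel)
  compute_metrics(segment_labels(val_sel), probs,
                  history = fit$history,
                  config_fingerprint = config_fingerprint(
                    list(policy = policy, model = mc, k = k)),
                  seeds = master_seed)
}

# Shared per-seed context so that across policies only augmentation differs:
# identical split and identical channel ranking (fit on training originals).
seed_context <- function(segments, seed, val_fraction, k, rf_trees) {
  split <- split_dataset(segments, val_fraction,
                         seed = derive_seed(seed, "split"))
  ranking <- rank_channels(split$train, n_trees = rf_trees,
                           seed = derive_seed(seed, "rank"))
  list(split = split, ranking = ranking)
}

#' Compare the four augmentation policies on one cohort
#'
#' Runs the full pipeline per (policy, seed): preprocess and segment the
#' cohort, split stratified by label, augment the training side only, rank
#' channels on training originals, project, train the CNN-LSTM, and evaluate
#' on the untouched validation originals. Within a seed, all policies share
#' the same split and ranking bit-for-bit, so performance differences are
#' attributable to the augmentation policy alone.
#'
#' @param cohort list of [gait_recording()] objects.
#' @param policies character vector of policy modes to compare.
#' @param model a [model_config()] (its seed is re-derived per run).
#' @param seeds integer vector of master seeds (>= 1).
#' @param warp a [warp_config()] shared by all augmenting policies.
#' @param pre_config a [preprocess_config()].
#' @param window_len segment length in samples.
#' @param val_fraction validation fraction for the stratified split.
#' @param retained_k channels kept after ranking; defaults to
#'   `min(64, n_channels)`.
#' @param rf_trees trees in the ranking forest.
#' @return An object of class `strategy_comparison`: a `summary` data frame
#'   (one row per policy: mean and sd of accuracy, AUC, sensitivity,
#'   specificity over seeds) plus the per-run `reports`.
#' @export
compare_strategies <- function(cohort,
                               policies = c("NONE", "HEALTHY_ONLY", "FULL",
                                            "PD_ONLY"),
                               model = model_config(), seeds = 1:5,
                               warp = warp_config(),
                               pre_config = preprocess_config(),
                               window_len = 125, val_fraction = 0.2,
                               retained_k = NULL, rf_trees = 200) {
  segments <- preprocess_cohort(cohort, pre_config, window_len)
  n_ch <- ncol(segments[[1]]$data)
  k <- if (is.null(retained_k)) min(64L, n_ch) else min(retained_k, n_ch)

  reports <- lapply(stats::setNames(nm = policies), function(p) vector("list", length(seeds)))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    ctx <- seed_context(segments, seed, val_fraction, k, rf_trees)
    for (p in policies) {
      wc <- warp
      wc$seed <- derive_seed(seed, "warp")
      pol <- augmentation_policy(p, wc)
      reports[[p]][[si]] <- run_policy_once(ctx$split, ctx$ranking, k, pol,
                                            model, seed)
    }
  }

  summary_df <- do.call(rbind, lapply(policies, function(p) {
    m <- vapply(reports[[p]], function(r) {
      c(r$accuracy, r$auc, r$sensitivity, r$specificity)
    }, numeric(4))
    data.frame(policy = p,
               mean_accuracy = mean(m[1, ]), sd_accuracy = sd(m[1, ]),
               mean_auc = mean(m[2, ]), sd_auc = sd(m[2, ]),
               mean_sensitivity = mean(m[3, ]), sd_sensitivity = sd(m[3, ]),
               mean_specificity = mean(m[4, ]), sd_specificity = sd(m[4, ]))
  }))
  rownames(summary_df) <- NULL
  structure(
    list(summary = summary_df, reports = reports, seeds = seeds,
         retained_k = k, warp = warp, model = model),
    class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison> over seeds:",
      paste(x$seeds, collapse = ", "), "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Sweep augmentation intensity for the selective policy
#'
#' Evaluates PD-only augmentation on a grid of augmentation factors (variants
#' per pathological segment) and warp intensities `sigma`, reporting mean and
#' sd of validation accuracy and AUC per cell. This probes the bounded range
#' of injected temporal variability within which augmentation helps: past it,
#' warps distort stride structure and performance degrades.
#'
#' @param cohort list of [gait_recording()] objects.
#' @param factors integer vector of variants per PD segment (0 = baseline).
#' @param sigmas numeric vector of warp standard deviations.
#' @inheritParams compare_strategies
#' @return An object of class `sweep_result` with a `grid` data frame.
#' @export
sweep_envelope <- function(cohort, factors = c(1, 3, 5, 8, 12),
                           sigmas = c(0.05, 0.2, 0.5, 1.0),
                           model = model_config(), seeds = 1:5,
                           pre_config = preprocess_config(), window_len = 125,
                           val_fraction = 0.2, retained_k = NULL,
                           rf_trees = 200) {
  segments <- preprocess_cohort(cohort, pre_config, window_len)
  n_ch <- ncol(segments[[1]]$data)
  k <- if (is.null(retained_k)) min(64L, n_ch) else min(retained_k, n_ch)

  contexts <- lapply(seeds, function(seed) {
    seed_context(segments, seed, val_fraction, k, rf_trees)
  })

  rows <- list()
  for (f in factors) {
    for (sg in sigmas) {
      accs <- numeric(length(seeds))
      aucs <- numeric(length(seeds))
      for (si in seq_along(seeds)) {
        seed <- seeds[si]
        wc <- warp_config(sigma = sg, n_variants = f,
                          seed = derive_seed(seed, "warp"))
        pol <- if (f == 0) augmentation_policy("NONE", wc) else
          augmentation_policy("PD_ONLY", wc)
        rep_i <- run_policy_once(contexts[[si]]$split, contexts[[si]]$ranking,
                                 k, pol, model, seed)
        accs[si] <- rep_i$accuracy
        aucs[si] <- rep_i$auc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, sigma = sg,
        mean_accuracy = mean(accs), sd_accuracy = sd(accs),
        mean_auc = mean(aucs), sd_auc = sd(aucs))
    }
  }
  structure(list(grid = do.call(rbind, rows), seeds = seeds, retained_k = k),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> over seeds:", paste(x$seeds, collapse = ", "), "\n")
  print(x$grid, digits = 3)
  invisible(x)
}
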