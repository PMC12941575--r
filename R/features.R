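#' Per-channel summary features of a segment
#'
#' For every channel: mean, standard deviation, RMS, mean absolute first
#' difference, and the dominant-frequency power fraction (largest non-DC
#' periodogram bin over total non-DC power). These summaries feed the
#' Random-Forest channel ranking; they deliberately aggregate over time so
#' feature importances aggregate naturally per channel.
#'
#' @param segment a [gait_segment()].
#' @return Numeric matrix, channels x 5 named features.
#' @export
channel_summary_features <- function(segment) {
  x <- segment$data
  n <- nrow(x)
  feats <- t(apply(x, 2, function(ch) {
    p <- Mod(fft(ch))^2
    nonr <- p[2:(floor(n / 2) + 1)]
    tot <- sum(nonr)
    c(mean = mean(ch), sd = sd(ch), rms = sqrt(mean(ch^2)),
      madiff = mean(abs(diff(ch))),
      dompow = if (tot > 0) max(nonr) / tot else 0)
  }))
  rownames(feats) <- colnames(x)
  feats
}

#' Rank channels by Random-Forest importance
#'
#' Per-channel summary features of every segment are stacked into a feature
#' table (segments x channels*5) on which a seeded Random Forest classifies
#' the segment label. A channel's importance is the sum of its features'
#' impurity importances, renormalized to sum to 1.
#'
#' @param segments list of [gait_segment()] objects (at least 2 per class).
#' @param n_trees number of trees.
#' @param seed RNG seed for the forest.
#' @return An object of class `channel_ranking` with `channel_names` in
#'   descending importance order and aligned `importances` summing to 1.
#' @export
rank_channels <- function(segments, n_trees = 500, seed = 1L) {
  labels <- segment_labels(segments)
  tab <- table(factor(labels, levels = GAIT_LABELS))
  if (any(tab < 2)) {
    stop("rank_channels needs at least 2 segments per class (got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")",
         call. = FALSE)
  }
  ch_names <- colnames(segments[[1]]$data)
  feat_rows <- lapply(segments, function(s) {
    f <- channel_summary_features(s)
    stats::setNames(as.numeric(t(f)),
                    as.vector(t(outer(rownames(f), colnames(f), paste,
                                      sep = "."))))
  })
  X <- do.call(rbind, feat_rows)
  y <- factor(labels, levels = GAIT_LABELS)
  fit <- with_seed(seed, randomForest::randomForest(x = as.data.frame(X),
                                                    y = y, ntree = n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  per_channel <- vapply(ch_names, function(ch) {
    sum(imp[startsWith(names(imp), paste0(ch, "."))])
  }, numeric(1))
  total <- sum(per_channel)
  if (total <= 0) {
    per_channel <- rep(1 / length(per_channel), length(per_channel))
  } else {
    per_channel <- per_channel / total
  }
  ord <- order(per_channel, decreasing = TRUE)
  structure(
    list(channel_names = ch_names[ord], importances = per_channel[ord],
         n_trees = n_trees, seed = as.integer(seed)),
    class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat("<channel_ranking>\n")
  print(round(x$importances, 4))
  invisible(x)
}

#' Project segments onto the top-ranked channels
#'
#' A pure projection: every segment is reduced to the `k` most important
#' channels, in ranking order, with values and metadata unchanged.
#'
#' @param segments list of [gait_segment()] objects.
#' @param ranking a [rank_channels()] result.
#' @param k number of channels to retain (<= number of channels).
#' @return List of reduced [gait_segment()] objects.
#' @export
select_channels <- function(segments, ranking, k) {
  keep <- utils::head(ranking$channel_names, k)
  if (k > length(ranking$channel_names)) {
    stop("k (", k, ") exceeds the number of ranked channels (",
         length(ranking$channel_names), ")", call. = FALSE)
  }
  lapply(segments, function(s) {
    if (!all(keep %in% colnames(s$data))) {
      stop("segment ", s$id, " lacks ranked channels", call. = FALSE)
    }
    s$data <- s$data[, keep, drop = FALSE]
    s
  })
}
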