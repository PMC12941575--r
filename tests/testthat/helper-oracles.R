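# Independent oracles and small fixture builders used across the suite.

# Brute-force AUC: fraction of correctly ordered positive-negative score
# pairs, ties counted one half. O(P * N), independent of the ROC sweep.
pair_auc <- function(labels, scores) {
  pos <- scores[labels == "PD"]
  neg <- scores[labels == "HEALTHY"]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Naive O(N^2) sample entropy: direct template counting with Chebyshev
# distance <= r, both template sets anchored at 1 .. N-m, self-matches
# excluded. Written independently of the compiled implementation.
naive_sampen <- function(x, m = 2, r_factor = 0.2) {
  r <- r_factor * sd(x)
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# Direct sliding least-squares polynomial fit (interior points only):
# the definitional form of Savitzky-Golay smoothing.
sliding_ls_fit <- function(x, window, polyorder) {
  half <- (window - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in (half + 1):(n - half)) {
    idx <- (t - half):(t + half)
    fit <- lm(y ~ poly(s, polyorder, raw = TRUE),
              data = data.frame(y = x[idx], s = idx - t))
    out[t] <- unname(coef(fit)[1])
  }
  out
}

# Small labelled segment fixtures built in code.
make_segment <- function(data, label = "HEALTHY", subject = "S1", index = 1L) {
  colnames(data) <- sprintf("ch%02d", seq_len(ncol(data)))
  gait_segment(data, label, subject, index)
}

# A toy separable classification set: the class is the sign of channel 1's
# mean; remaining channels are pure noise.
toy_separable_segments <- function(n, len = 30, n_ch = 3, shift = 0.8,
                                   seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- if (i %% 2 == 0) "PD" else "HEALTHY"
    mu <- if (lab == "PD") shift else -shift
    d <- matrix(rnorm(len * n_ch), len, n_ch)
    d[, 1] <- d[, 1] + mu
    make_segment(d, lab, sprintf("T%03d", i), 1L)
  })
}

# Small preprocessed cohort cache so several tests can share one simulation.
small_cohort_segments <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulator_config(n_healthy_subjects = 6, n_pd_subjects = 6,
                              duration_s = 60, seed = 301)
      cache <<- preprocess_cohort(simulate_cohort(cfg))
    }
    cache
  }
})
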