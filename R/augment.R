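#' Configure smooth time-warping
#'
#' A warp is built from `n_interior_knots + 2` knots placed uniformly on the
#' segment's time axis. Inter-knot spacings are multiplied by independent
#' Gaussian factors `max(eps, 1 + N(0, sigma))`, cumulated, rescaled so the
#' endpoints are fixed, and interpolated with a monotone cubic scheme. At
#' `sigma = 0` the warp is the identity; larger `sigma` injects stronger
#' local timing perturbations while amplitude structure is untouched.
#'
#' @param sigma standard deviation of the Gaussian knot perturbations
#'   (default 0.2, the intensity used for selective augmentation).
#' @param n_variants synthetic variants generated per targeted segment
#'   (default 5).
#' @param n_interior_knots number of interior knots (>= 1).
#' @param seed master seed for per-variant warp draws.
#' @return An object of class `warp_config`.
#' @export
warp_config <- function(sigma = 0.2, n_variants = 5, n_interior_knots = 4,
                        seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (n_variants < 0) stop("n_variants must be non-negative", call. = FALSE)
  if (n_interior_knots < 1) {
    stop("n_interior_knots must be at least 1", call. = FALSE)
  }
  structure(
    list(sigma = sigma, n_variants = as.integer(n_variants),
         n_interior_knots = as.integer(n_interior_knots),
         seed = as.integer(seed)),
    class = "warp_config")
}

#' Draw a smooth monotone warp of the time axis
#'
#' Constructs an endpoint-preserving, strictly increasing map
#' `w: [0, L-1] -> [0, L-1]` evaluated on the sample grid. The positivity
#' clip at 0.05 keeps every inter-knot spacing positive, which together with
#' monotone (Hyman-filtered) cubic interpolation guarantees strict
#' monotonicity of the map.
#'
#' @param length segment length `L` in samples (>= 4).
#' @param config a [warp_config()].
#' @param draw_seed integer seed for this draw.
#' @return An object of class `warp_function` with fields `source_len`,
#'   `knot_positions`, `knot_images`, and `w` (the map evaluated at
#'   `0:(L-1)`).
#' @examples
#' w <- make_warp(125, warp_config(sigma = 0.2), draw_seed = 1)
#' range(diff(w$w)) # strictly positive
#' @export
make_warp <- function(length, config = warp_config(), draw_seed = 0L) {
  if (length < 4) stop("warp length must be at least 4", call. = FALSE)
  if (config$sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  L <- as.integer(length)
  k <- config$n_interior_knots
  u <- seq(0, L - 1, length.out = k + 2L)
  g <- with_seed(draw_seed, pmax(0.05, 1 + rnorm(k + 1L, 0, config$sigma)))
  v <- c(0, cumsum(g))
  v <- v * (L - 1) / v[k + 2L]
  f <- splinefun(u, v, method = "hyman")
  w <- f(0:(L - 1))
  w <- pmin(pmax(w, 0), L - 1)
  w[1L] <- 0
  w[L] <- L - 1
  structure(
    list(source_len = L, knot_positions = u, knot_images = v, w = w),
    class = "warp_function")
}

#' @export
print.warp_function <- function(x, ...) {
  cat(sprintf("<warp_function> L = %d, %d knots, max |w(t) - t| = %.2f\n",
              x$source_len, length(x$knot_positions),
              max(abs(x$w - (seq_len(x$source_len) - 1)))))
  invisible(x)
}

#' Apply a warp to a segment
#'
#' All channels are resampled along the same warped time base (by linear
#' interpolation of the source at `w(t)`), preserving inter-channel
#' coordination; the output keeps the source length, so warped segments stay
#' pipeline-compatible. The result carries provenance `"SYNTHETIC"` with the
#' source segment as parent.
#'
#' @param segment a [gait_segment()].
#' @param warp a [warp_function()][make_warp] with matching `source_len`.
#' @param id_suffix appended to the parent id to form the variant id.
#' @return A synthetic [gait_segment()].
#' @export
warp_segment <- function(segment, warp, id_suffix = "_w") {
  L <- nrow(segment$data)
  if (L != warp$source_len) {
    stop("segment length (", L, ") does not match warp source_len (",
         warp$source_len, ")", call. = FALSE)
  }
  grid <- 0:(L - 1)
  out <- apply(segment$data, 2, function(x) approx(grid, x, xout = warp$w)$y)
  out <- matrix(out, nrow = L,
                dimnames = list(NULL, colnames(segment$data)))
  gait_segment(out, segment$label, segment$subject_id,
               segment$segment_index, provenance = "SYNTHETIC",
               parent_id = segment$id, id = paste0(segment$id, id_suffix))
}

#' Define a class-selective augmentation policy
#'
#' The four regimes under comparison: no augmentation, augmentation of the
#' healthy class only, of both classes, or of the Parkinsonian class only
#' (the selective strategy, which leaves healthy variability untouched).
#'
#' @param mode one of `"NONE"`, `"HEALTHY_ONLY"`, `"FULL"`, `"PD_ONLY"`.
#' @param warp a [warp_config()].
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(mode = c("PD_ONLY", "NONE", "HEALTHY_ONLY",
                                         "FULL"),
                                warp = warp_config()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, warp = warp), class = "augmentation_policy")
}

policy_targets <- function(mode) {
  switch(mode,
         NONE = character(0),
         HEALTHY_ONLY = "HEALTHY",
         PD_ONLY = "PD",
         FULL = c("HEALTHY", "PD"),
         stop("unknown augmentation mode: ", mode, call. = FALSE))
}

#' Augment a segment set under a class-selective policy
#'
#' Original segments are always retained. For every original segment of a
#' targeted class, `n_variants` time-warped variants are appended, each with
#' a fresh warp whose seed is derived deterministically from
#' `(warp seed, subject id, segment index, variant index)`; the whole
#' operation is a pure function of `(segments, policy)`. Inputs containing
#' synthetic segments are refused so variants are never compounded.
#'
#' @param segments list of ORIGINAL [gait_segment()] objects.
#' @param policy an [augmentation_policy()].
#' @return List of segments: the originals followed by the variants.
#' @export
augment_dataset <- function(segments, policy) {
  if (any(segment_provenance(segments) != "ORIGINAL")) {
    stop("augment_dataset expects ORIGINAL segments only; augmenting ",
         "synthetic segments would compound warps", call. = FALSE)
  }
  targets <- policy_targets(policy$mode)
  wc <- policy$warp
  synth <- list()
  if (wc$n_variants > 0 && length(targets) > 0) {
    for (seg in segments) {
      if (!seg$label %in% targets) next
      for (v in seq_len(wc$n_variants)) {
        ds <- derive_seed(wc$seed, seg$subject_id, seg$segment_index, v)
        w <- make_warp(nrow(seg$data), wc, draw_seed = ds)
        synth[[length(synth) + 1L]] <-
          warp_segment(seg, w, id_suffix = sprintf("_v%d", v))
      }
    }
  }
  c(segments, synth)
}
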