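#' Overlap-detection parameters
#'
#' Bundles every tunable of the detection pipeline into one validated record.
#'
#' @param k seed length in bases. Larger k is more repeat-robust but yields
#'   fewer shared seeds on noisy reads.
#' @param ks small seed length used by the second-stage rescue of large anchor
#'   gaps; must be smaller than `k`.
#' @param s extraction step on the first read of a pair: seeds are taken at
#'   every `s`-th position. `s = 1` keeps all seeds.
#' @param f_min minimum dataset-wide frequency of a solid k-mer. Frequency-1
#'   k-mers are seen in a single read only and cannot witness an overlap.
#' @param theta cumulative-mass quantile in (0, 1] used to derive the upper
#'   solid frequency bound `f_max` from the k-mer frequency histogram.
#' @param alpha stage-1 distance bound in bases: two consecutive chain anchors
#'   must be closer than `alpha` on both reads.
#' @param beta stage-2 distance bound in bases: anchor gaps up to `beta` may be
#'   rescued by a path of shared `ks`-mers through the gap sequences.
#' @param gamma maximum relative difference between the two inter-anchor
#'   distances (and between the two final overlap lengths).
#' @param epsilon minimum accepted overlap length in bases.
#' @param count strand-vote threshold: the winning orientation class must hold
#'   strictly more than `count` anchors.
#' @param min_read_len reads shorter than this are dropped at load time.
#' @return object of class `overlap_params` (a named list).
#' @examples
#' p <- overlap_params()
#' p$alpha
#' @export
overlap_params <- function(k = 15L, ks = 9L, s = 1L, f_min = 2L, theta = 0.9,
                           alpha = 400, beta = 1500, gamma = 0.3,
                           epsilon = 500, count = 5L, min_read_len = 2000L) {
  k <- as.integer(k); ks <- as.integer(ks); s <- as.integer(s)
  f_min <- as.integer(f_min); count <- as.integer(count)
  min_read_len <- as.integer(min_read_len)
  stopifnot(
    "k must be a positive integer" = k >= 1L,
    "ks must satisfy 1 <= ks < k" = ks >= 1L && ks < k,
    "k too large for exact packing" = k <= 26L,
    "s must be a positive integer" = s >= 1L,
    "f_min must be >= 2" = f_min >= 2L,
    "theta must be in (0, 1]" = theta > 0 && theta <= 1,
    "alpha must be positive" = alpha > 0,
    "beta must exceed alpha" = beta > alpha,
    "gamma must be in [0, 1)" = gamma >= 0 && gamma < 1,
    "epsilon must be positive" = epsilon > 0,
    "count must be non-negative" = count >= 0L,
    "min_read_len must be positive" = min_read_len >= 1L
  )
  structure(list(k = k, ks = ks, s = s, f_min = f_min, theta = theta,
                 alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon,
                 count = count, min_read_len = min_read_len),
            class = "overlap_params")
}

#' @export
print.overlap_params <- function(x, ...) {
  cat("overlap detection parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
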