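# Anchor chaining.
#
# A chain is a P1-ordered run of anchors in which every consecutive pair is
# "consistent". Consistency is decided in two stages:
#   stage 1 (fast): correct ordering on both reads (C1 forward / C2 reverse),
#     both start-to-start distances D1, D2 below alpha (C3), and relative
#     distance difference below gamma (C4);
#   stage 2 (rescue): for gaps up to beta, the two inter-anchor gap sequences
#     are searched for shared small ks-mers, and the pair is consistent when
#     a monotone path of C3/C4-linked ks-mers connects the two anchors.
# The candidate overlap is the largest greedy chain over all start anchors.

# Scalar/vectorized stage-1 predicate on 0-based start positions.
# positive: TRUE when the pair's relative strand is "+".
.consistent1 <- function(p1a, p2a, p1b, p2b, positive, alpha, gamma) {
  d1 <- p1b - p1a
  d2 <- if (positive) p2b - p2a else p2a - p2b
  mx <- pmax(d1, d2)
  mn <- pmin(d1, d2)
  # (mx - mn) < gamma * mx avoids 0/0 when both distances are zero
  d1 > 0 & d2 > 0 & d1 < alpha & d2 < alpha & (mx - mn) < gamma * mx
}

# Stage-2 rescue on 0-based positions. R1/R2 are the full read sequences.
.stage2_gap <- function(p1a, p2a, p1b, p2b, positive, R1, R2, params) {
  k <- params$k; ks <- params$ks
  alpha <- params$alpha; beta <- params$beta; gamma <- params$gamma
  d1 <- p1b - p1a
  d2 <- if (positive) p2b - p2a else p2a - p2b
  if (d1 <= 0 || d2 <= 0 || d1 >= beta || d2 >= beta) return(FALSE)
  # gap regions between the end of a's k-mer and the start of b's k-mer,
  # with the R2 gap reverse-complemented into the forward frame for "-" pairs
  if (d1 - k < ks || d2 - k < ks) return(FALSE)   # no room for any ks-mer
  reg1 <- substr(R1, p1a + k + 1L, p1b)
  reg2 <- if (positive) substr(R2, p2a + k + 1L, p2b)
          else revcomp(substr(R2, p2b + k + 1L, p2a))
  kc1 <- kmer_codes(reg1, ks)$fw
  kc2 <- kmer_codes(reg2, ks)$fw
  w1 <- which(!is.na(kc1)); v1 <- kc1[w1]
  w2 <- which(!is.na(kc2)); v2 <- kc2[w2]
  if (!length(v1) || !length(v2)) return(FALSE)
  # only ks-mers unique within both gap regions may anchor the path
  u1 <- !(duplicated(v1) | duplicated(v1, fromLast = TRUE))
  u2 <- !(duplicated(v2) | duplicated(v2, fromLast = TRUE))
  mi <- match(v1[u1], v2[u2])
  hit <- !is.na(mi)
  if (!any(hit)) return(FALSE)
  u <- w1[u1][hit] - 1L          # 0-based offsets within the gap regions
  v <- w2[u2][mi[hit]] - 1L
  o <- order(u, v)
  u <- u[o]; v <- v[o]
  m <- length(u)
  # virtual start node sits k before each gap region (the anchor's own start)
  reach <- .consistent1(-k, -k, u, v, TRUE, alpha, gamma)
  if (m > 1L) {
    for (j in 2:m) {
      if (!reach[j]) {
        i <- seq_len(j - 1L)
        reach[j] <- any(reach[i] &
                        .consistent1(u[i], v[i], u[j], v[j], TRUE, alpha, gamma))
      }
    }
  }
  any(reach & .consistent1(u, v, d1 - k, d2 - k, TRUE, alpha, gamma))
}

#' Stage-1 anchor consistency (conditions C1--C4)
#'
#' Two anchors `a`, `b` (with `a$P1 < b$P1`) are stage-1 consistent when the
#' second-read positions advance in the direction dictated by the strand
#' (C1/C2, strict), both start-to-start distances `D1 = |P1b - P1a|`,
#' `D2 = |P2b - P2a|` are below `alpha` (C3), and
#' `(max(D1,D2) - min(D1,D2)) / max(D1,D2) < gamma` (C4).
#'
#' @param a,b anchors: lists/rows with 0-based positions `P1`, `P2`.
#' @param strand `"+"` (positive) or `"-"` (opposite).
#' @param alpha stage-1 distance bound.
#' @param gamma relative distance-difference bound.
#' @return logical.
#' @export
consistent_stage1 <- function(a, b, strand, alpha = 400, gamma = 0.3) {
  .consistent1(a$P1, a$P2, b$P1, b$P2, strand == "+", alpha, gamma)
}

#' Stage-2 anchor consistency (small-seed rescue)
#'
#' Used when stage 1 fails: provided both distances are below `beta` and the
#' ordering condition holds, the gap sequences between the two anchors are
#' extracted from both reads (the second-read gap reverse-complemented for
#' `"-"` pairs), shared `ks`-mers unique within both gaps are collected, and
#' the anchors are consistent when a monotone path of C3/C4-linked `ks`-mers
#' leads from anchor `a` to anchor `b`.
#'
#' @inheritParams consistent_stage1
#' @param R1,R2 full sequences of the two reads.
#' @param params [overlap_params()].
#' @return logical.
#' @export
consistent_stage2 <- function(a, b, R1, R2, strand, params = overlap_params()) {
  .stage2_gap(a$P1, a$P2, b$P1, b$P2, strand == "+", R1, R2, params)
}

#' Two-stage anchor consistency
#'
#' Stage 1, and on failure stage 2.
#'
#' @inheritParams consistent_stage2
#' @return logical.
#' @export
determine_consistent <- function(a, b, R1, R2, strand, params = overlap_params()) {
  consistent_stage1(a, b, strand, params$alpha, params$gamma) ||
    consistent_stage2(a, b, R1, R2, strand, params)
}

# Greedy chain as integer anchor indices, starting at `start`.
.chain_indices <- function(A, positive, R1, R2, params, start) {
  P1 <- A$P1; P2 <- A$P2
  n <- length(P1)
  sel <- integer(n)
  sel[1L] <- start
  ns <- 1L
  cur <- start
  alpha <- params$alpha; gamma <- params$gamma
  j <- start + 1L
  while (j <= n) {
    ok <- .consistent1(P1[cur], P2[cur], P1[j], P2[j], positive, alpha, gamma)
    if (!ok)
      ok <- .stage2_gap(P1[cur], P2[cur], P1[j], P2[j], positive, R1, R2, params)
    if (ok) {
      ns <- ns + 1L
      sel[ns] <- j
      cur <- j
    }
    j <- j + 1L
  }
  sel[seq_len(ns)]
}

.make_chain <- function(A, idx, strand) {
  structure(list(anchors = A[idx], strand = strand, support = length(idx)),
            class = "anchor_chain")
}

#' Greedy chain from a fixed start anchor
#'
#' Starting from `anchors[start]`, scans the remaining anchors in P1 order and
#' appends the first one consistent (two-stage test) with the current chain
#' tail, repeating until all anchors are visited.
#'
#' @param cks a [classify_strand()] result (`common_kmer_set`).
#' @param start 1-based index of the starting anchor.
#' @param R1,R2 full read sequences (needed by stage 2).
#' @param params [overlap_params()].
#' @return object of class `anchor_chain`: list with `anchors` (data.table),
#'   `strand`, `support` (number of anchors).
#' @export
chain_from_start <- function(cks, start, R1, R2, params = overlap_params()) {
  stopifnot(inherits(cks, "common_kmer_set"),
            start >= 1L, start <= nrow(cks$anchors))
  idx <- .chain_indices(cks$anchors, cks$strand == "+", R1, R2, params, start)
  .make_chain(cks$anchors, idx, cks$strand)
}

#' Best greedy chain over all start anchors
#'
#' Runs [chain_from_start()] from every anchor (in P1 order) and keeps the
#' chain with the most anchors, first found winning ties. A start already
#' absorbed into an earlier chain is skipped: the greedy extension is
#' memoryless in the chain tail, so its chain is a strict suffix of the
#' earlier one and cannot win.
#'
#' @inheritParams chain_from_start
#' @return the best `anchor_chain`, or `NULL` when the best chain has fewer
#'   than 3 anchors (no candidate overlap).
#' @export
find_candidate_chain <- function(cks, R1, R2, params = overlap_params()) {
  if (is.null(cks) || !nrow(cks$anchors)) return(NULL)
  A <- cks$anchors
  n <- nrow(A)
  positive <- cks$strand == "+"
  best <- integer(0)
  seen <- logical(n)
  for (st in seq_len(n)) {
    if (seen[st]) next
    idx <- .chain_indices(A, positive, R1, R2, params, st)
    seen[idx] <- TRUE
    if (length(idx) > length(best)) best <- idx
  }
  if (length(best) <= 2L) return(NULL)
  .make_chain(A, best, cks$strand)
}

#' @export
print.anchor_chain <- function(x, ...) {
  cat(sprintf("anchor chain: strand %s, %d anchors, R1 span [%d, %d]\n",
              x$strand, x$support, x$anchors$P1[1L],
              x$anchors$P1[x$support]))
  invisible(x)
}
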