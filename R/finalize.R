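# Overlap revision and acceptance.
#
# The chain spans draft overlaps [P1, Pn + k] and [Q1, Qn + k] on the two
# reads (1-based starts of the first/last chain anchors; Q is taken in the
# frame where it increases with P, i.e. on the reverse complement of R2 for
# "-" pairs). Revision extends the draft to the read boundaries according to
# which read ends first on each side (dovetail vs containment geometry), and
# the revised overlap is accepted when the chain covers almost all of it, it
# is long enough, and the two per-read lengths are balanced.

# Vectorized revision of 1-based chain endpoints; returns a data.table.
.revise_coords <- function(P1, Pn, Q1, Qn, Len1, Len2) {
  right_le <- (Len1 - Pn) <= (Len2 - Qn)
  left_gt <- P1 > Q1
  SP1 <- ifelse(left_gt, P1 - Q1, 1)
  SP2 <- ifelse(left_gt, 1, pmax(1, Q1 - P1))
  EP1 <- ifelse(right_le, Len1, Pn + (Len2 - Qn))
  EP2 <- ifelse(right_le, Qn + (Len1 - Pn), Len2)
  data.table::data.table(SP1 = SP1, EP1 = EP1, SP2 = SP2, EP2 = EP2)
}

# 1-based chain endpoints in the frame where Q increases with P.
# For "-" chains the R2 coordinate q (0-based) maps to Len2 - q - k.
.chain_endpoints <- function(chain, Len2, k) {
  A <- chain$anchors
  n <- nrow(A)
  p1 <- A$P1[1L] + 1L
  pn <- A$P1[n] + 1L
  if (chain$strand == "+") {
    q1 <- A$P2[1L] + 1L
    qn <- A$P2[n] + 1L
  } else {
    q1 <- Len2 - A$P2[1L] - k + 1L
    qn <- Len2 - A$P2[n] - k + 1L
  }
  list(P1 = p1, Pn = pn, Q1 = q1, Qn = qn)
}

#' Revise a chain's draft overlap to boundary-extended coordinates
#'
#' Extends the candidate overlap implied by the chain's first/last anchors to
#' the read ends, covering the four dovetail/containment cases: on the left,
#' whichever read has the earlier anchor start is entered at position 1 and
#' the other at the anchor-start difference; on the right, whichever read has
#' less sequence after its last anchor is exited at its end and the remainder
#' is projected onto the other read.
#'
#' @param chain an [find_candidate_chain()] result (`anchor_chain`). For `"-"`
#'   chains the R2 coordinates are internally mapped into the
#'   reverse-complement frame, in which the returned `SP2`/`EP2` are expressed.
#' @param Len1,Len2 read lengths.
#' @param k seed length used to build the chain.
#' @return list with 1-based inclusive `SP1`, `EP1`, `SP2`, `EP2` and the
#'   chain endpoints `P1`, `Pn`, `Q1`, `Qn` used.
#' @export
revise_overlap <- function(chain, Len1, Len2, k = 15L) {
  e <- .chain_endpoints(chain, Len2, k)
  rv <- .revise_coords(e$P1, e$Pn, e$Q1, e$Qn, Len1, Len2)
  c(list(SP1 = rv$SP1, EP1 = rv$EP1, SP2 = rv$SP2, EP2 = rv$EP2), e)
}

#' Accept or reject a revised overlap
#'
#' Three conditions, all required: the chain must span the revised overlap to
#' within `alpha` on both reads (`(EP - SP) - (last + k - first) < alpha`);
#' the shorter overlap length must exceed `epsilon`; and the two per-read
#' overlap lengths must be balanced
#' (`(MaxOverlapLen - MinOverlapLen) / MaxOverlapLen < gamma`).
#'
#' @param ov a [revise_overlap()] result.
#' @param chain the `anchor_chain` the overlap was revised from.
#' @param params [overlap_params()].
#' @return logical: accept the overlap?
#' @export
evaluate_overlap <- function(ov, chain, params = overlap_params()) {
  k <- params$k
  l1 <- ov$EP1 - ov$SP1
  l2 <- ov$EP2 - ov$SP2
  mn <- min(l1, l2)
  mx <- max(l1, l2)
  (l1 - (ov$Pn + k - ov$P1) < params$alpha) &&
    (l2 - (ov$Qn + k - ov$Q1) < params$alpha) &&
    mn > params$epsilon &&
    (mx - mn) < params$gamma * mx
}

# Full finalization of one pair: revise, evaluate, and map "-" coordinates
# back to the original R2 strand. Returns a one-row data.table or NULL.
.finalize_pair <- function(chain, id1, id2, Len1, Len2, params) {
  ov <- revise_overlap(chain, Len1, Len2, params$k)
  if (!evaluate_overlap(ov, chain, params)) return(NULL)
  if (chain$strand == "+") {
    sp2 <- ov$SP2; ep2 <- ov$EP2
  } else {
    sp2 <- Len2 - ov$EP2 + 1L
    ep2 <- Len2 - ov$SP2 + 1L
  }
  data.table::data.table(
    id1 = id1, id2 = id2, strand = chain$strand,
    sp1 = as.integer(ov$SP1), ep1 = as.integer(ov$EP1),
    sp2 = as.integer(sp2), ep2 = as.integer(ep2),
    len1 = as.integer(Len1), len2 = as.integer(Len2),
    support = chain$support)
}
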