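# Common k-mers between a read pair.
#
# An anchor is a solid k-mer shared by the two reads, recorded as a
# four-tuple (P1, O1, P2, O2): 0-based start positions and orientations in
# each read. Anchors whose orientations agree are "positive", the rest
# "opposite"; a majority vote over the two classes fixes the pair's relative
# strand before chaining.

#' Find the raw common-k-mer anchors of a read pair
#'
#' Samples solid k-mers from the first read at every `s`-th start position and
#' matches them, via the index, against all their occurrences in the second
#' read. Each (position-in-R1, position-in-R2) combination yields one anchor.
#'
#' @param r1,r2 the two reads: read ids (as in `index$read_ids`) or integer
#'   read indices.
#' @param index a [build_solid_index()] result.
#' @param s extraction step on the first read (default 1 keeps all positions).
#' @return data.table of anchors with columns `code`, `P1`, `O1`, `P2`, `O2`,
#'   `positive` (`O1 == O2`), sorted by `P1` then `P2`. May be empty.
#' @export
find_common_kmers <- function(r1, r2, index, s = 1L) {
  i1 <- .read_index(r1, index)
  i2 <- .read_index(r2, index)
  p <- index$postings
  a1 <- p[read == i1]
  a2 <- p[read == i2]
  .pair_anchors(a1, a2, s)
}

.read_index <- function(r, index) {
  if (is.numeric(r)) return(as.integer(r))
  i <- match(r, index$read_ids)
  if (is.na(i)) stop("unknown read id: ", r, call. = FALSE)
  i
}

# a1/a2: postings (code, pos, orient) of the two reads
.pair_anchors <- function(a1, a2, s = 1L) {
  if (s > 1L) a1 <- a1[pos %% s == 0L]
  m <- merge(a1[, .(code, P1 = pos, O1 = orient)],
             a2[, .(code, P2 = pos, O2 = orient)],
             by = "code", allow.cartesian = TRUE)
  m[, positive := O1 == O2]
  data.table::setorder(m, P1, P2)
  m[]
}

#' Drop anchors of repeat-ambiguous k-mers
#'
#' A k-mer value matching at more than one position in either read produces
#' contradictory anchors (a within-pair repeat); all anchors of such a k-mer
#' are removed.
#'
#' @param anchors anchor table from [find_common_kmers()].
#' @return the filtered anchor table (k-mer values with a single anchor).
#' @export
remove_nonunique <- function(anchors) {
  if (!nrow(anchors)) return(anchors)
  anchors[, if (.N == 1L) .SD, by = code][]
}

#' Classify pair strand by anchor majority vote
#'
#' With `M` positive and `N` opposite anchors: keep the positive class when
#' `M > N` and `M > count`; keep the opposite class when `N > M` and
#' `N > count`; otherwise the pair has no credible overlap.
#'
#' @param anchors deduplicated anchor table ([remove_nonunique()]).
#' @param count strand-vote threshold (strict).
#' @return object of class `common_kmer_set` -- list with `anchors` (the
#'   winning class, sorted by `P1` then `P2`), `strand` (`"+"` or `"-"`),
#'   `M`, `N` -- or `NULL` when neither class wins (no overlap).
#' @export
classify_strand <- function(anchors, count = 5L) {
  M <- sum(anchors$positive)
  N <- nrow(anchors) - M
  if (M > N && M > count) {
    keep <- anchors[positive == TRUE]
    strand <- "+"
  } else if (N > M && N > count) {
    keep <- anchors[positive == FALSE]
    strand <- "-"
  } else {
    return(NULL)
  }
  data.table::setorder(keep, P1, P2)
  structure(list(anchors = keep, strand = strand, M = M, N = N),
            class = "common_kmer_set")
}

#' @export
print.common_kmer_set <- function(x, ...) {
  cat(sprintf("common k-mer set: strand %s, %d anchors (M=%d, N=%d)\n",
              x$strand, nrow(x$anchors), x$M, x$N))
  invisible(x)
}
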