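# Dataset-wide k-mer spectrum and the solid k-mer index.
#
# A k-mer is "solid" when its dataset frequency lies in [f_min, f_max]:
# frequent enough not to be a sequencing error, rare enough not to be
# repeat-derived. f_min is fixed (2 by default); f_max is derived from the
# frequency histogram F(x) so that the cumulative mass
#   S(y) = sum_{x = f_min..y} F(x)
# first exceeds theta * S(h), h being the largest observed frequency.

.seqs_of <- function(reads) {
  if (is.data.frame(reads)) as.character(reads$seq) else as.character(reads)
}

#' Count k-mers across a read set
#'
#' Counts every length-`k` window of every read. Counting is canonical by
#' default (forward and reverse-complement forms collapse to the smaller
#' packed code), which is what lets reads sequenced from opposite strands
#' share seeds. Windows containing a non-ACGT base are skipped.
#'
#' @param reads character vector of sequences, or a read set as returned by
#'   [load_reads()] / [read_set()].
#' @param k k-mer length.
#' @param canonical collapse each k-mer with its reverse complement
#'   (default `TRUE`). `canonical = FALSE` counts literal k-mers.
#' @return object of class `kmer_spectrum`: list with `freq` (a
#'   [data.table::data.table] of `code`, `kmer` frequency `count`), `k`,
#'   `canonical`, `n_occ` (total occurrences counted) and `n_skipped`
#'   (windows skipped for N). Histogram fields `F`, `h`, `f_max` are filled
#'   by [build_histogram()] and [derive_fmax()].
#' @export
count_kmers <- function(reads, k, canonical = TRUE) {
  seqs <- .seqs_of(reads)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 26L)
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad))
    .parse_error(paste0("read ", bad[1L],
                        " contains characters other than A/C/G/T/N"))
  codes <- vector("list", length(seqs))
  n_skipped <- 0L
  for (i in seq_along(seqs)) {
    kc <- kmer_codes(seqs[[i]], k)
    v <- if (canonical) kc$canon else kc$fw
    bad <- is.na(v)
    n_skipped <- n_skipped + sum(bad)
    codes[[i]] <- v[!bad]
  }
  all_codes <- unlist(codes, use.names = FALSE)
  freq <- if (length(all_codes)) {
    data.table::data.table(code = all_codes)[, .(count = .N), by = code]
  } else {
    data.table::data.table(code = numeric(0), count = integer(0))
  }
  data.table::setkey(freq, code)
  structure(list(freq = freq, k = k, canonical = canonical,
                 n_occ = length(all_codes), n_skipped = n_skipped,
                 F = NULL, h = NULL, f_max = NULL),
            class = "kmer_spectrum")
}

#' Build a k-mer spectrum directly from frequencies
#'
#' Convenience constructor for a spectrum from an explicit k-mer multiset or
#' frequency table (used for worked examples and tests).
#'
#' @param kmers character vector: a k-mer multiset (duplicates are counts).
#' @param canonical whether the multiset is to be read canonically.
#' @return `kmer_spectrum` object.
#' @export
kmer_spectrum <- function(kmers, canonical = FALSE) {
  k <- unique(nchar(kmers))
  stopifnot("all k-mers must share one length" = length(k) == 1L)
  count_kmers(kmers, k, canonical = canonical)
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("k-mer spectrum: k=%d, %d distinct / %d occurrences (%s)\n",
              x$k, nrow(x$freq), x$n_occ,
              if (x$canonical) "canonical" else "literal"))
  if (!is.null(x$f_max)) cat(sprintf("  solid interval: [f_min, %d]\n", x$f_max))
  invisible(x)
}

#' Frequency histogram of a k-mer spectrum
#'
#' Fills `F` and `h`: `F[x]` is the number of distinct k-mers whose frequency
#' is exactly `x`, for `x = 1..h`, `h` the maximum observed frequency.
#'
#' @param spectrum a `kmer_spectrum`.
#' @return the spectrum with `F` (integer vector indexed by frequency) and
#'   `h` filled; empty spectra get `F = integer(0)`, `h = 0`.
#' @export
build_histogram <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  cnt <- spectrum$freq$count
  if (!length(cnt)) {
    spectrum$F <- integer(0)
    spectrum$h <- 0L
    return(spectrum)
  }
  spectrum$h <- max(cnt)
  spectrum$F <- tabulate(cnt, nbins = spectrum$h)
  spectrum
}

#' Derive the upper solid-frequency bound f_max
#'
#' Scans the cumulative sum `S(y) = sum_{x=f_min..y} F(x)` and returns the
#' smallest `f` with `S(f) > theta * S(h)`.
#'
#' @param F frequency histogram: `F[x]` = number of distinct k-mers of
#'   frequency `x` (a `kmer_spectrum` may be passed instead).
#' @param f_min lower solid bound.
#' @param theta cumulative-mass quantile in (0, 1].
#' @return `f_max`, with `f_min <= f_max <= h`.
#' @export
derive_fmax <- function(F, f_min = 2L, theta = 0.9) {
  if (inherits(F, "kmer_spectrum")) {
    if (is.null(F$F)) F <- build_histogram(F)
    F <- F$F
  }
  f_min <- as.integer(f_min)
  h <- length(F)
  if (h < f_min || sum(F[f_min:h]) == 0)
    stop("degenerate spectrum: no k-mer with frequency >= f_min (",
         f_min, ")", call. = FALSE)
  cum <- cumsum(F[f_min:h])
  total <- cum[length(cum)]
  f_min + which(cum > theta * total)[1L] - 1L
}

#' Build the positional solid k-mer index
#'
#' Indexes every occurrence of a solid k-mer (dataset frequency in
#' `[f_min, f_max]`) as a posting `(read, 0-based start, orientation)`,
#' orientation `TRUE` when the literal k-mer equals its canonical form.
#'
#' @param reads read set ([load_reads()] / [read_set()]) or character vector.
#' @param spectrum `kmer_spectrum` with `f_max` already set (see
#'   [derive_fmax()]), or pass `f_max` explicitly.
#' @param params [overlap_params()].
#' @param f_max override for the upper solid bound.
#' @return object of class `solid_kmer_index`: list with `postings`
#'   (data.table `code`, `read` (integer index), `pos` (0-based), `orient`),
#'   `read_ids`, `read_len`, `k`, `f_min`, `f_max`.
#' @export
build_solid_index <- function(reads, spectrum, params = overlap_params(),
                              f_max = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (is.null(f_max)) f_max <- spectrum$f_max
  if (is.null(f_max)) f_max <- derive_fmax(spectrum, params$f_min, params$theta)
  seqs <- .seqs_of(reads)
  ids <- if (is.data.frame(reads)) as.character(reads$id) else
    if (!is.null(names(reads))) names(reads) else as.character(seq_along(seqs))
  k <- spectrum$k
  solid <- spectrum$freq[count >= params$f_min & count <= f_max, .(code)]
  data.table::setkey(solid, code)
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    kc <- kmer_codes(seqs[[i]], k)
    if (!kc$n) next
    keep <- !is.na(kc$canon) & !is.na(solid[data.table::data.table(code = kc$canon),
                                           on = "code", which = TRUE])
    if (!any(keep)) next
    w <- which(keep)
    parts[[i]] <- data.table::data.table(
      code = kc$canon[w], read = i, pos = w - 1L, orient = kc$fwd_is_canon[w])
  }
  postings <- data.table::rbindlist(parts)
  if (!nrow(postings))
    postings <- data.table::data.table(code = numeric(0), read = integer(0),
                                       pos = integer(0), orient = logical(0))
  data.table::setkey(postings, code, read, pos)
  structure(list(postings = postings, read_ids = ids,
                 read_len = nchar(seqs), k = k,
                 f_min = params$f_min, f_max = f_max),
            class = "solid_kmer_index")
}

#' @export
print.solid_kmer_index <- function(x, ...) {
  cat(sprintf("solid k-mer index: k=%d, solid interval [%d, %d], %d postings, %d reads\n",
              x$k, x$f_min, x$f_max, nrow(x$postings), length(x$read_ids)))
  invisible(x)
}

#' Dump the frequency histogram as TSV
#'
#' Two columns: frequency and F(frequency), for spectrum inspection.
#'
#' @param spectrum `kmer_spectrum` (histogram is built if absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  if (is.null(spectrum$F)) spectrum <- build_histogram(spectrum)
  data.table::fwrite(
    data.table::data.table(frequency = seq_along(spectrum$F), F = spectrum$F),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}
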