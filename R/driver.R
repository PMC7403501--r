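# End-to-end orchestration: read input, build the solid index, enumerate
# candidate pairs, run per-pair detection, write PAF.

.parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("koverlap_parse_error", "error")))
}

#' Construct a read set from sequences
#'
#' @param seqs named character vector of sequences (names are read ids), or a
#'   data.frame with `id` and `seq` columns.
#' @return data.table with columns `id`, `seq`, `length`.
#' @export
read_set <- function(seqs) {
  if (is.data.frame(seqs)) {
    dt <- data.table::data.table(id = as.character(seqs$id),
                                 seq = toupper(as.character(seqs$seq)))
  } else {
    ids <- names(seqs)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    dt <- data.table::data.table(id = ids, seq = toupper(unname(seqs)))
  }
  if (anyDuplicated(dt$id))
    .parse_error(paste0("duplicate read id: ", dt$id[duplicated(dt$id)][1L]))
  if (any(grepl("[^ACGTN]", dt$seq)))
    .parse_error("sequences contain characters other than A/C/G/T/N")
  dt[, length := nchar(seq)]
  dt[]
}

#' Load long reads from FASTA/FASTQ
#'
#' Accepts plain or gzipped FASTA/FASTQ (format sniffed from the first record
#' character). Sequences are uppercased; ids are the first whitespace-separated
#' header token; reads shorter than `min_read_len` are dropped.
#'
#' @param path input file.
#' @param min_read_len length cutoff in bases (default 2000).
#' @param quiet suppress the kept/dropped message.
#' @return data.table with columns `id`, `seq`, `length`.
#' @export
load_reads <- function(path, min_read_len = 2000L, quiet = FALSE) {
  if (!file.exists(path)) .parse_error(paste0("no such file: ", path))
  con <- gzfile(path, "rt")
  first_line <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                         error = function(e) character(0))
  close(con)
  first <- substr(first_line, 1L, 1L)
  if (!length(first) || !nzchar(first)) {
    if (!quiet) warning("empty input file: ", path, call. = FALSE)
    return(data.table::data.table(id = character(0), seq = character(0),
                                  length = integer(0)))
  }
  fmt <- if (first == "@") "fastq" else if (first == ">") "fasta" else
    .parse_error(paste0(path, ": not FASTA/FASTQ (first character '",
                        first, "')"))
  xs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e)
      .parse_error(paste0(path, ": malformed ", fmt, ": ",
                          conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids))
    .parse_error(paste0(path, ": duplicate read id: ",
                        ids[duplicated(ids)][1L]))
  dt <- data.table::data.table(id = ids, seq = toupper(as.character(xs)))
  dt[, length := nchar(seq)]
  n0 <- nrow(dt)
  dt <- dt[length >= min_read_len]
  if (!quiet)
    message(sprintf("loaded %d reads from %s (%d kept, %d below %d bp)",
                    n0, path, nrow(dt), n0 - nrow(dt), min_read_len))
  dt[]
}

#' Write a read set as FASTA
#'
#' @param reads read set (data.table with `id`, `seq`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  xs <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Enumerate candidate read pairs
#'
#' Yields every unordered pair of distinct reads sharing at least one solid
#' k-mer, exactly once, as integer read indices `i < j` (input order).
#'
#' @param index a [build_solid_index()] result.
#' @return data.table with columns `i`, `j`.
#' @export
enumerate_pairs <- function(index) {
  u <- unique(index$postings[, .(code, read)])
  pr <- merge(u, u, by = "code", allow.cartesian = TRUE,
              suffixes = c("", ".j"))[read < read.j, .(i = read, j = read.j)]
  unique(pr)[order(i, j)]
}

#' Detect all overlaps in a read set
#'
#' The full pipeline: count k-mers, derive the solid interval, index solid
#' k-mers, enumerate candidate pairs, and for each pair find common k-mers,
#' vote the strand, chain, and revise/accept the overlap. Deterministic given
#' the input order and parameters.
#'
#' @param reads read set ([load_reads()] / [read_set()]).
#' @param params [overlap_params()].
#' @param quiet suppress progress messages.
#' @return data.table of accepted overlaps, one row per pair: `id1`, `id2`,
#'   `strand` (`"+"`/`"-"`), 1-based inclusive `sp1`, `ep1`, `sp2`, `ep2`
#'   (second-read coordinates on its original strand), `len1`, `len2`,
#'   `support` (chain anchors). Sorted by `id1`, `id2`; attribute `"k"`
#'   carries the seed length for [write_paf()].
#' @export
detect_all <- function(reads, params = overlap_params(), quiet = FALSE) {
  empty <- data.table::data.table(
    id1 = character(0), id2 = character(0), strand = character(0),
    sp1 = integer(0), ep1 = integer(0), sp2 = integer(0), ep2 = integer(0),
    len1 = integer(0), len2 = integer(0), support = integer(0))
  data.table::setattr(empty, "k", params$k)
  if (nrow(reads) < 2L) return(empty)

  spec <- count_kmers(reads, params$k)
  spec <- build_histogram(spec)
  spec$f_max <- tryCatch(
    derive_fmax(spec$F, params$f_min, params$theta),
    error = function(e) {
      if (!quiet) message("no solid k-mers (", conditionMessage(e),
                          "); no overlaps reported")
      NULL
    })
  if (is.null(spec$f_max)) return(empty)
  index <- build_solid_index(reads, spec, params)
  pairs <- enumerate_pairs(index)
  if (!quiet)
    message(sprintf("solid interval [%d, %d]; %d postings; %d candidate pairs",
                    index$f_min, index$f_max, nrow(index$postings),
                    nrow(pairs)))
  if (!nrow(pairs)) return(empty)

  by_read <- split(index$postings, by = "read", keep.by = FALSE)
  out <- vector("list", nrow(pairs))
  n_out <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    a1 <- by_read[[as.character(i)]]
    a2 <- by_read[[as.character(j)]]
    anchors <- .pair_anchors(a1, a2, params$s)
    anchors <- remove_nonunique(anchors)
    cks <- classify_strand(anchors, params$count)
    if (is.null(cks)) next
    R1 <- reads$seq[i]; R2 <- reads$seq[j]
    chain <- find_candidate_chain(cks, R1, R2, params)
    if (is.null(chain)) next
    row <- .finalize_pair(chain, reads$id[i], reads$id[j],
                          reads$length[i], reads$length[j], params)
    if (!is.null(row)) {
      n_out <- n_out + 1L
      out[[n_out]] <- row
    }
  }
  res <- if (n_out) data.table::rbindlist(out[seq_len(n_out)]) else empty
  data.table::setorder(res, id1, id2)
  data.table::setattr(res, "k", params$k)
  if (!quiet) message(sprintf("%d overlaps accepted", nrow(res)))
  res[]
}

#' Write overlaps as PAF
#'
#' Standard 12-column PAF: query name/length/start/end, strand, target
#' name/length/start/end, residue matches (chain support x k, a proxy),
#' alignment block length, mapping quality (255). Coordinates are 0-based
#' half-open on the original strands. Rows are sorted by query then target id.
#'
#' @param overlaps a [detect_all()] result.
#' @param path output file.
#' @param k seed length for the residue-match proxy (taken from the
#'   `"k"` attribute of `overlaps` when present).
#' @return `path`, invisibly.
#' @export
write_paf <- function(overlaps, path, k = NULL) {
  if (is.null(k)) k <- attr(overlaps, "k")
  if (is.null(k)) k <- 15L
  if (!nrow(overlaps)) {
    ok <- file.create(path)
    if (!ok) stop("cannot write PAF to ", path, call. = FALSE)
    return(invisible(path))
  }
  paf <- overlaps[order(id1, id2), .(
    qname = id1, qlen = len1, qstart = sp1 - 1L, qend = ep1,
    strand = strand,
    tname = id2, tlen = len2, tstart = sp2 - 1L, tend = ep2,
    nmatch = support * k,
    blocklen = pmax(ep1 - sp1 + 1L, ep2 - sp2 + 1L),
    mapq = 255L)]
  tryCatch(
    data.table::fwrite(paf, path, sep = "\t", col.names = FALSE),
    error = function(e) stop("cannot write PAF to ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a PAF file back into the overlap-table layout
#'
#' @param path PAF file.
#' @return data.table with the same columns as [detect_all()] (1-based
#'   inclusive coordinates); `support` is reconstructed from the
#'   residue-match proxy only if `k` is given.
#' @param k seed length used when the file was written (optional).
#' @export
read_paf <- function(path, k = NULL) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "blocklen", "mapq")
  if (file.size(path) == 0)
    return(data.table::data.table(
      id1 = character(0), id2 = character(0), strand = character(0),
      sp1 = integer(0), ep1 = integer(0), sp2 = integer(0), ep2 = integer(0),
      len1 = integer(0), len2 = integer(0), support = integer(0)))
  paf <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = cols,
                           colClasses = list(character = c(1L, 5L, 6L)))
  out <- paf[, .(id1 = qname, id2 = tname, strand = strand,
                 sp1 = qstart + 1L, ep1 = qend,
                 sp2 = tstart + 1L, ep2 = tend,
                 len1 = qlen, len2 = tlen,
                 support = if (!is.null(k)) as.integer(nmatch / k) else
                   NA_integer_)]
  out[]
}

#' End-to-end detection: file in, PAF out
#'
#' @param input FASTA/FASTQ path.
#' @param output PAF path.
#' @param params [overlap_params()].
#' @param quiet suppress messages.
#' @return the overlap table, invisibly.
#' @export
detect_overlaps <- function(input, output, params = overlap_params(),
                            quiet = FALSE) {
  reads <- load_reads(input, params$min_read_len, quiet = quiet)
  ov <- detect_all(reads, params, quiet = quiet)
  write_paf(ov, output)
  invisible(ov)
}
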