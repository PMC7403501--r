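# Synthetic long-read datasets with ground-truth overlaps, and the
# precision/recall/F1 scoring protocol.
#
# The generator emulates third-generation sequencing reads: a random genome,
# reads sampled uniformly at recorded positions/strands, and independent
# per-base substitution/insertion/deletion errors at a configurable total
# rate. The ground truth lists every read pair whose genome intervals
# intersect, with the shared interval projected into each read's error-free
# coordinate frame.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' @param genome_length genome size in bases.
#' @param n_reads number of reads; when `NULL`, chosen to hit `coverage`.
#' @param coverage target sequencing depth (used only when `n_reads = NULL`).
#' @param read_len_mean,read_len_sd normal read-length model in bases;
#'   lengths are clamped to `[min_sim_len, genome_length]`.
#' @param min_sim_len shortest simulated read; kept above the detection
#'   pipeline's default length cutoff so simulated sets survive loading.
#' @param error_rate total per-base error probability (SMRT-like 0.15 by
#'   default).
#' @param error_mix proportions of substitution/insertion/deletion summing to
#'   1; scaled by `error_rate` into per-base event probabilities. The
#'   insertion-heavy default mirrors SMRT error profiles.
#' @param revcomp_prob probability a read is sampled from the reverse strand.
#' @param min_truth_overlap genome-interval intersections must exceed this to
#'   enter the truth table (0 records every positive overlap; scoring applies
#'   its own length floor to the recall denominator).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, n_reads = NULL, coverage = 10,
                       read_len_mean = 7000, read_len_sd = 1500,
                       min_sim_len = 2500L,
                       error_rate = 0.15,
                       error_mix = c(sub = 0.2, ins = 0.5, del = 0.3),
                       revcomp_prob = 0.5, min_truth_overlap = 0L,
                       seed = 1L) {
  genome_length <- as.integer(genome_length)
  if (is.null(n_reads))
    n_reads <- max(1L, as.integer(round(coverage * genome_length /
                                          read_len_mean)))
  stopifnot(genome_length > 0L, n_reads > 0L,
            read_len_mean > 0, read_len_sd >= 0,
            error_rate >= 0 && error_rate < 1,
            length(error_mix) == 3L, all(error_mix >= 0),
            revcomp_prob >= 0 && revcomp_prob <= 1)
  mix <- error_mix / sum(error_mix)
  structure(list(genome_length = genome_length, n_reads = as.integer(n_reads),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 min_sim_len = as.integer(min_sim_len),
                 error_rate = error_rate,
                 p_sub = error_rate * mix[[1L]],
                 p_ins = error_rate * mix[[2L]],
                 p_del = error_rate * mix[[3L]],
                 revcomp_prob = revcomp_prob,
                 min_truth_overlap = as.integer(min_truth_overlap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Apply per-base errors; at most one event per template base, one inserted
# base after an insertion site. Returns the errored sequence; op counts are
# attached as an attribute for error-rate sanity checks.
.mutate_seq <- function(seq, p_sub, p_ins, p_del) {
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  u <- stats::runif(L)
  del <- u < p_del
  sub <- !del & u < p_del + p_sub
  ins <- u >= p_del + p_sub & u < p_del + p_sub + p_ins
  if (any(sub)) {
    codes <- .base_lut[utf8ToInt(seq)][sub]
    ch[sub] <- .BASES[((codes + sample.int(3L, sum(sub), replace = TRUE)) %% 4) + 1L]
  }
  ch[del] <- ""
  insv <- character(L)
  if (any(ins)) insv[ins] <- sample(.BASES, sum(ins), replace = TRUE)
  out <- paste0(paste0(ch, insv), collapse = "")
  attr(out, "ops") <- c(sub = sum(sub), ins = sum(ins), del = sum(del))
  out
}

#' Simulate a long-read dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `reads` (read set: `id`, `seq`, `length`), `truth`
#'   (data.table `id1`, `id2`, `strand`, `s1`, `e1`, `s2`, `e2`: 1-based
#'   inclusive overlap intervals in each read's error-free frame, on the
#'   stored strand), `layout` (per-read genome placement: `id`, `start`,
#'   `end`, `strand`, `tlen` template length), `genome`, and `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  G <- config$genome_length
  n <- config$n_reads
  genome <- paste0(sample(.BASES, G, replace = TRUE), collapse = "")
  tlen <- as.integer(pmin(pmax(round(stats::rnorm(n, config$read_len_mean,
                                                  config$read_len_sd)),
                               config$min_sim_len), G))
  start <- as.integer(floor(stats::runif(n) * (G - tlen + 1))) + 1L
  end <- start + tlen - 1L
  rev <- stats::runif(n) < config$revcomp_prob
  ids <- sprintf("read_%06d", seq_len(n))

  seqs <- character(n)
  ops <- matrix(0L, n, 3L, dimnames = list(NULL, c("sub", "ins", "del")))
  for (i in seq_len(n)) {
    tmpl <- substr(genome, start[i], end[i])
    if (rev[i]) tmpl <- revcomp(tmpl)
    s <- .mutate_seq(tmpl, config$p_sub, config$p_ins, config$p_del)
    ops[i, ] <- attr(s, "ops")
    seqs[i] <- s
  }
  reads <- data.table::data.table(id = ids, seq = seqs, length = nchar(seqs))
  layout <- data.table::data.table(id = ids, start = start, end = end,
                                   strand = ifelse(rev, "-", "+"),
                                   tlen = tlen)
  truth <- .truth_table(layout, config$min_truth_overlap)
  list(reads = reads, truth = truth, layout = layout, genome = genome,
       config = config, error_ops = ops)
}

# Ground-truth pairs from genome placements: every pair of reads whose
# genome intervals intersect by more than min_overlap, with the shared
# interval projected onto each read (error-free frame, stored strand).
.truth_table <- function(layout, min_overlap = 0L) {
  n <- nrow(layout)
  rows <- list()
  nr <- 0L
  for (i in seq_len(max(0L, n - 1L))) {
    js <- which(layout$start[(i + 1L):n] <= layout$end[i] &
                layout$end[(i + 1L):n] >= layout$start[i]) + i
    for (j in js) {
      os <- max(layout$start[i], layout$start[j])
      oe <- min(layout$end[i], layout$end[j])
      if (oe - os + 1L <= min_overlap) next
      p1 <- .project_interval(os, oe, layout$start[i], layout$tlen[i],
                              layout$strand[i])
      p2 <- .project_interval(os, oe, layout$start[j], layout$tlen[j],
                              layout$strand[j])
      nr <- nr + 1L
      rows[[nr]] <- data.table::data.table(
        id1 = layout$id[i], id2 = layout$id[j],
        strand = if (layout$strand[i] == layout$strand[j]) "+" else "-",
        s1 = p1[1L], e1 = p1[2L], s2 = p2[1L], e2 = p2[2L])
    }
  }
  if (!nr)
    return(data.table::data.table(id1 = character(0), id2 = character(0),
                                  strand = character(0), s1 = integer(0),
                                  e1 = integer(0), s2 = integer(0),
                                  e2 = integer(0)))
  data.table::rbindlist(rows[seq_len(nr)])
}

.project_interval <- function(os, oe, read_start, tlen, strand) {
  s <- os - read_start + 1L
  e <- oe - read_start + 1L
  if (strand == "-") c(tlen - e + 1L, tlen - s + 1L) else c(s, e)
}

#' Write / read a ground-truth overlap table (TSV)
#'
#' Columns: `id1`, `id2`, `strand`, `s1`, `e1`, `s2`, `e2`.
#'
#' @param truth truth table from [simulate_reads()].
#' @param path file path.
#' @return `path` (write) / the truth data.table (read).
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("id1", "id2", "strand")))
}

#' Score detected overlaps against ground truth
#'
#' A detected pair is a true positive when the unordered read pair appears in
#' the truth table with the same relative strand and the detected interval on
#' each read intersects the true interval by at least `min_frac` of the
#' shorter of the two (reciprocal criterion). Precision is the matched
#' fraction of detections; recall is the fraction of truth pairs of overlap
#' length at least `min_len` (shorter side) that were matched.
#'
#' @param detected a [detect_all()] overlap table or a PAF file path.
#' @param truth truth table ([simulate_reads()] or [read_truth()]).
#' @param min_len recall denominator floor on the true overlap length
#'   (shorter side), matching the detector's minimum overlap length.
#' @param min_frac reciprocal-intersection fraction (default 0.5).
#' @return list with `precision`, `recall`, `f1`, `tp` (matched detections),
#'   `n_detected`, `n_truth` (truth pairs at or above `min_len`).
#' @export
score_overlaps <- function(detected, truth, min_len = 500L, min_frac = 0.5) {
  if (is.character(detected)) detected <- read_paf(detected)
  det <- data.table::as.data.table(detected)
  tru <- data.table::as.data.table(truth)
  kt <- paste(pmin(tru$id1, tru$id2), pmax(tru$id1, tru$id2))
  if (anyDuplicated(kt))
    stop("truth table has duplicate pairs", call. = FALSE)
  elig <- pmin(tru$e1 - tru$s1, tru$e2 - tru$s2) + 1L >= min_len

  n_det <- nrow(det)
  tp_det <- logical(n_det)
  hit_truth <- integer(0)
  if (n_det) {
    kd <- paste(pmin(det$id1, det$id2), pmax(det$id1, det$id2))
    ti <- match(kd, kt)
    for (r in which(!is.na(ti))) {
      t <- ti[r]
      if (det$strand[r] != tru$strand[t]) next
      swap <- det$id1[r] != tru$id1[t]
      d1 <- if (swap) c(det$sp2[r], det$ep2[r]) else c(det$sp1[r], det$ep1[r])
      d2 <- if (swap) c(det$sp1[r], det$ep1[r]) else c(det$sp2[r], det$ep2[r])
      ok1 <- .reciprocal_hit(d1, c(tru$s1[t], tru$e1[t]), min_frac)
      ok2 <- .reciprocal_hit(d2, c(tru$s2[t], tru$e2[t]), min_frac)
      if (ok1 && ok2) {
        tp_det[r] <- TRUE
        hit_truth <- c(hit_truth, t)
      }
    }
  }
  precision <- if (n_det) sum(tp_det) / n_det else 0
  n_truth <- sum(elig)
  recall <- if (n_truth) length(unique(hit_truth[elig[hit_truth]])) / n_truth
            else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = sum(tp_det), n_detected = n_det, n_truth = n_truth)
}

.reciprocal_hit <- function(d, t, min_frac) {
  inter <- min(d[2L], t[2L]) - max(d[1L], t[1L]) + 1L
  shorter <- min(d[2L] - d[1L], t[2L] - t[1L]) + 1L
  inter >= min_frac * shorter
}
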