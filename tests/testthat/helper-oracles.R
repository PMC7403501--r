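# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use plain string operations and direct formula evaluation, not the package's
# packed-code machinery.

rand_seq <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

decode_kmer_strings <- function(code, k) koverlap:::decode_kmer(code, k)

rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

substr_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1), k:L)
}

canon_str <- function(km) {
  rc <- vapply(km, rc_str, character(1), USE.NAMES = FALSE)
  ifelse(km <= rc, km, rc)
}

# literal or canonical k-mer frequency table (named integer vector)
brute_count_kmers <- function(seqs, k, canonical = TRUE) {
  km <- unlist(lapply(seqs, substr_kmers, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (canonical) km <- canon_str(km)
  tab <- table(km)
  stats::setNames(as.integer(tab), names(tab))
}

# smallest f with S(f) = sum_{x=f_min..f} F(x) > theta * S(h), by direct scan
brute_fmax <- function(F, f_min, theta) {
  h <- length(F)
  total <- sum(F[f_min:h])
  for (f in f_min:h) {
    if (sum(F[f_min:f]) > theta * total) return(f)
  }
  NA_integer_
}

# all-vs-all common k-mer matching between two sequences, canonical identity,
# restricted to k-mers in `solid` (canonical strings); returns a data.frame
# of 0-based P1, P2 and orientation agreement
brute_common_kmers <- function(s1, s2, k, solid) {
  k1 <- substr_kmers(s1, k); c1 <- canon_str(k1)
  k2 <- substr_kmers(s2, k); c2 <- canon_str(k2)
  out <- list(); n <- 0L
  for (i in seq_along(k1)) {
    if (!(c1[i] %in% solid)) next
    for (j in seq_along(k2)) {
      if (c1[i] == c2[j]) {
        n <- n + 1L
        out[[n]] <- data.frame(P1 = i - 1L, P2 = j - 1L,
                               positive = (k1[i] == c1[i]) == (k2[j] == c2[j]))
      }
    }
  }
  if (!n) return(data.frame(P1 = integer(0), P2 = integer(0),
                            positive = logical(0)))
  do.call(rbind, out)
}

# direct evaluation of C1-C4 for two anchors (0-based positions)
oracle_stage1 <- function(p1a, p2a, p1b, p2b, strand, alpha, gamma) {
  orient_ok <- if (strand == "+") p1a < p1b && p2a < p2b
               else p1a < p1b && p2a > p2b
  if (!orient_ok) return(FALSE)
  D1 <- abs(p1b - p1a); D2 <- abs(p2b - p2a)
  if (!(D1 < alpha && D2 < alpha)) return(FALSE)
  (max(D1, D2) - min(D1, D2)) / max(D1, D2) < gamma
}

# independent greedy chainer: plain loop over anchors using the public
# two-stage predicate, one chain per start, best size wins (first found)
oracle_best_chain_size <- function(cks, R1, R2, params) {
  A <- cks$anchors
  n <- nrow(A)
  best <- 0L
  for (st in seq_len(n)) {
    cur <- st; size <- 1L
    if (st < n) for (j in (st + 1L):n) {
      a <- list(P1 = A$P1[cur], P2 = A$P2[cur])
      b <- list(P1 = A$P1[j], P2 = A$P2[j])
      if (determine_consistent(a, b, R1, R2, cks$strand, params)) {
        cur <- j; size <- size + 1L
      }
    }
    if (size > best) best <- size
  }
  best
}

# common-k-mer-set object from bare anchor coordinates (for chaining tests)
make_cks <- function(P1, P2, strand = "+") {
  A <- data.table::data.table(code = seq_along(P1), P1 = as.integer(P1),
                              O1 = TRUE, O2 = strand == "+",
                              P2 = as.integer(P2),
                              positive = strand == "+")
  data.table::setorder(A, P1, P2)
  structure(list(anchors = A, strand = strand,
                 M = if (strand == "+") nrow(A) else 0L,
                 N = if (strand == "-") nrow(A) else 0L),
            class = "common_kmer_set")
}

# index over a small read set with an explicit or derived f_max
make_index <- function(seqs, params = overlap_params(), f_max = NULL) {
  reads <- read_set(seqs)
  spec <- build_histogram(count_kmers(reads, params$k))
  build_solid_index(reads, spec, params, f_max = f_max)
}

# random CKS instance over genuine sequences: a noisy collinear band plus
# scattered outlier anchors, on reads long enough for stage-2 extraction
random_cks_instance <- function(n_diag = 12L, n_noise = 3L, strand = "+",
                                L = 4000L) {
  p1 <- sort(sample.int(L - 400L, n_diag))
  off <- cumsum(sample(-20:20, n_diag, replace = TRUE))
  p2 <- pmax(0L, pmin(L - 16L, p1 + 150L + off))
  if (n_noise > 0L) {
    p1 <- c(p1, sample.int(L - 400L, n_noise))
    p2 <- c(p2, sample.int(L - 400L, n_noise))
  }
  if (strand == "-") p2 <- (L - 16L) - p2
  list(cks = make_cks(p1, p2, strand), R1 = rand_seq(L), R2 = rand_seq(L))
}
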