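# Low-level k-mer machinery.
#
# k-mers are packed into doubles with 2 bits per base (A=0, C=1, G=2, T=3).
# 4^k must stay below 2^53 for exact integer arithmetic in doubles, i.e.
# k <= 26 -- far above the k = 15 / k_s = 9 defaults.

.base_lut <- local({
  lut <- rep(NA_real_, 256L)
  lut[utf8ToInt("A")] <- 0
  lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2
  lut[utf8ToInt("T")] <- 3
  lut
})

.comp_chr <- c("T", "G", "C", "A")

#' Numeric base codes of a sequence
#'
#' @param seq single nucleotide string (uppercase).
#' @return numeric vector, one code per base; `NA` for any non-ACGT character
#'   (an `N` poisons every k-mer window covering it).
#' @keywords internal
base_codes <- function(seq) {
  .base_lut[utf8ToInt(seq)]
}

#' Packed k-mer codes at every start position of a sequence
#'
#' Computes, for each 0-based start position `0..L-k`, the forward code, the
#' reverse-complement code, the canonical code (the smaller of the two) and
#' the orientation flag (`TRUE` when the literal k-mer equals its canonical
#' form; ties from palindromic even-k k-mers count as forward).
#'
#' @param seq nucleotide string.
#' @param k k-mer length.
#' @return list with numeric vectors `fw`, `rc`, `canon`, logical `fwd_is_canon`,
#'   and `n` (number of windows, `max(0, L - k + 1)`). Windows containing a
#'   non-ACGT base have `NA` codes.
#' @keywords internal
kmer_codes <- function(seq, k) {
  b <- base_codes(seq)
  L <- length(b)
  n <- L - k + 1L
  if (n <= 0L) {
    return(list(fw = numeric(0), rc = numeric(0), canon = numeric(0),
                fwd_is_canon = logical(0), n = 0L))
  }
  fw <- numeric(n)
  rc <- numeric(n)
  for (j in 0:(k - 1L)) {
    bj <- b[(1L + j):(n + j)]
    fw <- fw + bj * 4^(k - 1L - j)
    rc <- rc + (3 - bj) * 4^j
  }
  fwd <- fw <= rc              # NA where window has N
  canon <- pmin(fw, rc)
  list(fw = fw, rc = rc, canon = canon, fwd_is_canon = fwd, n = n)
}

#' Decode a packed k-mer code back to a string
#'
#' @param code numeric vector of packed codes.
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @keywords internal
decode_kmer <- function(code, k) {
  out <- matrix("", nrow = length(code), ncol = k)
  rem <- code
  for (j in seq_len(k)) {
    p <- 4^(k - j)
    d <- rem %/% p
    out[, j] <- c("A", "C", "G", "T")[d + 1]
    rem <- rem - d * p
  }
  apply(out, 1L, paste0, collapse = "")
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences (A/C/G/T/N).
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}
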