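# IO, pair enumeration, end-to-end orchestration, PAF, CLI.

P <- overlap_params()

write_tmp <- function(lines, ext = ".fasta") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("load_reads filters by length and sniffs FASTA/FASTQ", {
  set.seed(401)
  f <- write_tmp(c(">short desc", rand_seq(1500), ">long", rand_seq(2500)))
  rd <- load_reads(f, 2000, quiet = TRUE)
  expect_equal(rd$id, "long")
  expect_equal(rd$length, 2500L)

  fq <- write_tmp(c("@a", "ACGTACGTAA", "+", "IIIIIIIIII",
                    "@b", "TTTTACGTAC", "+", "IIIIIIIIII"), ".fastq")
  rd <- load_reads(fq, 5, quiet = TRUE)
  expect_equal(rd$id, c("a", "b"))
  expect_equal(rd$length, c(10L, 10L))
  # round-trip ids and lengths through FASTA
  out <- tempfile(fileext = ".fasta")
  write_fasta(rd, out)
  rd2 <- load_reads(out, 5, quiet = TRUE)
  expect_equal(rd2, rd)
})

test_that("load_reads handles gzip, empty files and malformed input", {
  set.seed(402)
  gz <- tempfile(fileext = ".fasta.gz")
  con <- gzfile(gz, "wt")
  writeLines(c(">r1", rand_seq(50)), con)
  close(con)
  expect_equal(load_reads(gz, 10, quiet = TRUE)$id, "r1")

  empty <- tempfile()
  file.create(empty)
  expect_warning(rd <- load_reads(empty, 10), "empty")
  expect_equal(nrow(rd), 0L)

  dup <- write_tmp(c(">x", "ACGT", ">x", "ACGT"))
  expect_error(load_reads(dup, 1, quiet = TRUE),
               class = "koverlap_parse_error")
  bad <- write_tmp(c("not a fasta", "at all"))
  expect_error(load_reads(bad, 1, quiet = TRUE),
               class = "koverlap_parse_error")
  expect_error(read_set(c(a = "ACGJ")), class = "koverlap_parse_error")
})

test_that("candidate pairs are reads sharing at least one solid k-mer", {
  set.seed(403)
  shared <- rand_seq(15)
  seqs <- c(a = paste0(rand_seq(40), shared, rand_seq(40)),
            b = paste0(rand_seq(30), shared, rand_seq(50)),
            c = paste0(shared, rand_seq(80)))
  idx <- make_index(seqs)
  pr <- enumerate_pairs(idx)
  expect_equal(pr, data.table::data.table(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)),
               ignore_attr = TRUE)

  # disjoint k-mer content: no pairs
  idx0 <- make_index(c(a = rand_seq(100), b = rand_seq(100)), f_max = 10L)
  expect_equal(nrow(enumerate_pairs(idx0)), 0L)
})

test_that("pair enumeration equals the brute-force intersection test", {
  set.seed(404)
  g <- rand_seq(2000)
  starts <- sample(1:1500, 8)
  seqs <- stats::setNames(substring(g, starts, starts + 499), paste0("r", 1:8))
  idx <- make_index(seqs, f_max = 10L)
  pr <- enumerate_pairs(idx)
  solid_sets <- lapply(seqs, function(s) {
    km <- canon_str(substr_kmers(s, 15))
    intersect(km, decode_kmer_strings(unique(idx$postings$code), 15))
  })
  for (a in 1:7) for (b in (a + 1):8) {
    shared <- length(intersect(solid_sets[[a]], solid_sets[[b]])) > 0
    expect_equal(any(pr$i == a & pr$j == b), shared)
  }
})

test_that("detect_all finds dovetail and reverse-strand overlaps only", {
  set.seed(405)
  g <- rand_seq(13000)
  reads <- read_set(c(
    r1 = substr(g, 1, 10000),
    r2 = paste0(substr(g, 7001, 10000), rand_seq(2000)),  # 3 kb dovetail
    r3 = rand_seq(5000)))                                  # unrelated
  ov <- detect_all(reads, P, quiet = TRUE)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov[, c("id1", "id2", "strand")],
               data.table::data.table(id1 = "r1", id2 = "r2", strand = "+"),
               ignore_attr = TRUE)
  expect_lte(abs((ov$ep1 - ov$sp1 + 1L) - 3000L), 15L)

  # reverse-complemented suffix: one "-" overlap
  reads2 <- read_set(c(r1 = substr(g, 1, 10000),
                       r2 = rc_str(substr(g, 7001, 10000))))
  ov2 <- detect_all(reads2, P, quiet = TRUE)
  expect_equal(ov2$strand, "-")
  expect_lte(abs(ov2$sp1 - 7001L), 15L)
  expect_equal(ov2$sp2, 1L)

  # unrelated random reads: empty result through the degenerate-spectrum path
  expect_equal(nrow(detect_all(read_set(c(a = rand_seq(10000),
                                          b = rand_seq(10000))),
                               P, quiet = TRUE)), 0L)
})

test_that("PAF output is 12 tab-separated columns that round-trip", {
  set.seed(406)
  g <- rand_seq(8000)
  reads <- read_set(c(r1 = substr(g, 1, 5000),
                      r2 = rc_str(substr(g, 3001, 8000))))
  ov <- detect_all(reads, P, quiet = TRUE)
  expect_equal(nrow(ov), 1L)
  f <- tempfile(fileext = ".paf")
  write_paf(ov, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_length(fields, 12L)
  expect_equal(fields[5], "-")
  expect_equal(as.integer(fields[12]), 255L)
  back <- read_paf(f, k = attr(ov, "k"))
  expect_equal(back, ov, ignore_attr = TRUE)

  # empty overlap set: empty file
  f0 <- tempfile(fileext = ".paf")
  write_paf(ov[0], f0)
  expect_equal(file.size(f0), 0)
  expect_equal(nrow(read_paf(f0)), 0L)
})

test_that("detection is deterministic across runs", {
  set.seed(407)
  sim <- simulate_reads(sim_config(genome_length = 20000L, coverage = 6,
                                   error_rate = 0.1, seed = 17))
  f1 <- tempfile(); f2 <- tempfile()
  write_paf(detect_all(sim$reads, P, quiet = TRUE), f1)
  write_paf(detect_all(sim$reads, P, quiet = TRUE), f2)
  expect_gt(file.size(f1), 0)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the CLI dispatches, honours config overrides and exit codes", {
  set.seed(408)
  expect_equal(koverlap_main(character(0)), 1L)
  expect_equal(koverlap_main("bogus"), 1L)

  g <- rand_seq(9000)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(read_set(c(r1 = substr(g, 1, 6000),
                         r2 = substr(g, 3001, 9000))), fa)
  paf <- tempfile(fileext = ".paf")
  expect_equal(
    suppressMessages(koverlap_main(c("detect", fa, "-o", paf, "-q",
                                     "--min-read-len", "1000"))), 0L)
  expect_equal(nrow(read_paf(paf)), 1L)

  bad <- write_tmp(c("garbage"))
  expect_equal(
    suppressMessages(koverlap_main(c("detect", bad, "-o", paf))), 2L)

  cfg <- write_tmp(c("# comment", "k = 13", "epsilon = 400"), ".cfg")
  opt <- list(config = cfg, k = 17L)
  pars <- koverlap:::.effective_params(opt)
  expect_equal(pars$k, 17L)        # CLI flag beats config
  expect_equal(pars$epsilon, 400)  # config beats default

  # simulate + score subcommands end to end
  pre <- tempfile()
  expect_equal(suppressMessages(koverlap_main(
    c("simulate", "--genome-length", "15000", "--coverage", "5",
      "--error-rate", "0.05", "--seed", "3", "-o", pre))), 0L)
  paf2 <- tempfile(fileext = ".paf")
  expect_equal(suppressMessages(koverlap_main(
    c("detect", paste0(pre, ".fasta"), "-o", paf2, "-q"))), 0L)
  out <- capture.output(
    st <- suppressMessages(koverlap_main(
      c("score", "--paf", paf2, "--truth", paste0(pre, ".truth.tsv")))))
  expect_equal(st, 0L)
  expect_true(any(grepl("^precision", out)))
})
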