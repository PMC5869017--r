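test_that("2P-seq trimming enforces the 10-A tail and 20-nt length rules", {
  # 30-nt read ending in 12 A: trimmed to 18 nt, below the length floor
  r30 <- paste0(random_dna(18), strrep("A", 12))
  res <- trim_polya_2pseq(r30)
  expect_false(res$retained)
  expect_identical(res$reason, "too_short")

  # 40-nt read ending in 12 A: retained with 28 nt and tail 12
  set.seed(3)
  body <- gsub("A", "C", random_dna(28))  # avoid accidental 10-A runs
  res <- trim_polya_2pseq(paste0(body, strrep("A", 12)))
  expect_true(res$retained)
  expect_identical(nchar(res$trimmed), 28L)
  expect_identical(res$tail_length, 12L)

  # longest A-run of 9 does not qualify
  res <- trim_polya_2pseq(paste0(strrep("C", 30), strrep("A", 9), "G"))
  expect_false(res$retained)
  expect_identical(res$reason, "no_tail")
})

test_that("2P-seq trimming removes the tail and any adapter remnant beyond it", {
  read <- paste0(strrep("G", 25), strrep("A", 11), "CTGTCTCT")
  res <- trim_polya_2pseq(read)
  expect_true(res$retained)
  expect_identical(res$trimmed, strrep("G", 25))
})

test_that("5'-as-T mode reverse-complements before locating the tail", {
  insert <- gsub("T", "G", random_dna(24))
  read <- paste0(strrep("T", 12), oracle_revcomp(insert))
  res <- trim_polya_2pseq(read, tail_end = "5p_as_T")
  expect_true(res$retained)
  expect_identical(res$trimmed, insert)
})

test_that("generic trimming keeps one terminal A and the 20-nt boundary", {
  res <- trim_polya_generic(paste0(strrep("C", 25), "A"))
  expect_true(res$retained)
  expect_identical(res$tail_length, 1L)
  expect_identical(nchar(res$trimmed), 25L)

  res <- trim_polya_generic(paste0(strrep("C", 25), "G"))
  expect_false(res$retained)
  expect_identical(res$reason, "no_tail")

  # exactly 20 nt after removing the tail is retained (20 is not "< 20")
  res <- trim_polya_generic(paste0(strrep("C", 20), "A"))
  expect_true(res$retained)
  expect_identical(nchar(res$trimmed), 20L)

  res <- trim_polya_generic(paste0(strrep("C", 19), "A"))
  expect_false(res$retained)
  expect_identical(res$reason, "too_short")
})

test_that("trimming is idempotent on retained output", {
  set.seed(5)
  reads <- replicate(50, paste0(gsub("A", "G", random_dna(30)),
                                strrep("A", sample(10:15, 1))))
  first <- trim_polya_2pseq(reads)
  again <- trim_polya_2pseq(first$trimmed[first$retained])
  # a retained read has no qualifying tail left, so it is reported no_tail
  # and its sequence is unchanged by construction
  expect_true(all(!again$retained & again$reason == "no_tail"))
})

test_that("internal-priming rule matches the quoted examples", {
  g <- make_genome(chr1 = paste0("G", "AAAAAAGCGCGCGCGCGCGC"))
  res <- internal_priming_filter(coverage_tbl(0, 1), g)
  expect_false(res$keep)   # six consecutive A downstream

  # 6 A in every 12-mer, longest run 2: below both thresholds
  g <- make_genome(chr1 = paste0("G", "AAGGAAGGAAGGAAGGAAGG"))
  res <- internal_priming_filter(coverage_tbl(0, 1), g)
  expect_true(res$keep)
  # one extra A tips a 12-mer to 7: discarded
  g <- make_genome(chr1 = paste0("G", "AAGGAAGGAAGAAAGGGGGG"))
  expect_false(internal_priming_filter(coverage_tbl(0, 1), g)$keep)

  g <- make_genome(chr1 = paste0("G", strrep("C", 20)))
  expect_true(internal_priming_filter(coverage_tbl(0, 1), g)$keep)
})

test_that("internal-priming filter agrees with the exhaustive scanner", {
  set.seed(23)
  n <- 2000
  # half uniform, half A-enriched so both rules actually fire
  mers <- c(replicate(n / 2, random_dna(20)),
            replicate(n / 2, paste(sample(c("A", "C", "G", "T"), 20, TRUE,
                                          prob = c(0.45, 0.2, 0.2, 0.15)), collapse = "")))
  g <- make_genome(chr1 = paste0("G", paste(mers, collapse = "")))
  ends <- coverage_tbl(0:(n - 1) * 20L, rep(1L, n))
  res <- internal_priming_filter(ends, g)
  expected <- !vapply(mers, oracle_a_rich, logical(1), USE.NAMES = FALSE)
  expect_identical(res$keep, expected)
  expect_gt(sum(!expected), 50)  # the fixture exercises the discard branch
})

test_that("only the downstream 20-mer matters, and truncated windows scan as-is", {
  down <- "AAGGAAGGAAGGAAGGAAGG"
  for (up in c("AAAAAAAAAA", "CCCCCCCCCC", "GTGTGTGTGT")) {
    g <- make_genome(chr1 = paste0(up, down))
    expect_true(internal_priming_filter(coverage_tbl(9, 1), g)$keep)
  }
  # minus strand: downstream runs leftwards; 6 T upstream of the end = 6 A
  g <- make_genome(chr1 = paste0("TTTTTT", "GG"))
  expect_false(internal_priming_filter(coverage_tbl(6, 1, strand = "-"), g)$keep)
  # truncated window at a chromosome end: only 5 bases remain, all A but < 6
  g <- make_genome(chr1 = paste0("G", "AAAAA"))
  expect_true(internal_priming_filter(coverage_tbl(0, 1), g)$keep)
})

test_that("untemplated-A rule compares tail length with templated genomic A", {
  expect_true(untemplated_a_filter(3, "AAGCC"))    # 2 templated, 1 untemplated
  expect_false(untemplated_a_filter(2, "AAACC"))   # all templated
  expect_true(untemplated_a_filter(1, "GCCCC"))
  expect_identical(untemplated_a_filter(c(3, 2, 1), c("AAGCC", "AAACC", "GCCCC")),
                   c(TRUE, FALSE, TRUE))
})

test_that("FASTQ trimming writes retained reads and a rejection log", {
  fq <- tempfile(fileext = ".fastq")
  reads <- c(paste0(strrep("G", 25), strrep("A", 12)),   # retained
             paste0(strrep("G", 10), strrep("A", 12)),   # too short
             strrep("G", 40))                            # no tail
  writeLines(unlist(lapply(seq_along(reads), function(i) {
    c(paste0("@r", i), reads[i], "+", strrep("I", nchar(reads[i])))
  })), fq)
  out <- tempfile(fileext = ".fastq"); log <- tempfile(fileext = ".tsv")
  res <- trim_fastq(fq, out, log, protocol = "2pseq")
  kept <- Biostrings::readDNAStringSet(out, format = "fastq")
  expect_identical(length(kept), 1L)
  expect_identical(as.character(kept[[1]]), strrep("G", 25))
  rej <- readr::read_tsv(log, show_col_types = FALSE)
  expect_setequal(rej$reason, c("too_short", "no_tail"))
})
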