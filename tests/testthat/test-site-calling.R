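test_that("clustering merges within the gap, drops sub-threshold peaks", {
  cov <- coverage_tbl(c(100, 110, 200), c(3, 4, 6))
  cl <- cluster_ends(cov)
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$start, c(100, 200))
  expect_equal(cl$end, c(111, 201))
  expect_equal(cl$n_reads, c(7, 6))
  expect_equal(cl$summit_pos, c(110, 200))

  expect_identical(nrow(cluster_ends(coverage_tbl(50, 4))), 0L)
  empty <- cluster_ends(coverage_tbl(integer(), integer()))
  expect_identical(nrow(empty), 0L)
})

test_that("clustering equals the brute-force transitive merge on random coverages", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(1:25, 1)
    pos <- sort(sample(0:400, n))
    count <- sample(1:10, n, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    got <- cluster_ends(coverage_tbl(pos, count, strand = strand))
    want <- oracle_cluster(pos, count, strand = strand)
    if (is.null(want) || nrow(want) == 0) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- want[order(want$start), ]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_reads, want$n_reads)
      expect_equal(got$summit_pos, want$summit_pos)
      expect_equal(got$summit_count, want$summit_count)
    }
  }
})

test_that("read counts are conserved between retained and dropped peaks", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    cov <- coverage_tbl(sample(0:600, n), sample(1:8, n, replace = TRUE))
    cl <- cluster_ends(cov)
    expect_equal(sum(cl$n_reads) + attr(cl, "dropped_reads"), sum(cov$count))
  }
})

test_that("summit ties break to the 5'-most position in transcript orientation", {
  cl <- cluster_ends(coverage_tbl(c(50, 60), c(5, 5)))
  expect_equal(cl$summit_pos, 50)
  cl <- cluster_ends(coverage_tbl(c(50, 60), c(5, 5), strand = "-"))
  expect_equal(cl$summit_pos, 60)
})

# -- classification fixtures ------------------------------------------------
# plus-strand gene: tx [100, 400), CDS [140, 320), 3'UTR [320, 1400)
plus_gene <- function() toy_gene("gP", "chr1", "+", cbind(140, 320), 100, 400)
# two-exon gene with an intron [200, 260)
split_gene <- function() toy_gene("gS", "chr1", "+", rbind(c(140, 200), c(260, 320)),
                                  100, 400)

fake_cluster <- function(summit, strand = "+", count = 10) {
  tibble::tibble(chrom = "chr1", strand = strand, start = summit, end = summit + 1L,
                 n_reads = count, summit_pos = as.integer(summit), summit_count = count)
}

test_that("summits classify as UTR3 / ORF / intron / UTR5 / intergenic", {
  ann <- plus_gene()
  prof <- species_profile("ncrassa")
  expect_identical(classify_sites(fake_cluster(350), ann, prof)$class, "UTR3")
  expect_identical(classify_sites(fake_cluster(1399), ann, prof)$class, "UTR3")
  # ORF: summit at 200, PAS window [170, 191) fully inside CDS [140, 320)
  s <- classify_sites(fake_cluster(200), ann, prof)
  expect_identical(s$class, "ORF")
  expect_equal(s$pas_start, 170)
  expect_equal(s$pas_end, 191)
  # summit at 150: window [120, 141) leaves the CDS, falls through
  expect_false(identical(classify_sites(fake_cluster(150), ann, prof)$class, "ORF"))
  expect_identical(classify_sites(fake_cluster(120), ann, prof)$class, "UTR5")
  expect_identical(classify_sites(fake_cluster(5000), ann, prof)$class, "intergenic")
})

test_that("a PAS window crossing an intron boundary denies the ORF class", {
  ann <- split_gene()
  prof <- species_profile("ncrassa")
  # summit 280 is in exon 2 but its window [250, 271) crosses the intron
  s <- classify_sites(fake_cluster(280), ann, prof)
  expect_identical(s$class, "intron")
  # summit 300: window [270, 291) fully inside exon 2
  expect_identical(classify_sites(fake_cluster(300), ann, prof)$class, "ORF")
  # summit inside the intron itself
  expect_identical(classify_sites(fake_cluster(230), ann, prof)$class, "intron")
})

test_that("summits claimed by two same-strand genes are flagged ambiguous", {
  ann <- dplyr::bind_rows(
    toy_gene("g1", "chr1", "+", cbind(100, 220), 80, 260),
    toy_gene("g2", "chr1", "+", cbind(600, 700), 580, 750)
  )
  # 3'UTR of g1 extends to 1260 and covers g2's 3'UTR start region
  s <- classify_sites(fake_cluster(760), ann, species_profile("ncrassa"))
  expect_identical(s$class, "UTR3")
  expect_true(s$ambiguous)
  expect_true(is.na(s$gene_id))
  # ambiguous sites are excluded from the gene table
  gt <- gene_termination_table(s, ann, library_size = 100)
  expect_identical(nrow(gt), 0L)
})

test_that("classification is strand-antisymmetric under genome mirroring", {
  prof <- species_profile("ncrassa")
  L <- 2000L
  ann_f <- toy_gene("gM", "chr1", "+", cbind(140, 320), 100, 400)
  for (summit in c(200L, 350L, 120L, 230L)) {
    mirror <- function(x) L - 1L - x
    ann_r <- toy_gene("gM", "chr1", "-", cbind(mirror(319) , mirror(140) + 1L),
                      mirror(399), mirror(100) + 1L)
    cf <- classify_sites(fake_cluster(summit), ann_f, prof)
    cr <- classify_sites(fake_cluster(mirror(summit), strand = "-"), ann_r, prof)
    expect_identical(cr$class, cf$class)
  }
})

test_that("the major 3'UTR site takes the highest summit, ties most 3'", {
  ann <- plus_gene()
  prof <- species_profile("ncrassa")
  mk <- function(summits, counts, strand = "+") {
    classify_sites(dplyr::bind_rows(purrr::map2(summits, counts,
                                                ~fake_cluster(.x, strand, .y))),
                   ann, prof)
  }
  s <- mk(c(330, 360, 390), c(10, 30, 7))
  expect_equal(major_utr3_site(s)$summit_pos, 360)
  s <- mk(350, 12)
  expect_equal(major_utr3_site(s)$summit_pos, 350)
  s <- mk(c(350, 390), c(10, 10))
  expect_equal(major_utr3_site(s)$summit_pos, 390)  # most 3' on plus strand
})

test_that("termination table implements the normalized ratio and its guards", {
  ann <- toy_gene("gT", "chr1", "+", cbind(0, 1000), 0, 1400)
  prof <- species_profile("ncrassa")
  sites <- dplyr::bind_rows(
    dplyr::mutate(fake_cluster(500, count = 2), class = "ORF", gene_id = "gT",
                  ambiguous = FALSE, pas_start = NA_integer_, pas_end = NA_integer_),
    dplyr::mutate(fake_cluster(1100, count = 100), class = "UTR3", gene_id = "gT",
                  ambiguous = FALSE, pas_start = NA_integer_, pas_end = NA_integer_)
  )
  gt <- gene_termination_table(sites, ann, library_size = 1e6)
  expect_equal(gt$ratio, 2 * 1000 / (100 * 1000))  # 0.02
  expect_equal(gt$rpm, 100)
  expect_equal(gt$log10_ratio, log10(0.02))

  # no ORF reads: ratio 0
  gt0 <- gene_termination_table(sites[2, ], ann, library_size = 1e6)
  expect_equal(gt0$ratio, 0)

  # no UTR3 reads: gene omitted
  gt_na <- gene_termination_table(sites[1, ], ann, library_size = 1e6)
  expect_identical(nrow(gt_na), 0L)

  expect_error(gene_termination_table(sites, ann, library_size = 0), "positive")
})

test_that("implanted sites are recovered exactly at zero dispersion", {
  spec <- synthetic_spec(n_genes = 20, dispersion = 0, artifact_rate = 0)
  sim <- generate_genome(spec, seed = 41)
  reads <- simulate_reads(sim$genome, sim$truth, spec, seed = 42)
  cl <- cluster_ends(reads$coverage)
  truth <- reads$truth[reads$truth$n_reads >= 5, ]
  for (i in seq_len(nrow(truth))) {
    expect_true(any(cl$strand == truth$strand[i] &
                      cl$summit_pos == truth$cleavage_pos[i]))
  }
})
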