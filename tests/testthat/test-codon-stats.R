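# usage table with controlled RSCA classes for the alanine family:
# GCC -> 1.0 (optimal), GCT -> 0.5 (random), GCA -> 0.1 (rare)
fixture_usage <- function() {
  compute_rsca(c(GCC = 100, GCT = 50, GCA = 10, GCG = 90,
                 AAA = 80, AAG = 100, TGG = 7, ATG = 12))
}

test_that("RSCA divides by the most abundant synonymous codon", {
  u <- compute_rsca(c(GCC = 100, GCT = 50))
  expect_equal(u$rsca[u$codon == "GCC"], 1)
  expect_equal(u$rsca[u$codon == "GCT"], 0.5)
  # single-codon families score 1 whenever observed
  u2 <- compute_rsca(c(ATG = 5, TGG = 3))
  expect_equal(u2$rsca[u2$codon == "ATG"], 1)
  expect_equal(u2$rsca[u2$codon == "TGG"], 1)
  # stop codons carry no RSCA
  u3 <- compute_rsca(c(TAA = 10, TAG = 5))
  expect_true(all(is.na(u3$rsca[u3$aa == "*"])))
})

test_that("RSCA matches a per-family max-normalisation oracle on random counts", {
  set.seed(43)
  counts <- stats::setNames(sample(1:500, 64, replace = TRUE),
                            chartr("U", "T", names(Biostrings::GENETIC_CODE)))
  u <- compute_rsca(counts)
  gc <- Biostrings::GENETIC_CODE
  for (aa in setdiff(unique(gc), "*")) {
    fam <- chartr("U", "T", names(gc)[gc == aa])
    want <- counts[fam] / max(counts[fam])
    got <- stats::setNames(u$rsca, u$codon)[fam]
    expect_equal(unname(got), unname(want))
  }
})

test_that("CBI closed forms hold", {
  u <- fixture_usage()
  # all codons optimal
  expect_equal(compute_cbi(strrep("GCC", 40), u), 1)
  # N_opt = 60, N_ran = 30, N_tot = 100 -> 30/70
  cds <- paste0(strrep("GCC", 60), strrep("GCT", 30), strrep("GCA", 10))
  expect_equal(compute_cbi(cds, u), 30 / 70)
  # all codons rare -> 0
  expect_equal(compute_cbi(strrep("GCA", 25), u), 0)
  # N_tot == N_ran is undefined
  expect_true(is.na(compute_cbi(strrep("GCT", 25), u)))
})

test_that("CAI is the geometric mean of RSCA values", {
  u <- compute_rsca(c(GCC = 100, GCT = 25))
  expect_equal(compute_cai("GCCGCT", u), 0.5)         # sqrt(1 * 0.25)
  expect_equal(compute_cai(strrep("GCC", 10), u), 1)
  # terminal stop codons are dropped before averaging
  expect_equal(compute_cai("GCCGCTTAA", u), 0.5)
})

test_that("per-gene indices agree with a direct per-codon oracle", {
  spec <- synthetic_spec(n_genes = 12, cds_codons = c(60, 120), orf_site_rate = 0)
  sim <- generate_genome(spec, seed = 47)
  usage <- codon_usage(sim$annotation, sim$genome)
  idx <- gene_codon_indices(sim$annotation, sim$genome, usage)
  rsca <- stats::setNames(usage$rsca, usage$codon)
  cls <- stats::setNames(usage$class, usage$codon)
  for (i in seq_len(nrow(sim$annotation))) {
    cds <- gene_cds_seq(sim$annotation[i, ], sim$genome)
    cc <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    cc <- cc[!cc %in% c("TAA", "TAG", "TGA")]
    n_opt <- sum(cls[cc] == "optimal"); n_ran <- sum(cls[cc] == "random")
    row <- idx[idx$gene_id == sim$annotation$gene_id[i], ]
    expect_equal(row$cbi, (n_opt - n_ran) / (length(cc) - n_ran), tolerance = 1e-12)
    expect_equal(row$cai, exp(mean(log(rsca[cc]))), tolerance = 1e-12)
  }
})

# ORF sites placed at known coding offsets on synthetic genes
orf_sites_at <- function(sim, coding_offset) {
  purrr::map_dfr(seq_len(nrow(sim$annotation)), function(i) {
    g <- sim$annotation[i, ]
    gpos <- if (g$strand == "+") g$cds_start + coding_offset
            else g$cds_end - 1L - coding_offset
    tibble::tibble(chrom = g$chrom, strand = g$strand, start = gpos, end = gpos + 1L,
                   n_reads = 10L, summit_pos = as.integer(gpos), summit_count = 10L,
                   gene_id = g$gene_id, class = "ORF", ambiguous = FALSE,
                   pas_start = NA_integer_, pas_end = NA_integer_)
  })
}

test_that("NCUF is near zero when foreground matches the background sampler", {
  spec <- synthetic_spec(n_genes = 60, orf_site_rate = 0)
  sim <- generate_genome(spec, seed = 53)
  # windows at arbitrary mid-CDS offsets: composition identical to background.
  # Codons are selected by background abundance; selecting by foreground
  # count would condition on upward fluctuations.
  sites <- orf_sites_at(sim, 120L)
  tab <- ncuf(sites, sim$annotation, sim$genome, seed = 54)
  busy <- tab[tab$bg_count >= 100 & tab$flag == "ok", ]
  expect_gt(nrow(busy), 5)
  expect_lt(mean(abs(busy$log2_ratio)), 0.5)
  expect_lt(abs(mean(busy$log2_ratio)), 0.25)
})

test_that("NCUF and NCPF recover implanted PAS codons and pairs", {
  spec <- synthetic_spec(n_genes = 40, orf_site_rate = 0.5)
  sim <- generate_genome(spec, seed = 59)
  reads <- simulate_reads(sim$genome, sim$truth, spec, seed = 60)
  sites <- classify_sites(cluster_ends(reads$coverage), sim$annotation)
  nc <- ncuf(sites, sim$annotation, sim$genome, seed = 61)
  expect_gt(nc$log2_ratio[nc$unit == "AAT"], 0)
  expect_gt(nc$log2_ratio[nc$unit == "AAA"], 0)
  np <- ncpf(sites, sim$annotation, sim$genome, seed = 62)
  ok <- np[np$flag == "ok", ]
  expect_identical(ok$unit[which.max(ok$log2_ratio)], "AAT|AAA")
})

test_that("true/false PAS classification follows the 5-35 nt window and strand", {
  # motif at [100,106), summit placed at varying distances downstream
  place <- function(d, strand = "+") {
    s <- strrep("C", 400)
    substr(s, 101, 106) <- "AATAAA"
    g <- make_genome(chr1 = s)
    ann <- toy_gene("gX", "chr1", "+", cbind(60, 300), 40, 360)
    sites <- tibble::tibble(chrom = "chr1", strand = strand, summit_pos = 105L + d)
    classify_true_false_pas("AATAAA", g, sites, ann)
  }
  expect_true(place(18)$true_pas)    # 18 nt downstream
  expect_false(place(4)$true_pas)    # too close
  expect_false(place(36)$true_pas)   # too far
  expect_true(place(5)$true_pas)     # boundary inclusive
  expect_true(place(35)$true_pas)
  expect_false(place(18, strand = "-")$true_pas)  # opposite strand never counts
})

test_that("PAS occurrence context requires full containment in ORF or 3'UTR", {
  s <- strrep("G", 500)
  substr(s, 101, 106) <- "AATAAA"  # genomic [100, 106) inside CDS [60, 300)
  substr(s, 311, 316) <- "AATAAA"  # genomic [310, 316) inside 3'UTR [300, ...)
  substr(s, 297, 302) <- "AATAAA"  # straddles the CDS/3'UTR boundary
  g <- make_genome(chr1 = s)
  ann <- toy_gene("gX", "chr1", "+", cbind(60, 300), 40, 360, chrom_len = 500)
  occ <- classify_true_false_pas("AATAAA", g,
                                 tibble::tibble(chrom = character(), strand = character(),
                                                summit_pos = integer()), ann)
  expect_identical(nrow(occ), 2L)
  expect_setequal(occ$context, c("ORF", "UTR3"))
  # order of the motif list does not matter, and the call is idempotent
  occ2 <- classify_true_false_pas(c("TTTTTT", "AATAAA"), g,
                                  tibble::tibble(chrom = character(), strand = character(),
                                                 summit_pos = integer()), ann)
  expect_equal(occ, occ2[occ2$motif_dna == "AATAAA", ], ignore_attr = TRUE)
})

test_that("RCUF is zero for identical flank composition and flags absent codons", {
  # periodic CDS: every 15-codon flank has identical composition
  cds <- strrep("GCCAAT", 200)  # alternating GCC/AAT codons
  g <- make_genome(chr1 = paste0(strrep("C", 50), cds, strrep("C", 50)))
  ann <- toy_gene("gY", "chr1", "+", cbind(50, 50 + nchar(cds)), 30, 1400)
  # two same-composition occurrence groups at codon boundaries
  occ <- tibble::tibble(
    motif = "GCCAAU", motif_dna = "GCCAAT", chrom = "chr1", strand = "+",
    start = c(50 + 300, 50 + 600, 50 + 900), end = c(50 + 306, 50 + 606, 50 + 906),
    gene_id = "gY", context = "ORF", true_pas = c(TRUE, FALSE, FALSE)
  )
  tab <- rcuf(occ, ann, g)
  ok <- tab[tab$flag == "ok", ]
  expect_true(all(abs(ok$log2_ratio) < 1e-12))
  expect_setequal(ok$unit, c("GCC", "AAT"))
  # a codon absent from the false group is flagged, not infinite
  expect_true(all(is.finite(ok$log2_ratio)))
  expect_error(rcuf(occ[occ$true_pas, ], ann, g), "both")
})

test_that("A/T content profiles separate A-rich from balanced flanks", {
  s <- paste0(strrep("A", 200), strrep("GC", 100))
  g <- make_genome(chr1 = s)
  occ <- tibble::tibble(
    motif = "AAUAAA", motif_dna = "AATAAA", chrom = "chr1", strand = "+",
    start = c(100L, 300L), end = c(106L, 306L),
    gene_id = "gZ", context = "ORF", true_pas = c(TRUE, FALSE)
  )
  prof <- at_content_profile(occ, g, flank_nt = 80)
  means <- attr(prof, "mean_at")
  expect_equal(means$mean_at[means$true_pas], 1)
  expect_gt(means$mean_at[means$true_pas], means$mean_at[!means$true_pas])
  # per-position frequencies stay in [0, 1]
  expect_true(all(prof$at >= 0 & prof$at <= 1))
})
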