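#' Specification for a synthetic PCPA study
#'
#' Bundles the knobs of the synthetic genome/read generator: gene count and
#' length distributions, the wobble-position G/C bias `beta` (probability
#' that a synonymous codon ends in G or C; a scalar or a
#' per-gene-uniform range), implanted 3'UTR and ORF PAS motifs with the
#' motif-to-cleavage gap, cleavage-site dispersion, and the
#' internal-priming artifact rate at genomic A-runs. Defaults emulate a
#' compact fungal-like genome: a few dozen single-exon genes, 150-300
#' codon ORFs, ~200 nt 3'UTRs, kilobase-scale intergenic spacing (so 3'UTR
#' search intervals with their 1-kb extension do not collide), an AAUAAA
#' signal ending 18 nt upstream of the cleavage site, and read 3'-ends
#' dispersed geometrically with mean 2 nt.
#'
#' @param n_genes Number of genes (default 60).
#' @param cds_codons Range of amino-acid counts per ORF (default 150-300).
#' @param utr5_len 5'UTR length in nt (default 40).
#' @param utr3_len Range of 3'UTR lengths in nt (default 120-220).
#' @param intergenic Range of intergenic spacer lengths (default 1100-1600).
#' @param beta Wobble G/C bias in `[0,1]`; scalar, or length-2 range for
#'   per-gene uniform draws (default `c(0.3, 0.95)`, a net genome-wide G/C wobble preference).
#' @param expression Lognormal parameters (`meanlog`, `sdlog`) for per-gene
#'   expected 3'UTR read counts.
#' @param utr3_motif,orf_motif Implanted PAS hexamers (DNA alphabet).
#' @param motif_gap Nucleotides between the motif 3' end and the cleavage
#'   site (default 18, within the 5-35 nt true-PAS window).
#' @param cleavage_margin 3'UTR nucleotides retained downstream of the
#'   cleavage site (default 40).
#' @param orf_site_rate Fraction of genes given an implanted ORF site
#'   (default 0.4).
#' @param orf_usage ORF-site usage scale (default 0.15): a gene's ORF site
#'   gets expected reads `expression * orf_usage * ((1 - beta) / 0.5)^2`,
#'   so premature termination increases with the gene's rare-codon
#'   content (the dose dependence the generator emulates).
#' @param orf_sites_in `"low_beta"` (ORF sites go to the genes with the
#'   smallest beta, emulating rare-codon-rich genes terminating early) or
#'   `"random"`.
#' @param dispersion Mean absolute read 3'-end offset from the cleavage
#'   site (two-sided geometric; 0 = exact).
#' @param artifact_rate Probability that a genomic run of >= 6 A spawns an
#'   internal-priming artifact cluster (default 0.15).
#' @param artifact_reads Poisson mean of reads per artifact (default 6).
#' @param aa_weights `"uniform"` or `"at_rich"` (Ile/Lys/Asn/Tyr enriched).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 60, cds_codons = c(150, 300), utr5_len = 40,
                           utr3_len = c(120, 220), intergenic = c(1100, 1600),
                           beta = c(0.3, 0.95),
                           expression = list(meanlog = log(60), sdlog = 0.5),
                           utr3_motif = "AATAAA", orf_motif = "AATAAA",
                           motif_gap = 18, cleavage_margin = 40,
                           orf_site_rate = 0.4, orf_usage = 0.15,
                           orf_sites_in = c("low_beta", "random"),
                           dispersion = 2, artifact_rate = 0.15,
                           artifact_reads = 6,
                           aa_weights = c("uniform", "at_rich")) {
  orf_sites_in <- match.arg(orf_sites_in)
  aa_weights <- match.arg(aa_weights)
  stopifnot(n_genes >= 1, all(beta >= 0 & beta <= 1),
            orf_site_rate >= 0, orf_site_rate <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            dispersion >= 0, motif_gap >= 0, all(cds_codons > 0),
            all(utr3_len > 0))
  structure(list(n_genes = n_genes, cds_codons = cds_codons, utr5_len = utr5_len,
                 utr3_len = utr3_len, intergenic = intergenic, beta = beta,
                 expression = expression, utr3_motif = toupper(utr3_motif),
                 orf_motif = toupper(orf_motif), motif_gap = motif_gap,
                 cleavage_margin = cleavage_margin, orf_site_rate = orf_site_rate,
                 orf_usage = orf_usage, orf_sites_in = orf_sites_in,
                 dispersion = dispersion, artifact_rate = artifact_rate,
                 artifact_reads = artifact_reads, aa_weights = aa_weights),
            class = "synthetic_spec")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Synonymous codon families split by wobble G/C vs A/T ending.
codon_families <- function() {
  gc <- genetic_code_table()
  gc <- gc[gc$aa != "*", ]
  split(gc$codon, gc$aa)
}

# Each family has one preferred codon (the first G/C-ending one, mimicking
# wobble-G/C-preferring genomes); beta is the probability a gene uses it,
# the remaining synonymous codons being drawn uniformly.
sample_cds <- function(n_aa, beta_g, fams, aa_pool) {
  aas <- sample(aa_pool$aa, n_aa, replace = TRUE, prob = aa_pool$w)
  codons <- vapply(aas, function(a) {
    f <- fams[[a]]
    if (length(f) == 1) return(f)
    gcend <- f[substr(f, 3, 3) %in% c("G", "C")]
    pref <- if (length(gcend)) gcend[1] else f[1]
    rest <- setdiff(f, pref)
    if (stats::runif(1) < beta_g) pref else rest[sample.int(length(rest), 1)]
  }, character(1), USE.NAMES = FALSE)
  paste(c("ATG", codons, "TAA"), collapse = "")
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Places non-overlapping single-exon genes on alternating strands of one
#' chromosome, each with a 5'UTR, a CDS sampled under the gene's wobble
#' G/C bias, and a 3'UTR carrying the implanted PAS motif upstream of the
#' true cleavage site. Selected genes additionally carry an in-frame ORF
#' PAS motif (written at a codon boundary) with a cleavage site
#' `motif_gap` nt downstream. Deterministic for a fixed spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list: `genome` (DNAStringSet), `annotation` (tibble in the
#'   [load_annotation()] schema, 1-kb 3'UTR extension applied), `truth`
#'   (per-site tibble: `gene_id`, `chrom`, `strand`, `class`,
#'   `cleavage_pos`, `expected_reads`, `motif_start`, `motif_end`,
#'   `beta`), `genes` (per-gene tibble with `beta` and `expression`).
#' @export
generate_genome <- function(spec, seed = 1) {
  with_seed_(seed, {
    fams <- codon_families()
    aa_pool <- if (spec$aa_weights == "at_rich") {
      w <- stats::setNames(rep(1, length(fams)), names(fams))
      w[c("I", "K", "N", "Y")] <- 3
      list(aa = names(fams), w = w / sum(w))
    } else {
      list(aa = names(fams), w = rep(1 / length(fams), length(fams)))
    }
    n <- spec$n_genes
    beta_g <- if (length(spec$beta) == 1) rep(spec$beta, n)
    else stats::runif(n, spec$beta[1], spec$beta[2])
    expr_g <- stats::rlnorm(n, spec$expression$meanlog, spec$expression$sdlog)
    orf_genes <- if (spec$orf_site_rate > 0) {
      k <- max(1L, floor(spec$orf_site_rate * n))
      if (spec$orf_sites_in == "low_beta") order(beta_g)[seq_len(k)]
      else sample.int(n, k)
    } else integer()

    chunks <- character(0)
    offset <- 0L
    ann <- list(); truth <- list()
    for (g in seq_len(n)) {
      spacer <- rand_seq(sample(spec$intergenic[1]:spec$intergenic[2], 1))
      n_aa <- sample(spec$cds_codons[1]:spec$cds_codons[2], 1)
      u3 <- sample(spec$utr3_len[1]:spec$utr3_len[2], 1)
      cds <- sample_cds(n_aa, beta_g[g], fams, aa_pool)
      utr3 <- rand_seq(u3)
      # implant UTR3 motif and fix the cleavage site geometry
      cleave_u3 <- u3 - spec$cleavage_margin  # 0-based index in UTR3
      m_end <- cleave_u3 - spec$motif_gap     # index of motif 3' end
      m_start <- m_end - nchar(spec$utr3_motif) + 1L
      stopifnot(m_start >= 0)
      substr(utr3, m_start + 1L, m_end + 1L) <- spec$utr3_motif
      orf_here <- g %in% orf_genes
      cds_len <- nchar(cds)
      if (orf_here) {
        j <- nchar(cds) %/% 6L  # codon index near mid-CDS
        substr(cds, 3L * j + 1L, 3L * j + nchar(spec$orf_motif)) <- spec$orf_motif
        orf_m_start_c <- 3L * j
        orf_m_end_c <- orf_m_start_c + nchar(spec$orf_motif) - 1L
        orf_cleave_c <- orf_m_end_c + spec$motif_gap
        stopifnot(orf_cleave_c < cds_len)
      }
      tx <- paste0(rand_seq(spec$utr5_len), cds, utr3)
      L <- nchar(tx)
      strand <- if (g %% 2L == 1L) "+" else "-"
      block <- if (strand == "+") tx else reverse_complement_chr(tx)
      gstart <- offset + nchar(spacer)
      chunks <- c(chunks, spacer, block)
      offset <- gstart + L
      # genomic coordinate of transcript offset t
      gpos <- function(t) if (strand == "+") gstart + t else gstart + L - 1L - t
      cds_g <- sort(c(gpos(spec$utr5_len), gpos(spec$utr5_len + cds_len - 1L)))
      gene_id <- sprintf("g%03d", g)
      ann[[g]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
        chrom = "chr1", strand = strand,
        cds = list(tibble::tibble(start = cds_g[1], end = cds_g[2] + 1L)),
        cds_start = cds_g[1], cds_end = cds_g[2] + 1L, cds_len = cds_len,
        frame_invalid = FALSE,
        tx_start = min(gpos(0L), gpos(L - 1L)),
        tx_end = max(gpos(0L), gpos(L - 1L)) + 1L
      )
      cleave_t <- spec$utr5_len + cds_len + cleave_u3
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_id = gene_id, chrom = "chr1", strand = strand, class = "UTR3",
        cleavage_pos = gpos(cleave_t), expected_reads = expr_g[g],
        motif_start = min(gpos(spec$utr5_len + cds_len + m_start),
                          gpos(spec$utr5_len + cds_len + m_end)),
        motif_end = max(gpos(spec$utr5_len + cds_len + m_start),
                        gpos(spec$utr5_len + cds_len + m_end)) + 1L,
        beta = beta_g[g]
      )
      if (orf_here) {
        truth[[length(truth) + 1L]] <- tibble::tibble(
          gene_id = gene_id, chrom = "chr1", strand = strand, class = "ORF",
          cleavage_pos = gpos(spec$utr5_len + orf_cleave_c),
          expected_reads = expr_g[g] * spec$orf_usage * ((1 - beta_g[g]) / 0.5)^2,
          motif_start = min(gpos(spec$utr5_len + orf_m_start_c),
                            gpos(spec$utr5_len + orf_m_end_c)),
          motif_end = max(gpos(spec$utr5_len + orf_m_start_c),
                          gpos(spec$utr5_len + orf_m_end_c)) + 1L,
          beta = beta_g[g]
        )
      }
    }
    chunks <- c(chunks, rand_seq(spec$intergenic[2]))
    genome <- Biostrings::DNAStringSet(paste(chunks, collapse = ""))
    names(genome) <- "chr1"
    chrom_len <- length(genome[[1]])
    annotation <- dplyr::bind_rows(ann) |>
      dplyr::mutate(
        utr3_start = ifelse(.data$strand == "+", .data$cds_end,
                            pmax(0L, .data$tx_start - 1000L)),
        utr3_end = ifelse(.data$strand == "+",
                          pmin(chrom_len, .data$tx_end + 1000L), .data$cds_start),
        utr5_start = ifelse(.data$strand == "+", .data$tx_start, .data$cds_end),
        utr5_end = ifelse(.data$strand == "+", .data$cds_start, .data$tx_end),
        introns = list(tibble::tibble(start = integer(), end = integer()))
      )
    list(genome = genome, annotation = annotation,
         truth = dplyr::bind_rows(truth),
         genes = tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                                beta = beta_g, expression = expr_g))
  })
}

#' Simulate 3'-end read coverage from ground truth
#'
#' Per site, the read count is Poisson with the site's expected reads; each
#' read's 3'-end is offset from the cleavage site by a two-sided geometric
#' displacement with mean `spec$dispersion`. Internal-priming artifact
#' reads are placed immediately upstream of genomic runs of six or more
#' strand-matched adenosines at rate `spec$artifact_rate`.
#'
#' @param genome,truth From [generate_genome()].
#' @param spec The same [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list: `coverage` (tibble `chrom`, `strand`, `pos`, `count`),
#'   `truth` (input truth plus the drawn `n_reads`), `artifacts` (tibble of
#'   artifact positions and counts).
#' @export
simulate_reads <- function(genome, truth, spec, seed = 1) {
  with_seed_(seed, {
    chrom_len <- length(genome[[1]])
    p_geom <- 1 / (1 + spec$dispersion)
    truth$n_reads <- stats::rpois(nrow(truth), truth$expected_reads)
    pos_list <- lapply(seq_len(nrow(truth)), function(i) {
      k <- truth$n_reads[i]
      if (k == 0) return(integer())
      mag <- if (spec$dispersion == 0) rep(0L, k) else stats::rgeom(k, p_geom)
      sgn <- sample(c(-1L, 1L), k, replace = TRUE)
      pmin(pmax(truth$cleavage_pos[i] + sgn * mag, 0L), chrom_len - 1L)
    })
    cov <- tibble::tibble(
      chrom = "chr1",
      strand = rep(truth$strand, lengths(pos_list)),
      pos = unlist(pos_list, use.names = FALSE)
    )
    # internal-priming artifacts at A-runs (plus) / T-runs (minus)
    seq1 <- as.character(genome[[1]])
    runs <- function(pattern, strand) {
      m <- gregexpr(pattern, seq1)[[1]]
      if (m[1] == -1) return(NULL)
      tibble::tibble(start = as.integer(m) - 1L,
                     len = attr(m, "match.length"), strand = strand)
    }
    ar <- dplyr::bind_rows(runs("A{6,}", "+"), runs("T{6,}", "-"))
    artifacts <- NULL
    if (!is.null(ar) && nrow(ar) > 0 && spec$artifact_rate > 0) {
      hit <- stats::runif(nrow(ar)) < spec$artifact_rate
      ar <- ar[hit, ]
      if (nrow(ar) > 0) {
        ar$count <- stats::rpois(nrow(ar), spec$artifact_reads)
        ar <- ar[ar$count > 0, ]
        if (nrow(ar) > 0) {
          ar$pos <- ifelse(ar$strand == "+", ar$start - 1L, ar$start + ar$len)
          ar <- ar[ar$pos >= 0 & ar$pos < chrom_len, ]
          artifacts <- tibble::tibble(chrom = "chr1", strand = ar$strand,
                                      pos = ar$pos, count = ar$count)
          cov <- dplyr::bind_rows(cov, tibble::tibble(
            chrom = "chr1",
            strand = rep(ar$strand, ar$count),
            pos = rep(ar$pos, ar$count)
          ))
        }
      }
    }
    coverage <- cov |>
      dplyr::count(.data$chrom, .data$strand, .data$pos, name = "count") |>
      dplyr::arrange(.data$chrom, .data$strand, .data$pos)
    list(coverage = coverage, truth = truth,
         artifacts = if (is.null(artifacts)) {
           tibble::tibble(chrom = character(), strand = character(),
                          pos = integer(), count = integer())
         } else artifacts)
  })
}

#' Write a synthetic dataset to standard files
#'
#' Emits FASTA, GTF (transcript/exon/CDS features, 1-based closed), two
#' per-strand bedGraph files, and a ground-truth TSV, all parseable by the
#' package's own readers.
#'
#' @param sim Output of [generate_genome()], optionally with a `coverage`
#'   element from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of written paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"), gtf = file.path(dir, "genes.gtf"),
             plus = file.path(dir, "ends_plus.bedgraph"),
             minus = file.path(dir, "ends_minus.bedgraph"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["fasta"])
  ann <- sim$annotation
  gtf_lines <- unlist(lapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', a$gene_id, a$transcript_id)
    feat <- function(type, s, e) {
      paste(a$chrom, "pcpatools", type, s + 1L, e, ".", a$strand, ".", attrs,
            sep = "\t")
    }
    cds <- a$cds[[1]]
    c(feat("transcript", a$tx_start, a$tx_end),
      feat("exon", a$tx_start, a$tx_end),
      unlist(lapply(seq_len(nrow(cds)), function(k) feat("CDS", cds$start[k], cds$end[k]))))
  }))
  writeLines(gtf_lines, paths["gtf"])
  if (!is.null(sim$coverage)) {
    write_end_coverage(sim$coverage, paths["plus"], paths["minus"])
  }
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Run the full pipeline on synthetic data and report recovery
#'
#' Generates a genome and reads from `spec`, applies the internal-priming
#' filter, calls and classifies poly(A) sites, and reports: site recall and
#' precision at the given tolerance, the discovery rank of the implanted
#' 3'UTR motif, and the Pearson/Spearman correlation between the log10
#' normalized ORF/3'UTR termination ratio and CBI across genes.
#'
#' Recall is measured over truth sites whose simulated read count reaches
#' the peak-calling threshold; precision over all called summits.
#'
#' @param spec A [synthetic_spec()] with at least 50 genes.
#' @param seed Integer seed.
#' @param tolerance Summit-matching tolerance in nt (default 5).
#' @param n_shuffles Shuffles for motif discovery (default 200 here; the
#'   discovery default is 1000).
#' @return A list of summary statistics and intermediate tables.
#' @export
end_to_end_recovery <- function(spec, seed = 1, tolerance = 5, n_shuffles = 200) {
  sim <- generate_genome(spec, seed = seed)
  reads <- simulate_reads(sim$genome, sim$truth, spec, seed = seed + 1L)
  filtered <- filter_end_coverage(reads$coverage, sim$genome)
  clusters <- cluster_ends(filtered)
  profile <- species_profile("ncrassa")
  sites <- classify_sites(clusters, sim$annotation, profile)

  truth <- reads$truth
  eligible <- truth[truth$n_reads >= 5, ]
  match_tol <- function(p, q) vapply(p, function(x) any(abs(q - x) <= tolerance), logical(1))
  by_cs <- function(df) split(df, paste(df$chrom, df$strand))
  recall_hits <- unlist(purrr::map(by_cs(eligible), function(tr) {
    called <- sites$summit_pos[sites$chrom == tr$chrom[1] & sites$strand == tr$strand[1]]
    match_tol(tr$cleavage_pos, called)
  }))
  precision_hits <- unlist(purrr::map(by_cs(sites), function(cl) {
    tru <- truth$cleavage_pos[truth$chrom == cl$chrom[1] & truth$strand == cl$strand[1]]
    match_tol(cl$summit_pos, tru)
  }))
  recall <- mean(recall_hits)
  precision <- if (length(precision_hits)) mean(precision_hits) else NA_real_

  utr3 <- dplyr::filter(sites, .data$class == "UTR3")
  win <- profile$pas_window_utr3
  iv <- t(mapply(function(p, s) offset_interval(p, s, win[1], win[2]),
                 utr3$summit_pos, utr3$strand))
  pas_windows <- fetch_windows(sim$genome, utr3$chrom, iv[, 1], iv[, 2], utr3$strand)
  pas_windows <- pas_windows[!is.na(pas_windows)]
  motifs <- discover_pas_hexamers(pas_windows, n_shuffles = n_shuffles, seed = seed + 2L)
  implanted_rank <- motifs$rank[match(spec$utr3_motif, motifs$hexamer_dna)]

  gene_tab <- gene_termination_table(sites, sim$annotation, library_size = sum(filtered$count))
  idx <- gene_codon_indices(sim$annotation, sim$genome)
  joined <- dplyr::inner_join(gene_tab, idx, by = "gene_id") |>
    dplyr::filter(is.finite(.data$log10_ratio))
  cor_p <- if (nrow(joined) >= 3) stats::cor(joined$log10_ratio, joined$cbi) else NA_real_
  cor_s <- if (nrow(joined) >= 3) {
    stats::cor(joined$log10_ratio, joined$cbi, method = "spearman")
  } else NA_real_

  list(recall = recall, precision = precision,
       n_truth = nrow(eligible), n_called = nrow(sites),
       implanted_motif = chartr("T", "U", spec$utr3_motif),
       implanted_rank = implanted_rank, motifs = motifs,
       cor_pearson = cor_p, cor_spearman = cor_s,
       gene_table = gene_tab, indices = idx, sites = sites)
}
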