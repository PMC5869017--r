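#' Species analysis presets
#'
#' Bundles the per-species analysis settings: the A-rich ORF PAS window
#' (N. crassa and mouse -30..-10 nt; S. pombe -25..-12 nt upstream of the
#' cleavage site), the 3'UTR PAS window, the PSSM window around the site,
#' the read protocol, the 1-kb 3'UTR extension, the 24-nt merge gap and
#' 5-read peak threshold, the internal-priming scan window, and the motif
#' selection rule for true/false PAS classification (top 40 discovered
#' 3'UTR hexamers, or the two canonical mammalian signals AAUAAA/AUUAAA
#' for mouse).
#'
#' @param name `"ncrassa"`, `"spombe"` or `"mouse"`.
#' @return A `species_profile` list.
#' @export
species_profile <- function(name = c("ncrassa", "spombe", "mouse")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    pas_window_utr3 = c(-30L, -10L),
    pssm_window = c(-30L, 10L),
    utr_extension = 1000L,
    merge_gap = 24L,
    min_reads = 5L,
    ip_window = 20L,
    rpm_expressed = 1,
    rpm_high = 10
  )
  extra <- switch(name,
    ncrassa = list(pas_window_orf = c(-30L, -10L), protocol = "2pseq",
                   motif_rule = list(kind = "top_n", n = 40)),
    spombe = list(pas_window_orf = c(-25L, -12L), protocol = "polya_seq",
                  motif_rule = list(kind = "top_n", n = 40)),
    mouse = list(pas_window_orf = c(-30L, -10L), protocol = "polya_seq",
                 motif_rule = list(kind = "named", motifs = c("AAUAAA", "AUUAAA")))
  )
  structure(c(base, extra), class = "species_profile")
}

#' Assemble and validate a pipeline run configuration
#'
#' @param genome Path to the genome FASTA (required).
#' @param gtf Path to the gene annotation (required).
#' @param coverage_plus,coverage_minus Per-strand bedGraph paths of read
#'   3'-ends (either these or `bed`).
#' @param bed Alternative 6-column BED of 1-base read 3'-ends.
#' @param species Species preset name (default `"ncrassa"`).
#' @param out_dir Output directory (required).
#' @param seed Seed for the stochastic stages (default 1).
#' @param n_shuffles Shuffled replicates in motif discovery (default 1000).
#' @return A validated `run_config` list.
#' @export
run_config <- function(genome, gtf, coverage_plus = NULL, coverage_minus = NULL,
                       bed = NULL, species = "ncrassa", out_dir, seed = 1,
                       n_shuffles = 1000) {
  if (missing(genome) || is.null(genome)) stop("config field missing: genome")
  if (missing(gtf) || is.null(gtf)) stop("config field missing: gtf")
  if (missing(out_dir) || is.null(out_dir)) stop("config field missing: out_dir")
  if (is.null(bed) && (is.null(coverage_plus) || is.null(coverage_minus))) {
    stop("config field missing: coverage_plus/coverage_minus (or bed)")
  }
  structure(list(genome = genome, gtf = gtf, coverage_plus = coverage_plus,
                 coverage_minus = coverage_minus, bed = bed, species = species,
                 out_dir = out_dir, seed = seed, n_shuffles = n_shuffles),
            class = "run_config")
}

stage_log <- function(report, stage, ...) {
  msg <- sprintf(...)
  message("[", stage, "] ", msg)
  report$log <- c(report$log, paste0("[", stage, "] ", msg))
  report
}

#' Run the full PCPA analysis pipeline
#'
#' Executes internal-priming filtering, poly(A)-site calling and
#' classification, the per-gene termination table, 3'UTR PAS hexamer
#' discovery, PSSM construction and PAS scoring, codon usage indices, and
#' true/false PAS classification with NCUF/NCPF/RCUF enrichment tables.
#' Every table is written as TSV (sites additionally as BED) into
#' `config$out_dir` along with the serialised configuration and a manifest
#' with md5 checksums; per-stage input/output counts are logged.
#'
#' @param config A [run_config()].
#' @return Invisibly, a report list with stage counts, result tables and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("genome", "gtf", "coverage_plus", "coverage_minus", "bed")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", f, " = ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- species_profile(config$species)
  report <- list(log = character(), files = character())
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(df, path)
    report$files <<- c(report$files, path)
    path
  }

  genome <- load_genome(config$genome)
  annotation <- load_annotation(config$gtf, utr_extension = profile$utr_extension,
                                genome = genome)
  report <- stage_log(report, "load", "%d chromosomes, %d genes",
                      length(genome), nrow(annotation))

  coverage <- load_end_coverage(plus = config$coverage_plus,
                                minus = config$coverage_minus, bed = config$bed)
  n_in <- sum(coverage$count)
  filtered <- filter_end_coverage(coverage, genome, window = profile$ip_window)
  disc <- attr(filtered, "discarded")
  report <- stage_log(report, "internal-priming", "reads in %d, discarded %d at %d positions",
                      n_in, disc$reads, disc$positions)

  clusters <- cluster_ends(filtered, merge_gap = profile$merge_gap,
                           min_reads = profile$min_reads)
  report <- stage_log(report, "call-sites", "%d peaks (>=%d reads); %d reads in dropped peaks",
                      nrow(clusters), profile$min_reads, attr(clusters, "dropped_reads"))
  sites <- classify_sites(clusters, annotation, profile)
  report <- stage_log(report, "classify", "%s",
                      paste(names(table(sites$class)), table(sites$class),
                            sep = "=", collapse = " "))
  emit(dplyr::mutate(sites, cds = NULL), "sites.tsv")
  bed <- sites |>
    dplyr::transmute(.data$chrom, start = .data$summit_pos, end = .data$summit_pos + 1L,
                     name = paste(dplyr::coalesce(.data$gene_id, "."), .data$class, sep = "|"),
                     score = .data$n_reads, .data$strand)
  emit(bed, "sites.bed")

  library_size <- sum(filtered$count)
  gene_tab <- gene_termination_table(sites, annotation, library_size)
  emit(gene_tab, "gene_termination.tsv")
  report <- stage_log(report, "gene-table", "%d genes with 3'UTR signal; %d expressed (RPM>%g)",
                      nrow(gene_tab), sum(gene_tab$rpm > profile$rpm_expressed),
                      profile$rpm_expressed)

  utr3 <- dplyr::filter(sites, .data$class == "UTR3")
  win <- profile$pas_window_utr3
  iv <- t(mapply(function(p, s) offset_interval(p, s, win[1], win[2]),
                 utr3$summit_pos, utr3$strand))
  pas_seqs <- fetch_windows(genome, utr3$chrom, iv[, 1], iv[, 2], utr3$strand)
  pas_seqs <- pas_seqs[!is.na(pas_seqs)]
  motifs <- discover_pas_hexamers(pas_seqs, n_shuffles = config$n_shuffles,
                                  seed = config$seed)
  emit(motifs, "pas_hexamers.tsv")
  report <- stage_log(report, "discover-motifs", "%d candidates tested, %d accepted",
                      nrow(motifs), sum(motifs$accepted))

  pw <- profile$pssm_window
  ivp <- t(mapply(function(p, s) offset_interval(p, s, pw[1], pw[2]),
                  utr3$summit_pos, utr3$strand))
  pssm_windows <- fetch_windows(genome, utr3$chrom, ivp[, 1], ivp[, 2], utr3$strand)
  pssm <- build_pssm(pssm_windows[!is.na(pssm_windows)], genome_background(genome),
                     offsets = pw)
  pssm_path <- file.path(config$out_dir, "pssm.tsv")
  readr::write_tsv(tibble::as_tibble(pssm$m, rownames = "base"), pssm_path)
  report$files <- c(report$files, pssm_path)
  iva <- t(mapply(function(p, s) offset_interval(p, s, pw[1], pw[2]),
                  sites$summit_pos, sites$strand))
  scores <- tibble::tibble(
    class = sites$class,
    score = pas_score(fetch_windows(genome, sites$chrom, iva[, 1], iva[, 2],
                                    sites$strand), pssm)
  )
  emit(scores, "pas_scores.tsv")

  usage <- codon_usage(annotation, genome)
  emit(usage, "codon_usage.tsv")
  indices <- gene_codon_indices(annotation, genome, usage)
  emit(indices, "gene_codon_indices.tsv")
  report <- stage_log(report, "codon-stats", "%d genes indexed", nrow(indices))

  motif_set <- if (profile$motif_rule$kind == "named") {
    profile$motif_rule$motifs
  } else {
    head(motifs$hexamer[motifs$accepted], profile$motif_rule$n)
  }
  if (length(motif_set) > 0) {
    occ <- classify_true_false_pas(motif_set, genome, sites, annotation)
    emit(occ, "pas_occurrences.tsv")
    report <- stage_log(report, "pas-truth", "%d occurrences: %d true, %d false",
                        nrow(occ), sum(occ$true_pas), sum(!occ$true_pas))
    orf_occ <- occ[occ$context == "ORF", ]
    if (any(orf_occ$true_pas) && any(!orf_occ$true_pas)) {
      emit(rcuf(occ, annotation, genome), "rcuf.tsv")
      emit(at_content_profile(occ[occ$context == "ORF", ], genome), "at_profile_orf.tsv")
    }
    report$occurrences <- occ
  }
  if (any(sites$class == "ORF" & !sites$ambiguous & !is.na(sites$gene_id))) {
    emit(ncuf(sites, annotation, genome, profile, seed = config$seed), "ncuf.tsv")
    ncpf_try <- try(ncpf(sites, annotation, genome, profile, seed = config$seed),
                    silent = TRUE)
    if (!inherits(ncpf_try, "try-error")) emit(ncpf_try, "ncpf.tsv")
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  writeLines(paste0(names(unclass(config)), ": ",
                    vapply(unclass(config), function(x) {
                      if (is.null(x)) "~" else paste(x, collapse = ",")
                    }, character(1))), cfg_path)
  report$files <- c(report$files, cfg_path)
  manifest <- tibble::tibble(file = basename(report$files),
                             md5 = unname(tools::md5sum(report$files)))
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  writeLines(report$log, file.path(config$out_dir, "run.log"))

  report$sites <- sites
  report$gene_table <- gene_tab
  report$motifs <- motifs
  report$pssm <- pssm
  report$indices <- indices
  report$manifest <- manifest
  invisible(report)
}

#' Empirical choice of the ORF PAS window by A/T content
#'
#' Scans candidate upstream windows around called ORF poly(A) summits and
#' reports each window's mean A/T content, compared with a distal upstream
#' control region (-60..-40 nt) by a paired t-test. The A/T-maximising
#' candidate is reported as `selected` only when it is significantly
#' enriched over the control; the selection is reported, never silently
#' applied.
#'
#' @param sites Classified sites; ORF summits are used.
#' @param genome Genome.
#' @param candidates List of length-2 offset vectors (defaults include
#'   -30..-10 and -25..-12).
#' @param control Control window offsets (default `c(-60, -40)`).
#' @return A tibble of candidates (`from`, `to`, `n`, `mean_at`,
#'   `control_at`, `p_value`); attributes `selected` (length-2 vector or
#'   `NULL`) and `message`.
#' @export
empirical_pas_window_test <- function(sites, genome,
                                      candidates = list(c(-30L, -10L), c(-25L, -12L),
                                                        c(-20L, -5L)),
                                      control = c(-60L, -40L)) {
  orf <- dplyr::filter(sites, .data$class == "ORF")
  if (nrow(orf) == 0) stop("no ORF sites to profile")
  at_frac <- function(win) {
    iv <- t(mapply(function(p, s) offset_interval(p, s, win[1], win[2]),
                   orf$summit_pos, orf$strand))
    seqs <- fetch_windows(genome, orf$chrom, iv[, 1], iv[, 2], orf$strand)
    ifelse(is.na(seqs), NA_real_,
           (stringr::str_count(seqs, "A") + stringr::str_count(seqs, "T")) / nchar(seqs))
  }
  ctrl <- at_frac(control)
  res <- purrr::map_dfr(candidates, function(win) {
    at <- at_frac(win)
    ok <- !is.na(at) & !is.na(ctrl)
    p <- if (sum(ok) >= 3 && stats::sd(at[ok] - ctrl[ok]) > 0) {
      stats::t.test(at[ok], ctrl[ok], paired = TRUE, alternative = "greater")$p.value
    } else NA_real_
    tibble::tibble(from = win[1], to = win[2], n = sum(ok),
                   mean_at = mean(at[ok]), control_at = mean(ctrl[ok]), p_value = p)
  })
  enriched <- which(!is.na(res$p_value) & res$p_value < 0.05 &
                      res$mean_at > res$control_at)
  if (length(enriched)) {
    best <- enriched[which.max(res$mean_at[enriched])]
    attr(res, "selected") <- c(res$from[best], res$to[best])
    attr(res, "message") <- sprintf("window %d..%d is A/T-enriched over control (p=%.3g)",
                                    res$from[best], res$to[best], res$p_value[best])
  } else {
    attr(res, "selected") <- NULL
    attr(res, "message") <- "no candidate window significantly A/T-enriched over control"
  }
  res
}
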