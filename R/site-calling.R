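#' Cluster read 3'-ends into poly(A)-site peaks
#'
#' Occupied positions on the same chromosome and strand are merged
#' transitively whenever at most `merge_gap` unoccupied bases separate two
#' consecutive occupied positions (the strand-aware merge of 1-base
#' intervals at distance `merge_gap`). Peaks with fewer than `min_reads`
#' total reads are dropped. The summit — the position with the highest
#' count, ties resolved to the 5'-most position in transcript orientation —
#' is the called poly(A) site.
#'
#' @param coverage A coverage tibble (`chrom`, `strand`, `pos`, `count`).
#' @param merge_gap Maximum gap between member positions (default 24 nt).
#' @param min_reads Minimum reads per retained peak (default 5).
#' @return A tibble: `chrom`, `strand`, `start`, `end` (0-based half-open
#'   span of occupied positions), `n_reads`, `summit_pos`, `summit_count`.
#'   Reads in dropped sub-threshold peaks are recorded in the
#'   `"dropped_reads"` attribute.
#' @export
cluster_ends <- function(coverage, merge_gap = 24, min_reads = 5) {
  if (nrow(coverage) == 0) {
    out <- tibble::tibble(chrom = character(), strand = character(),
                          start = integer(), end = integer(), n_reads = integer(),
                          summit_pos = integer(), summit_count = integer())
    attr(out, "dropped_reads") <- 0L
    return(out)
  }
  dat <- coverage |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos) |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(cl = cumsum(c(1L, as.integer(diff(.data$pos) > merge_gap + 1L)))) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$cl) |>
    dplyr::summarise(
      start = min(.data$pos),
      end = max(.data$pos) + 1L,
      n_reads = sum(.data$count),
      summit_pos = {
        best <- .data$pos[.data$count == max(.data$count)]
        if (.data$strand[1] == "+") min(best) else max(best)
      },
      summit_count = max(.data$count),
      .groups = "drop"
    ) |>
    dplyr::select(-"cl")
  kept <- dplyr::filter(dat, .data$n_reads >= min_reads)
  attr(kept, "dropped_reads") <- sum(dat$n_reads) - sum(kept$n_reads)
  kept
}

# Class of one summit relative to one gene; NA when the gene does not claim
# it. ORF requires the full PAS window inside the CDS exon union.
site_class_for_gene <- function(gene, summit, pas_window_orf) {
  if (summit >= gene$utr3_start && summit < gene$utr3_end) return("UTR3")
  w <- offset_interval(summit, gene$strand, pas_window_orf[1], pas_window_orf[2])
  in_cds <- summit >= gene$cds_start && summit < gene$cds_end &&
    !is.na(genomic_to_coding(gene, summit))
  if (in_cds && interval_in_cds(gene, w[1], w[2])) return("ORF")
  introns <- gene$introns[[1]]
  if (nrow(introns) &&
      any(summit >= introns$start & summit < introns$end)) return("intron")
  if (in_cds) return("intron")  # summit in CDS but PAS window not: falls through
  if (gene$utr5_start < gene$utr5_end &&
      summit >= gene$utr5_start && summit < gene$utr5_end) return("UTR5")
  NA_character_
}

#' Classify called poly(A) sites against gene annotation
#'
#' Each summit is assigned to a same-strand gene and one of the classes
#' 3'UTR, ORF, intron, 5'UTR or intergenic, with precedence
#' UTR3 > ORF > intron > UTR5 when several features of one gene could claim
#' it. An ORF call requires the species-specific PAS window (for example
#' -30..-10 nt upstream of the summit) to lie fully within the CDS exon
#' union; a summit inside coding sequence whose window crosses an intron
#' boundary is not an ORF site. Summits claimed by two or more distinct
#' same-strand genes keep their class but are flagged `ambiguous` and
#' excluded from gene-level statistics.
#'
#' @param clusters Output of [cluster_ends()].
#' @param annotation Annotation tibble from [load_annotation()].
#' @param profile A species profile from [species_profile()] (supplies the
#'   PAS windows).
#' @return The cluster tibble with `gene_id`, `class`, `ambiguous`,
#'   `pas_start`, `pas_end` (genomic interval of the A-rich PAS window).
#' @export
classify_sites <- function(clusters, annotation, profile = species_profile("ncrassa")) {
  n <- nrow(clusters)
  gene_id <- rep(NA_character_, n)
  class <- rep("intergenic", n)
  ambiguous <- rep(FALSE, n)
  pas_start <- pas_end <- rep(NA_integer_, n)
  prec <- c(UTR3 = 4L, ORF = 3L, intron = 2L, UTR5 = 1L)
  for (i in seq_len(n)) {
    cl <- clusters[i, ]
    cand <- annotation[annotation$chrom == cl$chrom & annotation$strand == cl$strand, ]
    if (nrow(cand) == 0) next
    # cheap territory pre-filter
    lo <- pmin(cand$utr3_start, cand$tx_start)
    hi <- pmax(cand$utr3_end, cand$tx_end)
    cand <- cand[cl$summit_pos >= lo & cl$summit_pos < hi, ]
    if (nrow(cand) == 0) next
    cls <- vapply(seq_len(nrow(cand)), function(k) {
      site_class_for_gene(cand[k, ], cl$summit_pos, profile$pas_window_orf)
    }, character(1))
    ok <- !is.na(cls)
    if (!any(ok)) next
    best <- max(prec[cls[ok]])
    winners <- which(ok)[prec[cls[ok]] == best]
    class[i] <- names(prec)[match(best, prec)]
    if (length(winners) > 1) {
      ambiguous[i] <- TRUE
    } else {
      gene_id[i] <- cand$gene_id[winners]
    }
    win <- if (class[i] == "ORF") profile$pas_window_orf else profile$pas_window_utr3
    w <- offset_interval(cl$summit_pos, cl$strand, win[1], win[2])
    pas_start[i] <- w[1]; pas_end[i] <- w[2]
  }
  dplyr::mutate(clusters, gene_id = gene_id, class = class,
                ambiguous = ambiguous, pas_start = pas_start, pas_end = pas_end)
}

#' Major 3'UTR poly(A) site per gene
#'
#' Among a gene's 3'UTR peaks, the one with the highest summit count is the
#' gene's major poly(A) site; ties go to the most 3' position in transcript
#' orientation.
#'
#' @param sites Classified sites from [classify_sites()].
#' @return One row per gene with at least one 3'UTR site.
#' @export
major_utr3_site <- function(sites) {
  sites |>
    dplyr::filter(.data$class == "UTR3", !.data$ambiguous, !is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$summit_count),
                   dplyr::desc(ifelse(.data$strand == "+", .data$summit_pos, -.data$summit_pos)),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Per-gene premature-termination table
#'
#' For every gene with 3'UTR poly(A) signal, reports ORF and 3'UTR read and
#' event (peak) counts, expression as RPM (reads per million filtered
#' poly(A)-supporting reads), and the normalized ORF/3'UTR termination
#' ratio `N_ORF * 1000 / (N_UTR3 * L)` where `L` is the CDS length in nt.
#' Reads are the default numerator/denominator; event counts are reported
#' alongside. Genes with no 3'UTR reads are omitted (the ratio is
#' undefined); ambiguous sites are excluded.
#'
#' @param sites Classified sites from [classify_sites()].
#' @param annotation Annotation tibble.
#' @param library_size Total filtered poly(A)-supporting reads (RPM
#'   denominator); must be positive.
#' @return A tibble: `gene_id`, `n_orf_reads`, `n_utr3_reads`,
#'   `n_orf_events`, `n_utr3_events`, `cds_len`, `rpm`, `ratio`,
#'   `log10_ratio` (`-Inf` when no ORF reads).
#' @export
gene_termination_table <- function(sites, annotation, library_size) {
  if (is.null(library_size) || library_size <= 0) stop("library_size must be positive")
  ok <- dplyr::filter(sites, !.data$ambiguous, !is.na(.data$gene_id))
  counts <- ok |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_orf_reads = sum(.data$n_reads[.data$class == "ORF"]),
      n_utr3_reads = sum(.data$n_reads[.data$class == "UTR3"]),
      n_orf_events = sum(.data$class == "ORF"),
      n_utr3_events = sum(.data$class == "UTR3"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_utr3_reads > 0)
  counts |>
    dplyr::left_join(dplyr::select(annotation, "gene_id", "cds_len"), by = "gene_id") |>
    dplyr::mutate(
      rpm = 1e6 * .data$n_utr3_reads / library_size,
      ratio = .data$n_orf_reads * 1000 / (.data$n_utr3_reads * .data$cds_len),
      log10_ratio = log10(.data$ratio)
    )
}
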