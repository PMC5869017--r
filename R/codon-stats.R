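split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0) return(character())
  substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = chartr("U", "T", names(gc)), aa = unname(gc))
}

#' Genome-wide codon usage and relative synonymous codon adaptiveness
#'
#' Counts codons over the spliced CDS of every frame-valid gene (terminal
#' stop codons dropped) and computes each codon's RSCA: its count divided
#' by the count of the most abundant synonymous codon, so the most abundant
#' codon of each family has RSCA 1. Codons never observed in a non-empty
#' family receive a half-count floor before normalisation so downstream
#' geometric means stay defined. Codons are classed by RSCA as optimal
#' (>= 0.9), rare (< 0.3) or random (otherwise); stop codons are excluded
#' from the indices.
#'
#' @param annotation Annotation tibble from [load_annotation()].
#' @param genome A genome from [load_genome()].
#' @return A `codon_usage` tibble: `codon`, `aa`, `count`, `rsca`, `class`.
#' @export
codon_usage <- function(annotation, genome) {
  genes <- dplyr::filter(annotation, !.data$frame_invalid)
  if (nrow(genes) == 0) stop("no frame-valid genes")
  codons <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    cds <- gene_cds_seq(genes[i, ], genome)
    cc <- split_codons(cds)
    if (length(cc) && cc[length(cc)] %in% STOP_CODONS) cc <- cc[-length(cc)]
    cc
  }), use.names = FALSE)
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  tab <- table(factor(codons, levels = genetic_code_table()$codon))
  compute_rsca(stats::setNames(as.integer(tab), names(tab)))
}

#' RSCA from a codon count vector
#'
#' @param counts Named integer vector of codon counts (DNA alphabet, 64
#'   codons or a subset; missing codons count 0).
#' @return A `codon_usage` tibble (see [codon_usage()]).
#' @export
compute_rsca <- function(counts) {
  gc <- genetic_code_table()
  cnt <- stats::setNames(rep(0, nrow(gc)), gc$codon)
  cnt[names(counts)] <- counts
  out <- gc |>
    dplyr::mutate(count = unname(cnt[.data$codon])) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      eff = ifelse(sum(.data$count) > 0 & .data$count == 0, 0.5, .data$count),
      rsca = dplyr::if_else(rep(sum(.data$count) > 0, dplyr::n()),
                            .data$eff / max(.data$eff, 1e-9), NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      rsca = ifelse(.data$aa == "*", NA_real_, .data$rsca),
      class = dplyr::case_when(
        is.na(.data$rsca) ~ NA_character_,
        .data$rsca >= 0.9 ~ "optimal",
        .data$rsca < 0.3 ~ "rare",
        TRUE ~ "random"
      )
    ) |>
    dplyr::select("codon", "aa", "count", "rsca", "class")
  class(out) <- c("codon_usage", class(out))
  out
}

#' Per-gene codon bias and codon adaptation indices
#'
#' For each frame-valid gene (terminal stop dropped, internal stop codons
#' excluded from the counts): CBI = (N_opt - N_ran) / (N_tot - N_ran) with
#' optimal/random/rare codon classes taken from the usage table's RSCA
#' thresholds (0.9 and 0.3), and CAI = the geometric mean of the RSCA
#' values of the gene's codons. CBI is `NA` (gene flagged) when
#' N_tot = N_ran.
#'
#' @param annotation Annotation tibble.
#' @param genome Genome.
#' @param usage A `codon_usage` table; computed from the same annotation
#'   and genome when omitted.
#' @return A tibble: `gene_id`, `n_opt`, `n_ran`, `n_rare`, `n_tot`,
#'   `cbi`, `cai`.
#' @export
gene_codon_indices <- function(annotation, genome, usage = NULL) {
  if (is.null(usage)) usage <- codon_usage(annotation, genome)
  cls <- stats::setNames(usage$class, usage$codon)
  lrsca <- stats::setNames(log(usage$rsca), usage$codon)
  genes <- dplyr::filter(annotation, !.data$frame_invalid)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    cds <- gene_cds_seq(genes[i, ], genome)
    cc <- split_codons(cds)
    if (length(cc) && cc[length(cc)] %in% STOP_CODONS) cc <- cc[-length(cc)]
    cc <- cc[!cc %in% STOP_CODONS & !grepl("N", cc, fixed = TRUE)]
    k <- cls[cc]
    n_opt <- sum(k == "optimal", na.rm = TRUE)
    n_ran <- sum(k == "random", na.rm = TRUE)
    n_rare <- sum(k == "rare", na.rm = TRUE)
    n_tot <- length(cc)
    tibble::tibble(
      gene_id = genes$gene_id[i],
      n_opt = n_opt, n_ran = n_ran, n_rare = n_rare, n_tot = n_tot,
      cbi = if (n_tot > n_ran) (n_opt - n_ran) / (n_tot - n_ran) else NA_real_,
      cai = exp(mean(lrsca[cc], na.rm = TRUE))
    )
  })
}

cds_to_codons <- function(cds) {
  cc <- split_codons(toupper(cds))
  if (length(cc) && cc[length(cc)] %in% STOP_CODONS) cc <- cc[-length(cc)]
  cc[!cc %in% STOP_CODONS & !grepl("N", cc, fixed = TRUE)]
}

#' Codon bias index of a single CDS
#'
#' CBI = (N_opt - N_ran) / (N_tot - N_ran), with codons classed as optimal
#' (RSCA >= 0.9), random (0.3 < RSCA < 0.9) or rare (RSCA < 0.3) by the
#' usage table. Terminal stop codons are dropped; `NA` when
#' N_tot = N_ran.
#'
#' @param cds An in-frame CDS sequence.
#' @param usage A `codon_usage` table from [codon_usage()] or
#'   [compute_rsca()].
#' @return CBI as a scalar.
#' @export
compute_cbi <- function(cds, usage) {
  cc <- cds_to_codons(cds)
  k <- stats::setNames(usage$class, usage$codon)[cc]
  n_opt <- sum(k == "optimal", na.rm = TRUE)
  n_ran <- sum(k == "random", na.rm = TRUE)
  n_tot <- length(cc)
  if (n_tot <= n_ran) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Codon adaptation index of a single CDS
#'
#' CAI is the geometric mean of the RSCA values of the gene's codons
#' (terminal stop dropped), computed in the log domain.
#'
#' @inheritParams compute_cbi
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(cds, usage) {
  cc <- cds_to_codons(cds)
  exp(mean(log(stats::setNames(usage$rsca, usage$codon)[cc]), na.rm = TRUE))
}

# Codon index ranges fully inside coding offsets [cfrom, cto] (inclusive).
codons_in_range <- function(cfrom, cto) {
  lo <- ceiling(cfrom / 3)
  hi <- floor((cto - 2) / 3)
  if (hi < lo) integer() else lo:hi
}

# Extract per-ORF-site foreground codon indices and gene context.
orf_site_codons <- function(sites, annotation, genome, profile) {
  orf <- dplyr::filter(sites, .data$class == "ORF", !.data$ambiguous, !is.na(.data$gene_id))
  orf <- dplyr::semi_join(orf, dplyr::filter(annotation, !.data$frame_invalid), by = "gene_id")
  if (nrow(orf) == 0) return(NULL)
  win <- profile$pas_window_orf
  purrr::map(seq_len(nrow(orf)), function(i) {
    g <- annotation[annotation$gene_id == orf$gene_id[i], ]
    cs <- genomic_to_coding(g, orf$summit_pos[i])
    if (is.na(cs)) return(NULL)
    idx <- codons_in_range(cs + win[1], cs + win[2])
    if (!length(idx)) return(NULL)
    cds_codons <- split_codons(gene_cds_seq(g, genome))
    if (length(cds_codons) && cds_codons[length(cds_codons)] %in% STOP_CODONS) {
      cds_codons <- cds_codons[-length(cds_codons)]
    }
    idx <- idx[idx < length(cds_codons)]
    if (!length(idx)) return(NULL)
    list(gene = g, cds_codons = cds_codons, idx = idx)
  }) |> purrr::compact()
}

count_units <- function(codon_vec, idx, pairs) {
  if (pairs) {
    if (length(idx) < 2) return(character())
    i <- idx[-length(idx)]
    keep <- idx[-1] == i + 1L
    paste(codon_vec[i[keep]], codon_vec[i[keep] + 1L], sep = "|")
  } else {
    codon_vec[idx]
  }
}

enrichment_table <- function(fg, bg) {
  units <- sort(unique(c(fg, bg)))
  fgc <- as.integer(table(factor(fg, levels = units)))
  bgc <- as.integer(table(factor(bg, levels = units)))
  fg_freq <- fgc / max(sum(fgc), 1L)
  bg_freq <- bgc / max(sum(bgc), 1L)
  tibble::tibble(
    unit = units,
    fg_count = fgc, bg_count = bgc,
    fg_freq = fg_freq, bg_freq = bg_freq,
    log2_ratio = ifelse(fgc > 0 & bgc > 0, log2(fg_freq / bg_freq), NA_real_),
    flag = dplyr::case_when(fgc == 0 ~ "zero_foreground",
                            bgc == 0 ~ "zero_background",
                            TRUE ~ "ok")
  )
}

#' Normalized codon usage frequency (NCUF) in ORF PAS regions
#'
#' For every called ORF poly(A) site on a frame-valid gene, the codons
#' lying fully inside the species PAS window (annotated frame) form the
#' foreground. The background pools, for each site, `n_random` stretches of
#' the same codon count sampled uniformly from in-frame positions of the
#' same ORF, excluding overlap with the PAS window. NCUF is the log2 ratio
#' of pooled foreground to background codon frequencies; entries with a
#' zero count on either side are flagged rather than reported as infinite.
#'
#' @param sites Classified sites from [classify_sites()].
#' @param annotation Annotation tibble.
#' @param genome Genome.
#' @param profile Species profile (supplies the ORF PAS window).
#' @param n_random Background stretches per site (default 10).
#' @param seed Optional seed for background sampling.
#' @return An enrichment tibble: `unit` (codon), `fg_count`, `bg_count`,
#'   `fg_freq`, `bg_freq`, `log2_ratio`, `flag`.
#' @export
ncuf <- function(sites, annotation, genome, profile = species_profile("ncrassa"),
                 n_random = 10, seed = NULL) {
  pas_codon_enrichment(sites, annotation, genome, profile, n_random, seed, pairs = FALSE)
}

#' Normalized codon-pair usage frequency (NCPF) in ORF PAS regions
#'
#' As [ncuf()], over adjacent in-frame codon pairs; sites whose PAS window
#' holds fewer than two full codons are skipped.
#'
#' @inheritParams ncuf
#' @return An enrichment tibble over codon pairs (`unit` = `"XXX|YYY"`).
#' @export
ncpf <- function(sites, annotation, genome, profile = species_profile("ncrassa"),
                 n_random = 10, seed = NULL) {
  pas_codon_enrichment(sites, annotation, genome, profile, n_random, seed, pairs = TRUE)
}

pas_codon_enrichment <- function(sites, annotation, genome, profile,
                                 n_random, seed, pairs) {
  ctx <- orf_site_codons(sites, annotation, genome, profile)
  if (is.null(ctx)) stop("no usable ORF poly(A) sites on frame-valid genes")
  with_seed_(seed, {
    fg <- character(); bg <- character()
    for (x in ctx) {
      k <- length(x$idx)
      if (pairs && k < 2) next
      n_cod <- length(x$cds_codons)
      fg <- c(fg, count_units(x$cds_codons, x$idx + 1L, pairs))
      starts <- setdiff(0:(n_cod - k), (x$idx[1] - k + 1):x$idx[k])
      starts <- starts[starts >= 0]
      if (!length(starts)) next
      for (s in sample(starts, n_random, replace = TRUE)) {
        bg <- c(bg, count_units(x$cds_codons, (s + 1):(s + k), pairs))
      }
    }
    if (!length(fg)) stop("no foreground codons in PAS windows")
    enrichment_table(fg, bg)
  })
}

#' Locate PAS motif occurrences and classify them as true or false PAS
#'
#' Finds strand-specific genomic occurrences of each motif, keeps those
#' fully inside the coding region (context `"ORF"`) or the 3'UTR search
#' interval (context `"UTR3"`) of a same-strand gene, and labels an
#' occurrence a true PAS when at least one called poly(A) summit lies 5-35
#' nt downstream of the motif's 3' end on the same strand; otherwise it is
#' a false PAS.
#'
#' @param motifs Character vector of hexamers (DNA or RNA alphabet).
#' @param genome Genome.
#' @param sites Called sites (any tibble with `chrom`, `strand`,
#'   `summit_pos`); all summits count as pA signal.
#' @param annotation Annotation tibble.
#' @param window Downstream distance window in nt (default `c(5, 35)`).
#' @return A tibble: `motif` (RNA), `motif_dna`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), `gene_id`, `context`, `true_pas`.
#' @export
classify_true_false_pas <- function(motifs, genome, sites, annotation,
                                    window = c(5, 35)) {
  motifs_dna <- unique(chartr("U", "T", toupper(motifs)))
  occ <- purrr::map_dfr(motifs_dna, function(m) {
    hits_p <- Biostrings::vmatchPattern(m, genome)
    hits_m <- Biostrings::vmatchPattern(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(m))), genome)
    both <- function(hits, strand) {
      purrr::map_dfr(names(genome), function(cm) {
        r <- hits[[cm]]
        if (length(r) == 0) return(NULL)
        tibble::tibble(motif_dna = m, chrom = cm, strand = strand,
                       start = IRanges::start(r) - 1L,
                       end = IRanges::end(r))
      })
    }
    dplyr::bind_rows(both(hits_p, "+"), both(hits_m, "-"))
  })
  if (nrow(occ) == 0) {
    return(tibble::tibble(motif = character(), motif_dna = character(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          gene_id = character(), context = character(),
                          true_pas = logical()))
  }
  # context assignment
  ctx <- purrr::map_dfr(seq_len(nrow(occ)), function(i) {
    o <- occ[i, ]
    cand <- annotation[annotation$chrom == o$chrom & annotation$strand == o$strand, ]
    for (k in seq_len(nrow(cand))) {
      g <- cand[k, ]
      if (interval_in_cds(g, o$start, o$end)) {
        return(tibble::tibble(gene_id = g$gene_id, context = "ORF"))
      }
      if (o$start >= g$utr3_start && o$end <= g$utr3_end) {
        return(tibble::tibble(gene_id = g$gene_id, context = "UTR3"))
      }
    }
    tibble::tibble(gene_id = NA_character_, context = NA_character_)
  })
  occ <- dplyr::bind_cols(occ, ctx) |> dplyr::filter(!is.na(.data$context))
  if (nrow(occ) == 0) {
    occ$true_pas <- logical()
    occ$motif <- character()
    return(dplyr::select(occ, "motif", "motif_dna", dplyr::everything()))
  }
  summits <- dplyr::distinct(sites, .data$chrom, .data$strand, .data$summit_pos)
  occ$true_pas <- vapply(seq_len(nrow(occ)), function(i) {
    o <- occ[i, ]
    ss <- summits$summit_pos[summits$chrom == o$chrom & summits$strand == o$strand]
    if (!length(ss)) return(FALSE)
    d <- if (o$strand == "+") ss - (o$end - 1L) else o$start - ss
    any(d >= window[1] & d <= window[2])
  }, logical(1))
  occ$motif <- chartr("T", "U", occ$motif_dna)
  dplyr::select(occ, "motif", "motif_dna", "chrom", "strand", "start", "end",
                "gene_id", "context", "true_pas")
}

#' Relative codon usage frequency (RCUF) around true vs false ORF PAS motifs
#'
#' Pools the in-frame codons lying fully within `flank_codons` codons
#' upstream and downstream of each ORF motif occurrence (clipped at CDS
#' bounds, motif codons excluded), separately for the true- and false-PAS
#' groups, and reports RCUF = log2(freq_true / freq_false) per codon.
#' Codons absent from either group are flagged rather than infinite.
#'
#' @param occurrences Output of [classify_true_false_pas()].
#' @param annotation Annotation tibble.
#' @param genome Genome.
#' @param flank_codons Codons taken on each side (default 15).
#' @return An enrichment tibble (`unit`, counts, freqs, `log2_ratio`
#'   = RCUF, `flag`).
#' @export
rcuf <- function(occurrences, annotation, genome, flank_codons = 15) {
  orf <- occurrences |>
    dplyr::filter(.data$context == "ORF") |>
    dplyr::semi_join(dplyr::filter(annotation, !.data$frame_invalid), by = "gene_id")
  if (!any(orf$true_pas) || !any(!orf$true_pas)) {
    stop("need both true- and false-PAS ORF occurrences")
  }
  flank_nt <- 3L * flank_codons
  grab <- function(rows) {
    unlist(purrr::map(seq_len(nrow(rows)), function(i) {
      o <- rows[i, ]
      g <- annotation[annotation$gene_id == o$gene_id, ]
      five <- if (o$strand == "+") o$start else o$end - 1L
      cstart <- genomic_to_coding(g, five)
      if (is.na(cstart)) return(character())
      cend <- cstart + (o$end - o$start) - 1L
      L <- g$cds_len
      cds_codons <- split_codons(gene_cds_seq(g, genome))
      idx <- c(codons_in_range(max(0L, cstart - flank_nt), cstart - 1L),
               codons_in_range(cend + 1L, min(L - 1L, cend + flank_nt)))
      idx <- idx[idx >= 0 & idx < length(cds_codons)]
      cds_codons[idx + 1L]
    }), use.names = FALSE)
  }
  enrichment_table(grab(orf[orf$true_pas, ]), grab(orf[!orf$true_pas, ]))
}

#' A/T content profile around true vs false PAS motifs
#'
#' Collects `flank_nt` of sequence on each side of every motif occurrence
#' (transcript orientation; edge-truncated windows excluded) and reports,
#' per truth class, the per-position A/U frequency across the motif and
#' flanks, plus each class's mean flank A/U content.
#'
#' @param occurrences Output of [classify_true_false_pas()].
#' @param genome Genome.
#' @param flank_nt Flank length in nt (default 80).
#' @return A tibble `true_pas`, `position` (0 = motif start), `A`, `C`,
#'   `G`, `U`, `at`; attribute `mean_at` holds the per-class mean flank
#'   A/U content.
#' @export
at_content_profile <- function(occurrences, genome, flank_nt = 80) {
  grab <- function(rows) {
    if (nrow(rows) == 0) return(NULL)
    seqs <- fetch_windows(genome, rows$chrom, rows$start - flank_nt,
                          rows$end + flank_nt, rows$strand)
    seqs[!is.na(seqs) & !grepl("N", seqs, fixed = TRUE)]
  }
  motif_len <- unique(occurrences$end - occurrences$start)
  out <- purrr::map_dfr(c(TRUE, FALSE), function(tp) {
    seqs <- grab(occurrences[occurrences$true_pas == tp, ])
    if (is.null(seqs) || length(seqs) == 0) return(NULL)
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs), as.prob = TRUE)
    pos <- seq(-flank_nt, flank_nt + motif_len[1] - 1L)
    getrow <- function(b) if (b %in% rownames(cm)) cm[b, ] else rep(0, length(pos))
    tibble::tibble(true_pas = tp, position = pos, A = getrow("A"), C = getrow("C"),
                   G = getrow("G"), U = getrow("T"), at = getrow("A") + getrow("T"))
  })
  means <- out |>
    dplyr::filter(.data$position < 0 | .data$position >= motif_len[1]) |>
    dplyr::group_by(.data$true_pas) |>
    dplyr::summarise(mean_at = mean(.data$at), .groups = "drop")
  attr(out, "mean_at") <- means
  out
}
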