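#' Load a genome FASTA as an uppercase DNAStringSet
#'
#' Chromosome names are taken from FASTA headers up to the first whitespace.
#' Sequences are uppercase-normalised; `N` bases are allowed.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Fetch a genomic window in transcript orientation
#'
#' Coordinates are 0-based half-open on the genome. On the minus strand the
#' window sequence is reverse-complemented so it reads 5' to 3' along the
#' transcript.
#'
#' @param genome A [Biostrings::DNAStringSet] from [load_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar (possibly empty when `start == end`).
#' @export
fetch_window <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start > end) {
    stop("window [", start, ",", end, ") out of bounds for ", chrom, " (length ", len, ")")
  }
  if (start == end) return("")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# Vectorised fetch for many same-length windows; returns NA for out-of-bounds.
fetch_windows <- function(genome, chrom, start, end, strand) {
  n <- length(start)
  out <- rep(NA_character_, n)
  for (cm in unique(chrom)) {
    len <- length(genome[[cm]])
    sel <- which(chrom == cm & start >= 0 & end <= len & start < end)
    if (!length(sel)) next
    v <- Biostrings::Views(genome[[cm]], start = start[sel] + 1L, end = end[sel])
    ss <- as.character(Biostrings::DNAStringSet(v))
    neg <- strand[sel] == "-"
    if (any(neg)) {
      ss[neg] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ss[neg])))
    }
    out[sel] <- ss
  }
  out
}

#' Load a gene annotation from GTF/GFF
#'
#' Builds one record per gene from its representative transcript (the
#' transcript with the longest total CDS; ties broken by lexicographically
#' smallest transcript id). GTF 1-based closed coordinates are converted to
#' the package-internal 0-based half-open convention. The 3'UTR search
#' interval runs from the CDS end to the annotated transcript 3' end plus
#' `utr_extension` nucleotides, clipped at chromosome bounds when `genome`
#' is supplied.
#'
#' Genes whose total CDS length is not divisible by 3 are flagged
#' `frame_invalid`; they are kept for site classification but excluded from
#' codon statistics.
#'
#' @param path GTF/GFF file with CDS features carrying gene/transcript ids.
#' @param utr_extension Nucleotides appended past the annotated 3' end
#'   (default 1000).
#' @param genome Optional genome for chromosome-bound clipping.
#' @return A tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `cds` (list of 0-based half-open interval tibbles,
#'   sorted by genomic start), `cds_start`, `cds_end`, `cds_len`,
#'   `frame_invalid`, `tx_start`, `tx_end`, `utr3_start`, `utr3_end`,
#'   `utr5_start`, `utr5_end`, `introns` (list column).
#' @export
load_annotation <- function(path, utr_extension = 1000, genome = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$type)) stop("annotation lacks a feature type column")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # convert 1-based closed to 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = if (!is.null(md$transcript_id)) as.character(md$transcript_id) else NA_character_
  )
  cds <- dplyr::filter(df, .data$type == "CDS")
  if (nrow(cds) == 0) stop("annotation contains no CDS features")
  cds$transcript_id <- dplyr::coalesce(cds$transcript_id, cds$gene_id)

  # transcript extents from transcript/mRNA/exon rows when present
  tx_feats <- dplyr::filter(df, .data$type %in% c("transcript", "mRNA", "exon"),
                            !is.na(.data$transcript_id))
  tx_bounds <- if (nrow(tx_feats)) {
    dplyr::summarise(dplyr::group_by(tx_feats, .data$transcript_id),
                     feat_start = min(.data$start), feat_end = max(.data$end),
                     .groups = "drop")
  } else {
    tibble::tibble(transcript_id = character(), feat_start = integer(), feat_end = integer())
  }

  per_tx <- cds |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    dplyr::summarise(
      cds = {
        s0 <- .data$start; e0 <- .data$end; o <- order(s0)
        list(tibble::tibble(start = s0[o], end = e0[o]))
      },
      cds_len = sum(.data$end - .data$start),
      cds_start = min(.data$start),
      cds_end = max(.data$end),
      .groups = "drop"
    )

  # representative transcript: longest CDS, tie -> smallest transcript id
  rep_tx <- per_tx |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$cds_len), .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::left_join(tx_bounds, by = "transcript_id") |>
    dplyr::mutate(
      tx_start = pmin(dplyr::coalesce(.data$feat_start, .data$cds_start), .data$cds_start),
      tx_end = pmax(dplyr::coalesce(.data$feat_end, .data$cds_end), .data$cds_end),
      frame_invalid = .data$cds_len %% 3L != 0L
    ) |>
    dplyr::select(-"feat_start", -"feat_end")

  chrom_len <- function(cm) {
    if (is.null(genome)) rep(.Machine$integer.max, length(cm))
    else unname(Biostrings::width(genome)[match(cm, names(genome))])
  }
  rep_tx <- rep_tx |>
    dplyr::mutate(
      utr3_start = ifelse(.data$strand == "+",
                          .data$cds_end,
                          pmax(0L, .data$tx_start - as.integer(utr_extension))),
      utr3_end = ifelse(.data$strand == "+",
                        pmin(chrom_len(.data$chrom), .data$tx_end + as.integer(utr_extension)),
                        .data$cds_start),
      utr5_start = ifelse(.data$strand == "+", .data$tx_start, .data$cds_end),
      utr5_end = ifelse(.data$strand == "+", .data$cds_start, .data$tx_end),
      introns = purrr::map(.data$cds, cds_gaps)
    )
  dplyr::select(rep_tx, "gene_id", "transcript_id", "chrom", "strand", "cds",
                "cds_start", "cds_end", "cds_len", "frame_invalid",
                "tx_start", "tx_end", "utr3_start", "utr3_end",
                "utr5_start", "utr5_end", "introns")
}

cds_gaps <- function(iv) {
  if (nrow(iv) < 2) return(tibble::tibble(start = integer(), end = integer()))
  tibble::tibble(start = iv$end[-nrow(iv)], end = iv$start[-1])
}

#' Load strand-specific read 3'-end coverage
#'
#' Accepts either a pair of per-strand bedGraph files or a single 6-column
#' BED of 1-base 3'-end intervals. bedGraph intervals wider than one base
#' are expanded to per-position counts; BED intervals wider than one base
#' are rejected, since a read has a single 3'-end position.
#'
#' @param plus,minus bedGraph paths for the plus and minus strand.
#' @param bed Alternative: one BED6 path with strand in column 6 and read
#'   count in the score column (score 0 or missing is taken as count 1).
#' @return A tibble `chrom`, `strand`, `pos` (0-based), `count`.
#' @export
load_end_coverage <- function(plus = NULL, minus = NULL, bed = NULL) {
  if (!is.null(bed)) {
    gr <- rtracklayer::import(bed, format = "BED")
    w <- GenomicRanges::width(gr)
    if (any(w != 1)) {
      stop("3'-end BED interval of length ", w[which(w != 1)[1]],
           " at record ", which(w != 1)[1], "; expected 1-base intervals")
    }
    score <- S4Vectors::mcols(gr)$score
    if (is.null(score)) score <- rep(1, length(gr))
    score[is.na(score) | score == 0] <- 1
    cov <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      pos = GenomicRanges::start(gr) - 1L,
      count = as.integer(score)
    )
  } else {
    if (is.null(plus) && is.null(minus)) stop("supply bedGraph paths or a BED file")
    read_bg <- function(path, strand) {
      if (is.null(path)) return(NULL)
      gr <- rtracklayer::import(path, format = "bedGraph")
      tibble::tibble(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = strand,
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        count = as.integer(S4Vectors::mcols(gr)$score)
      ) |>
        dplyr::filter(.data$count > 0) |>
        dplyr::reframe(chrom = rep(.data$chrom, .data$end - .data$start),
                       strand = rep(.data$strand, .data$end - .data$start),
                       pos = unlist(purrr::map2(.data$start, .data$end - 1L, seq.int),
                                    use.names = FALSE),
                       count = rep(.data$count, .data$end - .data$start))
    }
    cov <- dplyr::bind_rows(read_bg(plus, "+"), read_bg(minus, "-"))
  }
  cov |>
    dplyr::group_by(.data$chrom, .data$strand, .data$pos) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
}

#' Write 3'-end coverage as per-strand bedGraph files
#'
#' @param coverage A coverage tibble (`chrom`, `strand`, `pos`, `count`).
#' @param plus,minus Output bedGraph paths.
#' @return Invisibly, the input coverage.
#' @export
write_end_coverage <- function(coverage, plus, minus) {
  emit <- function(str, path) {
    d <- coverage |>
      dplyr::filter(.data$strand == str) |>
      dplyr::arrange(.data$chrom, .data$pos) |>
      dplyr::transmute(.data$chrom, start = .data$pos, end = .data$pos + 1L, .data$count)
    readr::write_tsv(d, path, col_names = FALSE)
  }
  emit("+", plus)
  emit("-", minus)
  invisible(coverage)
}

#' Extract the spliced CDS sequence of a gene in transcript orientation
#'
#' @param gene One row of the annotation tibble.
#' @param genome A genome from [load_genome()].
#' @return Character scalar: the CDS sequence 5' to 3'.
#' @export
gene_cds_seq <- function(gene, genome) {
  iv <- gene$cds[[1]]
  parts <- vapply(seq_len(nrow(iv)), function(i) {
    fetch_window(genome, gene$chrom, iv$start[i], iv$end[i], "+")
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
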