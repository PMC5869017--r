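#' Trim poly(A) tails from 2P-seq reads
#'
#' 2P-seq reads are primed from the poly(A) tail, so a genuine read carries a
#' run of at least `min_tail` consecutive adenosines (default 10). The
#' 5'-most qualifying A-run and everything distal to it (tail plus any
#' adapter remnant) are removed; reads with no qualifying run are discarded
#' as `no_tail`, and trimmed reads shorter than `min_length` (default 20 nt)
#' as `too_short`.
#'
#' @param reads Character vector of read sequences (A/C/G/T/N), or a data
#'   frame with a `seq` column.
#' @param min_tail Minimum length of the poly(A) run (default 10).
#' @param min_length Minimum retained read length after trimming (default 20).
#' @param tail_end `"3p"` (default) when the tail appears as a 3' A-run;
#'   `"5p_as_T"` when reads are sequenced from the priming side so the tail
#'   appears as a 5' T-run (the read is reverse-complemented before
#'   trimming and returned in transcript sense).
#' @return A tibble: `seq`, `retained`, `trimmed`, `tail_length`, `reason`
#'   (`NA`, `"no_tail"` or `"too_short"`).
#' @export
trim_polya_2pseq <- function(reads, min_tail = 10, min_length = 20,
                             tail_end = c("3p", "5p_as_T")) {
  tail_end <- match.arg(tail_end)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  work <- if (tail_end == "5p_as_T") reverse_complement_chr(seqs) else seqs
  m <- regexpr(sprintf("A{%d,}", as.integer(min_tail)), work)
  tail_len <- ifelse(m > 0, attr(m, "match.length"), 0L)
  trimmed <- ifelse(m > 0, substr(work, 1L, as.integer(m) - 1L), NA_character_)
  reason <- dplyr::case_when(
    m < 0 ~ "no_tail",
    nchar(trimmed) < min_length ~ "too_short",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    seq = seqs,
    retained = is.na(reason),
    trimmed = ifelse(is.na(reason), trimmed, NA_character_),
    tail_length = as.integer(ifelse(m > 0, tail_len, 0L)),
    reason = reason
  )
}

#' Trim terminal poly(A) stretches from poly(A)-seq reads
#'
#' The fission-yeast/mouse protocol keeps any read with at least one
#' adenosine at its 3' end, removes the terminal A-stretch, records its
#' length (used later by the untemplated-A filter), and discards reads
#' shorter than `min_length` after trimming. A 20-nt trimmed read is kept:
#' only reads strictly shorter than `min_length` are dropped.
#'
#' @inheritParams trim_polya_2pseq
#' @param min_tail Minimum terminal A-run (default 1).
#' @return A tibble as for [trim_polya_2pseq()].
#' @export
trim_polya_generic <- function(reads, min_tail = 1, min_length = 20) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  m <- regexpr("A+$", seqs)
  tail_len <- ifelse(m > 0, attr(m, "match.length"), 0L)
  trimmed <- ifelse(tail_len >= min_tail, substr(seqs, 1L, nchar(seqs) - tail_len), NA_character_)
  reason <- dplyr::case_when(
    tail_len < min_tail ~ "no_tail",
    nchar(trimmed) < min_length ~ "too_short",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    seq = seqs,
    retained = is.na(reason),
    trimmed = ifelse(is.na(reason), trimmed, NA_character_),
    tail_length = as.integer(tail_len),
    reason = reason
  )
}

# A-richness rule on a downstream sequence: >=6 consecutive A, or >=7 A in
# any 12-nt window fully inside the sequence.
a_rich_downstream <- function(s) {
  if (is.na(s) || nchar(s) == 0) return(FALSE)
  if (grepl("AAAAAA", s, fixed = TRUE)) return(TRUE)
  n <- nchar(s)
  if (n < 12) return(FALSE)
  isa <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == "A")
  cs <- c(0L, cumsum(isa))
  any(cs[13:(n + 1)] - cs[1:(n - 11)] >= 7)
}

#' Internal-priming filter for mapped read 3'-ends
#'
#' Oligo-dT priming on genomic A-runs produces false 3'-end signal. A
#' mapped 3'-end is discarded when the `window` nucleotides immediately
#' downstream of it (transcript orientation) contain six or more
#' consecutive adenosines, or seven or more adenosines within any 12-nt
#' window fully inside the region. Windows truncated by a chromosome end
#' are scanned as-is.
#'
#' @param ends A tibble with `chrom`, `strand`, `pos` (0-based position of
#'   the read 3'-end, the last transcribed base).
#' @param genome A genome from [load_genome()].
#' @param window Downstream scan length in nt (default 20).
#' @return The input tibble with a logical `keep` column.
#' @export
internal_priming_filter <- function(ends, genome, window = 20) {
  stopifnot(all(c("chrom", "strand", "pos") %in% names(ends)))
  chrom_len <- Biostrings::width(genome)[match(ends$chrom, names(genome))]
  gstart <- ifelse(ends$strand == "+", ends$pos + 1L, pmax(0L, ends$pos - as.integer(window)))
  gend <- ifelse(ends$strand == "+", pmin(chrom_len, ends$pos + 1L + as.integer(window)), ends$pos)
  gstart <- pmin(gstart, gend)
  down <- fetch_windows(genome, ends$chrom, gstart, gend, ends$strand)
  down[is.na(down)] <- ""
  dplyr::mutate(tibble::as_tibble(ends),
                keep = !vapply(down, a_rich_downstream, logical(1), USE.NAMES = FALSE))
}

#' Filter a 3'-end coverage table for internal-priming artifacts
#'
#' Applies [internal_priming_filter()] to every occupied position and drops
#' discarded positions. The counts removed are attached as the
#' `"discarded"` attribute (positions and reads).
#'
#' @inheritParams internal_priming_filter
#' @param coverage A coverage tibble from [load_end_coverage()].
#' @return The filtered coverage tibble.
#' @export
filter_end_coverage <- function(coverage, genome, window = 20) {
  flagged <- internal_priming_filter(coverage, genome, window)
  out <- dplyr::select(dplyr::filter(flagged, .data$keep), -"keep")
  dropped <- dplyr::filter(flagged, !.data$keep)
  attr(out, "discarded") <- list(positions = nrow(dropped), reads = sum(dropped$count))
  out
}

#' Untemplated-A filter for mapped poly(A)-seq reads
#'
#' A read's recorded poly(A)-tail length is compared with the genomic
#' adenosines immediately downstream of its mapped 3'-end: the read is kept
#' only when at least one tail A cannot be templated by the genome
#' (tail length exceeds the leading genomic A-run).
#'
#' @param tail_length Integer vector of recorded tail lengths.
#' @param genomic_downstream Character vector of genomic sequence starting
#'   immediately downstream of each mapped 3'-end (transcript orientation).
#' @return Logical vector: `TRUE` to keep.
#' @export
untemplated_a_filter <- function(tail_length, genomic_downstream) {
  m <- regexpr("^A*", genomic_downstream)
  templated <- attr(m, "match.length")
  tail_length > templated
}

#' Trim a FASTQ file and write retained reads plus a rejection log
#'
#' @param path_in Input FASTQ.
#' @param path_out Output FASTQ of trimmed, retained reads.
#' @param log_out TSV rejection log (`read_id`, `reason`); `NULL` to skip.
#' @param protocol `"2pseq"` (10-A tail rule) or `"generic"` (>=1 terminal A).
#' @param ... Passed to the trimming function.
#' @return Invisibly, the per-read trim tibble with a `read_id` column.
#' @export
trim_fastq <- function(path_in, path_out, log_out = NULL,
                       protocol = c("2pseq", "generic"), ...) {
  protocol <- match.arg(protocol)
  reads <- Biostrings::readDNAStringSet(path_in, format = "fastq", with.qualities = TRUE)
  res <- if (protocol == "2pseq") {
    trim_polya_2pseq(as.character(reads), ...)
  } else {
    trim_polya_generic(as.character(reads), ...)
  }
  res$read_id <- sub("\\s.*$", "", names(reads))
  kept <- which(res$retained)
  out <- Biostrings::DNAStringSet(res$trimmed[kept])
  names(out) <- res$read_id[kept]
  quals <- Biostrings::BStringSet(substr(as.character(S4Vectors::mcols(reads)$qualities[kept]),
                                         1L, nchar(res$trimmed[kept])))
  Biostrings::writeXStringSet(out, path_out, format = "fastq", qualities = quals)
  if (!is.null(log_out)) {
    readr::write_tsv(dplyr::select(dplyr::filter(res, !.data$retained), "read_id", "reason"),
                     log_out)
  }
  invisible(res)
}
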