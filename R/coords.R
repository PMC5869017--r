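# Strand-aware coordinate helpers shared by site classification and codon
# statistics. Internal convention: genomic 0-based half-open; "coding"
# coordinates are 0-based offsets along the spliced CDS in transcript
# orientation.

# Genomic half-open interval covering transcript-relative offsets
# [from, to] (inclusive) around an anchor position.
offset_interval <- function(anchor, strand, from, to) {
  stopifnot(from <= to)
  if (strand == "+") c(anchor + from, anchor + to + 1L)
  else c(anchor - to, anchor - from + 1L)
}

# Is [gstart, gend) fully contained in the union of CDS exon intervals?
interval_in_cds <- function(gene, gstart, gend) {
  iv <- gene$cds[[1]]
  covered <- 0L
  for (i in seq_len(nrow(iv))) {
    s <- max(gstart, iv$start[i]); e <- min(gend, iv$end[i])
    if (e > s) covered <- covered + (e - s)
  }
  covered == (gend - gstart)
}

# Map one genomic position to its coding offset (0-based along the spliced
# CDS, transcript orientation); NA when outside the CDS exon union.
genomic_to_coding <- function(gene, gpos) {
  iv <- gene$cds[[1]]
  widths <- iv$end - iv$start
  if (gene$strand == "+") {
    off <- 0L
    for (i in seq_len(nrow(iv))) {
      if (gpos >= iv$start[i] && gpos < iv$end[i]) return(off + (gpos - iv$start[i]))
      off <- off + widths[i]
    }
  } else {
    off <- 0L
    for (i in rev(seq_len(nrow(iv)))) {
      if (gpos >= iv$start[i] && gpos < iv$end[i]) return(off + (iv$end[i] - 1L - gpos))
      off <- off + widths[i]
    }
  }
  NA_integer_
}

# Inverse of genomic_to_coding.
coding_to_genomic <- function(gene, cpos) {
  iv <- gene$cds[[1]]
  widths <- iv$end - iv$start
  if (gene$strand == "+") {
    off <- 0L
    for (i in seq_len(nrow(iv))) {
      if (cpos < off + widths[i]) return(iv$start[i] + (cpos - off))
      off <- off + widths[i]
    }
  } else {
    off <- 0L
    for (i in rev(seq_len(nrow(iv)))) {
      if (cpos < off + widths[i]) return(iv$end[i] - 1L - (cpos - off))
      off <- off + widths[i]
    }
  }
  NA_integer_
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
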