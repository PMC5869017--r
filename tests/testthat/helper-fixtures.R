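# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (no calls into the code paths they check).

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(toupper(seqs))
  names(g) <- names(seqs)
  g
}

write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), path)
  path
}

# GTF writer for hand-built single- or multi-exon genes. `features` is a
# data.frame with chrom, type, start, end (1-based closed), strand,
# gene_id, transcript_id.
write_tmp_gtf <- function(features) {
  path <- tempfile(fileext = ".gtf")
  writeLines(apply(features, 1, function(r) {
    paste(r[["chrom"]], "test", r[["type"]], r[["start"]], r[["end"]], ".",
          r[["strand"]], ".",
          sprintf('gene_id "%s"; transcript_id "%s";', r[["gene_id"]], r[["transcript_id"]]),
          sep = "\t")
  }), path)
  path
}

# Independent reverse complement (chartr + rev, no Biostrings).
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]), collapse = "")
}

# Brute-force transitive merge of occupied positions: union-find over all
# pairs at distance <= merge_gap + 1 (i.e. <= merge_gap unoccupied bases
# between them).
oracle_cluster <- function(pos, count, merge_gap = 24, min_reads = 5, strand = "+") {
  n <- length(pos)
  if (n == 0) return(NULL)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(pos[i] - pos[j]) <= merge_gap + 1) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- lapply(unique(roots), function(r) {
    sel <- roots == r
    p <- pos[sel]; cnt <- count[sel]
    best <- p[cnt == max(cnt)]
    summit <- if (strand == "+") min(best) else max(best)
    data.frame(start = min(p), end = max(p) + 1L, n_reads = sum(cnt),
               summit_pos = summit, summit_count = max(cnt))
  })
  out <- do.call(rbind, out)
  out[out$n_reads >= min_reads, , drop = FALSE]
}

# Exhaustive A-richness scan: >= 6 consecutive A, or any fully-contained
# 12-mer with >= 7 A, checked by explicit loops.
oracle_a_rich <- function(s) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(x)
  run <- 0
  for (i in seq_len(n)) {
    run <- if (x[i] == "A") run + 1 else 0
    if (run >= 6) return(TRUE)
  }
  if (n >= 12) {
    for (i in 1:(n - 11)) {
      if (sum(x[i:(i + 11)] == "A") >= 7) return(TRUE)
    }
  }
  FALSE
}

dinuc_counts <- function(s) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(x) < 2) return(character())
  sort(paste0(x[-length(x)], x[-1]))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Minimal annotation row in the load_annotation() schema.
toy_gene <- function(gene_id, chrom, strand, cds_intervals, tx_start, tx_end,
                     utr_extension = 1000, chrom_len = NULL) {
  iv <- tibble::tibble(start = as.integer(cds_intervals[, 1]),
                       end = as.integer(cds_intervals[, 2]))
  iv <- iv[order(iv$start), ]
  cds_len <- sum(iv$end - iv$start)
  lim <- if (is.null(chrom_len)) .Machine$integer.max else chrom_len
  tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
    chrom = chrom, strand = strand, cds = list(iv),
    cds_start = min(iv$start), cds_end = max(iv$end), cds_len = cds_len,
    frame_invalid = cds_len %% 3L != 0L,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    utr3_start = if (strand == "+") max(iv$end) else max(0L, tx_start - utr_extension),
    utr3_end = if (strand == "+") min(lim, tx_end + utr_extension) else min(iv$start),
    utr5_start = if (strand == "+") as.integer(tx_start) else max(iv$end),
    utr5_end = if (strand == "+") min(iv$start) else as.integer(tx_end),
    introns = list(if (nrow(iv) < 2) tibble::tibble(start = integer(), end = integer())
                   else tibble::tibble(start = iv$end[-nrow(iv)], end = iv$start[-1]))
  )
}

coverage_tbl <- function(pos, count, strand = "+", chrom = "chr1") {
  tibble::tibble(chrom = chrom, strand = strand, pos = as.integer(pos),
                 count = as.integer(count))
}
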