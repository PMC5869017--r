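# Run expr with a temporarily-seeded RNG, restoring global RNG state after.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a nucleotide sequence while preserving its exact dinucleotide
#' counts, using the Altschul-Erickson Eulerian-path construction: a random
#' last-exit edge arborescence toward the terminal base guarantees every
#' arrangement of the remaining edges is a valid walk.
#'
#' @param sequence A single A/C/G/T string of length >= 2. `N` is rejected.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (nchar(sequence) < 2) stop("sequence must have length >= 2")
  if (grepl("N", sequence, fixed = TRUE)) stop("sequence contains N")
  with_seed_(seed, .dinuc_shuffle_one(sequence))
}

# All hexamer substrings of each sequence (list of unique 6-mers).
hexamer_sets <- function(seqs) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 6) return(character())
    unique(substring(s, 1:(n - 5), 6:n))
  })
}

#' Discover enriched PAS hexamers against a dinucleotide-shuffle null
#'
#' Iterative discovery over a set of uniform-length PAS-region sequences:
#' (1) find the hexamer present in the most remaining sequences; (2)
#' estimate its null presence rate from `n_shuffles` dinucleotide-shuffled
#' replicates of the remaining sequences; (3) accept it when its fold
#' enrichment over the null is at least `min_fold` and the binomial upper
#' tail probability of the observed presence count is below `alpha`; (4)
#' remove every sequence containing an accepted hexamer. Rejected hexamers
#' are masked from further candidacy without removing sequences. The loop
#' stops when the most common remaining hexamer is present in fewer than
#' `stop_fraction` of the remaining sequences.
#'
#' Occurrence is counted as sequence-level presence/absence, matching the
#' sequence-removal step; set `count_mode = "occurrence"` to count total
#' occurrences instead. Sequences containing `N` are excluded up front.
#'
#' Because each candidate is selected as the maximum over the 4^6 hexamer
#' space, a raw `p < alpha` cut is anti-conservative and accepts spurious
#' motifs from pure noise. With the default
#' `multiple_testing = "bonferroni"` the significance cut is
#' `alpha / 4096` and the binomial tail is evaluated against the upper
#' 97.5% Clopper-Pearson bound of the shuffle-estimated null rate, which
#' keeps the loop calibrated (no acceptances) on dinucleotide-matched
#' noise while leaving strongly enriched signals untouched.
#' `multiple_testing = "none"` applies the raw threshold to the point
#' estimate.
#'
#' @param pas_sequences Character vector of uniform-length sequences
#'   (length >= 6), DNA alphabet.
#' @param n_shuffles Shuffled replicates per candidate (default 1000).
#' @param min_fold Minimum fold enrichment (default 2).
#' @param alpha Binomial significance level (default 0.05).
#' @param stop_fraction Stop when the top hexamer's presence fraction among
#'   remaining sequences falls below this (default 0.01).
#' @param seed Optional seed.
#' @param count_mode `"presence"` (default) or `"occurrence"`.
#' @param multiple_testing `"bonferroni"` (default; selection-aware, see
#'   Details) or `"none"` (raw threshold).
#' @return A `hexamer_discovery` tibble of all tested candidates in
#'   discovery order: `hexamer` (RNA alphabet), `hexamer_dna`, `observed`,
#'   `n_sequences` (remaining when tested), `expected`, `fold`, `p_value`
#'   (the tail probability used for the decision), `rank` (among accepted,
#'   `NA` for rejected), `accepted`.
#' @export
discover_pas_hexamers <- function(pas_sequences, n_shuffles = 1000, min_fold = 2,
                                  alpha = 0.05, stop_fraction = 0.01, seed = NULL,
                                  count_mode = c("presence", "occurrence"),
                                  multiple_testing = c("bonferroni", "none")) {
  count_mode <- match.arg(count_mode)
  multiple_testing <- match.arg(multiple_testing)
  alpha_eff <- if (multiple_testing == "bonferroni") alpha / 4096 else alpha
  seqs <- pas_sequences[!grepl("N", pas_sequences, fixed = TRUE)]
  rows <- list()
  with_seed_(seed, {
    sets <- hexamer_sets(seqs)
    masked <- character()
    rank_next <- 1L
    while (length(seqs) > 0) {
      tab <- if (count_mode == "presence") {
        table(unlist(sets, use.names = FALSE))
      } else {
        table(unlist(lapply(seqs, function(s) {
          n <- nchar(s); substring(s, 1:(n - 5), 6:n)
        }), use.names = FALSE))
      }
      tab <- tab[!names(tab) %in% masked]
      if (length(tab) == 0) break
      top <- names(tab)[which.max(tab)]
      k <- as.integer(tab[top])
      nseq <- length(seqs)
      if (k / nseq < stop_fraction) break
      shuffled <- .dinuc_shuffle_many(seqs[sample.int(nseq, n_shuffles, replace = TRUE)])
      null_hits <- if (count_mode == "presence") {
        sum(grepl(top, shuffled, fixed = TRUE))
      } else {
        sum(vapply(shuffled, function(s) {
          n <- nchar(s); sum(substring(s, 1:(n - 5), 6:n) == top)
        }, numeric(1)))
      }
      p0 <- max(null_hits / n_shuffles, 0.5 / n_shuffles)
      expected <- p0 * nseq
      fold <- k / expected
      p0_test <- if (multiple_testing == "bonferroni") {
        # Clopper-Pearson upper bound guards against underestimated nulls
        stats::qbeta(0.975, null_hits + 1, n_shuffles - null_hits)
      } else p0
      p_value <- stats::pbinom(k - 1L, nseq, min(p0_test, 1), lower.tail = FALSE)
      accepted <- fold >= min_fold && p_value < alpha_eff
      rows[[length(rows) + 1L]] <- tibble::tibble(
        hexamer = chartr("T", "U", top), hexamer_dna = top,
        observed = k, n_sequences = nseq, expected = expected,
        fold = fold, p_value = p_value,
        rank = if (accepted) rank_next else NA_integer_,
        accepted = accepted
      )
      if (accepted) {
        rank_next <- rank_next + 1L
        has <- vapply(sets, function(h) top %in% h, logical(1))
        seqs <- seqs[!has]
        sets <- sets[!has]
      } else {
        masked <- c(masked, top)
      }
    }
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    hexamer = character(), hexamer_dna = character(), observed = integer(),
    n_sequences = integer(), expected = numeric(), fold = numeric(),
    p_value = numeric(), rank = integer(), accepted = logical()
  )
  class(out) <- c("hexamer_discovery", class(out))
  out
}

#' Genomic mononucleotide background frequencies
#'
#' @param genome A genome from [load_genome()].
#' @return Named numeric vector of A/C/G/T frequencies (N excluded),
#'   summing to 1.
#' @export
genome_background <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(genome, c("A", "C", "G", "T")))
  counts / sum(counts)
}

#' Build a position-specific scoring matrix around poly(A) sites
#'
#' Foreground frequencies `f[i,j]` come from column base counts over the
#' aligned windows (plus `pseudocount` per cell); the background `g[i]` is
#' the genomic mononucleotide frequency. Matrix entries are
#' `M[i,j] = log2(f[i,j] / g[i])`. Windows containing `N` are excluded.
#'
#' @param windows Character vector of uniform-length aligned sequences
#'   (transcript orientation).
#' @param background Named A/C/G/T frequency vector, e.g. from
#'   [genome_background()].
#' @param pseudocount Count added to each cell before normalising
#'   (default 0.5; 0 permits `-Inf` entries).
#' @param offsets Length-2 integer vector giving the transcript-relative
#'   offsets of the first and last window position (e.g. `c(-30, 10)` with
#'   0 at the poly(A) site); defaults to `0:(width-1)`.
#' @return A `pas_pssm` object: list with `m` (4 x width matrix, rows
#'   A/C/G/T), `f`, `g`, `pseudocount`, `n_sequences`, `positions`.
#' @export
build_pssm <- function(windows, background, pseudocount = 0.5, offsets = NULL) {
  windows <- windows[!is.na(windows) & !grepl("N", windows, fixed = TRUE)]
  if (length(windows) == 0) stop("no usable (N-free) windows to build a PSSM")
  w <- unique(nchar(windows))
  if (length(w) != 1) stop("windows must have uniform length")
  positions <- if (is.null(offsets)) 0:(w - 1) else seq(offsets[1], offsets[2])
  if (length(positions) != w) stop("offsets do not match window width")
  counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  bases <- c("A", "C", "G", "T")
  cnt <- matrix(0, 4, w, dimnames = list(bases, positions))
  for (b in bases) if (b %in% rownames(counts)) cnt[b, ] <- counts[b, ]
  f <- sweep(cnt + pseudocount, 2, colSums(cnt + pseudocount), "/")
  g <- background[bases] / sum(background[bases])
  m <- log2(sweep(f, 1, g, "/"))
  structure(list(m = m, f = f, g = g, pseudocount = pseudocount,
                 n_sequences = length(windows), positions = positions),
            class = "pas_pssm")
}

#' @export
print.pas_pssm <- function(x, ...) {
  cat("PAS position-specific scoring matrix\n")
  cat("  positions:", x$positions[1], "..", x$positions[length(x$positions)],
      " (", length(x$positions), " nt)\n", sep = "")
  cat("  built from", x$n_sequences, "windows, pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Score sequence windows with a PAS PSSM
#'
#' The PAS score of a window is the sum over positions of the matrix entry
#' for the observed base, `S = sum_j M[base_j, j]`. Windows containing `N`
#' score `NA` and are excluded from downstream summaries.
#'
#' @param windows Character vector with width equal to the PSSM width.
#' @param pssm A `pas_pssm` from [build_pssm()].
#' @return Numeric vector of scores.
#' @export
pas_score <- function(windows, pssm) {
  w <- length(pssm$positions)
  vapply(windows, function(s) {
    if (is.na(s) || nchar(s) != w) {
      if (!is.na(s)) stop("window length ", nchar(s), " does not match PSSM width ", w)
      return(NA_real_)
    }
    b <- match(strsplit(s, "", fixed = TRUE)[[1]], rownames(pssm$m))
    if (anyNA(b)) return(NA_real_)
    sum(pssm$m[cbind(b, seq_len(w))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Positional nucleotide composition around poly(A) sites
#'
#' Aligns windows from `upstream` nt before to `downstream` nt after each
#' summit (position 0 is the mapped 3' end) in transcript orientation and
#' reports per-position base frequencies, with T reported as U. Windows
#' truncated by a chromosome end or containing `N` are excluded.
#'
#' @param sites Tibble with `chrom`, `strand`, `summit_pos`.
#' @param genome A genome from [load_genome()].
#' @param upstream,downstream Window half-widths in nt.
#' @return A `nucleotide_profile` tibble: `position`, `A`, `C`, `G`, `U`;
#'   attribute `n_windows` gives the number of windows used.
#' @export
nucleotide_profile <- function(sites, genome, upstream = 50, downstream = 50) {
  iv <- t(mapply(function(p, s) offset_interval(p, s, -upstream, downstream),
                 sites$summit_pos, sites$strand))
  seqs <- fetch_windows(genome, sites$chrom, iv[, 1], iv[, 2], sites$strand)
  seqs <- seqs[!is.na(seqs) & !grepl("N", seqs, fixed = TRUE)]
  if (length(seqs) == 0) stop("no usable windows for nucleotide profile")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs), as.prob = TRUE)
  pos <- seq(-upstream, downstream)
  getrow <- function(b) if (b %in% rownames(cm)) cm[b, ] else rep(0, length(pos))
  out <- tibble::tibble(position = pos, A = getrow("A"), C = getrow("C"),
                        G = getrow("G"), U = getrow("T"))
  attr(out, "n_windows") <- length(seqs)
  class(out) <- c("nucleotide_profile", class(out))
  out
}
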