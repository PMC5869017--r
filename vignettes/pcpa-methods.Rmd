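---
title: "Methods: poly(A)-site calling, PAS motif discovery, and codon usage statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A)-site calling, PAS motif discovery, and codon usage statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpatools)
```

# The problem

Cleavage and polyadenylation normally happen in a gene's 3'UTR, guided by an
A/U-rich polyadenylation signal (PAS, canonically AAUAAA) ~10-30 nt upstream
of the cleavage site. Premature cleavage and polyadenylation (PCPA) — the
same event inside a coding region — truncates the transcript. Because
synonymous codon choice changes the nucleotide composition of an ORF,
rare-codon-rich (A/U-rich) coding sequence can harbour PAS-like elements and
terminate early. `pcpatools` implements the computational side of testing
this idea genome-wide: from strand-specific read 3'-end positions to called
poly(A) sites, discovered PAS hexamers, PAS scores, and codon usage
statistics around termination sites.

# Pipeline model and assumptions

**Read filters.** Two protocols are supported. Poly(A)-tail-primed 3'-end
reads (2P-seq) must carry a run of at least 10 consecutive adenosines; the
run and everything distal to it are trimmed, and trimmed reads shorter than
20 nt are discarded. The generic poly(A)-seq protocol keeps reads with at
least one terminal A, records the tail length, and applies the same 20-nt
floor. After mapping, two artifact filters act on 3'-end positions:

* *Internal priming*: a 3'-end is discarded when the 20 nt immediately
  downstream (transcript orientation) contain ≥6 consecutive A, or ≥7 A in
  any 12-nt window fully inside the region. Windows truncated by a
  chromosome end are scanned as-is — a conservative choice that only
  affects chromosome-terminal positions.
* *Untemplated A* (poly(A)-seq only): a read is kept only when its recorded
  tail is longer than the genomic A-run at its mapped 3' end, so at least
  one tail adenosine cannot be templated.

**Site calling.** Occupied 3'-end positions on one chromosome and strand
are merged transitively whenever at most 24 unoccupied bases separate two
occupied positions (the strand-aware merge of 1-base intervals at distance
24, i.e. the semantics of `bedtools merge -s -d 24`). Peaks with fewer than
5 reads are dropped. The summit — the position with the highest count — is
the called poly(A) site; ties break to the 5'-most position in transcript
orientation, a deterministic choice on which the source protocol is silent.

**Classification.** Because reference 3'UTR annotations are unreliable,
each gene's 3'UTR search interval runs from the CDS end to the annotated
transcript 3' end plus a 1-kb extension. A summit classifies with
precedence UTR3 > ORF > intron > UTR5 > intergenic; the ORF class
additionally requires the species PAS window (N. crassa and mouse
-30..-10 nt, S. pombe -25..-12 nt upstream of the summit) to lie fully
within the CDS exon union, so a window crossing an intron boundary denies
the ORF call. Summits claimable by two or more same-strand genes keep a
class but are flagged ambiguous and excluded from gene-level statistics.
One representative transcript per gene is used (longest CDS, ties by
lexicographic transcript id); isoform handling is not specified by the
source protocol, so the choice is deterministic and documented. The
`empirical_pas_window_test()` helper reproduces the empirical window
choice: it reports the mean A/T content of candidate windows around ORF
summits against a distal upstream control and only *reports* the A/T
maximising window, never silently applies it.

**Per-gene termination.** For every gene with 3'UTR signal the normalized
ORF/3'UTR termination ratio is
$$\mathrm{ratio} = \frac{N_{\mathrm{ORF}} \times 1000}{N_{\mathrm{3'UTR}} \times L},$$
with read counts by default (event counts are reported alongside) and $L$
the CDS length in nt. Genes with no 3'UTR reads are omitted rather than
given an arbitrary value. Expression is RPM over all filtered
poly(A)-supporting reads.

# PAS hexamer discovery

Discovery iterates over uniform-length PAS-window sequences: find the
hexamer present in the most remaining sequences, estimate its null presence
rate from 1000 dinucleotide-preserving shuffles of the remaining sequences,
accept it when fold enrichment is at least 2 and the binomial upper-tail
probability of the observed presence count is significant, remove all
sequences containing an accepted hexamer, and stop when the top hexamer
falls below 1% presence. Rejected hexamers are masked from future
candidacy without sequence removal, keeping rejection side-effect-free.

The shuffle is the Altschul-Erickson Eulerian-walk construction
(implemented in C++; exact dinucleotide counts preserved, first and last
base fixed). Counting is sequence-level presence/absence, matching the
removal step; total-occurrence counting is available as a switch.

**Why the significance cut is selection-aware.** Each candidate is the
*maximum* over the $4^6 = 4096$ hexamer space, so comparing its raw
binomial tail with $\alpha = 0.05$ is anti-conservative: on
dinucleotide-matched noise (1000 random 21-mers) the top hexamer typically
appears in ~1.2% of sequences against a ~0.4% null, passing both the
2-fold and the raw $p < 0.05$ cut by selection alone. The package's
default decision rule therefore (i) Bonferroni-corrects $\alpha$ over the
4096-hexamer candidate space and (ii) evaluates the binomial tail against
the Clopper-Pearson 97.5% upper bound of the shuffle-estimated null rate,
which guards against the null rate being underestimated from finitely many
shuffles. Under this rule a pure-noise run accepts nothing (20/20 clean
calibration runs in the test suite) while a genuinely implanted motif at
40% prevalence is still accepted at rank 1 with fold ≈ 9 and vanishing
p-value. `multiple_testing = "none"` restores the raw rule for comparison.

# PAS score

From windows aligned around 3'UTR poly(A) sites (-30..+10 nt), the PSSM is
$M_{ij} = \log_2(f_{ij} / g_i)$ with $f_{ij}$ the foreground frequency of
base $i$ at position $j$ and $g_i$ the genomic mononucleotide frequency. A
pseudocount of 0.5 per cell keeps entries finite (a pseudocount of 0 is
allowed and reproduces closed-form checks). The PAS score of a window is
the positional sum $S = \sum_j m_{i_j, j}$; windows containing N score
`NA` and are excluded from summaries.

# Codon usage statistics

* **RSCA**: each codon's count divided by the most abundant synonymous
  codon's count, so family maxima are 1. Codons never observed in a
  non-empty family receive a half-count floor before normalisation so the
  geometric mean underlying CAI stays defined; stop codons carry no RSCA.
* **CBI**: $(N_{opt} - N_{ran}) / (N_{tot} - N_{ran})$ with optimal
  (RSCA ≥ 0.9), random (0.3 < RSCA < 0.9) and rare (RSCA < 0.3) classes;
  RSCA exactly 0.3 falls in the random class. Undefined (flagged) when
  $N_{tot} = N_{ran}$.
* **CAI**: geometric mean of RSCA over a gene's codons, computed in the
  log domain.
* **NCUF / NCPF**: codon (pair) frequencies pooled over the in-frame
  codons lying fully inside each ORF PAS window, normalised to 10
  same-length in-frame stretches per site sampled uniformly from the same
  ORF (overlap with the PAS window excluded; sampling seeded). Log2
  ratios with a zero numerator or denominator are flagged missing rather
  than floored — missingness is more honest than an arbitrary pseudocount.
* **True/false PAS**: a motif occurrence is a true PAS when a called
  summit lies 5-35 nt downstream of its 3' end on the same strand; ORF
  occurrences must lie fully inside coding sequence, 3'UTR occurrences
  fully inside the 3'UTR search interval.
* **RCUF**: log2 ratio of codon frequencies in the 15-codon flanks of
  true vs false ORF PAS motifs, clipped at CDS bounds.

Genes whose CDS length is not divisible by 3 are excluded from all codon
statistics but retained for site classification.

# The synthetic data generator

The generator produces the study conditions every test runs under: one
chromosome of non-overlapping single-exon genes on alternating strands
(default 60 genes, 150-300 codons, ~40 nt 5'UTRs, 120-220 nt 3'UTRs),
kilobase-scale intergenic spacing (1100-1600 nt) so that 3'UTR search
intervals with their 1-kb extension cannot collide with neighbouring
genes, and lognormal per-gene expression (meanlog log 60, sdlog 0.5).

Codon choice models a wobble-G/C-preferring genome: each synonymous family
has one preferred codon (its first G/C-ending member) used with per-gene
probability $\beta$, the remainder drawn uniformly. $\beta$ is uniform in
[0.3, 0.95] per gene, giving a net genome-wide G/C wobble preference (as
in Neurospora or mouse) so that RSCA classes are stable and per-gene CBI
tracks $\beta$; at $\beta$ mean 0.5 the preferred codon of a two-fold
family is a coin flip and CBI decouples from the bias parameter, which is
not the regime the analysis assumes.

Every gene carries an AAUAAA signal ending 18 nt upstream of its 3'UTR
cleavage site — the canonical geometry in which a PAS sits inside the
-30..-10 A-rich region and within the 5-35 nt true-PAS window. The 40% of
genes with the lowest $\beta$ additionally carry an in-frame ORF AAUAAA
(written at a codon boundary) with a cleavage site 18 nt downstream; its
usage scales as $\mathrm{expression} \times 0.15 \times ((1-\beta)/0.5)^2$,
encoding the dose dependence of premature termination on rare-codon
content. Read 3'-ends disperse around each cleavage site by a two-sided
geometric displacement with mean 2 nt (0 = exact); internal-priming
artifacts appear immediately upstream of genomic runs of ≥6 strand-matched
adenosines at rate 0.15 with Poisson(6) reads, and are removed by the
internal-priming filter with certainty by construction.

What the generator does **not** emulate: introns (classification handles
them, exercised by hand-built fixtures), overlapping genes, alternative
isoforms, sequencing error, non-uniform amino-acid composition (an
AT-rich preset exists but is off by default), and chromatin- or
expression-coupled effects. Passing tests therefore demonstrate that the
statistics behave as specified under their own assumptions, not that real
libraries are free of mapping or annotation artifacts.

Problem sizes in the test suite and acceptance script are desk-scale by
design: 60-gene genomes (~130 kb), ~4500 reads, 1000 discovery sequences,
20 null calibration runs, 5 correlation seeds. These sizes make every
property re-checkable in minutes while keeping Monte-Carlo noise well
inside the asserted tolerances.

# Numerical choices

* Coordinates are 0-based half-open internally; GTF input is 1-based
  closed; BED output 0-based half-open.
* Summit ties: 5'-most in transcript orientation. Major-site ties: most
  3' site wins.
* Windows truncated by chromosome ends are excluded from profiles and
  PSSMs; N-containing windows are excluded from motif counting, PSSM
  construction, and scoring.
* The shuffle-estimated null rate is floored at half an event per shuffle
  set so fold enrichment stays finite.
* All stochastic stages (shuffles, background sampling, simulation) take
  explicit seeds and restore the caller's RNG state.

# Known limitations

* The normalized ratio is undefined for genes without 3'UTR signal; such
  genes are dropped, which biases gene-level summaries toward expressed
  genes (matching the RPM > 1 / RPM > 10 expression filters).
* ORF PAS codon statistics require frame-valid single-frame annotations;
  programmed frameshifts are not modelled.
* The discovery loop tests hexamers only; longer or degenerate motifs are
  out of scope.
* With very few input sequences the 1%-presence stop rule can halt
  discovery after the first motif; discovery is intended for hundreds to
  thousands of PAS windows.
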