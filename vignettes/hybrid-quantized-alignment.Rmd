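---
title: "Hybrid quantized alignment for structural-variant detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid quantized alignment for structural-variant detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hqalign)
```

## The model

Nanopore sequencing reads a DNA strand by measuring ionic current while the
strand translocates the pore. Each measured level is determined not by one
base but by a window of `Q` consecutive bases (here `Q = 6`), and many
distinct Q-mers produce nearly indistinguishable median currents. Basecalling
errors are therefore *biased*: a miscalled region tends to be a different
nucleotide sequence with a near-identical current profile. An aligner that
scores in nucleotide space treats these confusions as ordinary independent
errors; an aligner that scores in *current space* sees through them.

`hqalign` exploits this with a quantized representation. The Q-mer map (a
table of median currents per Q-mer, `qmer_map()`) translates a nucleotide
sequence of length `n` into `n - Q + 1` current levels, which are hard
thresholded into `L` levels (`L = 3`, the ternary "HQ3" mode, by default).
Two sequences whose windows fall into the same current bins become the *same*
quantized sequence, so current-confusable basecalling errors vanish in the
transformed space.

The pipeline is two-staged:

1. **Stage 1 (nucleotide).** The read is aligned to the genome with an
   ordinary minimizer seed–chain–extend pass. Each retained chain defines a
   region of interest `[s, e)` with aligned fraction `f = (e - s)/n`.
2. **Extension.** Each region is widened by `b = round(max(1 - f, 0.25) n)`
   bases on both sides — a quarter read length for well-anchored reads,
   growing as the stage-1 anchoring weakens — and overlapping regions merge.
3. **Stage 2 (quantized).** The quantized read *and its separately quantized
   reverse complement* are aligned to the quantized genome restricted to the
   extended regions. The reverse complement must be a second query because
   quantization does not commute with reverse complementation: the levels of
   the reverse strand are unrelated to the forward levels, so an inverted
   segment is *invisible* unless both orientations are scored. The
   best-scoring orientation becomes the primary record; leftover query
   intervals are re-chained in the other orientation, which is what turns a
   read across an inversion into the characteristic `+ / − / +` split
   alignment.

Quantized coordinates translate back to nucleotides by widening: a quantized
symbol at position `p` summarizes bases `p .. p+Q-1`, so an interval
`[qs, qe)` covers nucleotides `[qs, qe + Q - 1)`.

## Quantizer design

The supplementary material of the method this package implements describes
the quantizer only as hard thresholding of current levels; the placement of
the cutoffs is this package's own choice: the empirical quantiles of the
`4^Q` model currents at fractions `j/L`. This makes the `L` symbols
equally occupied — the maximum-entropy alphabet — which is consistent with a
ternary mode being useful at all: badly unbalanced bins would collapse most
of the genome onto one symbol. Ties at a cutoff go to the lower level, and a
window containing a non-ACGT base receives the middle level rather than an
invented current. Both rules are deterministic and tested.

## Aligner internals and their defaults

The aligner is a generic seed–chain–extend engine over a configurable
alphabet (4 letters for nucleotides, `L` for quantized), with affine-gap
scoring `match +2, mismatch −4, gap open −4, gap extend −2`.

* **Minimizers.** `k = 15` for nucleotides; `k = 18` for the ternary
  alphabet, the one seed length the method prescribes (18 ternary symbols
  carry about as much information as an 11–12-mer over 4 letters and span 23
  bases of sequence). The window is `w = 6` for both: the source method
  leaves `w` unspecified, and at the package's desk scale a denser seed set
  is both more sensitive and *faster*, because anchors land closer together
  and the inter-anchor gap DPs shrink.
* **Occurrence cap.** Seeds occurring more than `max_occ = 10` times are
  skipped. Inside a tandem array every seed is high-occurrence, so a read
  confined to an array would lose all anchors; if no chain forms at the
  strict cap the collection is retried once with a relaxed cap — such arrays
  are usually still unique loci.
* **Chaining.** Chain score is the anchor count minus, per link,
  `min(0.01 g + 0.5 log2(g+1), 15)` where `g` is the query/target gap
  difference. The cap is the load-bearing part: a chain can jump a 10 kb
  insertion or deletion for a bounded price, so a structural variant stays
  *inside* one alignment record as a long `I`/`D` run instead of shattering
  into fragments. Chains whose query and target intervals overlap a better
  chain by more than 80% are dropped as tandem-shifted duplicates.
* **Gap filling and splitting.** Inter-anchor gaps are filled by banded
  affine DP (band = gap imbalance + 12). A *balanced* gap (neither side
  dominating) that aligns with both a poor score and a match fraction below
  0.78 of what homologous sequence would give is declared foreign: the
  record is split there. This is how an inverted segment — which in
  quantized space is unrelated to the forward sequence — surfaces as a
  split. One-sided gaps are never split; they are the indel runs SV calling
  feeds on. The 0.78 boundary sits between the match fraction optimal DP
  attains on unrelated ternary sequence (≈ 0.66) and on percent-level-noisy
  homologous sequence (≈ 0.89).
* **Extension.** Records extend past their outermost anchors by x-drop DP
  (drop 400), keeping the furthest point scoring within 50 of the best —
  a small score concession that stops noisy-but-homologous tails from being
  soft-clipped (a 10% base error corrupts nearly half of all Q-wide windows,
  so quantized tails are far noisier than their nucleotide counterparts).
  Split boundaries also extend toward each other so breakpoints are
  reported at the junction rather than at the last anchor, and a split
  whose gap those extensions nearly close (both sides under ~120/180
  symbols) is re-joined: it was a local noise burst, not a foreign
  segment. A genuinely inverted region resists extension and stays split.
* **MAPQ.** 60 for a unique hit, otherwise
  `40 (1 − second/best) · min(1, anchors/10)`, where only chains at a
  genuinely alternative locus (under 50% target overlap with the primary)
  count as "second best" — a repeat-shifted chain over the same locus does
  not make a hit ambiguous.

## The SV caller

The caller is deliberately the simplest machinery sufficient for a simulated
benchmark — it is a stand-in for a production caller, not a re-creation of
one. Three signature sources per read:

* **CIGAR indel runs.** Runs ≥ 10 symbols are collected and grouped across
  aligned islands up to 1 kb wide; the group's *net* query/target imbalance
  gives the event's type and size. Netting matters twice over a small
  alphabet: a large indel gets shattered by spurious short matches (random
  ternary positions agree 1/3 of the time), and conversely balanced
  insertion/deletion artifact pairs in tandem repeats cancel to nothing.
* **Split pairs.** Adjacent same-strand records with imbalanced query vs
  target gaps mark insertions/deletions the aligner expressed as a record
  break; adjacent opposite-strand records mark an inversion breakpoint, and
  since the inverted segment maps in reverse, the minus record's far end
  gives the *opposite* breakpoint — one breakpoint-spanning read determines
  the whole inverted interval.
* **Clustering.** Same-type signatures cluster by single linkage (window
  500 bp, widened for long events whose position estimates scatter with
  size), emit median position/length, require support from ≥ 3 distinct
  reads, and — for events under 1 kb — support of at least 25% of the local
  primary-record coverage (long events are visible only to the long reads
  that span them, so raw coverage would overstate their eligible support).
  Overlapping same-type calls of similar length are duplicate estimates of
  one event (planted variants never overlap) and are deduplicated.

Benchmarking follows the Truvari-style gate: candidate pairs share
chromosome and type, their breakpoint score `(|Δstart| + |Δend|)/2` is at
most 500 bp, and their length similarity `min/max` is at least 0.7; greedy
one-to-one assignment by ascending breakpoint score. The union model keeps
every call of one set plus the other set's unmatched calls, which can only
raise recall.

## What the generators emulate — and what they do not

`generate_genome()` produces uniform-GC background interleaved with VNTR-like
tandem arrays (units of 10–100 bp, arrays of 0.2–2 kb) to a target repeat
fraction of 20%. Successive copies of a unit diverge by 5% substitutions, as
real VNTR copies do; with *exact* copies every coordinate inside an array is
globally ambiguous and even a perfect caller's breakpoints can legitimately
sit an array-length away from the planted ones. `plant_svs()` places
insertions, deletions and inversions (lengths uniform on a given range) with
non-overlapping footprints separated by ≥ 2 kb, preserving the
non-interacting-variant regime of a sparse genome-scale simulation at desk
scale. `simulate_reads()` draws log-normal read lengths fitted to a given
mean and median (the heavy tail is what spans large variants), errors at a
total rate split 40/30/30 into substitutions/insertions/deletions, and — the
mechanism this package exists to exploit — substitutions that with
probability `confusion_weight` are chosen to keep the altered Q-mer in its
original current bin: errors invisible in quantized space.

What these generators do *not* model: realistic base-quality strings, motif-
or homopolymer-dependent error hotspots, segmental duplications or dispersed
repeat families, diploidy/heterozygosity, and chimeric reads. Passing the
simulated benchmark therefore demonstrates the pipeline's mechanics (two
domains, orientation handling, SV representation and scoring), not
performance on real flow-cell data.

## Study conditions and problem sizes

The packaged end-to-end experiments use, as their defaults, a 1.2 Mb genome
with 20% repeats, 100 indels + 20 inversions with lengths uniform on
[50, 10000], and ~40× coverage of reads with mean 3 kb (median scaled to
3000 · 4.5/14 ≈ 964, preserving the tail shape of a 14 kb/4.5 kb
nanopore-like length distribution), 10% error, and `confusion_weight` 0.5.
`hq_sv_experiment()` runs simulation → hybrid alignment → calling →
benchmarking for one seed; the nucleotide-only comparator is the pipeline's
own stage-1 record set from the same run. `hq_alignment_experiment()` runs
the paired per-read normalized-edit-distance comparison (2000 reads, no
planted variants) and reports the OLS slope. Read-length maximum is capped
at 50 kb (megabase-scale reads exist on real flow cells but are impractical
to simulate and align at these genome sizes), and the alignment-comparison
cohort additionally caps reads at 15 kb because its per-read edit-distance
computation is quadratic in read length and the regression does not need
the extreme tail.

## Numerical choices and degenerate inputs

Quantile type 7 (R's default) for thresholds; a current exactly at a cutoff
takes the lower level. Sequences shorter than `Q` quantize to an empty
sequence; reads shorter than the minimizer span are unmapped. Chain
tie-breaks prefer smaller target start, then smaller target id, making
output order deterministic; no step of alignment uses randomness. The edit
distance is exact Levenshtein via band doubling. Within the caller, medians
of integer positions are rounded; cluster output is invariant to input
order.

## Known limitations

* Inversions confined entirely to a single tandem array can be absorbed as
  noisy forward alignment (array vs reverse-complemented array is itself
  array-like), and inversions close to the read-length scale depend on the
  few reads long enough to bracket a breakpoint; both classes lose recall.
* Reads much shorter than a tandem array that land inside one are
  intrinsically ambiguous; the occurrence-relaxation retry places them at
  the right array but contiguity near the edges suffers. The pipeline's
  mapping-contiguity property (≥ 95% of reads primary-aligned to their
  source interval) is therefore asserted for reads ≥ 1 kb.
* The caller has no genotyping, no duplication/translocation classes, and
  no breakend notation; `union_model()` deduplicates at the matching gate
  only.
* SAM output emits quantized-domain CIGARs at back-translated nucleotide
  positions with `SEQ` omitted; downstream tools that require SEQ-consistent
  CIGARs should use the nucleotide-domain records.

## A short worked example

```{r example, eval = FALSE}
qmap <- synthesize_qmer_map(6, seed = 1)
genome <- generate_genome(3e5, repeat_fraction = 0.2, seed = 2)
planted <- plant_svs(genome, n_indel = 30, n_inv = 6, seed = 3)
reads <- simulate_reads(planted$genome, coverage = 40, mean_len = 3000,
                        median_len = 964, error_rate = 0.1, qmap = qmap,
                        confusion_weight = 0.5, seed = 4)
ix <- hq_index(genome, qmap)
aln <- run_hqalign(reads, ix)
calls <- call_svs(dplyr::filter(aln, domain == "quantized"))
glance(match_calls(planted$truth, calls))
```
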