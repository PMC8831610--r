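---
title: "Discovering and modeling plant microexons with mekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and modeling plant microexons with mekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mekit)
```

## The problem

Internal exons of 1–15 nt ("microexons" in this package's strict sense;
the broader literature stretches the term to ≤51 nt) are systematically
missed or misannotated by HMM-based genome annotators, which need a minimum
feature length to emit an exon at all. In plants roughly half of these
microexons are not multiples of 3 nt, so a missed microexon usually
frameshifts the gene model, truncates the predicted protein, and erases
real protein domains (the 9-nt AP2-domain microexon encoding VYLG is the
canonical casualty). `mekit` implements two complementary strategies:

1. **Read-based discovery** — find microexons from spliced RNA-seq
   alignments via the junction signature they leave in CIGAR strings.
2. **Homology-based modeling** — once a conserved microexon is known in a
   few species, find it in any genome without RNA-seq, by scanning with a
   position weight matrix split at the exon boundaries of a fixed-length
   "microexon-tag".

Everything is exercised on seeded synthetic fixtures generated by the
package itself, so each claim made below is one the test suite actually
computes.

## Read-based discovery

### Spanning reads

A microexon-spanning read aligns as five parts `M,N,M,N,M`: a 5′ exon
anchor, an intron gap, the microexon itself, a second gap, and a 3′
anchor. `detect_spanning()` accepts a window when

* the middle match block is within `me_len_range` (default 1–15 nt),
* both gaps are within `intron_range` (default 20–20 000 nt, the intron
  bounds a spliced aligner would be run with), and
* both outer anchors extend at least `min_anchor = 6` nt into the
  flanking exons.

Anchors are measured as the full match block adjoining the junction;
an insertion or deletion next to a junction breaks the pattern and
disqualifies the window. Reads with more than five parts are scanned for
every embedded qualifying window.

### Junction counting and the microexon-part exemption

`count_junctions()` gives every `N` op of a uniquely mapped read
("unique" = `NH == 1` when the tag is present, else `MAPQ >= 20`) one
count for its intron, provided the adjoining match blocks are anchored.
One wrinkle matters: the match block *on the microexon itself* is at most
15 nt and often shorter than any sensible anchor. A block that is bounded
by a further `N` on its far side is therefore exempt from the anchor
minimum — its anchor effectively continues across the next junction into
the true flanking exon. Without this rule, microexons shorter than the
anchor could never accumulate junction support and would be structurally
uncallable, which would contradict both the spanning-read definition and
the support threshold below.

### Calling and PSI

`call_microexons()` searches same-chromosome, same-strand intron pairs
whose genomic gap is 1–15 nt. Both introns must have canonical splice
motifs (GT-AG or GC-AG, read from the genome and orienting the strand),
and at least one single sample must support *both* introns with
`min_support = 5` reads. When alternative introns compete on one side of
a candidate exon, the intron with the highest mean junction count across
the sample population wins; ties go to the shorter intron, then the
leftmost.

Percent spliced-in is the standard event-level estimator

$$\mathrm{PSI} = \frac{I}{I + E}, \qquad
  I = \tfrac12\,(I_\mathrm{left} + I_\mathrm{right}),$$

with $I_\mathrm{left}, I_\mathrm{right}$ the two inclusion-junction
counts summed over samples and $E$ the count of the exclusion junction
joining the two flanking exons directly. Counts are pooled over samples
(the support rule stays per-sample); only a canonical exclusion junction
contributes to $E$, for symmetry with inclusion filtering. PSI is `NA`
when $I + E = 0$.

`classify_vs_annotation()` sorts calls into `annotated_exact` (an
annotated internal exon with the same interval *and* the same flanking
introns), `within_larger_exon`, `intronic`, and `unannotated_gene`;
`validate_annotated_microexons()` runs the audit in the opposite
direction, flagging annotated internal exons ≤ 15 nt that no sample
supports at the same threshold.

## Microexon-tags, clustering, and the split-PWM scan

### Tags

A microexon-tag is a `tag_len = 108` nt in-frame coding window centred on
the microexon within the longest ATG-initiated ORF of the transcript
(ties broken 5′-most; ORFs under 30 nt are ignored). The window is
shifted by at most one nucleotide so it starts on a codon boundary —
phase here is the number of CDS nucleotides 5′ of the microexon, mod 3 —
and truncated in frame where it would run past either end of the ORF.
When `tag_len - me_size` is odd the spare nucleotide goes 3′; this is
arbitrary but fixed. A full-length tag translates to a 36-aa peptide.
Exon junctions inside the window are recorded as offsets: they are where
the PWM will later be split.

### Clustering

Tags are grouped by (size, phase) — members of a cluster always share
both — and clustered on global pairwise BLOSUM62 alignment scores of
their peptides (gap opening 10, extension 0.5, the alignment function's
common defaults; only the substitution matrix is dictated by the method).
Scores become distances $d_{ij} = s_{\max} - s_{ij}$ and the
complete-linkage tree is cut at height $s_{\max} - 50$: complete linkage
is chosen deliberately because it makes the score-50 cut-off mean "every
within-cluster pair aligns with score ≥ 50", the strictest reading.
Clusters must contain at least three distinct species. Tags are sorted by
identifier before clustering so the result is independent of input
order.

### PWM construction and scanning

`filter_homolog_sequences()` merges member tags with any externally
retrieved coding fragments, dropping sequences with in-frame stops,
sequences shorter than the cluster tag length, and duplicates.
`build_pwm()` uses column probabilities
$p_b = (n_b + \alpha)/(N + 4\alpha)$ with pseudocount $\alpha = 0.25$ and
base-2 log-odds against a uniform 0.25 background. The matrix is split at
the cluster's canonical exon-boundary offsets (the modal offsets over
member tags), giving a microexon part plus two or more flank parts — up
to five parts when the flanking exons are short.

`scan_and_assemble()` scans each part on both strands, keeping windows
scoring at least `min_score_frac = 0.8` of the way from the part's
minimum to its maximum achievable log-odds score (the threshold
convention of the common PWM matchers; exposed as a parameter). Part hits
are chained in order with inter-part gaps of exactly 0 (intron lost) or
within 20 bp – 10 kb (intron present); a nonzero gap must begin `GT` or
`GC` and end `AG` in the strand's reading sense. Overlapping chains are
resolved by total score, then leftmost. Classification:

* `microexon` — both gaps flanking the microexon part are introns;
* `merged` — at least one such gap is 0 (the tag survives but the
  microexon is fused into a long exon, not an actual microexon);
* `partial` — an outer flank part is missing; reported for diagnostics
  but excluded from rates.

`summarize_rates()` reports, per cluster per species, the microexon
fraction of informative hits: 1 microexon + 1 merged locus gives rate
0.5; no informative hit gives `NA`. Whether probability or log-odds
scores are used for matching is not dictated by the method description;
log-odds is the default here.

## Intron retention and splicing-enhancer statistics

For each flanking intron, `intron_boundary_counts()` counts reads whose
continuous match block crosses the exon–intron (`i1`) or intron–exon
(`i2`) boundary by at least 4 nt on each side (strand-aware), spliced
reads whose gap equals the intron (`e`), and other overlapping gapped
reads (`o`); the 4-nt rule is applied to gapped junction reads as well.
Then

$$\mathrm{PIR} = 100 \times \frac{i_1 + i_2}{i_1 + i_2 + 2e + 2o},$$

set to `NA` below 10 total junction reads. The method leaves open whether
$e$ and $o$ count doubly in that NA rule; the single-count reading
$i_1+i_2+e+o$ is the default, with `double_count_spliced` as the
alternative. The unspliced ratio is PIR/100. `classify_detained()`
averages replicate ratios per cellular fraction: introns with mean
cytoplasmic ratio ≥ 0.2 are excluded (not constitutively spliced), and a
mean chromatin-bound ratio > 0.1 marks a detained intron requiring
post-transcriptional splicing. Averaging before thresholding (rather than
thresholding per replicate) follows the replicate-averaged presentation
of those ratios.

`motif_window_scan()` flags U(T)-rich and G-rich intronic-splicing-
enhancer content on the intron interior (10 nt inside each splice site):
a 20-nt window with strictly more than 80 % T, or a 10-nt window with
strictly more than 80 % G. The 80 % boundary is strict — 16/20 T does not
count. `motif_enrichment()` contrasts presence between microexon-flanking
and control introns with Pearson's chi-squared (no continuity
correction); control introns are drawn with a seeded sampler
(`sample_control_introns()`, default 1000) from constitutively spliced
introns.

## Supermatrix construction

`consensus_string()` takes the per-site majority base per species per
cluster (ties broken in the fixed order A < C < G < T; N is ignored for
counting), and `build_supermatrix()` concatenates cluster blocks in
ascending cluster-id order, filling species missing a cluster with `-`
across the whole block. All tags in a cluster have the same length, so
the concatenation *is* the alignment. Output formats: FASTA, relaxed
PHYLIP, and a per-cluster partition file for downstream tree inference
(tree search itself is out of scope).

## The synthetic fixtures

`fixture_spec()` / `generate_genome()` plant five-exon coding genes: the
middle exon is the microexon, introns are canonical (GT..AG by default,
GC..AG configurable) with lengths in 80–500 nt by default, the background
GC content is 0.36 (plant-like), and the spliced transcript carries a
single unambiguous ATG..stop ORF containing the microexon at the
requested phase (the 5′ UTR is capped with stop codons in all three
frames so no upstream ORF can run through). `simulate_reads()` draws
error-free reads with exactly computed CIGARs; molecule types (inclusion
at probability `psi`, exclusion, and independent retention of each
flanking intron at probability `retention`) are sampled proportional to
abundance times the number of valid read start positions — the uniform-
fragment model — which is what makes the PIR and PSI estimators converge
to the planted values. `mutate_homologs()` derives cross-species tag
families by synonymous-biased point mutation (third codon positions hit
4× as often), reverting any mutation that creates an in-frame stop.

Problem sizes used by the suite: oracle concordance runs on 10 000
simulated reads over 25 genes; parameter recovery on 50 planted genes at
120 reads per gene (chosen so every junction comfortably clears the
5-read support threshold under constitutive inclusion); PSI calibration
on 100 seeded replicates at 150 reads; training-locus recovery on a
10-species family mutated at rate 0.1.

What the fixtures deliberately do *not* emulate: alignment errors and
soft-clipped tails, mismapping, non-uniform expression, fragment-size
distributions, quality strings, and paired-end structure (mates are
treated independently; a junction seen by both mates counts twice).
Passing tests therefore demonstrate the correctness of the logic
downstream of the aligner, not robustness to mapper artifacts.

## Numerical and degenerate-input choices

* All internal genomic coordinates are 1-based closed, matching
  GTF/SAM and the Bioconductor containers used; offsets within a tag are
  nucleotide counts (a boundary after position *k* is recorded as *k*).
* Candidate and chain tie-breaks are deterministic everywhere (mean
  support, then length, then position; score, then position).
* Degenerate chi-squared tables (a zero margin) return `NA` rather than
  erroring; introns ≤ 40 nt return all-false window flags with a
  warning; PWM construction requires ≥ 2 equal-length A/C/G/T sequences
  and drops N-containing ones with a warning.
* Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state, so pipelines are bit-identical across runs given
  the same seed.

## Known limitations

* Discovery candidates come from intron pairs in junction tables, not
  from assembled transcripts; transcript assembly is out of scope and
  annotation comparison substitutes for assembly context.
* The scanner enumerates part chains exhaustively; it is sized for
  cluster-scale models (≤ 5 parts) on genomes up to tens of megabases,
  not for degenerate PWMs at permissive thresholds.
* EST/homolog retrieval, de-novo motif discovery, motif database search,
  and maximum-likelihood tree inference are accepted as inputs or left
  to external tools; only their interfaces are implemented here.
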