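---
title: "Methods: codon-level readout of translation in stem-cell states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level readout of translation in stem-cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ribocodon)
```

This vignette records the models, parameter choices and numerical rules
behind each stage of the package, and what the synthetic-data generators do
and do not emulate.

## Coding sequences and codon vectors

Each gene is represented by one representative CDS (isoform collapsing is
the caller's responsibility). The contract is strict: length a positive
multiple of three, alphabet `A/C/G/T/N`, and at most one stop codon, at the
terminal position; a permissive flag downgrades internal stops to a warning
for curated inputs known to contain read-throughs. Codons containing `N`
are skipped and excluded from every denominator rather than imputed, so
frequencies remain unbiased. Stop codons are counted in the 64-vector by
default because the ribosome-site analysis needs them; amino-acid-level
summaries exclude them via `include_stops = FALSE`. All sequences use the
DNA alphabet (T, not U), including tRNA references, matching sequencing
data.

GC1/GC2/GC3 are the G+C fractions at the three codon positions over counted
codons; `gc_total` is their mean, so the identity
`gc_total == (gc1 + gc2 + gc3) / 3` holds exactly when no `N` is present.

## Ribosome-site occupancy

### Coordinates

Everything is 0-based, half-open. A calibrated footprint holds nine codons
at positions −5 … +3 with 0 the A-site: after trimming the read-length-
specific 5′ offset, read nucleotides `[0, 27)` are the nine codons, the
P-site at `[12, 15)` and the A-site at `[15, 18)`. This is the only indexing
under which a single-nucleotide P-site offset of 12 and a nine-codon span
are mutually consistent.

### Frame and offset detection

For each read length, 5′ ends within codon positions −7 … +32 around the
TIS are counted by reading frame, overall and per codon position (a codon
position is "won" only by a strict majority; ties count for no frame). A
length is selected when one frame (a) is the most abundant overall, (b) wins
more codon positions than any other frame, and (c) exceeds the runner-up at
least five-fold both overall and in codon wins. The selected frame `f`
implies a trim of `(3 − f) mod 3` nt, restoring the P-site to read position
12–14. A human-style processing mode skips detection and fixes lengths
27–29 in frame 0. Lengths with no reads near the TIS are reported
unselected with reason `"no data"` rather than erroring.

### Extraction filters and edge rule

Reads are dropped, with per-reason tallies, when mapping quality is below
20, CDS overlap is below 50% of the read, the read length is unselected,
the 5′ frame disagrees with the selected frame, or fewer than 27 nt remain
after trimming. The nine-codon window must lie inside the *transcript*, not
the CDS: a read with a stop codon at its A-site legitimately reads its
+1 … +3 codons from the 3′ UTR, and removing such reads would erase the
termination signal the method is designed to see. Because any surviving
read contributes exactly one codon to each of the nine positions, column
sums are identical across positions by construction.

### Normalization and testing

Counts become per-position fractions; each codon's fraction at a position
is divided by its mean fraction over the nine positions. Codons never
observed are reported `NA`, not zero. The row-mean-equals-one identity is
enforced in tests at 1e−9.

Condition differences are tested per (codon, position) on the replicate
normalized values. Welch's unequal-variance t-test is the default — the more
conservative choice when replicate variances differ — with a
`var_equal = TRUE` switch restoring the pooled-variance (Student) test.
Degenerate inputs follow fixed rules: both groups constant and equal gives
p = 1 (and log2 fold-change 0); constant but unequal gives the smallest
positive double with a `degenerate` flag rather than a silent zero; any
missing replicate value leaves the pair untested. FDR control is
Benjamini–Hochberg step-up across all tested pairs. Pooled-replicate count
matrices are provided for display, but tests always use per-replicate
matrices.

### A compositional caveat

Normalized occupancy is compositional: planting (or observing) higher dwell
on a set of codons necessarily depresses every other codon's fraction at
that position. With a ×1.5 dwell change on the eight nnC codons the planted
effect is ≈ +0.45 log2 while the spillover on the remaining codons is
≈ −0.09 log2 — small, but *real* signal that becomes statistically
significant at high depth. Detection experiments therefore balance effect
size and depth (the package's validation uses ×1.5 at 48,000 reads per
replicate, 4 vs 4), and users should read genome-wide weak opposite shifts
as the arithmetic complement of a concentrated change, not as independent
biology.

### TIS boundary effect

The initiator ATG occurs once per gene and can occupy window positions
≤ 0 only (the A-site cannot lie upstream of the start codon). Its
normalized values are therefore structurally elevated a few percent at
−5 … −3 and depressed at +1 … +3, by roughly `(2/3)/(L̄ · f_ATG)` relative
terms for mean CDS length `L̄` — about ±8% at realistic human lengths. This
is a property of any transcriptome with a TIS, affects only ATG among
well-observed codons, and is why the flank-flatness control is read as a
distributional statement rather than a per-codon identity.

## Synthetic-data generators

All generators draw from one seed and are bit-reproducible for identical
(config, seed). They emulate:

- a transcriptome of `n_genes` CDS (default 300) with lengths uniform in
  150–750 codons — bracketing the human mean protein length of ~460 aa;
  much shorter genes inflate the TIS effect above — flanked by 25–60 nt
  UTRs so that any footprint whose A-site is on the first or last codon
  fits inside the transcript;
- per-gene GC3 targets uniform in 0.2–0.8, realized by weighting G/C-ending
  sense codons by the target (realized-vs-planted correlation is checked at
  r > 0.9);
- footprints placed positionally — gene ∝ expression, A-site codon ∝ dwell
  weight of the codon at a configurable `dwell_site` — rather than by an
  elongation-kinetics model, because occupancy ∝ dwell is precisely the
  assumption the nine-position statistic encodes; stop codons default to
  dwell 4 (slow termination);
- read lengths 27/28/29 at 25/50/25% in frame 0 by default (the human-like
  setting); mixtures of frames within one length are expressible for
  exercising the rejection rule;
- DE tables drawn directly (log2FC and adjusted p from a planted
  null/alternative mix) rather than via a count-model fit, since downstream
  stages consume only the table;
- tRNA-seq reads copying a mature reference, with the wobble A written G
  with per-tRNA probability θ and uniform per-base sequencing error ε
  (default 10⁻³); two tRNAs carry introns and one reference set lacks the
  CCA tail so maturation is exercised;
- planted translation-efficiency classes with baseline 5% per direction
  and odds multipliers 3.0 ("higher", giving ≈13.6% among nnC-high genes)
  and 1.45 ("lower", ≈7.1%).

They do **not** emulate: base-quality models, PCR duplicates, genome-space
alignment or splicing, rRNA/tRNA contamination of footprint libraries, UTR
compositional realism, initiation/termination ramp kinetics, or tRNA
abundance differences. Passing recovery tests on these data therefore
demonstrates correctness of the statistics under their own assumptions, not
robustness to every artifact of real libraries.

## Enrichment and GO PCA

Gene-set summaries are unweighted means of per-gene frequency vectors —
matching the "average per term" convention — with a pooled-count alternative
(`method = "pooled"`) that weights genes by length; the two differ exactly
when gene length correlates with composition. Background-vs-itself
enrichment is identically zero, which tests assert at 1e−12. A zero
background frequency for a feature present in the group yields `Inf` with a
warning rather than an error.

Stability-class analysis requires a codon→class map covering the 61 sense
codons. No published classification is bundled: `synthetic_stability_map()`
(G/C-ending = stabilizing) is a clearly-labelled synthetic stand-in for
tests, and real analyses should supply a published map. The between-group
test is a two-sided Wilcoxon rank-sum on per-gene class frequencies,
BH-adjusted across classes — chosen for robustness since per-gene class
frequencies are bounded sums.

GO terms keep genes that have codon vectors, then apply the ≥ 40-gene size
filter. The PCA is the correlation-matrix convention, computed as
`prcomp` on centred, scaled columns: mathematically the same eigen-problem
as a correlation-matrix `princomp`, but valid when terms are fewer than the
64 codon columns (where `princomp` refuses). Zero-variance codon columns
are dropped with a message. Components are sign-indeterminate, so PC1 is
oriented to correlate positively with term-mean AT3 (= 1 − GC3); under a
planted GC3 gradient the eight hetADAT nnC codons then load together with
the four-fold-degenerate nnG codons, the expected third-base structure.

## Wobble-inosine quantification

The wobble position is located from the annotation (`anticodon_start`,
recomputed after intron splicing and verified against the expected
anticodon — an error names the offending tRNA), never from a fixed
"position 34", because tRNA length variation makes absolute coordinates
unreliable. Only the first anticodon base is counted. The per-tRNA A34I
level is G/(A+C+G+T) at that position; the per-sample aggregate is
read-weighted (Σ G / Σ depth over substrate tRNAs), so deep tRNAs dominate
exactly as they do in the read pool. tRNAs at or below the depth threshold
(default 10 reads) leave the per-tRNA distribution but stay in the
aggregate; tRNAs whose reference wobble base is not A are reported but
excluded, and claiming one as a substrate is an error.

No background-error subtraction is applied. Under the uniform error model
the estimator's bias is `−θε + (1 − θ)ε/3`, bounded by ε/3 in magnitude —
negligible at ε = 10⁻³ and characterized in tests at ε = 10⁻². At 500 reads
per tRNA the binomial standard error is ≈ 0.02, so per-tRNA estimates
should be read with ±0.04–0.06 (2–3 SE) uncertainty; the aggregate over
eight tRNAs is ~√8 tighter. Condition comparisons use replicate-mean
per-tRNA deltas and a two-sided t-test on per-replicate aggregates when at
least two replicates exist per condition; with single samples the test is
omitted with a warning instead of fabricating degrees of freedom.

## nnC-high translation efficiency

The nnC-high threshold is a linear-interpolation percentile (R type 7) of
per-gene hetADAT-nnC codon fractions, default the 99th; fewer than 100
genes warns but still computes. "Occupancy two-fold higher independent of
mRNA level" is implemented as `ribo log2FC − rna log2FC > 1` (strict), the
only reading invariant to adding a constant to both tables; the boundary
case delta = 1 is "similar". The enrichment test is a chi-square on the
2×3 class table comparing nnC-high genes against the *disjoint* remainder
(a flag includes them in the background instead), with per-class
two-proportion follow-ups, BH-adjusted, and a Fisher-exact option for small
sets. With ~50 nnC-high genes (1% of 5,000) the chi-square has moderate
power (~60%) against the planted odds; at the gene counts of a real
transcriptome (~200+ nnC-high genes) power exceeds 99%, so non-detection at
small simulated scales reflects sample size, not the statistic.

## Problem sizes and tolerances

Validation runs use: 1,000–2,000 genes and 200k–500k footprints for dwell
recovery (A-site agreement with the closed-form positional expectation
within ±0.15 log2 for codons with ≥500 expected counts); 150 genes ×
48k reads × 4 replicates per condition for differential recovery; 20
repetitions of a 4 vs 4 null at 6k reads for FDR calibration (≤7.5% of
pairs flagged); 500 reads per tRNA for inosine recovery; and 5,000 genes
for the TE classification experiment. Exact identities (normalization row
means, aggregate-vs-weighted-mean, oracle equality of site counts) are
asserted at 1e−9–1e−12 or integer equality; statistical recoveries use
3-sigma binomial bounds.

## Known limitations

- Transcript-space only: genome-aligned reads must be projected upstream.
- Ungapped, single-end alignments; spliced or paired data are out of scope.
- The stability-class default is synthetic; conclusions about mRNA
  stability require a published map.
- The inosine estimator reports raw mismatch fractions; other
  misincorporation-prone modifications at the anticodon loop of a real
  tRNA would be counted if they produce A→G signal at the wobble base.
- Compositional spillover (above) means differential codon tables should
  be interpreted jointly, not codon-by-codon.
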