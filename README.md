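# ribocodon

Codon-level analysis of translation in self-renewing versus differentiating
embryonic stem cells: synonymous codon usage and GC3 of gene sets, GO-term
codon-profile PCA, ribosome E/P/A-site codon occupancy from Ribo-seq,
differential codon-usage testing between cell states, tRNA wobble-inosine
(A34I) quantification from tRNA-seq, and translation-efficiency
classification of hetADAT-dependent nnC-codon-rich genes. Every input the
pipeline consumes can also be generated synthetically with planted ground
truth, so each stage is testable end to end.

## The science in brief

Cell state can be read out at the level of single codons. Two linked
signals are of interest:

**Ribosome-site codon occupancy.** A ribosome footprint protects nine
codons, numbered −5 … +3 with 0 the A-site (−1 = P, −2 = E). After
reading-frame and P-site-offset calibration per read length, the first 27 nt
of each footprint are split into those nine codons and counted per position.
The central statistic normalizes the codon fraction at one position by that
codon's mean fraction across all nine:

```
value(c, p) = frac(c, p) / mean_{p' in -5..+3} frac(c, p')
```

This cancels mRNA abundance and codon composition, leaving position-specific
dwell signal: stop codons enrich strongly at the A-site and vanish from P/E,
and condition differences are tested per (codon, position) with Welch's
t-test across biological replicates, BH-corrected. Flanking positions
(−5..−3, +1..+3) track the expression-weighted genomic codon distribution
and serve as the built-in negative control.

**Wobble inosine (A34I).** The hetADAT enzyme (ADAT2/ADAT3) deaminates A34
to inosine in eight tRNA isotypes (Ala, Arg, Ile, Leu, Pro, Ser, Thr, Val),
letting one tRNA read nnT, nnC and nnA codons; the eight nnC codons depend
on it entirely. Sequencers read inosine as G, so the A34I level is the A→G
mismatch fraction at the annotated wobble position of a mature-tRNA
alignment, aggregated read-weighted across substrate tRNAs. Genes in the top
percentile of nnC-codon fraction ("nnC-high") are tested for enrichment of
translation-efficiency changes, where TE change is the difference of
Ribo-seq and RNA-seq log2 fold-changes with a two-fold class boundary.

## Worked example

Simulate a 200-gene transcriptome with a planted GC3 gradient, 50k
footprints with slow termination (stop-codon dwell ×4), then recover frames
and site occupancy:

```r
library(ribocodon)
cfg <- simulation_config(seed = 1, n_genes = 200, n_footprints = 50000,
                         dwell_weights = c(TAA = 4, TAG = 4, TGA = 4))
tx    <- simulate_transcriptome(cfg)
usage <- codon_usage(tx$cds)
usage[1:3, c("gene_id", "n_codons", "gc3", "GCC", "GCA")]
#>   gene_id n_codons   gc3    GCC    GCA
#> 1 g0001        236 0.364 0.0169 0.0212
#> 2 g0002        568 0.695 0.0194 0.0194
#> 3 g0003        652 0.577 0.0184 0.0107

expr <- simulate_expression(cfg, tx)
fp   <- simulate_footprints(tx,
          dplyr::rename(expr$expression[, c("gene_id", "expression_a")],
                        expression = "expression_a"), cfg)
bed  <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
prof <- profile_frames(fp$reads, bed)
prof[, c("read_length", "n_reads", "frame_0", "frame_1", "frame_2",
         "selected", "trim")]
#>   read_length n_reads frame_0 frame_1 frame_2 selected  trim
#> 1          27    1097    1097       0       0 TRUE         0
#> 2          28    2111    2111       0       0 TRUE         0
#> 3          29    1062    1062       0       0 TRUE         0

norm <- normalize_site_counts(
          extract_site_codons(fp$reads, bed, tx$transcripts, prof))
dplyr::arrange(norm[norm$position == 0, ], dplyr::desc(value))[1:4, ]
#>   codon position fraction value
#> 1 TGA          0  0.00471  4.90
#> 2 TAG          0  0.00313  4.32
#> 3 TAA          0  0.00206  3.83
#> 4 GGC          0  0.0181   1.06
```

Every read length is pure frame 0 (the 5′ ends sit 15 nt upstream of the
A-site, so the P-site is read nt 12–14), and the three stop codons top the
A-site ranking near their planted dwell of 4 while no sense codon deviates
much from 1 — the nine-position normalization at work.

`run_all(pipeline_config(seed = 1), "out/")` executes the full pipeline
(codon vectors → enrichment and GO PCA → site occupancy and differential
codon usage → inosine quantification → TE classification) and writes every
table as TSV plus a checksummed run manifest.

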