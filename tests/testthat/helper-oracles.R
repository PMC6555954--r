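# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use plain loops and no package
# internals beyond exported constants.

ALL_CODONS <- sort(names(Biostrings::GENETIC_CODE))

oracle_codon_counts <- function(sequence) {
  counts <- setNames(rep(0L, 64L), ALL_CODONS)
  n <- 0L
  for (i in seq(1L, nchar(sequence) - 2L, by = 3L)) {
    cod <- substr(sequence, i, i + 2L)
    if (grepl("N", cod, fixed = TRUE)) next
    counts[cod] <- counts[cod] + 1L
    n <- n + 1L
  }
  list(freq = counts / n, n = n)
}

oracle_gc <- function(sequence, pos) {
  hits <- 0L
  n <- 0L
  for (i in seq(1L, nchar(sequence) - 2L, by = 3L)) {
    cod <- substr(sequence, i, i + 2L)
    if (grepl("N", cod, fixed = TRUE)) next
    n <- n + 1L
    if (substr(cod, pos, pos) %in% c("G", "C")) hits <- hits + 1L
  }
  hits / n
}

# Naive per-read enumeration of E/P/A-site codon counts: loops over reads,
# applies each filter explicitly, and tallies codons one by one.
oracle_site_counts <- function(reads, cds, transcripts, selected,
                               min_overlap = 0.5, mapq_min = 20) {
  counts <- matrix(0L, nrow = 64L, ncol = 9L,
    dimnames = list(ALL_CODONS, as.character(-5:3)))
  used <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (!is.null(r$mapq) && !is.na(r$mapq) && r$mapq < mapq_min) next
    k <- which(cds$transcript_id == r$transcript_id)
    if (length(k) != 1L) next
    ov <- min(r$start + r$length, cds$cds_end[k]) - max(r$start,
      cds$cds_start[k])
    if (ov / r$length < min_overlap) next
    s <- which(selected$read_length == r$length)
    if (length(s) != 1L) next
    if ((r$start - cds$cds_start[k]) %% 3L != selected$dominant_frame[s]) next
    tstart <- r$start + selected$trim[s]
    if (r$length - selected$trim[s] < 27L) next
    seq_k <- transcripts$sequence[transcripts$transcript_id ==
      r$transcript_id]
    if (tstart < 0L || tstart + 27L > nchar(seq_k)) next
    for (p in 0:8) {
      cod <- substr(seq_k, tstart + 3L * p + 1L, tstart + 3L * p + 3L)
      counts[cod, p + 1L] <- counts[cod, p + 1L] + 1L
    }
    used <- used + 1L
  }
  list(counts = counts, used = used)
}

site_counts_matrix <- function(sc) {
  m <- matrix(sc$count, nrow = 64L,
    dimnames = list(sc$codon[1:64], as.character(-5:3)))
  m
}

# Small standard transcriptome + expression for ribosite tests.
make_fixture <- function(seed = 42, n_genes = 100, n_footprints = 20000,
                         ...) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
    n_footprints = n_footprints, ...)
  tx <- simulate_transcriptome(cfg)
  expr <- withr_seed_expr(seed, n_genes)
  list(cfg = cfg, tx = tx, expr = expr,
    bed = tx$transcripts[, c("transcript_id", "cds_start", "cds_end")])
}

withr_seed_expr <- function(seed, n) {
  set.seed(seed + 777L)
  tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    expression = stats::rlnorm(n, log(100), 1)
  )
}
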