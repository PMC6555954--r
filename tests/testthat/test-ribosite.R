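# Synthetic read tables for frame-profiling fixtures: n_per_frame 5' ends per
# frame, spread across codon positions so per-codon majorities are controlled.
frame_fixture_reads <- function(totals, majority_codons, length = 28L,
                                cds_start = 30L) {
  # majority_codons: number of codon positions (out of 40 in the window)
  # whose strict majority is frame 0 / 1 / 2
  reads <- list()
  pos_seq <- -7:32
  stopifnot(sum(majority_codons) <= length(pos_seq))
  frames_by_codon <- rep(0:2, majority_codons)
  remaining <- totals
  for (i in seq_along(frames_by_codon)) {
    f <- frames_by_codon[i]
    cp <- pos_seq[i]
    k <- min(remaining[f + 1], ceiling(totals[f + 1] / majority_codons[f + 1]))
    if (k <= 0) next
    reads[[length(reads) + 1L]] <- tibble::tibble(
      transcript_id = "t1",
      start = cds_start + 3L * cp + f,
      length = length, n = k
    )
    remaining[f + 1] <- remaining[f + 1] - k
  }
  d <- dplyr::bind_rows(reads)
  d <- d[rep(seq_len(nrow(d)), d$n), c("transcript_id", "start", "length")]
  d
}

fixture_cds <- tibble::tibble(transcript_id = "t1", cds_start = 30L,
  cds_end = 330L)

test_that("a five-fold dominant frame with matching majorities is selected", {
  reads <- frame_fixture_reads(c(500L, 50L, 40L), c(38L, 2L, 0L))
  prof <- profile_frames(reads, fixture_cds)
  expect_true(prof$selected)
  expect_equal(prof$dominant_frame, 0L)
  expect_equal(prof$trim, 0L)
  expect_equal(prof$frame_0, 500L)
})

test_that("a frame below five-fold total dominance is rejected", {
  reads <- frame_fixture_reads(c(500L, 150L, 10L), c(30L, 8L, 2L))
  prof <- profile_frames(reads, fixture_cds)
  expect_false(prof$selected)
  expect_match(prof$reason, "total dominance")
})

test_that("disagreement between total and per-codon winners is rejected", {
  # frame 0 wins in total but frame 1 wins more codon positions
  reads <- dplyr::bind_rows(
    frame_fixture_reads(c(600L, 0L, 0L), c(2L, 0L, 0L)),
    frame_fixture_reads(c(0L, 90L, 0L), c(0L, 30L, 0L))
  )
  prof <- profile_frames(reads, fixture_cds)
  expect_false(prof$selected)
  expect_match(prof$reason, "disagrees")
})

test_that("lengths with no reads near the TIS are marked no-data", {
  reads <- tibble::tibble(transcript_id = "t1", start = 250L, length = 28L)
  prof <- profile_frames(reads, fixture_cds)
  expect_false(prof$selected)
  expect_equal(prof$reason, "no data")
})

test_that("planted frames are recovered and mixed-frame lengths rejected", {
  rl <- tibble::tibble(
    length = c(28L, 29L, 31L, 33L, 33L, 33L),
    fraction = c(0.25, 0.2, 0.15, 0.16, 0.14, 0.10),
    frame = c(0L, 1L, 2L, 0L, 1L, 2L)
  )
  cfg <- simulation_config(seed = 42, n_genes = 60, n_footprints = 60000L,
    read_length_table = rl)
  tx <- simulate_transcriptome(cfg)
  expr <- withr_seed_expr(42, 60)
  fp <- simulate_footprints(tx, expr, cfg)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  prof <- profile_frames(fp$reads, bed)
  sel <- prof[prof$selected, ]
  expect_setequal(sel$read_length, c(28L, 29L, 31L))
  expect_equal(sel$dominant_frame[sel$read_length == 28L], 0L)
  expect_equal(sel$dominant_frame[sel$read_length == 29L], 1L)
  expect_equal(sel$dominant_frame[sel$read_length == 31L], 2L)
  expect_equal(sel$trim[sel$read_length == 29L], 2L)
  expect_equal(sel$trim[sel$read_length == 31L], 1L)
  expect_false(prof$selected[prof$read_length == 33L])
})

test_that("a single known read increments the correct P- and A-site codons", {
  tx_seq <- paste0(
    strrep("T", 18),
    "ATG", "GCT", "AAA", "CCG", "TGG", "GAT", "CAA", "GTT", "CGA", "TAC",
    "TAA", strrep("A", 20)
  )
  transcripts <- tibble::tibble(transcript_id = "t1", sequence = tx_seq,
    length = nchar(tx_seq))
  cds <- tibble::tibble(transcript_id = "t1", cds_start = 18L, cds_end = 51L)
  # 5' end at CDS start (frame 0): trimmed window holds codons 0..8 of the
  # CDS; P-site = read nt 12-14 = 5th codon (TGG), A-site = nt 15-17 (GAT)
  reads <- tibble::tibble(transcript_id = "t1", start = 18L, length = 28L,
    mapq = 42L)
  sc <- extract_site_codons(reads, cds, transcripts, NULL)
  m <- site_counts_matrix(sc)
  expect_equal(attr(sc, "n_reads_used"), 1L)
  expect_equal(sum(m), 9L)
  expect_equal(m["TGG", "-1"], 1L)
  expect_equal(m["GAT", "0"], 1L)
  expect_equal(m["ATG", "-5"], 1L)
  expect_equal(m["CAA", "1"], 1L)
})

test_that("reads failing the overlap, mapq or frame filters are discarded", {
  transcripts <- tibble::tibble(transcript_id = "t1",
    sequence = strrep("ACGT", 100), length = 400L)
  cds <- tibble::tibble(transcript_id = "t1", cds_start = 100L,
    cds_end = 300L)
  # ~43% CDS overlap: start 288 length 28 -> overlap 12/28 < 0.5
  r_overlap <- tibble::tibble(transcript_id = "t1", start = 288L,
    length = 28L, mapq = 42L)
  sc <- extract_site_codons(r_overlap, cds, transcripts, NULL)
  expect_equal(attr(sc, "n_reads_used"), 0L)
  expect_equal(attr(sc, "discards")[["low_overlap"]], 1L)

  r_mapq <- tibble::tibble(transcript_id = "t1", start = 130L, length = 28L,
    mapq = 5L)
  sc2 <- extract_site_codons(r_mapq, cds, transcripts, NULL)
  expect_equal(attr(sc2, "discards")[["mapq"]], 1L)

  r_frame <- tibble::tibble(transcript_id = "t1", start = 131L, length = 28L,
    mapq = 42L)
  sc3 <- extract_site_codons(r_frame, cds, transcripts, NULL)
  expect_equal(attr(sc3, "discards")[["wrong_frame"]], 1L)
})

test_that("site extraction equals the per-read enumeration oracle exactly", {
  cfg <- simulation_config(seed = 42, n_genes = 40, n_footprints = 1000L)
  tx <- simulate_transcriptome(cfg)
  expr <- withr_seed_expr(42, 40)
  fp <- simulate_footprints(tx, expr, cfg)
  sam <- tempfile(fileext = ".sam")
  write_footprint_sam(fp, tx, sam)
  reads <- read_footprints(sam)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  prof <- profile_frames(reads, bed)
  sc <- extract_site_codons(reads, bed, tx$transcripts, prof)
  sel <- prof[prof$selected, c("read_length", "dominant_frame", "trim")]
  oracle <- oracle_site_counts(reads, bed, tx$transcripts, sel)
  expect_identical(site_counts_matrix(sc), oracle$counts)
  expect_identical(attr(sc, "n_reads_used"), oracle$used)
})

test_that("nine-position normalization has unit row means and known values", {
  counts <- tibble::tibble(
    codon = rep(c("AAA", "GCT"), each = 9L),
    position = rep(-5:3, 2L),
    count = c(rep(20L, 9L), c(rep(20L, 5L), 40L, rep(20L, 3L)))
  )
  ns <- normalize_site_counts(counts)
  # AAA has equal fraction everywhere except the A-site column's total grew
  row_means <- tapply(ns$value, ns$codon, mean)
  expect_true(all(abs(row_means - 1) < 1e-9))
  # per-position fractions sum to 1
  pos_sums <- tapply(ns$fraction, ns$position, sum)
  expect_true(all(abs(pos_sums - 1) < 1e-9))
})

test_that("a codon fraction of 0.04 at A against 0.02 elsewhere gives 1.8", {
  # construct totals so the target codon's fractions are exactly 0.02/0.04
  other <- 1000L
  counts <- tibble::tibble(
    codon = rep(c("GCT", "AAA"), each = 9L),
    position = rep(-5:3, 2L),
    count = c(
      c(rep(20L, 5L), 40L, rep(20L, 3L)),
      c(rep(980L, 5L), 960L, rep(980L, 3L))
    )
  )
  ns <- normalize_site_counts(counts)
  a_val <- ns$value[ns$codon == "GCT" & ns$position == 0]
  expect_equal(a_val, 0.04 / (0.20 / 9), tolerance = 1e-12)
})

test_that("unobserved codons are reported missing, not zero", {
  counts <- tibble::tibble(
    codon = rep(c("AAA", "TTT"), each = 9L),
    position = rep(-5:3, 2L),
    count = c(rep(5L, 9L), rep(0L, 9L))
  )
  ns <- normalize_site_counts(counts)
  expect_true(all(is.na(ns$value[ns$codon == "TTT"])))
  expect_error(normalize_site_counts(counts[counts$codon == "TTT", ]),
    "empty")
  gap <- counts[counts$codon == "AAA", ]
  gap$count[gap$position == 3] <- 0L
  expect_error(normalize_site_counts(gap), "zero counts")
})

test_that("stop-codon stalling shows A-site enrichment and P/E depletion", {
  cfg <- simulation_config(seed = 42, n_genes = 150, n_footprints = 120000L,
    dwell_weights = c(TAA = 4, TAG = 4, TGA = 4))
  tx <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(tx, withr_seed_expr(42, 150), cfg)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  ns <- normalize_site_counts(
    extract_site_codons(fp$reads, bed, tx$transcripts, NULL))
  stops <- c("TAA", "TAG", "TGA")
  expect_true(all(ns$value[ns$codon %in% stops & ns$position == 0] > 1))
  expect_true(all(ns$value[ns$codon %in% stops &
    ns$position %in% c(-1, -2)] < 1))
})

test_that("identical replicates give p = 1 and zero fold change", {
  cfg <- simulation_config(seed = 42, n_genes = 40, n_footprints = 5000L)
  tx <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(tx, withr_seed_expr(42, 40), cfg)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  ns <- normalize_site_counts(
    extract_site_codons(fp$reads, bed, tx$transcripts, NULL))
  dt <- differential_codon_usage(list(ns, ns), list(ns, ns))
  tested <- dt[!is.na(dt$p), ]
  expect_true(all(tested$p == 1))
  expect_true(all(tested$log2_fc == 0))
  expect_true(all(tested$degenerate))
})

test_that("zero-variance unequal means are flagged, not silently perfect", {
  mk_norm <- function(v) {
    tibble::tibble(codon = "AAA", position = 0L, fraction = NA_real_,
      value = v)
  }
  dt <- differential_codon_usage(
    list(mk_norm(1), mk_norm(1)), list(mk_norm(2), mk_norm(2))
  )
  expect_true(dt$degenerate)
  expect_equal(dt$p, .Machine$double.xmin)
  expect_equal(dt$log2_fc, 1)
})

test_that("correlating a table with itself or its negation is exact", {
  cfg <- simulation_config(seed = 42, n_genes = 60, n_footprints = 8000L)
  tx <- simulate_transcriptome(cfg)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  mk <- function(s) {
    fp <- simulate_footprints(tx, withr_seed_expr(42, 60), cfg, seed = s)
    normalize_site_counts(
      extract_site_codons(fp$reads, bed, tx$transcripts, NULL))
  }
  dt <- differential_codon_usage(list(mk(1), mk(2)), list(mk(3), mk(4)))
  self_cor <- correlate_codon_shifts(dt, dt, position = -1L)
  expect_equal(self_cor$r[self_cor$set == "all"], 1, tolerance = 1e-9)
  neg <- dt
  neg$log2_fc <- -neg$log2_fc
  anti <- correlate_codon_shifts(dt, neg, position = -1L)
  expect_equal(anti$r[anti$set == "all"], -1, tolerance = 1e-9)
})

test_that("raising a codon's A-site dwell never lowers its recovered value", {
  vals <- vapply(c(1, 2, 4), function(w) {
    cfg <- simulation_config(seed = 42, n_genes = 80, n_footprints = 40000L,
      dwell_weights = c(GCT = w))
    tx <- simulate_transcriptome(cfg)
    fp <- simulate_footprints(tx, withr_seed_expr(42, 80), cfg)
    bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
    ns <- normalize_site_counts(
      extract_site_codons(fp$reads, bed, tx$transcripts, NULL))
    ns$value[ns$codon == "GCT" & ns$position == 0]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("flank concordance is high at flanks under uniform dwell", {
  cfg <- simulation_config(seed = 42, n_genes = 150, n_footprints = 100000L,
    dwell_weights = numeric(0))
  tx <- simulate_transcriptome(cfg)
  expr <- withr_seed_expr(42, 150)
  fp <- simulate_footprints(tx, expr, cfg)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  sc <- extract_site_codons(fp$reads, bed, tx$transcripts, NULL)
  genomic <- genomic_codon_distribution(codon_usage(tx$cds), expr)
  qc <- flank_concordance(sc, genomic)
  flanks <- qc$r[qc$position %in% c(-5, -4, -3, 1, 2, 3)]
  expect_true(all(flanks > 0.95))
  empty <- tibble::tibble(codon = "AAA", position = 0L, count = 0L)
  expect_error(flank_concordance(empty, genomic), "empty")
})

test_that("stop-codon stalling depresses A-site concordance below flanks", {
  cfg <- simulation_config(seed = 42, n_genes = 150, n_footprints = 100000L,
    dwell_weights = c(TAA = 6, TAG = 6, TGA = 6))
  tx <- simulate_transcriptome(cfg)
  expr <- withr_seed_expr(42, 150)
  fp <- simulate_footprints(tx, expr, cfg)
  bed <- tx$transcripts[, c("transcript_id", "cds_start", "cds_end")]
  sc <- extract_site_codons(fp$reads, bed, tx$transcripts, NULL)
  qc <- flank_concordance(sc, genomic_codon_distribution(codon_usage(tx$cds),
    expr))
  a_r <- qc$r[qc$position == 0]
  flank_r <- qc$r[qc$position %in% c(-5, -4, -3, 1, 2, 3)]
  expect_true(all(a_r < flank_r))
})
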