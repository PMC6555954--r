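# Full 64-codon dwell-weight vector from a (possibly partial) named vector.
dwell_weight_vector <- function(dwell_weights) {
  w <- stats::setNames(rep(1, 64L), CODONS)
  if (length(dwell_weights)) {
    unknown <- setdiff(names(dwell_weights), CODONS)
    if (length(unknown)) {
      stop("unknown codons in dwell_weights: ", paste(unknown, collapse = ", "))
    }
    w[names(dwell_weights)] <- dwell_weights
  }
  w
}

# One row per (gene, codon index): the sampling frame for footprint placement.
# Weight = expression x dwell weight of the codon at (index + dwell_site);
# positions whose dwell codon falls outside the CDS take weight 1.
footprint_sampling_frame <- function(tx, expression, config) {
  w <- dwell_weight_vector(config$dwell_weights)
  ds <- config$dwell_site
  codon_list <- split_codons(tx$cds$sequence)
  expr <- expression$expression[match(tx$cds$gene_id, expression$gene_id)]
  if (anyNA(expr)) stop("expression missing for some genes")
  lens <- lengths(codon_list)
  gene_idx <- rep.int(seq_along(codon_list), lens)
  a_idx <- unlist(lapply(lens, function(L) seq_len(L) - 1L), use.names = FALSE)
  dwell_idx <- a_idx + ds
  dwell_codon <- unlist(codon_list, use.names = FALSE)
  # codon at the dwell site, where it exists within the CDS
  ok <- dwell_idx >= 0L & dwell_idx < rep.int(lens, lens)
  dwell_w <- rep(1, length(a_idx))
  offs <- c(0L, cumsum(lens))[gene_idx]
  dwell_w[ok] <- w[dwell_codon[offs[ok] + dwell_idx[ok] + 1L]]
  tibble::tibble(
    gene_idx = gene_idx, a_index = a_idx,
    weight = expr[gene_idx] * dwell_w
  )
}

#' Simulate ribosome footprints with planted codon dwell weights
#'
#' Draws `n_footprints` reads under the positional occupancy model the
#' nine-position statistic assumes: a read's gene is chosen proportionally to
#' expression, and its A-site codon proportionally to the dwell weight of the
#' codon at `dwell_site` positions from the A-site (default 0, the A-site
#' itself). Each read is emitted so that, before the per-read-length 5' frame
#' shift of `(3 - frame) %% 3` nt, its A-site occupies read nucleotides
#' 15-17 (0-based; P-site at 12-14). Read lengths and frames follow
#' `config$read_length_table`. Reads are ungapped, single-end and
#' transcript-space.
#'
#' @param tx A `sim_transcriptome`.
#' @param expression Tibble with `gene_id` and `expression` (one condition's
#'   expected abundance), e.g. one column of [simulate_expression()] output.
#' @param config A [simulation_config()].
#' @param seed Seed for this sample; defaults to `config$seed`. Give each
#'   replicate its own seed.
#' @return A list of class `sim_footprints`: `reads` (tibble `read_id`,
#'   `transcript_id`, `start` (0-based), `length`, `frame`, `a_index`,
#'   `mapq`, `sequence`) and `truth` (planted dwell weights, dwell site and
#'   read-length table).
#' @export
simulate_footprints <- function(tx, expression, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  frame_tab <- footprint_sampling_frame(tx, expression, config)
  rl <- config$read_length_table
  with_seed(stage_seed(seed, 4L), {
    n <- config$n_footprints
    pick <- sample.int(nrow(frame_tab), n, replace = TRUE,
      prob = frame_tab$weight)
    stratum <- sample.int(nrow(rl), n, replace = TRUE, prob = rl$fraction)
    gene_idx <- frame_tab$gene_idx[pick]
    a_index <- frame_tab$a_index[pick]
    len <- rl$length[stratum]
    frame <- rl$frame[stratum]
    trim <- (3L - frame) %% 3L
    cds_start <- tx$transcripts$cds_start[gene_idx]
    start <- cds_start + 3L * a_index - 15L - trim
    tx_len <- tx$transcripts$length[gene_idx]
    if (any(start < 0L) || any(start + len > tx_len)) {
      stop("internal error: simulated read outside transcript")
    }
    seqs <- substring(tx$transcripts$sequence[gene_idx], start + 1L,
      start + len)
    structure(list(
      reads = tibble::tibble(
        read_id = sprintf("fp%07d", seq_len(n)),
        transcript_id = tx$transcripts$transcript_id[gene_idx],
        start = start, length = len, frame = frame,
        a_index = a_index, mapq = 42L, sequence = seqs
      ),
      truth = list(
        dwell_weights = dwell_weight_vector(config$dwell_weights),
        dwell_site = config$dwell_site,
        read_length_table = rl
      )
    ), class = "sim_footprints")
  })
}

#' Write simulated footprints as a transcript-space SAM file
#'
#' Single-end, ungapped alignments with one `@SQ` line per transcript and
#' flags 0 only.
#'
#' @param fp A `sim_footprints` object (or any tibble with `read_id`,
#'   `transcript_id`, `start`, `length`, `mapq`, `sequence`).
#' @param tx The `sim_transcriptome` the reads were drawn from.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_footprint_sam <- function(fp, tx, path) {
  reads <- if (inherits(fp, "sim_footprints")) fp$reads else fp
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", tx$transcripts$transcript_id,
      tx$transcripts$length)
  )
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
    reads$read_id, reads$transcript_id, reads$start + 1L, reads$mapq,
    reads$length, reads$sequence)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned footprints from SAM/BAM
#'
#' Accepts transcript-space, single-end, ungapped alignments. SAM input is
#' converted on the fly with Rsamtools. Unmapped reads are dropped.
#'
#' @param path `.sam` or `.bam` file with `@SQ` header lines.
#' @return Tibble with `transcript_id`, `start` (0-based), `length`, `mapq`.
#' @export
read_footprints <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
      destination = tempfile(fileext = ""), overwrite = TRUE,
      indexDestination = FALSE
    )
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "mapq", "flag")
  ))[[1]]
  keep <- !bitwAnd(res$flag, 4L)
  tibble::tibble(
    transcript_id = as.character(res$rname)[keep],
    start = res$pos[keep] - 1L,
    length = res$qwidth[keep],
    mapq = res$mapq[keep]
  )
}

#' Closed-form expected site counts under the footprint model
#'
#' Computes, by direct enumeration over every (gene, A-site position,
#' read-length stratum) triple, the expected codon-by-position count matrix
#' implied by the planted dwell weights, the expression vector and the
#' extraction filters, without simulating any reads. Serves as the analytic
#' reference that recovered occupancy is compared against.
#'
#' @inheritParams simulate_footprints
#' @param min_overlap Minimum read/CDS overlap fraction mirrored from the
#'   extraction step.
#' @return Tibble with `codon`, `position` (-5..+3), `expected_count` and
#'   `expected_value` (nine-position-normalized expectation).
#' @export
site_count_expectation <- function(tx, expression, config, min_overlap = 0.5) {
  frame_tab <- footprint_sampling_frame(tx, expression, config)
  rl <- config$read_length_table
  cds_start <- tx$transcripts$cds_start[frame_tab$gene_idx]
  cds_len <- tx$cds$length[frame_tab$gene_idx]
  # fraction of the length mixture that survives the CDS-overlap filter
  keep_frac <- rep(0, nrow(frame_tab))
  for (k in seq_len(nrow(rl))) {
    trim <- (3L - rl$frame[k]) %% 3L
    s_rel <- 3L * frame_tab$a_index - 15L - trim
    ov <- pmin(s_rel + rl$length[k], cds_len) - pmax(s_rel, 0L)
    keep_frac <- keep_frac +
      rl$fraction[k] * ((ov / rl$length[k]) >= min_overlap)
  }
  w <- frame_tab$weight * keep_frac
  counts <- matrix(0, nrow = 64L, ncol = 9L,
    dimnames = list(CODONS, as.character(-5:3)))
  tx_seq <- tx$transcripts$sequence[frame_tab$gene_idx]
  for (p in -5:3) {
    nt0 <- cds_start + 3L * (frame_tab$a_index + p)
    cod <- substring(tx_seq, nt0 + 1L, nt0 + 3L)
    sums <- rowsum(w, factor(cod, levels = CODONS))
    counts[rownames(sums), as.character(p)] <- sums[, 1]
  }
  frac <- sweep(counts, 2L, colSums(counts), "/")
  value <- frac / rowMeans(frac)
  tibble::tibble(
    codon = rep(CODONS, 9L),
    position = rep(-5:3, each = 64L),
    expected_count = as.vector(counts),
    expected_value = as.vector(value)
  )
}
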