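# Anticodon placed at mature position 33 (0-based), the classical tRNA
# position 34 wobble site at its first base.
TRNA_ANTICODON_START <- 33L
TRNA_BODY_LENGTH <- 72L
TRNA_INTRON_LENGTH <- 10L

#' Simulate a tRNA pool and tRNA-seq reads with planted wobble inosine
#'
#' Builds one reference per tRNA in `config$trna_set`: a random body with the
#' annotated anticodon embedded, an optional intron just downstream of the
#' anticodon (exercising mature-reference construction), and a CCA tail on
#' intronless entries. Reads copy the mature reference end to end; with
#' probability `theta_t` the wobble adenosine is written as G (how reverse
#' transcriptase reads inosine), and every base is independently flipped to a
#' uniformly chosen other base with probability `seq_error_rate`.
#'
#' @param config A [simulation_config()]; `inosine_rates` supplies
#'   `theta_t` per tRNA and must only name tRNAs whose wobble base is A.
#' @param seed Seed for this sample; defaults to `config$seed`.
#' @return List of class `sim_trna`: `records` (mature reference tibble:
#'   `trna_id`, `isotype`, `anticodon`, `anticodon_start`, `mature_sequence`),
#'   `raw` (pre-splicing annotation tibble: `trna_id`, `isotype`,
#'   `anticodon`, `anticodon_start`, `intron_start`, `intron_end`,
#'   `sequence`), `reads` (tibble `read_id`, `trna_id`, `start`, `sequence`)
#'   and `truth` (planted `theta` per tRNA).
#' @export
simulate_trna_reads <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  set <- config$trna_set
  theta <- config$inosine_rates
  with_seed(stage_seed(seed, 5L), {
    bodies <- random_dna(rep(TRNA_BODY_LENGTH, nrow(set)))
    mature <- paste0(
      substr(bodies, 1L, TRNA_ANTICODON_START),
      set$anticodon,
      substr(bodies, TRNA_ANTICODON_START + 4L, TRNA_BODY_LENGTH),
      "CCA"
    )
    wobble <- substr(mature, TRNA_ANTICODON_START + 1L,
      TRNA_ANTICODON_START + 1L)
    bad <- names(theta)[wobble[match(names(theta), set$trna_id)] != "A"]
    if (length(bad)) {
      stop("inosine rate planted on tRNA without wobble A: ",
        paste(bad, collapse = ", "))
    }
    # Pre-splicing sequences: intron inserted 6 nt downstream of the
    # anticodon; intron-bearing entries are also written without the CCA
    # tail so that both maturation steps are exercised.
    intron_site <- TRNA_ANTICODON_START + 3L + 6L
    raw <- set
    raw$anticodon_start <- TRNA_ANTICODON_START
    raw$intron_start <- ifelse(set$has_intron, intron_site, NA_integer_)
    raw$intron_end <- ifelse(set$has_intron, intron_site + TRNA_INTRON_LENGTH,
      NA_integer_)
    introns <- random_dna(rep(TRNA_INTRON_LENGTH, nrow(set)))
    raw$sequence <- ifelse(set$has_intron,
      paste0(
        substr(mature, 1L, intron_site), introns,
        substr(mature, intron_site + 1L, TRNA_BODY_LENGTH + 3L - 3L)
      ),
      mature
    )

    n_per <- config$reads_per_trna
    trna_idx <- rep(seq_len(nrow(set)), each = n_per)
    th <- theta[set$trna_id[trna_idx]]
    th[is.na(th)] <- 0
    seqs <- mature[trna_idx]
    edit <- stats::runif(length(seqs)) < th
    substr(seqs[edit], TRNA_ANTICODON_START + 1L, TRNA_ANTICODON_START + 1L) <-
      "G"
    seqs <- apply_sequencing_errors(seqs, config$seq_error_rate)
    structure(list(
      records = tibble::tibble(
        trna_id = set$trna_id, isotype = set$isotype,
        anticodon = set$anticodon, anticodon_start = TRNA_ANTICODON_START,
        mature_sequence = mature
      ),
      raw = raw[, c("trna_id", "isotype", "anticodon", "anticodon_start",
        "intron_start", "intron_end", "sequence")],
      reads = tibble::tibble(
        read_id = sprintf("tr%06d", seq_along(seqs)),
        trna_id = set$trna_id[trna_idx],
        start = 0L,
        sequence = seqs
      ),
      truth = tibble::tibble(
        trna_id = set$trna_id, isotype = set$isotype,
        theta = unname(ifelse(is.na(theta[set$trna_id]), 0,
          theta[set$trna_id])),
        modified = set$trna_id %in% names(theta)
      )
    ), class = "sim_trna")
  })
}

# Independent per-base substitution to a uniformly drawn other base.
apply_sequencing_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  flat <- sample.int(total, n_err)
  ends <- cumsum(lens)
  read_i <- findInterval(flat - 1L, ends) + 1L
  pos <- flat - c(0L, ends)[read_i]
  for (k in seq_len(n_err)) {
    old <- substr(seqs[read_i[k]], pos[k], pos[k])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seqs[read_i[k]], pos[k], pos[k]) <- new
  }
  seqs
}

#' Write simulated tRNA references and reads to disk
#'
#' Writes the pre-splicing reference FASTA, its annotation TSV
#' (`trna_id`, `isotype`, `anticodon`, `anticodon_start`, `intron_start`,
#' `intron_end`; 0-based half-open intron), a SAM of reads aligned to the
#' mature reference, and the planted truth.
#'
#' @param sim A `sim_trna`.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_trna_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trna_fasta = file.path(dir, "trna_raw.fa"),
    trna_annotation = file.path(dir, "trna_annotation.tsv"),
    trna_sam = file.path(dir, "trna_reads.sam"),
    truth = file.path(dir, "trna_truth.tsv")
  )
  write_fasta(sim$raw$sequence, sim$raw$trna_id, paths["trna_fasta"])
  readr::write_tsv(sim$raw[, setdiff(names(sim$raw), "sequence")],
    paths["trna_annotation"])
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", sim$records$trna_id,
      nchar(sim$records$mature_sequence))
  )
  body <- sprintf("%s\t0\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t*",
    sim$reads$read_id, sim$reads$trna_id, sim$reads$start + 1L,
    nchar(sim$reads$sequence), sim$reads$sequence)
  writeLines(c(header, body), paths["trna_sam"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Build mature tRNA references from raw sequences and annotation
#'
#' Splices out annotated introns, appends the CCA tail when absent,
#' recomputes the anticodon offset in mature coordinates and verifies that
#' the expected anticodon is found there — the guard ensuring substitutions
#' are counted at the correct nucleotide.
#'
#' @param fasta Path to the raw (pre-splicing) tRNA FASTA.
#' @param annotation Path to the annotation TSV with columns `trna_id`,
#'   `isotype`, `anticodon`, `anticodon_start` (0-based, raw coordinates)
#'   and 0-based half-open `intron_start`/`intron_end` (NA when intronless).
#' @return Tibble of mature records: `trna_id`, `isotype`, `anticodon`,
#'   `anticodon_start` (mature coordinates), `mature_sequence` (ends in CCA),
#'   `wobble_base`.
#' @export
build_mature_reference <- function(fasta, annotation) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- stats::setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  ann <- readr::read_tsv(annotation, show_col_types = FALSE)
  missing <- setdiff(ann$trna_id, names(seqs))
  if (length(missing)) {
    stop("tRNAs missing from FASTA: ", paste(missing, collapse = ", "))
  }
  rows <- purrr::pmap_dfr(ann, function(trna_id, isotype, anticodon,
                                        anticodon_start, intron_start,
                                        intron_end, ...) {
    s <- seqs[[trna_id]]
    ac_start <- anticodon_start
    if (!is.na(intron_start) && !is.na(intron_end)) {
      if (intron_start >= intron_end || intron_end > nchar(s)) {
        stop("invalid intron interval for ", trna_id)
      }
      s <- paste0(substr(s, 1L, intron_start),
        substr(s, intron_end + 1L, nchar(s)))
      if (intron_start <= ac_start) {
        ac_start <- ac_start - (intron_end - intron_start)
      }
    }
    if (substr(s, nchar(s) - 2L, nchar(s)) != "CCA") s <- paste0(s, "CCA")
    found <- substr(s, ac_start + 1L, ac_start + 3L)
    if (found != anticodon) {
      stop("anticodon not found for ", trna_id, ": expected ", anticodon,
        " at position ", ac_start, ", found ", found)
    }
    tibble::tibble(
      trna_id = trna_id, isotype = isotype, anticodon = anticodon,
      anticodon_start = ac_start, mature_sequence = s,
      wobble_base = substr(s, ac_start + 1L, ac_start + 1L)
    )
  })
  rows
}

#' Base-count pileup of tRNA-seq reads
#'
#' Tallies A/C/G/T counts per reference position from ungapped, single-end
#' transcript-space alignments (SAM/BAM).
#'
#' @param path SAM or BAM of reads aligned to the mature tRNA reference.
#' @return Tibble of class `trna_pileup`: `trna_id`, `pos` (0-based),
#'   `A`, `C`, `G`, `T`, `depth`.
#' @export
trna_pileup <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(),
      overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "seq", "flag", "cigar")
  ))[[1]]
  keep <- !bitwAnd(res$flag, 4L)
  if (any(grepl("[^0-9M]", res$cigar[keep]))) {
    stop("only ungapped (all-M CIGAR) tRNA alignments are supported")
  }
  seqs <- as.character(res$seq)[keep]
  rname <- as.character(res$rname)[keep]
  start0 <- res$pos[keep] - 1L
  lens <- nchar(seqs)
  base <- unlist(strsplit(seqs, ""), use.names = FALSE)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    start0[i] + seq_len(lens[i]) - 1L
  }), use.names = FALSE)
  trna <- rep.int(rname, lens)
  tab <- tibble::tibble(trna_id = trna, pos = pos, base = base) %>%
    dplyr::filter(.data$base %in% c("A", "C", "G", "T")) %>%
    dplyr::count(.data$trna_id, .data$pos, .data$base) %>%
    tidyr::pivot_wider(names_from = "base", values_from = "n",
      values_fill = 0L)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(tab)) tab[[b]] <- 0L
  tab <- tab[, c("trna_id", "pos", "A", "C", "G", "T")]
  tab$depth <- tab$A + tab$C + tab$G + tab$T
  structure(dplyr::arrange(tab, .data$trna_id, .data$pos),
    class = c("trna_pileup", class(tab)))
}

#' Quantify wobble inosine from a tRNA pileup
#'
#' Inosine is read as G by sequencing, so the per-tRNA A34I level is the G
#' fraction at the first anticodon base. hetADAT-substrate tRNAs must carry
#' reference A at that position; tRNAs with another wobble base are reported
#' but excluded from the modification aggregate. Entries with wobble depth
#' `<= min_depth` are excluded from the per-tRNA distribution (flag
#' `included`) but still contribute to the read-weighted aggregate.
#'
#' @param pileup A [trna_pileup()].
#' @param records Mature records from [build_mature_reference()].
#' @param min_depth Depth above which a tRNA enters the per-tRNA
#'   distribution (default 10, i.e. more than 10 reads).
#' @return Tibble of class `inosine_table`: `trna_id`, `isotype`,
#'   `anticodon`, `wobble_base`, `depth`, `g_count`, `fraction`, `included`,
#'   `is_substrate`; attributes `aggregate` (read-weighted A34I level over
#'   substrate tRNAs) and `isotype_summary`.
#' @export
estimate_inosine <- function(pileup, records, min_depth = 10) {
  het <- records$isotype %in% names(HETADAT_ISOTYPES)
  bad <- records$trna_id[het & records$wobble_base != "A"]
  if (length(bad)) {
    stop("hetADAT substrate without wobble A in reference: ",
      paste(bad, collapse = ", "))
  }
  wob <- dplyr::inner_join(
    records[, c("trna_id", "isotype", "anticodon", "anticodon_start",
      "wobble_base")],
    pileup, by = "trna_id"
  ) %>%
    dplyr::filter(.data$pos == .data$anticodon_start)
  out <- tibble::tibble(
    trna_id = wob$trna_id, isotype = wob$isotype, anticodon = wob$anticodon,
    wobble_base = wob$wobble_base, depth = wob$depth, g_count = wob$G,
    fraction = wob$G / wob$depth,
    is_substrate = wob$wobble_base == "A" &
      wob$isotype %in% names(HETADAT_ISOTYPES)
  )
  out$included <- out$depth > min_depth & out$is_substrate
  sub <- out[out$is_substrate, ]
  aggregate <- sum(sub$g_count) / sum(sub$depth)
  iso <- out %>%
    dplyr::filter(.data$included) %>%
    dplyr::group_by(.data$isotype) %>%
    dplyr::summarise(
      mean_fraction = mean(.data$fraction), n_trna = dplyr::n(),
      .groups = "drop"
    )
  structure(out,
    class = c("inosine_table", class(out)),
    aggregate = aggregate, isotype_summary = iso, min_depth = min_depth
  )
}

#' @rdname estimate_inosine
#' @param x An `inosine_table`.
#' @export
inosine_aggregate <- function(x) attr(x, "aggregate")

#' @rdname estimate_inosine
#' @export
inosine_isotype_summary <- function(x) attr(x, "isotype_summary")

#' Compare wobble-inosine levels between two conditions
#'
#' Takes one `inosine_table` (or a list of replicate tables) per condition
#' and reports per-tRNA and per-isotype differences (B minus A) of replicate-
#' mean fractions. With at least two replicates per condition the per-sample
#' aggregate levels are compared with a two-sided t-test; with single
#' samples the test is omitted with a warning.
#'
#' @param a,b An `inosine_table` or list of replicate `inosine_table`s.
#' @return List of class `inosine_comparison`: `per_trna`, `per_isotype`,
#'   `aggregates` (per replicate) and `test` (htest or `NULL`).
#' @export
compare_inosine_conditions <- function(a, b) {
  as_list <- function(x) if (inherits(x, "inosine_table")) list(x) else x
  a <- as_list(a)
  b <- as_list(b)
  mean_tbl <- function(tabs) {
    dplyr::bind_rows(lapply(tabs, tibble::as_tibble)) %>%
      dplyr::filter(.data$is_substrate) %>%
      dplyr::group_by(.data$trna_id, .data$isotype) %>%
      dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  }
  ma <- mean_tbl(a)
  mb <- mean_tbl(b)
  per_trna <- dplyr::inner_join(ma, mb, by = c("trna_id", "isotype"),
    suffix = c("_a", "_b")) %>%
    dplyr::mutate(delta = .data$fraction_b - .data$fraction_a)
  if (nrow(per_trna) == 0L) stop("no shared tRNA ids between conditions")
  per_isotype <- per_trna %>%
    dplyr::group_by(.data$isotype) %>%
    dplyr::summarise(mean_delta = mean(.data$delta), n_trna = dplyr::n(),
      .groups = "drop")
  agg_a <- vapply(a, inosine_aggregate, numeric(1))
  agg_b <- vapply(b, inosine_aggregate, numeric(1))
  test <- NULL
  if (length(agg_a) >= 2L && length(agg_b) >= 2L) {
    test <- stats::t.test(agg_b, agg_a)
  } else {
    warning("fewer than 2 replicates per condition; aggregate test omitted")
  }
  structure(list(
    per_trna = per_trna, per_isotype = per_isotype,
    aggregates = tibble::tibble(
      condition = rep(c("a", "b"), c(length(agg_a), length(agg_b))),
      aggregate = c(agg_a, agg_b)
    ),
    test = test
  ), class = "inosine_comparison")
}
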