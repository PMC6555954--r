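SITE_POSITIONS <- -5:3 # codon positions; 0 = A-site, -1 = P, -2 = E

#' Reading-frame periodicity and P-site offset per read length
#'
#' For each footprint length, counts 5' read ends falling in each reading
#' frame within the window of codon positions -7..+32 around the translation
#' initiation site, and the per-codon majority frame. A read length is
#' selected when the globally most abundant frame (a) also wins more codon
#' positions than any other frame, and (b) is at least `fold` times more
#' abundant than the runner-up both in total reads and in per-codon
#' majorities. The selected frame determines the 5' trim (0, 1 or 2 nt) that
#' places the P-site at read nucleotides 12-14 and the A-site at 15-17
#' (0-based).
#'
#' @param reads Tibble of aligned footprints (`transcript_id`, `start`,
#'   `length`), e.g. from [read_footprints()] or `sim_footprints$reads`.
#' @param cds Tibble of CDS intervals (`transcript_id`, `cds_start`,
#'   `cds_end`), e.g. from [read_cds_bed()].
#' @param tis_window Codon-position window around the TIS used for counting.
#' @param fold Required dominance ratio over the runner-up frame.
#' @return Tibble of class `frame_profile`, one row per read length:
#'   `read_length`, `n_reads`, `frame_0/1/2` (total 5' end counts),
#'   `codon_wins_0/1/2`, `dominant_frame`, `selected`, `trim`, `reason`.
#' @export
profile_frames <- function(reads, cds, tis_window = c(-7L, 32L), fold = 5) {
  d <- dplyr::inner_join(reads, cds, by = "transcript_id")
  d$rel <- d$start - d$cds_start
  d$codon_pos <- d$rel %/% 3L
  d$frame <- d$rel %% 3L
  d <- d[d$codon_pos >= tis_window[1] & d$codon_pos <= tis_window[2], ]
  all_lengths <- sort(unique(reads$length))
  rows <- lapply(all_lengths, function(L) {
    dl <- d[d$length == L, ]
    base <- tibble::tibble(
      read_length = L, n_reads = nrow(dl),
      frame_0 = sum(dl$frame == 0L), frame_1 = sum(dl$frame == 1L),
      frame_2 = sum(dl$frame == 2L)
    )
    if (nrow(dl) == 0L) {
      return(dplyr::mutate(base,
        codon_wins_0 = 0L, codon_wins_1 = 0L, codon_wins_2 = 0L,
        dominant_frame = NA_integer_, selected = FALSE, trim = NA_integer_,
        reason = "no data"
      ))
    }
    totals <- c(base$frame_0, base$frame_1, base$frame_2)
    per_codon <- table(dl$codon_pos, factor(dl$frame, levels = 0:2))
    maj <- apply(per_codon, 1L, which.max) - 1L
    # a codon position only counts as a win for its strict majority frame
    strict <- apply(per_codon, 1L, function(x) sum(x == max(x)) == 1L)
    wins <- tabulate(maj[strict] + 1L, nbins = 3L)
    g <- which.max(totals) - 1L
    ok <- TRUE
    reason <- "selected"
    if (wins[g + 1L] <= max(wins[-(g + 1L)])) {
      ok <- FALSE
      reason <- "per-codon majority frame disagrees with total"
    } else if (totals[g + 1L] < fold * max(totals[-(g + 1L)])) {
      ok <- FALSE
      reason <- sprintf("total dominance below %g-fold", fold)
    } else if (wins[g + 1L] < fold * max(wins[-(g + 1L)])) {
      ok <- FALSE
      reason <- sprintf("per-codon dominance below %g-fold", fold)
    }
    dplyr::mutate(base,
      codon_wins_0 = wins[1], codon_wins_1 = wins[2], codon_wins_2 = wins[3],
      dominant_frame = g, selected = ok,
      trim = if (ok) (3L - g) %% 3L else NA_integer_,
      reason = reason
    )
  })
  structure(dplyr::bind_rows(rows),
    class = c("frame_profile", "tbl_df", "tbl", "data.frame"))
}

# Frame profile rows for fixed read lengths with a known frame
# (the human-style processing path: lengths 27-29, frame 0, P-site offset 12).
forced_frame_profile <- function(lengths, frame = 0L) {
  tibble::tibble(
    read_length = as.integer(lengths), n_reads = NA_integer_,
    frame_0 = NA_integer_, frame_1 = NA_integer_, frame_2 = NA_integer_,
    codon_wins_0 = NA_integer_, codon_wins_1 = NA_integer_,
    codon_wins_2 = NA_integer_,
    dominant_frame = as.integer(frame), selected = TRUE,
    trim = (3L - as.integer(frame)) %% 3L, reason = "forced"
  )
}

#' Extract E/P/A-site codon counts from footprints
#'
#' Filters footprints (mapping quality, CDS overlap, selected read length,
#' 5'-end frame agreement), trims each read's 5' end so that the P-site sits
#' at read nucleotides 12-14, splits the first 27 trimmed nucleotides into
#' nine codons at positions -5..+3 (0 = A-site, -1 = P, -2 = E) and
#' accumulates codon counts per position. Reads shorter than 27 nt after
#' trimming, or whose 27-nt window leaves the transcript, are discarded
#' entirely so every counted read contributes exactly one codon to each of
#' the nine positions.
#'
#' @param reads Tibble of aligned footprints (`transcript_id`, `start`,
#'   `length`, optionally `mapq`).
#' @param cds CDS intervals (`transcript_id`, `cds_start`, `cds_end`).
#' @param transcripts Transcript sequences (`transcript_id`, `sequence`),
#'   e.g. from [load_transcripts()].
#' @param profiles A `frame_profile` from [profile_frames()], or `NULL` to
#'   force the human-style default of read lengths 27-29 in frame 0.
#' @param lengths Optional read-length whitelist applied on top of the
#'   profile's selection.
#' @param min_overlap Minimum fraction of the read overlapping the CDS.
#' @param mapq_min Minimum mapping quality (reads without `mapq` pass).
#' @return Long tibble of class `site_counts` with columns `codon`,
#'   `position`, `count`; attributes `n_reads_used` and `discards` (tally of
#'   per-reason discarded reads).
#' @export
extract_site_codons <- function(reads, cds, transcripts, profiles = NULL,
                                lengths = NULL, min_overlap = 0.5,
                                mapq_min = 20) {
  if (is.null(profiles)) profiles <- forced_frame_profile(27:29)
  sel <- profiles[profiles$selected, c("read_length", "dominant_frame", "trim")]
  if (!is.null(lengths)) sel <- sel[sel$read_length %in% lengths, ]
  if (nrow(sel) == 0L) stop("no selected read lengths")
  n0 <- nrow(reads)
  discards <- c(
    mapq = 0L, low_overlap = 0L, unselected_length = 0L,
    wrong_frame = 0L, too_short = 0L, outside_transcript = 0L
  )
  if ("mapq" %in% names(reads)) {
    keep <- is.na(reads$mapq) | reads$mapq >= mapq_min
    discards["mapq"] <- sum(!keep)
    reads <- reads[keep, ]
  }
  d <- dplyr::inner_join(reads, cds, by = "transcript_id")
  ov <- pmin(d$start + d$length, d$cds_end) - pmax(d$start, d$cds_start)
  keep <- ov / d$length >= min_overlap
  discards["low_overlap"] <- sum(!keep)
  d <- d[keep, ]
  idx <- match(d$length, sel$read_length)
  discards["unselected_length"] <- sum(is.na(idx))
  d <- d[!is.na(idx), ]
  idx <- idx[!is.na(idx)]
  frame <- (d$start - d$cds_start) %% 3L
  keep <- frame == sel$dominant_frame[idx]
  discards["wrong_frame"] <- sum(!keep)
  d <- d[keep, ]
  idx <- idx[keep]
  trim <- sel$trim[idx]
  keep <- d$length - trim >= 27L
  discards["too_short"] <- sum(!keep)
  d <- d[keep, ]
  trim <- trim[keep]
  tstart <- d$start + trim
  tx_seq <- transcripts$sequence[match(d$transcript_id,
    transcripts$transcript_id)]
  keep <- tstart >= 0L & tstart + 27L <= nchar(tx_seq)
  discards["outside_transcript"] <- sum(!keep)
  d <- d[keep, ]
  tstart <- tstart[keep]
  tx_seq <- tx_seq[keep]

  counts <- matrix(0L, nrow = 64L, ncol = 9L,
    dimnames = list(CODONS, as.character(SITE_POSITIONS)))
  for (i in seq_along(SITE_POSITIONS)) {
    nt0 <- tstart + 3L * (i - 1L)
    cod <- substring(tx_seq, nt0 + 1L, nt0 + 3L)
    tab <- tabulate(factor(cod, levels = CODONS), nbins = 64L)
    counts[, i] <- tab
  }
  out <- tibble::tibble(
    codon = rep(CODONS, length(SITE_POSITIONS)),
    position = rep(SITE_POSITIONS, each = 64L),
    count = as.integer(counts)
  )
  structure(out,
    class = c("site_counts", class(out)),
    n_reads_used = nrow(d), discards = discards, n_reads_input = n0
  )
}

#' Nine-position normalization of site codon counts
#'
#' Converts counts to per-position codon fractions and divides each codon's
#' fraction at a position by that codon's mean fraction across all nine
#' positions. Values of exactly 1 mean the codon is no more or less frequent
#' at a position than its footprint-wide average; mRNA abundance and codon
#' composition differences cancel out. Codons never observed are reported as
#' missing (`NA`), not zero.
#'
#' @param counts A `site_counts` tibble from [extract_site_codons()].
#' @return Tibble of class `site_norm`: `codon`, `position`, `fraction`,
#'   `value`.
#' @export
normalize_site_counts <- function(counts) {
  if (!all(c("codon", "position", "count") %in% names(counts))) {
    stop("expected a site_counts tibble")
  }
  if (sum(counts$count) == 0) stop("empty site count matrix")
  totals <- tapply(counts$count, counts$position, sum)
  if (any(totals == 0)) stop("a position has zero counts")
  d <- tibble::as_tibble(counts[, c("codon", "position", "count")])
  d$fraction <- d$count / as.numeric(totals[as.character(d$position)])
  mean_frac <- tapply(d$fraction, d$codon, mean)
  mf <- as.numeric(mean_frac[d$codon])
  d$value <- ifelse(mf > 0, d$fraction / mf, NA_real_)
  structure(d[, c("codon", "position", "fraction", "value")],
    class = c("site_norm", "tbl_df", "tbl", "data.frame"))
}

#' Differential codon usage between conditions at each ribosome position
#'
#' Tests, for every (codon, position) pair, whether the nine-position-
#' normalized codon value differs between two conditions, using the
#' biological replicates as the unit of observation. Welch's unequal-
#' variance two-sided t-test is the default; `var_equal = TRUE` restores the
#' pooled-variance test. P-values are Benjamini-Hochberg adjusted across all
#' tested pairs. The fold change is `log2(mean(B) / mean(A))`.
#'
#' @param cond_a,cond_b Lists of replicate `site_norm` tibbles
#'   (at least 2 each).
#' @param alpha FDR threshold recorded in the `significant` column.
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch's.
#' @return Tibble of class `codon_shift`: `codon`, `position`, `mean_a`,
#'   `mean_b`, `log2_fc`, `t_statistic`, `p`, `q`, `significant`,
#'   `degenerate` (zero-variance flag), plus hetADAT annotation.
#' @export
differential_codon_usage <- function(cond_a, cond_b, alpha = 0.05,
                                     var_equal = FALSE) {
  stopifnot(length(cond_a) >= 2L, length(cond_b) >= 2L)
  stack <- function(reps, cond) {
    dplyr::bind_rows(lapply(seq_along(reps), function(i) {
      r <- tibble::as_tibble(reps[[i]])[, c("codon", "position", "value")]
      r$replicate <- i
      r$cond <- cond
      r
    }))
  }
  d <- dplyr::bind_rows(stack(cond_a, "a"), stack(cond_b, "b"))
  res <- d %>%
    dplyr::group_by(.data$codon, .data$position) %>%
    dplyr::summarise(
      test = list(welch_row(
        .data$value[.data$cond == "a"], .data$value[.data$cond == "b"],
        var_equal = var_equal
      )),
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("test")
  tested <- !is.na(res$p)
  res$q <- NA_real_
  res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$significant <- !is.na(res$q) & res$q < alpha
  ann <- codon_table()[, c("codon", "is_stop", "hetadat_class")]
  res <- dplyr::left_join(res, ann, by = "codon")
  structure(res,
    class = c("codon_shift", "tbl_df", "tbl", "data.frame"),
    alpha = alpha, var_equal = var_equal
  )
}

# One Welch (or Student) t-test row with documented degenerate rules:
# both groups constant and equal -> p = 1; constant but unequal -> smallest
# positive double, flagged; any missing replicate value -> untested (NA).
welch_row <- function(x, y, var_equal = FALSE) {
  out <- list(
    mean_a = mean(x), mean_b = mean(y),
    log2_fc = if (isTRUE(all.equal(mean(x), mean(y)))) 0 else
      log2(mean(y) / mean(x)),
    t_statistic = NA_real_, p = NA_real_, degenerate = FALSE
  )
  if (anyNA(x) || anyNA(y)) {
    out$mean_a <- NA_real_
    out$mean_b <- NA_real_
    out$log2_fc <- NA_real_
    return(out)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    out$degenerate <- TRUE
    out$p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else
      .Machine$double.xmin
    out$t_statistic <- if (out$p == 1) 0 else Inf * sign(mean(y) - mean(x))
    return(out)
  }
  tt <- stats::t.test(y, x, var.equal = var_equal)
  out$t_statistic <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

#' Correlate per-codon usage shifts between two datasets
#'
#' Pearson correlation of per-codon log2 fold-changes at one ribosome
#' position between two differential tables (e.g. human vs mouse
#' differentiation), reported for all shared codons and for the hetADAT
#' codon subsets.
#'
#' @param table_a,table_b `codon_shift` tibbles.
#' @param position Ribosome-protected codon position (default -1, the
#'   P-site).
#' @return Tibble with one row per codon set (`all`, `nnC`, `nnT`, `nnA`,
#'   `non_hetadat`): `set`, `n`, `r`, `p`.
#' @export
correlate_codon_shifts <- function(table_a, table_b, position = -1L) {
  a <- table_a[table_a$position == position, c("codon", "log2_fc")]
  b <- table_b[table_b$position == position, c("codon", "log2_fc")]
  m <- dplyr::inner_join(a, b, by = "codon", suffix = c("_a", "_b"))
  m <- m[stats::complete.cases(m$log2_fc_a, m$log2_fc_b), ]
  if (nrow(m) < 3L) stop("fewer than 3 shared codons at position ", position)
  ann <- codon_table()
  sets <- list(
    all = m$codon,
    nnC = intersect(m$codon, hetadat_codons("nnC")),
    nnT = intersect(m$codon, hetadat_codons("nnT")),
    nnA = intersect(m$codon, hetadat_codons("nnA")),
    non_hetadat = setdiff(m$codon,
      ann$codon[!is.na(ann$hetadat_class)])
  )
  purrr::map_dfr(names(sets), function(s) {
    mm <- m[m$codon %in% sets[[s]], ]
    if (nrow(mm) < 3L) {
      return(tibble::tibble(set = s, n = nrow(mm), r = NA_real_,
        p = NA_real_))
    }
    ct <- stats::cor.test(mm$log2_fc_a, mm$log2_fc_b, method = "pearson")
    tibble::tibble(set = s, n = nrow(mm), r = unname(ct$estimate),
      p = ct$p.value)
  })
}

#' Concordance of positional codon fractions with the genomic distribution
#'
#' The codon fractions at the positions flanking the tRNA-bound sites
#' (-5..-3 and +1..+3) are expected to follow the expression-weighted
#' genomic codon distribution; the A- and P-sites may deviate. Pearson r per
#' position against that distribution provides the quality-control gate.
#'
#' @param counts A `site_counts` tibble.
#' @param genomic Output of [genomic_codon_distribution()].
#' @return Tibble with `position`, `n_codons`, `r`.
#' @export
flank_concordance <- function(counts, genomic) {
  if (sum(counts$count) == 0) stop("empty site count matrix")
  d <- tibble::as_tibble(counts) %>%
    dplyr::group_by(.data$position) %>%
    dplyr::mutate(fraction = .data$count / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::left_join(genomic, by = "codon")
  d %>%
    dplyr::group_by(.data$position) %>%
    dplyr::summarise(
      n_codons = sum(.data$count > 0),
      r = stats::cor(.data$fraction, .data$freq),
      .groups = "drop"
    )
}

#' Pool replicate site-count matrices for display
#'
#' Sums counts across replicates; used for figure-style summaries while
#' statistical testing always runs on the per-replicate matrices.
#'
#' @param counts_list List of `site_counts` tibbles.
#' @return A pooled `site_counts` tibble.
#' @export
pool_site_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L)
  d <- dplyr::bind_rows(lapply(counts_list, tibble::as_tibble)) %>%
    dplyr::group_by(.data$codon, .data$position) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  structure(d,
    class = c("site_counts", "tbl_df", "tbl", "data.frame"),
    n_reads_used = sum(vapply(counts_list,
      function(x) attr(x, "n_reads_used") %||% NA_integer_, numeric(1)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
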