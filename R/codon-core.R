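# Split a vector of CDS strings into per-gene codon character vectors.
split_codons <- function(seqs) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  })
}

#' Load coding sequences from a FASTA file
#'
#' Reads one representative CDS per gene and validates the coding-sequence
#' contract: length a multiple of three, and at most one stop codon, located
#' at the terminal position. Isoform collapsing is the caller's job; duplicate
#' gene identifiers are rejected.
#'
#' @param path Path to a FASTA file of coding sequences (DNA, `A/C/G/T/N`).
#' @param permissive If `TRUE`, sequences with internal stop codons are kept
#'   (with a warning) instead of raising an error.
#' @return A tibble with columns `gene_id`, `sequence` and `length`
#'   (nucleotides), in file order.
#' @export
load_cds <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate gene_ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  seqs <- toupper(as.character(ss))
  validate_cds(tibble::tibble(
    gene_id = ids, sequence = unname(seqs),
    length = unname(nchar(seqs))
  ), permissive = permissive)
}

# Shared validator so simulated and loaded CDS obey the same contract.
validate_cds <- function(cds, permissive = FALSE) {
  bad_alpha <- grepl("[^ACGTN]", cds$sequence)
  if (any(bad_alpha)) {
    stop(
      "non-ACGTN characters in: ",
      paste(cds$gene_id[bad_alpha], collapse = ", ")
    )
  }
  bad_len <- cds$length %% 3L != 0L | cds$length == 0L
  if (any(bad_len)) {
    stop(
      "CDS length not a positive multiple of 3 for: ",
      paste(cds$gene_id[bad_len], collapse = ", ")
    )
  }
  codon_list <- split_codons(cds$sequence)
  internal <- vapply(codon_list, function(cod) {
    hits <- which(cod %in% STOP_CODONS)
    length(hits[hits < length(cod)]) > 0L
  }, logical(1))
  if (any(internal)) {
    msgs <- vapply(which(internal), function(i) {
      pos <- which(codon_list[[i]] %in% STOP_CODONS)[1]
      paste0(cds$gene_id[i], " (internal stop at codon ", pos, ")")
    }, character(1))
    msg <- paste0("internal stop codon in: ", paste(msgs, collapse = ", "))
    if (permissive) warning(msg) else stop(msg)
  }
  cds
}

#' Per-gene codon frequency vectors and positional GC content
#'
#' Represents each gene as a vector of 64 relative codon frequencies,
#' together with the G+C fraction at each codon position (GC1/GC2/GC3) and
#' overall. Codons containing `N` are skipped and excluded from all
#' denominators. Stop codons are counted by default; set
#' `include_stops = FALSE` for amino-acid-level summaries over the 61 sense
#' codons.
#'
#' @param cds A tibble as returned by [load_cds()] or
#'   [simulate_transcriptome()] (columns `gene_id`, `sequence`).
#' @param include_stops Count the three stop codons (default `TRUE`).
#' @return A tibble with one row per gene: `gene_id`, one column per codon in
#'   fixed alphabetical order (relative frequency, summing to 1), `n_codons`,
#'   `gc1`, `gc2`, `gc3`, `gc_total`.
#' @examples
#' cds <- tibble::tibble(gene_id = "g1", sequence = "ATGGCTTAA")
#' codon_usage(cds)
#' @export
codon_usage <- function(cds, include_stops = TRUE) {
  stopifnot(is.data.frame(cds), all(c("gene_id", "sequence") %in% names(cds)))
  keep_codons <- if (include_stops) CODONS else SENSE_CODONS
  codon_list <- split_codons(toupper(cds$sequence))
  rows <- lapply(seq_along(codon_list), function(i) {
    cod <- codon_list[[i]]
    cod <- cod[!grepl("N", cod, fixed = TRUE)]
    cod <- cod[cod %in% keep_codons]
    n <- length(cod)
    if (n == 0L) {
      stop("no countable codons for gene ", cds$gene_id[i])
    }
    counts <- tabulate(factor(cod, levels = CODONS), nbins = 64L)
    gc <- vapply(1:3, function(p) {
      mean(substr(cod, p, p) %in% c("G", "C"))
    }, numeric(1))
    c(counts / n, n, gc, mean(gc))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(CODONS, "n_codons", "gc1", "gc2", "gc3", "gc_total")
  out <- tibble::as_tibble(mat)
  out$n_codons <- as.integer(out$n_codons)
  dplyr::bind_cols(tibble::tibble(gene_id = cds$gene_id), out)
}

#' Fraction of hetADAT-dependent nnC codons per gene
#'
#' The eight `nnC` codons (GCC, CGC, ATC, CTC, CCC, TCC, ACC, GTC) rely on
#' wobble-inosine-modified tRNAs for translation. This computes, per gene, the
#' fraction of codons falling in that set, the statistic used to define
#' nnC-high genes.
#'
#' @inheritParams codon_usage
#' @return A tibble with columns `gene_id`, `n_codons`, `nnc_fraction`.
#' @examples
#' cds <- tibble::tibble(gene_id = "g1", sequence = "GCCGCCATGTAA")
#' nnc_codon_fraction(cds)
#' @export
nnc_codon_fraction <- function(cds) {
  nnc <- hetadat_codons("nnC")
  codon_list <- split_codons(toupper(cds$sequence))
  res <- vapply(seq_along(codon_list), function(i) {
    cod <- codon_list[[i]]
    cod <- cod[!grepl("N", cod, fixed = TRUE)]
    if (length(cod) == 0L) stop("no countable codons for gene ", cds$gene_id[i])
    c(length(cod), sum(cod %in% nnc) / length(cod))
  }, numeric(2))
  tibble::tibble(
    gene_id = cds$gene_id,
    n_codons = as.integer(res[1, ]),
    nnc_fraction = res[2, ]
  )
}

#' Expression-weighted genomic codon distribution
#'
#' Averages per-gene codon frequency vectors, optionally weighted by gene
#' expression, giving the background codon distribution that footprint flank
#' positions are expected to follow.
#'
#' @param usage Codon usage tibble from [codon_usage()].
#' @param expression Optional tibble with `gene_id` and `expression` weights;
#'   `NULL` gives the unweighted mean.
#' @return A tibble with columns `codon` and `freq` (summing to 1).
#' @export
genomic_codon_distribution <- function(usage, expression = NULL) {
  w <- rep(1, nrow(usage))
  if (!is.null(expression)) {
    idx <- match(usage$gene_id, expression$gene_id)
    if (anyNA(idx)) stop("expression missing for some genes")
    w <- expression$expression[idx]
  }
  freq <- colSums(as.matrix(usage[, CODONS]) * w) / sum(w)
  tibble::tibble(codon = CODONS, freq = unname(freq))
}

#' Write / read codon usage tables as TSV
#'
#' Plain-TSV round trip for [codon_usage()] output: `gene_id`, the 64 codon
#' columns in fixed alphabetical order, `n_codons`, `gc1`, `gc2`, `gc3`,
#' `gc_total`.
#'
#' @param usage Codon usage tibble.
#' @param path Output path.
#' @return `write_codon_usage()` returns `path` invisibly;
#'   `read_codon_usage()` returns the tibble.
#' @export
write_codon_usage <- function(usage, path) {
  readr::write_tsv(usage, path)
  invisible(path)
}

#' @rdname write_codon_usage
#' @export
read_codon_usage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
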