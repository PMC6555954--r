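#' Simulate a transcriptome with controllable codon usage
#'
#' Generates `n_genes` coding sequences, each starting with ATG, ending with
#' a single stop codon and free of internal stops. Every gene draws a target
#' third-position GC (GC3) uniformly from `gc3_range`; interior codons are
#' then sampled from the 61 sense codons with weight `p` for G/C-ending and
#' `1 - p` for A/T-ending codons, so realized GC3 tracks the planted target.
#' Each CDS is embedded in a transcript between random UTRs so that
#' footprints spanning the first and last codons fit inside the transcript.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_transcriptome` with elements
#'   `cds` (tibble: `gene_id`, `sequence`, `length`),
#'   `transcripts` (tibble: `transcript_id`, `sequence`, `length`,
#'   `cds_start`, `cds_end`; 0-based half-open CDS interval), and
#'   `truth` (tibble: `gene_id`, `gc3_planted`, `n_codons`).
#' @examples
#' tx <- simulate_transcriptome(simulation_config(seed = 1, n_genes = 20))
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 1L), {
    n <- config$n_genes
    len <- sample_int_range(config$length_range_codons[1],
      config$length_range_codons[2], n)
    gc3 <- stats::runif(n, config$gc3_range[1], config$gc3_range[2])
    third_sc <- substr(SENSE_CODONS, 3, 3) %in% c("G", "C")
    cds_seq <- vapply(seq_len(n), function(i) {
      w <- ifelse(third_sc, gc3[i], 1 - gc3[i])
      interior <- sample(SENSE_CODONS, len[i] - 2L, replace = TRUE, prob = w)
      paste(c("ATG", interior, sample(STOP_CODONS, 1L)), collapse = "")
    }, character(1))
    utr5 <- sample_int_range(config$utr_length_range[1],
      config$utr_length_range[2], n)
    utr3 <- sample_int_range(config$utr_length_range[1],
      config$utr_length_range[2], n)
    gene_id <- sprintf("g%04d", seq_len(n))
    tx_seq <- paste0(random_dna(utr5), cds_seq, random_dna(utr3))
    structure(list(
      cds = tibble::tibble(
        gene_id = gene_id, sequence = cds_seq, length = nchar(cds_seq)
      ),
      transcripts = tibble::tibble(
        transcript_id = gene_id, sequence = tx_seq, length = nchar(tx_seq),
        cds_start = utr5, cds_end = utr5 + nchar(cds_seq)
      ),
      truth = tibble::tibble(
        gene_id = gene_id, gc3_planted = gc3, n_codons = len
      )
    ), class = "sim_transcriptome")
  })
}

#' Write a simulated transcriptome to FASTA/BED/TSV
#'
#' Writes the transcript sequences as FASTA, the CDS intervals as a 6-column
#' BED (0-based, half-open), the bare CDS sequences as a second FASTA, and
#' the planted truth as TSV.
#'
#' @param tx A `sim_transcriptome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_transcriptome <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    transcript_fasta = file.path(dir, "transcripts.fa"),
    cds_fasta = file.path(dir, "cds.fa"),
    cds_bed = file.path(dir, "cds.bed"),
    truth = file.path(dir, "transcriptome_truth.tsv")
  )
  write_fasta(tx$transcripts$sequence, tx$transcripts$transcript_id,
    paths["transcript_fasta"])
  write_fasta(tx$cds$sequence, tx$cds$gene_id, paths["cds_fasta"])
  bed <- tx$transcripts
  readr::write_tsv(
    tibble::tibble(
      chrom = bed$transcript_id, start = bed$cds_start, end = bed$cds_end,
      name = bed$transcript_id, score = 0L, strand = "+"
    ),
    paths["cds_bed"], col_names = FALSE
  )
  readr::write_tsv(tx$truth, paths["truth"])
  invisible(paths)
}

write_fasta <- function(seqs, ids, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a BED file of CDS intervals
#'
#' @param path 6-column (or 3-column) BED, 0-based half-open.
#' @return Tibble with `transcript_id`, `cds_start`, `cds_end`.
#' @export
read_cds_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(
    transcript_id = bed[[1]], cds_start = bed[[2]], cds_end = bed[[3]]
  )
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA of transcript sequences.
#' @return Tibble with `transcript_id`, `sequence`, `length`.
#' @export
load_transcripts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    transcript_id = sub("\\s.*$", "", names(ss)),
    sequence = toupper(unname(as.character(ss))),
    length = nchar(as.character(ss))
  )
}

#' Simulate per-gene expression and differential-expression tables
#'
#' Baseline expression is log-normal. A planted fraction of genes changes
#' between conditions with a log2 fold-change of random sign drawn from
#' `de_log2fc_range`; those genes receive small adjusted p-values, the rest
#' draw from the null. A translation-efficiency component is planted on top:
#' a small fraction of genes gains a ribosome-occupancy change exceeding the
#' two-fold boundary, with the odds of the "higher" class multiplied by
#' `te_odds` for genes whose hetADAT-nnC codon fraction exceeds the top
#' percentile (when `nnc` is supplied).
#'
#' @param config A [simulation_config()].
#' @param tx A `sim_transcriptome`.
#' @param nnc Optional output of [nnc_codon_fraction()] used to couple the
#'   planted translation-efficiency classes to nnC-rich genes.
#' @param te_alt_fraction Baseline probability that a gene is planted in the
#'   `higher` (and, independently, `lower`) occupancy class.
#' @param te_odds Odds multiplier for the `higher` class among nnC-high
#'   genes. The default 3 turns a 5% baseline into ~13.6% of nnC-high genes
#'   with enhanced occupancy.
#' @param te_odds_lower Odds multiplier for the `lower` class among nnC-high
#'   genes (default 1.45, turning a 5% baseline into ~7.1%), so that
#'   nnC-high genes are enriched for changes in both directions.
#' @param nnc_percentile Percentile defining nnC-high genes.
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return List of class `sim_expression`: `expression` (tibble `gene_id`,
#'   `expression_a`, `expression_b`), `de_rna` and `de_ribo` (tibbles
#'   `gene_id`, `log2fc`, `padj`), and `truth` (planted DE status, TE class
#'   and nnC-high flag per gene).
#' @export
simulate_expression <- function(config, tx, nnc = NULL,
                                te_alt_fraction = 0.05, te_odds = 3,
                                te_odds_lower = 1.45,
                                nnc_percentile = 99, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(stage_seed(seed, 2L), {
    n <- nrow(tx$cds)
    gene_id <- tx$cds$gene_id
    base <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    is_de <- stats::runif(n) < config$de_fraction
    lfc <- ifelse(is_de,
      sample(c(-1, 1), n, replace = TRUE) *
        stats::runif(n, config$de_log2fc_range[1], config$de_log2fc_range[2]),
      stats::rnorm(n, 0, 0.1)
    )
    padj_rna <- ifelse(is_de, stats::runif(n, 0, 0.01), stats::runif(n, 0.05, 1))

    is_high <- rep(FALSE, n)
    if (!is.null(nnc)) {
      thr <- stats::quantile(nnc$nnc_fraction, nnc_percentile / 100,
        names = FALSE)
      is_high <- nnc$nnc_fraction[match(gene_id, nnc$gene_id)] > thr
    }
    p_hi <- ifelse(is_high,
      odds_scale(te_alt_fraction, te_odds), te_alt_fraction)
    p_lo <- ifelse(is_high,
      odds_scale(te_alt_fraction, te_odds_lower), te_alt_fraction)
    u <- stats::runif(n)
    te_class <- ifelse(u < p_hi, "higher",
      ifelse(u < p_hi + p_lo, "lower", "similar"))
    te_delta <- ifelse(te_class == "higher", stats::runif(n, 1.2, 2.5),
      ifelse(te_class == "lower", -stats::runif(n, 1.2, 2.5),
        stats::rnorm(n, 0, 0.2)))
    ribo_lfc <- lfc + te_delta
    padj_ribo <- ifelse(is_de | te_class != "similar",
      stats::runif(n, 0, 0.01), stats::runif(n, 0.05, 1))

    structure(list(
      expression = tibble::tibble(
        gene_id = gene_id, expression_a = base,
        expression_b = base * 2^lfc
      ),
      de_rna = tibble::tibble(gene_id = gene_id, log2fc = lfc, padj = padj_rna),
      de_ribo = tibble::tibble(
        gene_id = gene_id, log2fc = ribo_lfc, padj = padj_ribo
      ),
      truth = tibble::tibble(
        gene_id = gene_id, is_de = is_de, log2fc_true = lfc,
        te_class_true = te_class, te_delta_true = te_delta,
        is_nnc_high = is_high
      )
    ), class = "sim_expression")
  })
}

# Multiply the odds of probability p by k.
odds_scale <- function(p, k) {
  o <- k * p / (1 - p)
  o / (1 + o)
}

#' Simulate gene-to-GO-term assignments
#'
#' Builds synthetic GO terms either as sliding windows over the genes ranked
#' by a covariate (default: planted GC3, producing a smooth codon-usage
#' gradient across terms, the structure the GO PCA is designed to expose) or
#' as random gene draws.
#'
#' @param tx A `sim_transcriptome`.
#' @param n_terms Number of terms.
#' @param genes_per_term Genes per term.
#' @param mode `"gc3_gradient"` or `"random"`.
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `term_id` (many-to-many).
#' @export
simulate_gene2go <- function(tx, n_terms = 30, genes_per_term = 50,
                             mode = c("gc3_gradient", "random"), seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(tx$truth)
  stopifnot(genes_per_term <= n)
  with_seed(stage_seed(seed, 3L), {
    purrr::map_dfr(seq_len(n_terms), function(k) {
      genes <- if (mode == "gc3_gradient") {
        ord <- order(tx$truth$gc3_planted)
        centre <- 1 + (k - 1) / max(1, n_terms - 1) * (n - genes_per_term)
        idx <- round(centre) + seq_len(genes_per_term) - 1L
        tx$truth$gene_id[ord[pmin(pmax(idx, 1L), n)]]
      } else {
        sample(tx$truth$gene_id, genes_per_term)
      }
      tibble::tibble(gene_id = unique(genes), term_id = sprintf("GO:%07d", k))
    })
  })
}
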