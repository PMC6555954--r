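#' Pipeline configuration
#'
#' Validates and bundles every input path and threshold of the end-to-end
#' analysis. In `simulate = TRUE` mode all inputs are generated by the
#' seeded synthetic-data module and `paths` may be empty; otherwise `paths`
#' must name the required files.
#'
#' @param simulate Generate all inputs with the synthetic-data module.
#' @param seed Integer seed for every stochastic stage.
#' @param sim A [simulation_config()] used when `simulate = TRUE`.
#' @param paths Named list of input files for real-data runs:
#'   `cds_fasta`, `transcript_fasta`, `cds_bed`, `footprint_sams_a`,
#'   `footprint_sams_b` (character vectors, one SAM/BAM per replicate),
#'   `trna_fasta`, `trna_annotation`, `trna_sams_a`, `trna_sams_b`,
#'   `de_rna`, `de_ribo`, `gene2go`, `stability_map`. Unknown keys are
#'   rejected.
#' @param mode `"human"` forces read lengths 27-29 in frame 0 (P-site offset
#'   12); `"auto"` detects frames and offsets per read length from the data.
#' @param alpha FDR threshold for differential codon usage.
#' @param min_overlap Minimum read/CDS overlap fraction.
#' @param mapq_min Minimum mapping quality.
#' @param min_depth Minimum wobble depth for the per-tRNA inosine
#'   distribution.
#' @param percentile Percentile defining nnC-high genes.
#' @param fold Fold boundary for translation-efficiency classes.
#' @param padj_cutoff Adjusted-p threshold defining DE gene sets.
#' @param min_genes Minimum genes per GO term.
#' @param nnc_dwell_b A-site dwell multiplier planted on the eight
#'   hetADAT-nnC codons in simulated condition B (differentiation-like
#'   enrichment at the A-site).
#' @param inosine_rate_b Wobble inosine level planted on every hetADAT tRNA
#'   in simulated condition B (condition A uses `sim$inosine_rates`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, seed = 1L,
                            sim = simulation_config(seed = seed),
                            paths = list(), mode = c("auto", "human"),
                            alpha = 0.05, min_overlap = 0.5, mapq_min = 20,
                            min_depth = 10, percentile = 99, fold = 2,
                            padj_cutoff = 0.05, min_genes = 40,
                            nnc_dwell_b = 1.5, inosine_rate_b = 0.70) {
  mode <- match.arg(mode)
  known <- c(
    "cds_fasta", "transcript_fasta", "cds_bed", "footprint_sams_a",
    "footprint_sams_b", "trna_fasta", "trna_annotation", "trna_sams_a",
    "trna_sams_b", "de_rna", "de_ribo", "gene2go", "stability_map"
  )
  unknown <- setdiff(names(paths), known)
  if (length(unknown)) {
    stop("unknown path keys: ", paste(unknown, collapse = ", "))
  }
  if (!simulate) {
    required <- c("cds_fasta", "transcript_fasta", "cds_bed",
      "footprint_sams_a", "footprint_sams_b", "de_rna", "de_ribo")
    missing <- setdiff(required, names(paths))
    if (length(missing)) {
      stop("missing required path(s): ", paste(missing, collapse = ", "))
    }
    for (key in intersect(names(paths), known)) {
      bad <- paths[[key]][!file.exists(paths[[key]])]
      if (length(bad)) {
        stop("input file for '", key, "' not found: ",
          paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(
    simulate = simulate, seed = as.integer(seed), sim = sim, paths = paths,
    mode = mode, alpha = alpha, min_overlap = min_overlap,
    mapq_min = mapq_min, min_depth = min_depth, percentile = percentile,
    fold = fold, padj_cutoff = padj_cutoff, min_genes = min_genes,
    nnc_dwell_b = nnc_dwell_b, inosine_rate_b = inosine_rate_b
  ), class = "pipeline_config")
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `padj`.
#' @return A tibble with those columns.
#' @export
read_de_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(d)))
  d
}

#' Run the full codon-usage analysis pipeline
#'
#' Executes the stages in dependency order — simulate (optional), codon
#' vectors, expression enrichment and GO PCA, ribosome-site extraction and
#' differential codon usage, wobble-inosine quantification, and
#' translation-efficiency classification — writing every result as TSV
#' under `out_dir` and recording a manifest of stages, outputs and
#' checksums. A stage failure stops downstream stages; completed outputs
#' are retained and the manifest records the failing stage before the error
#' is re-raised.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The run manifest (tibble: `stage`, `status`, `outputs`,
#'   `checksum`, `detail`), invisibly. Also written to
#'   `out_dir/manifest.tsv`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  failed <- NULL
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, code) {
    if (!is.null(failed)) {
      manifest[[name]] <<- stage_row(name, "skipped", character(0),
        paste("blocked by", failed))
      return(invisible(NULL))
    }
    res <- tryCatch({
      outputs <- code
      manifest[[name]] <<- stage_row(name, "ok", outputs, "")
    }, error = function(e) {
      failed <<- name
      manifest[[name]] <<- stage_row(name, "failed", character(0),
        conditionMessage(e))
    })
    invisible(res)
  }

  run_stage("inputs", pipeline_inputs(config, out_dir, env))
  run_stage("codon_vectors", {
    env$usage <- codon_usage(env$cds)
    env$nnc <- nnc_codon_fraction(env$cds)
    p <- file.path(out_dir, "codon_usage.tsv")
    write_codon_usage(env$usage, p)
    p2 <- file.path(out_dir, "nnc_fraction.tsv")
    readr::write_tsv(env$nnc, p2)
    c(p, p2)
  })
  run_stage("enrichment", {
    sets <- de_gene_sets(env$de_rna, config$padj_cutoff)
    out <- character(0)
    for (s in names(sets)) {
      if (length(sets[[s]]) == 0L) next
      for (lvl in c("codon", "amino_acid")) {
        e <- group_codon_enrichment(env$usage, sets[[s]], level = lvl)
        p <- file.path(out_dir, sprintf("enrichment_%s_%s.tsv", s, lvl))
        readr::write_tsv(tibble::as_tibble(e), p)
        out <- c(out, p)
      }
    }
    if (length(sets$up) && length(sets$down)) {
      st <- stability_enrichment(env$usage, sets$up, sets$down,
        env$stability_map)
      p <- file.path(out_dir, "stability_tests.tsv")
      readr::write_tsv(st$tests, p)
      out <- c(out, p)
    }
    gc <- gc_expression_association(env$usage, env$de_rna,
      config$padj_cutoff)
    p <- file.path(out_dir, "gc3_association.tsv")
    readr::write_tsv(
      tibble::tibble(rho = gc$rho, p = gc$p, n = gc$n), p)
    c(out, p)
  })
  run_stage("go_pca", if (is.null(env$gene2go)) character(0) else {
    prof <- go_profiles(env$gene2go, env$usage, config$min_genes)
    pca <- go_pca(prof)
    p1 <- file.path(out_dir, "go_pca_scores.tsv")
    p2 <- file.path(out_dir, "go_pca_loadings.tsv")
    readr::write_tsv(pca$scores, p1)
    readr::write_tsv(pca$loadings, p2)
    env$go_pca <- pca
    c(p1, p2)
  })
  run_stage("ribosite", {
    norm <- list()
    pooled <- list()
    for (cond in c("a", "b")) {
      sams <- env$footprint_sams[[cond]]
      counts <- lapply(sams, function(sam) {
        reads <- read_footprints(sam)
        prof <- if (config$mode == "human") {
          forced_frame_profile(27:29)
        } else {
          profile_frames(reads, env$cds_bed)
        }
        extract_site_codons(reads, env$cds_bed, env$transcripts, prof,
          min_overlap = config$min_overlap, mapq_min = config$mapq_min)
      })
      norm[[cond]] <- lapply(counts, normalize_site_counts)
      pooled[[cond]] <- pool_site_counts(counts)
    }
    shift <- differential_codon_usage(norm$a, norm$b, alpha = config$alpha)
    env$codon_shift <- shift
    genomic <- genomic_codon_distribution(env$usage, env$expression_a)
    qc <- flank_concordance(pooled$a, genomic)
    p1 <- file.path(out_dir, "site_counts_pooled_a.tsv")
    p2 <- file.path(out_dir, "site_counts_pooled_b.tsv")
    p3 <- file.path(out_dir, "differential_codon_usage.tsv")
    p4 <- file.path(out_dir, "flank_concordance.tsv")
    readr::write_tsv(tibble::as_tibble(pooled$a), p1)
    readr::write_tsv(tibble::as_tibble(pooled$b), p2)
    readr::write_tsv(tibble::as_tibble(shift), p3)
    readr::write_tsv(qc, p4)
    c(p1, p2, p3, p4)
  })
  run_stage("inosine", if (is.null(env$trna_fasta)) character(0) else {
    records <- build_mature_reference(env$trna_fasta, env$trna_annotation)
    est <- lapply(c(a = "a", b = "b"), function(cond) {
      lapply(env$trna_sams[[cond]], function(sam) {
        estimate_inosine(trna_pileup(sam), records, config$min_depth)
      })
    })
    cmp <- compare_inosine_conditions(est$a, est$b)
    env$inosine <- cmp
    p1 <- file.path(out_dir, "inosine_per_trna.tsv")
    p2 <- file.path(out_dir, "inosine_comparison.tsv")
    readr::write_tsv(tibble::as_tibble(est$a[[1]]), p1)
    readr::write_tsv(cmp$per_trna, p2)
    c(p1, p2)
  })
  run_stage("te_nnc", {
    thr <- suppressWarnings(
      nnc_percentile_threshold(env$nnc, config$percentile))
    te <- classify_te(env$de_ribo, env$de_rna, env$nnc, thr,
      fold = config$fold)
    env$te <- te
    p1 <- file.path(out_dir, "te_classes.tsv")
    p2 <- file.path(out_dir, "te_summary.tsv")
    readr::write_tsv(tibble::as_tibble(te), p1)
    readr::write_tsv(te_summary(te), p2)
    c(p1, p2)
  })

  man <- dplyr::bind_rows(manifest)
  man$version <- as.character(utils::packageVersion("ribocodon"))
  readr::write_tsv(man, file.path(out_dir, "manifest.tsv"))
  if (!is.null(failed)) {
    stop("pipeline stage '", failed, "' failed: ",
      man$detail[man$stage == failed], call. = FALSE)
  }
  invisible(man)
}

stage_row <- function(stage, status, outputs, detail) {
  tibble::tibble(
    stage = stage, status = status,
    outputs = paste(basename(outputs), collapse = ";"),
    checksum = if (length(outputs)) {
      paste(unname(tools::md5sum(outputs)), collapse = ";")
    } else {
      ""
    },
    detail = detail
  )
}

# Stage 0: load or simulate every input, populating the shared environment.
pipeline_inputs <- function(config, out_dir, env) {
  outputs <- character(0)
  if (config$simulate) {
    sim_dir <- file.path(out_dir, "sim")
    tx <- simulate_transcriptome(config$sim)
    paths_tx <- write_transcriptome(tx, sim_dir)
    nnc <- nnc_codon_fraction(tx$cds)
    expr <- simulate_expression(config$sim, tx, nnc = nnc)
    readr::write_tsv(expr$de_rna, file.path(sim_dir, "de_rna.tsv"))
    readr::write_tsv(expr$de_ribo, file.path(sim_dir, "de_ribo.tsv"))
    readr::write_tsv(expr$truth, file.path(sim_dir, "expression_truth.tsv"))
    g2g <- simulate_gene2go(tx,
      n_terms = 30, genes_per_term = max(50, config$min_genes + 10),
      seed = config$seed)
    readr::write_tsv(g2g, file.path(sim_dir, "gene2go.tsv"))

    cfg_b <- config$sim
    nnc_w <- stats::setNames(
      rep(config$nnc_dwell_b, 8L), hetadat_codons("nnC"))
    cfg_b$dwell_weights <- c(cfg_b$dwell_weights, nnc_w)
    sams <- list(a = character(0), b = character(0))
    for (r in seq_len(config$sim$n_replicates)) {
      fa <- simulate_footprints(tx,
        dplyr::rename(expr$expression[, c("gene_id", "expression_a")],
          expression = "expression_a"),
        config$sim, seed = config$seed + 10L * r)
      fb <- simulate_footprints(tx,
        dplyr::rename(expr$expression[, c("gene_id", "expression_b")],
          expression = "expression_b"),
        cfg_b, seed = config$seed + 10L * r + 5L)
      pa <- file.path(sim_dir, sprintf("footprints_a_rep%d.sam", r))
      pb <- file.path(sim_dir, sprintf("footprints_b_rep%d.sam", r))
      write_footprint_sam(fa, tx, pa)
      write_footprint_sam(fb, tx, pb)
      sams$a <- c(sams$a, pa)
      sams$b <- c(sams$b, pb)
    }

    cfg_tb <- config$sim
    cfg_tb$inosine_rates[] <- config$inosine_rate_b
    trna_sams <- list(a = character(0), b = character(0))
    trna_paths <- NULL
    for (r in seq_len(config$sim$n_replicates)) {
      ta <- simulate_trna_reads(config$sim, seed = config$seed + 100L * r)
      tb <- simulate_trna_reads(cfg_tb, seed = config$seed + 100L * r + 7L)
      if (r == 1L) trna_paths <- write_trna_data(ta, sim_dir)
      pa <- file.path(sim_dir, sprintf("trna_a_rep%d.sam", r))
      pb <- file.path(sim_dir, sprintf("trna_b_rep%d.sam", r))
      write_trna_sam(ta, pa)
      write_trna_sam(tb, pb)
      trna_sams$a <- c(trna_sams$a, pa)
      trna_sams$b <- c(trna_sams$b, pb)
    }

    env$cds <- tx$cds
    env$transcripts <- tx$transcripts
    env$cds_bed <- tx$transcripts[, c("transcript_id", "cds_start",
      "cds_end")]
    env$expression_a <- dplyr::rename(
      expr$expression[, c("gene_id", "expression_a")],
      expression = "expression_a")
    env$de_rna <- expr$de_rna
    env$de_ribo <- expr$de_ribo
    env$gene2go <- g2g
    env$stability_map <- synthetic_stability_map()
    env$footprint_sams <- sams
    env$trna_fasta <- trna_paths[["trna_fasta"]]
    env$trna_annotation <- trna_paths[["trna_annotation"]]
    env$trna_sams <- trna_sams
    outputs <- c(paths_tx, file.path(sim_dir, "de_rna.tsv"),
      file.path(sim_dir, "de_ribo.tsv"), sams$a, sams$b,
      trna_sams$a, trna_sams$b)
  } else {
    p <- config$paths
    env$cds <- load_cds(p$cds_fasta)
    env$transcripts <- load_transcripts(p$transcript_fasta)
    env$cds_bed <- read_cds_bed(p$cds_bed)
    env$expression_a <- NULL
    env$de_rna <- read_de_table(p$de_rna)
    env$de_ribo <- read_de_table(p$de_ribo)
    env$gene2go <- if (!is.null(p$gene2go)) read_gene2go(p$gene2go) else NULL
    env$stability_map <- if (!is.null(p$stability_map)) {
      read_stability_map(p$stability_map)
    } else {
      synthetic_stability_map()
    }
    env$footprint_sams <- list(a = p$footprint_sams_a,
      b = p$footprint_sams_b)
    env$trna_fasta <- p$trna_fasta
    env$trna_annotation <- p$trna_annotation
    env$trna_sams <- list(a = p$trna_sams_a, b = p$trna_sams_b)
  }
  outputs
}

# SAM of simulated tRNA reads against the mature reference.
write_trna_sam <- function(sim, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", sim$records$trna_id,
      nchar(sim$records$mature_sequence))
  )
  body <- sprintf("%s\t0\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t*",
    sim$reads$read_id, sim$reads$trna_id, sim$reads$start + 1L,
    nchar(sim$reads$sequence), sim$reads$sequence)
  writeLines(c(header, body), path)
  invisible(path)
}
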