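#' Define up/down gene sets from a differential-expression table
#'
#' Splits a DE table (`gene_id`, `log2fc`, `padj`) into significantly
#' up- and downregulated sets at an adjusted-p cutoff.
#'
#' @param de_table Tibble with `gene_id`, `log2fc`, `padj`.
#' @param padj_cutoff Adjusted-p threshold (default 0.05).
#' @return Named list of two character vectors, `up` and `down`.
#' @export
de_gene_sets <- function(de_table, padj_cutoff = 0.05) {
  sig <- de_table$padj < padj_cutoff
  list(
    up = de_table$gene_id[sig & de_table$log2fc > 0],
    down = de_table$gene_id[sig & de_table$log2fc < 0]
  )
}

#' Codon or amino-acid enrichment of a gene set
#'
#' Compares the unweighted mean per-gene codon (or amino-acid) frequency of
#' a gene set against the mean over all background genes, as
#' `log2(group / background)`. Amino-acid level sums synonymous codon
#' frequencies per gene before averaging. `method = "pooled"` instead pools
#' codon counts (weighting genes by length) before comparing.
#'
#' @param usage Codon usage tibble from [codon_usage()] — the background
#'   universe.
#' @param group Character vector of gene ids (must all have usage rows).
#' @param level `"codon"` or `"amino_acid"`.
#' @param method `"mean"` (per-gene average, default) or `"pooled"`.
#' @return Tibble of class `enrichment_table`: one row per codon or amino
#'   acid with `group_mean_freq`, `background_mean_freq`, `log2_fc` and, at
#'   codon level, annotation columns `third_base_class`, `degeneracy`,
#'   `hetadat_class`. A zero background frequency for a feature present in
#'   the group yields `log2_fc = Inf` with a warning.
#' @export
group_codon_enrichment <- function(usage, group,
                                   level = c("codon", "amino_acid"),
                                   method = c("mean", "pooled")) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (length(group) == 0L) stop("empty gene group")
  missing <- setdiff(group, usage$gene_id)
  if (length(missing)) {
    stop("group genes without codon vectors: ",
      paste(utils::head(missing, 5L), collapse = ", "))
  }
  mat <- as.matrix(usage[, CODONS])
  rownames(mat) <- usage$gene_id
  if (level == "amino_acid") {
    tab <- codon_table()
    aa <- tab$aa[match(colnames(mat), tab$codon)]
    mat <- t(rowsum(t(mat), aa))
  }
  in_group <- usage$gene_id %in% group
  summarise_freq <- function(m, w) {
    if (method == "mean") colMeans(m) else colSums(m * w) / sum(w)
  }
  w_all <- usage$n_codons
  grp <- summarise_freq(mat[in_group, , drop = FALSE], w_all[in_group])
  bkg <- summarise_freq(mat, w_all)
  lfc <- log2(grp / bkg)
  if (any(is.infinite(lfc) & grp > 0)) {
    warning("zero background frequency for a feature present in the group")
  }
  out <- tibble::tibble(
    feature = names(grp), group_mean_freq = unname(grp),
    background_mean_freq = unname(bkg), log2_fc = unname(lfc)
  )
  if (level == "codon") {
    ann <- codon_table()[, c("codon", "third_base_class", "degeneracy",
      "hetadat_class")]
    out <- dplyr::left_join(out, ann, by = c(feature = "codon"))
  }
  structure(out,
    class = c("enrichment_table", "tbl_df", "tbl", "data.frame"),
    level = level, method = method, n_group = sum(in_group),
    n_background = nrow(usage)
  )
}

#' Stability-class codon enrichment and between-group comparison
#'
#' Maps each sense codon to an mRNA-stability class (e.g. the zebrafish
#' stabilizing/destabilizing/neutral classification), computes each gene's
#' per-class frequency as the sum of its member-codon frequencies, reports
#' enrichment of two gene sets versus the background, and tests the
#' between-group difference per class with a two-sided Wilcoxon rank-sum
#' test on per-gene values, Benjamini-Hochberg adjusted across classes.
#'
#' @param usage Codon usage tibble (background universe).
#' @param group_a,group_b Character vectors of gene ids.
#' @param class_map Tibble with `codon` and `stability_class` covering all
#'   61 sense codons, e.g. from [read_stability_map()].
#' @return List of class `stability_enrichment`: `enrichment` (per class and
#'   group: mean frequency, background, log2_fc) and `tests` (per class:
#'   rank-sum `p`, `q`, group medians).
#' @export
stability_enrichment <- function(usage, group_a, group_b, class_map) {
  stopifnot(all(c("codon", "stability_class") %in% names(class_map)))
  unknown <- setdiff(class_map$codon, SENSE_CODONS)
  if (length(unknown)) {
    stop("unknown codon in class map: ", paste(unknown, collapse = ", "))
  }
  uncovered <- setdiff(SENSE_CODONS, class_map$codon)
  if (length(uncovered)) {
    stop("class map must cover all 61 sense codons; missing: ",
      paste(utils::head(uncovered, 5L), collapse = ", "))
  }
  mat <- as.matrix(usage[, class_map$codon])
  cls <- factor(class_map$stability_class)
  per_gene <- t(rowsum(t(mat), cls)) # gene x class frequency sums
  rownames(per_gene) <- usage$gene_id
  groups <- list(a = group_a, b = group_b)
  enrichment <- purrr::map_dfr(names(groups), function(g) {
    idx <- usage$gene_id %in% groups[[g]]
    if (!any(idx)) stop("empty group ", g)
    tibble::tibble(
      group = g, stability_class = colnames(per_gene),
      group_mean_freq = colMeans(per_gene[idx, , drop = FALSE]),
      background_mean_freq = colMeans(per_gene),
      log2_fc = log2(colMeans(per_gene[idx, , drop = FALSE]) /
        colMeans(per_gene))
    )
  })
  tests <- purrr::map_dfr(colnames(per_gene), function(cl) {
    xa <- per_gene[usage$gene_id %in% group_a, cl]
    xb <- per_gene[usage$gene_id %in% group_b, cl]
    wt <- suppressWarnings(stats::wilcox.test(xa, xb))
    tibble::tibble(
      stability_class = cl, median_a = stats::median(xa),
      median_b = stats::median(xb), p = wt$p.value
    )
  })
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  structure(list(enrichment = enrichment, tests = tests),
    class = "stability_enrichment")
}

#' Read a codon-to-stability-class map from TSV
#'
#' @param path TSV with columns `codon`, `stability_class`.
#' @return Tibble with those columns.
#' @export
read_stability_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' A synthetic stability-class map for testing
#'
#' Splits the 61 sense codons into `stabilizing` (G/C-ending) and
#' `destabilizing` (A/T-ending) classes — a caricature of published
#' optimality classifications, clearly labelled synthetic. Real analyses
#' should supply a published map via [read_stability_map()].
#'
#' @return Tibble with `codon`, `stability_class`.
#' @export
synthetic_stability_map <- function() {
  tibble::tibble(
    codon = SENSE_CODONS,
    stability_class = ifelse(substr(SENSE_CODONS, 3, 3) %in% c("G", "C"),
      "stabilizing", "destabilizing")
  )
}

#' Association of third-position GC with expression change
#'
#' Spearman correlation of per-gene GC3 with DE log2 fold-change, plus GC3
#' summaries stratified by significance class (up / down / not significant).
#'
#' @param usage Codon usage tibble (provides `gc3`).
#' @param de_table Tibble with `gene_id`, `log2fc`, `padj`.
#' @param padj_cutoff Significance threshold for the stratified summary.
#' @return List of class `gc_association`: `rho`, `p`, `n`, and `strata`
#'   (tibble with per-class mean/median GC3).
#' @export
gc_expression_association <- function(usage, de_table, padj_cutoff = 0.05) {
  m <- dplyr::inner_join(usage[, c("gene_id", "gc3")], de_table,
    by = "gene_id")
  if (nrow(m) < 3L) stop("fewer than 3 matched genes")
  ct <- suppressWarnings(
    stats::cor.test(m$gc3, m$log2fc, method = "spearman")
  )
  m$class <- ifelse(m$padj >= padj_cutoff, "not_significant",
    ifelse(m$log2fc > 0, "up", "down"))
  strata <- m %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      n = dplyr::n(), mean_gc3 = mean(.data$gc3),
      median_gc3 = stats::median(.data$gc3), .groups = "drop"
    )
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m),
    strata = strata), class = "gc_association")
}

#' Mean codon-frequency profiles per GO term
#'
#' Averages per-gene codon frequency vectors (and GC metrics) within each GO
#' term. Genes lacking codon vectors are dropped from a term before the
#' size filter; only terms retaining at least `min_genes` genes are kept.
#'
#' @param gene2go Tibble with `gene_id`, `term_id` (many-to-many), e.g. from
#'   [read_gene2go()].
#' @param usage Codon usage tibble.
#' @param min_genes Minimum genes per retained term (default 40).
#' @return Tibble of class `go_profiles`: `term_id`, `n_genes`, the 64 mean
#'   codon-frequency columns, `gc1`, `gc2`, `gc3`.
#' @export
go_profiles <- function(gene2go, usage, min_genes = 40) {
  m <- dplyr::inner_join(gene2go, usage, by = "gene_id")
  if (nrow(m) == 0L) stop("no overlap between gene2go and codon vectors")
  prof <- m %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(
      n_genes = dplyr::n_distinct(.data$gene_id),
      dplyr::across(dplyr::all_of(c(CODONS, "gc1", "gc2", "gc3")), mean),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_genes >= min_genes)
  structure(prof, class = c("go_profiles", "tbl_df", "tbl", "data.frame"),
    min_genes = min_genes)
}

#' @rdname go_profiles
#' @param path TSV with columns `gene_id`, `term_id`.
#' @export
read_gene2go <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Correlation-matrix PCA of GO-term codon profiles
#'
#' Principal component analysis of the per-term mean codon frequencies on
#' standardized columns (the correlation-matrix convention). Codon columns
#' with zero variance across terms are dropped with a message. The sign of
#' PC1 is oriented so that its scores correlate positively with term-mean
#' AT3 (= 1 - GC3), making the GC3 gradient read left-to-right.
#'
#' @param profiles A `go_profiles` tibble (at least 3 terms).
#' @return Object of class `go_pca` with elements `scores` (tibble:
#'   `term_id`, `gc3`, `PC1..k`), `loadings` (tibble: `codon`, annotation,
#'   `PC1..k`), `explained_variance` (fractions, non-increasing).
#' @export
go_pca <- function(profiles) {
  if (nrow(profiles) < 3L) stop("need at least 3 GO-term profiles")
  x <- as.matrix(profiles[, CODONS])
  keep <- apply(x, 2L, stats::sd) > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " zero-variance codon column(s): ",
      paste(utils::head(CODONS[!keep], 5L), collapse = ", "))
  }
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  at3 <- 1 - profiles$gc3
  if (stats::sd(pc$x[, 1]) > 0 && !is.na(stats::cor(pc$x[, 1], at3)) &&
    stats::cor(pc$x[, 1], at3) < 0) {
    pc$x[, 1] <- -pc$x[, 1]
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    profiles[, c("term_id", "n_genes", "gc3")],
    tibble::as_tibble(pc$x)
  )
  ann <- codon_table()[, c("codon", "third_base_class", "degeneracy",
    "hetadat_class")]
  loadings <- dplyr::left_join(
    dplyr::bind_cols(tibble::tibble(codon = colnames(x)),
      tibble::as_tibble(pc$rotation)),
    ann, by = "codon"
  )
  structure(list(
    scores = scores, loadings = loadings, explained_variance = ev,
    n_terms = nrow(profiles), n_codons = ncol(x)
  ), class = "go_pca")
}

#' @export
print.go_pca <- function(x, ...) {
  cat("GO-term codon-frequency PCA:", x$n_terms, "terms,", x$n_codons,
    "codon columns\n")
  cat("explained variance (first 5):",
    paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance, 5L)),
      collapse = ", "), "\n")
  invisible(x)
}
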