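#' Percentile threshold on hetADAT-nnC codon fractions
#'
#' The nnC-high gene set is defined as genes whose fraction of the eight
#' hetADAT-dependent nnC codons exceeds a high percentile (default the 99th,
#' i.e. the top 1%) of the distribution over all genes. Linear-interpolation
#' percentile (R quantile type 7).
#'
#' @param nnc Tibble from [nnc_codon_fraction()].
#' @param percentile Percentile in (0, 100).
#' @return The threshold fraction (scalar). Fewer than 100 genes triggers a
#'   warning; the threshold is still computed.
#' @export
nnc_percentile_threshold <- function(nnc, percentile = 99) {
  stopifnot(percentile > 0, percentile < 100)
  if (nrow(nnc) < 100L) {
    warning("fewer than 100 genes; the ", percentile,
      "th percentile is poorly resolved")
  }
  stats::quantile(nnc$nnc_fraction, percentile / 100, type = 7,
    names = FALSE)
}

#' Classify translation-efficiency changes and test nnC-high enrichment
#'
#' For each gene, the ribosome-occupancy change independent of mRNA level is
#' `delta = ribo_log2fc - rna_log2fc`. Genes with `delta > log2(fold)` are
#' classed `higher`, below `-log2(fold)` `lower`, otherwise `similar`
#' (default fold = 2). Genes whose nnC codon fraction exceeds `threshold`
#' form the nnC-high set; the 3-class distribution of that set is compared
#' against the remaining genes (or all genes when
#' `include_high_in_background = TRUE`) with a chi-square test on the 2x3
#' table, with per-class two-proportion follow-ups, BH-adjusted.
#'
#' @param de_ribo,de_rna DE tibbles (`gene_id`, `log2fc`, `padj`).
#' @param nnc Tibble from [nnc_codon_fraction()].
#' @param threshold nnC fraction above which a gene is nnC-high, e.g. from
#'   [nnc_percentile_threshold()].
#' @param fold Fold-change boundary (> 1) separating the classes.
#' @param include_high_in_background Compare against all genes instead of
#'   the disjoint complement.
#' @param exact Use Fisher's exact test instead of chi-square (small sets).
#' @return Tibble of class `te_class`, one row per matched gene: `gene_id`,
#'   `rna_log2fc`, `ribo_log2fc`, `delta`, `te_class`, `nnc_fraction`,
#'   `is_nnc_high`; attributes `summary` (class proportions per set),
#'   `test` (htest), `followups` (per-class two-proportion tests),
#'   `threshold`, `fold`.
#' @export
classify_te <- function(de_ribo, de_rna, nnc, threshold, fold = 2,
                        include_high_in_background = FALSE, exact = FALSE) {
  if (fold <= 1) stop("fold must exceed 1")
  m <- dplyr::inner_join(
    dplyr::rename(de_rna[, c("gene_id", "log2fc")], rna_log2fc = "log2fc"),
    dplyr::rename(de_ribo[, c("gene_id", "log2fc")], ribo_log2fc = "log2fc"),
    by = "gene_id"
  ) %>%
    dplyr::inner_join(nnc[, c("gene_id", "nnc_fraction")], by = "gene_id")
  if (nrow(m) == 0L) stop("no genes shared across the three inputs")
  bound <- log2(fold)
  m$delta <- m$ribo_log2fc - m$rna_log2fc
  m$te_class <- factor(
    ifelse(m$delta > bound, "higher",
      ifelse(m$delta < -bound, "lower", "similar")),
    levels = c("higher", "lower", "similar")
  )
  m$is_nnc_high <- m$nnc_fraction > threshold
  bg <- if (include_high_in_background) rep(TRUE, nrow(m)) else !m$is_nnc_high
  tab <- rbind(
    nnc_high = table(m$te_class[m$is_nnc_high]),
    background = table(m$te_class[bg])
  )
  if (any(rowSums(tab) == 0)) {
    warning("empty nnC-high or background set; enrichment test omitted")
    test <- NULL
    followups <- tibble::tibble(te_class = character(0),
      prop_nnc_high = numeric(0), prop_background = numeric(0),
      p = numeric(0), q = numeric(0))
  } else {
    test <- if (exact) {
      stats::fisher.test(tab)
    } else {
      suppressWarnings(stats::chisq.test(tab))
    }
    followups <- purrr::map_dfr(colnames(tab), function(cl) {
      pt <- suppressWarnings(stats::prop.test(tab[, cl], rowSums(tab)))
      tibble::tibble(
        te_class = cl,
        prop_nnc_high = tab["nnc_high", cl] / sum(tab["nnc_high", ]),
        prop_background = tab["background", cl] / sum(tab["background", ]),
        p = pt$p.value
      )
    })
    followups$q <- stats::p.adjust(followups$p, method = "BH")
  }
  summary <- purrr::map_dfr(rownames(tab), function(s) {
    tibble::tibble(
      set = s, te_class = colnames(tab),
      n = as.integer(tab[s, ]), proportion = tab[s, ] / sum(tab[s, ])
    )
  })
  structure(m,
    class = c("te_class", "tbl_df", "tbl", "data.frame"),
    summary = summary, test = test, followups = followups,
    threshold = threshold, fold = fold,
    include_high_in_background = include_high_in_background
  )
}

#' @rdname classify_te
#' @param x A `te_class` table.
#' @export
te_summary <- function(x) attr(x, "summary")

#' @rdname classify_te
#' @export
te_test <- function(x) attr(x, "test")
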