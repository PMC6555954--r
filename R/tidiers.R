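#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GO-term codon PCA
#'
#' @param x A `go_pca` object.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in long or wide form depending on `matrix`.
#' @export
tidy.go_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                        ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(
      component = seq_along(x$explained_variance),
      explained_variance = x$explained_variance,
      cumulative = cumsum(x$explained_variance)
    )
  )
}

#' @rdname tidy.go_pca
#' @export
glance.go_pca <- function(x, ...) {
  tibble::tibble(
    n_terms = x$n_terms, n_codons = x$n_codons,
    var_pc1 = x$explained_variance[1],
    var_pc2 = x$explained_variance[2]
  )
}

#' Tidy differential codon-usage results
#'
#' @param x A `codon_shift` table.
#' @param ... Unused.
#' @return The underlying tibble (`tidy`); one-row summary (`glance`) with
#'   the number of tested pairs, significant pairs, and the position where
#'   most significant shifts fall.
#' @export
tidy.codon_shift <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.codon_shift
#' @export
glance.codon_shift <- function(x, ...) {
  sig <- x[x$significant %in% TRUE, ]
  mode_pos <- if (nrow(sig)) {
    as.integer(names(sort(table(sig$position), decreasing = TRUE))[1])
  } else {
    NA_integer_
  }
  tibble::tibble(
    n_tested = sum(!is.na(x$p)), n_significant = nrow(sig),
    alpha = attr(x, "alpha"), top_position = mode_pos
  )
}

#' Tidy an inosine table or comparison
#'
#' @param x An `inosine_table` or `inosine_comparison`.
#' @param ... Unused.
#' @return Per-tRNA tibble (`tidy`); `glance` reports the read-weighted
#'   aggregate A34I level and counts.
#' @export
tidy.inosine_table <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.inosine_table
#' @export
glance.inosine_table <- function(x, ...) {
  tibble::tibble(
    aggregate = inosine_aggregate(x),
    n_substrate = sum(x$is_substrate),
    n_included = sum(x$included),
    total_depth = sum(x$depth[x$is_substrate])
  )
}

#' @rdname tidy.inosine_table
#' @export
tidy.inosine_comparison <- function(x, ...) x$per_trna

#' @rdname tidy.inosine_table
#' @export
glance.inosine_comparison <- function(x, ...) {
  tibble::tibble(
    mean_delta = mean(x$per_trna$delta),
    n_trna = nrow(x$per_trna),
    p = if (is.null(x$test)) NA_real_ else x$test$p.value
  )
}

#' Tidy translation-efficiency classification results
#'
#' @param x A `te_class` table.
#' @param ... Unused.
#' @return Per-gene tibble (`tidy`); `glance` gives the enrichment-test
#'   statistic and the class proportions of the nnC-high set.
#' @export
tidy.te_class <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.te_class
#' @export
glance.te_class <- function(x, ...) {
  s <- te_summary(x)
  hi <- s[s$set == "nnc_high", ]
  test <- te_test(x)
  tibble::tibble(
    n_genes = nrow(x), n_nnc_high = sum(x$is_nnc_high),
    prop_higher = hi$proportion[hi$te_class == "higher"],
    prop_lower = hi$proportion[hi$te_class == "lower"],
    statistic = if (is.null(test)) NA_real_ else
      unname(test$statistic %||% NA_real_),
    p = if (is.null(test)) NA_real_ else test$p.value
  )
}
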