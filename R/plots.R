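#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of nine-position-normalized codon occupancy
#'
#' @param object A `site_norm` tibble.
#' @param ... Unused.
#' @return A ggplot: codon by ribosome position, fill = normalized value.
#' @export
autoplot.site_norm <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$position, levels = sort(unique(.data$position))),
    y = .data$codon, fill = log2(.data$value)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
      high = "firebrick", na.value = "grey85") +
    ggplot2::labs(x = "ribosome-protected codon position (0 = A-site)",
      y = NULL, fill = "log2 norm.\noccupancy") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
}

#' Differential codon usage across ribosome positions
#'
#' @param object A `codon_shift` table.
#' @param ... Unused.
#' @return A ggplot of per-codon log2 fold-changes by position, significant
#'   shifts coloured by direction and hetADAT codons marked.
#' @export
autoplot.codon_shift <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$status <- ifelse(!d$significant | is.na(d$significant), "ns",
    ifelse(d$log2_fc > 0, "up", "down"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$position, y = .data$log2_fc, colour = .data$status,
    shape = !is.na(.data$hetadat_class)
  )) +
    ggplot2::geom_jitter(width = 0.18, height = 0, size = 1.4, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(ns = "grey70", up = "firebrick", down = "steelblue")
    ) +
    ggplot2::scale_x_continuous(breaks = -5:3) +
    ggplot2::labs(x = "ribosome-protected codon position (0 = A-site)",
      y = "log2 FC normalized codon usage (B vs A)",
      colour = NULL, shape = "hetADAT codon") +
    ggplot2::theme_minimal()
}

#' GO-term PCA score plot coloured by GC3
#'
#' @param object A `go_pca` object.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 term scores.
#' @export
autoplot.go_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, colour = .data$gc3
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = "term mean GC3"
    ) +
    ggplot2::theme_minimal()
}

#' Per-tRNA wobble inosine levels by isotype
#'
#' @param object An `inosine_table`.
#' @param ... Unused.
#' @return A ggplot of per-tRNA A34I fractions grouped by isotype, with the
#'   read-weighted aggregate as a dashed line.
#' @export
autoplot.inosine_table <- function(object, ...) {
  d <- tibble::as_tibble(object)[object$included, ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$isotype, y = .data$fraction
  )) +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = inosine_aggregate(object),
      linetype = 2, colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "tRNA isotype", y = "A34I level (G fraction)") +
    ggplot2::theme_minimal()
}

#' Reading-frame counts per footprint length
#'
#' @param object A `frame_profile`.
#' @param ... Unused.
#' @return A ggplot of 5'-end frame counts per read length with the
#'   selection verdict.
#' @export
autoplot.frame_profile <- function(object, ...) {
  d <- tibble::as_tibble(object) %>%
    tidyr::pivot_longer(dplyr::all_of(c("frame_0", "frame_1", "frame_2")),
      names_to = "frame", values_to = "count") %>%
    dplyr::mutate(frame = sub("frame_", "", .data$frame))
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$read_length), y = .data$count, fill = .data$frame,
    alpha = .data$selected
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = "read length (nt)", y = "5' ends near TIS",
      fill = "frame", alpha = "selected") +
    ggplot2::theme_minimal()
}
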