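#' Plot red-on-green autofluorescence with fitted lines
#'
#' Scatter of log2 red against log2 green for mock spots of a few allergens,
#' with each allergen's fitted autofluorescence line overlaid — the visual
#' check that the linear null model holds.
#'
#' @param mock_processed Preprocessed mock spots.
#' @param calibration An `ige_calibration`.
#' @param allergens Labels to show (default: first 6 calibrated).
#' @return A ggplot.
#' @export
plot_autofluorescence <- function(mock_processed, calibration,
                                  allergens = NULL) {
  if (is.null(allergens)) {
    allergens <- utils::head(calibration$name[calibration$calibrated], 6)
  }
  d <- dplyr::filter(mock_processed, .data$name %in% allergens)
  coefs <- calibration |>
    dplyr::filter(.data$name %in% allergens) |>
    tibble::as_tibble()
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_green, .data$log2_red)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(
      data = coefs,
      ggplot2::aes(slope = .data$m, intercept = .data$b),
      colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~name, scales = "free") +
    ggplot2::labs(x = "log2 green (532 nm)", y = "log2 red (635 nm)",
                  title = "Per-allergen autofluorescence on mock arrays")
}

#' Histogram of corrected mock signal
#'
#' After subtracting the fitted autofluorescence, mock-array signal should be
#' tightly centered at 0; thresholds sit in the upper tail.
#'
#' @param mock_corrected Corrected mock spots.
#' @param binwidth Histogram bin width (default 0.1).
#' @return A ggplot.
#' @export
plot_corrected_mock <- function(mock_corrected, binwidth = 0.1) {
  d <- dplyr::filter(mock_corrected, !is.na(.data$corrected))
  ggplot2::ggplot(d, ggplot2::aes(.data$corrected)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "corrected log2 intensity", y = "spots",
                  title = "Corrected mock-array signal")
}

#' @rdname plot_autofluorescence
#' @param object An `ige_calibration`.
#' @param ... Unused.
#' @export
autoplot.ige_calibration <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$calibrated)
  ggplot2::ggplot(d, ggplot2::aes(.data$m, .data$tau)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class)) +
    ggplot2::labs(x = "autofluorescence slope m",
                  y = expression(threshold ~ tau),
                  title = "Calibration summary per allergen")
}

#' Dendrogram with bootstrap support labels
#'
#' Segment-based ggplot rendering of an average-linkage tree; internal nodes
#' annotated with `AU/BP` (or `BP` alone) when support is supplied.
#'
#' @param dend An `ige_dendrogram`.
#' @param support Optional `cluster_support`.
#' @return A ggplot.
#' @export
plot_dendrogram <- function(dend, support = NULL) {
  n <- length(dend$labels)
  depth <- dend$height / 2
  xpos <- numeric(nrow(dend$merge))
  leaf_x <- stats::setNames(seq_len(n), dend$order)
  pos <- function(node) {
    if (node < 0) return(unname(leaf_x[as.character(-node)]))
    xpos[node]
  }
  segs <- list(); labs <- list()
  for (k in seq_len(nrow(dend$merge))) {
    ch <- dend$merge[k, ]
    x1 <- pos(ch[1]); x2 <- pos(ch[2])
    y1 <- if (ch[1] < 0) 0 else depth[ch[1]]
    y2 <- if (ch[2] < 0) 0 else depth[ch[2]]
    xpos[k] <- (x1 + x2) / 2
    segs[[k]] <- tibble::tibble(
      x = c(x1, x2, x1), xend = c(x1, x2, x2),
      y = c(y1, y2, depth[k]), yend = c(depth[k], depth[k], depth[k])
    )
    if (!is.null(support)) {
      row <- support[support$node == k, ]
      lab <- if ("au" %in% names(row) && nrow(row)) {
        sprintf("%.2f/%.2f", row$au[1], row$bp[1])
      } else if (nrow(row)) sprintf("%.2f", row$bp[1]) else ""
      labs[[k]] <- tibble::tibble(x = xpos[k], y = depth[k], label = lab)
    }
  }
  leaves <- tibble::tibble(x = seq_len(n),
                           label = dend$labels[dend$order])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::bind_rows(segs),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend)
    ) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "correlation-distance depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (length(labs)) {
    p <- p + ggplot2::geom_text(
      data = dplyr::bind_rows(labs),
      ggplot2::aes(.data$x, .data$y, label = .data$label),
      vjust = -0.4, size = 2.8, colour = "firebrick"
    )
  }
  p
}
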