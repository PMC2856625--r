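#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration model
#'
#' @param x An `ige_calibration`.
#' @param ... Unused.
#' @return One row per allergen: slope, intercept, residual sd, spot counts,
#'   threshold and confidence flags.
#' @export
tidy.ige_calibration <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a calibration model
#'
#' @param x An `ige_calibration`.
#' @param ... Unused.
#' @return Tibble with allergen counts, median slope/intercept/residual sd,
#'   median threshold, and the percentile used.
#' @export
glance.ige_calibration <- function(x, ...) {
  tibble::tibble(
    n_allergens = nrow(x),
    n_calibrated = sum(x$calibrated),
    n_low_confidence = sum(x$low_confidence, na.rm = TRUE),
    median_m = stats::median(x$m, na.rm = TRUE),
    median_b = stats::median(x$b, na.rm = TRUE),
    median_sigma = stats::median(x$sigma, na.rm = TRUE),
    median_tau = stats::median(x$tau, na.rm = TRUE),
    percentile = attr(x, "percentile"),
    quantile_type = attr(x, "quantile_type")
  )
}

#' @export
print.ige_calibration <- function(x, ...) {
  cat("<ige_calibration> ", sum(x$calibrated), "/", nrow(x),
      " allergens calibrated", sep = "")
  p <- attr(x, "percentile")
  if (!is.na(p)) cat("; thresholds at percentile", p)
  cat("\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Tidy pairwise replicate regressions
#'
#' @param x A `replicate_concordance`.
#' @param ... Unused.
#' @return One row per replicate array pair with slope and R-squared.
#' @export
tidy.replicate_concordance <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize replicate concordance
#'
#' @param x A `replicate_concordance`.
#' @param ... Unused.
#' @return Tibble `n_pairs`, `median_r_squared`, `median_slope`.
#' @export
glance.replicate_concordance <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    median_r_squared = stats::median(x$r_squared),
    median_slope = stats::median(x$slope)
  )
}

#' Tidy a matched-pairs comparison
#'
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @return Tibble `estimate`, `t`, `df`, `p_value`, `n_pairs`.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a concordance table
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return The 2x2 counts with proportions, long form.
#' @export
tidy.concordance_table <- function(x, ...) {
  x$counts
}

#' Summarize a concordance table
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return Tibble `n_total`, `elisa_positive_capture`, `agreement`.
#' @export
glance.concordance_table <- function(x, ...) {
  agree <- sum(x$counts$n[x$counts$array_call == x$counts$elisa_call])
  tibble::tibble(
    n_total = x$n_total,
    elisa_positive_capture = x$elisa_positive_capture,
    agreement = agree / x$n_total
  )
}

#' Tidy clade support values
#'
#' @param x A `cluster_support`.
#' @param ... Unused.
#' @return One row per internal node with `clade` flattened to a
#'   `|`-separated string.
#' @export
tidy.cluster_support <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(clade = purrr::map_chr(.data$clade, paste, collapse = "|"))
}
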