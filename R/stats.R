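#' Coefficient-of-variation reproducibility report
#'
#' Summarizes replicate agreement as CV = sd / mean at three replication
#' levels: `intra_slide` (across arrays of one serum on one slide),
#' `inter_slide` (across slide means of that serum), and
#' `inter_assay` (across days). Cells whose replicate mean is at or below
#' `mean_floor` (default 0.5 microarray units) are excluded so that small
#' differences among near-zero values do not skew the report; the median CV
#' is then taken within each allergen class.
#'
#' @param m An `ige_matrix` built with `collapse = "array"`, joined to its
#'   design metadata (`slide_id`, `day`) — see [run_pipeline()] or join the
#'   study manifest by `array_id`.
#' @param layout An [array_layout()] supplying allergen classes.
#' @param levels Which levels to report (default all three).
#' @param mean_floor Replicate-mean floor (default 0.5, strict `>` retained).
#' @return Tibble `level`, `class`, `median_cv`, `n_cells`; a level/class
#'   with no qualifying cells is reported with `n_cells = 0` and `NA` CV.
#' @export
cv_report <- function(m, layout,
                      levels = c("intra_slide", "inter_slide", "inter_assay"),
                      mean_floor = 0.5) {
  need <- c("serum_id", "name", "value", "slide_id", "day")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("`m` lacks design columns: ", paste(miss, collapse = ", "),
         "; join the study manifest by array_id first", call. = FALSE)
  }
  classes <- layout$allergens
  cv <- function(x) stats::sd(x) / mean(x)

  level_cells <- function(level) {
    if (level == "intra_slide") {
      cells <- m |>
        dplyr::group_by(.data$serum_id, .data$name, .data$slide_id) |>
        dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                         cv = cv(stats::na.omit(.data$value)),
                         n = sum(!is.na(.data$value)), .groups = "drop")
    } else if (level == "inter_slide") {
      cells <- m |>
        dplyr::group_by(.data$serum_id, .data$name, .data$slide_id) |>
        dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::group_by(.data$serum_id, .data$name) |>
        dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                         cv = cv(stats::na.omit(.data$value)),
                         n = sum(!is.na(.data$value)), .groups = "drop")
    } else if (level == "inter_assay") {
      cells <- m |>
        dplyr::group_by(.data$serum_id, .data$name, .data$day) |>
        dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::group_by(.data$serum_id, .data$name) |>
        dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                         cv = cv(stats::na.omit(.data$value)),
                         n = sum(!is.na(.data$value)), .groups = "drop")
    } else stop("unknown level: ", level, call. = FALSE)
    cells |>
      dplyr::filter(.data$n >= 2, !is.na(.data$mean),
                    .data$mean > mean_floor)
  }

  purrr::map_dfr(levels, function(lv) {
    cells <- level_cells(lv) |>
      dplyr::left_join(classes, by = "name")
    classes |>
      dplyr::distinct(.data$class) |>
      dplyr::left_join(
        cells |>
          dplyr::group_by(.data$class) |>
          dplyr::summarise(median_cv = stats::median(.data$cv),
                           n_cells = dplyr::n(), .groups = "drop"),
        by = "class"
      ) |>
      dplyr::mutate(level = lv,
                    n_cells = tidyr::replace_na(.data$n_cells, 0L)) |>
      dplyr::select("level", "class", "median_cv", "n_cells")
  })
}

#' Percent-of-total variance shares
#'
#' Converts a set of sums of squares (factors plus error) into percent of the
#' total sum of squares, `SS / sum(SS) * 100`.
#'
#' @param ss Named numeric vector of sums of squares.
#' @return Tibble `term`, `ss`, `pct_ss_total` (sums to 100).
#' @export
variance_share <- function(ss) {
  stopifnot(is.numeric(ss), all(ss >= 0), !is.null(names(ss)))
  tibble::tibble(term = names(ss), ss = unname(ss),
                 pct_ss_total = unname(ss) / sum(ss) * 100)
}

#' ANOVA variance partitioning of fluorescence values
#'
#' Fits a crossed fixed-main-effects model by sequential (type I) sums of
#' squares in the stated factor order and reports each factor's share of the
#' total sum of squares, error included. Factors with a single observed
#' level are dropped with a warning.
#'
#' @param data Long tibble with a numeric response and factor columns.
#' @param response Response column name (default `"value"`).
#' @param factors Factor columns, in entry order (default array position on
#'   the slide, slide, serum, allergen: `c("array_position", "slide_id",
#'   "serum_id", "name")`; array identity would alias slide and serum, so the
#'   12-level position factor plays the design's "array" role).
#' @return Tibble `term`, `ss`, `df`, `pct_ss_total` (error row labelled
#'   `"error"`).
#' @export
anova_components <- function(data, response = "value",
                             factors = c("array_position", "slide_id",
                                         "serum_id", "name")) {
  keep <- character()
  for (f in factors) {
    if (!f %in% names(data)) stop("factor column not found: ", f,
                                  call. = FALSE)
    if (dplyr::n_distinct(data[[f]]) < 2) {
      warning("factor '", f, "' has a single level; dropped", call. = FALSE)
    } else keep <- c(keep, f)
  }
  if (!length(keep)) stop("no factor with >= 2 levels", call. = FALSE)
  d <- data |>
    dplyr::filter(!is.na(.data[[response]])) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(keep), as.factor))
  form <- stats::reformulate(keep, response = response)
  tab <- stats::anova(stats::lm(form, data = d))
  terms <- rownames(tab)
  terms[terms == "Residuals"] <- "error"
  out <- tibble::tibble(term = terms, ss = tab$`Sum Sq`, df = tab$Df)
  out$pct_ss_total <- out$ss / sum(out$ss) * 100
  out
}

#' Regression concordance of one replicate pair
#'
#' Ordinary least squares of one replicate profile on another over their
#' shared non-missing allergens, returning the slope (beta) and coefficient
#' of determination.
#'
#' @param x,y Paired numeric vectors (one value per allergen).
#' @return Tibble `slope`, `r_squared`, `n`; zero rows with a warning if x
#'   has no variance.
#' @export
replicate_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 shared non-missing allergens",
                          call. = FALSE)
  if (stats::var(x) == 0) {
    warning("zero variance in x; regression undefined, pair skipped",
            call. = FALSE)
    return(tibble::tibble(slope = double(), r_squared = double(),
                          n = integer()))
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 n = length(x))
}

#' Pairwise replicate concordance across a study
#'
#' Enumerates all pairs of replicate arrays of each serum and regresses one
#' profile on the other ([replicate_regression()]); replicate agreement is
#' summarized by the median R-squared and median slope over all pairs.
#'
#' @param m An `ige_matrix` built with `collapse = "array"`.
#' @return Tibble of class `replicate_concordance`: `serum_id`, `array_x`,
#'   `array_y`, `slope`, `r_squared`, `n`. Medians via [generics::glance()].
#' @export
replicate_concordance <- function(m) {
  wide <- ige_matrix_wide(m)
  out <- wide |>
    dplyr::group_by(.data$serum_id) |>
    dplyr::group_map(function(g, key) {
      ids <- g$array_id
      if (length(ids) < 2) return(NULL)
      prof <- t(as.matrix(g[, setdiff(names(g), "array_id")]))
      pairs <- utils::combn(seq_along(ids), 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        reg <- replicate_regression(prof[, i], prof[, j])
        if (!nrow(reg)) return(NULL)
        dplyr::mutate(reg, serum_id = key$serum_id,
                      array_x = ids[i], array_y = ids[j], .before = 1)
      })
    }) |>
    dplyr::bind_rows()
  structure(out, class = c("replicate_concordance", class(out)))
}

#' Matched-pairs comparison of two allergen fractions
#'
#' Tests whether sera carry more specific IgE to one extract fraction than
#' another: per serum, the mean microarray units over each fraction's
#' allergen columns (complete cases within the comparison) are paired and a
#' two-tailed paired t-test is run on the differences.
#'
#' @param wide Wide sera-by-allergens tibble ([ige_matrix_wide()]).
#' @param cols_a,cols_b Allergen column names for the two fractions (equal
#'   length if `pairwise = TRUE`, in which case per-serum values are means of
#'   paired column differences; otherwise set means are compared).
#' @return Tibble of class `paired_comparison`: `estimate` (mean difference
#'   A - B), `t`, `df`, `p_value`, `n_pairs`.
#' @export
paired_fraction_test <- function(wide, cols_a, cols_b) {
  stopifnot(all(cols_a %in% names(wide)), all(cols_b %in% names(wide)))
  a <- rowMeans(wide[, cols_a, drop = FALSE], na.rm = TRUE)
  b <- rowMeans(wide[, cols_b, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("all paired differences are equal; test undefined (zero variance)",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  structure(
    tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   n_pairs = length(a)),
    class = c("paired_comparison", "tbl_df", "tbl", "data.frame")
  )
}

#' Call ELISA positivity
#'
#' Clinical rule: a specific-IgE ELISA value is positive when strictly
#' greater than 0.35 kU/L.
#'
#' @param values Numeric kU/L values (must be >= 0; NA allowed).
#' @param cutoff Cutoff (default 0.35).
#' @return Logical vector.
#' @export
elisa_calls <- function(values, cutoff = 0.35) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("ELISA values must be >= 0", call. = FALSE)
  }
  values > cutoff
}

#' Cross-tabulate array and ELISA calls
#'
#' Builds the 2x2 concordance of microarray positivity (thresholded signal
#' strictly above the allergen-specific threshold) against ELISA positivity,
#' with proportions of total and the fraction of ELISA positives the array
#' captures. Pairs with a missing call are dropped.
#'
#' @param array_calls,elisa_calls Paired logical vectors.
#' @return A list of class `concordance_table`: `counts` (tibble
#'   `array_call`, `elisa_call`, `n`, `proportion`), `n_total`,
#'   `elisa_positive_capture` (array+/elisa+ over all elisa+).
#' @export
concordance_table <- function(array_calls, elisa_calls) {
  if (length(array_calls) != length(elisa_calls)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(array_calls) & !is.na(elisa_calls)
  a <- array_calls[ok]; e <- elisa_calls[ok]
  if (!length(a)) stop("no complete call pairs", call. = FALSE)
  counts <- tidyr::expand_grid(array_call = c(TRUE, FALSE),
                               elisa_call = c(TRUE, FALSE)) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = sum(a == .data$array_call & e == .data$elisa_call)) |>
    dplyr::ungroup() |>
    dplyr::mutate(proportion = .data$n / length(a))
  capture <- if (sum(e) > 0) sum(a & e) / sum(e) else NA_real_
  structure(
    list(counts = counts, n_total = length(a),
         elisa_positive_capture = capture),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table> n =", x$n_total, "\n")
  print(x$counts)
  cat("ELISA-positive capture:",
      sprintf("%.0f%%", 100 * x$elisa_positive_capture), "\n")
  invisible(x)
}
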