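#' Preprocess a scanned array
#'
#' First stage of the quantification pipeline: discard QC-flagged spots, then
#' log2-transform both channels. Intensities are floored at 1 before the
#' transform so zero-intensity spots map to 0 rather than -Inf.
#'
#' @param spots Spot tibble (one or several arrays; see [read_gpr()]).
#' @param floor Intensity floor applied before log2 (default 1).
#' @param flag_keep Predicate deciding which flag codes are usable; defaults
#'   to the scanner convention that negative flags mean bad/absent spots.
#' @return The surviving rows with `log2_red` and `log2_green` added.
#'   Warns if every spot was flagged.
#' @export
preprocess <- function(spots, floor = 1, flag_keep = function(flag) flag >= 0) {
  out <- spots |>
    dplyr::filter(flag_keep(.data$flag)) |>
    dplyr::mutate(
      log2_red = log2(pmax(.data$red_median, floor)),
      log2_green = log2(pmax(.data$green_median, floor))
    )
  if (nrow(out) == 0 && nrow(spots) > 0) {
    warning("all spots flagged; preprocessed array is empty", call. = FALSE)
  }
  out
}

#' Fit per-allergen autofluorescence models on mock arrays
#'
#' On buffer-only (mock) arrays the red channel is pure autofluorescence, and
#' red tracks green linearly: `R_AF = m * G_AF + b` on the log2 scale. This
#' fits that line per allergen by ordinary least squares over all unflagged
#' mock spots of the allergen, pooled across mock arrays. Allergens with
#' fewer than `min_spots` usable spots are marked uncalibratable; an allergen
#' whose green channel has zero variance falls back to an intercept-only
#' model (`m = 0`, `b` = mean log2 red) with a warning.
#'
#' @param mock_processed Preprocessed mock spots ([preprocess()] output;
#'   typically several arrays bound together).
#' @param layout An [array_layout()]; only its allergen labels are fitted.
#' @param min_spots Minimum usable spots per allergen (default 3).
#' @return A calibration tibble of class `ige_calibration`: one row per
#'   layout allergen with `name`, `class`, `m`, `b`, `sigma` (residual sd),
#'   `n_fit`, `calibrated`, `note`. Threshold columns are filled later by
#'   [calibrate_thresholds()].
#' @export
fit_autofluorescence <- function(mock_processed, layout, min_spots = 3) {
  stopifnot(inherits(layout, "array_layout"))
  if (any(!is.na(mock_processed$serum_id))) {
    stop("`mock_processed` contains serum arrays; fit on mock arrays only",
         call. = FALSE)
  }
  mock <- dplyr::semi_join(mock_processed, layout$allergens, by = "name")
  fits <- layout$allergens |>
    dplyr::mutate(purrr::map_dfr(.data$name, function(a) {
      d <- dplyr::filter(mock, .data$name == a)
      n <- nrow(d)
      if (n < min_spots) {
        return(tibble::tibble(m = NA_real_, b = NA_real_, sigma = NA_real_,
                              n_fit = n, calibrated = FALSE,
                              note = "too few mock spots"))
      }
      if (stats::var(d$log2_green) == 0) {
        warning("zero green variance for '", a,
                "'; intercept-only autofluorescence model", call. = FALSE)
        res <- d$log2_red - mean(d$log2_red)
        return(tibble::tibble(
          m = 0, b = mean(d$log2_red),
          sigma = stats::sd(d$log2_red), n_fit = n, calibrated = TRUE,
          note = "intercept-only (degenerate green)"
        ))
      }
      fit <- stats::lm(log2_red ~ log2_green, data = d)
      tibble::tibble(
        m = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
        sigma = summary(fit)$sigma, n_fit = n, calibrated = TRUE,
        note = NA_character_
      )
    }))
  fits$tau <- NA_real_
  fits$n_tau <- NA_integer_
  fits$low_confidence <- NA
  structure(fits, class = c("ige_calibration", class(fits)),
            percentile = NA_real_, quantile_type = NA_integer_)
}

#' Subtract modeled autofluorescence from sample arrays
#'
#' Applies the mock-fitted linear model to estimate each spot's
#' autofluorescence from its green channel and subtracts it from the red
#' channel: `corrected = log2_red - (m * log2_green + b)`. The corrected
#' value estimates the specific-IgE contribution; on mock arrays it is an OLS
#' residual, so per-allergen corrected mock values average exactly 0. Spots
#' of uncalibrated allergens get `NA`.
#'
#' @param processed Preprocessed spots ([preprocess()]).
#' @param calibration An `ige_calibration` ([fit_autofluorescence()]).
#' @return `processed` with a `corrected` column.
#' @export
correct_autofluorescence <- function(processed, calibration) {
  coefs <- calibration |>
    dplyr::select("name", "m", "b") |>
    tibble::as_tibble()
  processed |>
    dplyr::left_join(coefs, by = "name") |>
    dplyr::mutate(corrected = .data$log2_red -
                    (.data$m * .data$log2_green + .data$b)) |>
    dplyr::select(-"m", -"b")
}

#' Interpolated empirical quantile
#'
#' Thin wrapper over [stats::quantile()] restricted to the two linearly
#' interpolated conventions the threshold calibration supports: type 6
#' (plotting position `(n+1)p`; a fresh null draw exceeds the estimate with
#' probability `1 - p` on average, so the realized false-positive rate
#' matches `1 - p` even at modest n) and type 7 (R's default, `(n-1)p + 1`).
#'
#' @param x Numeric values.
#' @param p Probability.
#' @param type 6 (default) or 7.
#' @return The interpolated quantile (unnamed scalar).
#' @export
interp_quantile <- function(x, p, type = 6) {
  stopifnot(type %in% c(6, 7))
  unname(stats::quantile(x, p, type = type, names = FALSE, na.rm = TRUE))
}

#' Calibrate allergen-specific detection thresholds
#'
#' The detection threshold for an allergen is an upper percentile (default
#' the 99th) of the corrected signal distribution on mock arrays, so that a
#' null spot is called positive with probability `1 - p` (1% by default).
#' Thresholds from fewer than `min_values` mock values are kept but flagged
#' low-confidence; allergens with no corrected mock values are uncalibratable.
#'
#' @param calibration An `ige_calibration` with fits
#'   ([fit_autofluorescence()]).
#' @param mock_corrected Corrected mock spots ([correct_autofluorescence()]
#'   applied to preprocessed mocks).
#' @param p Percentile (default 0.99).
#' @param type Quantile interpolation convention passed to
#'   [interp_quantile()]; the type-6 default makes the held-out
#'   false-positive rate match `1 - p` at the mock-count this design uses.
#' @param min_values Values below which a threshold is flagged
#'   low-confidence (default 20).
#' @return The calibration with `tau`, `n_tau`, `low_confidence` filled and
#'   attributes `percentile` and `quantile_type` set.
#' @export
calibrate_thresholds <- function(calibration, mock_corrected, p = 0.99,
                                 type = 6, min_values = 20) {
  vals <- mock_corrected |>
    dplyr::filter(!is.na(.data$corrected)) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      tau = interp_quantile(.data$corrected, p, type = type),
      n_tau = dplyr::n(), .groups = "drop"
    )
  out <- calibration |>
    dplyr::select(-"tau", -"n_tau", -"low_confidence") |>
    dplyr::left_join(vals, by = "name") |>
    dplyr::mutate(
      calibrated = .data$calibrated & !is.na(.data$tau),
      low_confidence = !is.na(.data$n_tau) & .data$n_tau < min_values,
      note = dplyr::if_else(.data$calibrated | !is.na(.data$note), .data$note,
                            "no corrected mock values")
    )
  structure(out, class = class(calibration), percentile = p,
            quantile_type = as.integer(type))
}

#' Full calibration from mock arrays
#'
#' Convenience wrapper: preprocess the mock arrays, fit the per-allergen
#' autofluorescence models, correct the same mocks, and calibrate thresholds.
#'
#' @param mock_spots Raw mock spot tibble (one or several arrays).
#' @param layout An [array_layout()].
#' @inheritParams calibrate_thresholds
#' @inheritParams fit_autofluorescence
#' @return An `ige_calibration` with fits and thresholds.
#' @export
calibrate <- function(mock_spots, layout, p = 0.99, type = 6, min_spots = 3,
                      min_values = 20) {
  pp <- preprocess(mock_spots)
  cal <- fit_autofluorescence(pp, layout, min_spots = min_spots)
  corrected <- correct_autofluorescence(pp, cal)
  calibrate_thresholds(cal, corrected, p = p, type = type,
                       min_values = min_values)
}

#' Apply calibrated thresholds
#'
#' Subtracts each allergen's threshold from the corrected signal:
#' `thresholded = corrected - tau`. A spot is called positive when its
#' thresholded value is strictly greater than 0 (a corrected signal exactly
#' at threshold is negative). Missing corrected values propagate.
#'
#' @param corrected Corrected spots ([correct_autofluorescence()]).
#' @param calibration An `ige_calibration` with thresholds.
#' @return Input with `thresholded` and logical `positive` columns.
#' @export
apply_thresholds <- function(corrected, calibration) {
  if (all(is.na(calibration$tau))) {
    stop("calibration has no thresholds; run calibrate_thresholds() first",
         call. = FALSE)
  }
  taus <- calibration |>
    dplyr::select("name", "tau") |>
    tibble::as_tibble()
  corrected |>
    dplyr::left_join(taus, by = "name") |>
    dplyr::mutate(
      thresholded = .data$corrected - .data$tau,
      positive = !is.na(.data$thresholded) & .data$thresholded > 0
    ) |>
    dplyr::select(-"tau")
}

#' One-step Tukey biweight mean
#'
#' Robust location estimate used to aggregate replicate spots: weights are
#' `(1 - u^2)^2` for `|u| < 1` (0 otherwise) with `u = (x - M) / (c * S)`,
#' `M` the median and `S` the unscaled median absolute deviation. When the
#' MAD is 0 the median is returned.
#'
#' @param x Numeric values (NAs dropped).
#' @param c Tuning constant (default 5).
#' @return Weighted mean (scalar); `NA` for empty input.
#' @export
tukey_biweight <- function(x, c = 5) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  if (s == 0) return(m)
  u <- (x - m) / (c * s)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Tukey trimean
#'
#' `(Q1 + 2 * median + Q3) / 4`, offered as an alternative replicate
#' aggregate.
#'
#' @inheritParams tukey_biweight
#' @return Scalar; `NA` for empty input.
#' @export
tukey_trimean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  (q[1] + 2 * q[2] + q[3]) / 4
}

#' Aggregate replicate values for one serum-allergen cell
#'
#' Applies the missingness rule, then a robust location estimate: if more
#' than 50% of the cell's expected replicates are missing the cell is
#' recorded as missing; otherwise the replicates are combined with the
#' one-step Tukey biweight mean (default), trimean, or median.
#'
#' @param x Observed replicate values (thresholded microarray units).
#' @param expected_n Replicates the layout expects for the cell (default:
#'   `length(x)` including NAs).
#' @param method `"biweight"` (default), `"trimean"`, or `"median"`.
#' @param c Biweight tuning constant (default 5).
#' @param max_missing Missing fraction above which the cell is dropped
#'   (default 0.5, strict).
#' @return Scalar microarray units, or `NA` if the cell is discarded.
#' @export
aggregate_replicates <- function(x, expected_n = length(x),
                                 method = c("biweight", "trimean", "median"),
                                 c = 5, max_missing = 0.5) {
  method <- match.arg(method)
  obs <- x[!is.na(x)]
  if (expected_n <= 0) return(NA_real_)
  if ((expected_n - length(obs)) / expected_n > max_missing) return(NA_real_)
  if (!length(obs)) return(NA_real_)
  switch(method,
    biweight = tukey_biweight(obs, c = c),
    trimean = tukey_trimean(obs),
    median = stats::median(obs)
  )
}

#' Assemble the specific-IgE matrix
#'
#' Collapses thresholded replicate spots into microarray units per
#' serum-allergen cell. With `collapse = "array"` (default) replicate arrays
#' of one serum stay separate (one row per array); with `collapse = "serum"`
#' all of a serum's arrays contribute to a single cell. Only calibrated
#' allergens appear as columns in the wide view; uncalibratable allergens are
#' listed in the `dropped_allergens` attribute.
#'
#' @param thresholded Thresholded sample spots ([apply_thresholds()]),
#'   serum arrays only, with an `array_id` column (added by
#'   [simulate_study()] or derivable as slide/position).
#' @param layout An [array_layout()].
#' @param calibration The `ige_calibration` used.
#' @param collapse `"array"` or `"serum"`.
#' @inheritParams aggregate_replicates
#' @return A long tibble of class `ige_matrix`: `serum_id`, `array_id`
#'   (collapse = "array" only), `name`, `value`, `n_obs`, `n_expected`.
#' @export
build_ige_matrix <- function(thresholded, layout, calibration,
                             collapse = c("array", "serum"),
                             method = "biweight", c = 5, max_missing = 0.5) {
  collapse <- match.arg(collapse)
  samples <- dplyr::filter(thresholded, !is.na(.data$serum_id))
  if (nrow(samples) == 0) stop("no sample (serum) arrays supplied",
                               call. = FALSE)
  if (!"array_id" %in% names(samples)) {
    samples$array_id <- paste0(samples$slide_id, "_a",
                               sprintf("%02d", samples$array_position))
  }
  keep <- calibration$name[calibration$calibrated]
  samples <- dplyr::filter(samples, .data$name %in% keep)
  rep_per_array <- layout$replicates_per_allergen
  groups <- if (collapse == "array") c("serum_id", "array_id", "name")
            else c("serum_id", "name")
  n_arrays <- samples |>
    dplyr::distinct(.data$serum_id, .data$array_id) |>
    dplyr::count(.data$serum_id, name = "n_arrays")
  out <- samples |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$thresholded)),
      values = list(.data$thresholded), .groups = "drop"
    )
  if (collapse == "array") {
    out$n_expected <- rep_per_array
  } else {
    out <- dplyr::left_join(out, n_arrays, by = "serum_id")
    out$n_expected <- rep_per_array * out$n_arrays
    out$n_arrays <- NULL
  }
  # complete missing cells (e.g. all replicates flagged) as fully missing
  frame <- samples |>
    dplyr::distinct(dplyr::across(dplyr::all_of(groups[-length(groups)]))) |>
    tidyr::expand_grid(name = keep)
  out <- dplyr::left_join(frame, out, by = groups) |>
    dplyr::mutate(
      n_obs = tidyr::replace_na(.data$n_obs, 0L),
      n_expected = tidyr::replace_na(.data$n_expected, rep_per_array),
      value = purrr::map2_dbl(.data$values, .data$n_expected,
                              ~ aggregate_replicates(.x %||% NA_real_,
                                                     expected_n = .y,
                                                     method = method, c = c,
                                                     max_missing = max_missing))
    ) |>
    dplyr::select(-"values")
  dropped <- calibration$name[!calibration$calibrated]
  structure(out, class = c("ige_matrix", class(out)),
            collapse = collapse, dropped_allergens = dropped)
}

#' Widen an IgE matrix to sera-by-allergens
#'
#' @param m An `ige_matrix` (long) from [build_ige_matrix()].
#' @return Wide tibble: one row per serum (or array), one column per
#'   calibrated allergen.
#' @export
ige_matrix_wide <- function(m) {
  id_cols <- intersect(c("serum_id", "array_id"), names(m))
  tidyr::pivot_wider(tibble::as_tibble(m),
                     id_cols = dplyr::all_of(id_cols),
                     names_from = "name", values_from = "value")
}

#' QC the IgE standard dilution curve
#'
#' Checks that the secondary antibody worked: the mean red signal over IgE
#' standard spots must increase with printed pg/spot (Spearman rank
#' correlation above `min_cor`). The standards are used only as a pass/fail
#' check, never for normalization. IgG/IgA standards are not evaluated.
#'
#' @param processed Preprocessed spots of one array.
#' @param layout An [array_layout()].
#' @param min_cor Pass bar on the rank correlation (default 0.9).
#' @return Tibble with `rho`, `n_levels`, `pass`; zero rows (with a warning)
#'   if no IgE standard spots are present.
#' @export
qc_standard_curve <- function(processed, layout, min_cor = 0.9) {
  spots <- layout_spots(layout) |>
    dplyr::filter(.data$spot_type == "standard", .data$isotype == "IgE") |>
    dplyr::distinct(.data$name, .data$conc_pg)
  std <- dplyr::inner_join(processed, spots, by = "name")
  if (nrow(std) == 0) {
    warning("no IgE standard spots found; QC skipped", call. = FALSE)
    return(tibble::tibble(rho = double(), n_levels = integer(),
                          pass = logical()))
  }
  curve <- std |>
    dplyr::group_by(.data$conc_pg) |>
    dplyr::summarise(mean_red = mean(.data$log2_red), .groups = "drop")
  rho <- stats::cor(curve$conc_pg, curve$mean_red, method = "spearman")
  tibble::tibble(rho = rho, n_levels = nrow(curve), pass = rho > min_cor)
}
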