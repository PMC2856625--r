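#' Configure a pipeline run
#'
#' Collects every knob of the calibrate - quantify - report - cluster
#' pipeline into one serializable list, so a run is reproducible from
#' (config, input files).
#'
#' @param manifest Path to a slide manifest ([read_manifest()]); `NULL` when
#'   passing an in-memory `ige_study` to [run_pipeline()].
#' @param out_dir Output directory.
#' @param percentile Threshold percentile (default 0.99).
#' @param quantile_type Interpolated-quantile convention, 6 or 7
#'   ([interp_quantile()]).
#' @param aggregate Replicate aggregation: `"biweight"`, `"trimean"`,
#'   `"median"`.
#' @param mean_floor CV report replicate-mean floor (default 0.5).
#' @param collapse IgE matrix granularity, `"array"` or `"serum"`.
#' @param cluster_B Bootstrap replicates (default 1000).
#' @param cluster_scales Multiscale-bootstrap scales (`NULL` disables AU).
#' @param seed Top-level seed for all stochastic stages.
#' @param layout An [array_layout()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = "serochip_run",
                       percentile = 0.99, quantile_type = 6,
                       aggregate = "biweight", mean_floor = 0.5,
                       collapse = "array", cluster_B = 1000,
                       cluster_scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
                       layout = default_array_layout()) {
  structure(
    list(manifest = manifest, out_dir = out_dir, percentile = percentile,
         quantile_type = quantile_type, aggregate = aggregate,
         mean_floor = mean_floor, collapse = collapse, cluster_B = cluster_B,
         cluster_scales = cluster_scales, seed = as.integer(seed),
         layout = layout),
    class = "run_config"
  )
}

config_hash <- function(config) {
  # hash the analysis parameters, not file-system locations
  keep <- setdiff(names(config), c("layout", "out_dir", "manifest"))
  substr(rlang::hash(config[keep]), 1, 12)
}

#' Run the full quantification pipeline
#'
#' Orchestrates preprocess, autofluorescence fitting, correction, threshold
#' calibration, thresholding, replicate aggregation, reproducibility
#' statistics, and clustering, and writes every artifact (calibration JSON,
#' IgE matrix CSV, stats CSVs, Newick tree, machine-readable run report) to
#' `config$out_dir`. Stages that cannot run (no sample arrays, too few sera
#' to cluster) are skipped with a notice recorded in the run report; nothing
#' is silently dropped — the report counts flagged spots, uncalibratable
#' allergens, and discarded cells.
#'
#' @param config A [run_config()].
#' @param study Optional in-memory `ige_study` ([simulate_study()]); when
#'   `NULL`, arrays are read from `config$manifest`.
#' @return Invisibly, a list with `calibration`, `matrix` (long IgE matrix
#'   joined to design metadata), `cv`, `anova`, `concordance` (replicate
#'   regression), `support`, `report`, and the output paths.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  notices <- character()
  layout <- config$layout

  if (is.null(study)) {
    if (is.null(config$manifest)) {
      stop("supply either `study` or a manifest path in the config",
           call. = FALSE)
    }
    man <- read_manifest(config$manifest)
    arrays <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
      scan <- read_gpr(man$file[i], layout = layout)
      scan$slide_id <- man$slide_id[i]
      scan$array_position <- man$array_position[i]
      scan$serum_id <- man$serum_id[i]
      if ("day" %in% names(man)) scan$day <- as.integer(man$day[i])
      if ("dilution" %in% names(man)) scan$dilution <- man$dilution[i]
      scan$array_id <- sprintf("%s_a%02d", man$slide_id[i],
                               man$array_position[i])
      scan
    })
    manifest <- man |>
      dplyr::mutate(array_id = sprintf("%s_a%02d", .data$slide_id,
                                       .data$array_position))
  } else {
    arrays <- study$arrays
    manifest <- study$manifest
  }

  n_spots <- nrow(arrays)
  mock_raw <- dplyr::filter(arrays, is.na(.data$serum_id))
  sample_raw <- dplyr::filter(arrays, !is.na(.data$serum_id))
  if (nrow(mock_raw) == 0) {
    stop("calibration error: the manifest resolves to no mock arrays; ",
         "mock (buffer-only) arrays are required to fit autofluorescence ",
         "and thresholds", call. = FALSE)
  }

  # calibrate
  mock_pp <- preprocess(mock_raw)
  cal <- fit_autofluorescence(mock_pp, layout)
  mock_corr <- correct_autofluorescence(mock_pp, cal)
  cal <- calibrate_thresholds(cal, mock_corr, p = config$percentile,
                              type = config$quantile_type)
  cal_path <- file.path(config$out_dir, "calibration.json")
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         percentile = config$percentile,
         quantile_type = config$quantile_type,
         allergens = tibble::as_tibble(cal)),
    cal_path, auto_unbox = TRUE, digits = NA, na = "null"
  )

  mat <- NULL; cvr <- NULL; an <- NULL; conc <- NULL; support <- NULL
  if (nrow(sample_raw) == 0) {
    notices <- c(notices, "no sample arrays: quantification, stats and clustering skipped")
  } else {
    pp <- preprocess(sample_raw)
    th <- apply_thresholds(correct_autofluorescence(pp, cal), cal)
    mat <- build_ige_matrix(th, layout, cal, collapse = config$collapse,
                            method = config$aggregate)
    meta <- manifest |>
      dplyr::distinct(.data$array_id, .data$slide_id, .data$array_position,
                      .data$day)
    mat_meta <- dplyr::left_join(tibble::as_tibble(mat), meta,
                                 by = intersect("array_id", names(mat)))
    readr::write_csv(
      ige_matrix_wide(mat) |>
        dplyr::mutate(.config = config_hash(config), .seed = config$seed),
      file.path(config$out_dir, "ige_matrix.csv")
    )

    if (config$collapse == "array" && all(c("slide_id", "day") %in%
                                          names(mat_meta))) {
      cvr <- cv_report(mat_meta, layout, mean_floor = config$mean_floor)
      readr::write_csv(cvr, file.path(config$out_dir, "cv_report.csv"))
      an <- tryCatch(
        anova_components(mat_meta, response = "value"),
        error = function(e) {
          notices <<- c(notices, paste("ANOVA skipped:", conditionMessage(e)))
          NULL
        })
      if (!is.null(an)) {
        readr::write_csv(an, file.path(config$out_dir, "anova.csv"))
      }
      conc <- replicate_concordance(mat)
      readr::write_csv(tibble::as_tibble(conc),
                       file.path(config$out_dir, "replicate_regression.csv"))
    }

    wide <- ige_matrix_wide(mat)
    if (nrow(wide) >= 4) {
      boot <- function() {
        if (is.null(config$cluster_scales)) {
          bootstrap_support(wide, B = config$cluster_B, seed = config$seed)
        } else {
          multiscale_au(wide, scales = config$cluster_scales,
                        B = config$cluster_B, seed = config$seed)
        }
      }
      support <- tryCatch(suppressWarnings(boot()), error = function(e) {
        notices <<- c(notices, paste("clustering skipped:",
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(support)) {
        writeLines(
          export_newick(attr(support, "dendrogram"), support),
          file.path(config$out_dir, "tree.nwk")
        )
        readr::write_csv(
          tibble::as_tibble(support) |>
            dplyr::mutate(clade = purrr::map_chr(.data$clade, paste,
                                                 collapse = "|")),
          file.path(config$out_dir, "cluster_support.csv")
        )
      }
    } else {
      notices <- c(notices, "fewer than 4 profile rows: clustering skipped")
    }
  }

  report <- list(
    config_hash = config_hash(config), seed = config$seed,
    config = config[setdiff(names(config), "layout")],
    n_spots = n_spots,
    n_arrays = dplyr::n_distinct(arrays$array_id %||%
                                   paste(arrays$slide_id,
                                         arrays$array_position)),
    n_mock_arrays = dplyr::n_distinct(
      paste(mock_raw$slide_id, mock_raw$array_position)),
    n_flagged_spots = sum(arrays$flag < 0),
    uncalibratable_allergens = cal$name[!cal$calibrated],
    n_cells_discarded_missing = if (!is.null(mat)) {
      sum(is.na(mat$value))
    } else 0L,
    notices = notices
  )
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (msg in notices) message(msg)
  invisible(list(calibration = cal, matrix = if (!is.null(mat)) mat_meta,
                 cv = cvr, anova = an, concordance = conc,
                 support = support, report = report,
                 out_dir = config$out_dir))
}
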