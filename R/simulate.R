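#' Parameterize a synthetic microarray study
#'
#' Builds the full generative parameterization for synthetic slides. Each
#' printed label gets its own autofluorescence model: log2 green intensity is
#' Normal(`mu_g`, `sigma_g`) and log2 red is `m * log2(green) + b` plus
#' Normal(0, `sigma_eps`) residual noise — the linear red-on-green null model
#' the correction stage assumes. Serum-specific IgE is added to the red
#' channel only, on the log2 scale by default. Per-label parameters are drawn
#' once, deterministically from `seed`, when the config is created; all
#' simulators are then pure functions of (config, seed).
#'
#' @param layout An [array_layout()] (default [default_array_layout()]).
#' @param seed Integer seed governing parameter draws and, by default, the
#'   simulators.
#' @param mu_g_range Range of per-label mean log2 green intensity.
#' @param sigma_g Spot-to-spot sd of log2 green within a label.
#' @param m_range Range of per-label red-on-green slopes.
#' @param b_range Range of per-label intercepts (log2 units).
#' @param sigma_eps Residual sd of log2 red about the line.
#' @param flag_rate Probability a spot is QC-flagged (flag -100).
#' @param signal_scale `"log2"` (IgE adds to log2 red; default) or `"raw"`
#'   (IgE adds on the intensity scale) — two regimes for sensitivity checks.
#' @param n_sera,arrays_per_serum,n_mock_arrays,n_days Reproducibility design:
#'   defaults 6 sera x 18 arrays (6 arrays/slide x 3 slides over 3 days) plus
#'   36 mock arrays, i.e. 144 arrays on 12 twelve-array slides.
#' @param dilution_ref Reference serum fraction at which IgE effects are
#'   expressed (default 0.25).
#' @param dilution_series Serum fractions for dilution-response runs.
#' @param ige_std_gain log2 red gain per log2 pg/spot on IgE standard spots
#'   (secondary antibody binds printed IgE directly, so these light up on
#'   mock and serum arrays alike; IgG/IgA standards stay at autofluorescence).
#' @return A `simulation_config` (list) with the per-label parameter tibble in
#'   `$af_params` (columns `name`, `mu_g`, `sigma_g`, `m`, `b`).
#' @export
simulation_config <- function(layout = default_array_layout(),
                              seed = 1L,
                              mu_g_range = c(6, 12),
                              sigma_g = 0.5,
                              m_range = c(0.8, 1.1),
                              b_range = c(0.5, 2),
                              sigma_eps = 0.3,
                              flag_rate = 0.02,
                              signal_scale = c("log2", "raw"),
                              n_sera = 6L,
                              arrays_per_serum = 18L,
                              n_mock_arrays = 36L,
                              n_days = 3L,
                              dilution_ref = 0.25,
                              dilution_series = c(0.5, 0.25, 0.125, 0.0625,
                                                  0.03125),
                              ige_std_gain = 0.6) {
  stopifnot(inherits(layout, "array_layout"),
            sigma_g >= 0, sigma_eps >= 0,
            flag_rate >= 0, flag_rate <= 1,
            dilution_ref > 0, dilution_ref <= 1)
  signal_scale <- match.arg(signal_scale)
  label_info <- layout_spots(layout) |>
    dplyr::distinct(.data$name, .data$spot_type, .data$isotype,
                    .data$conc_pg)
  af_params <- withr::with_seed(seed, {
    # a standard dilution series is one printed material: share its AF
    # parameters per isotype and scale the mean intensity with pg/spot
    grp <- ifelse(label_info$spot_type == "standard",
                  paste0("std:", label_info$isotype), label_info$name)
    ug <- unique(grp)
    base <- tibble::tibble(
      grp = ug,
      mu_g = stats::runif(length(ug), mu_g_range[1], mu_g_range[2]),
      m = stats::runif(length(ug), m_range[1], m_range[2]),
      b = stats::runif(length(ug), b_range[1], b_range[2])
    )
    label_info |>
      dplyr::mutate(grp = grp) |>
      dplyr::left_join(base, by = "grp") |>
      dplyr::mutate(
        mu_g = .data$mu_g + dplyr::if_else(
          .data$spot_type == "standard",
          0.5 * log2(.data$conc_pg /
                       max(c(layout$standard_concentrations, 1))),
          0
        ),
        sigma_g = sigma_g
      ) |>
      dplyr::select("name", "mu_g", "sigma_g", "m", "b")
  })
  structure(
    list(
      layout = layout, seed = as.integer(seed), af_params = af_params,
      sigma_eps = sigma_eps, flag_rate = flag_rate,
      signal_scale = signal_scale,
      n_sera = as.integer(n_sera),
      arrays_per_serum = as.integer(arrays_per_serum),
      n_mock_arrays = as.integer(n_mock_arrays),
      n_days = as.integer(n_days),
      dilution_ref = dilution_ref, dilution_series = dilution_series,
      ige_std_gain = ige_std_gain
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  labels:", nrow(x$af_params), " sigma_eps:", x$sigma_eps,
      " flag_rate:", x$flag_rate, " scale:", x$signal_scale, "\n")
  cat("  design:", x$n_sera, "sera x", x$arrays_per_serum, "arrays +",
      x$n_mock_arrays, "mocks over", x$n_days, "days; seed", x$seed, "\n")
  invisible(x)
}

#' Draw serum IgE profiles
#'
#' A profile is the per-allergen specific-IgE signal a serum adds to the red
#' channel (log2 scale) at the reference dilution; zero means not sensitized.
#' Optionally, allergens are partitioned into blocks whose effects are shared
#' (scaled per serum) within a block — planting correlation structure that
#' downstream clustering should recover.
#'
#' @param config A [simulation_config()].
#' @param n_sera Number of profiles (default from the config design).
#' @param prevalence Baseline probability an (serum, allergen) pair is
#'   sensitized (that of a `"moderate"` total-IgE serum).
#' @param effect_range Range of sensitized effects, log2 units at reference
#'   dilution.
#' @param total_ige_classes Per-serum total-IgE class, recycled over sera:
#'   `"none"`, `"low"`, `"moderate"`, `"high"`. Classes scale sensitization
#'   prevalence (x 0, 0.5, 1, 1.75) and effect size (x 0, 0.7, 1, 1.3), so a
#'   panel spans a wide range of specific-IgE load. Default cycles
#'   low/moderate/high; ignored when `blocks` is given.
#' @param blocks Optional named list of character vectors of allergen names;
#'   allergens within one block receive a common sensitization pattern.
#' @param seed Seed (default derived from the config seed).
#' @return Tibble with columns `serum_id`, `name` (allergen), `effect`, and
#'   `total_ige_class`, one row per serum-allergen pair (zeros included).
#' @export
simulate_profiles <- function(config, n_sera = config$n_sera,
                              prevalence = 0.2,
                              effect_range = c(1.5, 5),
                              total_ige_classes = c("low", "moderate",
                                                    "high"),
                              blocks = NULL,
                              seed = config$seed + 1000L) {
  allergens <- config$layout$allergens$name
  sera <- sprintf("serum%02d", seq_len(n_sera))
  class_prev <- c(none = 0, low = 0.5, moderate = 1, high = 1.75)
  class_eff <- c(none = 0, low = 0.7, moderate = 1, high = 1.3)
  serum_class <- stats::setNames(rep_len(total_ige_classes, n_sera), sera)
  stopifnot(all(serum_class %in% names(class_prev)))
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(serum_id = sera, name = allergens)
    if (is.null(blocks)) {
      prev <- pmin(prevalence * class_prev[serum_class[grid$serum_id]], 1)
      eff_mult <- class_eff[serum_class[grid$serum_id]]
      grid$effect <- ifelse(
        stats::runif(nrow(grid)) < prev,
        eff_mult * stats::runif(nrow(grid), effect_range[1], effect_range[2]),
        0
      )
      grid$total_ige_class <- unname(serum_class[grid$serum_id])
    } else {
      block_of <- rep(NA_character_, length(allergens))
      names(block_of) <- allergens
      for (bn in names(blocks)) block_of[blocks[[bn]]] <- bn
      # per (serum, block) a shared sensitization toggle and base effect;
      # small per-allergen jitter keeps within-block correlation < 1
      bl <- tidyr::expand_grid(serum_id = sera,
                               block = unique(stats::na.omit(block_of)))
      bl$on <- stats::runif(nrow(bl)) < 0.5
      bl$base <- stats::runif(nrow(bl), effect_range[1], effect_range[2])
      grid$block <- block_of[grid$name]
      grid <- dplyr::left_join(grid, bl, by = c("serum_id", "block"))
      in_block <- !is.na(grid$block)
      grid$effect <- 0
      grid$effect[in_block] <- ifelse(
        grid$on[in_block],
        pmax(0, grid$base[in_block] + stats::rnorm(sum(in_block), 0, 0.3)),
        0
      )
      loose <- !in_block
      grid$effect[loose] <- ifelse(
        stats::runif(sum(loose)) < prevalence,
        stats::runif(sum(loose), effect_range[1], effect_range[2]), 0
      )
      grid$total_ige_class <- "moderate"
      grid <- dplyr::select(grid, "serum_id", "name", "effect",
                            "total_ige_class")
    }
    grid
  })
}

# shared spot generator: effects is a named vector of log2-red additions
simulate_spots <- function(config, effects, meta, seed) {
  spots <- layout_spots(config$layout)
  spots <- dplyr::left_join(spots, config$af_params, by = "name")
  withr::with_seed(seed, {
    n <- nrow(spots)
    g <- stats::rnorm(n, spots$mu_g, spots$sigma_g)
    eps <- if (config$sigma_eps > 0) stats::rnorm(n, 0, config$sigma_eps)
           else numeric(n)
    r_af <- spots$m * g + spots$b + eps
    # IgE standard spots bind the secondary antibody directly
    std_gain <- ifelse(
      spots$spot_type == "standard" & spots$isotype == "IgE" &
        !is.na(spots$conc_pg),
      config$ige_std_gain * log2(spots$conc_pg), 0
    )
    std_gain[is.na(std_gain)] <- 0
    eff <- effects[spots$name]
    eff[is.na(eff)] <- 0
    if (config$signal_scale == "log2") {
      r <- 2^(r_af + std_gain + eff)
    } else {
      r <- 2^(r_af) + 2^(std_gain + eff) - 1
    }
    flag <- ifelse(stats::runif(n) < config$flag_rate, -100L, 0L)
    spots |>
      dplyr::transmute(
        block = .data$block, column = .data$column, row = .data$row,
        name = .data$name, replicate_index = .data$replicate_index,
        red_median = r, green_median = 2^g, flag = flag,
        slide_id = meta$slide_id,
        array_position = as.integer(meta$array_position),
        serum_id = meta$serum_id, day = as.integer(meta$day),
        dilution = meta$dilution
      )
  })
}

#' Simulate one mock (buffer-only) array
#'
#' Mock arrays carry pure autofluorescence: red and green follow the
#' linear-Gaussian null model of the config exactly, so they define the null
#' distribution the threshold calibration uses.
#'
#' @param config A [simulation_config()].
#' @param slide_id,array_position,day Array metadata.
#' @param seed Simulation seed (default the config seed).
#' @return A spot tibble (see [read_gpr()] for columns); `serum_id` is `NA`.
#' @export
simulate_mock_array <- function(config, slide_id = "S01", array_position = 1L,
                                day = 1L, seed = config$seed) {
  simulate_spots(
    config, effects = numeric(0),
    meta = list(slide_id = slide_id, array_position = array_position,
                serum_id = NA_character_, day = day, dilution = NA_real_),
    seed = seed
  )
}

#' Simulate one serum-probed array
#'
#' As [simulate_mock_array()], but the red channel is augmented by the serum's
#' specific-IgE effects scaled by the dilution response
#' `h(d) = d / dilution_ref` (so `h = 1` at the reference fraction); the green
#' channel is untouched by IgE.
#'
#' @param config A [simulation_config()].
#' @param profile One serum's rows of [simulate_profiles()] (columns `name`,
#'   `effect`; a `serum_id` column, if present, must be constant).
#' @param dilution Serum fraction in (0, 1].
#' @param slide_id,array_position,day Array metadata.
#' @param seed Simulation seed.
#' @return A spot tibble.
#' @export
simulate_serum_array <- function(config, profile,
                                 dilution = config$dilution_ref,
                                 slide_id = "S01", array_position = 1L,
                                 day = 1L, seed = config$seed) {
  if (!is.numeric(dilution) || dilution <= 0 || dilution > 1) {
    stop("`dilution` must be in (0, 1]", call. = FALSE)
  }
  serum_id <- if ("serum_id" %in% names(profile)) {
    unique(profile$serum_id)
  } else "serum"
  stopifnot(length(serum_id) == 1)
  if (any(profile$effect < 0)) stop("profile effects must be >= 0",
                                    call. = FALSE)
  h <- dilution / config$dilution_ref
  effects <- stats::setNames(h * profile$effect, profile$name)
  simulate_spots(
    config, effects = effects,
    meta = list(slide_id = slide_id, array_position = array_position,
                serum_id = serum_id, day = day, dilution = dilution),
    seed = seed
  )
}

#' Simulate a set of mock arrays
#'
#' Convenience wrapper around [simulate_mock_array()]: generates `n` mock
#' arrays laid out on consecutive slides, with per-array seeds derived
#' deterministically from one top-level seed (the same derivation
#' [simulate_study()] uses).
#'
#' @param config A [simulation_config()].
#' @param n Number of mock arrays (default the config design's mock count).
#' @param seed Top-level seed.
#' @param slide_prefix Slide-id prefix (default "M").
#' @return One long spot tibble with an `array_id` column.
#' @export
simulate_mock_arrays <- function(config, n = config$n_mock_arrays,
                                 seed = config$seed, slide_prefix = "M") {
  aps <- config$layout$arrays_per_slide
  purrr::map_dfr(seq_len(n), function(i) {
    scan <- simulate_mock_array(
      config,
      slide_id = sprintf("%s%02d", slide_prefix, (i - 1) %/% aps + 1),
      array_position = (i - 1) %% aps + 1,
      day = (i - 1) %/% aps + 1,
      seed = (seed + 7919L * i) %% .Machine$integer.max
    )
    scan$array_id <- sprintf("%s_a%02d", scan$slide_id[1],
                             scan$array_position[1])
    scan
  })
}

#' Simulate a full reproducibility study
#'
#' Lays out mock and serum arrays across slides and days following the
#' config's design: per day, each serum is probed on `arrays_per_serum /
#' n_days` arrays, packed onto twelve-array slides, plus `n_mock_arrays /
#' n_days` mock arrays per day on their own slides. The default design (6
#' sera x 18 arrays + 36 mocks over 3 days) yields 144 arrays on 12 slides.
#'
#' @param config A [simulation_config()].
#' @param profiles Profile tibble from [simulate_profiles()]; `NULL` draws
#'   defaults; zero-row input emits mock arrays only.
#' @param seed Top-level seed; per-array seeds are derived from it.
#' @return A list of class `ige_study`: `$arrays` (one long spot tibble with
#'   an `array_id` column), `$manifest` (one row per array), and `$truth`
#'   (the config's `af_params` and the profiles).
#' @export
simulate_study <- function(config, profiles = NULL, seed = config$seed) {
  if (is.null(profiles)) profiles <- simulate_profiles(config)
  sera <- unique(profiles$serum_id)
  aps <- config$layout$arrays_per_slide
  if (config$arrays_per_serum %% config$n_days != 0 ||
      config$n_mock_arrays %% config$n_days != 0) {
    stop("infeasible design: arrays_per_serum and n_mock_arrays must divide ",
         "evenly over n_days", call. = FALSE)
  }
  per_day <- config$arrays_per_serum / config$n_days
  mocks_per_day <- config$n_mock_arrays / config$n_days

  # enumerate arrays: per day, mocks first, then sera round-robin onto slides
  plan <- list()
  slide_n <- 0L
  for (d in seq_len(config$n_days)) {
    # rotate serum order across days so slide/serum pairings vary
    rot <- if (length(sera)) {
      sera[(seq_along(sera) + d - 2L) %% length(sera) + 1L]
    } else sera
    kinds <- c(rep(NA_character_, mocks_per_day),
               rep(rot, each = per_day))
    for (i in seq_along(kinds)) {
      pos <- (i - 1L) %% aps + 1L
      if (pos == 1L) slide_n <- slide_n + 1L
      plan[[length(plan) + 1L]] <- tibble::tibble(
        day = d, slide_id = sprintf("S%02d", slide_n), array_position = pos,
        serum_id = kinds[i]
      )
    }
  }
  plan <- dplyr::bind_rows(plan) |>
    dplyr::mutate(array_id = sprintf("%s_a%02d", .data$slide_id,
                                     .data$array_position))

  arrays <- purrr::map(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    array_seed <- (seed + 7919L * i) %% .Machine$integer.max
    scan <- if (is.na(row$serum_id)) {
      simulate_mock_array(config, slide_id = row$slide_id,
                          array_position = row$array_position, day = row$day,
                          seed = array_seed)
    } else {
      simulate_serum_array(
        config, dplyr::filter(profiles, .data$serum_id == row$serum_id),
        dilution = config$dilution_ref, slide_id = row$slide_id,
        array_position = row$array_position, day = row$day, seed = array_seed
      )
    }
    scan$array_id <- row$array_id
    scan
  })
  structure(
    list(
      arrays = dplyr::bind_rows(arrays),
      manifest = plan |>
        dplyr::mutate(dilution = dplyr::if_else(is.na(.data$serum_id),
                                                NA_real_,
                                                config$dilution_ref)),
      truth = list(af_params = config$af_params, profiles = profiles)
    ),
    class = "ige_study"
  )
}

#' @export
print.ige_study <- function(x, ...) {
  n_arr <- dplyr::n_distinct(x$arrays$array_id)
  n_mock <- sum(is.na(x$manifest$serum_id))
  cat("<ige_study> ", n_arr, " arrays (", n_mock, " mock) on ",
      dplyr::n_distinct(x$manifest$slide_id), " slides, ",
      dplyr::n_distinct(stats::na.omit(x$manifest$serum_id)), " sera\n",
      sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits one GPR-dialect file per array, a `manifest.csv`, and the ground
#' truth (`truth_af_params.csv`, `truth_profiles.csv`).
#'
#' @param study An `ige_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(study$arrays$array_id)
  files <- character(length(ids))
  for (i in seq_along(ids)) {
    scan <- dplyr::filter(study$arrays, .data$array_id == ids[i])
    files[i] <- file.path(dir, paste0(ids[i], ".gpr"))
    write_gpr(dplyr::select(scan, -"array_id"), files[i])
  }
  man <- study$manifest
  man$file <- file.path(dir, paste0(man$array_id, ".gpr"))
  readr::write_csv(man, file.path(dir, "manifest.csv"), na = "")
  readr::write_csv(study$truth$af_params,
                   file.path(dir, "truth_af_params.csv"))
  readr::write_csv(study$truth$profiles, file.path(dir, "truth_profiles.csv"))
  invisible(dir)
}

#' Simulate an ELISA panel in kU/L
#'
#' Generates clinical-style ELISA values for serum-allergen pairs so that
#' concordance analyses against the array are testable. Sensitized pairs
#' (profile effect > 0) exceed the 0.35 kU/L clinical cutoff with probability
#' `sensitivity`; non-sensitized pairs stay below it with probability
#' `specificity`. With `noise_sd = 0` all non-sensitized values are exactly 0
#' and sensitized values are deterministic.
#'
#' @param profiles Profile tibble ([simulate_profiles()]).
#' @param allergens Allergen subset to assay (default: all in `profiles`).
#' @param sensitivity,specificity Call probabilities (defaults 0.85, 0.97).
#' @param noise_sd Half-normal sd of negative-pair background, kU/L.
#' @param seed Integer seed.
#' @return Tibble `serum_id`, `name`, `kU_L`, `sensitized` (truth).
#' @export
simulate_elisa_panel <- function(profiles, allergens = NULL,
                                 sensitivity = 0.85, specificity = 0.97,
                                 noise_sd = 0.15, seed = 1L) {
  tab <- profiles
  if (!is.null(allergens)) tab <- dplyr::filter(tab, .data$name %in% allergens)
  withr::with_seed(seed, {
    n <- nrow(tab)
    sens <- tab$effect > 0
    value <- numeric(n)
    if (noise_sd == 0) {
      value[sens] <- 0.35 + 0.2 * tab$effect[sens]
      value[!sens] <- 0
    } else {
      u <- stats::runif(n)
      hit <- ifelse(sens, u < sensitivity, u < (1 - specificity))
      # positive tail: exponential above the cutoff, scaled by effect size
      pos_scale <- 0.3 + 0.2 * tab$effect
      value[hit] <- 0.35 + stats::rexp(sum(hit), rate = 1 / pos_scale[hit])
      neg <- !hit
      value[neg] <- pmin(abs(stats::rnorm(sum(neg), 0, noise_sd)), 0.35)
    }
    tab |>
      dplyr::transmute(serum_id = .data$serum_id, name = .data$name,
                       kU_L = value, sensitized = sens)
  })
}
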