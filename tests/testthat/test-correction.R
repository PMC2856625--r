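test_that("preprocess discards flagged spots and log2-transforms with floor", {
  spots <- tibble::tibble(
    block = 1L, column = 1:10, row = 1L,
    name = paste0("a", 1:10), replicate_index = 1L,
    red_median = c(1024, rep(8, 8), 0), green_median = c(256, rep(4, 9)),
    flag = c(0L, rep(0L, 6), rep(-100L, 3)),
    slide_id = "S", array_position = 1L, serum_id = NA_character_,
    day = 1L, dilution = NA_real_
  )
  pp <- preprocess(spots)
  expect_equal(nrow(pp), 7)
  expect_equal(pp$log2_red[1], 10)
  expect_equal(pp$log2_green[1], 8)

  zero <- preprocess(dplyr::mutate(spots[1, ], red_median = 0))
  expect_equal(zero$log2_red, 0)

  expect_warning(preprocess(dplyr::mutate(spots, flag = -50L)),
                 "all spots flagged")
})

test_that("autofluorescence fits recover exact and simulated models", {
  lay <- tiny_layout(2)
  # exact line log2R = 1 * log2G + 0
  exact <- tibble::tibble(
    block = 1L, column = 1:6, row = 1L,
    name = rep(c("alg01", "alg02"), each = 3), replicate_index = rep(1:3, 2),
    green_median = 2^c(5, 7, 9, 4, 6, 8), red_median = 2^c(5, 7, 9, 4, 6, 8),
    flag = 0L, slide_id = "S", array_position = 1L,
    serum_id = NA_character_, day = 1L, dilution = NA_real_
  )
  cal <- suppressWarnings(fit_autofluorescence(preprocess(exact), lay))
  expect_equal(cal$m, c(1, 1), tolerance = 1e-12)
  expect_equal(cal$b, c(0, 0), tolerance = 1e-12)
  expect_equal(cal$sigma, c(0, 0), tolerance = 1e-7)

  # too few spots -> uncalibratable
  two <- exact[c(1, 2, 4, 5, 6), ]
  cal2 <- suppressWarnings(fit_autofluorescence(preprocess(two), lay))
  expect_false(cal2$calibrated[cal2$name == "alg01"])
  expect_match(cal2$note[cal2$name == "alg01"], "too few")

  # degenerate green -> intercept-only fallback with warning
  flat <- dplyr::mutate(exact, green_median = 16)
  expect_warning(cal3 <- fit_autofluorescence(preprocess(flat), lay),
                 "zero green variance")
  expect_equal(cal3$m[1], 0)
  expect_equal(cal3$b[1], mean(log2(c(2^5, 2^7, 2^9))))

  # simulated recovery within 3 SE of the generating values
  cfg <- tiny_config(seed = 303)
  mocks <- purrr::map_dfr(1:70, ~ simulate_mock_array(
    cfg, slide_id = sprintf("S%02d", (.x - 1) %/% 12 + 1),
    array_position = (.x - 1) %% 12 + 1, seed = 900 + .x))
  cal4 <- fit_autofluorescence(preprocess(mocks), cfg$layout)
  truth <- dplyr::inner_join(tibble::as_tibble(cal4), cfg$af_params,
                             by = "name", suffix = c("_hat", "_true"))
  se_m <- truth$sigma / (sqrt(truth$n_fit - 1) * truth$sigma_g)  # approx
  expect_true(all(abs(truth$m_hat - truth$m_true) < 4 * se_m))
})

test_that("correction is the residual from the fitted line", {
  lay <- tiny_layout(2)
  cfg <- tiny_config(seed = 8)
  mocks <- purrr::map_dfr(1:10, ~ simulate_mock_array(cfg, seed = 40 + .x,
                                                      array_position = .x))
  pp <- preprocess(mocks)
  cal <- fit_autofluorescence(pp, cfg$layout)
  corr <- correct_autofluorescence(pp, cal)

  # spot exactly on the line -> 0; line + 2 -> 2
  co <- dplyr::filter(cal, name == "alg01")
  on_line <- tibble::tibble(
    name = "alg01", log2_green = 8, log2_red = co$m * 8 + co$b
  )
  expect_equal(correct_autofluorescence(on_line, cal)$corrected, 0)
  shifted <- dplyr::mutate(on_line, log2_red = log2_red + 2)
  expect_equal(correct_autofluorescence(shifted, cal)$corrected, 2)

  # mean corrected value per allergen on the fitting mocks is exactly 0 (OLS)
  means <- corr |>
    dplyr::semi_join(cfg$layout$allergens, by = "name") |>
    dplyr::group_by(name) |>
    dplyr::summarise(m = mean(corrected))
  expect_true(all(abs(means$m) < 1e-10))
})

test_that("threshold quantiles follow the configurable conventions", {
  vals <- tibble::tibble(name = "a", corrected = as.numeric(1:100))
  cal <- fit_autofluorescence(
    preprocess(simulate_mock_array(tiny_config())), tiny_layout())
  expect_equal(interp_quantile(1:100, 0.99, type = 7), 99.01)
  expect_equal(interp_quantile(1:100, 0.99, type = 6), 99.99)

  cal7 <- calibrate_thresholds(cal, vals, p = 0.99, type = 7)
  expect_equal(cal7$tau[cal7$name == "a"], numeric(0))  # not a layout allergen

  vals2 <- tibble::tibble(name = "alg01", corrected = as.numeric(1:100))
  cal7 <- calibrate_thresholds(cal, vals2, p = 0.99, type = 7)
  expect_equal(cal7$tau[cal7$name == "alg01"], 99.01)
  cal6 <- calibrate_thresholds(cal, vals2, p = 0.99, type = 6)
  expect_equal(cal6$tau[cal6$name == "alg01"], 99.99)

  # constant corrected values -> threshold at that constant
  const <- tibble::tibble(name = "alg01", corrected = rep(0, 50))
  calc <- calibrate_thresholds(cal, const)
  expect_equal(calc$tau[calc$name == "alg01"], 0)
  # other allergens have no corrected mock values -> uncalibratable
  expect_false(any(calc$calibrated[calc$name != "alg01"]))
})

test_that("thresholding uses a strict positivity rule and propagates NA", {
  cfg <- tiny_config()
  mocks <- purrr::map_dfr(1:8, ~ simulate_mock_array(cfg, seed = 60 + .x,
                                                     array_position = .x))
  cal <- calibrate(mocks, cfg$layout)
  tau1 <- cal$tau[cal$name == "alg01"]
  probe <- tibble::tibble(
    name = "alg01",
    corrected = c(tau1, tau1 + 1.5, NA_real_)
  )
  th <- apply_thresholds(probe, cal)
  expect_equal(th$thresholded, c(0, 1.5, NA_real_))
  expect_identical(th$positive, c(FALSE, TRUE, FALSE))
})

test_that("replicate aggregation applies the biweight and missingness rules", {
  expect_equal(aggregate_replicates(c(2, 2, 2)), 2)
  expect_equal(aggregate_replicates(c(2, 2, 2), method = "trimean"), 2)
  expect_equal(aggregate_replicates(c(2, 2, 2), method = "median"), 2)

  # hand computation: M = 2, MAD = 1, weights (0.9216, 1, 0)
  expect_equal(tukey_biweight(c(1, 2, 10), c = 5), 2.9216 / 1.9216,
               tolerance = 1e-10)
  expect_equal(aggregate_replicates(c(1, 2, 10)), 2.9216 / 1.9216,
               tolerance = 1e-10)

  # >50% missing -> missing; exactly half missing survives
  expect_true(is.na(aggregate_replicates(c(5, NA, NA))))
  expect_equal(aggregate_replicates(c(5, 7, NA, NA), expected_n = 4), 6)
  # zero MAD falls back to the median
  expect_equal(tukey_biweight(c(3, 3, 9)), 3)
})

test_that("the IgE matrix has the right shape and recovers planted effects", {
  fix <- default_study()
  cfg <- fix$config; st <- fix$study
  cal <- calibrate(dplyr::filter(st$arrays, is.na(serum_id)), cfg$layout)
  th <- apply_thresholds(
    correct_autofluorescence(
      preprocess(dplyr::filter(st$arrays, !is.na(serum_id))), cal), cal)
  mat <- build_ige_matrix(th, cfg$layout, cal, collapse = "serum")
  expect_equal(dplyr::n_distinct(mat$serum_id), 6)
  expect_equal(dplyr::n_distinct(mat$name), sum(cal$calibrated))
  wide <- ige_matrix_wide(mat)
  expect_equal(dim(wide), c(6, 1 + sum(cal$calibrated)))

  truth <- st$truth$profiles
  joined <- dplyr::inner_join(tibble::as_tibble(mat), truth,
                              by = c("serum_id", "name")) |>
    dplyr::filter(!is.na(value))
  # planted effect sizes are recovered in rank among sensitized cells
  sens <- dplyr::filter(joined, effect > 0)
  expect_gt(cor(sens$value, sens$effect, method = "spearman"), 0.9)
  # and sensitized cells separate cleanly from null cells (AUC)
  null_vals <- joined$value[joined$effect == 0]
  auc <- mean(outer(sens$value, null_vals, ">"))
  expect_gt(auc, 0.95)
})

test_that("calibration is invariant to spot and array order", {
  cfg <- tiny_config(seed = 12)
  mocks <- purrr::map_dfr(1:6, ~ simulate_mock_array(cfg, seed = 70 + .x,
                                                     array_position = .x))
  cal1 <- calibrate(mocks, cfg$layout)
  shuffled <- mocks[withr::with_seed(5, sample(nrow(mocks))), ]
  cal2 <- calibrate(shuffled, cfg$layout)
  expect_equal(cal1$m, cal2$m)
  expect_equal(cal1$tau, cal2$tau)
})

test_that("estimates tighten as the mock-spot count grows", {
  cfg <- tiny_config(seed = 404)
  err <- vapply(c(6, 24, 96), function(k) {
    mocks <- purrr::map_dfr(seq_len(k), ~ simulate_mock_array(
      cfg, seed = 1000 + .x, array_position = (.x - 1) %% 12 + 1,
      slide_id = sprintf("S%02d", (.x - 1) %/% 12 + 1)))
    cal <- calibrate(mocks, cfg$layout)
    truth <- dplyr::inner_join(tibble::as_tibble(cal), cfg$af_params,
                               by = "name", suffix = c("_hat", "_true"))
    mean(abs(truth$m_hat - truth$m_true))
  }, 1)
  expect_lt(err[3], err[1])
})

test_that("IgE standard-curve QC passes monotone curves and fails shuffles", {
  cfg <- tiny_config(flag_rate = 0)
  pp <- preprocess(simulate_mock_array(cfg, seed = 31))
  qc <- qc_standard_curve(pp, cfg$layout)
  expect_true(qc$pass)

  # break monotonicity by shuffling red signal across IgE standard levels
  std_names <- unique(grep("^IgE std", pp$name, value = TRUE))
  shuffled <- pp
  idx <- shuffled$name %in% std_names
  shuffled$log2_red[idx] <- withr::with_seed(
    2, sample(shuffled$log2_red[idx]))
  qc2 <- qc_standard_curve(shuffled, cfg$layout)
  expect_false(qc2$pass)

  # IgG/IgA flat is irrelevant: only the IgE curve is scored
  flat_other <- pp
  other <- grepl("^(IgG|IgA) std", flat_other$name)
  flat_other$log2_red[other] <- 5
  expect_true(qc_standard_curve(flat_other, cfg$layout)$pass)

  no_std <- dplyr::filter(pp, !grepl(" std ", name))
  expect_warning(out <- qc_standard_curve(no_std, cfg$layout), "skipped")
  expect_equal(nrow(out), 0)
})
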