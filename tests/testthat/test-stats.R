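make_cv_input <- function(values_by_array, name = "alg01",
                          serum = "serum01") {
  # one serum, one allergen: 6 arrays on each of 3 slides, one slide per day
  tibble::tibble(
    serum_id = serum, name = name,
    value = values_by_array,
    slide_id = rep(c("S1", "S2", "S3"), each = 6),
    day = rep(1:3, each = 6),
    array_id = sprintf("a%02d", seq_along(values_by_array))
  )
}

test_that("CV uses sd/mean, the mean floor, and is scale invariant", {
  lay <- tiny_layout(1)
  m <- make_cv_input(rep(c(1, 2, 3), 6))
  rep123 <- cv_report(m, lay, levels = "intra_slide")
  # intra-slide cells are (1,2,3,1,2,3): mean 2, sample sd = sqrt(0.8)
  expect_equal(rep123$median_cv[rep123$class == "surface"],
               sd(c(1, 2, 3, 1, 2, 3)) / 2)

  ident <- cv_report(make_cv_input(rep(3, 18)), lay, levels = "intra_slide")
  expect_equal(ident$median_cv[ident$class == "surface"], 0)

  # replicate mean at or below 0.5 is excluded
  low <- cv_report(make_cv_input(rep(c(0.1, 0.2), 9)), lay,
                   levels = "intra_slide")
  expect_equal(low$n_cells[low$class == "surface"], 0)
  expect_true(is.na(low$median_cv[low$class == "surface"]))

  # scale invariance (for means above the floor)
  base <- cv_report(make_cv_input(rep(c(2, 3, 4), 6)), lay)
  scaled <- cv_report(make_cv_input(7 * rep(c(2, 3, 4), 6)), lay)
  expect_equal(base$median_cv, scaled$median_cv)
})

test_that("variance shares are SS / total and sum to 100", {
  vs <- variance_share(c(a = 2, b = 3, error = 5))
  expect_equal(vs$pct_ss_total, c(20, 30, 50))
  expect_equal(sum(vs$pct_ss_total), 100)
})

test_that("sequential ANOVA matches closed-form balanced sums of squares", {
  # two groups, means 0 and 1, n = 4 each: between SS = n * sum((mean-grand)^2)
  d <- tibble::tibble(
    value = c(0, 0, 0, 0, 1, 1, 1, 1) +
      c(-.3, -.1, .1, .3, -.3, -.1, .1, .3),
    g = rep(c("A", "B"), each = 4)
  )
  out <- anova_components(d, response = "value", factors = "g")
  expect_equal(out$ss[out$term == "g"], 2.0)
  expect_equal(out$df[out$term == "g"], 1)

  # constant response: all SS zero
  const <- tibble::tibble(value = rep(1, 8), g = rep(c("A", "B"), 4))
  out0 <- suppressWarnings(
    anova_components(const, response = "value", factors = "g"))
  expect_equal(out0$ss, c(0, 0))

  # row-order invariance and the sum-to-100 invariant
  fix <- default_study()
  st <- fix$study
  res <- suppressMessages(run_pipeline(
    run_config(out_dir = withr::local_tempdir(), cluster_B = 10,
               cluster_scales = NULL), study = st))
  an1 <- res$anova
  expect_equal(sum(an1$pct_ss_total), 100, tolerance = 1e-9)
  perm <- res$matrix[withr::with_seed(3, sample(nrow(res$matrix))), ]
  an2 <- anova_components(perm)
  expect_equal(an1$ss, an2$ss)

  # single-level factors are dropped with a warning
  one <- tibble::tibble(value = rnorm(6), g = rep(c("A", "B"), 3), h = "x")
  expect_warning(anova_components(one, factors = c("h", "g")), "single level")
})

test_that("replicate regression returns slope and R^2 with guard rails", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(suppressWarnings(replicate_regression(x, x)),
               tibble::tibble(slope = 1, r_squared = 1, n = 5L))
  half <- suppressWarnings(replicate_regression(x, 0.5 * x))
  expect_equal(half$slope, 0.5)
  expect_equal(half$r_squared, 1)

  expect_error(replicate_regression(c(1, 2), c(1, 2)), ">= 3")
  expect_warning(out <- replicate_regression(rep(1, 5), x), "zero variance")
  expect_equal(nrow(out), 0)

  # independent noise: R^2 behaves like the permutation null
  withr::with_seed(11, {
    xn <- rnorm(80); yn <- rnorm(80)
    obs <- replicate_regression(xn, yn)$r_squared
    perm <- replicate(200, replicate_regression(xn, sample(yn))$r_squared)
    expect_lt(obs, quantile(perm, 0.999))
    expect_lt(median(perm), 0.1)
  })
})

test_that("matched-pairs tests agree with the closed-form t oracle", {
  # per-serum fraction difference (1, 2, 3, 4)
  wide <- tibble::tibble(
    serum_id = paste0("s", 1:4),
    cytA = c(2, 3, 4, 5), comA = c(1, 1, 1, 1)
  )
  out <- paired_fraction_test(wide, "cytA", "comA")
  d <- c(1, 2, 3, 4)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(out$t, t_oracle)
  expect_equal(out$df, 3)
  expect_equal(out$p_value, 2 * pt(-abs(t_oracle), df = 3))
  expect_equal(out$estimate, 2.5)

  expect_error(paired_fraction_test(wide, "cytA", "cytA"), "zero variance")
  expect_error(paired_fraction_test(wide[1, ], "cytA", "comA"), ">= 2")
})

test_that("ELISA calls use the strict 0.35 kU/L rule", {
  expect_identical(elisa_calls(c(0.36, 0.35, 0, 10)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_error(elisa_calls(c(-0.1, 2)), ">= 0")
})

test_that("concordance tables cross-tabulate calls with proportions", {
  # perfect agreement: no off-diagonal counts
  ct <- concordance_table(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  counts <- tidy(ct)
  off <- counts$n[counts$array_call != counts$elisa_call]
  expect_equal(off, c(0, 0))
  expect_equal(ct$elisa_positive_capture, 1)

  # one of each combination
  ct2 <- concordance_table(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tidy(ct2)$proportion, rep(0.25, 4))
  expect_equal(glance(ct2)$agreement, 0.5)

  expect_error(concordance_table(TRUE, c(TRUE, FALSE)), "equal length")
  expect_error(concordance_table(NA, TRUE), "no complete")
})

test_that("replicate concordance summarizes all within-serum array pairs", {
  fix <- default_study()
  st <- fix$study; cfg <- fix$config
  cal <- calibrate(dplyr::filter(st$arrays, is.na(serum_id)), cfg$layout)
  th <- apply_thresholds(
    correct_autofluorescence(
      preprocess(dplyr::filter(st$arrays, !is.na(serum_id))), cal), cal)
  mat <- build_ige_matrix(th, cfg$layout, cal)
  conc <- replicate_concordance(mat)
  # 6 sera x choose(18, 2) pairs
  expect_equal(nrow(conc), 6 * choose(18, 2))
  g <- glance(conc)
  expect_gt(g$median_r_squared, 0.5)
  expect_true(all(conc$r_squared >= 0 & conc$r_squared <= 1))
})
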