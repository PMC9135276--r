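make_mtt_table <- function(rows) {
  tibble::tibble(
    well = paste0("W", seq_len(nrow(rows))),
    condition = rows$condition, dose_M = rows$dose_M,
    replicate = rows$replicate, a560 = rows$a560, a690 = rows$a690
  )
}

test_that("MTT normalization reproduces hand-computed viabilities", {
  rows <- tibble::tibble(
    condition = c("A", "A", "blank"),
    dose_M = c(0, 1e-8, 0), replicate = 1,
    a560 = c(1.2, 1.2, 0.2), a690 = c(0.2, 0.2, 0.2)
  )
  out <- normalize_mtt(make_mtt_table(rows))
  expect_equal(out$viability[out$dose_M == 1e-8], 1.0)

  rows2 <- tibble::tibble(
    condition = c("A", "A", "blank"),
    dose_M = c(0, 1e-8, 0), replicate = 1,
    a560 = c(1.0, 0.7, 0.3), a690 = c(0.1, 0.2, 0.2)
  )
  # net treated = 0.5 - 0.1 (blank) = 0.4; untreated net = 0.9 - 0.1 = 0.8
  out2 <- normalize_mtt(make_mtt_table(rows2))
  expect_equal(out2$viability[out2$dose_M == 1e-8], 0.5)
})

test_that("MTT normalization rejects non-positive untreated signal", {
  rows <- tibble::tibble(
    condition = "A", dose_M = c(0, 1e-8), replicate = 1,
    a560 = c(0.2, 0.5), a690 = c(0.2, 0.1)
  )
  expect_error(normalize_mtt(make_mtt_table(rows)), "untreated net")
  expect_error(normalize_mtt(tibble::tibble(well = "a")), "missing required")
})

test_that("noiseless dose-response data is recovered to high precision", {
  tabs <- gen_protection_tables(independent_protection_spec())
  fit <- fit_dose_response(dplyr::rename(tabs$mono, viability = value))
  g <- glance(fit)
  expect_equal(g$ic50_mean[g$condition == "sensitive"], 1e-8, tolerance = 1e-6)
  expect_equal(g$ic50_mean[g$condition == "resistant"], 3e-6, tolerance = 1e-6)
  expect_true(all(tidy(fit)$converged))
  expect_false(any(tidy(fit)$extrapolated))
})

test_that("flat responses are flagged non-convergent without an IC50", {
  flat <- tidyr::expand_grid(
    condition = "A", dose_M = 10^seq(-9, -5, length.out = 6), replicate = 1:2
  ) |>
    dplyr::mutate(viability = 1.0)
  expect_warning(fit <- fit_dose_response(flat), "did not converge")
  expect_true(all(!tidy(fit)$converged))
  expect_true(all(is.na(tidy(fit)$ic50)))
})

test_that("noisy IC50 recovery stays within 10%", {
  # 11-point 3-fold dilution series around the IC50, sigma = 0.05, with the
  # six technical replicates averaged before fitting (the assay design);
  # averaged over five simulated experiments to keep the check stable
  est <- vapply(41:45, function(s) {
    tabs <- gen_protection_tables(protection_spec(
      ic50_sensitive = 1e-8, ic50_resistant = 3e-6,
      concentrations = 1e-8 * 3^seq(-5, 5),
      replicate_noise_sd = 0.05, n_replicates = 6, seed = s
    ))
    ds <- tabs$mono |>
      dplyr::filter(condition == "sensitive") |>
      dplyr::group_by(condition, dose_M) |>
      dplyr::summarise(viability = mean(value), .groups = "drop") |>
      dplyr::mutate(replicate = 1)
    glance(fit_dose_response(ds))$ic50_mean
  }, numeric(1))
  expect_lt(abs(mean(est) - 1e-8) / 1e-8, 0.1)
})

test_that("dose-response fitting is invariant to dose-unit rescaling", {
  tabs <- gen_protection_tables(independent_protection_spec(noise = 0.02,
                                                            seed = 5))
  ds <- dplyr::rename(tabs$mono, viability = value)
  fit_M <- fit_dose_response(ds)
  fit_uM <- fit_dose_response(dplyr::mutate(ds, dose_M = dose_M * 1e6))
  expect_equal(glance(fit_uM)$ic50_mean, glance(fit_M)$ic50_mean * 1e6,
               tolerance = 1e-6)
})

test_that("fold-resistance reproduces the reported subclone and spheroid ratios", {
  expect_equal(fold_resistance(3000e-9, 10e-9), 300)
  expect_equal(fold_resistance(140e-9, 10e-9), 14)
  expect_equal(fold_resistance(11e-6, 10e-9), 1100)
  expect_equal(fold_resistance(5e-8, 5e-8), 1)
  expect_equal(fold_resistance(2e-8, 8e-9) * fold_resistance(8e-9, 2e-8), 1)
  expect_error(fold_resistance(-1, 1), "positive")
})

test_that("cytotoxicity normalization divides area by viability against controls", {
  df <- tibble::tibble(
    condition = "A", dose_M = c(0, 1e-7), replicate = 1,
    red_area = c(100, 400), viability = c(1, 0.5)
  )
  out <- normalize_cytotox(df)
  expect_equal(out$relative_death[out$dose_M == 0], 1)
  expect_equal(out$relative_death[out$dose_M == 1e-7], 8)
  # zero-viability wells are excluded with a warning
  df_bad <- dplyr::add_row(df, condition = "A", dose_M = 1e-6, replicate = 1,
                           red_area = 500, viability = 0)
  expect_warning(out2 <- normalize_cytotox(df_bad), "viability <= 0")
  expect_false(1e-6 %in% out2$dose_M)
})

test_that("logistic growth fitting inverts the generator analytically", {
  fit <- fit_logistic_growth(gen_growth_curve(K = 95, r = log(2) / 23, t0 = 90))
  expect_true(fit$converged)
  expect_lt(abs(fit$doubling_time_h - 23) / 23, 0.001)
})

test_that("degenerate confluency series are flagged, noisy series recovered", {
  flat <- tibble::tibble(time_h = seq(0, 180, by = 4), confluency = 50)
  expect_warning(f <- fit_logistic_growth(flat), "non-convergent")
  expect_false(f$converged)
  expect_true(is.na(f$doubling_time_h))

  decreasing <- tibble::tibble(time_h = seq(0, 180, by = 4),
                               confluency = seq(90, 20, length.out = 46))
  expect_warning(f2 <- fit_logistic_growth(decreasing), "non-convergent")
  expect_false(f2$converged)

  noisy <- gen_growth_curve(K = 90, r = log(2) / 32, t0 = 90,
                            times = seq(0, 176, by = 4), noise_sd = 1, seed = 11)
  f3 <- fit_logistic_growth(noisy)
  expect_lt(abs(f3$doubling_time_h - 32) / 32, 0.05)
})

test_that("IC50 and doubling-time recovery is essentially unbiased over many seeds", {
  ic50_hat <- vapply(1:100, function(s) {
    tabs <- gen_protection_tables(protection_spec(
      ic50_sensitive = 1e-8, ic50_resistant = 3e-6,
      concentrations = 10^seq(-10, -4, length.out = 11),
      replicate_noise_sd = 0.05, n_replicates = 1, seed = s
    ))
    ds <- dplyr::rename(tabs$mono, viability = value) |>
      dplyr::filter(condition == "sensitive")
    glance(fit_dose_response(ds))$ic50_mean
  }, numeric(1))
  # geometric mean: the model is fit on log(IC50), so per-fit errors are
  # symmetric on the log scale
  expect_lt(abs(exp(mean(log(ic50_hat))) - 1e-8) / 1e-8, 0.02)

  td_hat <- vapply(1:100, function(s) {
    fit_logistic_growth(gen_growth_curve(K = 90, r = log(2) / 23, t0 = 90,
                                         noise_sd = 1, seed = s))$doubling_time_h
  }, numeric(1))
  expect_lt(abs(mean(td_hat) - 23) / 23, 0.02)
})
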