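test_that("spheroid generation is bit-identical for the same spec and seed", {
  spec <- spheroid_spec(image_size_px = c(192L, 192L), spheroid_radius_px = 70,
                        n_cells = 500, seed = 7)
  a <- gen_spheroid_image(spec)
  b <- gen_spheroid_image(spec)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$cell_centers, b$truth$cell_centers)
})

test_that("labeled fraction and well-mixed placement match the sampling model", {
  spec <- spheroid_spec(sorting_strength = 0, labeled_fraction = 0.25, seed = 7)
  gen <- gen_spheroid_image(spec)
  centers <- gen$truth$cell_centers
  frac <- mean(centers$population == "labeled")
  se <- sqrt(0.25 * 0.75 / spec$n_cells)
  expect_lt(abs(frac - 0.25), 3 * se)
  expect_equal(gen$truth$true_edge_center_ratio, 1)
})

test_that("strong sorting pushes labeled cells into the shell band", {
  gen <- gen_spheroid_image(spheroid_spec(
    sorting_strength = 5, shell_band = c(0.7, 1.0), seed = 3
  ))
  lab <- dplyr::filter(gen$truth$cell_centers, population == "labeled")
  expect_gte(mean(lab$r_norm > 0.7), 0.9)
})

test_that("well-mixed labeled radii are consistent with the uniform disk over many seeds", {
  # chi-squared test of labeled-cell counts in equal-area radial bins against
  # the uniform-disk expectation; at alpha = 0.001 essentially no seed
  # should reject.
  bins <- sqrt(seq(0, 1, length.out = 11))  # equal-area bins in r_norm
  rejections <- sum(vapply(1:50, function(s) {
    gen <- gen_spheroid_image(spheroid_spec(
      image_size_px = c(192L, 192L), spheroid_radius_px = 70,
      n_cells = 800, sorting_strength = 0, noise_sd = 0, seed = s
    ))
    lab <- dplyr::filter(gen$truth$cell_centers, population == "labeled")
    counts <- tabulate(findInterval(lab$r_norm, bins, rightmost.closed = TRUE),
                       nbins = 10)
    suppressWarnings(stats::chisq.test(counts, p = rep(0.1, 10))$p.value) < 0.001
  }, logical(1)))
  expect_lte(rejections, 1)
})

test_that("a spheroid that does not fit the image is rejected", {
  expect_error(spheroid_spec(image_size_px = c(128L, 128L), spheroid_radius_px = 60),
               "does not fit")
  expect_error(spheroid_spec(shell_band = c(0.9, 0.5)), "increasing interval")
})

test_that("protection tables follow the closed-form mixture construction", {
  spec <- independent_protection_spec()
  tabs <- gen_protection_tables(spec)
  truth <- tabs$truth
  # independent mode, no noise: observed co-culture equals the weighted
  # mixture exactly at every dose
  expect_equal(truth$observed_true, truth$expected_true)
  co <- tabs$co |> dplyr::distinct(dose_M, value)
  expect_equal(co$value,
               (3 * truth$v_sensitive + truth$v_resistant) / 4)

  # attenuation_factor = 1 in shielding mode reduces to independent mode
  shield1 <- protection_spec(
    ic50_sensitive = 1e-8, ic50_resistant = 3e-6,
    concentrations = spec$concentrations,
    mode = "shell_shielding_spheroid", attenuation_factor = 1
  )
  expect_equal(gen_protection_tables(shield1)$co$value, tabs$co$value)
})

test_that("shielding raises observed viability above the expected mixture", {
  spec <- protection_spec(
    ic50_sensitive = 1e-8, ic50_resistant = 3e-6,
    concentrations = c(1e-9, 1e-7), mode = "shell_shielding_spheroid",
    attenuation_factor = 10
  )
  truth <- gen_protection_tables(spec)$truth
  # closed forms at dose = 10 x sensitive IC50
  d <- 1e-7
  obs <- (3 / (1 + (d / 10) / 1e-8) + 1 / (1 + d / 3e-6)) / 4
  exp_v <- (3 / (1 + d / 1e-8) + 1 / (1 + d / 3e-6)) / 4
  i <- which(truth$dose_M == d)
  expect_equal(truth$observed_true[i], obs)
  expect_equal(truth$expected_true[i], exp_v)
  expect_gt(truth$observed_true[i], truth$expected_true[i])
  expect_true(all(truth$observed_true >= truth$expected_true))
})

test_that("invalid protection concentrations are rejected", {
  expect_error(protection_spec(1e-8, 3e-6, concentrations = c(0, 1e-8)),
               "strictly positive")
  expect_error(protection_spec(1e-8, 3e-6, concentrations = c(1e-6, 1e-8)),
               "increasing")
})

test_that("growth curves obey the logistic midpoint and asymptote", {
  curve <- gen_growth_curve(K = 80, r = 0.05, t0 = 60, times = c(60, 2000))
  expect_equal(curve$confluency[1], 40)
  expect_equal(curve$confluency[2], 80, tolerance = 1e-8)
  expect_error(gen_growth_curve(K = 80, r = -0.1, t0 = 60), "positive")
})

test_that("monolayer marker is uniform within cells when enrichment is 0", {
  gen <- gen_monolayer_image(30, enrichment = 0, seed = 2, noise_sd = 0,
                             image_size_px = c(256L, 256L))
  marker <- get_channel(gen$image, "marker")
  inside <- gen$truth$cells > 0
  expect_equal(stats::sd(marker[inside]), 0)
  # seeded reproducibility
  gen2 <- gen_monolayer_image(30, enrichment = 0, seed = 2, noise_sd = 0,
                              image_size_px = c(256L, 256L))
  expect_identical(gen$image$channels, gen2$image$channels)
})

test_that("monolayer band elevation matches a pixel-summation oracle", {
  gen <- gen_monolayer_image(30, enrichment = 5, seed = 2, noise_sd = 0,
                             image_size_px = c(256L, 256L))
  marker <- get_channel(gen$image, "marker")
  band <- gen$truth$band
  cyto <- gen$truth$cells > 0 & !band
  ratio <- mean(marker[band]) / mean(marker[cyto])
  expect_gt(ratio, 2)
  # band and cytoplasm both sit on the constant background level
  expect_equal(ratio, (2 + 50 * gen$truth$intended_band_ratio) / (2 + 50),
               tolerance = 1e-8)
})

test_that("overly dense monolayers are rejected", {
  expect_error(
    gen_monolayer_image(500, enrichment = 0, image_size_px = c(128L, 128L)),
    "too dense|too small"
  )
})

test_that("migration truth encodes the requested sheet geometry", {
  gen <- gen_migration_image(200, c(300, 280, 260), seed = 1)
  expect_equal(mean(gen$truth$sheets$end_distance_px) / 200, 1.4)
  expect_error(gen_migration_image(200, c(90, 300)), "exceed the spheroid radius")
  bare <- gen_migration_image(200, numeric(0), seed = 1)
  expect_equal(nrow(bare$truth$sheets), 0)
  # coincident end distances stay distinct components (distinct angles)
  same <- gen_migration_image(200, c(260, 260, 260), seed = 1)
  expect_equal(nrow(dplyr::distinct(same$truth$sheets, angle_rad)), 3)
})

test_that("Ct tables are constructed so the delta-Ct chain recovers the truth", {
  ct <- gen_ct_table(c(ref = 2, amp = 8), "ref", replicate_sd = 0, seed = 1)
  wide <- ct |>
    dplyr::group_by(sample, gene) |>
    dplyr::summarise(ct = mean(ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = gene, values_from = ct)
  dct <- wide$RRM1 - wide$RNaseP
  expect_equal(dct[wide$sample == "amp"] - dct[wide$sample == "ref"], -2)
  expect_error(gen_ct_table(c(a = -1), "a"), "strictly positive")
  expect_identical(gen_ct_table(c(a = 2, b = 4), "a", seed = 3),
                   gen_ct_table(c(a = 2, b = 4), "a", seed = 3))
})
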