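test_that("spheroid detection recovers a clean disk and picks the largest object", {
  disk <- uniform_disk(100, size = 256, level = 10, background = 0.01)
  img <- multichannel_image(list(brightfield = disk$mat))
  mask <- detect_spheroid_mask(img)
  expect_lt(abs(mask$area_px - pi * 100^2) / (pi * 100^2), 0.02)
  expect_equal(unname(mask$centroid), unname(disk$center), tolerance = 0.01)

  expect_error(
    detect_spheroid_mask(multichannel_image(list(brightfield = matrix(0, 64, 64)))),
    "No spheroid detected"
  )

  two <- matrix(0.01, 200, 200)
  g <- expand.grid(y = 1:200, x = 1:200)
  two[(g$x - 60)^2 + (g$y - 60)^2 <= 40^2] <- 10   # area ~5000 px^2 scale
  two[(g$x - 160)^2 + (g$y - 160)^2 <= 16^2] <- 10 # smaller
  img2 <- multichannel_image(list(brightfield = two))
  m2 <- detect_spheroid_mask(img2)
  expect_equal(unname(m2$centroid), c(60, 60), tolerance = 0.05)
})

test_that("radial profiles are exact for uniform images and conserve intensity", {
  flat <- matrix(1, 128, 128)
  prof <- radial_profile(flat, c(64.5, 64.5))
  expect_equal(prof$mean_intensity, rep(1, nrow(prof)))
  # exact conservation: sum(mean x count) equals image sum over covered pixels
  noisy <- matrix(runif(128^2), 128, 128)
  p2 <- radial_profile(noisy, c(64.5, 64.5))
  g <- expand.grid(y = 1:128, x = 1:128)
  covered <- floor(sqrt((g$x - 64.5)^2 + (g$y - 64.5)^2)) + 1 <= max(p2$r_outer)
  expect_equal(sum(p2$mean_intensity * p2$n_px), sum(noisy[covered]))
  expect_error(radial_profile(flat, c(-3, 10)), "inside the image")
})

test_that("radial profiles track a smooth radially symmetric intensity", {
  f <- function(r) exp(-(r / 60)^2)
  img <- radial_image(f, size = 256)
  prof <- radial_profile(img$mat, img$center)
  keep <- prof$r_mid <= 100
  expect_lt(max(abs(prof$mean_intensity[keep] - f(prof$r_mid[keep])) /
                  f(prof$r_mid[keep])), 0.02)

  # single bright pixel at center
  spot <- matrix(0, 65, 65); spot[33, 33] <- 5
  p <- radial_profile(spot, c(33, 33))
  expect_gt(p$mean_intensity[1], 0)
  expect_equal(sum(p$mean_intensity[-1]), 0)
})

test_that("the 95% enclosure radius matches sqrt(0.95) R for uniform disks", {
  for (R in c(50, 80, 100)) {
    disk <- uniform_disk(R, size = 2 * R + 56)
    prof <- radial_profile(disk$mat, disk$center)
    r95 <- radius_enclosing_fraction(prof, 0.95)
    expect_lt(abs(r95 - sqrt(0.95) * R) / (sqrt(0.95) * R), 0.015)
  }
})

test_that("enclosure radius handles concentrated and total-fraction cases", {
  spot <- matrix(0, 65, 65); spot[33, 33] <- 5
  p <- radial_profile(spot, c(33, 33))
  expect_lte(radius_enclosing_fraction(p, 0.95), 1)
  disk <- uniform_disk(20, size = 100)
  p2 <- radial_profile(disk$mat, disk$center)
  expect_equal(radius_enclosing_fraction(p2, 1), max(p2$r_outer[p2$mean_intensity > 0]))
  empty <- radial_profile(matrix(0, 65, 65), c(33, 33))
  expect_error(radius_enclosing_fraction(empty), "zero")
  expect_error(radius_enclosing_fraction(p2, 0), "fraction")
})

test_that("center normalization rescales both axes and guards the center", {
  flat <- matrix(2, 128, 128)
  prof <- radial_profile(flat, c(64.5, 64.5))
  norm <- normalize_profile(prof, spheroid_radius = 50)
  expect_equal(norm$intensity[norm$r_norm <= 1], rep(1, sum(norm$r_norm <= 1)))
  expect_equal(attr(norm, "center_value"), 2)

  # center 2.0, value 6.0 at r = 0.77 x radius -> normalized value 3.0
  R <- 50
  f <- function(r) ifelse(abs(r - 0.77 * R) < 3, 6, 2)
  img <- radial_image(f, size = 160)
  p <- radial_profile(img$mat, img$center)
  n <- normalize_profile(p, R)
  expect_equal(stats::approx(n$r_norm, n$intensity, xout = 0.77)$y, 3,
               tolerance = 0.01)

  hollow <- radial_image(function(r) ifelse(r < 20, 0, 1), size = 128)
  ph <- radial_profile(hollow$mat, hollow$center)
  expect_error(normalize_profile(ph, 80), "normalization undefined")
})

test_that("the sorting statistic summarizes per-spheroid edge values", {
  flat <- matrix(3, 128, 128)
  prof <- normalize_profile(radial_profile(flat, c(64.5, 64.5)), 40)
  stat <- sorting_statistic(rep(list(prof), 20))
  expect_equal(stat$edge_center_ratio, 1)
  expect_equal(stat$sem, 0)
  expect_equal(stat$n, 20)

  single <- sorting_statistic(prof)
  expect_equal(single$n, 1)
  expect_true(is.na(single$sem))

  # profile that stops short of 0.77 is excluded
  short <- normalize_profile(radial_profile(flat, c(64.5, 64.5)), 200)
  expect_warning(st <- sorting_statistic(list(prof, short)), "does not span")
  expect_equal(st$n_excluded, 1)
  expect_error(suppressWarnings(sorting_statistic(list(short))), "No profile spans")
})

test_that("sorting recovery is monotone in the generator sorting strength", {
  strengths <- c(0, 0.6, 1.2, 1.8)
  ratios <- vapply(strengths, function(s) {
    imgs <- lapply(1:6, function(i) {
      gen_spheroid_image(spheroid_spec(sorting_strength = s,
                                       seed = 500 + i))$image
    })
    suppressWarnings(spheroid_sorting_pipeline(imgs))$statistic$edge_center_ratio
  }, numeric(1))
  expect_gt(stats::cor(strengths, ratios, method = "spearman"), 0.9)
  expect_true(all(diff(ratios) > 0))
})

test_that("PI death scoring normalizes integrated intensity to controls", {
  disk <- uniform_disk(40, size = 128, level = 5, background = 0.01)
  img <- multichannel_image(list(brightfield = disk$mat, PI = disk$mat))
  mask <- detect_spheroid_mask(img)
  ctrl <- integrate_pi(img, mask)
  expect_equal(pi_death_score(img, mask, ctrl), 1)

  treated <- multichannel_image(list(brightfield = disk$mat, PI = disk$mat * 4))
  expect_equal(pi_death_score(treated, mask, c(ctrl, ctrl)), 4)
  expect_equal(pi_death_score(treated, mask, c(2e6, 2e6)) * 2e6,
               integrate_pi(treated, mask))

  empty <- mask; empty$mask[] <- FALSE
  expect_error(integrate_pi(img, empty), "Empty spheroid mask")
  expect_error(pi_death_score(img, mask, 0), "not positive")
})
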