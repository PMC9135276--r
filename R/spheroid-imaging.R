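# Spheroid detection, radial intensity profiling, the edge-at-0.77
# cell-sorting statistic, and integrated-PI death scoring.

#' Detect the spheroid mask in a well image
#'
#' Gaussian smoothing, global Otsu threshold, largest connected component,
#' hole filling. The centroid is the intensity-weighted center of the masked
#' region in the original (unsmoothed) channel.
#'
#' @param img A [multichannel_image()].
#' @param channel Channel to segment on (default `"brightfield"`).
#' @param sigma Smoothing sigma in pixels.
#'
#' @return An object of class `spheroid_mask`: list with `mask` (logical
#'   raster, one connected component), `centroid` (`c(x, y)` in pixel
#'   coordinates), `area_px` and `equiv_radius_px` (`sqrt(area / pi)`).
#' @export
detect_spheroid_mask <- function(img, channel = "brightfield", sigma = 2) {
  m <- get_channel(img, channel)
  smoothed <- EBImage::imageData(EBImage::gblur(as_ebimage(m), sigma = sigma))
  th <- tryCatch(otsu_threshold(smoothed), error = function(e) NULL)
  if (is.null(th)) abort("No spheroid detected: image is constant.")
  fg <- smoothed > th
  comp <- largest_component(fg)
  if (is.null(comp) || sum(comp) == 0) abort("No spheroid detected: no foreground after thresholding.")
  comp <- EBImage::imageData(EBImage::fillHull(as_ebimage(comp * 1))) > 0
  grid <- pixel_grid(dim(m))
  wts <- m * comp
  total <- sum(wts)
  centroid <- if (total > 0) {
    c(x = sum(grid$x * wts) / total, y = sum(grid$y * wts) / total)
  } else {
    c(x = mean(grid$x[comp]), y = mean(grid$y[comp]))
  }
  structure(
    list(
      mask = comp,
      centroid = centroid,
      area_px = sum(comp),
      equiv_radius_px = sqrt(sum(comp) / pi)
    ),
    class = "spheroid_mask"
  )
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf(
    "<spheroid_mask> area %d px^2, equivalent radius %.1f px, centroid (%.1f, %.1f)\n",
    x$area_px, x$equiv_radius_px, x$centroid[["x"]], x$centroid[["y"]]
  ))
  invisible(x)
}

#' Estimate image background outside the spheroid
#'
#' Median intensity of pixels farther than `dilation_factor` times the
#' spheroid's equivalent radius from its centroid.
#'
#' @param channel Numeric matrix.
#' @param mask A [detect_spheroid_mask()] result.
#' @param dilation_factor Radius multiplier delimiting the excluded zone.
#' @return Scalar background estimate (0 if no outside pixels remain).
#' @export
estimate_background <- function(channel, mask, dilation_factor = 1.5) {
  stopifnot(inherits(mask, "spheroid_mask"))
  grid <- pixel_grid(dim(channel))
  d2 <- (grid$x - mask$centroid[["x"]])^2 + (grid$y - mask$centroid[["y"]])^2
  outside <- d2 > (dilation_factor * mask$equiv_radius_px)^2
  if (!any(outside)) return(0)
  median(channel[outside])
}

#' Radial intensity profile around a center
#'
#' Mean intensity in concentric 1-px half-open annuli `[r, r+1)` around
#' `center`, out to the nearest image border (annuli are fully contained in
#' the image, so `sum(mean_intensity * n_px)` over the profile equals the
#' image sum over the covered pixels exactly).
#'
#' @param channel Numeric matrix (or a [multichannel_image()] together with
#'   `channel_name`).
#' @param center `c(x, y)` center in pixel coordinates, inside the image.
#' @param channel_name Channel to profile when `channel` is a
#'   multi-channel image.
#' @param background Constant subtracted from the channel before profiling
#'   (see [estimate_background()]). Residuals are deliberately not clipped
#'   at zero, so background noise cancels in annulus means instead of
#'   accumulating with annulus area.
#'
#' @return A tibble of class `radial_profile` with columns `r_inner`,
#'   `r_outer`, `r_mid`, `mean_intensity`, `n_px`, and attributes `center`
#'   and `normalization` (`"raw"`).
#' @export
radial_profile <- function(channel, center, channel_name = NULL, background = 0) {
  if (inherits(channel, "multichannel_image")) {
    channel <- get_channel(channel, channel_name %||% names(channel$channels)[1])
  }
  dim_yx <- dim(channel)
  if (center[[1]] < 1 || center[[1]] > dim_yx[2] ||
      center[[2]] < 1 || center[[2]] > dim_yx[1]) {
    abort("`center` must lie inside the image.")
  }
  if (background != 0) channel <- channel - background
  grid <- pixel_grid(dim_yx)
  d <- sqrt((grid$x - center[[1]])^2 + (grid$y - center[[2]])^2)
  r_max <- floor(min(center[[1]] - 1, dim_yx[2] - center[[1]],
                     center[[2]] - 1, dim_yx[1] - center[[2]]))
  if (r_max < 1) abort("`center` is too close to the image border for any annulus.")
  bin <- floor(d) + 1  # annulus [r, r+1) -> bin r+1
  keep <- bin <= r_max
  sums <- tapply(channel[keep], bin[keep], sum)
  counts <- tapply(rep(1, sum(keep)), bin[keep], sum)
  r_inner <- as.numeric(names(sums)) - 1
  prof <- tibble(
    r_inner = r_inner,
    r_outer = r_inner + 1,
    r_mid = r_inner + 0.5,
    mean_intensity = as.numeric(sums) / as.numeric(counts),
    n_px = as.numeric(counts)
  ) |>
    arrange(.data$r_inner)
  structure(prof, class = c("radial_profile", class(prof)),
            center = c(x = center[[1]], y = center[[2]]),
            normalization = "raw")
}

#' Radius enclosing a given fraction of total intensity
#'
#' Accumulates annulus intensity (annulus mean times annulus pixel count)
#' outward and returns, by linear interpolation within the crossing
#' annulus, the radius at which the cumulative intensity reaches `fraction`
#' of the total. For a uniform disk of radius R this is `sqrt(fraction) R`.
#'
#' @param profile A raw [radial_profile()].
#' @param fraction Fraction of total intensity in `(0, 1]`.
#' @return Radius in pixels.
#' @export
radius_enclosing_fraction <- function(profile, fraction = 0.95) {
  check_number(fraction, "fraction", lower = 0, upper = 1, allow_equal_lower = FALSE)
  intensity <- profile$mean_intensity * profile$n_px
  total <- sum(intensity)
  if (total <= 0) abort("Total integrated intensity is zero; enclosure radius undefined.")
  if (fraction == 1) {
    return(max(profile$r_outer[intensity > 0]))
  }
  cum <- cumsum(intensity)
  target <- fraction * total
  i <- which(cum >= target)[1]
  below <- if (i == 1) 0 else cum[i - 1]
  profile$r_inner[i] + (target - below) / intensity[i] *
    (profile$r_outer[i] - profile$r_inner[i])
}

#' Center-normalize a radial profile
#'
#' Divides the distance axis by `spheroid_radius` and the intensities by the
#' center intensity, estimated as the pixel-weighted mean of the annuli
#' within the innermost `center_fraction` of the spheroid radius (at least
#' the first annulus). The default center region is the innermost 20% of
#' the radius: a single-pixel center is noise-dominated, and for a
#' sparse-label disk even a few-percent region holds too few labeled cells
#' for a stable denominator. The profile is then resampled by linear
#' interpolation onto `n_bins` uniform bins spanning normalized distances
#' `[0, max_norm]`; bins beyond the measured profile are `NA`.
#'
#' @param profile A raw [radial_profile()].
#' @param spheroid_radius Radius used for distance normalization (e.g. the
#'   spheroid-type mean of [radius_enclosing_fraction()] at 0.95).
#' @param center_fraction Fraction of the radius defining the center region
#'   (default 0.2).
#' @param n_bins,max_norm Resampling grid: `n_bins` uniform bins on
#'   `[0, max_norm]`.
#'
#' @return A tibble of class `radial_profile_norm` with columns `r_norm`
#'   (bin centers) and `intensity` (center value 1 at `r_norm = 0`), and
#'   attributes `center_value` and `spheroid_radius`.
#' @export
normalize_profile <- function(profile, spheroid_radius, center_fraction = 0.2,
                              n_bins = 100, max_norm = 1.2) {
  check_number(spheroid_radius, "spheroid_radius", lower = 0, allow_equal_lower = FALSE)
  in_center <- profile$r_mid <= max(center_fraction * spheroid_radius, profile$r_mid[1])
  center_value <- sum(profile$mean_intensity[in_center] * profile$n_px[in_center]) /
    sum(profile$n_px[in_center])
  if (!is.finite(center_value) || center_value <= 0) {
    abort("Center intensity is not positive; normalization undefined.")
  }
  grid <- seq(0, max_norm, length.out = n_bins)
  x <- c(0, profile$r_mid / spheroid_radius)
  y <- c(center_value, profile$mean_intensity) / center_value
  res <- approx(x, y, xout = grid, rule = 1)
  out <- tibble(r_norm = grid, intensity = res$y)
  structure(out, class = c("radial_profile_norm", class(out)),
            center_value = center_value,
            spheroid_radius = spheroid_radius,
            normalization = "center-normalized")
}

#' Edge-at-0.77 cell-sorting statistic across spheroids
#'
#' For each center-normalized profile, reads the intensity at normalized
#' distance `edge_position` (0.77 by default) by linear interpolation; the
#' per-spheroid edge value equals the edge/center intensity ratio because
#' the center is normalized to 1. Profiles that do not span `edge_position`
#' are excluded with a warning. Reports the mean ratio and its SEM across
#' spheroids.
#'
#' @param profiles A list of [normalize_profile()] results (or a single
#'   one).
#' @param edge_position Normalized distance defining the spheroid edge
#'   region.
#'
#' @return An object of class `sorting_statistic`: list with
#'   `edge_center_ratio`, `sem` (`NA` for a single spheroid),
#'   `n`, `n_excluded`, `edge_values`, `edge_position`.
#' @export
sorting_statistic <- function(profiles, edge_position = 0.77) {
  if (inherits(profiles, "radial_profile_norm")) profiles <- list(profiles)
  if (length(profiles) < 1) abort("At least one normalized profile is required.")
  edge_values <- vapply(profiles, function(p) {
    ok <- is.finite(p$intensity)
    if (edge_position > max(p$r_norm[ok])) return(NA_real_)
    approx(p$r_norm[ok], p$intensity[ok], xout = edge_position, rule = 1)$y
  }, numeric(1))
  excluded <- !is.finite(edge_values)
  if (any(excluded)) {
    warn(sprintf(
      "%d spheroid(s) excluded: profile does not span normalized distance %.2f.",
      sum(excluded), edge_position
    ))
  }
  kept <- edge_values[!excluded]
  if (length(kept) == 0) abort("No profile spans the edge position; statistic undefined.")
  structure(
    list(
      edge_center_ratio = mean(kept),
      sem = sem(kept),
      n = length(kept),
      n_excluded = sum(excluded),
      edge_values = kept,
      edge_position = edge_position
    ),
    class = "sorting_statistic"
  )
}

#' @export
print.sorting_statistic <- function(x, ...) {
  cat(sprintf(
    "<sorting_statistic> edge/center ratio at %.2f: %.3f +/- %s (n = %d%s)\n",
    x$edge_position, x$edge_center_ratio,
    if (is.na(x$sem)) "NA" else sprintf("%.3f", x$sem), x$n,
    if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""
  ))
  invisible(x)
}

#' @method tidy sorting_statistic
#' @export
tidy.sorting_statistic <- function(x, ...) {
  tibble(
    edge_position = x$edge_position,
    edge_center_ratio = x$edge_center_ratio,
    sem = x$sem, n = x$n, n_excluded = x$n_excluded
  )
}

#' Full radial cell-sorting analysis of a set of spheroid images
#'
#' Convenience pipeline for one spheroid type: detects each spheroid,
#' subtracts background from the label channel, computes the raw radial
#' profile about the detected centroid and the 95%-enclosure radius, sets
#' the type radius (by default the mean enclosure radius over spheroids,
#' matching a per-type normalization; `radius_scope = "spheroid"` uses each
#' spheroid's own), center-normalizes each profile, and computes the
#' [sorting_statistic()]. The type-level mean profile is formed by
#' averaging the raw profiles on the normalized-distance grid first and
#' then center-normalizing the average (`profile_order = "average_first"`,
#' the default); `"normalize_first"` averages the per-spheroid normalized
#' profiles instead. Under the default order the reported edge/center ratio
#' is read from the averaged-then-normalized profile (robust to sparse
#' label signal in any single spheroid's center), while the per-spheroid
#' edge values provide the SEM and are kept as
#' `statistic$per_spheroid_mean`.
#'
#' @param images List of [multichannel_image()]s of one spheroid type.
#' @param label_channel Channel carrying the tracked population's label.
#' @param detect_channel Channel used for spheroid detection.
#' @param edge_position,enclosure_fraction Statistic and radius parameters.
#' @param radius_scope `"type"` (default) or `"spheroid"`.
#' @param profile_order `"average_first"` (default) or `"normalize_first"`.
#'
#' @return A list of class `sorting_result`: `statistic`
#'   (a [sorting_statistic()]), `mean_profile`, `profiles` (per-spheroid
#'   normalized profiles), `radii` (per-spheroid enclosure radii),
#'   `type_radius`.
#' @export
spheroid_sorting_pipeline <- function(images,
                                      label_channel = "labeled",
                                      detect_channel = "brightfield",
                                      edge_position = 0.77,
                                      enclosure_fraction = 0.95,
                                      radius_scope = c("type", "spheroid"),
                                      profile_order = c("average_first", "normalize_first")) {
  radius_scope <- match.arg(radius_scope)
  profile_order <- match.arg(profile_order)
  raw <- lapply(images, function(img) {
    mask <- detect_spheroid_mask(img, channel = detect_channel)
    ch <- get_channel(img, label_channel)
    bg <- estimate_background(ch, mask)
    radial_profile(ch, center = mask$centroid, background = bg)
  })
  radii <- vapply(raw, radius_enclosing_fraction, numeric(1),
                  fraction = enclosure_fraction)
  type_radius <- mean(radii)
  profiles <- purrr::map2(raw, radii, function(p, r_i) {
    normalize_profile(p, if (radius_scope == "type") type_radius else r_i)
  })
  stat <- sorting_statistic(profiles, edge_position = edge_position)
  stat$per_spheroid_mean <- stat$edge_center_ratio

  grid <- profiles[[1]]$r_norm
  if (profile_order == "average_first") {
    # Pool the raw profiles annulus-by-annulus, then center-normalize the
    # pooled profile with the same center-region rule: pooling before
    # normalizing removes the small-denominator bias of per-spheroid center
    # estimates; per-spheroid values still supply the SEM.
    len <- min(vapply(raw, nrow, integer(1)))
    pooled <- tibble(
      r_inner = raw[[1]]$r_inner[seq_len(len)],
      r_outer = raw[[1]]$r_outer[seq_len(len)],
      r_mid = raw[[1]]$r_mid[seq_len(len)],
      mean_intensity = colMeans(do.call(
        rbind, lapply(raw, function(p) p$mean_intensity[seq_len(len)])
      )),
      n_px = raw[[1]]$n_px[seq_len(len)]
    )
    pooled_norm <- normalize_profile(pooled, type_radius)
    mean_profile <- tibble(r_norm = pooled_norm$r_norm,
                           intensity = pooled_norm$intensity)
    ok <- is.finite(mean_profile$intensity)
    stat$edge_center_ratio <- approx(mean_profile$r_norm[ok],
                                     mean_profile$intensity[ok],
                                     xout = edge_position, rule = 1)$y
  } else {
    mat <- do.call(rbind, lapply(profiles, function(p) p$intensity))
    mean_profile <- tibble(r_norm = grid, intensity = colMeans(mat, na.rm = TRUE))
  }
  structure(
    list(statistic = stat, mean_profile = mean_profile, profiles = profiles,
         radii = radii, type_radius = type_radius),
    class = "sorting_result"
  )
}

#' @export
print.sorting_result <- function(x, ...) {
  cat(sprintf("<sorting_result> %d spheroid(s), type radius %.1f px\n",
              x$statistic$n + x$statistic$n_excluded, x$type_radius))
  print(x$statistic)
  invisible(x)
}

#' Integrated propidium-iodide intensity over a spheroid mask
#'
#' @param img A [multichannel_image()] with a PI channel.
#' @param mask A [detect_spheroid_mask()] result.
#' @param channel PI channel name.
#' @return The summed PI intensity over mask pixels.
#' @export
integrate_pi <- function(img, mask, channel = "PI") {
  stopifnot(inherits(mask, "spheroid_mask"))
  ch <- get_channel(img, channel)
  if (sum(mask$mask) == 0) abort("Empty spheroid mask; PI integral undefined.")
  sum(ch[mask$mask])
}

#' Relative spheroid death from integrated PI intensity
#'
#' Integrated PI intensity across the spheroid area, normalized to the mean
#' of the same quantity over untreated control wells.
#'
#' @param img,mask Treated-well image and its spheroid mask.
#' @param control_integrals Numeric vector of control-well PI integrals
#'   (from [integrate_pi()] on untreated wells).
#' @param channel PI channel name.
#' @return Relative death score (1 = untreated level).
#' @export
pi_death_score <- function(img, mask, control_integrals, channel = "PI") {
  if (length(control_integrals) < 1) abort("At least one control well is required.")
  ctrl <- mean(control_integrals)
  if (!is.finite(ctrl) || ctrl <= 0) {
    abort("Mean control PI integral is not positive; death score undefined.")
  }
  integrate_pi(img, mask, channel = channel) / ctrl
}
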