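# Synthetic-data generators with known ground truth. Each generator is a
# pure function of its arguments and seed: identical inputs give
# bit-identical outputs, and the global RNG state is left untouched.

#' Specification for a synthetic two-population spheroid image
#'
#' Describes a spheroid of `n_cells` cells, a fraction of which carry a
#' cytoplasmic label (emulating CellTracker-stained cells mixed into an
#' unlabeled majority). `sorting_strength` controls radial cell-sorting:
#' at 0 labeled cells are placed uniformly over the spheroid disk; for
#' larger values labeled cells are preferentially placed in `shell_band`
#' (a normalized-radius interval), with placement density elevated by a
#' factor `exp(sorting_strength)` inside the band. Cells are rendered as
#' isotropic Gaussian spots (sigma = `cell_radius_px / 2`), matching the
#' blurred appearance of cytoplasmic fluorescence.
#'
#' @param image_size_px Integer pair, image height and width in pixels.
#' @param spheroid_radius_px Spheroid radius in pixels; the spheroid must fit
#'   in the image with a margin of at least 10% of its radius.
#' @param n_cells Total number of cells.
#' @param labeled_fraction Fraction of cells in the labeled population,
#'   in `[0, 1]`.
#' @param sorting_strength Non-negative sorting parameter; 0 = well mixed.
#' @param cell_radius_px Apparent cell radius in pixels.
#' @param shell_band Normalized-radius interval (within `[0, 1]`) receiving
#'   preferential labeled-cell placement.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units), clipped at zero.
#' @param background_level Constant background intensity.
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return A `spheroid_spec` list, validated.
#' @export
spheroid_spec <- function(image_size_px = c(256L, 256L),
                          spheroid_radius_px = 100,
                          n_cells = 2000,
                          labeled_fraction = 0.25,
                          sorting_strength = 0,
                          cell_radius_px = 4,
                          shell_band = c(0.7, 1.0),
                          noise_sd = 0.5,
                          background_level = 2,
                          seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 16))
  check_number(spheroid_radius_px, "spheroid_radius_px", lower = 1)
  check_number(n_cells, "n_cells", lower = 1)
  check_number(labeled_fraction, "labeled_fraction", lower = 0, upper = 1)
  check_number(sorting_strength, "sorting_strength", lower = 0)
  check_number(cell_radius_px, "cell_radius_px", lower = 0.5)
  stopifnot(length(shell_band) == 2)
  if (shell_band[1] < 0 || shell_band[2] > 1 || shell_band[1] >= shell_band[2]) {
    abort("`shell_band` must be an increasing interval within [0, 1].")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(background_level, "background_level", lower = 0)
  if (1.1 * spheroid_radius_px > min(image_size_px) / 2) {
    abort(sprintf(
      "Spheroid of radius %g px does not fit in a %d x %d image with a 10%% margin.",
      spheroid_radius_px, image_size_px[1], image_size_px[2]
    ))
  }
  structure(list(
    image_size_px = as.integer(image_size_px),
    spheroid_radius_px = spheroid_radius_px,
    n_cells = as.integer(n_cells),
    labeled_fraction = labeled_fraction,
    sorting_strength = sorting_strength,
    cell_radius_px = cell_radius_px,
    shell_band = shell_band,
    noise_sd = noise_sd,
    background_level = background_level,
    seed = as.integer(seed)
  ), class = "spheroid_spec")
}

# Render point impulses at (x, y) as Gaussian spots of total intensity
# `amplitude` each, on an image of size dim_yx.
render_spots <- function(x, y, dim_yx, sigma, amplitude = 100) {
  acc <- matrix(0, dim_yx[1], dim_yx[2])
  if (length(x) > 0) {
    xi <- pmin(pmax(round(x), 1), dim_yx[2])
    yi <- pmin(pmax(round(y), 1), dim_yx[1])
    idx <- (xi - 1) * dim_yx[1] + yi
    tab <- tabulate(idx, nbins = prod(dim_yx))
    acc[] <- tab * amplitude
    acc <- EBImage::imageData(EBImage::gblur(as_ebimage(acc), sigma = sigma))
  }
  acc
}

#' Generate a synthetic two-population spheroid image with ground truth
#'
#' Samples cell centers over the spheroid disk (area-uniform radii; labeled
#' cells rejection-sampled with weight `exp(sorting_strength)` inside
#' `shell_band`), renders each population into its own channel as
#' Gaussian-blurred spots, and adds background plus Gaussian noise clipped
#' at zero.
#'
#' @param spec A [spheroid_spec()].
#'
#' @return A list with elements:
#' * `image`: [multichannel_image()] with channels `labeled`, `unlabeled`
#'   and `brightfield` (sum of both populations).
#' * `truth`: list with `cell_centers` (tibble of `x`, `y`, `population`),
#'   `true_radial_density` (labeled-cell counts and per-area density per
#'   normalized-radius bin), `true_edge_center_ratio`
#'   (`exp(sorting_strength)`, the in-band vs out-of-band labeled placement
#'   density ratio; 1 when well mixed), and `mask` (logical raster of the
#'   spheroid disk).
#' @export
gen_spheroid_image <- function(spec) {
  stopifnot(inherits(spec, "spheroid_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    R <- spec$spheroid_radius_px
    labeled <- runif(n) < spec$labeled_fraction
    r_norm <- sqrt(runif(n))
    s <- spec$sorting_strength
    if (s > 0 && any(labeled)) {
      # Rejection sampling: accept a proposed radius with probability
      # proportional to exp(s * [r in shell_band]); monotone in s.
      idx <- which(labeled)
      accepted <- rep(FALSE, length(idx))
      prop <- r_norm[idx]
      while (!all(accepted)) {
        todo <- which(!accepted)
        in_band <- prop[todo] >= spec$shell_band[1] & prop[todo] <= spec$shell_band[2]
        w <- exp(s * in_band) / exp(s)
        ok <- runif(length(todo)) < w
        accepted[todo[ok]] <- TRUE
        if (any(!ok)) prop[todo[!ok]] <- sqrt(runif(sum(!ok)))
      }
      r_norm[idx] <- prop
    }
    theta <- runif(n, 0, 2 * pi)
    cx <- (spec$image_size_px[2] + 1) / 2
    cy <- (spec$image_size_px[1] + 1) / 2
    x <- cx + r_norm * R * cos(theta)
    y <- cy + r_norm * R * sin(theta)

    dim_yx <- spec$image_size_px
    sigma <- spec$cell_radius_px / 2
    ch_lab <- render_spots(x[labeled], y[labeled], dim_yx, sigma)
    ch_unl <- render_spots(x[!labeled], y[!labeled], dim_yx, sigma)
    add_noise <- function(m) {
      m <- m + spec$background_level
      if (spec$noise_sd > 0) m <- m + rnorm(length(m), 0, spec$noise_sd)
      pmax(m, 0)
    }
    ch_lab <- add_noise(ch_lab)
    ch_unl <- add_noise(ch_unl)

    img <- multichannel_image(
      list(labeled = ch_lab, unlabeled = ch_unl, brightfield = ch_lab + ch_unl),
      provenance = sprintf("gen_spheroid_image(seed = %d)", spec$seed)
    )

    bins <- seq(0, 1, length.out = 21)
    counts <- tabulate(findInterval(r_norm[labeled], bins, rightmost.closed = TRUE),
                       nbins = 20)
    area <- pi * R^2 * diff(bins^2)
    grid <- pixel_grid(dim_yx)
    mask <- (grid$x - cx)^2 + (grid$y - cy)^2 <= R^2

    truth <- list(
      cell_centers = tibble(
        x = x, y = y,
        r_norm = r_norm,
        population = ifelse(labeled, "labeled", "unlabeled")
      ),
      true_radial_density = tibble(
        bin_lo = bins[-21], bin_hi = bins[-1],
        n_labeled = counts, density = counts / area
      ),
      true_edge_center_ratio = exp(s),
      mask = mask
    )
    list(image = img, truth = truth)
  })
}

# Three-parameter inhibition curve with unit Hill slope.
inhibition_curve <- function(dose, ic50, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + dose / ic50)
}

#' Specification for synthetic chemoprotection viability tables
#'
#' Describes a two-population (drug-sensitive / drug-resistant) culture whose
#' mono-culture viabilities follow three-parameter inhibition curves. In
#' `independent_2d` mode the co-culture is the weight-averaged mixture of the
#' mono-culture responses (no interaction). In `shell_shielding_spheroid`
#' mode the sensitive component of the co-culture sees only
#' `dose / attenuation_factor`, emulating drug depletion/limited transport in
#' a spheroid whose shell is occupied by resistant cells;
#' `attenuation_factor = 1` reduces it to the independent mode.
#'
#' @param ic50_sensitive,ic50_resistant Mono-culture IC50s (molar).
#' @param mixture_weights Positive seeding weights, named `sensitive` and
#'   `resistant` (default 3:1).
#' @param concentrations Strictly positive, sorted molar doses.
#' @param mode `"independent_2d"` or `"shell_shielding_spheroid"`.
#' @param attenuation_factor Factor (>= 1) dividing the dose reaching the
#'   sensitive co-culture component in shielding mode.
#' @param replicate_noise_sd Gaussian noise SD added per replicate viability.
#' @param n_replicates Experimental replicates per condition.
#' @param seed Integer seed.
#'
#' @return A validated `protection_spec` list.
#' @export
protection_spec <- function(ic50_sensitive,
                            ic50_resistant,
                            concentrations,
                            mixture_weights = c(sensitive = 3, resistant = 1),
                            mode = c("independent_2d", "shell_shielding_spheroid"),
                            attenuation_factor = 1,
                            replicate_noise_sd = 0,
                            n_replicates = 3,
                            seed = 1L) {
  mode <- match.arg(mode)
  check_number(ic50_sensitive, "ic50_sensitive", lower = 0, allow_equal_lower = FALSE)
  check_number(ic50_resistant, "ic50_resistant", lower = 0, allow_equal_lower = FALSE)
  if (any(concentrations <= 0)) abort("`concentrations` must be strictly positive.")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    abort("`concentrations` must be strictly increasing.")
  }
  if (length(mixture_weights) != 2 || any(mixture_weights <= 0)) {
    abort("`mixture_weights` must be two positive weights.")
  }
  if (is.null(names(mixture_weights))) {
    names(mixture_weights) <- c("sensitive", "resistant")
  }
  check_number(attenuation_factor, "attenuation_factor", lower = 1)
  check_number(replicate_noise_sd, "replicate_noise_sd", lower = 0)
  check_number(n_replicates, "n_replicates", lower = 1)
  structure(list(
    ic50_sensitive = ic50_sensitive, ic50_resistant = ic50_resistant,
    concentrations = concentrations, mixture_weights = mixture_weights,
    mode = mode, attenuation_factor = attenuation_factor,
    replicate_noise_sd = replicate_noise_sd,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "protection_spec")
}

#' Generate mono- and co-culture viability tables with known protection
#'
#' @param spec A [protection_spec()].
#'
#' @return A list with long-format tibbles `mono` (conditions `sensitive`,
#'   `resistant`) and `co` (condition `co_culture`), each with columns
#'   `well`, `condition`, `dose_M`, `replicate`, `value` (normalized
#'   viability), plus `truth`: the noiseless per-dose component curves and
#'   the exact observed and expected co-culture viabilities.
#' @export
gen_protection_tables <- function(spec) {
  stopifnot(inherits(spec, "protection_spec"))
  w <- spec$mixture_weights / sum(spec$mixture_weights)
  d <- spec$concentrations
  v_s <- inhibition_curve(d, spec$ic50_sensitive)
  v_r <- inhibition_curve(d, spec$ic50_resistant)
  d_core <- if (spec$mode == "shell_shielding_spheroid") d / spec$attenuation_factor else d
  v_s_co <- inhibition_curve(d_core, spec$ic50_sensitive)
  observed_true <- w[["sensitive"]] * v_s_co + w[["resistant"]] * v_r
  expected_true <- w[["sensitive"]] * v_s + w[["resistant"]] * v_r

  with_seed(spec$seed, {
    make_table <- function(condition, values) {
      grid <- tidyr::expand_grid(
        dose_i = seq_along(d),
        replicate = seq_len(spec$n_replicates)
      )
      v <- values[grid$dose_i]
      if (spec$replicate_noise_sd > 0) {
        # not clipped at zero: background-subtracted viabilities can dip
        # below 0, and clipping would bias near-zero means upward
        v <- v + rnorm(length(v), 0, spec$replicate_noise_sd)
      }
      tibble(
        well = sprintf("%s-d%02d-r%d", condition, grid$dose_i, grid$replicate),
        condition = condition,
        dose_M = d[grid$dose_i],
        replicate = grid$replicate,
        value = v
      )
    }
    list(
      mono = bind_rows(
        make_table("sensitive", v_s),
        make_table("resistant", v_r)
      ),
      co = make_table("co_culture", observed_true),
      truth = tibble(
        dose_M = d, v_sensitive = v_s, v_resistant = v_r,
        v_sensitive_core = v_s_co,
        observed_true = observed_true, expected_true = expected_true
      )
    )
  })
}

#' Generate a logistic confluency growth curve
#'
#' Confluency follows `K / (1 + exp(-r (t - t0)))` with additive Gaussian
#' noise, clipped to `[0, 100]` percent.
#'
#' @param K Carrying capacity, percent confluency in `(0, 100]`.
#' @param r Logistic growth rate per hour, `> 0`; the exponential-phase
#'   doubling time is `log(2) / r`.
#' @param t0 Inflection (half-capacity) time in hours.
#' @param times Measurement times in hours.
#' @param noise_sd Gaussian noise SD in percent confluency.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `time_h`, `confluency`.
#' @export
gen_growth_curve <- function(K, r, t0, times = seq(0, 180, by = 4),
                             noise_sd = 0, seed = 1L) {
  check_number(K, "K", lower = 0, upper = 100, allow_equal_lower = FALSE)
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
    abort("`r` must be a single positive growth rate (per hour).")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    y <- K / (1 + exp(-r * (times - t0)))
    if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
    tibble(time_h = times, confluency = pmin(pmax(y, 0), 100))
  })
}

#' Generate a synthetic monolayer image with nuclei and a membrane marker
#'
#' Emulates an epithelial colony patch surrounded by background: cell
#' seeds are placed by dart-throwing with a minimum spacing inside a
#' centered colony disk, cells are the nearest-seed (Voronoi) regions
#' within the colony foreground, nuclei are rendered as disks at the
#' seeds, and the marker channel is a uniform cytoplasmic level elevated
#' by a factor `(1 + enrichment)` within `band_px` pixels of any cell
#' outline (cell-cell junction or colony edge). The background margin
#' around the colony is what downstream foreground detection segments
#' against.
#'
#' @param n_cells Number of cells (>= 1).
#' @param enrichment Non-negative junction-enrichment parameter; 0 gives a
#'   marker uniform within each cell.
#' @param seed Integer seed.
#' @param image_size_px Integer pair, image size.
#' @param nucleus_radius_px Nucleus disk radius.
#' @param min_spacing_px Minimum seed-to-seed distance; placement fails with
#'   an error if the cells are too dense to tessellate.
#' @param cell_reach_px Maximum distance from a seed that belongs to its
#'   cell; pixels beyond every seed's reach are background.
#' @param colony_radius_px Radius of the centered disk within which seeds
#'   are placed; the default keeps the colony (including cell reach) inside
#'   the image with a small margin. Too many cells for this disk at the
#'   requested spacing is rejected with an error.
#' @param band_px Width of the elevated outline band, pixels.
#' @param cyto_level Cytoplasmic marker intensity.
#' @param background_level,noise_sd Background intensity and Gaussian noise
#'   SD applied to both channels.
#'
#' @return A list with `image` ([multichannel_image()] with channels `dapi`
#'   and `marker`) and `truth`: `cells` (integer label raster, 0 =
#'   background), `band` (logical raster of the elevated outline band),
#'   `nuclei_centers` (tibble `cell`, `x`, `y`), `band_px`, and
#'   `intended_band_ratio` (`1 + enrichment`).
#' @export
gen_monolayer_image <- function(n_cells, enrichment, seed = 1L,
                                image_size_px = c(256L, 256L),
                                nucleus_radius_px = 5,
                                min_spacing_px = 24,
                                cell_reach_px = 1.4 * min_spacing_px,
                                colony_radius_px = NULL,
                                band_px = 2,
                                cyto_level = 50,
                                background_level = 2,
                                noise_sd = 1) {
  check_number(n_cells, "n_cells", lower = 1)
  check_number(enrichment, "enrichment", lower = 0)
  n_cells <- as.integer(n_cells)
  dim_yx <- as.integer(image_size_px)
  colony_radius_px <- colony_radius_px %||%
    (min(dim_yx) / 2 - cell_reach_px - 2)
  if (colony_radius_px < min_spacing_px) {
    abort("Image too small for the requested colony and cell reach.")
  }
  with_seed(seed, {
    cx <- (dim_yx[2] + 1) / 2
    cy <- (dim_yx[1] + 1) / 2
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < n_cells) {
      attempts <- attempts + 1L
      if (attempts > 300L * n_cells) {
        abort("Cells too dense to tessellate: could not place seeds at the requested minimum spacing.")
      }
      a <- runif(1, 0, 2 * pi)
      rr <- colony_radius_px * sqrt(runif(1))
      px <- cx + rr * cos(a)
      py <- cy + rr * sin(a)
      if (length(xs) == 0 || all((xs - px)^2 + (ys - py)^2 >= min_spacing_px^2)) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }

    grid <- pixel_grid(dim_yx)
    npx <- prod(dim_yx)
    nearest <- integer(npx)
    best <- rep(Inf, npx)
    for (i in seq_len(n_cells)) {
      di <- (as.vector(grid$x) - xs[i])^2 + (as.vector(grid$y) - ys[i])^2
      upd <- di < best
      best[upd] <- di[upd]
      nearest[upd] <- i
    }
    labels <- nearest
    labels[best > cell_reach_px^2] <- 0L
    labels <- matrix(labels, dim_yx[1], dim_yx[2])

    # Outline pixels: 4-neighborhood contains a different label (or background).
    pad <- function(m, dr, dc) {
      out <- m
      out[] <- m[pmin(pmax(row(m) + dr, 1), nrow(m)) +
                 (pmin(pmax(col(m) + dc, 1), ncol(m)) - 1) * nrow(m)]
      out
    }
    boundary <- (labels != pad(labels, 1, 0)) | (labels != pad(labels, -1, 0)) |
      (labels != pad(labels, 0, 1)) | (labels != pad(labels, 0, -1))
    dist_boundary <- EBImage::imageData(EBImage::distmap(as_ebimage(1 - boundary * 1)))

    inside <- labels > 0
    band <- inside & (dist_boundary <= band_px)
    marker <- background_level + cyto_level * inside + enrichment * cyto_level * band
    nuclei <- matrix(0, dim_yx[1], dim_yx[2])
    for (i in seq_len(n_cells)) {
      disk <- (grid$x - xs[i])^2 + (grid$y - ys[i])^2 <= nucleus_radius_px^2
      nuclei[disk] <- 200
    }
    nuclei <- EBImage::imageData(EBImage::gblur(as_ebimage(nuclei), sigma = 1)) +
      background_level
    if (noise_sd > 0) {
      marker <- marker + rnorm(npx, 0, noise_sd)
      nuclei <- nuclei + rnorm(npx, 0, noise_sd)
    }
    img <- multichannel_image(
      list(dapi = pmax(nuclei, 0), marker = pmax(marker, 0)),
      provenance = sprintf("gen_monolayer_image(seed = %d)", seed)
    )
    list(
      image = img,
      truth = list(
        cells = labels,
        band = band,
        nuclei_centers = tibble(cell = seq_len(n_cells), x = xs, y = ys),
        band_px = band_px,
        intended_band_ratio = 1 + enrichment
      )
    )
  })
}

#' Generate a synthetic collagen-invasion field
#'
#' Renders a central labeled spheroid disk plus radially oriented labeled
#' sheets, each connected to the disk and ending at a given distance from
#' the center. Sheets are laid out at evenly spaced angles (with a seeded
#' angular offset), so coincident end distances remain distinct components.
#'
#' @param spheroid_diameter_px Starting spheroid diameter, pixels.
#' @param sheet_end_distances_px Numeric vector of center-to-sheet-end
#'   distances, each strictly greater than the spheroid radius; may be
#'   empty for a bare spheroid.
#' @param seed Integer seed.
#' @param image_size_px Optional integer pair; default leaves a 30 px margin
#'   around the farthest sheet end.
#' @param sheet_width_px Sheet width, pixels.
#' @param intensity Label intensity of disk and sheets.
#' @param background_level,noise_sd Background and Gaussian noise SD.
#'
#' @return A list with `image` ([multichannel_image()], channel `label`),
#'   and `truth`: `center` (x, y), `initial_mask` (logical raster of the
#'   starting disk), `sheets` (tibble `sheet`, `angle_rad`,
#'   `end_distance_px`).
#' @export
gen_migration_image <- function(spheroid_diameter_px, sheet_end_distances_px,
                                seed = 1L, image_size_px = NULL,
                                sheet_width_px = 20,
                                intensity = 100,
                                background_level = 1, noise_sd = 0.5) {
  check_number(spheroid_diameter_px, "spheroid_diameter_px", lower = 4)
  R <- spheroid_diameter_px / 2
  if (length(sheet_end_distances_px) > 0 && any(sheet_end_distances_px <= R)) {
    abort("Every sheet end distance must exceed the spheroid radius.")
  }
  extent <- max(c(R, sheet_end_distances_px)) + 30
  if (is.null(image_size_px)) image_size_px <- rep(2 * ceiling(extent), 2)
  dim_yx <- as.integer(image_size_px)
  with_seed(seed, {
    cx <- (dim_yx[2] + 1) / 2
    cy <- (dim_yx[1] + 1) / 2
    grid <- pixel_grid(dim_yx)
    dx <- grid$x - cx
    dy <- grid$y - cy
    disk <- dx^2 + dy^2 <= R^2
    fg <- disk
    n_sheet <- length(sheet_end_distances_px)
    angles <- numeric(0)
    if (n_sheet > 0) {
      offset <- runif(1, 0, 2 * pi)
      angles <- offset + 2 * pi * (seq_len(n_sheet) - 1) / n_sheet
      for (i in seq_len(n_sheet)) {
        along <- dx * cos(angles[i]) + dy * sin(angles[i])
        perp <- abs(-dx * sin(angles[i]) + dy * cos(angles[i]))
        fg <- fg | (along >= 0 & along <= sheet_end_distances_px[i] &
                      perp <= sheet_width_px / 2)
      }
    }
    label <- intensity * fg + background_level
    if (noise_sd > 0) label <- label + rnorm(length(label), 0, noise_sd)
    img <- multichannel_image(
      list(label = pmax(label, 0)),
      provenance = sprintf("gen_migration_image(seed = %d)", seed)
    )
    list(
      image = img,
      truth = list(
        center = c(x = cx, y = cy),
        initial_mask = disk,
        sheets = tibble(
          sheet = seq_len(n_sheet),
          angle_rad = angles,
          end_distance_px = as.numeric(sheet_end_distances_px)
        )
      )
    )
  })
}

#' Generate a qPCR Ct table with known copy numbers
#'
#' For each sample the target-gene Ct is placed at
#' `ct_ref_gene - log2(n_rel)` with `n_rel = copy_number / 2`, so that the
#' standard delta-Ct chain (see [cnv_from_ct()]) recovers the true copy
#' number against a diploid reference sample. Gaussian noise of SD
#' `replicate_sd` is added independently to every Ct measurement.
#'
#' @param true_copy_numbers Named numeric vector of true copy numbers per
#'   sample, all strictly positive; the reference sample should be diploid
#'   (copy number 2).
#' @param reference_sample Name of the diploid reference sample.
#' @param target_gene,reference_gene Gene labels written to the table.
#' @param ct_ref_gene Baseline Ct of the reference gene.
#' @param replicate_sd Per-measurement Ct noise SD.
#' @param n_tech Technical replicates per (sample, gene, analysis).
#' @param n_analyses Independent analysis repeats.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `sample`, `gene`, `analysis`, `replicate`,
#'   `ct`.
#' @export
gen_ct_table <- function(true_copy_numbers, reference_sample,
                         target_gene = "RRM1", reference_gene = "RNaseP",
                         ct_ref_gene = 26, replicate_sd = 0.1,
                         n_tech = 3, n_analyses = 1, seed = 1L) {
  if (is.null(names(true_copy_numbers)) || any(!nzchar(names(true_copy_numbers)))) {
    abort("`true_copy_numbers` must be a named vector (one entry per sample).")
  }
  if (any(true_copy_numbers <= 0)) abort("Copy numbers must be strictly positive.")
  if (!reference_sample %in% names(true_copy_numbers)) {
    abort("`reference_sample` must be one of the named samples.")
  }
  check_number(replicate_sd, "replicate_sd", lower = 0)
  with_seed(seed, {
    rows <- tidyr::expand_grid(
      sample = names(true_copy_numbers),
      gene = c(target_gene, reference_gene),
      analysis = seq_len(n_analyses),
      replicate = seq_len(n_tech)
    )
    n_rel <- true_copy_numbers / 2
    base_ct <- ifelse(
      rows$gene == target_gene,
      ct_ref_gene - log2(n_rel[rows$sample]),
      ct_ref_gene
    )
    noise <- if (replicate_sd > 0) rnorm(nrow(rows), 0, replicate_sd) else 0
    mutate(rows, ct = base_ct + noise)
  })
}
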