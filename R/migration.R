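# Collagen-invasion quantification: distance from the spheroid center to
# the ends of the longest continuous labeled invasive sheets.

#' Identify invasive cell sheets in a labeled invasion field
#'
#' Thresholds the label channel (Otsu), removes the (slightly dilated)
#' initial spheroid region, and keeps the connected components that touch
#' the initial spheroid boundary — the operational definition of a
#' "continuous" invasive sheet — and exceed a minimum area.
#'
#' @param label Numeric matrix (tracked-population channel) or a
#'   [multichannel_image()].
#' @param initial_mask Logical raster of the spheroid at embedding time
#'   (t = 0), e.g. `detect_spheroid_mask(t0_img)$mask`.
#' @param channel Channel name when `label` is a multi-channel image.
#' @param min_area_px Minimum sheet area (default 50 px).
#' @param contact_px Maximum gap (pixels) between a sheet and the initial
#'   boundary still counted as contact.
#'
#' @return A list with `sheets` (integer label raster of sheet components,
#'   0 elsewhere) and `areas` (named integer vector of sheet areas). Zero
#'   sheets is a valid, empty result.
#' @export
identify_invasive_sheets <- function(label, initial_mask, channel = "label",
                                     min_area_px = 50, contact_px = 3) {
  if (inherits(label, "multichannel_image")) label <- get_channel(label, channel)
  stopifnot(identical(dim(label), dim(initial_mask)))
  empty <- list(sheets = matrix(0L, nrow(label), ncol(label)), areas = integer(0))
  th <- tryCatch(otsu_threshold(label), error = function(e) NULL)
  if (is.null(th)) return(empty)
  fg <- label > th
  d_mask <- EBImage::imageData(EBImage::distmap(as_ebimage(1 - initial_mask * 1)))
  outside <- fg & !(d_mask <= contact_px / 2 | initial_mask)
  if (!any(outside)) return(empty)
  comp <- EBImage::imageData(EBImage::bwlabel(as_ebimage(outside * 1)))
  storage.mode(comp) <- "integer"
  touching <- sort(unique(comp[comp > 0 & d_mask <= contact_px]))
  areas <- tabulate(comp[comp > 0])
  keep <- intersect(touching, which(areas >= min_area_px))
  if (length(keep) == 0) return(empty)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  sheets <- matrix(0L, nrow(comp), ncol(comp))
  nz <- comp > 0 & comp %in% keep
  sheets[nz] <- relabel[comp[nz]]
  list(sheets = sheets, areas = setNames(areas[keep], seq_along(keep)))
}

#' Normalized invasion distance to the ends of the longest sheets
#'
#' For each sheet, the end distance is the maximum Euclidean distance from
#' the spheroid center over the sheet's pixels. The `top_k` largest end
#' distances (ties broken by component area, larger first, then by label)
#' are averaged and divided by the starting spheroid diameter. With fewer
#' than `top_k` sheets the available ones are averaged and the result
#' flagged `"k<3"`; with no sheets the statistic takes the center-to-boundary
#' floor value 0.5 and is flagged `"no invasion"`.
#'
#' @param sheets Result of [identify_invasive_sheets()].
#' @param center Spheroid center `c(x, y)` in pixel coordinates (from the
#'   t = 0 mask).
#' @param starting_diameter Starting spheroid diameter in pixels
#'   (conventionally `2 * equiv_radius_px` of the t = 0 mask).
#' @param top_k Number of longest sheets to average (default 3).
#'
#' @return An object of class `migration_measurement`: list with
#'   `normalized_distance`, `per_sheet` (tibble `sheet`, `end_distance_px`,
#'   `area_px`, `used`), `n_sheets`, `starting_diameter`, `flags`.
#' @export
migration_distance <- function(sheets, center, starting_diameter, top_k = 3) {
  check_number(starting_diameter, "starting_diameter", lower = 0, allow_equal_lower = FALSE)
  lab <- sheets$sheets
  n_sheets <- max(lab)
  flags <- character(0)
  if (n_sheets == 0) {
    return(structure(
      list(
        normalized_distance = 0.5,
        per_sheet = tibble(sheet = integer(0), end_distance_px = numeric(0),
                           area_px = numeric(0), used = logical(0)),
        n_sheets = 0L, starting_diameter = starting_diameter,
        flags = "no invasion"
      ),
      class = "migration_measurement"
    ))
  }
  grid <- pixel_grid(dim(lab))
  d <- sqrt((grid$x - center[[1]])^2 + (grid$y - center[[2]])^2)
  per_sheet <- tibble(
    sheet = seq_len(n_sheets),
    end_distance_px = as.numeric(tapply(d[lab > 0], lab[lab > 0], max)),
    area_px = as.numeric(tabulate(lab[lab > 0], nbins = n_sheets))
  ) |>
    arrange(desc(.data$end_distance_px), desc(.data$area_px), .data$sheet) |>
    mutate(used = row_number() <= top_k)
  if (n_sheets < top_k) flags <- c(flags, sprintf("k<%d", top_k))
  structure(
    list(
      normalized_distance =
        mean(per_sheet$end_distance_px[per_sheet$used]) / starting_diameter,
      per_sheet = per_sheet,
      n_sheets = as.integer(n_sheets),
      starting_diameter = starting_diameter,
      flags = flags
    ),
    class = "migration_measurement"
  )
}

#' @export
print.migration_measurement <- function(x, ...) {
  cat(sprintf(
    "<migration_measurement> normalized distance %.3f (%d sheet(s)%s)\n",
    x$normalized_distance, x$n_sheets,
    if (length(x$flags) > 0) paste0("; ", paste(x$flags, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' @method tidy migration_measurement
#' @export
tidy.migration_measurement <- function(x, ...) x$per_sheet

#' @method glance migration_measurement
#' @export
glance.migration_measurement <- function(x, ...) {
  tibble(
    normalized_distance = x$normalized_distance,
    n_sheets = x$n_sheets,
    starting_diameter = x$starting_diameter,
    flags = paste(x$flags, collapse = ";")
  )
}
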