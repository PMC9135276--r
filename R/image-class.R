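#' Multi-channel 2D image
#'
#' The unit of all imaging operations: a set of named, equally sized 2D pixel
#' rasters (e.g. `brightfield`, `CTR`, `PI`, `dapi`), optionally carrying a
#' physical pixel size. Matrices are stored in `[row = y, col = x]`
#' orientation with the origin at the top-left pixel.
#'
#' @param channels Named list of numeric matrices, all of identical
#'   dimensions, with finite non-negative intensities.
#' @param pixel_size_um Optional pixel edge length in micrometres.
#' @param provenance Optional free-text tag recording where the image came
#'   from (file path, generator call, ...).
#'
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_um = NULL, provenance = NULL) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1)))) {
    abort("Every channel must be a numeric matrix.")
  }
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All channels must have identical dimensions.")
  }
  bad <- vapply(channels, function(m) any(!is.finite(m)) || any(m < 0), logical(1))
  if (any(bad)) {
    abort(sprintf(
      "Channel(s) %s contain negative or non-finite intensities.",
      paste0("`", names(channels)[bad], "`", collapse = ", ")
    ))
  }
  if (!is.null(pixel_size_um)) check_number(pixel_size_um, "pixel_size_um", lower = 0, allow_equal_lower = FALSE)
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um, provenance = provenance),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<multichannel_image> %d x %d px, %d channel(s): %s\n",
    d[1], d[2], length(x$channels), paste(names(x$channels), collapse = ", ")
  ))
  if (!is.null(x$pixel_size_um)) cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  if (!is.null(x$provenance)) cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$channels[[1]])

#' Extract a channel matrix
#'
#' @param img A [multichannel_image()].
#' @param channel Channel name.
#' @return The channel's numeric matrix.
#' @export
get_channel <- function(img, channel) {
  stopifnot(inherits(img, "multichannel_image"))
  if (!channel %in% names(img$channels)) {
    abort(sprintf(
      "Channel `%s` not found; available channels: %s.",
      channel, paste(names(img$channels), collapse = ", ")
    ))
  }
  img$channels[[channel]]
}

#' Read a multi-page TIFF as a multi-channel image
#'
#' Pages are mapped to channels by position via `channel_names`.
#'
#' @param path Path to a single- or multi-page TIFF file.
#' @param channel_names Character vector naming each page, in page order.
#' @param pixel_size_um Optional pixel size to attach.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, channel_names, pixel_size_um = NULL) {
  if (!file.exists(path)) abort(sprintf("Image file `%s` does not exist.", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grayscale-as-RGB pages
    p
  })
  if (length(channel_names) != length(pages)) {
    abort(sprintf(
      "Channel mapping names %d channel(s) but `%s` has %d page(s): pages are %s.",
      length(channel_names), path, length(pages),
      paste(seq_along(pages), collapse = ", ")
    ))
  }
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort(sprintf("Pages of `%s` differ in shape.", path))
  }
  multichannel_image(setNames(pages, channel_names),
                     pixel_size_um = pixel_size_um, provenance = path)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` by `max_value` and written as
#' lossless 16-bit pages, one per channel, in channel order.
#'
#' @param img A [multichannel_image()].
#' @param path Output file path.
#' @param max_value Intensity mapped to white; defaults to the image maximum.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, max_value = NULL) {
  stopifnot(inherits(img, "multichannel_image"))
  mx <- max_value %||% max(unlist(lapply(img$channels, max)), 1e-12)
  pages <- lapply(img$channels, function(m) pmin(pmax(m / mx, 0), 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16, compression = "none")
  invisible(path)
}
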