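# Nuclei-seeded cell segmentation and edge-vs-cytoplasm marker enrichment.

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, global Otsu threshold, watershed split of touching
#' objects on the distance transform, size filter.
#'
#' @param dapi Numeric matrix (DAPI channel) or a [multichannel_image()].
#' @param channel Channel name when `dapi` is a multi-channel image.
#' @param sigma Smoothing sigma, pixels.
#' @param min_size Minimum nucleus area in pixels.
#'
#' @return Integer label matrix (0 = background), labels `1..n` in
#'   decreasing area order.
#' @export
segment_nuclei <- function(dapi, channel = "dapi", sigma = 2, min_size = 30) {
  if (inherits(dapi, "multichannel_image")) dapi <- get_channel(dapi, channel)
  smoothed <- EBImage::imageData(EBImage::gblur(as_ebimage(dapi), sigma = sigma))
  th <- tryCatch(otsu_threshold(smoothed), error = function(e) NULL)
  if (is.null(th)) abort("No nuclei found: channel is constant.")
  binary <- smoothed > th
  if (!any(binary)) abort("No nuclei found after thresholding.")
  dm <- EBImage::distmap(as_ebimage(binary * 1))
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_size)
  if (length(keep) == 0) abort("No nuclei found: all objects below the size filter.")
  relabel <- integer(length(areas))
  relabel[keep[order(areas[keep], decreasing = TRUE)]] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- relabel[labels[nz]]
  out
}

#' Propagate cell outlines from nuclear seeds
#'
#' Seeded region growing over the marker foreground (smoothed marker above
#' its Otsu threshold, union the nuclei themselves), assigning every
#' foreground pixel to exactly one nucleus using the CellProfiler
#' propagation metric. With a flat guidance image the assignment reduces to
#' nearest-seed (geodesic) growth.
#'
#' @param marker Numeric matrix (junction marker channel) or a
#'   [multichannel_image()].
#' @param nuclei Integer nuclei label matrix from [segment_nuclei()].
#' @param channel Channel name when `marker` is a multi-channel image.
#' @param sigma Smoothing sigma for foreground detection.
#' @param lambda Propagation regularization; large values weight Euclidean
#'   distance over intensity gradients.
#'
#' @return A list with `labels` (integer cell label raster; every
#'   foreground pixel assigned to one nucleus), `border_cells` (labels
#'   touching the image border, whose outlines are truncated) and
#'   `isolated_cells` (labels whose nucleus fell outside the marker
#'   foreground, so the cell is the nucleus region only).
#' @export
propagate_cells <- function(marker, nuclei, channel = "marker", sigma = 2,
                            lambda = 1e4) {
  if (inherits(marker, "multichannel_image")) marker <- get_channel(marker, channel)
  if (max(nuclei) < 1) abort("At least one nucleus seed is required.")
  smoothed <- EBImage::imageData(EBImage::gblur(as_ebimage(marker), sigma = sigma))
  # Three-class threshold on log intensity, keeping the middle and upper
  # classes: bright junction bands make the within-cell intensities
  # bimodal, so a two-class split would cut through the cells instead of
  # separating them from background.
  th <- tryCatch(otsu3_lower(log1p(smoothed)), error = function(e) NULL)
  fg <- if (is.null(th)) smoothed >= 0 else log1p(smoothed) > th
  isolated <- sort(unique(nuclei[nuclei > 0 & !fg]))
  mask <- fg | nuclei > 0
  labels <- EBImage::imageData(EBImage::propagate(
    x = as_ebimage(smoothed), seeds = as_ebimage(nuclei),
    mask = as_ebimage(mask * 1), lambda = lambda
  ))
  storage.mode(labels) <- "integer"
  border <- sort(unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)])))
  isolated <- setdiff(
    isolated,
    sort(unique(labels[fg & labels > 0]))  # nuclei partly in foreground are fine
  )
  list(
    labels = labels,
    border_cells = setdiff(border, 0L),
    isolated_cells = isolated
  )
}

#' Per-cell edge bands and shrunken cytoplasm regions
#'
#' For each cell, the edge band is the cell outline expanded by `expand_px`
#' minus the outline shrunk by `shrink_px`; the shrunken cytoplasm is the
#' remainder of the cell. Expansion and shrinkage use per-cell Euclidean
#' distance-transform thresholds (isotropic, with a half-pixel offset
#' correcting pixel-center vs region-edge distances). Where the expanded
#' bands of neighboring cells would overlap, background pixels go to the
#' strictly nearest cell. Cells whose shrinkage empties them are excluded
#' with a warning.
#'
#' @param cells Output of [propagate_cells()], or a bare integer cell label
#'   matrix.
#' @param expand_px,shrink_px Outline expansion and shrinkage in pixels
#'   (defaults 2 and 7).
#'
#' @return An object of class `cell_segmentation`: list with `cells`,
#'   `edge` and `cytoplasm` integer label rasters (edge and cytoplasm are
#'   disjoint within every cell), `excluded` (labels emptied by the
#'   shrinkage), `border_cells`, and `background_adjacent` (cells whose
#'   edge band borders unassigned background, e.g. at a colony rim, rather
#'   than a neighboring cell).
#' @export
edge_cytoplasm_regions <- function(cells, expand_px = 2, shrink_px = 7) {
  border_cells <- integer(0)
  if (is.list(cells)) {
    border_cells <- cells$border_cells %||% integer(0)
    cells <- cells$labels
  }
  if (max(cells) < 1) abort("No cells in the label raster.")
  dim_yx <- dim(cells)
  labs <- sort(unique(cells[cells > 0]))
  margin <- ceiling(expand_px) + 2L

  cytoplasm <- matrix(0L, dim_yx[1], dim_yx[2])
  # Background pixels within reach of several dilated outlines compete by
  # Euclidean distance to each cell.
  claim_d <- matrix(Inf, dim_yx[1], dim_yx[2])
  claim <- matrix(0L, dim_yx[1], dim_yx[2])
  for (i in labs) {
    idx <- which(cells == i, arr.ind = TRUE)
    r0 <- max(min(idx[, 1]) - margin, 1L); r1 <- min(max(idx[, 1]) + margin, dim_yx[1])
    c0 <- max(min(idx[, 2]) - margin, 1L); c1 <- min(max(idx[, 2]) + margin, dim_yx[2])
    sub <- cells[r0:r1, c0:c1] == i
    d_in <- EBImage::imageData(EBImage::distmap(as_ebimage(sub * 1)))
    d_out <- EBImage::imageData(EBImage::distmap(as_ebimage((!sub) * 1)))
    cyto_sub <- sub & d_in > shrink_px
    win_cyto <- cytoplasm[r0:r1, c0:c1]
    win_cyto[cyto_sub] <- i
    cytoplasm[r0:r1, c0:c1] <- win_cyto
    dil <- !sub & cells[r0:r1, c0:c1] == 0 & d_out <= expand_px + 0.5
    win_d <- claim_d[r0:r1, c0:c1]
    win_c <- claim[r0:r1, c0:c1]
    upd <- dil & d_out < win_d
    win_d[upd] <- d_out[upd]
    win_c[upd] <- i
    claim_d[r0:r1, c0:c1] <- win_d
    claim[r0:r1, c0:c1] <- win_c
  }
  edge <- cells
  edge[cytoplasm > 0] <- 0L
  edge[claim > 0] <- claim[claim > 0]

  # Cells still adjacent to unassigned background after the expansion:
  # their edge band borders empty substrate rather than a neighbor, so the
  # junction-enrichment readout is contaminated for them.
  assigned <- cells
  assigned[claim > 0] <- claim[claim > 0]
  pad <- function(m, dr, dc) {
    m[pmin(pmax(row(m) + dr, 1), nrow(m)) +
        (pmin(pmax(col(m) + dc, 1), ncol(m)) - 1) * nrow(m)]
  }
  shift_zero <- function(dr, dc) assigned > 0 & pad(assigned, dr, dc) == 0
  adj <- shift_zero(1, 0) | shift_zero(-1, 0) | shift_zero(0, 1) | shift_zero(0, -1)
  dim(adj) <- dim_yx
  background_adjacent <- sort(unique(assigned[adj]))

  present <- sort(unique(cells[cells > 0]))
  kept <- sort(unique(cytoplasm[cytoplasm > 0]))
  excluded <- setdiff(present, kept)
  if (length(excluded) == length(present)) {
    abort(sprintf("All cells were emptied by the %d px shrinkage.", shrink_px))
  }
  if (length(excluded) > 0) {
    warn(sprintf(
      "%d cell(s) excluded: the %d px shrinkage empties them (labels %s).",
      length(excluded), shrink_px, paste(excluded, collapse = ", ")
    ))
    edge[matrix(edge %in% excluded, dim_yx[1], dim_yx[2])] <- 0L
  }
  structure(
    list(cells = cells, edge = edge, cytoplasm = cytoplasm,
         excluded = excluded, border_cells = border_cells,
         background_adjacent = background_adjacent,
         expand_px = expand_px, shrink_px = shrink_px),
    class = "cell_segmentation"
  )
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cell_segmentation> %d cell(s), edge band = +%g/-%g px, %d excluded, %d on border\n",
    length(unique(x$cells[x$cells > 0])), x$expand_px, x$shrink_px,
    length(x$excluded), length(x$border_cells)
  ))
  invisible(x)
}

#' Edge-to-cytoplasm marker enrichment ratio
#'
#' Per retained cell, the ratio of the mean marker intensity in the edge
#' band to the mean intensity in the shrunken cytoplasm; reported with the
#' field-of-view mean over cells. Border-touching cells (truncated
#' outlines), cells whose edge band borders empty background (their
#' junction readout is diluted by substrate signal) and cells with zero
#' cytoplasmic signal are excluded. A warning is raised when fewer than
#' `min_cells` cells are retained.
#'
#' @param marker Numeric matrix or [multichannel_image()].
#' @param seg A [edge_cytoplasm_regions()] segmentation.
#' @param channel Channel name when `marker` is a multi-channel image.
#' @param min_cells Cell-count warning threshold (default 160).
#' @param exclude_border Drop border-touching cells (default `TRUE`).
#' @param exclude_background_adjacent Drop colony-rim cells whose edge band
#'   borders unassigned background (default `TRUE`).
#'
#' @return An object of class `enrichment_result`: list with `per_cell`
#'   (tibble `cell`, `edge_mean`, `cyto_mean`, `ratio`), `field_mean`, `n`.
#' @export
enrichment_ratio <- function(marker, seg, channel = "marker", min_cells = 160,
                             exclude_border = TRUE,
                             exclude_background_adjacent = TRUE) {
  if (inherits(marker, "multichannel_image")) marker <- get_channel(marker, channel)
  stopifnot(inherits(seg, "cell_segmentation"))
  labels <- sort(unique(seg$cytoplasm[seg$cytoplasm > 0]))
  if (exclude_border) labels <- setdiff(labels, seg$border_cells)
  if (exclude_background_adjacent) {
    labels <- setdiff(labels, seg$background_adjacent)
  }
  if (length(labels) == 0) abort("No cells retained for enrichment analysis.")
  edge_sum <- tapply(marker[seg$edge > 0], seg$edge[seg$edge > 0], mean)
  cyto_sum <- tapply(marker[seg$cytoplasm > 0], seg$cytoplasm[seg$cytoplasm > 0], mean)
  per_cell <- tibble(
    cell = labels,
    edge_mean = as.numeric(edge_sum[as.character(labels)]),
    cyto_mean = as.numeric(cyto_sum[as.character(labels)])
  ) |>
    filter(is.finite(.data$edge_mean), is.finite(.data$cyto_mean))
  zero <- per_cell$cyto_mean <= 0
  if (any(zero)) {
    warn(sprintf("Excluding %d cell(s) with zero cytoplasmic signal.", sum(zero)))
    per_cell <- per_cell[!zero, , drop = FALSE]
  }
  if (nrow(per_cell) == 0) abort("No cells retained for enrichment analysis.")
  per_cell <- mutate(per_cell, ratio = .data$edge_mean / .data$cyto_mean)
  if (nrow(per_cell) < min_cells) {
    warn(sprintf(
      "Only %d cell(s) analyzed; below the recommended minimum of %d per field.",
      nrow(per_cell), min_cells
    ))
  }
  structure(
    list(per_cell = per_cell, field_mean = mean(per_cell$ratio), n = nrow(per_cell)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> field mean edge/cytoplasm ratio %.3f over %d cell(s)\n",
    x$field_mean, x$n
  ))
  invisible(x)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) x$per_cell

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(field_mean = x$field_mean, n = x$n, sem = sem(x$per_cell$ratio))
}
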