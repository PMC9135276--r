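test_that("nuclei segmentation counts separated nuclei and splits touching pairs", {
  gen <- gen_monolayer_image(40, enrichment = 0, seed = 8,
                             image_size_px = c(320L, 320L))
  nuc <- segment_nuclei(gen$image)
  expect_equal(max(nuc), 40)

  expect_error(segment_nuclei(matrix(0, 64, 64)), "No nuclei")

  # two blobs 1.2 diameters apart merge after blurring; watershed splits them
  pair <- matrix(0, 96, 96)
  g <- expand.grid(y = 1:96, x = 1:96)
  r_n <- 8
  for (cx in c(40, 40 + 1.2 * 2 * r_n)) {
    pair[(g$x - cx)^2 + (g$y - 48)^2 <= r_n^2] <- 100
  }
  pair <- EBImage::imageData(EBImage::gblur(EBImage::Image(pair), sigma = 4))
  labels <- segment_nuclei(pair, sigma = 1)
  expect_equal(max(labels), 2)
})

test_that("cell propagation covers the foreground and matches the tessellation truth", {
  # single nucleus on a uniform foreground island claims the whole island
  m <- matrix(1, 96, 96)
  g <- expand.grid(y = 1:96, x = 1:96)
  island <- (g$x - 48)^2 + (g$y - 48)^2 <= 30^2
  m[island] <- 60
  nuc <- matrix(0L, 96, 96)
  nuc[(g$x - 48)^2 + (g$y - 48)^2 <= 6^2] <- 1L
  cells <- propagate_cells(m, nuc, sigma = 1)
  inside <- cells$labels == 1
  expect_gt(sum(inside & island) / sum(island), 0.95)

  gen <- gen_monolayer_image(40, enrichment = 3, seed = 5,
                             image_size_px = c(320L, 320L))
  cells <- propagate_cells(gen$image, segment_nuclei(gen$image))
  tr <- gen$truth$cells
  both <- cells$labels > 0 & tr > 0
  # per-truth-cell majority mapping, then pixel-level agreement
  map <- vapply(seq_len(max(tr)), function(i) {
    v <- cells$labels[tr == i & both]
    if (length(v) == 0) return(0L)
    as.integer(names(which.max(table(v))))
  }, integer(1))
  agreement <- mean(map[tr[both]] == cells$labels[both])
  expect_gte(agreement, 0.9)
  expect_error(propagate_cells(m, matrix(0L, 96, 96)), "At least one nucleus")
})

test_that("edge bands are 9-px annuli for disk cells and partition each cell", {
  lab <- disk_labels(64, 64, 30, size = 128)
  seg <- edge_cytoplasm_regions(lab)
  # expanded by 2, shrunk by 7: annulus between radii 32 and 23
  target <- pi * (32^2 - 23^2)
  expect_lt(abs(sum(seg$edge == 1) - target) / target, 0.05)
  expect_equal(sum(seg$edge > 0 & seg$cytoplasm > 0), 0)

  # a 6-px cell is emptied by the 7-px shrinkage and excluded
  lab2 <- disk_labels(c(40, 100), c(64, 64), c(30, 6), size = 128)
  expect_warning(seg2 <- edge_cytoplasm_regions(lab2), "empties them")
  expect_equal(seg2$excluded, 2L)
  expect_error(
    suppressWarnings(edge_cytoplasm_regions(disk_labels(64, 64, 6, size = 64))),
    "All cells"
  )
})

test_that("overlapping expansions between neighbors resolve to the nearest cell", {
  # two disks 62 px apart with radius 30: 2-px dilations meet in the middle
  lab <- disk_labels(c(34, 96), c(64, 64), c(30, 30), size = 128)
  seg <- edge_cytoplasm_regions(lab)
  mid_left <- seg$edge[64, 65]   # [row=y, col=x]: x = 65 is nearer cell 1
  mid_right <- seg$edge[64, 66]
  expect_equal(mid_left, 1L)
  expect_equal(mid_right, 2L)
})

test_that("enrichment ratio discriminates uniform and edge-enriched markers", {
  field <- function(e) {
    gen <- gen_monolayer_image(40, enrichment = e, seed = 11,
                               image_size_px = c(320L, 320L))
    seg <- suppressWarnings(edge_cytoplasm_regions(
      propagate_cells(gen$image, segment_nuclei(gen$image))
    ))
    suppressWarnings(enrichment_ratio(gen$image, seg, min_cells = 5))
  }
  uniform <- field(0)
  expect_lt(abs(uniform$field_mean - 1), 0.05)
  ring <- field(50)
  expect_gt(ring$field_mean, 5)
})

test_that("the ratio is invariant to linear marker rescaling and monotone in enrichment", {
  gen <- gen_monolayer_image(40, enrichment = 3, seed = 11,
                             image_size_px = c(320L, 320L))
  seg <- suppressWarnings(edge_cytoplasm_regions(
    propagate_cells(gen$image, segment_nuclei(gen$image))
  ))
  marker <- get_channel(gen$image, "marker")
  r1 <- suppressWarnings(enrichment_ratio(marker, seg, min_cells = 5))
  r2 <- suppressWarnings(enrichment_ratio(marker * 7.3, seg, min_cells = 5))
  expect_equal(r2$field_mean, r1$field_mean)
  expect_equal(r2$per_cell$ratio, r1$per_cell$ratio)

  ratios <- vapply(c(0, 1, 3, 5), function(e) {
    gen_e <- gen_monolayer_image(40, enrichment = e, seed = 11,
                                 image_size_px = c(320L, 320L))
    seg_e <- suppressWarnings(edge_cytoplasm_regions(
      propagate_cells(gen_e$image, segment_nuclei(gen_e$image))
    ))
    suppressWarnings(enrichment_ratio(gen_e$image, seg_e, min_cells = 5))$field_mean
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("low cell counts trigger the minimum-cell warning", {
  gen <- gen_monolayer_image(20, enrichment = 0, seed = 4,
                             image_size_px = c(256L, 256L))
  seg <- suppressWarnings(edge_cytoplasm_regions(
    propagate_cells(gen$image, segment_nuclei(gen$image))
  ))
  expect_warning(enrichment_ratio(gen$image, seg), "minimum of 160")
})
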