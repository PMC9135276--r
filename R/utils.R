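# Internal helpers shared across modules.

# All generator randomness flows through this: the global RNG state is
# saved and restored so a call is a pure function of its seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (allow_equal_lower) "[" else "(", format(lower),
      format(upper), if (allow_equal_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s.", what,
      if (length(missing) > 1) "s" else "", paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# EBImage helpers: we keep channels as base matrices in [row = y, col = x]
# orientation; EBImage ops are orientation-agnostic for our purposes.
as_ebimage <- function(mat) EBImage::Image(mat)

otsu_threshold <- function(mat) {
  rng <- range(mat, finite = TRUE)
  if (rng[2] <= rng[1]) {
    abort("Cannot threshold a constant image.")
  }
  scaled <- (mat - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(as_ebimage(scaled), range = c(0, 1))
  th * (rng[2] - rng[1]) + rng[1]
}

# Lower threshold of a three-class Otsu split (exhaustive search over a
# 128-bin histogram). Used where the foreground itself is bimodal (dim
# cytoplasm + bright junction bands) and a two-class split would cut
# through the cells instead of separating them from background.
otsu3_lower <- function(mat, n_bins = 128) {
  rng <- range(mat, finite = TRUE)
  if (rng[2] <= rng[1]) abort("Cannot threshold a constant image.")
  h <- tabulate(pmin(floor((mat - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * (rng[2] - rng[1])
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  total <- cm[n_bins]
  best <- -Inf; best_t1 <- 1
  for (t1 in 1:(n_bins - 2)) {
    w1 <- cw[t1]
    if (w1 <= 0) next
    m1 <- cm[t1] / w1
    for (t2 in (t1 + 1):(n_bins - 1)) {
      w2 <- cw[t2] - cw[t1]
      w3 <- 1 - cw[t2]
      if (w2 <= 0 || w3 <= 0) next
      m2 <- (cm[t2] - cm[t1]) / w2
      m3 <- (total - cm[t2]) / w3
      v <- w1 * m1^2 + w2 * m2^2 + w3 * m3^2
      if (v > best) { best <- v; best_t1 <- t1 }
    }
  }
  rng[1] + best_t1 / n_bins * (rng[2] - rng[1])
}

largest_component <- function(binary) {
  lab <- EBImage::bwlabel(as_ebimage(binary * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  lab == keep
}

# Pixel-center coordinates of a matrix: x runs along columns, y along rows,
# origin at the top-left pixel center (1, 1).
pixel_grid <- function(dim_yx) {
  list(
    x = matrix(rep(seq_len(dim_yx[2]), each = dim_yx[1]), nrow = dim_yx[1]),
    y = matrix(rep(seq_len(dim_yx[1]), times = dim_yx[2]), nrow = dim_yx[1])
  )
}
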