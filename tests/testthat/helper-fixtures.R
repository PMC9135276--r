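# Shared in-code fixtures: small images with analytically known structure.

# Uniform disk of intensity `level` and radius R centered in a size x size
# image (pixel centers at integer coordinates, center at (size+1)/2).
uniform_disk <- function(R, size = 256, level = 1, background = 0) {
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  ctr <- (size + 1) / 2
  m <- matrix(background, size, size)
  m[sqrt((g$x - ctr)^2 + (g$y - ctr)^2) <= R] <- level
  list(mat = m, center = c(x = ctr, y = ctr), R = R)
}

# Radially symmetric image f(r) around the image center.
radial_image <- function(f, size = 256) {
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  ctr <- (size + 1) / 2
  r <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  list(mat = matrix(f(r), size, size), center = c(x = ctr, y = ctr))
}

# One-cell-per-disk label raster: disks of given radii at given centers.
disk_labels <- function(centers_x, centers_y, radii, size = 128) {
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  lab <- matrix(0L, size, size)
  for (i in seq_along(centers_x)) {
    inside <- (g$x - centers_x[i])^2 + (g$y - centers_y[i])^2 <= radii[i]^2
    lab[inside] <- i
  }
  lab
}

# Canonical synthetic protection study conditions (2D, independent action).
independent_protection_spec <- function(noise = 0, n_replicates = 3, seed = 1) {
  protection_spec(
    ic50_sensitive = 1e-8, ic50_resistant = 3e-6,
    concentrations = 10^seq(-10, -4, length.out = 11),
    replicate_noise_sd = noise, n_replicates = n_replicates, seed = seed
  )
}
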