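# Shared fixtures built in code at test time.

# a small closed square lattice of cells: k x k cells of side s with a
# 1-px border grid, surrounded by a margin of background
lattice_border_mask <- function(k = 3, s = 30, margin = 10) {
  n <- k * s + (k + 1) + 2 * margin
  m <- matrix(0L, n, n)
  lines_at <- margin + 1 + (0:k) * (s + 1)
  grid_range <- (margin + 1):(margin + k * s + k + 1)
  m[lines_at, grid_range] <- 1L
  m[grid_range, lines_at] <- 1L
  m
}

# expected cell centres (0-based x, y) of lattice_border_mask
lattice_cell_centers <- function(k = 3, s = 30, margin = 10) {
  first <- margin + (s + 1) / 2
  centers <- first + (0:(k - 1)) * (s + 1)
  expand.grid(x = centers, y = centers)
}

random_centroids <- function(n, w, h, image_id = "rnd") {
  centroid_set(data.frame(x = runif(n, 0, w - 1), y = runif(n, 0, h - 1)),
               image_id = image_id)
}

quick_mosaic <- function(..., seed = 1) {
  synthetic_sample(mosaic_spec(..., seed = seed))
}
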