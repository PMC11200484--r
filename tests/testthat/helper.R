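# Shared fixtures, all built in code.

# Signed distance of a disk, inside-negative.
disk_sdf <- function(n, cx, cy, r) {
  cg <- organoidseg:::coord_grids(n, n)
  sqrt((cg$x - cx)^2 + (cg$y - cy)^2) - r
}

# Noiseless two-phase image: disk of intensity `hi` on background `lo`.
two_phase_disk <- function(n = 128, cx = (n - 1) / 2, cy = (n - 1) / 2,
                           r = 0.3 * n, hi = 0.8, lo = 0.2) {
  d <- disk_sdf(n, cx, cy, r)
  img <- matrix(lo, n, n)
  img[d <= 0] <- hi
  list(grid = image_grid(img), truth = d <= 0, sdf = d)
}

# Centered rectangle as an init_rect object (0-based corner coordinates).
make_rect <- function(cx, cy, hw, hh) {
  structure(list(center = c(x = cx, y = cy), half_width = hw,
                 half_height = hh,
                 corners = c(xmin = cx - hw, ymin = cy - hh,
                             xmax = cx + hw, ymax = cy + hh),
                 seed = c(x = cx, y = cy)),
            class = "init_rect")
}

# Deterministic pseudo-random matrix without touching .Random.seed.
det_matrix <- function(n, m = n, k = 1) {
  idx <- outer(seq_len(n), seq_len(m), function(i, j) i * 7919 + j * 104729 + k * 31)
  matrix((sin(idx) + 1) / 2, n, m)
}

# A smooth deterministic level-set-like field with both signs.
det_levelset <- function(n, k = 1) {
  cg <- organoidseg:::coord_grids(n, n)
  sin(2 * pi * cg$x / n + k) * cos(2 * pi * cg$y / n - k) * n / 6 +
    0.3 * det_matrix(n, n, k)
}
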