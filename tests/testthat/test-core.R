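test_that("smoothed Heaviside matches its three-branch definition", {
  eps <- 1.5
  # independent direct evaluation of each branch
  href <- function(x, e) {
    ifelse(x > e, 1,
           ifelse(x < -e, 0, 0.5 * (1 + x / e + sin(pi * x / e) / pi)))
  }
  xs <- seq(-4, 4, by = 0.01)
  expect_equal(smoothed_heaviside(xs, eps), href(xs, eps), tolerance = 1e-12)
  expect_identical(smoothed_heaviside(0, eps), 0.5)
  expect_identical(smoothed_heaviside(2, eps), 1)
  expect_equal(smoothed_heaviside(0.75, eps), 0.75 + 1 / (2 * pi),
               tolerance = 1e-12)
  # monotone, range [0, 1]
  h <- smoothed_heaviside(xs, eps)
  expect_true(all(diff(h) >= -1e-15))
  expect_true(all(h >= -1e-15 & h <= 1 + 1e-15))
  expect_error(smoothed_heaviside(1, -1), class = "osg_param_error")
})

test_that("smoothed Dirac matches its definition and is the Heaviside derivative", {
  eps <- 1.5
  dref <- function(x, e) ifelse(abs(x) > e, 0, (1 + cos(pi * x / e)) / (2 * e))
  xs <- seq(-4, 4, by = 0.01)
  expect_equal(smoothed_dirac(xs, eps), dref(xs, eps), tolerance = 1e-12)
  expect_equal(smoothed_dirac(0, 2), 1 / 2, tolerance = 1e-12)
  expect_identical(smoothed_dirac(3, eps), 0)
  expect_true(all(smoothed_dirac(xs, eps) >= 0))
  # central-difference derivative of H on a 1e-3 grid
  h <- 1e-3
  xs2 <- seq(-2, 2, by = h)
  num <- (smoothed_heaviside(xs2 + h, eps) - smoothed_heaviside(xs2 - h, eps)) / (2 * h)
  expect_equal(num, smoothed_dirac(xs2, eps), tolerance = 1e-6)
  # unit mass
  for (e in c(0.7, 1.5, 3)) {
    q <- stats::integrate(smoothed_dirac, -e, e, eps = e, abs.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  expect_error(smoothed_dirac(1, 0), class = "osg_param_error")
})

test_that("region means recover two-phase levels and match a brute-force oracle", {
  # large disk so the smoothed band is a small fraction of either region
  tp <- two_phase_disk(128, r = 40)
  st <- compute_region_means(tp$grid, tp$sdf)
  expect_lt(abs(st$c1 - 0.8), 0.01)
  expect_lt(abs(st$c2 - 0.2), 0.01)

  flat <- image_grid(matrix(0.5, 32, 32))
  st2 <- compute_region_means(flat, disk_sdf(32, 15, 15, 8))
  expect_equal(st2$c1, 0.5, tolerance = 1e-12)
  expect_equal(st2$c2, 0.5, tolerance = 1e-12)

  # brute-force per-pixel double loop on a 16x16 image with a rectangle phi
  img <- det_matrix(16)
  phi <- rectangle_to_levelset(make_rect(7, 8, 4, 5), image_grid(img))
  eps <- 1.5
  si <- so <- wi <- wo <- 0
  for (i in 1:16) for (j in 1:16) {
    h <- smoothed_heaviside(phi[i, j], eps)
    wi <- wi + (1 - h); wo <- wo + h
    si <- si + img[i, j] * (1 - h); so <- so + img[i, j] * h
  }
  st3 <- compute_region_means(image_grid(img), phi, eps)
  expect_equal(st3$c1, si / wi, tolerance = 1e-12)
  expect_equal(st3$c2, so / wo, tolerance = 1e-12)

  # degenerate: phi all one sign far from the band
  expect_error(compute_region_means(flat, matrix(10, 32, 32)),
               class = "osg_degenerate_region")
})

test_that("curvature recovers analytic values and the CSI is the sign indicator", {
  # half-plane: flat interface, zero curvature away from the border
  cg <- organoidseg:::coord_grids(64, 64)
  half <- cg$x - 31.5
  k <- compute_curvature(half)$kappa
  expect_lt(max(abs(k[8:56, 8:56])), 1e-6)

  # disks: kappa = +1/R on the zero level set (inside-negative)
  for (R in c(10, 20, 40)) {
    n <- max(64, 3 * R)
    sdf <- disk_sdf(n, (n - 1) / 2, (n - 1) / 2, R)
    k <- compute_curvature(sdf)$kappa
    on_c <- abs(sdf) <= 0.5 & sdf + R >= 3   # zero level, away from center
    expect_true(all(abs(k[on_c] - 1 / R) / (1 / R) < 0.05))
  }

  # CSI: exact indicator of kappa >= 0 when smoothing is off
  phi <- det_levelset(32)
  cv <- compute_curvature(phi, csi_sigma = 0)
  expect_identical(cv$s, matrix(as.numeric(cv$kappa >= 0), 32, 32))
  expect_true(all(cv$s %in% c(0, 1)))
  expect_true(all(cv$s + (1 - cv$s) == 1))
})

test_that("edge indicator has the closed form and is antitone in gradient magnitude", {
  flat <- image_grid(matrix(0.42, 32, 32))
  expect_true(all(edge_indicator(flat) == 1))

  img <- image_grid(det_matrix(48))
  g <- edge_indicator(img, sigma = 1.5)
  expect_true(min(g) > 0 && max(g) <= 1)

  # oracle: dense direct convolution + gradient, plain formula (scale 1)
  n <- 32
  step <- matrix(0, n, n); step[, 17:n] <- 1
  sigma <- 1.5
  rad <- ceiling(4 * sigma)
  k1 <- exp(-0.5 * ((-rad):rad)^2 / sigma^2); k1 <- k1 / sum(k1)
  clampi <- function(i) pmin(pmax(i, 1L), n)
  sm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    acc <- 0
    for (u in (-rad):rad) for (v in (-rad):rad)
      acc <- acc + k1[u + rad + 1] * k1[v + rad + 1] *
        step[clampi(i + u), clampi(j + v)]
    sm[i, j] <- acc
  }
  gx <- (sm[, clampi(1:n + 1)] - sm[, clampi(1:n - 1)]) / 2
  gy <- (sm[clampi(1:n + 1), ] - sm[clampi(1:n - 1), ]) / 2
  m2 <- gx^2 + gy^2
  g1 <- edge_indicator(image_grid(step), sigma = sigma, edge_scale = 1)
  expect_equal(g1, 1 / (1 + m2), tolerance = 1e-10)

  # antitone: sorting by smoothed gradient magnitude reverse-sorts g
  ord <- order(m2)
  expect_true(all(diff(g1[ord]) <= 1e-12))

  expect_error(edge_indicator(img, sigma = 0), class = "osg_param_error")
})
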