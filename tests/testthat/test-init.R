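test_that("Canny outline of simple shapes has the expected geometry", {
  # filled disk: edge count close to the perimeter
  n <- 96
  mask <- disk_sdf(n, 47.5, 47.5, 30) <= 0
  ed <- extract_edges(mask)
  expect_gt(nrow(ed$coords), 0.8 * 2 * pi * 30)
  expect_lt(nrow(ed$coords), 1.3 * 2 * pi * 30)

  # filled rectangle: edges confined to a thin boundary ring
  rmask <- matrix(FALSE, 64, 64); rmask[20:44, 15:49] <- TRUE
  ed2 <- extract_edges(rmask)
  ring <- rmask & !(rbind(rmask[-1, ], FALSE) & rbind(FALSE, rmask[-64, ]) &
                      cbind(rmask[, -1], FALSE) & cbind(FALSE, rmask[, -64]))
  # every edge pixel within 2 px of the true boundary, none deep inside
  d_interior <- matrix(FALSE, 64, 64); d_interior[24:40, 19:45] <- TRUE
  expect_false(any(ed2$edge_mask & d_interior))
  expect_gt(nrow(ed2$coords), 0)

  # empty mask -> empty set
  ed3 <- extract_edges(matrix(FALSE, 32, 32))
  expect_identical(nrow(ed3$coords), 0L)
})

test_that("seed-anchored rectangle reproduces the worked construction", {
  # constructed edge set: B at (140,100), C at (100,70), distractors farther
  coords <- cbind(x = c(140, 100, 20, 100, 200),
                  y = c(100, 70, 100, 240, 200))
  edges <- structure(list(coords = coords, shape = c(256L, 256L)),
                     class = "edge_pixel_set")
  r <- generate_init_rectangle(edges, seed_point(100, 100), expansion = 0.2)
  expect_equal(r$half_width, 48)
  expect_equal(r$half_height, 36)
  expect_equal(unname(r$corners), c(52, 64, 148, 136))

  # zero expansion passes exactly through B and C
  r0 <- generate_init_rectangle(edges, seed_point(100, 100), expansion = 0)
  expect_equal(unname(r0$corners), c(60, 70, 140, 130))

  # centered click in a rasterized disk: half sizes = 1.2 R within 1 px
  n <- 128
  mask <- disk_sdf(n, 63, 63, 40) <= 0
  ed <- extract_edges(mask)
  rd <- generate_init_rectangle(ed, seed_point(63, 63))
  expect_lt(abs(rd$half_width - 48), 1.2 * 1 + 1e-9)
  expect_lt(abs(rd$half_height - 48), 1.2 * 1 + 1e-9)

  # error cases: no edge on the seed's row/column, or seed on an edge
  few <- structure(list(coords = cbind(x = 10, y = 10), shape = c(64L, 64L)),
                   class = "edge_pixel_set")
  expect_error(generate_init_rectangle(few, seed_point(30, 30)),
               class = "osg_init_error")
  on_edge <- structure(list(coords = cbind(x = c(30, 30), y = c(30, 10)),
                            shape = c(64L, 64L)), class = "edge_pixel_set")
  expect_error(generate_init_rectangle(on_edge, seed_point(30, 30)),
               class = "osg_init_error")
  empty <- structure(list(coords = coords[0, , drop = FALSE],
                          shape = c(64L, 64L)), class = "edge_pixel_set")
  expect_error(generate_init_rectangle(empty, seed_point(30, 30)),
               class = "osg_init_error")
})

test_that("rectangle-to-level-set is the exact signed distance to the outline", {
  n <- 64
  grid <- image_grid(matrix(0.5, n, n))
  rect <- make_rect(30, 28, 12, 9)
  phi <- rectangle_to_levelset(rect, grid)
  # center: minus the smaller half-size
  expect_equal(phi[29, 31], -9)
  # boundary pixel
  expect_lt(abs(phi[28 - 9 + 1, 31]), 0.5)
  # corner-adjacent exterior pixel: distance to the nearest corner,
  # against a brute-force min over densely sampled outline points
  px <- 46; py <- 42   # 0-based (x, y), beyond the (42, 37) corner
  ts <- seq(0, 1, length.out = 4000)
  bx <- c(18 + ts * 24, rep(42, 4000), 18 + ts * 24, rep(18, 4000))
  by <- c(rep(19, 4000), 19 + ts * 18, rep(37, 4000), 19 + ts * 18)
  want <- min(sqrt((bx - px)^2 + (by - py)^2))
  expect_equal(phi[py + 1, px + 1], want, tolerance = 1e-3)
  # inside-negative convention
  expect_true(all(phi[(28 - 8):(28 + 8) + 1, (30 - 11):(30 + 11) + 1] < 0))
})

test_that("rectangle generation is equivariant under translation", {
  n <- 128
  base <- disk_sdf(n, 50, 58, 24) <= 0
  shifted <- disk_sdf(n, 50 + 9, 58 + 6, 24) <= 0
  r1 <- generate_init_rectangle(extract_edges(base), seed_point(50, 58))
  r2 <- generate_init_rectangle(extract_edges(shifted), seed_point(59, 64))
  expect_equal(unname(r2$corners - r1$corners), c(9, 6, 9, 6), tolerance = 1e-9)
})

test_that("pre-segmentation captures the foreground and rejects blank images", {
  spec <- phantom_spec(size = c(128L, 128L),
                       organoids = list(organoid_spec(50, 64, 30),
                                        organoid_spec(95, 50, 20)),
                       seed = 7L)
  scene <- generate_phantom(spec)
  mask <- presegment_cv(scene$grid)
  un <- scene$masks[[1]] | scene$masks[[2]]
  expect_gte(sum(mask & un) / sum(un), 0.95)
  # deterministic
  expect_identical(mask, presegment_cv(scene$grid))

  blank <- image_grid(matrix(0.5, 64, 64))
  expect_error(presegment_cv(blank), class = "osg_init_error")
})

test_that("the full one-click pipeline is deterministic", {
  spec <- phantom_spec(size = c(128L, 128L),
                       organoids = list(organoid_spec(64, 64, 30)),
                       seed = 11L)
  scene <- generate_phantom(spec)
  a <- auto_initialize(scene$grid, c(64, 64))
  b <- auto_initialize(scene$grid, c(64, 64))
  expect_identical(a$phi0, b$phi0)
  expect_identical(a$rect$corners, b$rect$corners)
  # the rectangle strictly contains the organoid
  expect_true(all(a$phi0[scene$masks[[1]]] < 0))
  # out-of-bounds seed is rejected with the bound in the message
  expect_error(auto_initialize(scene$grid, c(127, 64)),
               class = "osg_param_error")
})
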