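#' Whole-image Chan-Vese pre-segmentation
#'
#' First step of the automatic initialization: segment the whole image with
#' the Chan-Vese model so the outline of every object (including the fused
#' outline of overlapping organoids) becomes available for edge extraction.
#'
#' The image is Gaussian-blurred first (`presmooth_sigma`) so that the
#' strongly inhomogeneous organoid interiors do not punch holes into the
#' foreground phase, the evolution starts from a tiled pattern (period
#' `period` px) so every object is near an initial contour, the foreground
#' is taken as the phase with the smaller area (organoids occupy a minority
#' of a dish image), and remaining interior holes are filled.
#'
#' @param grid [image_grid()].
#' @param params [cv_params()]; default `lambda1 = lambda2 = 1`,
#'   `mu_cv = 0.05`, 300 iterations.
#' @param period tile period of the initial level-set pattern (px).
#' @param presmooth_sigma Gaussian sd of the pre-blur (px).
#' @return logical foreground mask.
#' @export
presegment_cv <- function(grid, params = NULL, period = 40,
                          presmooth_sigma = 3) {
  grid <- as_image_grid(grid)
  if (is.null(params))
    params <- cv_params(mu_cv = 0.05, lambda1 = 1, lambda2 = 1,
                        max_iterations = 300L, snapshot_stride = 0L)
  work <- image_grid(cpp_gauss_blur(grid$intensities, presmooth_sigma),
                     grid$bit_depth)
  cg <- coord_grids(grid$height, grid$width)
  phi0 <- 2 * sin(2 * pi * cg$x / period) * sin(2 * pi * cg$y / period)
  res <- tryCatch(cv_evolve(phi0, work, params),
                  osg_degenerate_region = function(e) NULL)
  if (is.null(res) || all(res$mask) || !any(res$mask))
    stop_osg(paste0("pre-segmentation produced an empty mask; ",
                    "adjust the Chan-Vese parameters or supply a manual rectangle"),
             "osg_init_error")
  inside <- res$mask
  # foreground = minority phase
  if (sum(inside) > length(inside) / 2) inside <- !inside
  if (!any(inside))
    stop_osg("pre-segmentation produced an empty mask", "osg_init_error")
  # a featureless image yields phases with no contrast: nothing to segment
  if (abs(mean(grid$intensities[inside]) - mean(grid$intensities[!inside])) < 0.02)
    stop_osg(paste0("pre-segmentation found no foreground/background contrast; ",
                    "the image appears featureless"), "osg_init_error")
  cpp_fill_holes(inside)
}

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian blur, central-difference gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding (8-connected).  Thresholds are absolute values of
#' the gradient magnitude.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian sd (px).
#' @param low,high hysteresis thresholds on gradient magnitude.
#' @return logical edge mask.
#' @export
canny <- function(img, sigma = 1, low = 0.1, high = 0.2) {
  sm <- cpp_gauss_blur(img, sigma)
  gr <- cpp_grad(sm)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  nms <- cpp_canny_nms(mag, gr$gx, gr$gy)
  cpp_hysteresis(nms, low, high)
}

#' Extract outline edge pixels from a binary mask
#'
#' Applies the Canny operator to the float-cast mask; for a filled shape the
#' result is its outline.  Thresholds are uncritical on a binary input.
#'
#' @param mask logical (or 0/1) matrix.
#' @param low,high hysteresis thresholds.
#' @param sigma Gaussian sd for the Canny blur.
#' @return an `edge_pixel_set`: list with `coords` (two-column matrix of
#'   0-based `x`, `y` pixel coordinates; zero rows if no edges), `edge_mask`
#'   and `shape`.
#' @export
extract_edges <- function(mask, low = 0.1, high = 0.2, sigma = 1) {
  if (!is.matrix(mask)) stop_osg("`mask` must be a matrix", "osg_contract_error")
  m <- matrix(as.numeric(as.logical(mask)), nrow(mask), ncol(mask))
  em <- canny(m, sigma = sigma, low = low, high = high)
  idx <- which(em, arr.ind = TRUE)
  coords <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  structure(list(coords = coords, edge_mask = em, shape = dim(mask)),
            class = "edge_pixel_set")
}

#' Seed point
#'
#' The user's click at the inner center of the organoid to segment.
#' Coordinates are 0-based, `x` = column, `y` = row, and must lie at least
#' 2 px inside the image.
#'
#' @param x,y pixel coordinates (0-based).
#' @param shape image dimensions `c(height, width)` for bounds checking
#'   (optional).
#' @return a `seed_point`.
#' @export
seed_point <- function(x, y, shape = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!is.null(shape)) {
    if (x < 2 || y < 2 || x > shape[2] - 3 || y > shape[1] - 3)
      stop_osg(sprintf(
        "seed point (%g, %g) must lie inside the %d x %d image with a 2 px margin",
        x, y, shape[1], shape[2]), "osg_param_error")
  }
  structure(list(x = x, y = y), class = "seed_point")
}

#' Seed-anchored initial rectangle
#'
#' From the outline edge set, find the edge pixel `B` nearest to the seed
#' `A` on the same raster row (searching both directions) and the edge
#' pixel `C` nearest on the same column, expand the distances `|AB|` and
#' `|AC|` by `expansion` (20 percent by default), and return the rectangle
#' centered on `A` with half-width `(1+expansion)|AB|` and half-height
#' `(1+expansion)|AC|`, clipped to the image with a 1 px margin.  Ties are
#' broken toward the smaller coordinate.
#'
#' @param edges an `edge_pixel_set` from [extract_edges()].
#' @param seed a [seed_point()] (or `c(x, y)`).
#' @param expansion fractional expansion of the half-sizes.
#' @return an `init_rect`: list with `center`, `half_width`, `half_height`,
#'   and 0-based `corners` (`xmin`, `ymin`, `xmax`, `ymax`).
#' @export
generate_init_rectangle <- function(edges, seed, expansion = 0.2) {
  if (!inherits(seed, "seed_point")) seed <- seed_point(seed[1], seed[2])
  co <- edges$coords
  if (is.null(co) || nrow(co) == 0L)
    stop_osg("edge set is empty; re-click or supply a manual rectangle",
             "osg_init_error")
  on_row <- co[co[, "y"] == round(seed$y) & co[, "x"] != round(seed$x), , drop = FALSE]
  on_col <- co[co[, "x"] == round(seed$x) & co[, "y"] != round(seed$y), , drop = FALSE]
  if (nrow(on_row) == 0L || nrow(on_col) == 0L)
    stop_osg(paste0("no edge pixel found on the seed's ",
                    if (nrow(on_row) == 0L) "row" else "column",
                    "; re-click or supply a manual rectangle"),
             "osg_init_error")
  pick_nearest <- function(cand, coord, center) {
    d <- abs(cand[, coord] - center)
    hit <- which(d == min(d))
    if (length(hit) > 1L) hit <- hit[which.min(cand[hit, coord])]
    min(d)
  }
  ab <- pick_nearest(on_row, "x", seed$x)
  ac <- pick_nearest(on_col, "y", seed$y)
  if (ab == 0 || ac == 0)
    stop_osg("seed point lies on an edge; re-click inside the organoid",
             "osg_init_error")
  hw <- (1 + expansion) * ab
  hh <- (1 + expansion) * ac
  sh <- edges$shape
  xmin <- max(1, seed$x - hw); xmax <- min(sh[2] - 2, seed$x + hw)
  ymin <- max(1, seed$y - hh); ymax <- min(sh[1] - 2, seed$y + hh)
  if (xmax <= xmin || ymax <= ymin)
    stop_osg("degenerate initial rectangle after clipping", "osg_init_error")
  structure(list(center = c(x = (xmin + xmax) / 2, y = (ymin + ymax) / 2),
                 half_width = (xmax - xmin) / 2,
                 half_height = (ymax - ymin) / 2,
                 corners = c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
                 seed = c(x = seed$x, y = seed$y)),
            class = "init_rect")
}

#' Signed distance to a rectangle boundary
#'
#' Exact Euclidean signed distance to the rectangle outline, negative
#' inside (inside-negative convention), for use as the initial level-set
#' field.
#'
#' @param rect an `init_rect` from [generate_init_rectangle()].
#' @param grid [image_grid()].
#' @return level-set field matrix.
#' @export
rectangle_to_levelset <- function(rect, grid) {
  grid <- as_image_grid(grid)
  if (rect$half_width <= 0 || rect$half_height <= 0)
    stop_osg("degenerate rectangle", "osg_init_error")
  cg <- coord_grids(grid$height, grid$width)
  qx <- abs(cg$x - rect$center["x"]) - rect$half_width
  qy <- abs(cg$y - rect$center["y"]) - rect$half_height
  outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2)
  inside <- pmin(pmax(qx, qy), 0)
  outside + inside
}

#' One-click automatic initialization
#'
#' Full pipeline: Chan-Vese pre-segmentation of the whole image, Canny
#' outline extraction, seed-anchored rectangle with 20 percent expansion,
#' and conversion to a signed-distance level-set field.
#'
#' @param grid [image_grid()].
#' @param seed [seed_point()] or `c(x, y)` (0-based).
#' @param expansion rectangle expansion fraction.
#' @param preseg_params optional [cv_params()] for the pre-segmentation.
#' @return list with `phi0`, `rect`, `edges`, `preseg_mask`.
#' @export
auto_initialize <- function(grid, seed, expansion = 0.2,
                            preseg_params = NULL) {
  grid <- as_image_grid(grid)
  if (!inherits(seed, "seed_point"))
    seed <- seed_point(seed[1], seed[2], shape = c(grid$height, grid$width))
  mask <- presegment_cv(grid, preseg_params)
  edges <- extract_edges(mask)
  rect <- generate_init_rectangle(edges, seed, expansion)
  phi0 <- rectangle_to_levelset(rect, grid)
  list(phi0 = phi0, rect = rect, edges = edges, preseg_mask = mask)
}
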