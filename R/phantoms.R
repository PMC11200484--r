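#' Organoid description for a phantom scene
#'
#' Organoids are rendered as disks/ellipses (organoid growth is smoothly
#' round or oval): a dark smooth boundary ring around a strongly
#' inhomogeneous interior (seeded correlated texture) on a bright
#' homogeneous background, the main intensity structure of a bright-field
#' dish image.
#'
#' @param cx,cy center (0-based pixel coordinates, x = column).
#' @param a,b semi-axes in px (`b` defaults to `a`: a disk).
#' @param theta orientation in radians.
#' @param interior_level mean interior intensity.
#' @param texture_sd standard deviation of the correlated interior texture.
#' @param texture_corr correlation length (Gaussian sd, px) of the texture.
#' @param ring_level intensity of the boundary ring.
#' @param ring_width ring width in px.
#' @return an `organoid_spec` list.
#' @export
organoid_spec <- function(cx, cy, a, b = a, theta = 0,
                          interior_level = 0.55, texture_sd = 0.2,
                          texture_corr = 1.0, ring_level = 0.25,
                          ring_width = 2.5) {
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta,
                 interior_level = interior_level, texture_sd = texture_sd,
                 texture_corr = texture_corr, ring_level = ring_level,
                 ring_width = ring_width),
            class = "organoid_spec")
}

#' Phantom scene specification
#'
#' Generative description of a synthetic bright-field organoid scene:
#' homogeneous bright background, organoids per [organoid_spec()] (the
#' shared boundary dissolves where organoids overlap), small dark dish
#' impurities placed in the background, blurry out-of-focus distractors, a
#' mild global blur, and pixel noise.  Rendering is fully determined by the
#' spec including its `seed`.
#'
#' @param size `c(height, width)` in px.
#' @param background background intensity level.
#' @param noise_sd Gaussian pixel noise sd (applied last).
#' @param organoids list of [organoid_spec()] objects.
#' @param impurities list with `n`, `r_range = c(min, max)` and `level`
#'   (auto-placed in the background with the scene seed), or `NULL`.
#' @param distractors list of out-of-focus blobs, each
#'   `list(cx, cy, r, contrast, blur)`, or `NULL`.
#' @param blur_sd global blur sd (px) emulating the imaging optics.
#' @param seed integer RNG seed.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L), background = 0.85,
                         noise_sd = 0.01, organoids = list(),
                         impurities = NULL, distractors = NULL,
                         blur_sd = 0.8, seed = 1L) {
  if (length(organoids) == 0L)
    stop_osg("a phantom needs at least one organoid", "osg_spec_error")
  organoids <- lapply(organoids, function(o) {
    if (!inherits(o, "organoid_spec")) o <- do.call(organoid_spec, o)
    o
  })
  size <- as.integer(size)
  for (o in organoids) {
    r <- max(o$a, o$b)
    if (o$cx < -r || o$cx > size[2] + r || o$cy < -r || o$cy > size[1] + r)
      stop_osg("organoid lies entirely outside the frame", "osg_spec_error")
  }
  if (!is.null(impurities)) {
    if (is.null(impurities$n)) stop_osg("impurities need `n`", "osg_spec_error")
    impurities <- list(n = as.integer(impurities$n),
                       r_range = as.numeric(impurities$r_range %||% c(2, 4)),
                       level = impurities$level %||% 0.6)
  }
  if (!is.null(distractors))
    distractors <- lapply(distractors, function(d)
      list(cx = d$cx, cy = d$cy, r = d$r,
           contrast = d$contrast %||% -0.08, blur = d$blur %||% 6))
  structure(list(size = size, background = background, noise_sd = noise_sd,
                 organoids = organoids, impurities = impurities,
                 distractors = distractors, blur_sd = blur_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Elliptical radius field rho (1 on the boundary) and approximate signed
# distance in px for one organoid.
organoid_fields <- function(o, cg) {
  dx <- cg$x - o$cx
  dy <- cg$y - o$cy
  u <- cos(o$theta) * dx + sin(o$theta) * dy
  v <- -sin(o$theta) * dx + cos(o$theta) * dy
  rho <- sqrt((u / o$a)^2 + (v / o$b)^2)
  list(rho = rho, dist = (rho - 1) * min(o$a, o$b))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a phantom scene
#'
#' Renders the spec deterministically: background, organoid interiors
#' (later organoids overwrite earlier ones inside overlaps), boundary rings
#' (suppressed inside other organoids, so the shared boundary dissolves in
#' overlap regions), impurities, blurred distractors, global blur, then
#' pixel noise, clipped to `[0, 1]`.  Ground-truth masks are the
#' un-composited analytic ellipse masks, one per organoid.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_scene`: list with `grid` ([image_grid()]), `masks`
#'   (list of logical matrices), `background_mask` (pixels untouched by any
#'   object, for noise statistics), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_osg("not a phantom_spec", "osg_spec_error")
  h <- spec$size[1]; w <- spec$size[2]
  cg <- coord_grids(h, w)
  with_seed(spec$seed, {
    img <- matrix(spec$background, h, w)
    fields <- lapply(spec$organoids, organoid_fields, cg = cg)
    masks <- lapply(fields, function(f) f$rho <= 1)

    # interiors, in list order (later wins inside overlaps)
    for (k in seq_along(spec$organoids)) {
      o <- spec$organoids[[k]]
      tex <- cpp_gauss_blur(matrix(rnorm(h * w), h, w), o$texture_corr)
      tex <- tex / stats::sd(tex) * o$texture_sd
      m <- masks[[k]]
      img[m] <- (o$interior_level + tex)[m]
    }
    # boundary rings; a ring pixel strictly inside another organoid is
    # dissolved (overlap region shows no internal boundary)
    for (k in seq_along(spec$organoids)) {
      o <- spec$organoids[[k]]
      ring <- fields[[k]]$dist >= -o$ring_width & fields[[k]]$dist <= 0
      for (j in seq_along(spec$organoids)) if (j != k) {
        oj <- spec$organoids[[j]]
        ring <- ring & !(fields[[j]]$dist < -oj$ring_width)
      }
      img[ring] <- o$ring_level
    }

    clutter <- matrix(FALSE, h, w)  # impurity + distractor influence
    if (!is.null(spec$impurities) && spec$impurities$n > 0L) {
      for (i in seq_len(spec$impurities$n)) {
        placed <- FALSE
        for (try in 1:100) {
          cx <- runif(1, 8, w - 9)
          cy <- runif(1, 8, h - 9)
          r <- runif(1, spec$impurities$r_range[1], spec$impurities$r_range[2])
          clear <- min(vapply(fields, function(f)
            f$dist[round(cy) + 1, round(cx) + 1], 0))
          if (clear > r + 6) { placed <- TRUE; break }
        }
        if (!placed) next
        d2 <- (cg$x - cx)^2 + (cg$y - cy)^2
        blob <- d2 <= r^2
        img[blob] <- spec$impurities$level
        clutter <- clutter | (d2 <= (r + 4)^2)
      }
    }
    if (!is.null(spec$distractors)) {
      for (d in spec$distractors) {
        disk <- matrix(0, h, w)
        d2 <- (cg$x - d$cx)^2 + (cg$y - d$cy)^2
        disk[d2 <= d$r^2] <- 1
        img <- img + d$contrast * cpp_gauss_blur(disk, d$blur)
        clutter <- clutter | (d2 <= (d$r + 3 * d$blur)^2)
      }
    }

    if (spec$blur_sd > 0) img <- cpp_gauss_blur(img, spec$blur_sd)
    if (spec$noise_sd > 0) img <- img + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)

    near_organoid <- Reduce(`|`, lapply(fields, function(f) f$dist < 5))
    structure(list(grid = image_grid(img, bit_depth = 16L),
                   masks = masks,
                   background_mask = !near_organoid & !clutter,
                   spec = spec),
              class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d x %d px, %d organoid(s), seed %d\n",
              x$grid$height, x$grid$width, length(x$masks), x$spec$seed))
  invisible(x)
}

#' Default phantom benchmark suite
#'
#' Ten fixed-seed scenes, two per difficulty archetype observed in
#' bright-field organoid dishes: partially overlapping organoids
#' (`overlap`), a blurry out-of-focus neighbour (`out_of_focus`), dark dish
#' impurities (`impurities`), organoids with adjacent boundaries
#' (`adjacent`), and a weak target boundary (`weak_boundary`).  Each entry
#' documents the target organoid index, the seed point at its inner center,
#' and the recommended data weight `lambda1`, assigned by difficulty class
#' the way the weight is tuned on real images: 3.5 in general, 2.5 where
#' the distractor's intensity is close to the background (the out-of-focus
#' shadow scenes), and 3.0 where the main influence is a neighbouring
#' organoid boundary (the adjacent scenes).
#'
#' @return list of 10 scene entries, each
#'   `list(name, archetype, spec, target, seed_point, lambda1)`.
#' @export
default_phantom_suite <- function() {
  sc <- function(name, archetype, seed, organoids, target, lambda1 = 3.5,
                 impurities = NULL, distractors = NULL) {
    spec <- phantom_spec(organoids = organoids, impurities = impurities,
                         distractors = distractors, seed = seed)
    o <- spec$organoids[[target]]
    list(name = name, archetype = archetype, spec = spec, target = target,
         seed_point = c(x = round(o$cx), y = round(o$cy)), lambda1 = lambda1)
  }
  list(
    sc("overlap_1", "overlap", 101,
       list(organoid_spec(128, 96, 48),
            organoid_spec(139, 173, 44)), target = 1),
    sc("overlap_2", "overlap", 102,
       list(organoid_spec(120, 100, 52, 44, theta = 0.3),
            organoid_spec(100, 178, 46)), target = 1),
    sc("out_of_focus_1", "out_of_focus", 103,
       list(organoid_spec(110, 128, 50)), target = 1,
       lambda1 = 2.5,
       distractors = list(list(cx = 205, cy = 80, r = 45,
                               contrast = -0.08, blur = 6))),
    sc("out_of_focus_2", "out_of_focus", 104,
       list(organoid_spec(140, 130, 46, 54, theta = -0.4)), target = 1,
       lambda1 = 2.5,
       distractors = list(list(cx = 60, cy = 200, r = 40,
                               contrast = -0.1, blur = 6))),
    sc("impurities_1", "impurities", 105,
       list(organoid_spec(128, 128, 52)), target = 1,
       impurities = list(n = 3, r_range = c(2, 4), level = 0.6)),
    sc("impurities_2", "impurities", 106,
       list(organoid_spec(130, 120, 55, 47, theta = 0.5)), target = 1,
       impurities = list(n = 4, r_range = c(2, 4), level = 0.6)),
    sc("adjacent_1", "adjacent", 107,
       list(organoid_spec(100, 128, 46),
            organoid_spec(193, 128, 42)), target = 1, lambda1 = 3.0),
    sc("adjacent_2", "adjacent", 108,
       list(organoid_spec(128, 100, 44),
            organoid_spec(128, 187, 40, 36)), target = 1, lambda1 = 3.0),
    sc("weak_boundary_1", "weak_boundary", 109,
       list(organoid_spec(128, 128, 50, ring_level = 0.4, ring_width = 2)),
       target = 1),
    sc("weak_boundary_2", "weak_boundary", 110,
       list(organoid_spec(124, 132, 52, 46, theta = 0.2, ring_level = 0.42)),
       target = 1)
  )
}
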