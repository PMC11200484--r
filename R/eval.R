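#' Dice overlap score
#'
#' `Dice = 2 |A n G| / (|A| + |G|)` with exact integer pixel counts, between
#' a segmentation mask `A` and a ground-truth mask `G`.
#'
#' @param A,G logical (or 0/1) matrices of the same shape; `G` nonempty.
#' @return a `dice_score`: list with `value`, `area_a`, `area_g`,
#'   `overlap`.
#' @export
dice <- function(A, G) {
  if (!identical(dim(A), dim(G)))
    stop_osg("masks must have the same shape", "osg_contract_error")
  A <- as.logical(A); G <- as.logical(G)
  na <- sum(A); ng <- sum(G)
  if (na + ng == 0L)
    stop_osg("Dice is undefined for two empty masks", "osg_contract_error")
  ov <- sum(A & G)
  structure(list(value = 2 * ov / (na + ng),
                 area_a = na, area_g = ng, overlap = ov),
            class = "dice_score")
}

#' @export
print.dice_score <- function(x, ...) {
  cat(sprintf("Dice = %.4f  (|A|=%d, |G|=%d, |AnG|=%d)\n",
              x$value, x$area_a, x$area_g, x$overlap))
  invisible(x)
}

#' Convexity deficiency of a binary mask
#'
#' `1 - area(mask) / area(convex hull of mask)`, computed on pixel centers:
#' the hull polygon of the `TRUE` pixel centers is rasterized back to pixels
#' (a center on the hull boundary counts as inside), so a mask equal to its
#' own hull raster scores exactly 0.  Values are in `[0, 1)`; a convex shape
#' scores ~0 up to rasterization.
#'
#' @param mask logical matrix, nonempty.
#' @return scalar deficiency.
#' @export
convexity_deficiency <- function(mask) {
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop_osg("convexity deficiency is undefined for an empty mask",
             "osg_contract_error")
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  hull <- grDevices::chull(pts)
  if (length(hull) < 3L) return(0)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  # candidate pixels: hull bounding box; keep centers inside every half-plane
  xs <- seq(min(hx), max(hx)); ys <- seq(min(hy), max(hy))
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- rep(TRUE, length(px))
  n <- length(hull)
  # chull returns vertices clockwise in (x, y); orient via signed area
  area2 <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)
  ccw <- area2 > 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & if (ccw) cr >= -1e-9 else cr <= 1e-9
  }
  hull_area <- sum(inside)
  1 - nrow(idx) / hull_area
}

#' Run the comparative benchmark over a phantom suite
#'
#' For each scene: generate the phantom, run the one-click initialization
#' from the documented seed point, run each requested model from the same
#' initial rectangle, and score the final mask against the target
#' organoid's ground-truth mask (Dice) and for convexity deficiency.  A
#' model failure is recorded as a row with its termination reason, not an
#' abort.  Deterministic end-to-end.
#'
#' Scene-specific `lambda1` values documented in the suite are applied to
#' the proposed model (mirroring per-image tuning of the data weight);
#' baselines run with fixed parameters.
#'
#' @param suite list of scene entries as from [default_phantom_suite()].
#' @param models character subset of `c("proposed", "cplse", "cv")`.
#' @param params named list of parameter objects per model (defaults:
#'   [evolution_params()], [cplse_params()], [cv_params()]).
#' @param verbose print per-scene progress.
#' @return a `benchmark_report`: list with `rows` (data.frame: scene,
#'   archetype, model, dice, deficiency, iterations, reason), `summary`
#'   (per-model mean/sd Dice, mean iterations) and `timing` (informational
#'   wall-clock seconds, deliberately kept out of `rows` so reports are
#'   byte-deterministic).
#' @export
run_benchmark <- function(suite = default_phantom_suite(),
                          models = c("proposed", "cplse", "cv"),
                          params = list(), verbose = FALSE) {
  if (length(suite) == 0L) stop_osg("suite is empty", "osg_contract_error")
  models <- match.arg(models, c("proposed", "cplse", "cv"), several.ok = TRUE)
  defaults <- list(proposed = evolution_params(),
                   cplse = cplse_params(),
                   cv = cv_params())
  params <- utils::modifyList(defaults, params)
  rows <- list()
  timing <- list()  # wall-clock is informational only; kept out of `rows`
                    # so reports are byte-deterministic
  for (sc in suite) {
    scene <- generate_phantom(sc$spec)
    init <- auto_initialize(scene$grid, sc$seed_point)
    truth <- scene$masks[[sc$target]]
    for (m in models) {
      p <- params[[m]]
      if (m == "proposed" && !is.null(sc$lambda1)) p$lambda1 <- sc$lambda1
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        switch(m,
               proposed = evolve_proposed(init$phi0, scene$grid, p),
               cplse = cplse_evolve(init$phi0, scene$grid, p),
               cv = cv_evolve(init$phi0, scene$grid, p)),
        organoidseg_error = function(e) e)
      secs <- proc.time()[["elapsed"]] - t0
      timing[[length(timing) + 1L]] <- data.frame(
        scene = sc$name, model = m, seconds = round(secs, 2))
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          scene = sc$name, archetype = sc$archetype, model = m,
          dice = NA_real_, deficiency = NA_real_, iterations = NA_integer_,
          reason = conditionMessage(res))
        next
      }
      dv <- if (any(res$mask)) dice(res$mask, truth)$value else 0
      cd <- if (any(res$mask)) convexity_deficiency(res$mask) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scene = sc$name, archetype = sc$archetype, model = m,
        dice = dv, deficiency = cd, iterations = res$iterations,
        reason = res$reason)
      if (verbose)
        message(sprintf("%-16s %-8s dice=%.3f def=%.3f it=%d (%s)",
                        sc$name, m, dv, cd, res$iterations, res$reason))
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  agg <- do.call(rbind, lapply(split(rows, rows$model), function(d)
    data.frame(model = d$model[1],
               mean_iterations = mean(d$iterations, na.rm = TRUE),
               mean_dice = mean(d$dice, na.rm = TRUE),
               sd_dice = stats::sd(d$dice, na.rm = TRUE),
               mean_deficiency = mean(d$deficiency, na.rm = TRUE))))
  ord <- intersect(c("cv", "cplse", "proposed"), agg$model)
  agg <- agg[match(ord, agg$model), ]
  rownames(agg) <- NULL
  timing <- do.call(rbind, timing)
  rownames(timing) <- NULL
  structure(list(rows = rows, summary = agg, timing = timing),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark over", length(unique(x$rows$scene)), "scenes\n")
  cat(sprintf("%-10s %8s %18s %12s\n", "model", "iter", "Dice (mean+/-sd)",
              "deficiency"))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("%-10s %8.0f %9.2f%%+/-%.2f%% %12.4f\n", s$model,
                s$mean_iterations, 100 * s$mean_dice, 100 * s$sd_dice,
                s$mean_deficiency))
  }
  invisible(x)
}

#' Write a benchmark report to CSV / JSON / plain-text summary
#'
#' Deterministic output (no timestamps): `report.csv` with one row per
#' (scene, model), `report.json` with rows and summary, and `summary.txt`
#' echoing the printed per-model table.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  json <- file.path(dir, "report.json")
  txt <- file.path(dir, "summary.txt")
  utils::write.csv(report$rows, csv, row.names = FALSE)
  jsonlite::write_json(list(rows = report$rows, summary = report$summary),
                       json, digits = NA, auto_unbox = TRUE)
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(c(csv = csv, json = json, summary = txt))
}
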