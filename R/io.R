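#' Load a grayscale image
#'
#' Reads NetPBM images: PGM (`P2` ASCII / `P5` binary, 8- or 16-bit) and
#' PPM (`P3`/`P6`, converted to grayscale by Rec. 601 luminance).
#' Intensities are normalized to `[0, 1]` by dividing by the file's maxval;
#' the original bit depth is recorded on the returned grid.
#'
#' @param path file path.
#' @return an [image_grid()].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop_osg(sprintf("cannot read '%s': no such file", path), "osg_io_error")
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 2L || rawToChar(raw[1]) != "P")
    stop_osg(sprintf("'%s' is not a NetPBM (PGM/PPM) image; supported: P2/P3/P5/P6",
                     path), "osg_io_error")
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_osg(sprintf("unsupported NetPBM flavour '%s' in '%s'", magic, path),
             "osg_io_error")
  # tokenize the header: width, height, maxval; '#' starts a comment
  pos <- 3L
  tokens <- character(0)
  while (length(tokens) < 3L && pos <= length(raw)) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") {
      while (pos <= length(raw) && rawToChar(raw[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      tok <- ""
      while (pos <= length(raw) && grepl("[0-9]", rawToChar(raw[pos]))) {
        tok <- paste0(tok, rawToChar(raw[pos]))
        pos <- pos + 1L
      }
      tokens <- c(tokens, tok)
    } else pos <- pos + 1L
  }
  if (length(tokens) < 3L)
    stop_osg(sprintf("malformed NetPBM header in '%s'", path), "osg_io_error")
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * channels
  if (magic %in% c("P2", "P3")) {
    txt <- rawToChar(raw[pos:length(raw)])
    vals <- as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  } else {
    pos <- pos + 1L  # single whitespace after maxval
    if (maxval < 256L) {
      vals <- as.numeric(as.integer(raw[pos:(pos + n - 1L)]))
    } else {
      hi <- as.integer(raw[seq(pos, pos + 2L * n - 2L, by = 2L)])
      lo <- as.integer(raw[seq(pos + 1L, pos + 2L * n - 1L, by = 2L)])
      vals <- 256 * hi + lo
    }
  }
  if (length(vals) < n)
    stop_osg(sprintf("'%s': expected %d samples, found %d", path, n, length(vals)),
             "osg_io_error")
  vals <- vals[seq_len(n)]
  if (channels == 3L) {
    r <- vals[seq(1, n, 3)]; g <- vals[seq(2, n, 3)]; b <- vals[seq(3, n, 3)]
    vals <- 0.299 * r + 0.587 * g + 0.114 * b
  }
  mat <- matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  image_grid(pmin(pmax(mat, 0), 1),
             bit_depth = if (maxval > 255L) 16L else 8L)
}

#' Save a grayscale image as PGM
#'
#' @param img an [image_grid()] or `[0, 1]` matrix.
#' @param path output path.
#' @param maxval 255 (8-bit) or 65535 (16-bit).
#' @param ascii write ASCII `P2` instead of binary `P5`.
#' @return invisibly, `path`.
#' @export
save_image <- function(img, path, maxval = 65535L, ascii = FALSE) {
  mat <- if (inherits(img, "image_grid")) img$intensities else img
  vals <- round(pmin(pmax(mat, 0), 1) * maxval)
  write_netpbm(t(vals), dim(mat)[2], dim(mat)[1], maxval, path,
               magic = if (ascii) "P2" else "P5")
  invisible(path)
}

# vals: samples in file (row-major) order; for grayscale pass t(matrix).
write_netpbm <- function(vals, w, h, maxval, path, magic) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_osg(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
             "osg_io_error"))
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n%d\n", magic, w, h, maxval), con,
            eos = NULL)
  v <- as.integer(vals)
  if (magic %in% c("P2", "P3")) {
    writeChar(paste(v, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else if (maxval < 256L) {
    writeBin(as.raw(v), con)
  } else {
    bytes <- raw(2L * length(v))
    bytes[seq(1, length(bytes), 2)] <- as.raw(v %/% 256L)
    bytes[seq(2, length(bytes), 2)] <- as.raw(v %% 256L)
    writeBin(bytes, con)
  }
}

#' Save / load a binary mask
#'
#' Masks are 8-bit PGM with 255 = inside, 0 = outside; the round trip is
#' lossless.
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `save_mask`: invisibly `path`; `load_mask`: logical matrix.
#' @export
save_mask <- function(mask, path) {
  v <- matrix(0, nrow(mask), ncol(mask))
  v[mask != 0] <- 255
  write_netpbm(t(v), ncol(mask), nrow(mask), 255L, path, "P5")
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  load_image(path)$intensities >= 0.5
}

#' Contour pixels of a level-set field
#'
#' The inner boundary of the inside region: pixels with `phi < 0` having a
#' 4-neighbor with `phi >= 0` (i.e. the negative side of every sign change
#' along rows and columns).
#'
#' @param phi level-set field.
#' @return logical matrix.
#' @export
contour_mask <- function(phi) {
  neg <- phi < 0
  nr <- nrow(phi); nc <- ncol(phi)
  shift <- function(m, di, dj) {
    out <- m
    si <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    sj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    m[si, sj]
  }
  any_pos <- !shift(neg, 1L, 0L) | !shift(neg, -1L, 0L) |
    !shift(neg, 0L, 1L) | !shift(neg, 0L, -1L)
  neg & any_pos
}

#' Save a contour overlay
#'
#' Writes an RGB PPM (`P6`) of the grayscale image with the zero-level-set
#' contour drawn in red (the conventional rendering of active-contour
#' results).
#'
#' @param img an [image_grid()] or `[0, 1]` matrix.
#' @param phi level-set field (or a logical contour mask).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_overlay <- function(img, phi, path) {
  mat <- if (inherits(img, "image_grid")) img$intensities else img
  cm <- if (is.logical(phi)) phi else contour_mask(phi)
  if (!identical(dim(cm), dim(mat)))
    stop_osg("contour shape does not match the image", "osg_contract_error")
  g <- round(pmin(pmax(mat, 0), 1) * 255)
  r <- g; b <- g
  r[cm] <- 255; g[cm] <- 0; b[cm] <- 0
  inter <- rbind(as.vector(t(r)), as.vector(t(g)), as.vector(t(b)))
  write_netpbm(as.vector(inter), ncol(mat), nrow(mat), 255L, path, "P6")
  invisible(path)
}

#' Run configuration
#'
#' All tunable parameters of the segmentation workflow with their defaults
#' (`alpha = 1`, `mu = 10`, `lambda2 = 1`, `beta = 1`, `lambda1 = 3`,
#' `eps = 1.5`, `sigma = 1.5`, `dt` auto from the CFL bound,
#' `max_iterations = 1500`), plus initialization settings.  Unknown keys
#' are rejected by name; the JSON round trip (write then read) is the
#' identity.
#'
#' @param ... overrides of default fields.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    model = "proposed",
    lambda1 = 3.0, lambda2 = 1.0, alpha = 1.0, mu = 10.0, beta = 1.0,
    eps = 1.5, sigma = 1.5, edge_scale = 255, csi_sigma = 1.0,
    dt = NULL, max_iterations = 1500L, tolerance = 1e-4,
    checkpoint_stride = 20L, snapshot_stride = 200L, reinit_every = 5L,
    # Chan-Vese baseline / pre-segmentation
    mu_cv = 0.02, v = 0.0, cv_lambda1 = 1.0, cv_lambda2 = 1.0,
    preseg_iterations = 300L, preseg_mu_cv = 0.05, preseg_smooth = 3.0,
    # CPLSE baseline
    mu_reg = 0.2, lambda_len = 5.0, alpha_area = 1.5, cplse_dt = 1.0,
    # initialization
    expansion = 0.2, canny_sigma = 1.0, canny_low = 0.1, canny_high = 0.2,
    verbose = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stop_osg(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")), "osg_param_error")
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_osg(sprintf("cannot read config '%s'", path), "osg_io_error")
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_keys <- c("max_iterations", "checkpoint_stride", "snapshot_stride",
                "reinit_every", "preseg_iterations")
  for (k in names(vals)) {
    if (k %in% int_keys) vals[[k]] <- as.integer(vals[[k]])
    else if (is.numeric(vals[[k]])) vals[[k]] <- as.double(vals[[k]])
  }
  do.call(run_config, vals)
}

# parameter-object builders from a run_config
config_to_params <- function(cfg, model = cfg$model) {
  switch(model,
         proposed = evolution_params(
           lambda1 = cfg$lambda1, lambda2 = cfg$lambda2, alpha = cfg$alpha,
           mu = cfg$mu, beta = cfg$beta, eps = cfg$eps, sigma = cfg$sigma,
           edge_scale = cfg$edge_scale, csi_sigma = cfg$csi_sigma,
           dt = cfg$dt, max_iterations = cfg$max_iterations,
           tolerance = cfg$tolerance,
           checkpoint_stride = cfg$checkpoint_stride,
           snapshot_stride = cfg$snapshot_stride,
           reinit_every = cfg$reinit_every),
         cv = cv_params(
           mu_cv = cfg$mu_cv, v = cfg$v, lambda1 = cfg$cv_lambda1,
           lambda2 = cfg$cv_lambda2, eps = cfg$eps, dt = cfg$dt,
           max_iterations = cfg$max_iterations, tolerance = cfg$tolerance,
           checkpoint_stride = cfg$checkpoint_stride,
           snapshot_stride = cfg$snapshot_stride),
         cplse = cplse_params(
           mu_reg = cfg$mu_reg, lambda_len = cfg$lambda_len,
           alpha_area = cfg$alpha_area, eps = cfg$eps, sigma = cfg$sigma,
           edge_scale = cfg$edge_scale, csi_sigma = cfg$csi_sigma,
           dt = cfg$cplse_dt, max_iterations = cfg$max_iterations,
           tolerance = cfg$tolerance,
           checkpoint_stride = cfg$checkpoint_stride,
           snapshot_stride = cfg$snapshot_stride),
         stop_osg(sprintf("unknown model '%s'", model), "osg_param_error"))
}
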