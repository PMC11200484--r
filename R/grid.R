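#' Image grid
#'
#' Container for a single-channel image on the discrete pixel domain.
#' Intensities are stored normalized to `[0, 1]`; pixel spacing is fixed at 1
#' and isotropic.  Rows index `y` (top to bottom), columns index `x`.
#'
#' @param intensities numeric matrix of intensities in `[0, 1]`.
#' @param bit_depth original bit depth of the source image (8 or 16);
#'   informational only.
#' @return an object of class `image_grid` with fields `intensities`,
#'   `height`, `width`, `bit_depth`.
#' @examples
#' g <- image_grid(matrix(runif(32 * 32), 32, 32))
#' g$height
#' @export
image_grid <- function(intensities, bit_depth = 8L) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_osg("`intensities` must be a numeric matrix", "osg_param_error")
  if (nrow(intensities) < 16L || ncol(intensities) < 16L)
    stop_osg("image must be at least 16 x 16 pixels", "osg_param_error")
  if (!all(is.finite(intensities)))
    stop_osg("image intensities must all be finite", "osg_param_error")
  if (min(intensities) < 0 || max(intensities) > 1)
    stop_osg("image intensities must lie in [0, 1] (normalize on load)",
             "osg_param_error")
  structure(list(intensities = intensities,
                 height = nrow(intensities),
                 width = ncol(intensities),
                 bit_depth = as.integer(bit_depth)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %d-bit source, intensity range [%.3f, %.3f]\n",
              x$height, x$width, x$bit_depth,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

as_image_grid <- function(x) {
  if (inherits(x, "image_grid")) return(x)
  image_grid(x)
}

# Validate a level-set field against its grid.  A level-set field is a plain
# numeric matrix under the inside-negative convention.
check_levelset <- function(phi, grid = NULL) {
  if (!is.matrix(phi) || !is.numeric(phi))
    stop_osg("level-set field must be a numeric matrix", "osg_contract_error")
  if (!all(is.finite(phi)))
    stop_osg("level-set field contains non-finite values", "osg_numeric_error")
  if (!is.null(grid) &&
      (nrow(phi) != grid$height || ncol(phi) != grid$width))
    stop_osg("level-set field shape does not match the image grid",
             "osg_contract_error")
  invisible(phi)
}

#' Binary inside mask of a level-set field
#'
#' @param phi level-set field matrix (inside-negative convention).
#' @return logical matrix, `TRUE` where `phi < 0`.
#' @export
levelset_mask <- function(phi) {
  check_levelset(phi)
  phi < 0
}

# Pixel-coordinate matrices (0-based, x = column, y = row).
coord_grids <- function(height, width) {
  list(x = matrix(rep(0:(width - 1L), each = height), height, width),
       y = matrix(rep(0:(height - 1L), times = width), height, width))
}
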