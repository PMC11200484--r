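#' Write / read a phantom spec as JSON
#'
#' The sidecar JSON fully determines the scene: re-feeding it to
#' [generate_phantom()] reproduces the image and masks bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @param path JSON path.
#' @return `phantom_spec_to_json`: invisibly `path`;
#'   `phantom_spec_from_json`: a `phantom_spec`.
#' @export
phantom_spec_to_json <- function(spec, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(spec), path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname phantom_spec_to_json
#' @export
phantom_spec_from_json <- function(path) {
  if (!file.exists(path))
    stop_osg(sprintf("cannot read phantom spec '%s'", path), "osg_io_error")
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  phantom_spec(
    size = as.integer(num(l$size)),
    background = num(l$background),
    noise_sd = num(l$noise_sd),
    organoids = lapply(l$organoids, function(o) do.call(organoid_spec, o)),
    impurities = if (is.null(l$impurities)) NULL else
      list(n = as.integer(num(l$impurities$n)),
           r_range = num(l$impurities$r_range),
           level = num(l$impurities$level)),
    distractors = if (is.null(l$distractors)) NULL else l$distractors,
    blur_sd = num(l$blur_sd),
    seed = as.integer(num(l$seed)))
}
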