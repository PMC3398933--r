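#' Channel-to-double-cone mapping
#'
#' Defines how calibrated reflectance planes are combined into a single avian
#' double-cone ("luminance") photon-catch channel. The transform is a supplied
#' nonnegative weight per channel plus the photon catch assigned to the gray
#' reflectance standard; by default the visible plane carries all the weight
#' and the UV plane none, reflecting that pattern and texture perception in
#' birds is attributed to the achromatic double-cone channel.
#'
#' @param channel_weights Named (or ordered) nonnegative weights, one per image
#'   plane; at least one must be positive.
#' @param normalization Photon catch assigned to the gray standard (> 0).
#' @return An object of class `cone_mapping`.
#' @export
cone_mapping <- function(channel_weights = c(visible = 1, uv = 0),
                         normalization = 1) {
  if (!is.numeric(channel_weights) || length(channel_weights) < 1 ||
      any(!is.finite(channel_weights)) || any(channel_weights < 0)) {
    stop("`channel_weights` must be finite nonnegative numbers", call. = FALSE)
  }
  if (all(channel_weights == 0)) {
    stop("at least one channel weight must be positive", call. = FALSE)
  }
  stopifnot_scalar(normalization, "normalization")
  if (normalization <= 0) stop("`normalization` must be > 0", call. = FALSE)
  structure(list(channel_weights = channel_weights,
                 normalization = normalization),
            class = "cone_mapping")
}

#' Compute the double-cone photon-catch image
#'
#' Collapses a multichannel reflectance image into relative double-cone photon
#' catches: per pixel, the weighted sum of the channel reflectances divided by
#' the catch of the gray standard. A pixel spectrally identical to the standard
#' therefore maps to exactly 1. The egg mask and spatial scale are carried
#' through unchanged.
#'
#' @param image An `egg_image` (see [generate_egg_image()], [read_egg_image()]).
#' @param mapping A [cone_mapping()]; its weight count must equal the number of
#'   image planes.
#' @return An object of class `cone_catch_image`: fields `catch` (matrix of
#'   relative catches, >= 0), `mask`, `scale_mm_px`.
#' @export
compute_cone_catch <- function(image, mapping = cone_mapping()) {
  stopifnot(inherits(image, "egg_image"), inherits(mapping, "cone_mapping"))
  w <- mapping$channel_weights
  if (length(w) != length(image$planes)) {
    stop(sprintf("mapping has %d weights but image has %d planes",
                 length(w), length(image$planes)), call. = FALSE)
  }
  if (!is.null(names(w)) && !is.null(names(image$planes)) &&
      all(names(w) %in% names(image$planes))) {
    planes <- image$planes[names(w)]
  } else {
    planes <- image$planes
  }
  catch <- Reduce(`+`, Map(function(wi, p) wi * p, w, planes))
  catch <- catch / mapping$normalization
  structure(list(catch = catch, mask = image$mask,
                 scale_mm_px = image$scale_mm_px),
            class = "cone_catch_image")
}

#' @method print cone_catch_image
#' @export
print.cone_catch_image <- function(x, ...) {
  cat(sprintf("Double-cone catch image: %d x %d px, %d mask px, catch range [%.4f, %.4f]\n",
              nrow(x$catch), ncol(x$catch), sum(x$mask),
              min(x$catch[x$mask]), max(x$catch[x$mask])))
  invisible(x)
}
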