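#' All four pattern variables for one egg
#'
#' Deterministic composition of the measurement pipeline on a single egg:
#' multichannel image -> double-cone catch -> three regions -> granularity
#' spectrum -> marking size and pattern contrast; catch -> Otsu pigment mask
#' -> pattern coverage and (from the regional coverages) pattern dispersion.
#'
#' @param image An `egg_image`.
#' @param mapping A [cone_mapping()].
#' @param bands Filter bank from [default_bands()].
#' @param window Working-window side for the Fourier decomposition.
#' @param intensity_scale See [granularity_spectrum()].
#' @return A one-row data frame with columns `marking_size`,
#'   `pattern_contrast`, `pattern_coverage`, `pattern_dispersion`,
#'   `threshold`, plus `coverage_upper`, `coverage_middle`, `coverage_base`.
#'   `marking_size` is `NA` for a patternless egg.
#' @export
egg_pattern_metrics <- function(image, mapping = cone_mapping(),
                                bands = default_bands(), window = 256L,
                                intensity_scale = 65535) {
  catch <- compute_cone_catch(image, mapping)
  regions <- split_regions(catch)
  spec <- granularity_spectrum(regions, bands, window = window,
                               intensity_scale = intensity_scale)
  pig <- withCallingHandlers(
    threshold_pigment(catch),
    warning = function(w) {
      if (grepl("constant image", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  rc <- regional_coverage(pig)
  data.frame(
    marking_size = as.numeric(marking_size(spec)),
    pattern_contrast = pattern_contrast(spec),
    pattern_coverage = pattern_coverage(pig),
    pattern_dispersion = pattern_dispersion(rc),
    threshold = pig$threshold,
    coverage_upper = rc[["upper"]],
    coverage_middle = rc[["middle"]],
    coverage_base = rc[["base"]]
  )
}

#' Measure a batch of eggs
#'
#' @param eggs List whose elements each contain an `egg_image` under `$image`
#'   (as produced by [simulate_egg_population()]), or a bare list of
#'   `egg_image` objects.
#' @param ... Passed on to [egg_pattern_metrics()].
#' @return Data frame with one row per egg (column `egg` gives the index).
#' @export
measure_eggs <- function(eggs, ...) {
  rows <- lapply(seq_along(eggs), function(i) {
    img <- eggs[[i]]
    if (!inherits(img, "egg_image")) img <- img$image
    cbind(egg = i, egg_pattern_metrics(img, ...))
  })
  do.call(rbind, rows)
}
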