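#' The seven-octave granularity filter bank
#'
#' Band centres ("filter sizes") at 2, 4, 8, 16, 32, 64 and 128 cycles per
#' image width, with ideal (hard-cutoff) annular masks in the Fourier domain.
#' Band edges sit at the geometric midpoints `centre / sqrt(2)` and
#' `centre * sqrt(2)`, so successive bands tile the radial frequency axis
#' without overlap; the last band is extended to the corners of the Fourier
#' plane so no covered frequency is lost. Smaller filter sizes correspond to
#' larger markings.
#'
#' @param centres Band-centre frequencies in cycles per image width.
#' @return A data frame with columns `filter_size`, `low`, `high` (half-open
#'   interval `(low, high]`).
#' @export
default_bands <- function(centres = 2^(1:7)) {
  if (any(diff(centres) <= 0) || any(centres <= 0)) {
    stop("band centres must be positive and increasing", call. = FALSE)
  }
  # shared edges: each band's upper cutoff IS the next band's lower cutoff,
  # bit-identically, so boundary frequencies are never counted twice
  high <- centres * sqrt(2)
  low <- c(centres[1] / sqrt(2), high[-length(high)])
  high[length(high)] <- Inf  # sweep up the Fourier-plane corners
  data.frame(filter_size = centres, low = low, high = high)
}

# radial frequency (cycles per image width) for every cell of an n x n DFT grid
radial_freq_grid <- function(n) {
  k <- c(0:(n %/% 2 - 1), -(n - n %/% 2):-1)
  if (n %% 2 == 1) k <- c(0:((n - 1) %/% 2), -((n - 1) %/% 2):-1)
  sqrt(outer(k^2, k^2, `+`))
}

#' Split a cone-catch image into upper, middle and base egg regions
#'
#' Cuts the egg's bounding box into three equal-height horizontal slabs
#' (any remainder row goes to the middle slab). Row 1 of the image is the
#' pointed ("upper") end of the egg; the last rows are the blunt "base".
#' The slabs are disjoint and their union is the bounding box.
#'
#' @param image A `cone_catch_image`.
#' @return Named list (`upper`, `middle`, `base`) of `cone_catch_image`
#'   objects cropped to the slabs.
#' @export
split_regions <- function(image) {
  stopifnot(inherits(image, "cone_catch_image"))
  if (!any(image$mask)) stop("empty egg mask", call. = FALSE)
  bb <- mask_bbox(image$mask)
  if (length(bb$rows) < 3) stop("egg bounding box must span at least 3 rows", call. = FALSE)
  th <- third_heights(length(bb$rows))
  starts <- cumsum(c(0L, th[-3]))
  out <- lapply(1:3, function(i) {
    rows <- bb$rows[(starts[i] + 1L):(starts[i] + th[i])]
    structure(list(catch = image$catch[rows, bb$cols, drop = FALSE],
                   mask = image$mask[rows, bb$cols, drop = FALSE],
                   scale_mm_px = image$scale_mm_px),
              class = "cone_catch_image")
  })
  names(out) <- c("upper", "middle", "base")
  out
}

#' Fourier bandpass decomposition
#'
#' Decomposes a square image into one image per frequency band by restricting
#' its discrete Fourier coefficients to the band's radial annulus (in cycles
#' per image width) and inverse-transforming. The DC (mean) component is
#' excluded from every band, so a constant image decomposes to all-zero bands.
#'
#' @param x A square numeric matrix (the working window).
#' @param bands Band table as from [default_bands()].
#' @return A list of band images (real matrices), one per row of `bands`.
#' @export
bandpass_decompose <- function(x, bands = default_bands()) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("`x` must be a square matrix working window", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite pixels in working window", call. = FALSE)
  n <- nrow(x)
  FT <- stats::fft(x)
  r <- radial_freq_grid(n)
  lapply(seq_len(nrow(bands)), function(b) {
    sel <- r > bands$low[b] & r <= bands$high[b] & r > 0
    G <- matrix(0 + 0i, n, n)
    G[sel] <- FT[sel]
    Re(stats::fft(G, inverse = TRUE)) / (n * n)
  })
}

# Resample a region (catch + mask) to an n x n working window. Pixels outside
# the egg mask are filled with the masked mean first so shell texture, not the
# backdrop edge, dominates the spectrum.
resample_window <- function(region, n = 256L) {
  catch <- region$catch
  mask <- region$mask
  if (!any(mask)) stop("region contains no egg pixels", call. = FALSE)
  fill <- mean(catch[mask])
  catch[!mask] <- fill
  win <- as.matrix(EBImage::resize(catch, w = n, h = n, filter = "bilinear"))
  mres <- as.matrix(EBImage::resize(mask * 1, w = n, h = n, filter = "bilinear"))
  list(window = win, mask = mres >= 0.5)
}

#' Granularity spectrum of one egg
#'
#' Computes, for each of the three egg regions, the energy of every filter-bank
#' band — the mean squared band-image intensity over the egg mask — and
#' combines the regional spectra into a whole-egg spectrum by a mask-area
#' weighted mean. Each region is resampled to a square power-of-two working
#' window first so filter sizes are commensurate across eggs photographed at
#' the same distance.
#'
#' @param regions Three-region list from [split_regions()] (or any list of
#'   `cone_catch_image` regions from one egg).
#' @param bands Band table from [default_bands()].
#' @param window Side of the square working window (power of two).
#' @param intensity_scale Factor applied to the relative catch before the
#'   transform; the default expresses intensities in 16-bit digital counts,
#'   the storage scale of the calibrated images, so that contrast values are
#'   commensurate with published population statistics.
#' @return Object of class `granularity_spectrum`: `bands`, `energies`
#'   (length-7 nonnegative), `regional_energies` (3 x 7), `region_weights`.
#' @export
granularity_spectrum <- function(regions, bands = default_bands(),
                                 window = 256L, intensity_scale = 65535) {
  stopifnot(is.list(regions), length(regions) >= 1)
  reg_en <- t(vapply(regions, function(rg) {
    rw <- resample_window(rg, n = window)
    bi <- bandpass_decompose(rw$window * intensity_scale, bands)
    vapply(bi, function(b) mean(b[rw$mask]^2), numeric(1))
  }, numeric(nrow(bands))))
  wts <- vapply(regions, function(rg) sum(rg$mask), numeric(1))
  energies <- as.numeric(colSums(reg_en * wts) / sum(wts))
  structure(list(bands = bands, energies = energies,
                 regional_energies = reg_en, region_weights = wts),
            class = "granularity_spectrum")
}

#' @method print granularity_spectrum
#' @export
print.granularity_spectrum <- function(x, ...) {
  cat("Granularity spectrum (energy by filter size, cycles/image width):\n")
  print(stats::setNames(signif(x$energies, 4), x$bands$filter_size))
  ms <- marking_size(x)
  if (is.na(ms)) cat("no pattern detected\n")
  else cat(sprintf("marking size %g, pattern contrast %.2f\n", ms, pattern_contrast(x)))
  invisible(x)
}

#' @describeIn granularity_spectrum One row per band (`filter_size`, `low`,
#'   `high`, `energy`), ready for CSV export.
#' @param x A `granularity_spectrum`.
#' @param ... Unused.
#' @method as.data.frame granularity_spectrum
#' @export
as.data.frame.granularity_spectrum <- function(x, ...) {
  cbind(x$bands, energy = x$energies)
}

#' Predominant marking size
#'
#' The filter size (band-centre frequency, cycles per image width) of the
#' maximum-energy band. Smaller filter sizes correspond to larger markings;
#' ties are broken toward the smaller filter size (the larger marking). An
#' all-zero spectrum carries no pattern and yields `NA` with attribute
#' `no_pattern = TRUE` rather than a number.
#'
#' @param spectrum A `granularity_spectrum`.
#' @return Filter size of the peak band, or `NA_real_` for a patternless egg.
#' @export
marking_size <- function(spectrum) {
  stopifnot(inherits(spectrum, "granularity_spectrum"))
  e <- spectrum$energies
  if (all(e <= 0)) {
    return(structure(NA_real_, no_pattern = TRUE))
  }
  # bands are ordered by increasing filter size; which.max takes the first
  # (smallest filter size) on ties
  spectrum$bands$filter_size[which.max(e)]
}

#' Pattern contrast
#'
#' Square root of the summed band energies: an amplitude-scale measure of the
#' total pattern energy, higher for darker, more contrasting markings against
#' the pale shell ground. Doubling the image contrast doubles this value.
#'
#' @param spectrum A `granularity_spectrum`.
#' @return Nonnegative scalar.
#' @export
pattern_contrast <- function(spectrum) {
  stopifnot(inherits(spectrum, "granularity_spectrum"))
  sqrt(sum(spectrum$energies))
}
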