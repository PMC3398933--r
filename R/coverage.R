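#' Threshold an egg into pigment and background
#'
#' Classifies every pixel inside the egg mask as pigment (dark) or background
#' (pale shell) by Otsu's criterion: masked intensities are quantised to
#' 65,536 levels and the cutoff maximising the between-class variance is
#' selected; pixels at or below the cutoff are pigment. The threshold is
#' computed per egg, within the mask only, which makes the resulting coverage
#' invariant to affine rescaling of the intensities. A constant image carries
#' no pattern: by convention it yields an empty pigment mask, with a warning.
#'
#' @param image A `cone_catch_image`.
#' @param n_levels Number of quantisation levels for the histogram search.
#' @return Object of class `pigment_mask`: logical `pigment` plane (subset of
#'   the egg mask), the egg `mask`, and the `threshold` on the intensity scale
#'   (`NA` for a constant image).
#' @export
threshold_pigment <- function(image, n_levels = 65536L) {
  stopifnot(inherits(image, "cone_catch_image"))
  mask <- image$mask
  if (!any(mask)) stop("empty egg mask", call. = FALSE)
  v <- image$catch[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant image within mask: no pattern, empty pigment mask")
    return(structure(list(pigment = mask & FALSE, mask = mask,
                          threshold = NA_real_),
                     class = "pigment_mask"))
  }
  lev <- as.integer(round((v - rng[1]) / diff(rng) * (n_levels - 1)))
  counts <- tabulate(lev + 1L, nbins = n_levels)
  t_star <- otsu_level(counts)
  thr <- rng[1] + (t_star + 0.5) / (n_levels - 1) * diff(rng)
  pigment <- mask
  pigment[mask] <- lev <= t_star
  structure(list(pigment = pigment, mask = mask, threshold = thr),
            class = "pigment_mask")
}

# Otsu's between-class-variance maximiser over a histogram of counts for
# levels 0..(K-1). Returns the level t such that the classes are {<= t} and
# {> t}; the first maximiser (darkest cutoff) is taken on exact ties.
otsu_level <- function(counts) {
  K <- length(counts)
  lev <- 0:(K - 1)
  n <- sum(counts)
  w0 <- cumsum(as.numeric(counts))
  m0 <- cumsum(as.numeric(counts) * lev)
  mu_tot <- m0[K] / n
  valid <- w0 > 0 & w0 < n
  sigma_b <- rep(-Inf, K)
  sigma_b[valid] <- (mu_tot * w0[valid] - m0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  which.max(sigma_b) - 1L
}

#' Write a pigment mask as an 8-bit PNG for audit
#'
#' White = pigment, gray = unpigmented shell, black = outside the egg.
#'
#' @param pigment A `pigment_mask`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_pigment_mask <- function(pigment, path) {
  stopifnot(inherits(pigment, "pigment_mask"))
  img <- matrix(0, nrow(pigment$mask), ncol(pigment$mask))
  img[pigment$mask] <- 0.5
  img[pigment$pigment] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Pattern coverage
#'
#' Proportion of the egg covered with pigmentation: pigment pixels divided by
#' egg-mask pixels.
#'
#' @param pigment A `pigment_mask` from [threshold_pigment()].
#' @return Fraction in `[0, 1]`.
#' @export
pattern_coverage <- function(pigment) {
  stopifnot(inherits(pigment, "pigment_mask"))
  if (!any(pigment$mask)) stop("empty egg mask", call. = FALSE)
  sum(pigment$pigment) / sum(pigment$mask)
}

# pigment coverage within each of the three egg regions (upper/middle/base)
regional_coverage <- function(pigment) {
  stopifnot(inherits(pigment, "pigment_mask"))
  bb <- mask_bbox(pigment$mask)
  reg <- region_of_rows(bb$rows)
  out <- vapply(1:3, function(r) {
    rows <- bb$rows[reg == r]
    m <- pigment$mask[rows, , drop = FALSE]
    if (!any(m)) return(0)
    sum(pigment$pigment[rows, , drop = FALSE][m]) / sum(m)
  }, numeric(1))
  stats::setNames(out, c("upper", "middle", "base"))
}

#' Pattern dispersion
#'
#' Standard deviation of pattern coverage among the three egg regions (upper,
#' middle, base); high values indicate unevenly pigmented eggs. The sample
#' (n - 1 denominator) standard deviation is used — with three regions the
#' population alternative differs only by a constant factor, so the choice is
#' fixed and documented here.
#'
#' @param coverages Numeric vector of three regional coverage values.
#' @return Nonnegative scalar; zero iff all regional coverages are equal.
#' @export
pattern_dispersion <- function(coverages) {
  if (length(coverages) != 3L || any(!is.finite(coverages))) {
    stop("`coverages` must be three finite regional coverage values", call. = FALSE)
  }
  stats::sd(coverages)
}
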