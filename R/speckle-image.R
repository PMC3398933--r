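#' Parameters for the synthetic speckled-egg renderer
#'
#' Bundles the knobs controlling a rendered egg: how many pigment spots to
#' expect, how large and how dark they are, how unevenly they are laid down
#' along the egg's long axis, and the sensor noise level. Defaults are
#' calibrated so that a population of rendered eggs, pushed through the full
#' measurement pipeline, reproduces the published great tit population means of
#' the four pattern variables (marking size 11.95, pattern contrast 581.77,
#' pattern coverage 0.19, pattern dispersion 0.10).
#'
#' @param image_size Pixels per side of the square rendered frame.
#' @param spot_count_rate Expected number of pigment spots per egg (Poisson).
#' @param spot_diameter_mean,spot_diameter_sd Mean and standard deviation of
#'   the per-spot diameter in pixels; diameters are drawn from the lognormal
#'   distribution with these moments.
#' @param spot_darkness Pigment contrast against the background in `[0, 1)`:
#'   a fully pigmented pixel has reflectance `background_level * (1 - spot_darkness)`.
#' @param regional_weights Length-3 nonnegative vector of relative spot
#'   densities in the upper (pointed), middle and base (blunt) thirds of the
#'   egg; only ratios matter.
#' @param background_level Shell ground reflectance in `(0, 1]`, relative to
#'   the gray standard.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise on the
#'   reflectance scale.
#' @param uv_level UV-plane ground reflectance as a fraction of
#'   `background_level` (protoporphyrin maculation is mainly a luminance
#'   pattern; the UV plane carries only an attenuated copy).
#' @param uv_pattern Fraction of `spot_darkness` expressed in the UV plane.
#'
#' @return An object of class `speckle_params` (a validated list).
#' @seealso [generate_egg_image()], [simulate_egg_population()]
#' @export
speckle_params <- function(image_size = 256L,
                           spot_count_rate = 320,
                           spot_diameter_mean = 5.0,
                           spot_diameter_sd = 1.8,
                           spot_darkness = 0.0303,
                           regional_weights = c(0.45, 1.0, 1.75),
                           background_level = 0.90,
                           noise_sd = 0.004,
                           uv_level = 0.35,
                           uv_pattern = 0.30) {
  stopifnot_scalar(image_size, "image_size", lower = 8)
  stopifnot_scalar(spot_count_rate, "spot_count_rate", lower = 0)
  stopifnot_scalar(spot_diameter_mean, "spot_diameter_mean", lower = 0)
  stopifnot_scalar(spot_diameter_sd, "spot_diameter_sd", lower = 0)
  stopifnot_scalar(spot_darkness, "spot_darkness", lower = 0, upper = 1)
  stopifnot_scalar(background_level, "background_level")
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar(uv_level, "uv_level", lower = 0, upper = 1)
  stopifnot_scalar(uv_pattern, "uv_pattern", lower = 0, upper = 1)
  if (length(regional_weights) != 3L || any(!is.finite(regional_weights)) ||
      any(regional_weights < 0) || sum(regional_weights) <= 0) {
    stop("`regional_weights` must be three nonnegative numbers, not all zero",
         call. = FALSE)
  }
  if (background_level <= 0 || background_level > 1) {
    stop("`background_level` must lie in (0, 1]", call. = FALSE)
  }
  # Pigment can only darken: background > background * (1 - darkness) >= 0.
  if (spot_darkness >= 1) {
    stop("`spot_darkness` must be < 1 so pigment remains a darkening", call. = FALSE)
  }
  if (spot_diameter_mean >= image_size) {
    stop("`spot_diameter_mean` must be smaller than `image_size`", call. = FALSE)
  }
  structure(list(
    image_size = as.integer(image_size),
    spot_count_rate = spot_count_rate,
    spot_diameter_mean = spot_diameter_mean,
    spot_diameter_sd = spot_diameter_sd,
    spot_darkness = spot_darkness,
    regional_weights = as.numeric(regional_weights),
    background_level = background_level,
    noise_sd = noise_sd,
    uv_level = uv_level,
    uv_pattern = uv_pattern
  ), class = "speckle_params")
}

#' @method print speckle_params
#' @export
print.speckle_params <- function(x, ...) {
  cat("Speckled-egg renderer parameters\n")
  cat(sprintf("  frame: %d x %d px, background %.3f, noise sd %.4f\n",
              x$image_size, x$image_size, x$background_level, x$noise_sd))
  cat(sprintf("  spots: rate %.1f, diameter %.2f +/- %.2f px (lognormal), darkness %.4f\n",
              x$spot_count_rate, x$spot_diameter_mean, x$spot_diameter_sd,
              x$spot_darkness))
  cat(sprintf("  regional weights (upper/middle/base): %s\n",
              paste(format(x$regional_weights, digits = 3), collapse = " / ")))
  invisible(x)
}

# lognormal (meanlog, sdlog) matching a target mean and sd on the natural scale
lognormal_pars <- function(m, s) {
  if (m <= 0) stop("lognormal mean must be positive", call. = FALSE)
  if (s <= 0) return(c(meanlog = log(m), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# filled-ellipse egg mask; row 1 is the pointed (upper) end
egg_mask <- function(size, semi_row = 0.47, semi_col = 0.36) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - ctr) / (semi_row * size))^2 + ((cols - ctr) / (semi_col * size))^2 <= 1
}

# region id (1 = upper, 2 = middle, 3 = base) for every row of a bbox
region_of_rows <- function(bbox_rows) {
  h <- length(bbox_rows)
  th <- third_heights(h)
  rep.int(1:3, th)
}

#' Render a synthetic speckled egg with known ground truth
#'
#' Renders a two-plane (visible + UV) reflectance image of a speckled egg.
#' Spots are anti-aliased filled discs multiplied onto the shell background;
#' where spots overlap the darker value wins, so pigment never darkens beyond
#' `spot_darkness`. The returned ground truth records the pigment coverage
#' actually rendered (a pixel counts as pigmented when its spot opacity is at
#' least 0.5), per egg region and overall.
#'
#' @param params A [speckle_params()] object.
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   output.
#' @param scale_mm_px Physical scale recorded on the image (mm per pixel).
#'
#' @return A list with components `image` (an `egg_image`: named reflectance
#'   planes `visible` and `uv` in `[0, 1]`, logical egg `mask`, `scale_mm_px`,
#'   and gray-`standard` factor) and `truth` (list with `true_coverage`,
#'   `regional_coverage` (upper/middle/base) and `dominant_spot_diameter` in
#'   pixels, `NA` when no spots were drawn).
#' @export
generate_egg_image <- function(params = speckle_params(), seed = 1L,
                               scale_mm_px = 0.1) {
  stopifnot(inherits(params, "speckle_params"))
  n <- params$image_size
  mask <- egg_mask(n)
  with_seed(seed, {
    alpha <- matrix(0, n, n)
    n_spots <- stats::rpois(1L, params$spot_count_rate)
    diameters <- numeric(0)
    if (n_spots > 0) {
      lp <- lognormal_pars(params$spot_diameter_mean, params$spot_diameter_sd)
      diameters <- stats::rlnorm(n_spots, lp["meanlog"], lp["sdlog"])
      if (any(diameters >= n)) {
        stop("drawn spot diameter exceeds image size; reduce `spot_diameter_mean`/`_sd`",
             call. = FALSE)
      }
      # spot centres: masked pixels weighted by the regional densities
      bb <- mask_bbox(mask)
      reg_row <- integer(n)
      reg_row[bb$rows] <- region_of_rows(bb$rows)
      idx <- which(mask)                       # column-major indices
      px_row <- ((idx - 1L) %% n) + 1L
      px_col <- ((idx - 1L) %/% n) + 1L
      w <- params$regional_weights[reg_row[px_row]]
      pick <- sample.int(length(idx), n_spots, replace = TRUE, prob = w)
      cr <- px_row[pick]
      cc <- px_col[pick]
      for (s in seq_len(n_spots)) {
        rad <- diameters[s] / 2
        ext <- ceiling(rad + 1)
        rr <- max(1L, cr[s] - ext):min(n, cr[s] + ext)
        cl <- max(1L, cc[s] - ext):min(n, cc[s] + ext)
        d <- sqrt(outer((rr - cr[s])^2, (cl - cc[s])^2, `+`))
        a <- pmin(1, pmax(0, rad + 0.5 - d))
        alpha[rr, cl] <- pmax(alpha[rr, cl], a)
      }
    }
    alpha[!mask] <- 0
    bg <- params$background_level
    vis <- bg * (1 - params$spot_darkness * alpha)
    uv <- bg * params$uv_level * (1 - params$uv_pattern * params$spot_darkness * alpha)
    vis[!mask] <- 0.03   # black felt backdrop
    uv[!mask] <- 0.03
    if (params$noise_sd > 0) {
      vis <- vis + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
      uv <- uv + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
    }
    vis <- pmin(pmax(vis, 0), 1)
    uv <- pmin(pmax(uv, 0), 1)

    pig <- alpha >= 0.5
    bb <- mask_bbox(mask)
    reg <- region_of_rows(bb$rows)
    reg_cov <- vapply(1:3, function(r) {
      rows <- bb$rows[reg == r]
      m <- mask[rows, , drop = FALSE]
      if (!any(m)) return(0)
      sum(pig[rows, , drop = FALSE][m]) / sum(m)
    }, numeric(1))
    names(reg_cov) <- c("upper", "middle", "base")
    dom <- if (length(diameters)) {
      exp(stats::weighted.mean(log(diameters), w = diameters^2))
    } else NA_real_
    list(
      image = structure(list(
        planes = list(visible = vis, uv = uv),
        mask = mask,
        scale_mm_px = scale_mm_px,
        standard = 1
      ), class = "egg_image"),
      truth = list(
        true_coverage = sum(pig[mask]) / sum(mask),
        regional_coverage = reg_cov,
        dominant_spot_diameter = dom
      )
    )
  })
}

#' Simulate a population of eggs with between-egg heterogeneity
#'
#' Real clutches vary: some eggs carry more, darker or coarser maculation than
#' others. This wrapper draws per-egg multipliers (lognormal, unit median) for
#' the spot rate, darkness and diameter around a shared [speckle_params()]
#' baseline and renders each egg. The default coefficients of variation are
#' part of the calibrated population model: together with the baseline they
#' reproduce the published means of all four pattern variables.
#'
#' @param n_eggs Number of eggs to render.
#' @param params Baseline [speckle_params()].
#' @param seed Integer seed controlling both the heterogeneity draws and the
#'   per-egg rendering.
#' @param rate_cv,darkness_cv,diameter_cv Between-egg coefficients of variation
#'   of the spot rate, spot darkness, and mean spot diameter.
#' @return A list of length `n_eggs`; each element as in [generate_egg_image()],
#'   plus the per-egg `params` actually used.
#' @export
simulate_egg_population <- function(n_eggs, params = speckle_params(), seed = 1L,
                                    rate_cv = 0.35, darkness_cv = 0.15,
                                    diameter_cv = 0.24) {
  stopifnot(n_eggs >= 1)
  mults <- with_seed(seed, {
    draw <- function(cv) {
      if (cv <= 0) return(rep(1, n_eggs))
      sdl <- sqrt(log(1 + cv^2))
      stats::rlnorm(n_eggs, -sdl^2 / 2, sdl)
    }
    list(rate = draw(rate_cv), dark = draw(darkness_cv), diam = draw(diameter_cv))
  })
  lapply(seq_len(n_eggs), function(i) {
    p <- params
    p$spot_count_rate <- params$spot_count_rate * mults$rate[i]
    p$spot_darkness <- min(0.999, params$spot_darkness * mults$dark[i])
    p$spot_diameter_mean <- params$spot_diameter_mean * mults$diam[i]
    p$spot_diameter_sd <- params$spot_diameter_sd * mults$diam[i]
    out <- generate_egg_image(p, seed = as.integer(seed) + i)
    out$params <- p
    out
  })
}
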