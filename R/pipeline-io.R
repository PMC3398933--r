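#' Read a calibrated two-plane egg image from disk
#'
#' Reads the visible and UV reflectance planes (16-bit grayscale TIFF) and
#' the egg mask (PNG or TIFF), normalizes the planes by the gray-standard
#' factor, and binarizes the mask. All planes must share dimensions.
#'
#' @param visible_path,uv_path Paths to the plane TIFFs.
#' @param mask_path Path to the mask image (nonzero = egg).
#' @param standard Gray-standard normalization factor (> 0); plane values are
#'   divided by it, so a factor of 2 halves all reflectances.
#' @param scale_mm_px Physical scale, mm per pixel.
#' @return An `egg_image`.
#' @export
read_egg_image <- function(visible_path, uv_path, mask_path, standard = 1,
                           scale_mm_px = 0.1) {
  stopifnot_scalar(standard, "standard")
  if (standard <= 0) stop("`standard` must be > 0", call. = FALSE)
  read_plane <- function(p) {
    x <- if (grepl("\\.png$", p, ignore.case = TRUE)) png::readPNG(p)
         else tiff::readTIFF(p)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    x
  }
  vis <- read_plane(visible_path)
  uv <- read_plane(uv_path)
  mk <- read_plane(mask_path)
  dims <- list(dim(vis), dim(uv), dim(mk))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop(sprintf("plane dimension mismatch: visible %s, uv %s, mask %s",
                 paste(dims[[1]], collapse = "x"), paste(dims[[2]], collapse = "x"),
                 paste(dims[[3]], collapse = "x")), call. = FALSE)
  }
  structure(list(planes = list(visible = vis / standard, uv = uv / standard),
                 mask = mk > 0.5, scale_mm_px = scale_mm_px,
                 standard = standard),
            class = "egg_image")
}

#' Write an egg image to disk (16-bit TIFF planes + PNG mask)
#'
#' @param image An `egg_image`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_egg_image <- function(image, dir, prefix = "egg") {
  stopifnot(inherits(image, "egg_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_visible.tif", "_uv.tif", "_mask.png")))
  tiff::writeTIFF(pmin(pmax(image$planes$visible, 0), 1), paths[1],
                  bits.per.sample = 16L)
  tiff::writeTIFF(pmin(pmax(image$planes$uv, 0), 1), paths[2],
                  bits.per.sample = 16L)
  png::writePNG(image$mask * 1, paths[3])
  invisible(paths)
}

#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' experiment size, image-rendering baseline, filter-bank/working-window
#' settings, aggregation choices and which models to fit. Configurations
#' round-trip through YAML via [read_run_config()] / [write_run_config()].
#'
#' @param seed Master integer seed for the run.
#' @param output_dir Directory receiving all CSV outputs and the log.
#' @param n_nests,hatch_drop_rate Passed to [experiment_params()].
#' @param image_size Rendered frame side in pixels.
#' @param window Fourier working-window side.
#' @param first_n Eggs photographed per clutch.
#' @param pca_level `"egg"` or `"clutch"` (see [speckle_scores()]).
#' @param models Character subset of
#'   `c("provisioning", "chick_mass_3", "chick_mass_7", "chick_mass_15", "female_quality")`.
#' @param speckle Optional named list of [speckle_params()] overrides.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, output_dir = tempfile("eggspeckle_run_"),
                       n_nests = 12L, hatch_drop_rate = 0,
                       image_size = 128L, window = 256L, first_n = 4L,
                       pca_level = c("egg", "clutch"),
                       models = c("provisioning", "chick_mass_15", "female_quality"),
                       speckle = list()) {
  pca_level <- match.arg(pca_level)
  known <- c("provisioning", "chick_mass_3", "chick_mass_7", "chick_mass_15",
             "female_quality")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 n_nests = as.integer(n_nests), hatch_drop_rate = hatch_drop_rate,
                 image_size = as.integer(image_size), window = as.integer(window),
                 first_n = as.integer(first_n), pca_level = pca_level,
                 models = models, speckle = speckle),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# per-clutch speckle parameters: the latent clutch speckling score modulates
# spot rate and darkness around the calibrated baseline
clutch_speckle_params <- function(base, z) {
  p <- base
  p$spot_count_rate <- base$spot_count_rate * exp(0.35 * z)
  p$spot_darkness <- min(0.999, max(1e-4, base$spot_darkness * (1 + 0.2 * z)))
  p
}

#' Run the full pipeline end to end
#'
#' Simulates a double cross-fostering experiment, renders and measures the
#' first `first_n` eggs of every clutch, aggregates metrics to clutch level
#' with PCA speckling scores, joins the measured PC1 back onto the experiment
#' tables, fits the configured models, and writes every table as CSV plus a
#' plain-text log (seed, package version, stage timings). The run is
#' deterministic given the configuration: the same config produces
#' bit-identical CSVs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`experiment`,
#'   `egg_metrics`, `clutches`, `pca`, `fits`, `paths`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "run.log")
  log_lines <- c(sprintf("eggspeckle %s", as.character(utils::packageVersion("eggspeckle"))),
                 sprintf("seed %d", config$seed),
                 sprintf("n_nests %d, image_size %d, window %d, first_n %d, pca_level %s",
                         config$n_nests, config$image_size, config$window,
                         config$first_n, config$pca_level))
  fail <- function(stage, id, e) {
    stop(sprintf("pipeline stage `%s` failed at record %s: %s", stage, id,
                 conditionMessage(e)), call. = FALSE)
  }
  # --- stage 1: experiment ---
  ex <- tryCatch(generate_experiment(
    experiment_params(n_nests = config$n_nests,
                      hatch_drop_rate = config$hatch_drop_rate,
                      seed = config$seed)),
    error = function(e) fail("simulate-experiment", "-", e))
  # --- stage 2+3: render and measure the photographed eggs ---
  base <- do.call(speckle_params, c(list(image_size = config$image_size),
                                    config$speckle))
  metrics <- NULL
  for (i in seq_len(nrow(ex$nests))) {
    z <- ex$nests$pc1_speckling[i]
    p <- clutch_speckle_params(base, z)
    k <- min(config$first_n, ex$nests$clutch_size[i])
    for (e in seq_len(k)) {
      egg_seed <- config$seed + i * 101L + e
      img <- tryCatch(generate_egg_image(p, seed = egg_seed),
                      error = function(err) fail("simulate-images",
                                                 sprintf("nest %d egg %d", i, e), err))
      m <- tryCatch(egg_pattern_metrics(img$image, window = config$window),
                    error = function(err) fail("measure",
                                               sprintf("nest %d egg %d", i, e), err))
      metrics <- rbind(metrics, cbind(clutch_id = i, lay_order = e, m))
    }
  }
  # --- stage 4: clutch aggregation + PCA speckling scores ---
  sc <- tryCatch(speckle_scores(metrics, level = config$pca_level,
                                first_n = config$first_n),
                 error = function(e) fail("aggregate", "-", e))
  clutches <- sc$clutches
  # --- stage 5: join measured PC1 onto the experiment tables and fit ---
  pc1 <- stats::setNames(clutches$PC1, clutches$clutch_id)
  nests <- ex$nests
  nests$pc1_speckling <- unname(pc1[as.character(nests$nest_id)])
  ex_meas <- ex
  ex_meas$nests <- nests
  fits <- list()
  for (m in config$models) {
    fits[[m]] <- tryCatch(switch(m,
      provisioning = fit_provisioning(ex_meas),
      chick_mass_3 = fit_chick_mass(ex_meas, day = 3),
      chick_mass_7 = fit_chick_mass(ex_meas, day = 7),
      chick_mass_15 = fit_chick_mass(ex_meas, day = 15),
      female_quality = fit_female_quality(ex_meas)),
      error = function(e) fail("fit", m, e))
  }
  # --- outputs ---
  paths <- c(
    egg_metrics = file.path(config$output_dir, "egg_metrics.csv"),
    clutches = file.path(config$output_dir, "clutch_pattern.csv"),
    nests = file.path(config$output_dir, "nests.csv"),
    chicks = file.path(config$output_dir, "chicks.csv"),
    provisioning_tbl = file.path(config$output_dir, "provisioning.csv")
  )
  utils::write.csv(metrics, paths["egg_metrics"], row.names = FALSE)
  utils::write.csv(clutches, paths["clutches"], row.names = FALSE)
  utils::write.csv(nests, paths["nests"], row.names = FALSE)
  utils::write.csv(ex$chicks, paths["chicks"], row.names = FALSE)
  utils::write.csv(ex$provisioning, paths["provisioning_tbl"], row.names = FALSE)
  for (m in names(fits)) {
    fp <- file.path(config$output_dir, paste0("model_", m, ".csv"))
    utils::write.csv(fits[[m]]$table, fp, row.names = FALSE)
    paths[paste0("model_", m)] <- fp
  }
  log_lines <- c(log_lines,
                 sprintf("eggs measured: %d", nrow(metrics)),
                 sprintf("clutches: %d", nrow(clutches)),
                 sprintf("models fitted: %s", paste(names(fits), collapse = ", ")))
  writeLines(log_lines, logf)
  invisible(list(experiment = ex, egg_metrics = metrics, clutches = clutches,
                 pca = sc$pca, fits = fits, paths = paths, log = logf))
}
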