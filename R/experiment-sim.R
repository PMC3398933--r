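#' Parameters of a simulated double cross-fostering experiment
#'
#' True (generating) effect sizes are standardized slopes on Z-scales,
#' matching the convention under which the field models are reported; the
#' defaults are the published standardized coefficients for the effects the
#' study detected (brood size on male prey delivery 0.54; female mass on
#' egg speckling -0.55; average egg mass on day-15 chick mass 0.25; female
#' sex on day-15 mass -0.59; origin-within-foster-nest random-intercept
#' variance 0.28). The speckling-to-provisioning slope defaults to 0 — the
#' null world the experiment could not reject.
#'
#' @param n_nests Number of nests; must be a positive multiple of 4 so that
#'   the egg-swap pairing and the disjoint chick-swap pairing both exist.
#' @param clutch_size_range Inclusive integer interval of clutch sizes.
#' @param female_mass_to_speckling_slope Standardized slope of clutch
#'   speckling (PC1) on female mass.
#' @param egg_mass_to_day15_mass_slope Standardized slope of day-15 chick
#'   mass on origin-clutch average egg mass.
#' @param sex_effect_day15 Day-15 mass shift for female chicks (males are the
#'   reference level).
#' @param brood_size_to_prey_slope Standardized slope of male prey delivery
#'   on experimental brood size.
#' @param speckling_to_provisioning_slope Standardized slope of male prey
#'   delivery on the speckling of the eggs he saw (0 = null mode).
#' @param random_nest_sd SD of the origin-nest-within-foster-nest random
#'   intercept on the standardized chick-mass scale (variance
#'   `random_nest_sd^2`; the default gives variance 0.28).
#' @param residual_sd Residual SD of the standardized responses, or `NULL` to
#'   complete each response to unit total variance (so fitted standardized
#'   coefficients estimate the generating slopes directly).
#' @param hatch_drop_rate Per-egg probability of hatch failure/loss; 0 keeps
#'   every egg, larger values mimic field attrition.
#' @param seed Integer seed.
#' @return Object of class `experiment_params`.
#' @export
experiment_params <- function(n_nests = 48L,
                              clutch_size_range = c(6L, 10L),
                              female_mass_to_speckling_slope = -0.55,
                              egg_mass_to_day15_mass_slope = 0.25,
                              sex_effect_day15 = -0.59,
                              brood_size_to_prey_slope = 0.54,
                              speckling_to_provisioning_slope = 0,
                              random_nest_sd = sqrt(0.28),
                              residual_sd = NULL,
                              hatch_drop_rate = 0,
                              seed = 1L) {
  stopifnot_scalar(n_nests, "n_nests", lower = 1)
  if (n_nests < 4 || n_nests %% 4 != 0) {
    stop("`n_nests` must be a multiple of 4: the double cross-fostering needs ",
         "egg-swap pairs plus a second, disjoint chick-swap pairing",
         call. = FALSE)
  }
  if (length(clutch_size_range) != 2L || any(clutch_size_range < 1) ||
      clutch_size_range[1] > clutch_size_range[2]) {
    stop("`clutch_size_range` must be an increasing positive interval", call. = FALSE)
  }
  stopifnot_scalar(random_nest_sd, "random_nest_sd", lower = 0)
  stopifnot_scalar(hatch_drop_rate, "hatch_drop_rate", lower = 0, upper = 0.9)
  if (!is.null(residual_sd)) stopifnot_scalar(residual_sd, "residual_sd", lower = 0)
  structure(list(
    n_nests = as.integer(n_nests),
    clutch_size_range = as.integer(clutch_size_range),
    female_mass_to_speckling_slope = female_mass_to_speckling_slope,
    egg_mass_to_day15_mass_slope = egg_mass_to_day15_mass_slope,
    sex_effect_day15 = sex_effect_day15,
    brood_size_to_prey_slope = brood_size_to_prey_slope,
    speckling_to_provisioning_slope = speckling_to_provisioning_slope,
    random_nest_sd = random_nest_sd,
    residual_sd = residual_sd,
    hatch_drop_rate = hatch_drop_rate,
    seed = as.integer(seed)
  ), class = "experiment_params")
}

# residual sd completing a response to unit variance given the explained part
complete_resid <- function(explained_var, residual_sd) {
  if (!is.null(residual_sd)) return(residual_sd)
  sqrt(max(0.05, 1 - explained_var))
}

#' Pair clutches for the egg swap
#'
#' Whole clutches are exchanged at the start of incubation between nests that
#' began incubating on the same day and differ in clutch size by not more
#' than two eggs. Given nests' incubation dates and clutch sizes, this finds
#' such a perfect pairing (within each date, sorted clutch sizes are paired
#' adjacently) or fails loudly — an infeasible pairing is an error, never a
#' silent relaxation of the matching rule.
#'
#' @param clutch_sizes Integer vector.
#' @param dates Incubation start dates (same length); default all equal.
#' @param max_diff Maximum tolerated clutch-size difference.
#' @return Two-column matrix of nest indices, one row per swap pair.
#' @export
pair_clutches <- function(clutch_sizes, dates = rep(1L, length(clutch_sizes)),
                          max_diff = 2L) {
  n <- length(clutch_sizes)
  if (n < 2L || n %% 2L != 0L) {
    stop("need an even number (>= 2) of nests to pair", call. = FALSE)
  }
  if (length(dates) != n) stop("`dates` length mismatch", call. = FALSE)
  pairs <- NULL
  for (d in unique(dates)) {
    idx <- which(dates == d)
    if (length(idx) %% 2L != 0L) {
      stop(sprintf("infeasible pairing: odd number of nests began incubation on date %s", d),
           call. = FALSE)
    }
    idx <- idx[order(clutch_sizes[idx])]
    for (k in seq(1L, length(idx), by = 2L)) {
      a <- idx[k]; b <- idx[k + 1L]
      if (abs(clutch_sizes[a] - clutch_sizes[b]) > max_diff) {
        stop(sprintf(
          "infeasible pairing: nests %d and %d differ in clutch size by %d (> %d)",
          a, b, abs(clutch_sizes[a] - clutch_sizes[b]), max_diff), call. = FALSE)
      }
      pairs <- rbind(pairs, c(a, b))
    }
  }
  pairs
}

#' Cross-foster chicks between paired broods, matched for mass rank
#'
#' Within each pair of broods, chicks are ranked by mass (ties broken
#' randomly under the seed) and exchanged rank-for-rank: a swapped chick
#' occupies the same mass rank in the recipient brood that it held in the
#' donor brood. `ranks = "all"` exchanges every shared rank; `"alternate"`
#' exchanges ranks 1, 3, 5, ... (used by the double cross-fostering design so
#' each nest ends up rearing a mix from two origin nests); an integer vector
#' selects ranks explicitly. Ranks beyond the smaller brood stay put.
#'
#' @param broods List of numeric chick-mass vectors, one per brood (no brood
#'   may be empty).
#' @param pairs Two-column matrix of brood indices already assigned to swap
#'   pairs; default pairs consecutive broods.
#' @param ranks `"all"`, `"alternate"`, or an integer vector of ranks to swap.
#' @param seed Integer seed for random tie-breaking.
#' @return Data frame with one row per chick: `brood` (natal brood index),
#'   `chick` (index within brood), `mass`, `rank`, `swapped`, and `dest`
#'   (rearing brood index).
#' @export
crossfoster_chicks <- function(broods, pairs = NULL, ranks = "all", seed = 1L) {
  if (!is.list(broods) || !length(broods)) stop("`broods` must be a nonempty list", call. = FALSE)
  sizes <- lengths(broods)
  if (any(sizes == 0L)) stop("brood of size 0", call. = FALSE)
  if (is.null(pairs)) {
    if (length(broods) %% 2L != 0L) stop("odd number of broods and no `pairs` given", call. = FALSE)
    pairs <- matrix(seq_along(broods), ncol = 2L, byrow = TRUE)
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(broods), function(b) {
      data.frame(brood = b, chick = seq_len(sizes[b]), mass = broods[[b]],
                 rank = rank(broods[[b]], ties.method = "random"),
                 swapped = FALSE, dest = b)
    }))
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      m <- min(sizes[a], sizes[b])
      swap_ranks <- if (identical(ranks, "all")) seq_len(m)
        else if (identical(ranks, "alternate")) seq(1L, m, by = 2L)
        else intersect(as.integer(ranks), seq_len(m))
      ia <- which(out$brood == a & out$rank %in% swap_ranks)
      ib <- which(out$brood == b & out$rank %in% swap_ranks)
      out$dest[ia] <- b; out$swapped[ia] <- TRUE
      out$dest[ib] <- a; out$swapped[ib] <- TRUE
    }
    out
  })
}

#' Simulate a complete double cross-fostering experiment
#'
#' Generates a field season: paired nests swap whole clutches at the start of
#' incubation (partners share the incubation date and differ in clutch size by
#' at most two eggs); on day 1 hatchlings are swapped, matched for mass rank,
#' between broods of a second, disjoint pairing, so that each nest ultimately
#' rears chicks from two other nests and none of its own. Provisioning is
#' filmed on days 9-10 (prey delivered per hour = visit rate x average prey
#' size) and chicks are weighed on days 3, 7 and 15. All responses follow the
#' configured standardized linear structure plus an
#' origin-nest-within-foster-nest random intercept and residual noise.
#'
#' @param params An [experiment_params()] object.
#' @param seed Optional integer overriding `params$seed`.
#' @return Object of class `speckle_experiment`: data frames `nests`, `eggs`,
#'   `chicks`, `provisioning`, the egg-swap `pairs`, and `params`.
#' @seealso [provisioning_data()], [chick_data()] for the model frames.
#' @export
generate_experiment <- function(params = experiment_params(), seed = NULL) {
  stopifnot(inherits(params, "experiment_params"))
  if (is.null(seed)) seed <- params$seed
  n <- params$n_nests
  rng <- params$clutch_size_range
  with_seed(seed, {
    # --- nests, egg-swap pairs (generated jointly so pairing is feasible) ---
    pair_id <- rep(seq_len(n / 2L), each = 2L)
    egg_partner <- ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)
    # chick-swap partner: first nest of pair 2k-1 with first nest of pair 2k
    chick_partner <- integer(n)
    for (q in seq_len(n / 4L)) {
      base <- (q - 1L) * 4L
      chick_partner[base + 1:4] <- base + c(3L, 4L, 1L, 2L)
    }
    sample1 <- function(v) v[sample.int(length(v), 1L)]  # safe for length-1 v
    dates <- integer(n)
    clutch <- integer(n)
    npair <- n %/% 2L
    # incubation starts late enough that lay dates (start minus clutch size)
    # stay positive; dates are spread without replacement when possible
    date_pool <- 12:40
    pair_dates <- if (npair <= length(date_pool)) sample(date_pool, npair)
                  else sample(date_pool, npair, replace = TRUE)
    for (p in seq_len(npair)) {
      i <- (p - 1L) * 2L + 1:2
      dates[i] <- pair_dates[p]
      c1 <- sample1(rng[1]:rng[2])
      c2 <- sample1(max(rng[1], c1 - 2L):min(rng[2], c1 + 2L))
      clutch[i] <- c(c1, c2)
    }
    fm_z <- stats::rnorm(n); mm_z <- stats::rnorm(n)
    ft_z <- stats::rnorm(n); mt_z <- stats::rnorm(n)
    b_fm <- params$female_mass_to_speckling_slope
    pc1 <- b_fm * fm_z + complete_resid(b_fm^2, params$residual_sd) * stats::rnorm(n)
    eggmass_z <- stats::rnorm(n)
    nests <- data.frame(
      nest_id = seq_len(n), pair_id = pair_id, egg_partner = egg_partner,
      chick_partner = chick_partner, incubation_date = dates,
      lay_date = dates - clutch,
      clutch_size = clutch,
      female_mass = 18 + 1.2 * fm_z, female_tarsus = 19.5 + 0.6 * ft_z,
      male_mass = 18.5 + 1.2 * mm_z, male_tarsus = 19.8 + 0.6 * mt_z,
      pc1_speckling = pc1, egg_mass_z = eggmass_z,
      avg_egg_mass = 1.7 + 0.12 * eggmass_z
    )
    # --- eggs and the egg swap ---
    eggs <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- clutch[i]
      data.frame(egg_id = paste0(i, "-", seq_len(k)), origin_nest = i,
                 incubating_nest = egg_partner[i], lay_order = seq_len(k),
                 mass = nests$avg_egg_mass[i] + stats::rnorm(k, 0, 0.03))
    }))
    # --- hatching and chick swap ---
    eggs$hatched <- stats::rbinom(nrow(eggs), 1L, 1 - params$hatch_drop_rate) == 1L
    hatched <- eggs[eggs$hatched, , drop = FALSE]
    if (!nrow(hatched)) stop("no eggs hatched; lower `hatch_drop_rate`", call. = FALSE)
    chicks <- data.frame(
      chick_id = paste0("c", seq_len(nrow(hatched))),
      origin_nest = hatched$origin_nest,
      hatch_nest = hatched$incubating_nest,
      sex = factor(ifelse(stats::rbinom(nrow(hatched), 1L, 0.5) == 1L,
                          "female", "male"), levels = c("male", "female")),
      mass_d1 = 2.5 + 0.3 * stats::rnorm(nrow(hatched))
    )
    broods <- split(chicks$mass_d1, factor(chicks$hatch_nest, levels = seq_len(n)))
    nonempty <- which(lengths(broods) > 0L)
    swap_pairs <- unique(t(apply(cbind(seq_len(n), chick_partner), 1L, sort)))
    swap_pairs <- swap_pairs[swap_pairs[, 1] %in% nonempty &
                             swap_pairs[, 2] %in% nonempty, , drop = FALSE]
    cf <- crossfoster_chicks(broods[nonempty], pairs = matrix(
      match(swap_pairs, nonempty), ncol = 2L), ranks = "alternate",
      seed = sample.int(.Machine$integer.max %/% 2L, 1L))
    cf$brood <- nonempty[cf$brood]
    cf$dest <- nonempty[cf$dest]
    ord <- order(cf$brood, cf$chick)
    cf <- cf[ord, , drop = FALSE]
    chicks <- chicks[order(chicks$hatch_nest), , drop = FALSE]
    chicks$foster_nest <- cf$dest
    chicks$mass_rank <- cf$rank
    chicks$swapped <- cf$swapped
    # --- brood sizes after the swap ---
    brood_size <- tabulate(chicks$foster_nest, nbins = n)
    nests$brood_size_exp <- brood_size
    # --- chick masses (standardized scale, then raw grams) ---
    grp <- interaction(chicks$foster_nest, chicks$origin_nest, drop = TRUE)
    b_nest <- stats::rnorm(nlevels(grp), 0, params$random_nest_sd)[as.integer(grp)]
    var_b <- params$random_nest_sd^2
    e15 <- params$egg_mass_to_day15_mass_slope
    sx <- params$sex_effect_day15
    fem <- as.numeric(chicks$sex == "female")
    em <- nests$egg_mass_z[chicks$origin_nest]
    nk <- nrow(chicks)
    z3 <- b_nest + complete_resid(var_b, params$residual_sd) * stats::rnorm(nk)
    z7 <- 0.16 * em + b_nest +
      complete_resid(0.16^2 + var_b, params$residual_sd) * stats::rnorm(nk)
    z15 <- e15 * em + sx * fem + b_nest +
      complete_resid(e15^2 + sx^2 * 0.25 + var_b, params$residual_sd) * stats::rnorm(nk)
    chicks$mass_d3 <- 4 + 0.8 * z3
    chicks$mass_d7 <- 9 + 1.4 * z7
    chicks$mass_d15 <- 16 + 1.3 * z15
    # --- provisioning (days 9-10): prey delivered = visit rate x prey size ---
    brood_z <- as.numeric(scale(brood_size))
    pc1_inc <- nests$pc1_speckling[nests$egg_partner]
    bb <- params$brood_size_to_prey_slope
    bs <- params$speckling_to_provisioning_slope
    prey_m_z <- bb * brood_z + bs * pc1_inc +
      complete_resid(bb^2 + bs^2, params$residual_sd) * stats::rnorm(n)
    prey_f_z <- stats::rnorm(n)
    mk_prov <- function(z, parent) {
      delivered <- pmax(5, 60 + 15 * z)
      visits <- pmax(6, stats::rnorm(n, 14, 2.5))
      data.frame(nest_id = seq_len(n), parent = parent, visit_rate = visits,
                 prey_size = delivered / visits, prey_delivered = delivered)
    }
    provisioning <- rbind(mk_prov(prey_m_z, "male"), mk_prov(prey_f_z, "female"))
    rownames(eggs) <- rownames(chicks) <- rownames(provisioning) <- NULL
    structure(list(nests = nests, eggs = eggs, chicks = chicks,
                   provisioning = provisioning,
                   pairs = cbind(seq_len(n), egg_partner)[seq_len(n) %% 2L == 1L, , drop = FALSE],
                   params = params),
              class = "speckle_experiment")
  })
}

#' @method print speckle_experiment
#' @export
print.speckle_experiment <- function(x, ...) {
  cat(sprintf("Double cross-fostering experiment: %d nests, %d eggs (%d hatched), %d chicks\n",
              nrow(x$nests), nrow(x$eggs), sum(x$eggs$hatched), nrow(x$chicks)))
  invisible(x)
}

#' Nest-level model frame for the provisioning analysis
#'
#' One row per nest with the male-provisioning response and the covariates of
#' the provisioning model: experimental brood size, female prey delivery,
#' clutch size, the speckling of the eggs the female laid and of the eggs she
#' incubated (PC1), lay date and average egg mass.
#'
#' @param x A `speckle_experiment`.
#' @return Data frame.
#' @export
provisioning_data <- function(x) {
  stopifnot(inherits(x, "speckle_experiment"))
  nests <- x$nests
  pm <- x$provisioning[x$provisioning$parent == "male", ]
  pf <- x$provisioning[x$provisioning$parent == "female", ]
  data.frame(
    nest_id = nests$nest_id,
    prey_male = pm$prey_delivered[match(nests$nest_id, pm$nest_id)],
    prey_female = pf$prey_delivered[match(nests$nest_id, pf$nest_id)],
    brood_size = nests$brood_size_exp,
    clutch_size = nests$clutch_size,
    PC1_laid = nests$pc1_speckling,
    PC1_incubated = nests$pc1_speckling[nests$egg_partner],
    lay_date = nests$lay_date,
    avg_egg_mass = nests$avg_egg_mass
  )
}

#' Chick-level model frame for the chick-mass analyses
#'
#' One row per chick with the mass response at the requested day and the
#' fixed covariates of the chick-mass mixed model, including the three ways
#' egg speckling can enter: the speckling of the chick's origin clutch, of
#' the eggs its foster parents laid, and of the eggs the foster parents
#' incubated. `origin_nest` and `foster_nest` identify the random-factor
#' grouping (origin nest nested within foster nest).
#'
#' @param x A `speckle_experiment`.
#' @param day 3, 7 or 15.
#' @return Data frame (complete cases on the mass response).
#' @export
chick_data <- function(x, day = 15) {
  stopifnot(inherits(x, "speckle_experiment"))
  if (!day %in% c(3, 7, 15)) stop("`day` must be 3, 7 or 15", call. = FALSE)
  nests <- x$nests
  ch <- x$chicks
  d <- data.frame(
    chick_id = ch$chick_id,
    mass = ch[[paste0("mass_d", day)]],
    sex = ch$sex,
    origin_nest = ch$origin_nest,
    foster_nest = ch$foster_nest,
    lay_date = nests$lay_date[ch$foster_nest],
    brood_size = nests$brood_size_exp[ch$foster_nest],
    clutch_size = nests$clutch_size[ch$origin_nest],
    clutch_size_foster = nests$clutch_size[ch$foster_nest],
    avg_egg_mass = nests$avg_egg_mass[ch$origin_nest],
    PC1_origin = nests$pc1_speckling[ch$origin_nest],
    PC1_foster_laid = nests$pc1_speckling[ch$foster_nest],
    PC1_foster_incubated = nests$pc1_speckling[nests$egg_partner[ch$foster_nest]]
  )
  d[stats::complete.cases(d$mass), , drop = FALSE]
}

#' Simulate per-egg pattern metrics directly (no images)
#'
#' A lightweight metrics-level twin of the image generator for experiments
#' that need many replicated clutches of the four pattern variables (e.g. the
#' first-four-eggs-versus-whole-clutch comparison). Clutch identity induces
#' strong positive covariation among the variables; by default there is no
#' lay-order drift, so first-four and whole-clutch summaries differ only by
#' sampling noise. `drift` adds a standardized per-egg trend with lay order to
#' every variable (on the log/logit scale) for sensitivity analyses.
#'
#' @param n_clutches Number of clutches.
#' @param clutch_sizes Integer vector (recycled) of clutch sizes.
#' @param drift Lay-order drift, standardized per unit of scaled lay order.
#' @param seed Integer seed.
#' @return Data frame: `clutch_id`, `lay_order`, and the four metric columns.
#' @export
simulate_egg_metrics <- function(n_clutches, clutch_sizes = 8L, drift = 0,
                                 seed = 1L) {
  sizes <- rep_len(as.integer(clutch_sizes), n_clutches)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_clutches), function(cl) {
      k <- sizes[cl]
      s <- stats::rnorm(1)
      lay <- seq_len(k)
      tr <- drift * as.numeric(scale(lay))
      data.frame(
        clutch_id = cl, lay_order = lay,
        marking_size = exp(log(11) + 0.25 * s + tr + 0.35 * stats::rnorm(k)),
        pattern_contrast = exp(log(580) + 0.20 * s + tr + 0.10 * stats::rnorm(k)),
        pattern_coverage = stats::plogis(stats::qlogis(0.19) + 0.55 * s + tr +
                                           0.35 * stats::rnorm(k)),
        pattern_dispersion = 0.10 * exp(0.45 * s + tr + 0.35 * stats::rnorm(k))
      )
    }))
  })
}
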