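#' Z-standardize model columns
#'
#' Centres and scales the named numeric columns to mean 0, sample SD 1.
#' Principal-component score columns are already standardized by construction
#' and are passed through bit-identically; by default any column whose name
#' starts with `"PC"` is exempt.
#'
#' @param data Data frame.
#' @param columns Columns to standardize; default all numeric columns.
#' @param exempt Columns to pass through untouched.
#' @return `data` with the selected columns standardized.
#' @export
zstandardize <- function(data, columns = NULL,
                         exempt = grep("^PC", names(data), value = TRUE)) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  columns <- setdiff(columns, exempt)
  for (cn in columns) {
    v <- data[[cn]]
    if (!is.numeric(v)) stop(sprintf("column `%s` is not numeric", cn), call. = FALSE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("column `%s` is constant; cannot standardize", cn), call. = FALSE)
    }
    data[[cn]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  data
}

fit_table <- function(terms, B, den_df, Fval, lo, hi, P, num_df = 1) {
  data.frame(term = terms, B = B, num_df = num_df, den_df = den_df,
             F = Fval, ci_lower = lo, ci_upper = hi, P = P,
             row.names = NULL)
}

#' Fit a general linear model on standardized variables
#'
#' Least-squares fit of `response ~ predictors` after Z-standardizing the
#' numeric variables (PC-score columns exempt). Each term is reported the way
#' the field tables are laid out: standardized coefficient B, numerator and
#' denominator df, a marginal (type-III-style) F for that term, the 95%
#' confidence bounds and P, in the predictor order given.
#'
#' @param data Data frame (complete cases on the modelled columns are used).
#' @param response Response column name.
#' @param predictors Character vector of predictor column names, in reporting
#'   order. Factor predictors are allowed and are not standardized.
#' @param standardize Standardize numeric variables first (default `TRUE`).
#' @return Object of class `speckle_fit`.
#' @export
fit_glm <- function(data, response, predictors, standardize = TRUE) {
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (standardize) d <- zstandardize(d)
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient fit; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  tab <- fit_table(terms = rownames(sm),
                   B = sm[, "Estimate"],
                   den_df = fit$df.residual,
                   Fval = sm[, "t value"]^2,
                   lo = ci[, 1], hi = ci[, 2],
                   P = sm[, "Pr(>|t|)"])
  structure(list(table = tab, model = "glm", fit = fit,
                 n_obs = nrow(d), n_groups = NA_integer_,
                 random_variance = NULL),
            class = "speckle_fit")
}

# Closed-form REML log-likelihood for y = X beta + b[group] + e with
# disjoint groups: V = ve I + vb J per group (Woodbury). Used to attach a
# curvature-based SE to the random-intercept variance, which lme4 does not
# report, and as an independent cross-check of the REML variance estimate.
reml_loglik_nested <- function(vb, ve, y, X, group) {
  if (vb < 0 || ve <= 0) return(-Inf)
  p <- ncol(X)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yty <- 0
  logdet <- 0
  for (g in split(seq_along(y), group)) {
    ng <- length(g)
    Xg <- X[g, , drop = FALSE]; yg <- y[g]
    lam <- vb / (ve * (ve + ng * vb))
    sX <- colSums(Xg); sy <- sum(yg)
    XtVX <- XtVX + crossprod(Xg) / ve - lam * tcrossprod(sX)
    XtVy <- XtVy + crossprod(Xg, yg) / ve - lam * sX * sy
    yty <- yty + sum(yg^2) / ve - lam * sy^2
    logdet <- logdet + (ng - 1) * log(ve) + log(ve + ng * vb)
  }
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  quad <- yty - sum(XtVy * beta)
  -0.5 * (logdet + 2 * sum(log(diag(ch))) + quad)
}

# SE of the random-intercept variance from the curvature of the REML
# log-likelihood at (vb, ve), via the observed information (pracma Hessian).
reml_variance_se <- function(vb, ve, y, X, group) {
  f <- function(th) reml_loglik_nested(th[1], th[2], y, X, group)
  H <- tryCatch(pracma::hessian(f, c(vb, ve)), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(NA_real_)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || V[1, 1] <= 0) return(NA_real_)
  sqrt(V[1, 1])
}

#' Fit a linear mixed model with the nested nest random factor
#'
#' REML fit of `response ~ predictors + (1 | foster:origin)` after
#' Z-standardization (PC-score columns exempt), with Satterthwaite
#' (fractional) denominator degrees of freedom for the fixed-effect tests.
#' The random factor is the origin nest nested within the foster nest — one
#' intercept per unique origin-within-foster brood, which controls for
#' multiple chicks sharing both a genetic origin and a rearing nest. Sex is
#' coded with male as the reference level. A singular fit (variance estimate
#' on the zero boundary) is flagged, not masked. Alternatively
#' `random = "two_component"` adds a second intercept for the foster nest
#' itself.
#'
#' @param data Chick-level data frame (see [chick_data()]).
#' @param response Response column name.
#' @param predictors Fixed-effect column names in reporting order.
#' @param origin,foster Grouping column names.
#' @param random `"nested"` (one intercept per origin-within-foster group) or
#'   `"two_component"`.
#' @param standardize Standardize numeric variables first.
#' @param variance_se Attach a curvature SE and interval to the variance
#'   component (skippable in large simulation loops where only the fixed
#'   effects are monitored).
#' @return Object of class `speckle_fit`; `random_variance` holds the
#'   origin-within-foster intercept variance, its curvature SE, and the
#'   Wald interval on the log-variance scale.
#' @export
fit_lmm <- function(data, response, predictors, origin = "origin_nest",
                    foster = "foster_nest", random = c("nested", "two_component"),
                    standardize = TRUE, variance_se = TRUE) {
  random <- match.arg(random)
  cols <- c(response, predictors, origin, foster)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  d$.grp <- interaction(d[[foster]], d[[origin]], drop = TRUE)
  d$.foster <- factor(d[[foster]])
  if (standardize) {
    numcols <- setdiff(names(d)[vapply(d, is.numeric, logical(1))], c(origin, foster))
    d <- zstandardize(d, columns = numcols)
  }
  ranef_txt <- if (random == "nested") "(1 | .grp)" else "(1 | .foster) + (1 | .grp)"
  fml <- stats::as.formula(paste(response, "~",
                                 paste(c(predictors, ranef_txt), collapse = " + ")))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  sm <- summary(fit)$coefficients   # Estimate, SE, df (Satterthwaite), t, P
  tcrit <- stats::qt(0.975, sm[, "df"])
  tab <- fit_table(terms = rownames(sm),
                   B = sm[, "Estimate"],
                   den_df = sm[, "df"],
                   Fval = sm[, "t value"]^2,
                   lo = sm[, "Estimate"] - tcrit * sm[, "Std. Error"],
                   hi = sm[, "Estimate"] + tcrit * sm[, "Std. Error"],
                   P = sm[, "Pr(>|t|)"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == ".grp"]
  ve <- vc$vcov[vc$grp == "Residual"]
  se_vb <- if (variance_se && random == "nested") {
    X <- stats::model.matrix(stats::reformulate(predictors), data = d)
    reml_variance_se(max(vb, 1e-8), ve, d[[response]], X, d$.grp)
  } else NA_real_
  ci_vb <- if (is.finite(se_vb) && vb > 0) {
    exp(log(vb) + c(-1, 1) * 1.96 * se_vb / vb)
  } else c(NA_real_, NA_real_)
  if (singular) warning("singular fit: a random-effect variance is on the zero boundary")
  structure(list(table = tab, model = "lmm", fit = fit,
                 n_obs = nrow(d), n_groups = nlevels(d$.grp),
                 random_variance = list(estimate = vb, se = se_vb,
                                        ci = ci_vb, residual = ve),
                 singular = singular),
            class = "speckle_fit")
}

#' @method print speckle_fit
#' @export
print.speckle_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s fit on standardized variables (n = %d%s)\n",
              toupper(x$model), x$n_obs,
              if (!is.na(x$n_groups)) sprintf(", %d origin-within-foster groups", x$n_groups) else ""))
  tab <- x$table
  tab$df <- if (x$model == "glm") sprintf("1/%.0f", tab$den_df)
            else sprintf("%.2f", tab$den_df)
  out <- data.frame(term = tab$term, B = round(tab$B, digits), df = tab$df,
                    F = round(tab$F, 2),
                    `95% L` = round(tab$ci_lower, digits),
                    `95% U` = round(tab$ci_upper, digits),
                    P = signif(tab$P, 2), check.names = FALSE)
  print(out, row.names = FALSE)
  if (!is.null(x$random_variance)) {
    cat(sprintf("Random factor (origin nest within foster nest): variance %.3f +/- SE %.3f\n",
                x$random_variance$estimate, x$random_variance$se))
    if (isTRUE(x$singular)) cat("NOTE: singular fit (variance on boundary)\n")
  }
  invisible(x)
}

#' @method summary speckle_fit
#' @export
summary.speckle_fit <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.speckle_fit <- function(object, ...) {
  stats::setNames(object$table$B, object$table$term)
}

#' @export
confint.speckle_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) stop("only 95% intervals are tabulated", call. = FALSE)
  m <- as.matrix(object$table[c("ci_lower", "ci_upper")])
  rownames(m) <- object$table$term
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Paper-layout convenience fitters
#'
#' `fit_provisioning()` fits the male prey-delivery GLM (response: prey
#' delivered per hour by the male; brood size, female prey delivery, clutch
#' size, speckling of the eggs laid and incubated, lay date, average egg
#' mass). `fit_chick_mass()` fits the day-3/7/15 chick-mass mixed model with
#' the origin-within-foster random factor. `fit_female_quality()` fits the
#' egg-speckling GLM on female and male size measures.
#'
#' @param x A `speckle_experiment` (or a ready model frame for `data` forms).
#' @param day For `fit_chick_mass()`: 3, 7 or 15.
#' @param ... Passed to [fit_glm()] / [fit_lmm()].
#' @return A `speckle_fit`.
#' @export
fit_provisioning <- function(x, ...) {
  d <- if (inherits(x, "speckle_experiment")) provisioning_data(x) else x
  fit_glm(d, "prey_male",
          c("brood_size", "prey_female", "clutch_size", "PC1_laid",
            "lay_date", "PC1_incubated", "avg_egg_mass"), ...)
}

#' @rdname fit_provisioning
#' @export
fit_chick_mass <- function(x, day = 15, ...) {
  d <- if (inherits(x, "speckle_experiment")) chick_data(x, day = day) else x
  fit_lmm(d, "mass",
          c("lay_date", "brood_size", "PC1_origin", "sex", "avg_egg_mass",
            "PC1_foster_laid", "clutch_size", "clutch_size_foster",
            "PC1_foster_incubated"), ...)
}

#' @rdname fit_provisioning
#' @export
fit_female_quality <- function(x, ...) {
  d <- if (inherits(x, "speckle_experiment")) {
    n <- x$nests
    data.frame(PC1 = n$pc1_speckling, female_mass = n$female_mass,
               female_tarsus = n$female_tarsus, male_mass = n$male_mass,
               egg_mass = n$avg_egg_mass, lay_date = n$lay_date,
               clutch_size = n$clutch_size, male_tarsus = n$male_tarsus)
  } else x
  fit_glm(d, "PC1",
          c("female_mass", "female_tarsus", "male_mass", "egg_mass",
            "lay_date", "clutch_size", "male_tarsus"), ...)
}

#' Rejection rate of a model term over simulation replicates
#'
#' Simulates experiments from `params`, refits a model on each, and reports
#' the fraction of replicates in which each requested term is rejected at
#' `alpha`, with a two-sided exact binomial confidence interval. With the
#' speckling slopes at 0 this estimates the type-I error of the pipeline's
#' speckling tests.
#'
#' @param params [experiment_params()] for the generator.
#' @param fitter Function mapping a `speckle_experiment` to a `speckle_fit`
#'   (e.g. [fit_provisioning()] or `function(x) fit_chick_mass(x, day = 15)`).
#' @param terms Term names (rows of the fit table) to monitor.
#' @param reps Number of replicates (>= 1).
#' @param alpha Significance level; `alpha = 0` rejects nothing, exactly.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return Data frame: `term`, `rate`, `ci_lower`, `ci_upper`, `reps`.
#' @export
rejection_rate <- function(params, fitter, terms, reps = 200L, alpha = 0.05,
                           seed = 1L) {
  stopifnot(reps >= 1)
  hits <- matrix(0L, nrow = reps, ncol = length(terms),
                 dimnames = list(NULL, terms))
  for (r in seq_len(reps)) {
    ex <- generate_experiment(params, seed = as.integer(seed) + r)
    ft <- suppressWarnings(fitter(ex))
    p <- ft$table$P[match(terms, ft$table$term)]
    hits[r, ] <- as.integer(!is.na(p) & p < alpha)
  }
  rates <- colMeans(hits)
  ci <- t(vapply(colSums(hits), function(k) {
    as.numeric(stats::binom.test(k, reps)$conf.int)
  }, numeric(2)))
  data.frame(term = terms, rate = rates, ci_lower = ci[, 1], ci_upper = ci[, 2],
             reps = reps, row.names = NULL)
}

#' Paired t-tests: first four eggs versus the whole clutch
#'
#' For each of the four pattern variables, a classical paired t-test of the
#' clutch means computed from the first four eggs against those computed from
#' every egg in the clutch. Clutches whose paired difference is identically
#' zero across the board yield the degenerate-path report (`t = NA`,
#' `note = "zero difference"`) rather than a spurious statistic.
#'
#' @param first_four,whole Clutch-level tables from [clutch_pattern()] (modes
#'   `"first_n"` and `"whole"`), matched on `clutch_id`.
#' @return Data frame: `variable`, `t`, `df`, `P`, `mean_diff`, `note`.
#' @export
paired_t <- function(first_four, whole) {
  m <- merge(first_four, whole, by = "clutch_id", suffixes = c("_f4", "_all"))
  if (nrow(m) < 2) stop("need at least 2 paired clutches", call. = FALSE)
  out <- lapply(metric_cols, function(v) {
    d <- m[[paste0(v, "_f4")]] - m[[paste0(v, "_all")]]
    if (stats::sd(d) == 0) {
      return(data.frame(variable = v, t = NA_real_, df = length(d) - 1L,
                        P = NA_real_, mean_diff = mean(d),
                        note = "zero difference"))
    }
    tt <- stats::t.test(d)
    data.frame(variable = v, t = unname(tt$statistic), df = unname(tt$parameter),
               P = tt$p.value, mean_diff = mean(d), note = "")
  })
  do.call(rbind, out)
}
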