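#' Log-transform pattern metrics
#'
#' Natural log with a small offset `log(x + eps)`. Coverage and dispersion can
#' be exactly zero on lightly marked eggs, so a fixed offset of `1e-3` keeps
#' the transform defined; for marking size and contrast (bounded well away
#' from zero on patterned eggs) the offset is numerically irrelevant.
#'
#' @param x Numeric vector or data frame of the four metric columns.
#' @param eps Offset added before taking logs.
#' @return Same shape as `x`, log-transformed.
#' @export
log_metrics <- function(x, eps = 1e-3) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) log(col + eps))
    return(x)
  }
  log(x + eps)
}

metric_cols <- c("marking_size", "pattern_contrast",
                 "pattern_coverage", "pattern_dispersion")

#' Aggregate egg metrics to clutch level
#'
#' The unit of analysis is the clutch, not the egg: per-clutch means of the
#' log-transformed pattern variables are computed over the first `first_n`
#' eggs by lay order (the eggs that are photographed in the field), or over
#' all eggs in whole-clutch mode.
#'
#' @param eggs Data frame with columns `clutch_id`, `lay_order` and the four
#'   metric columns (`marking_size`, `pattern_contrast`, `pattern_coverage`,
#'   `pattern_dispersion`).
#' @param first_n Number of earliest-laid eggs to use; `Inf` (or
#'   `mode = "whole"`) uses every egg.
#' @param mode `"first_n"` or `"whole"`.
#' @param eps Log offset, see [log_metrics()].
#' @return Data frame, one row per clutch: `clutch_id`, the four log-metric
#'   means, `n_eggs` used, and `partial` (`TRUE` when a clutch supplied fewer
#'   than `first_n` eggs).
#' @export
clutch_pattern <- function(eggs, first_n = 4L, mode = c("first_n", "whole"),
                           eps = 1e-3) {
  mode <- match.arg(mode)
  need <- c("clutch_id", "lay_order", metric_cols)
  miss <- setdiff(need, names(eggs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  out <- lapply(split(eggs, eggs$clutch_id), function(cl) {
    cl <- cl[order(cl$lay_order), , drop = FALSE]
    use <- if (mode == "whole") cl else cl[seq_len(min(nrow(cl), first_n)), ]
    lm_ <- log_metrics(use[metric_cols], eps = eps)
    data.frame(clutch_id = cl$clutch_id[1],
               as.list(colMeans(lm_)),
               n_eggs = nrow(use),
               partial = (mode == "first_n" && nrow(cl) < first_n))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Principal components of the four pattern variables
#'
#' Eigendecomposition of the correlation matrix of the four (log) pattern
#' variables — the variables carry incommensurate units, so each is
#' standardised first. Component signs are fixed so that pattern coverage
#' loads positively: a high PC1 then means a more extensively, more darkly
#' speckled egg.
#'
#' @param x Data frame or matrix with the four metric columns (any additional
#'   columns are ignored); at least 5 rows, no constant column.
#' @return Object of class `speckle_pca`: `loadings` (4 x 4), `eigenvalues`,
#'   `percent_variance` (sums to 100), `scores` (one row per input row),
#'   `center`, `scale`.
#' @export
pca_pattern <- function(x) {
  if (is.data.frame(x) && all(metric_cols %in% names(x))) x <- x[metric_cols]
  X <- as.matrix(x)
  if (ncol(X) != 4L) stop("expected the four pattern-variable columns", call. = FALSE)
  if (nrow(X) < 5L) stop("need at least 5 rows for a 4-variable PCA", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2, ctr), 2, sds, `/`)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  L <- eig$vectors
  cov_row <- match("pattern_coverage", colnames(X))
  if (is.na(cov_row)) cov_row <- 3L
  for (j in seq_len(ncol(L))) {
    s <- L[cov_row, j]
    if (s == 0) s <- L[which.max(abs(L[, j])), j]
    if (s < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", 1:4))
  scores <- Z %*% L
  structure(list(loadings = L,
                 eigenvalues = eig$values,
                 percent_variance = 100 * eig$values / sum(eig$values),
                 scores = scores,
                 center = ctr, scale = sds),
            class = "speckle_pca")
}

#' @method print speckle_pca
#' @export
print.speckle_pca <- function(x, ...) {
  cat("PCA of the four egg-pattern variables (correlation matrix)\n")
  pv <- sprintf("%.1f%%", x$percent_variance)
  cat("  variance explained:", paste(paste0("PC", 1:4, " ", pv), collapse = ", "), "\n")
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Clutch-level speckling scores
#'
#' Computes PC1/PC2 speckling scores for each clutch. By default the PCA is
#' performed at egg level (pooling all measured eggs) and the per-egg scores
#' are averaged within clutch; the alternative performs the PCA directly on
#' the clutch-level log-metric means.
#'
#' @param eggs Per-egg metrics data frame (see [clutch_pattern()] for the
#'   required columns).
#' @param level `"egg"` (default) or `"clutch"`.
#' @param first_n,mode,eps Passed to [clutch_pattern()].
#' @return List with `clutches` (the [clutch_pattern()] table plus `PC1`,
#'   `PC2`) and `pca` (the fitted [pca_pattern()] object).
#' @export
speckle_scores <- function(eggs, level = c("egg", "clutch"), first_n = 4L,
                           mode = c("first_n", "whole"), eps = 1e-3) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  cl <- clutch_pattern(eggs, first_n = first_n, mode = mode, eps = eps)
  if (level == "egg") {
    lm_ <- log_metrics(eggs[metric_cols], eps = eps)
    pca <- pca_pattern(lm_)
    sc <- data.frame(clutch_id = eggs$clutch_id,
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
    # same egg subset as the clutch means
    ord <- order(eggs$clutch_id, eggs$lay_order)
    keep <- unlist(lapply(split(ord, eggs$clutch_id[ord]), function(i) {
      if (mode == "whole") i else i[seq_len(min(length(i), first_n))]
    }), use.names = FALSE)
    sc <- sc[keep, , drop = FALSE]
    agg <- stats::aggregate(cbind(PC1, PC2) ~ clutch_id, data = sc, FUN = mean)
  } else {
    pca <- pca_pattern(cl[metric_cols])
    agg <- data.frame(clutch_id = cl$clutch_id,
                      PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
  }
  list(clutches = merge(cl, agg, by = "clutch_id"), pca = pca)
}
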