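# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are deterministic without clobbering
# the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Row split of a height into three slabs (upper/middle/base), remainder to the
# middle slab.
third_heights <- function(h) {
  third <- h %/% 3L
  c(upper = third, middle = h - 2L * third, base = third)
}

# Bounding box of a logical mask: list(rows = r1:r2, cols = c1:c2).
mask_bbox <- function(mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(rows = rr[1]:rr[2], cols = cc[1]:cc[2])
}
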