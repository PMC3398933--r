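# Independent oracles, deliberately built from first principles rather than
# from the package's own code paths.

# Direct 2-D discrete Fourier transform via explicit DFT matrices
# (F = W %*% X %*% W, W_{jk} = exp(-2*pi*i*j*k/n)): a literal Fourier sum,
# independent of stats::fft.
dft2_direct <- function(x) {
  n <- nrow(x)
  jk <- outer(0:(n - 1), 0:(n - 1))
  W <- exp(-2i * pi * jk / n)
  W %*% x %*% W
}

# signed frequency index of DFT bin k (0-based) for an n-point transform
freq_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k < (n + 1) %/% 2, k, k - n)
}

# Per-band energies (window mean square) computed wholly in the frequency
# domain from the direct DFT, using Parseval's identity.
band_energies_direct <- function(x, bands) {
  n <- nrow(x)
  FT <- dft2_direct(x)
  f <- freq_index(n)
  r <- sqrt(outer(f^2, f^2, `+`))
  vapply(seq_len(nrow(bands)), function(b) {
    sel <- r > bands$low[b] & r <= bands$high[b] & r > 0
    sum(Mod(FT[sel])^2) / n^4
  }, numeric(1))
}

# Exhaustive Otsu search: tries every candidate cutoff level and computes the
# between-class variance directly from the raw pixel partition.
otsu_bruteforce <- function(values, n_levels = 4096L) {
  rng <- range(values)
  lev <- as.integer(round((values - rng[1]) / diff(rng) * (n_levels - 1)))
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:(n_levels - 1)) {
    a <- lev <= t
    n0 <- sum(a)
    if (n0 == 0 || n0 == length(lev)) next
    sb <- n0 * (length(lev) - n0) * (mean(lev[a]) - mean(lev[!a]))^2
    if (sb > best) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# build a bare cone_catch_image from a matrix (full mask unless given)
as_catch <- function(m, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  structure(list(catch = m, mask = mask, scale_mm_px = 0.1),
            class = "cone_catch_image")
}

# build a bare one- or two-plane egg_image
as_egg_image <- function(planes, mask = NULL) {
  if (!is.list(planes)) planes <- list(visible = planes)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(planes[[1]]), ncol(planes[[1]]))
  structure(list(planes = planes, mask = mask, scale_mm_px = 0.1, standard = 1),
            class = "egg_image")
}
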