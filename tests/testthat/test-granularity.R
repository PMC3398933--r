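spectrum_of <- function(energies) {
  structure(list(bands = default_bands(), energies = energies),
            class = "granularity_spectrum")
}

test_that("the filter bank tiles frequency space in non-overlapping octaves", {
  b <- default_bands()
  expect_equal(nrow(b), 7L)
  expect_equal(b$filter_size, c(2, 4, 8, 16, 32, 64, 128))
  expect_true(all(b$low < b$high))
  expect_equal(b$high[-7], b$low[-1])   # contiguous, no overlap
})

test_that("region split gives equal thirds with the remainder to the middle", {
  img300 <- as_catch(matrix(runif(300 * 40), 300, 40))
  r <- split_regions(img300)
  expect_equal(vapply(r, function(x) nrow(x$catch), numeric(1)),
               c(upper = 100, middle = 100, base = 100))
  img301 <- as_catch(matrix(runif(301 * 40), 301, 40))
  r2 <- split_regions(img301)
  expect_equal(vapply(r2, function(x) nrow(x$catch), numeric(1)),
               c(upper = 100, middle = 101, base = 100))
  # disjoint slabs covering the box: row counts add up and contents concatenate
  expect_equal(do.call(rbind, lapply(r2, function(x) x$catch)), img301$catch)
})

test_that("a constant image decomposes to all-zero bands", {
  bi <- bandpass_decompose(matrix(2.5, 32, 32))
  for (b in bi) expect_lt(max(abs(b)), 1e-12)
})

test_that("a pure sinusoid lands only in its own band", {
  n <- 64
  x <- matrix(sin(2 * pi * 8 * (0:(n - 1)) / n), n, n, byrow = TRUE)
  bi <- bandpass_decompose(x)
  en <- vapply(bi, function(b) mean(b^2), numeric(1))
  expect_equal(which.max(en), 3L)          # band centred on 8 cycles/width
  expect_lt(sum(en[-3]) / en[3], 1e-18)
})

test_that("band energies match a direct discrete-Fourier-sum oracle", {
  set.seed(11)
  x <- matrix(rnorm(64 * 64), 64, 64)
  bands <- default_bands()
  bi <- bandpass_decompose(x, bands)
  en <- vapply(bi, function(b) mean(b^2), numeric(1))
  oracle <- band_energies_direct(x, bands)
  expect_equal(en, oracle, tolerance = 1e-9)
})

test_that("band energies conserve the spectral energy of the covered annulus", {
  set.seed(12)
  x <- matrix(rnorm(64 * 64), 64, 64)
  bands <- default_bands()
  en <- vapply(bandpass_decompose(x, bands), function(b) mean(b^2), numeric(1))
  FT <- dft2_direct(x)
  f <- freq_index(64)
  r <- sqrt(outer(f^2, f^2, `+`))
  covered <- sum(Mod(FT[r > min(bands$low)])^2) / 64^4
  expect_equal(sum(en), covered, tolerance = 1e-9)
})

test_that("radially symmetric filters are robust to 90-degree rotation", {
  eg <- generate_egg_image(small_params(), seed = 3)
  x <- eg$image$planes$visible[17:80, 17:80]
  rot <- t(x)[, ncol(x):1]
  en <- vapply(bandpass_decompose(x), function(b) mean(b^2), numeric(1))
  en_r <- vapply(bandpass_decompose(rot), function(b) mean(b^2), numeric(1))
  nz <- en > 0   # the highest octave is empty below its Nyquist on this window
  expect_lt(max(abs(en[nz] - en_r[nz]) / en[nz]), 0.01)
})

test_that("the egg spectrum is the area-weighted mean of regional spectra", {
  set.seed(21)
  reg <- as_catch(matrix(runif(40 * 40), 40, 40))
  one <- granularity_spectrum(list(reg), window = 64, intensity_scale = 1)
  three <- granularity_spectrum(list(reg, reg, reg), window = 64, intensity_scale = 1)
  expect_equal(three$energies, one$energies, tolerance = 1e-12)
  # a flat region contributes zero energy to every band
  flat <- as_catch(matrix(0.7, 40, 40))
  mixed <- granularity_spectrum(list(flat, reg, reg), window = 64, intensity_scale = 1)
  expect_lt(max(mixed$regional_energies[1, ]), 1e-12)
  expect_equal(mixed$energies, 2 / 3 * one$energies, tolerance = 1e-9)
})

test_that("marking size is the peak filter size, ties to the larger marking", {
  expect_equal(marking_size(spectrum_of(c(0, 0, 1, 0, 0, 0, 0))), 8)
  expect_equal(marking_size(spectrum_of(c(0, 1, 1, 0, 0, 0, 0))), 4)
  ms <- marking_size(spectrum_of(rep(0, 7)))
  expect_true(is.na(ms))
  expect_true(attr(ms, "no_pattern"))
})

test_that("pattern contrast is amplitude-scale and matches the sinusoid oracle", {
  expect_equal(pattern_contrast(spectrum_of(rep(0, 7))), 0)
  n <- 64
  for (a in c(0.5, 1)) {
    x <- matrix(a * sin(2 * pi * 8 * (0:(n - 1)) / n), n, n, byrow = TRUE)
    sp <- granularity_spectrum(list(as_catch(x)), window = n, intensity_scale = 1)
    # a sinusoid of amplitude a has rms a/sqrt(2)
    expect_equal(pattern_contrast(sp), a / sqrt(2), tolerance = 1e-6)
  }
})
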