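test_that("clutch pairing enforces the matching rule", {
  p <- pair_clutches(c(8, 8))
  expect_equal(sort(p[1, ]), c(1, 2))
  expect_error(pair_clutches(c(6, 9)), "differ in clutch size by 3")
  expect_error(pair_clutches(c(8, 8, 8)), "even number")
  expect_error(pair_clutches(c(8, 8), dates = c(1, 2)), "odd number")
  # within-date adjacent-size pairing finds a feasible match when one exists
  p2 <- pair_clutches(c(6, 10, 7, 9), dates = c(1, 1, 1, 1))
  sizes <- matrix(c(6, 10, 7, 9)[p2], ncol = 2)
  expect_true(all(abs(sizes[, 1] - sizes[, 2]) <= 2))
})

test_that("chicks are exchanged rank for rank", {
  cf <- crossfoster_chicks(list(c(10, 12, 14), c(11, 13, 15)), seed = 1)
  expect_true(all(cf$swapped))
  expect_equal(cf$dest, c(2, 2, 2, 1, 1, 1))
  # rank-k of brood 1 pairs with rank-k of brood 2
  expect_equal(cf$rank[cf$brood == 1], cf$rank[cf$brood == 2])
  # alternate mode leaves even ranks at home
  cf2 <- crossfoster_chicks(list(c(10, 12, 14), c(11, 13, 15)),
                            ranks = "alternate", seed = 1)
  expect_equal(sort(cf2$rank[cf2$swapped & cf2$brood == 1]), c(1, 3))
  expect_error(crossfoster_chicks(list(numeric(0), c(1, 2))), "size 0")
})

test_that("tied masses break deterministically under the seed", {
  br <- list(rep(5, 4), rep(5, 4))
  a <- crossfoster_chicks(br, ranks = "alternate", seed = 3)
  b <- crossfoster_chicks(br, ranks = "alternate", seed = 3)
  expect_identical(a, b)
})

test_that("generated experiments satisfy the double cross-fostering invariants", {
  for (s in 1:30) {
    ex <- generate_experiment(experiment_params(n_nests = 8, seed = s))
    n <- ex$nests
    # egg swap: a perfect matching of nests, partners share the incubation
    # date and differ in clutch size by at most two eggs
    expect_equal(n$egg_partner[n$egg_partner], n$nest_id)
    expect_false(any(n$egg_partner == n$nest_id))
    expect_equal(n$incubation_date, n$incubation_date[n$egg_partner])
    expect_true(all(abs(n$clutch_size - n$clutch_size[n$egg_partner]) <= 2))
    # every incubated clutch originates from exactly one other nest
    inc <- unique(ex$eggs[c("origin_nest", "incubating_nest")])
    expect_equal(nrow(inc), 8)
    expect_false(any(inc$origin_nest == inc$incubating_nest))
    # chick stage: each nest rears chicks from exactly two origin nests and
    # none of its own
    ch <- ex$chicks
    for (nest in n$nest_id) {
      origins <- unique(ch$origin_nest[ch$foster_nest == nest])
      expect_equal(length(origins), 2L)
      expect_false(nest %in% origins)
    }
    # swapped chicks keep their mass rank in the recipient brood
    moved <- ch[ch$swapped, ]
    for (i in seq_len(nrow(moved))) {
      recip <- ch[ch$hatch_nest == moved$foster_nest[i], ]
      expect_true(moved$mass_rank[i] %in% recip$mass_rank)
    }
    # prey delivered is visit rate times average prey size
    pr <- ex$provisioning
    expect_equal(pr$prey_delivered, pr$visit_rate * pr$prey_size, tolerance = 1e-12)
    # brood sizes match the chick table
    expect_equal(n$brood_size_exp, tabulate(ch$foster_nest, nbins = 8))
  }
})

test_that("experiment generation is deterministic and validates its size", {
  a <- generate_experiment(experiment_params(n_nests = 8, seed = 4))
  b <- generate_experiment(experiment_params(n_nests = 8, seed = 4))
  expect_identical(a, b)
  expect_error(experiment_params(n_nests = 6), "multiple of 4")
  expect_error(experiment_params(n_nests = 2), "multiple of 4")
})

test_that("hatch attrition thins broods without breaking bookkeeping", {
  ex <- generate_experiment(experiment_params(n_nests = 16, hatch_drop_rate = 0.25,
                                              seed = 2))
  expect_lt(nrow(ex$chicks), sum(ex$nests$clutch_size))
  expect_equal(nrow(ex$chicks), sum(ex$eggs$hatched))
  expect_equal(ex$nests$brood_size_exp, tabulate(ex$chicks$foster_nest, nbins = 16))
})

test_that("female mass drives clutch speckling at the configured slope", {
  slopes <- vapply(1:40, function(s) {
    ex <- generate_experiment(experiment_params(n_nests = 48, seed = 100 + s))
    n <- ex$nests
    stats::coef(stats::lm(n$pc1_speckling ~ scale(n$female_mass)))[2]
  }, numeric(1))
  expect_equal(mean(slopes), -0.55, tolerance = 0.05)
})
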