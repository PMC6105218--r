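test_that("enumeration finds the expected compositions", {
  e1 <- enumerate_formulas(236.09496, 2, c(C = 20, H = 30, N = 5, O = 5))
  expect_true("C15H12N2O" %in% e1$formula)
  e2 <- enumerate_formulas(18.01056, 5, c(C = 5, H = 10, N = 3, O = 3))
  expect_true("H2O" %in% e2$formula)
  e3 <- enumerate_formulas(152.04734, 2, c(C = 20, H = 40, O = 10))
  expect_true("C8H8O3" %in% e3$formula)
  # sorted by |ppm|
  expect_true(all(diff(abs(e1$ppm)) >= 0))
  expect_error(enumerate_formulas(100, 0), "tolerance")
  expect_error(enumerate_formulas(-5, 2), "mass")
})

test_that("enumeration is complete and minimal against a brute-force oracle", {
  bounds <- c(C = 20, H = 40, N = 5, O = 10)
  for (mass in c(118.0864, 180.0634, 236.09496, 285.1) ) {
    mine <- enumerate_formulas(mass, 5, bounds)$formula
    ora <- oracle_enumerate(mass, 5, bounds)
    expect_setequal(mine, unname(ora))
  }
})

test_that("golden rules accept real molecules and reject absurd compositions", {
  ok <- golden_rules("C15H12N2O")
  expect_true(ok$rules_passed)
  bad <- golden_rules("CH30")
  expect_false(bad$rules_passed)
  expect_match(bad$failed_rule, "rule4_hc_ratio")
  expect_match(golden_rules("C2H8O")$failed_rule, "rule2_rdbe")  # RDBE < 0
  odd <- golden_rules("C6H7O2")              # half-integer RDBE
  expect_identical(odd$failed_rule, "rule2_rdbe")
  # all 12 packaged suspects pass every applied rule
  batch <- golden_rules(suspect_list()$formula)
  expect_true(all(batch$rules_passed))
})

test_that("isotope fit measures the worst absolute ratio deviation", {
  pat <- isotope_pattern("C15H12N2O", 3)
  expect_equal(isotope_fit("C15H12N2O", pat), 0, tolerance = 1e-9)
  # single observed peak vs a carbon-rich candidate: deviation = simulated M+1
  single <- data.frame(shift = 0L, abundance = 100)
  dev <- isotope_fit("C15H12N2O", single)
  expect_equal(dev, pat$abundance[pat$shift == 1], tolerance = 1e-6)
  # distorted chlorine cluster
  suc <- isotope_pattern("C12H19Cl3O8", 3)
  distorted <- suc
  distorted$abundance[distorted$shift == 2] <-
    distorted$abundance[distorted$shift == 2] - 5
  expect_equal(isotope_fit("C12H19Cl3O8", distorted), 5, tolerance = 1e-6)
  expect_error(isotope_fit("C6H6", data.frame()[0, ]), "at least one")
})

test_that("the composite score is 100 at zero error and strictly monotone", {
  expect_identical(identification_score(0, 0, 0), 100)
  expect_equal(identification_score(2, 5, 0.005), 100 * exp(-1),
               tolerance = 1e-9)
  for (i in 1:20) {
    a <- runif(1, 0, 4); b <- runif(1, 0, 10); c <- runif(1, 0, 0.01)
    expect_lt(identification_score(a + 0.5, b, c),
              identification_score(a, b, c))
    expect_lt(identification_score(a, b + 1, c),
              identification_score(a, b, c))
    expect_lt(identification_score(a, b, c + 0.002),
              identification_score(a, b, c))
  }
})

test_that("identification accepts the true formula of a clean feature, rank 1", {
  cfg <- tiny_preset(seed = 3, n_background = 0)
  run <- generate_run(cfg, "hall_of_separators", "A", "positive")
  f <- extract_features(run)
  cbz <- f[which.min(abs(f$mz - ion_mz("C15H12N2O", "M+H"))), ]
  res <- identify_feature(cbz)
  expect_identical(res$formula[1], "C15H12N2O")
  expect_true(res$accepted[1])
  expect_identical(sum(res$accepted), 1L)
})

test_that("every suspect planted noise-free identifies to its formula at rank 1", {
  cfg <- tiny_preset(seed = 3, n_background = 0)
  sus <- suspect_list()
  for (pol in c("positive", "negative")) {
    # hall-of-separators protocol that plants the most suspects per polarity
    run <- generate_run(cfg, "hall_of_separators", "A", pol)
    f <- extract_features(run)
    for (i in seq_len(nrow(f))) {
      truth <- run$truth[which.min(abs(run$truth$mz - f$mz[i])), ]
      res <- identify_feature(f[i, ])
      expect_identical(res$formula[1], truth$formula)
    }
  }
})

test_that("a 3 ppm planted mass error is eliminated by the 2 ppm gate", {
  mzt <- ion_mz("C15H12N2O", "M+H")
  feat <- list(neutral_mass = neutral_mass(mzt * (1 + 3e-6), "positive"),
               observed = isotope_pattern("C15H12N2O", 3))
  res <- identify_feature(feat)
  expect_false("C15H12N2O" %in% res$formula[res$accepted])
})

test_that("an 8%-distorted isotope cluster is rejected by the 5% gate", {
  pat <- isotope_pattern("C15H12N2O", 3)
  pat$abundance[pat$shift == 1] <- pat$abundance[pat$shift == 1] + 8
  feat <- list(neutral_mass = monoisotopic_mass("C15H12N2O"), observed = pat)
  res <- identify_feature(feat)
  expect_identical(sum(res$accepted), 0L)
})

test_that("identification gates are monotone in their thresholds", {
  pat <- isotope_pattern("C8H9NO2", 3)
  pat$abundance[pat$shift == 1] <- pat$abundance[pat$shift == 1] + 3
  feat <- list(neutral_mass = monoisotopic_mass("C8H9NO2") * (1 + 1.2e-6),
               observed = pat)
  strict <- identify_feature(feat, id_criteria(max_ppm = 2, max_iso_dev = 5,
                                               min_score = 98))
  relaxed <- identify_feature(feat, id_criteria(max_ppm = 4, max_iso_dev = 8,
                                                min_score = 50))
  acc_strict <- strict$formula[strict$accepted]
  acc_relaxed <- relaxed$formula[relaxed$accepted]
  expect_true(all(acc_strict %in% acc_relaxed))
  expect_gte(length(acc_relaxed), length(acc_strict))
})
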