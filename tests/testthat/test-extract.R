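make_peak_df <- function(mz, rt0, base, polarity = "positive",
                         rel = 100, spacing = 0.05, sd = 0.15) {
  # one Gaussian chromatographic peak per (mz, rel) pair
  scans <- seq(rt0 - 0.45, rt0 + 0.45, by = spacing)
  do.call(rbind, lapply(seq_along(mz), function(i) {
    data.frame(scan_id = seq_along(scans) + 100L, rt_min = scans,
               mz = mz[i],
               intensity = base * rel[i] / 100 * exp(-(scans - rt0)^2 / (2 * sd^2)),
               polarity = polarity, stringsAsFactors = FALSE)
  }))
}

test_that("a single bright compound yields exactly one feature at its m/z and RT", {
  pk <- make_peak_df(400.1234, rt0 = 10, base = 5e4)
  f <- extract_features(pk)
  expect_identical(nrow(f), 1L)
  expect_equal(f$mz, 400.1234, tolerance = 1e-9)
  expect_equal(f$rt, 10, tolerance = 0.051)
  expect_identical(f$charge, 1L)
})

test_that("runs whose every peak is below the noise threshold yield no features", {
  pk <- make_peak_df(400.1234, rt0 = 10, base = 1299)
  expect_identical(nrow(extract_features(pk)), 0L)
  expect_identical(nrow(extract_features(pk[0, ])), 0L)
  # and no emitted feature ever sits below the threshold
  cfg <- tiny_preset(seed = 6)
  f <- extract_features(generate_run(cfg, "hall_of_separators", "A", "negative"))
  expect_true(all(f$apex_intensity >= 1300))
})

test_that("deisotoping merges textbook clusters and infers charge from spacing", {
  # M and M+1 at 15%: one singly charged feature
  pk <- make_peak_df(c(300.2, 300.2 + 1.00336), rt0 = 8, base = 4e4,
                     rel = c(100, 15))
  f <- extract_features(pk)
  expect_identical(nrow(f), 1L)
  expect_identical(f$charge, 1L)
  obs <- as.numeric(strsplit(f$iso_abundances, ";")[[1]])
  expect_equal(obs, c(100, 15), tolerance = 1e-6)
  # half spacing: charge 2
  pk2 <- make_peak_df(c(500.5, 500.5 + 0.50168), rt0 = 8, base = 4e4,
                      rel = c(100, 40))
  f2 <- extract_features(pk2)
  expect_identical(nrow(f2), 1L)
  expect_identical(f2$charge, 2L)
  # isolated peak stays a singleton with charge 1
  f3 <- extract_features(make_peak_df(212.345, 5, 2e4))
  expect_identical(f3$charge, 1L)
  expect_identical(f3$iso_abundances, "100")
})

test_that("neutral mass inverts the ionization arithmetic", {
  expect_equal(neutral_mass(237.1022395, "positive"), 236.09496,
               tolerance = 1e-4 / 236)
  expect_equal(neutral_mass(151.0400676, "negative"), 152.04738,
               tolerance = 1e-4 / 152)
  mz <- ion_mz("C8H10N4O2", "M+H")
  expect_equal(ion_mz("C8H10N4O2", "M+H"),
               neutral_mass(mz, "positive") + 1.007276466879,
               tolerance = 1e-12)
  expect_error(neutral_mass(500, "positive", charge = 2), "singly charged")
})

test_that("extraction is invariant to scan-order permutation of the input", {
  cfg <- tiny_preset(seed = 8)
  run <- generate_run(cfg, "secondary_settlement", "B", "positive")
  f1 <- extract_features(run)
  set.seed(1)
  shuffled <- run$peaks[sample(nrow(run$peaks)), ]
  f2 <- extract_features(shuffled)
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
})

test_that("jitter-free extraction recovers the planted truth with precision and recall 1", {
  cfg <- wwtp_preset(seed = 5, n_background = 120)
  for (pol in c("positive", "negative")) {
    run <- generate_run(cfg, "hall_of_separators", "A", pol)
    f <- extract_features(run)
    truth <- run$truth
    # recall: every planted compound recovered at its exact m/z and RT
    matched <- vapply(seq_len(nrow(truth)), function(i) {
      any(abs(f$mz - truth$mz[i]) < 1e-5 & abs(f$rt - truth$rt[i]) <= 0.051)
    }, logical(1))
    expect_true(all(matched))
    # precision: every feature corresponds to some planted compound
    owner <- vapply(seq_len(nrow(f)), function(i) {
      any(abs(truth$mz - f$mz[i]) < 1e-5 & abs(truth$rt - f$rt[i]) <= 0.051)
    }, logical(1))
    expect_true(all(owner))
    expect_identical(nrow(f), nrow(truth))
  }
})
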