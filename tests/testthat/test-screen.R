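test_that("screening detects exactly the persistent suspects in effluent/C", {
  cfg <- tiny_preset(seed = 2, n_background = 25)
  feats <- do.call(rbind, lapply(c("positive", "negative"), function(pol) {
    f <- extract_features(generate_run(cfg, "effluent", "C", pol))
    f$feature_id <- paste0(pol, "_", f$feature_id)
    f
  }))
  det <- screen_suspects(feats, suspect_list())
  expect_setequal(unique(det$suspect),
                  c("acesulfame-K", "carbamazepine", "sucralose"))
  expect_true(all(abs(det$ppm) <= 2))
  expect_true(all(abs(det$rt_diff) <= 0.5))
})

test_that("screening gates on each of polarity, mass and retention time", {
  sus <- suspect_list()
  cbz <- sus[sus$name == "carbamazepine", ]
  base <- data.frame(feature_id = "F1", mz = cbz$theor_mz, rt = cbz$rt_min,
                     polarity = "positive", stringsAsFactors = FALSE)
  expect_identical(screen_suspects(base, cbz)$suspect, "carbamazepine")
  # empty feature table
  expect_identical(nrow(screen_suspects(base[0, ], sus)), 0L)
  # retention time off by 3 minutes
  off_rt <- transform(base, rt = rt + 3)
  expect_identical(nrow(screen_suspects(off_rt, cbz)), 0L)
  # mass off by 5 ppm
  off_mz <- transform(base, mz = mz * (1 + 5e-6))
  expect_identical(nrow(screen_suspects(off_mz, cbz)), 0L)
  # wrong polarity
  off_pol <- transform(base, polarity = "negative")
  expect_identical(nrow(screen_suspects(off_pol, cbz)), 0L)
})

test_that("tightening screening tolerances never adds detections", {
  cfg <- tiny_preset(seed = 7, n_background = 40, mass_jitter_ppm = 1)
  f <- extract_features(generate_run(cfg, "hall_of_separators", "A", "negative"))
  loose <- screen_suspects(f, suspect_list(), mz_tol_ppm = 5, rt_tol_min = 1)
  tight <- screen_suspects(f, suspect_list(), mz_tol_ppm = 2, rt_tol_min = 0.5)
  expect_true(all(tight$suspect %in% loose$suspect))
  expect_lte(nrow(tight), nrow(loose))
})

test_that("MS/MS confirmation requires the product ion above the intensity floor", {
  sus <- suspect_list()
  cbz <- sus[sus$name == "carbamazepine", ]
  hit <- data.frame(mz = c(237.10, 194.10), intensity = c(40, 100))
  expect_true(confirm_msms(hit, cbz))
  miss <- data.frame(mz = c(237.10, 150.02), intensity = c(40, 100))
  expect_false(confirm_msms(miss, cbz))
  weak <- data.frame(mz = c(237.10, 194.10), intensity = c(100, 1))
  expect_false(confirm_msms(weak, cbz))   # 1% < 5% floor
  expect_false(confirm_msms(hit[0, ], cbz))
  # simulated targeted spectra confirm every packaged suspect
  for (i in seq_len(nrow(sus)))
    expect_true(confirm_msms(simulate_msms(sus[i, ]), sus[i, ]))
})

test_that("detection matrices are idempotent, serializable and drive markers", {
  det <- data.frame(
    suspect = c("carbamazepine", "carbamazepine", "sucralose"),
    stage = c("effluent", "effluent", "hall_of_separators"),
    protocol = c("C", "C", "A"), stringsAsFactors = FALSE)
  dm <- detection_matrix(det, compounds = c("carbamazepine", "sucralose"))
  expect_identical(sum(dm), 2L)  # duplicate detection collapses to one "+"
  expect_true(dm["carbamazepine", "effluent.C"])
  # markers: only effluent-detected compounds qualify
  expect_identical(select_markers(dm), "carbamazepine")
  expect_identical(select_markers(detection_matrix(det[0, ])), character(0))
  # +/- CSV round trip is lossless
  p <- tempfile(fileext = ".csv")
  write_detection_matrix(dm, p)
  back <- read_detection_matrix(p)
  expect_identical(unclass(back), unclass(dm))
})

test_that("marker selection is monotone in the detection matrix", {
  ref <- reference_detections()
  m0 <- select_markers(ref)
  expect_setequal(m0, c("acesulfame-K", "carbamazepine", "sucralose"))
  ref2 <- ref
  ref2["caffeine", "effluent.A"] <- TRUE
  expect_true(all(m0 %in% select_markers(ref2)))
  expect_true("caffeine" %in% select_markers(ref2))
})
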