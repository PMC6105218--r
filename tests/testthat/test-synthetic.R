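test_that("the campaign preset plants exactly the packaged ground truth", {
  cfg <- wwtp_preset(seed = 3)
  ref <- reference_detections()
  # planted presence equals the packaged matrix in all cells
  for (i in seq_len(nrow(cfg$presence))) {
    row <- cfg$presence[i, ]
    expect_identical(row$present,
                     unname(ref[row$compound,
                                paste(row$stage, row$protocol, sep = ".")]))
  }
  expect_true(all(!ref["butyl paraben", ]))
  expect_true(all(ref["carbamazepine", ]))
  hit <- ref["ethyl paraben", ]
  expect_identical(names(hit)[hit], "hall_of_separators.A")
})

test_that("effluent/protocol-C runs plant only the persistent suspects", {
  cfg <- tiny_preset(seed = 2, n_background = 0)
  rn <- generate_run(cfg, "effluent", "C", "negative")
  expect_setequal(rn$truth$name[rn$truth$is_suspect],
                  c("acesulfame-K", "sucralose"))
  rp <- generate_run(cfg, "effluent", "C", "positive")
  expect_identical(rp$truth$name[rp$truth$is_suspect], "carbamazepine")
})

test_that("runs are reproducible and respect structural invariants", {
  cfg <- tiny_preset(seed = 9, mass_jitter_ppm = 1, rt_jitter_min = 0.05)
  r1 <- generate_run(cfg, "hall_of_separators", "B", "positive")
  r2 <- generate_run(cfg, "hall_of_separators", "B", "positive")
  expect_identical(r1$peaks, r2$peaks)
  expect_true(all(diff(r1$peaks$scan_id) >= 0))         # RT-ordered scans
  expect_true(all(r1$peaks$intensity > 0))
  expect_true(all(r1$peaks$mz >= cfg$mass_range[1] - 0.1 &
                    r1$peaks$mz <= cfg$mass_range[2] + 0.1))
  # serialization round-trip is bit-stable given the 6-dp dialect
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_peaklist(r1, p1)
  write_peaklist(generate_run(cfg, "hall_of_separators", "B", "positive"), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("with no background and no suspects a run has only sub-noise peaks", {
  cfg <- sim_config(seed = 5, n_background = 0)
  run <- generate_run(cfg, "effluent", "A", "positive")
  expect_true(all(run$peaks$intensity < cfg$noise_floor))
  expect_identical(nrow(run$truth), 0L)
})

test_that("jitter-free planted suspect m/z equals the theoretical ion m/z", {
  cfg <- tiny_preset(seed = 4, n_background = 0)
  run <- generate_run(cfg, "hall_of_separators", "A", "negative")
  sus <- suspect_list()
  tr <- run$truth
  expect_equal(tr$mz, sus$theor_mz[match(tr$name, sus$name)], tolerance = 1e-12)
})

test_that("background survival flags converge to the configured rates", {
  cfg <- wwtp_preset(seed = 11, n_background = 2000)
  for (pol in c("positive", "negative")) {
    gt <- ground_truth(cfg, pol)
    p <- cfg$survival[[pol]][1]
    expect_identical(nrow(gt), 2000L)
    expect_true(all(gt$hall_of_separators))
    expect_false(any(gt$effluent & !gt$secondary_settlement))
    # law of large numbers: within 3 binomial sd
    expect_lt(abs(mean(gt$secondary_settlement) - p),
              3 * sqrt(p * (1 - p) / 2000))
  }
})

test_that("matrix-effect sets reproduce the configured area ratios", {
  cfg <- wwtp_preset(seed = 2)
  pairs <- generate_matrix_effect_set(cfg)
  expect_identical(nrow(pairs), 12L * 3L)  # triplicate
  # deterministic by default: A_matrix = factor * A_solvent exactly
  sac <- pairs[pairs$compound == "saccharin", ]
  expect_equal(sac$a_matrix / sac$a_solvent, rep(0.8073, 3), tolerance = 1e-12)
  me <- matrix_effect_table(pairs)
  expect_equal(me$me[me$compound == "saccharin"], -19.27, tolerance = 1e-10)
  expect_equal(me$me[me$compound == "paracetamol"], 12.47, tolerance = 1e-10)
  # parabens and remaining sweeteners are strongly suppressed
  strong <- me$me[me$compound %in% c("aspartame", "sucralose", "cyclamate",
                                     "methyl paraben", "ethyl paraben",
                                     "butyl paraben", "acesulfame-K")]
  expect_true(all(strong >= -90 & strong <= -70))
  # with noise the per-compound mean ratio stays near the configured factor
  cfgn <- wwtp_preset(seed = 2, me_noise_cv = 0.05)
  men <- matrix_effect_table(generate_matrix_effect_set(cfgn))
  expect_equal(men$me[men$compound == "saccharin"], -19.27, tolerance = 5)
  expect_true(all(men$me_sd > 0))
})

test_that("unknown sample labels are rejected", {
  cfg <- tiny_preset(seed = 1)
  expect_error(generate_run(cfg, "tertiary", "A", "positive"), "stage")
  expect_error(generate_run(cfg, "effluent", "D", "positive"), "protocol")
  expect_error(sim_config(), "seed")
})
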