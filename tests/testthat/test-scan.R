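test_that("flank scoring walks reference residues and counts conserved
          columns", {
  fix <- positional_flank_fixture(left_conserved_at = c(1:4, 40))
  cfg <- scan_config()
  prof <- conservation_profile(fix$alignment, fix$partition, cfg)
  cand <- list(col_start = fix$span[1], col_end = fix$span[2])
  flanks <- score_flanks(fix$alignment, cand, prof, cfg, "in_01")
  expect_equal(flanks[["left"]], 5L)
  expect_equal(flanks[["right"]], 40L)

  # 4 conserved on the left, plenty on the right -> candidate rejected
  fix4 <- positional_flank_fixture(left_conserved_at = 1:4)
  scan4 <- scan_csi(fix4$alignment, fix4$partition, cfg)
  expect_equal(nrow(scan4), 0L)
  rej <- attr(scan4, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$left_flank_conserved, 4L)

  expect_error(
    score_flanks(fix$alignment, cand, prof, cfg, "ghost"),
    "not in alignment"
  )
})

test_that("a span at the alignment edge has an empty flank window", {
  aln <- make_aln(c(
    i1 = "CDEFGHIK", i2 = "CDEFGHIK", o1 = "--EFGHIK", o2 = "--EFGHIK"
  ))
  part <- taxon_partition(c("i1", "i2"), c("o1", "o2"))
  cfg <- scan_config(flank_window_aa = 4, min_flank_conserved = 1)
  prof <- conservation_profile(aln, part, cfg)
  flanks <- score_flanks(
    aln, list(col_start = 1, col_end = 2), prof, cfg, "i1"
  )
  expect_equal(flanks[["left"]], 0L)
  expect_equal(flanks[["right"]], 4L)
})

test_that("specificity is exclusive iff no out-group exception exists", {
  aln <- make_aln(c(
    i1 = "AACDAA", i2 = "AACDAA",
    o1 = "AA--AA", o2 = "AA--AA", o3 = "AACDAA"
  ))
  part_excl <- taxon_partition(c("i1", "i2", "o3"), c("o1", "o2"))
  cand <- list(col_start = 3, col_end = 4, type = "insert")
  res <- classify_specificity(aln, cand, part_excl)
  expect_equal(res$specificity, "exclusive")
  expect_equal(res$exception_ids, character(0))

  # o3 carries the insert -> enumerated exception
  part_exc <- taxon_partition(c("i1", "i2"), c("o1", "o2", "o3"))
  res2 <- classify_specificity(aln, cand, part_exc)
  expect_equal(res2$specificity, "shared_with_exceptions")
  expect_equal(res2$exception_ids, "o3")

  # deletion shared by two out-group rows: both listed
  aln2 <- make_aln(c(
    i1 = "AA--AA", i2 = "AA--AA",
    o1 = "AACDAA", o2 = "AA--AA", o3 = "AA--AA"
  ))
  res3 <- classify_specificity(
    aln2, list(col_start = 3, col_end = 4, type = "deletion"),
    taxon_partition(c("i1", "i2"), c("o1", "o2", "o3"))
  )
  expect_equal(res3$specificity, "shared_with_exceptions")
  expect_equal(res3$exception_ids, c("o2", "o3"))
})

test_that("noiseless planted insert is recovered as one exclusive call", {
  sim <- simulate_msa(synthetic_spec(
    seed = 2, substitution_rate = 0, core_length_aa = 200,
    planted_indels = list(planted_indel(100, 4, "insert"))
  ))
  scan <- scan_csi(sim$alignment, sim$partition)
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$type, "insert")
  expect_equal(c(scan$length_min, scan$length_max), c(4L, 4L))
  expect_equal(scan$specificity, "exclusive")
  expect_equal(
    c(scan$col_start, scan$col_end),
    c(sim$truth$col_start, sim$truth$col_end)
  )
  expect_equal(scan$reference_position, 100L)
})

test_that("length-variable in-group inserts report a min-max range", {
  sim <- simulate_msa(synthetic_spec(
    seed = 8, substitution_rate = 0, core_length_aa = 300,
    planted_indels = list(planted_indel(150, c(43, 44), "insert"))
  ))
  scan <- scan_csi(sim$alignment, sim$partition)
  expect_equal(nrow(scan), 1L)
  expect_equal(c(scan$length_min, scan$length_max), c(43L, 44L))
})

test_that("degrading one flank below the minimum suppresses the call", {
  sim <- simulate_msa(synthetic_spec(
    seed = 4, substitution_rate = 0, core_length_aa = 200,
    planted_indels = list(planted_indel(100, 4, "insert"))
  ))
  cfg <- scan_config()
  at_min <- degrade_flanks(
    sim$alignment, sim$truth, "left", cfg$min_flank_conserved, cfg,
    seed = 9
  )
  expect_equal(nrow(scan_csi(at_min, sim$partition, cfg)), 1L)
  below <- degrade_flanks(
    sim$alignment, sim$truth, "left", cfg$min_flank_conserved - 1L, cfg,
    seed = 9
  )
  expect_equal(nrow(scan_csi(below, sim$partition, cfg)), 0L)
})

test_that("call count is monotone in the flank and conservation
          thresholds", {
  sim <- simulate_msa(synthetic_spec(seed = 13, substitution_rate = 0.15))
  degraded <- degrade_flanks(
    sim$alignment, sim$truth, "left", 6, scan_config(), seed = 2,
    which = 2
  )
  n_calls_flank <- vapply(0:10, function(k) {
    nrow(scan_csi(
      degraded, sim$partition, scan_config(min_flank_conserved = k)
    ))
  }, integer(1))
  expect_true(all(diff(n_calls_flank) <= 0))

  n_calls_cons <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(f) {
    nrow(scan_csi(
      degraded, sim$partition, scan_config(conservation_fraction = f)
    ))
  }, integer(1))
  expect_true(all(diff(n_calls_cons) <= 0))
})

test_that("scan matches the brute-force interval oracle on small
          instances", {
  for (seed in 1:30) {
    inst <- random_small_instance(seed)
    got <- scan_as_plain(scan_csi(
      inst$alignment, inst$partition, inst$config, inst$reference
    ))
    want <- oracle_scan(
      inst$alignment, inst$partition, inst$config, inst$reference
    )
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})
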