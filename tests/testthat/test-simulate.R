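test_that("the generator is deterministic under spec + seed", {
  spec <- synthetic_spec(seed = 17)
  a <- simulate_msa(spec)
  b <- simulate_msa(spec)
  expect_identical(a$alignment$residues, b$alignment$residues)
  expect_identical(as.data.frame(a$partition), as.data.frame(b$partition))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- simulate_msa(synthetic_spec(seed = 18))
  expect_false(identical(a$alignment$residues, c$alignment$residues))
})

test_that("invalid specs are rejected", {
  expect_error(
    synthetic_spec(planted_indels = list(
      planted_indel(100, 4, "insert"), planted_indel(105, 2, "insert")
    )),
    "overlap"
  )
  expect_error(
    synthetic_spec(core_length_aa = 50, planted_indels = list(
      planted_indel(48, 4, "insert")
    )),
    "outside the core"
  )
  expect_error(planted_indel(10, c(2, 3), "deletion"), "fixed length")
  expect_error(synthetic_spec(substitution_rate = 1), "substitution_rate")
})

test_that("noiseless specs are always fully recovered at defaults", {
  for (seed in 1:15) {
    set.seed(seed + 500)
    n_indels <- sample(1:3, 1)
    pos <- sort(sample(seq(60, 340, by = 70), n_indels))
    indels <- lapply(pos, function(p) {
      planted_indel(
        p, sample(c(1, 2, 4, 7), 1),
        sample(c("insert", "deletion"), 1)
      )
    })
    sim <- simulate_msa(synthetic_spec(
      seed = seed, substitution_rate = 0, core_length_aa = 400,
      n_ingroup = sample(3:12, 1), n_outgroup = sample(3:10, 1),
      planted_indels = indels
    ))
    scan <- scan_csi(sim$alignment, sim$partition)
    rec <- evaluate_recovery(sim$truth, scan)
    expect_equal(rec$precision, 1, info = paste("seed", seed))
    expect_equal(rec$recall, 1, info = paste("seed", seed))
  }
})

test_that("exception rows share the indel and are classified as such", {
  sim <- simulate_msa(synthetic_spec(
    seed = 6, substitution_rate = 0, core_length_aa = 200,
    planted_indels = list(planted_indel(100, 4, "insert",
      n_exceptions = 2
    ))
  ))
  expect_equal(sim$truth$exception_ids[[1]], c("out_01", "out_02"))
  # strict out-group absence no longer holds...
  expect_equal(nrow(scan_csi(sim$alignment, sim$partition)), 0L)
  # ...relaxing it finds the region and enumerates the exceptions
  scan <- scan_csi(
    sim$alignment, sim$partition,
    scan_config(outgroup_absence_fraction = 0.75)
  )
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$specificity, "shared_with_exceptions")
  expect_equal(scan$exception_ids[[1]], c("out_01", "out_02"))
})

test_that("frozen flanks are fully conserved before degradation", {
  spec <- synthetic_spec(seed = 9, substitution_rate = 0.2,
    frozen_flank_aa = 8,
    planted_indels = list(planted_indel(300, 4, "insert")))
  sim <- simulate_msa(spec)
  cfg <- scan_config(flank_window_aa = 8)
  prof <- conservation_profile(sim$alignment, sim$partition, cfg)
  entry <- sim$truth[1, ]
  left <- (entry$col_start - 8):(entry$col_start - 1)
  right <- (entry$col_end + 1):(entry$col_end + 8)
  expect_true(all(prof$is_conserved[c(left, right)]))
})

test_that("degrade_flanks hits its target exactly and no-ops at the
          current count", {
  sim <- simulate_msa(synthetic_spec(
    seed = 12, substitution_rate = 0, core_length_aa = 200,
    planted_indels = list(planted_indel(100, 2, "insert"))
  ))
  cfg <- scan_config()
  prof_count <- function(aln, side) {
    prof <- conservation_profile(aln, sim$partition, cfg)
    entry <- sim$truth[1, ]
    cols <- if (side == "left") {
      (entry$col_start - cfg$flank_window_aa):(entry$col_start - 1)
    } else {
      (entry$col_end + 1):(entry$col_end + cfg$flank_window_aa)
    }
    sum(prof$is_conserved[cols])
  }
  expect_equal(prof_count(sim$alignment, "left"), 40L)
  deg <- degrade_flanks(sim$alignment, sim$truth, "left", 7, cfg, seed = 3)
  expect_equal(prof_count(deg, "left"), 7L)
  expect_equal(prof_count(deg, "right"), 40L)
  # same seed -> same degradation
  deg2 <- degrade_flanks(sim$alignment, sim$truth, "left", 7, cfg, seed = 3)
  expect_identical(deg$residues, deg2$residues)
  # no-op when the target equals the current count
  same <- degrade_flanks(sim$alignment, sim$truth, "left", 40, cfg,
    seed = 3
  )
  expect_identical(same$residues, sim$alignment$residues)
  # unreachable target
  expect_error(
    degrade_flanks(sim$alignment, sim$truth, "left", 41, cfg, seed = 3),
    "unreachable"
  )
})

test_that("recovery scoring follows the stated conventions", {
  truth <- structure(
    tibble::tibble(
      indel_id = 1:2, type = c("insert", "deletion"),
      position = c(10L, 20L), length_min = c(2L, 1L),
      length_max = c(2L, 1L), col_start = c(11L, 25L),
      col_end = c(12L, 25L), exception_ids = list(character(0),
        character(0)), per_row_lengths = list(NULL, NULL)
    ),
    class = c("csi_truth", class(tibble::tibble()))
  )
  calls <- tibble::tibble(
    call_id = 1:3, type = c("insert", "deletion", "insert"),
    col_start = c(11L, 25L, 40L), col_end = c(12L, 25L, 44L)
  )
  rec <- evaluate_recovery(truth, calls)
  expect_equal(rec$precision, 2 / 3)
  expect_equal(rec$recall, 1)

  # zero calls against non-empty truth: precision 1 by convention
  rec2 <- evaluate_recovery(truth, calls[0, ])
  expect_equal(rec2$precision, 1)
  expect_equal(rec2$recall, 0)

  # empty truth, no calls
  rec3 <- evaluate_recovery(truth[0, ], calls[0, ])
  expect_equal(c(rec3$precision, rec3$recall), c(1, 1))
})

test_that("realized in-group length range equals the planted range", {
  sim <- simulate_msa(synthetic_spec(
    seed = 31, substitution_rate = 0, core_length_aa = 300, n_ingroup = 20,
    planted_indels = list(planted_indel(150, c(3, 5), "insert"))
  ))
  lens <- sim$truth$per_row_lengths[[1]]
  in_lens <- lens[grep("^in_", names(lens))]
  expect_equal(range(in_lens), c(3L, 5L))
  expect_equal(
    c(sim$truth$length_min, sim$truth$length_max), c(3L, 5L)
  )
})
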