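test_that("conversion ratio spans the perfect and failed extremes", {
  # reference with 3 non-CpG Cs (none followed by G) and one CpG at 4
  ref <- find_cpg_sites("ACTCGTCA")   # CpG C at 4; non-CpG Cs at 2, 7 (and 4 excluded)
  expect_equal(ref$cpg_positions, 4L)

  perfect <- needleman_wunsch(ref$bases, "ATTCGTTA")  # both non-CpG Cs read T
  cr <- conversion_ratio(perfect, ref$cpg_positions)
  expect_equal(cr$ratio, 0)
  expect_equal(cr$n_nonCpG_C, 2L)

  failed <- needleman_wunsch(ref$bases, ref$bases)    # nothing converted
  cf <- conversion_ratio(failed, ref$cpg_positions)
  expect_equal(cf$ratio, 1)
  expect_equal(cf$n_unconverted, 2L)
})

test_that("planted conversion failures are counted exactly", {
  cfg <- sim_config(ref_length = 120, cpg_positions = toy_positions,
                    methylation_pattern = toy_pattern(), n_noncpg_c = 10,
                    conversion_failure_p = 0.2, seq_error_p = 0, seed = 9L)
  sim <- simulate_experiment(cfg)
  alns <- align_clones(sim$clones, sim$ref$bases)
  for (i in seq_len(nrow(alns))) {
    cr <- conversion_ratio(alns$alignment[[i]], sim$ref$cpg_positions)
    expect_equal(cr$n_nonCpG_C, 10L)
    expect_equal(cr$n_unconverted, sim$truth$clones$n_conversion_failures[i])
    expect_equal(cr$ratio, sim$truth$clones$n_conversion_failures[i] / 10)
  }
})

test_that("conversion ratio is invariant under the orientation transform", {
  cfg <- sim_config(ref_length = 100, cpg_positions = toy_positions,
                    methylation_pattern = toy_pattern(), n_noncpg_c = 8,
                    conversion_failure_p = 0.3, seed = 12L,
                    orientations = c("identity", "reverse", "complement",
                                     "reverse_complement"))
  sim <- simulate_experiment(cfg)
  alns <- align_clones(sim$clones, sim$ref$bases)
  expect_equal(alns$orientation, sim$truth$clones$orientation)
  ratios <- vapply(alns$alignment, function(a)
    conversion_ratio(a, sim$ref$cpg_positions)$ratio, numeric(1))
  expect_equal(ratios, sim$truth$clones$n_conversion_failures / 8)
})

test_that("identity rate follows its definition and flags 0/0", {
  expect_equal(identity_rate(100, 0), 1)
  expect_equal(identity_rate(3, 1), 0.75)
  expect_true(is.na(identity_rate(0, 0)))
  expect_error(identity_rate(-1, 2), class = "methclones_input_error")
})

test_that("identity rate tracks a planted substitution error rate", {
  cfg <- sim_config(ref_length = 400, cpg_positions = c(50L, 200L),
                    n_clones = 30, methylation_pattern = 1,
                    n_noncpg_c = 0, seq_error_p = 0.05, seed = 21L)
  sim <- simulate_experiment(cfg)
  alns <- align_clones(sim$clones, sim$ref$bases)
  qc <- qc_clones(alns, sim$ref)
  # ~5% of A/G/T bases substituted; a third of substitutions still match by
  # chance is impossible (always to a different base), but errors landing as
  # C on a ref A/G/T column count as mismatch; tolerance is generous
  expect_gt(mean(qc$identity_rate), 0.90)
  expect_lt(mean(qc$identity_rate), 0.99)
})

test_that("estimator recovers planted conversion-failure probabilities", {
  for (p in c(0, 0.05, 0.2)) {
    cfg <- sim_config(ref_length = 150, cpg_positions = toy_positions,
                      n_clones = 50, methylation_pattern = 0.5,
                      n_noncpg_c = 20, conversion_failure_p = p,
                      seed = 31L + round(100 * p))
    sim <- simulate_experiment(cfg)
    alns <- align_clones(sim$clones, sim$ref$bases)
    ratios <- vapply(alns$alignment, function(a)
      conversion_ratio(a, sim$ref$cpg_positions)$ratio, numeric(1))
    se <- sqrt(p * (1 - p) / (50 * 20))
    expect_lte(abs(mean(ratios) - p), max(3 * se, 1e-12))
  }
})

test_that("gates partition clones and name the violated criteria", {
  sim <- simulate_experiment(toy_config())
  alns <- align_clones(sim$clones, sim$ref$bases)
  qc <- qc_clones(alns, sim$ref)
  expect_true(all(qc$passed))
  expect_true(all(qc$failed_gates == ""))

  # boundary: a zero tolerance fails every clone with >= 1 unconverted C
  cfg <- sim_config(ref_length = 120, cpg_positions = toy_positions,
                    methylation_pattern = toy_pattern(), n_noncpg_c = 10,
                    conversion_failure_p = 0.5, seed = 3L)
  sim2 <- simulate_experiment(cfg)
  alns2 <- align_clones(sim2$clones, sim2$ref$bases)
  qc2 <- qc_clones(alns2, sim2$ref, max_conversion_ratio = 0)
  bad <- sim2$truth$clones$n_conversion_failures > 0
  expect_equal(!qc2$passed, bad)
  expect_true(all(grepl("conversion_ratio", qc2$failed_gates[bad])))
})

test_that("a single planted bad clone is the only gate failure", {
  # three clean clones plus one with total conversion failure
  good_cfg <- sim_config(ref_length = 100, cpg_positions = toy_positions,
                         methylation_pattern = toy_pattern()[1:3, ],
                         n_noncpg_c = 10, conversion_failure_p = 0, seed = 8L)
  good <- simulate_experiment(good_cfg)
  bad_clone <- tibble::tibble(id = "bad1", bases = good$reference$bases)
  clones <- dplyr::bind_rows(good$clones, bad_clone)
  alns <- align_clones(clones, good$ref$bases)
  qc <- qc_clones(alns, good$ref, max_conversion_ratio = 0.1,
                  min_identity = 0.9)
  expect_equal(qc$clone_id[!qc$passed], "bad1")
  expect_equal(qc$conversion_ratio[qc$clone_id == "bad1"], 1)
})

test_that("QC reports export to TSV and a text summary", {
  sim <- simulate_experiment(toy_config())
  alns <- align_clones(sim$clones, sim$ref$bases)
  qc <- qc_clones(alns, sim$ref)
  tsv <- tempfile(fileext = ".tsv"); txt <- tempfile(fileext = ".txt")
  export_qc(qc, tsv = tsv, txt = txt)
  expect_equal(nrow(read.delim(tsv)), 4L)
  expect_match(readLines(txt)[1], "4 passed")
})
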