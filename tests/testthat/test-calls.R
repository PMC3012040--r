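test_that("CpG sites are located on the forward strand, 1-based", {
  expect_equal(find_cpg_sites("ACGT")$cpg_positions, 2L)
  expect_equal(find_cpg_sites("CGCG")$cpg_positions, c(1L, 3L))
  expect_equal(find_cpg_sites("AAAA")$cpg_positions, integer(0))
  # the demonstration geometry: five CpGs at fixed hypothetical positions
  sim <- simulate_experiment(toy_config())
  expect_equal(sim$ref$cpg_positions, toy_positions)
})

test_that("methylation calls follow the C/T coding rule", {
  ref <- find_cpg_sites("AACGTTCGAA")
  expect_equal(ref$cpg_positions, c(3L, 7L))

  retained <- needleman_wunsch(ref$bases, ref$bases)
  expect_equal(unname(call_methylation(retained, ref)), c(1, 1))

  converted <- needleman_wunsch(ref$bases, "AATGTTTGAA")
  expect_equal(unname(call_methylation(converted, ref)), c(0, 0))

  mixed <- needleman_wunsch(ref$bases, "AACGTTTGAA")
  expect_equal(unname(call_methylation(mixed, ref)), c(1, 0))

  # a non-C/T base or an N at the CpG column is evidence of error: missing
  odd <- needleman_wunsch(ref$bases, "AAAGTTNGAA")
  expect_equal(unname(call_methylation(odd, ref)), c(NA_real_, NA_real_))
})

test_that("CpG positions outside the aligned span are missing", {
  cfg <- sim_config(ref_length = 100, cpg_positions = toy_positions,
                    methylation_pattern = toy_pattern(),
                    spans = tibble::tibble(start = 30, end = 80), seed = 2L)
  sim <- simulate_experiment(cfg)
  alns <- align_clones(sim$clones, sim$ref$bases)
  ds <- assemble_dataset(alns, sim$ref)
  expect_true(all(is.na(ds$calls[, 1])))              # CpG 7 not covered
  expect_equal(unname(ds$calls[, 2:5]), unname(toy_pattern()[, 2:5]))
})

test_that("the demonstration clones assemble into the expected 4x5 matrix", {
  sim <- simulate_experiment(toy_config())
  alns <- align_clones(sim$clones, sim$ref$bases)
  ds <- assemble_dataset(alns, sim$ref)
  expect_equal(dim(ds), c(4L, 5L))
  expect_equal(unname(ds$calls), unname(toy_pattern() + 0))
  expect_equal(ds$cpg_positions, toy_positions)
  expect_equal(ds$spans$ref_start, rep(1L, 4))
})

test_that("an empty clone set yields an empty dataset with positions kept", {
  ref <- find_cpg_sites("AACGTTCGAA")
  ds <- assemble_dataset(list(), ref)
  expect_equal(dim(ds), c(0L, 2L))
  expect_equal(ds$cpg_positions, c(3L, 7L))
  expect_equal(nrow(as_tibble(ds)), 0L)
})

test_that("meth_set validates its invariants", {
  expect_error(meth_set(matrix(0, 2, 3), c(1L, 5L)),
               class = "methclones_input_error")
  expect_error(meth_set(matrix(2, 2, 2), c(1L, 5L)),
               class = "methclones_input_error")
  expect_error(meth_set(matrix(0, 2, 2), c(5L, 1L)),
               class = "methclones_input_error")
  expect_error(meth_set(matrix(1, 2, 2), c(1L, 5L),
                        clone_ids = c("a", "a")),
               class = "methclones_input_error")
  # calls outside the aligned span violate the span rule
  expect_error(
    meth_set(matrix(1, 1, 2), c(1L, 5L), clone_ids = "c",
             spans = tibble::tibble(clone_id = "c", ref_start = 4L,
                                    ref_end = 6L)),
    class = "methclones_input_error")
})

test_that("dataset JSON serialization round-trips field for field", {
  cfg <- sim_config(ref_length = 100, cpg_positions = toy_positions,
                    methylation_pattern = toy_pattern(),
                    spans = tibble::tibble(start = c(1, 30, 1, 30),
                                           end = c(80, 100, 100, 80)),
                    seed = 4L)
  sim <- simulate_experiment(cfg)
  ds <- assemble_dataset(align_clones(sim$clones, sim$ref$bases), sim$ref)
  f <- tempfile(fileext = ".json")
  write_meth_json(ds, f)
  back <- read_meth_json(f)
  expect_equal(back$clone_ids, ds$clone_ids)
  expect_equal(back$cpg_positions, ds$cpg_positions)
  expect_equal(back$calls, ds$calls)
  expect_equal(back$spans, ds$spans)
  expect_error(read_meth_json(write_lines_tmp('{"schema": "other"}', ".json")),
               class = "methclones_format_error")
})

test_that("noise-free simulations are recovered exactly end to end", {
  set.seed(77)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    n <- sample(2:8, 1)
    pos <- sort(sample(seq(5, 90, by = 3), k))
    pat <- matrix(stats::rbinom(n * k, 1, 0.5), n, k)
    cfg <- sim_config(ref_length = 100, cpg_positions = pos,
                      methylation_pattern = pat, n_noncpg_c = 6,
                      conversion_failure_p = 0, seq_error_p = 0,
                      orientations = sample(c("identity", "reverse",
                                              "complement",
                                              "reverse_complement"),
                                            n, replace = TRUE),
                      seed = 1000L + rep)
    sim <- simulate_experiment(cfg)
    alns <- align_clones(sim$clones, sim$ref$bases)
    ds <- assemble_dataset(alns, sim$ref)
    expect_equal(unname(ds$calls), unname(pat + 0),
                 info = paste("rep", rep))
  }
})

test_that("the matrix TSV export carries positions in the header", {
  ds <- toy_dataset()
  f <- tempfile(fileext = ".tsv")
  write_meth_matrix(ds, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(names(tab), c("clone_id", as.character(toy_positions)))
  expect_equal(unname(as.matrix(tab[, -1])), unname(toy_pattern() + 0))
})
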