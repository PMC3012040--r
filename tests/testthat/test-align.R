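test_that("global alignment reproduces hand-checkable optima", {
  sch <- subst_scheme(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)

  a <- needleman_wunsch("ACGT", "ACGT", sch)
  expect_equal(a$score, 4)
  expect_equal(a$aligned_ref, "ACGT")
  expect_equal(a$aligned_clone, "ACGT")
  expect_equal(c(a$ref_start, a$ref_end), c(1L, 4L))

  # clone T against reference C is tolerated at full match score
  b <- needleman_wunsch("CG", "TG", sch)
  expect_equal(b$score, 2 * sch$match)

  # single deletion in the clone: 3 matches + one gap open
  d <- needleman_wunsch("ACGT", "AGT", sch)
  expect_equal(d$score, 3 * sch$match + sch$gap_open)
  expect_equal(lengths(regmatches(d$aligned_clone,
                                  gregexpr("-", d$aligned_clone))), 1L)
  expect_false(grepl("-", d$aligned_ref))
})

test_that("the bisulfite tolerance is directional", {
  sch <- subst_scheme()
  expect_equal(needleman_wunsch("C", "T", sch)$score, sch$bisulfite_TC)
  expect_equal(needleman_wunsch("T", "C", sch)$score, sch$mismatch)
})

test_that("N and ambiguity codes score by set membership", {
  sch <- subst_scheme()
  expect_equal(needleman_wunsch("N", "A", sch)$score, 0)
  expect_equal(needleman_wunsch("A", "N", sch)$score, 0)
  expect_equal(needleman_wunsch("R", "G", sch)$score, sch$match)  # R = A/G
  expect_equal(needleman_wunsch("R", "C", sch)$score, sch$mismatch)
})

test_that("global scores equal an independent dynamic-programming oracle", {
  set.seed(101)
  schemes <- list(subst_scheme(),
                  subst_scheme(match = 2, mismatch = -3, bisulfite_TC = 0,
                               gap_open = -5, gap_extend = -2))
  for (k in 1:60) {
    sch <- schemes[[1 + k %% 2]]
    ref <- random_dna(sample(1:12, 1))
    clone <- random_dna(sample(1:12, 1))
    expect_equal(needleman_wunsch(ref, clone, sch)$score,
                 r_nw_score(ref, clone, sch),
                 info = paste(ref, clone))
  }
})

test_that("returned alignments satisfy the column invariants", {
  set.seed(202)
  for (k in 1:25) {
    ref <- random_dna(sample(20:40, 1))
    clone <- random_dna(sample(10:40, 1))
    a <- needleman_wunsch(ref, clone)
    expect_equal(nchar(a$aligned_ref), nchar(a$aligned_clone))
    cols <- cbind(strsplit(a$aligned_ref, "")[[1]],
                  strsplit(a$aligned_clone, "")[[1]])
    expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
    expect_equal(gsub("-", "", a$aligned_ref),
                 substr(ref, a$ref_start, a$ref_end))
  }
})

test_that("orientation control recovers transforms and is a no-op on good input", {
  set.seed(7)
  ref <- random_dna(80)
  expect_equal(orient_clone(ref, ref)$orientation, "identity")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  a <- orient_clone(ref, rc)
  expect_equal(a$orientation, "reverse_complement")
  expect_equal(a$score, needleman_wunsch(ref, ref)$score)

  # symmetry: the same candidate set is scored either way round
  x <- random_dna(60)
  s1 <- orient_clone(ref, x)
  s2 <- orient_clone(ref, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x))))
  expect_equal(s1$score, s2$score)
})

test_that("unalignable clones are flagged, not silently returned", {
  # against an all-N reference every candidate scores 0 identically
  expect_warning(a <- orient_clone("NNNNNN", "ACGT"), "unalignable")
  expect_true(a$flagged)
})

test_that("A/G/T-restricted local identity counts exclude reference-C columns", {
  sch <- subst_scheme()
  r1 <- local_align_agt("AGTC", "AGTT", sch)
  expect_equal(c(r1$matches, r1$mismatches), c(3L, 0L))

  set.seed(5)
  ref <- random_dna(50)
  k <- sum(strsplit(ref, "")[[1]] == "C")
  r2 <- local_align_agt(ref, ref, sch)
  expect_equal(c(r2$matches, r2$mismatches), c(50L - k, 0L))

  # the optimal local alignment of AAGG vs AAGC is AAG/AAG: the trailing
  # G/C mismatch lowers the score, so it is not part of the optimum
  r3 <- local_align_agt("AAGG", "AAGC", sch)
  expect_equal(c(r3$matches, r3$mismatches), c(3L, 0L))

  expect_warning(r4 <- local_align_agt("AAAA", "TTTT", sch), "empty local")
  expect_equal(c(r4$matches, r4$mismatches), c(0L, 0L))
})

test_that("local alignment agrees with an established implementation", {
  # cross-check the Smith-Waterman kernel against Biostrings on plain
  # (non-bisulfite) scoring, where both define the same optimum
  set.seed(303)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  sch <- subst_scheme(match = 1, mismatch = -1, bisulfite_TC = -1,
                      gap_open = -3, gap_extend = -1)
  for (k in 1:15) {
    ref <- random_dna(sample(15:30, 1))
    clone <- random_dna(sample(15:30, 1))
    ours <- local_align_agt(ref, clone, sch)
    theirs <- Biostrings::pairwiseAlignment(
      ref, clone, type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)   # first gap base costs 3, as ours
    expect_equal(ours$score, Biostrings::score(theirs))
  }
})

test_that("batch alignment returns one oriented row per clone", {
  sim <- simulate_experiment(toy_config())
  alns <- align_clones(sim$clones, sim$ref$bases)
  expect_equal(alns$clone_id, sim$clones$id)
  expect_true(all(alns$orientation == "identity"))
  expect_true(all(!alns$flagged))
  f_tsv <- tempfile(fileext = ".tsv")
  f_fa <- tempfile(fileext = ".fasta")
  export_alignments(alns, tsv = f_tsv, fasta = f_fa)
  expect_equal(nrow(read.delim(f_tsv)), 4L)
  expect_equal(sum(grepl("^>", readLines(f_fa))), 8L)
})
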