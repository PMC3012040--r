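test_that("per-site summary excludes missing calls from the denominator", {
  s <- methylation_summary(toy_dataset())
  expect_equal(s$position, toy_positions)
  expect_equal(s$percent_methylated, c(50, 50, 50, 50, 25))

  ds <- meth_set(rbind(c(1, NA), c(NA, NA), c(NA, 0), c(NA, NA)), c(3L, 9L))
  s2 <- methylation_summary(ds)
  expect_equal(s2$percent_methylated, c(100, 0))
  expect_equal(s2$n_missing, c(3L, 3L))

  all_missing <- meth_set(matrix(NA_real_, 2, 1), 5L)
  expect_true(is.na(methylation_summary(all_missing)$percent_methylated))
})

test_that("toy co-occurrence shows perfect correlation and anti-correlation", {
  co <- cooccurrence(toy_dataset(), mode = "correlation")
  expect_equal(co$values[1, 2], 1)
  expect_equal(co$values[2, 3], -1)
  expect_true(all(diag(co$values) == 1))
  expect_true(isSymmetric(co$values))
})

test_that("shared-fraction mode is one minus the normalized Hamming distance", {
  ds <- toy_dataset()
  co <- cooccurrence(ds, mode = "shared_fraction")
  h <- hamming_distances(t(ds$calls))
  expect_equal(unname(co$values), unname(1 - h), ignore_attr = TRUE)
  expect_true(all(co$values >= 0 & co$values <= 1))
})

test_that("correlation entries equal a generic correlation oracle", {
  set.seed(404)
  for (rep in 1:5) {
    m <- matrix(stats::rbinom(60, 1, 0.5), 10, 6)
    m[sample(60, 12)] <- NA
    ds <- meth_set(m, seq(2, by = 5, length.out = 6))
    co <- cooccurrence(ds)
    oracle <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    # the unit diagonal is this package's convention; compare off-diagonal
    comparable <- !is.na(co$values) & !diag(TRUE, 6)
    expect_equal(co$values[comparable], oracle[comparable])
    # zero-variance and tiny-n pairs are flagged missing, never NaN
    expect_false(any(is.nan(co$values)))
  }
})

test_that("degenerate pairs are missing-flagged", {
  ds <- meth_set(rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, NA)),
                 c(2L, 8L, 14L))
  co <- cooccurrence(ds)
  expect_true(is.na(co$values[1, 2]))   # constant column: zero variance
  expect_equal(co$n_pairs[2, 3], 2L)
  nb <- neighbour_values(co)
  expect_equal(nrow(nb), 2L)
})

test_that("neighbours_only computes adjacent pairs and leaves distant ones missing", {
  co <- cooccurrence(toy_dataset(), neighbours_only = TRUE)
  expect_false(is.na(co$values[1, 2]))
  expect_true(is.na(co$values[1, 3]))
})

test_that("per-site Fisher tests match the enumeration oracle on known tables", {
  expect_equal(methclones:::fisher_p_2x2(matrix(c(3, 0, 0, 3), 2,
                                                byrow = TRUE))$p, 0.1)
  expect_equal(methclones:::fisher_p_2x2(matrix(c(2, 2, 2, 2), 2))$p, 1)
  expect_equal(methclones:::fisher_p_2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252)
  # degenerate margin: reported p = 1 with the flag, not tested
  deg <- methclones:::fisher_p_2x2(matrix(c(0, 0, 3, 2), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("fisher_site_test builds the right tables from calls and groups", {
  calls <- rbind(c(1, 1), c(1, 0), c(1, NA), c(0, 0), c(0, 1), c(NA, 0))
  ds <- meth_set(calls, c(4L, 9L),
                 clone_ids = paste0("c", 1:6))
  groups <- tibble::tibble(clone_id = paste0("c", 1:6),
                           group = rep(c("A", "B"), each = 3))
  res <- fisher_site_test(ds, groups)
  expect_equal(res$position, c(4L, 9L))
  # site 4: A has (1,1,1) -> a=3,b=0 ; B has (0,0,NA) -> c=0,d=2
  expect_equal(unlist(res[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 0, 0, 2))
  expect_equal(res$p_value[1], fisher_oracle_p(matrix(c(3, 0, 0, 2), 2,
                                                      byrow = TRUE)))
  res_bh <- fisher_site_test(ds, groups, adjust = "BH")
  expect_equal(res_bh$p_adjusted, p.adjust(res_bh$p_value, "BH"))
})

test_that("exact Mann-Whitney p matches full permutation enumeration", {
  set.seed(505)
  cases <- list(
    list(x = c(10, 20, 30), y = c(70, 80, 90)),
    list(x = c(1, 1, 2, 3), y = c(2, 2, 3, 4)),        # ties across groups
    list(x = c(5, 5, 5), y = c(5, 5, 5, 5)),           # all tied
    list(x = stats::runif(6), y = stats::runif(6)),
    list(x = sample(0:3, 5, TRUE), y = sample(0:3, 6, TRUE))
  )
  for (cs in cases) {
    expect_equal(methclones:::mw_exact_two_sided(cs$x, cs$y),
                 mw_oracle_p(cs$x, cs$y))
  }
  # tie-free exactness also agrees with the textbook implementation
  expect_equal(methclones:::mw_exact_two_sided(c(10, 20, 30), c(70, 80, 90)),
               stats::wilcox.test(c(10, 20, 30), c(70, 80, 90))$p.value)
})

test_that("the set test compares per-site percentages between two datasets", {
  # group A percentages (10, 20, 30); group B (70, 80, 90), 10 clones each
  mk <- function(counts) {
    m <- sapply(counts, function(k) c(rep(1, k), rep(0, 10 - k)))
    meth_set(m, c(2L, 10L, 20L))
  }
  res <- mannwhitney_set_test(mk(c(1, 2, 3)), mk(c(7, 8, 9)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)

  same <- mannwhitney_set_test(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_equal(same$p_value, 1)

  expect_error(mannwhitney_set_test(mk(c(1, 2, 3)),
                                    meth_set(matrix(1, 2, 2), c(2L, 10L))),
               class = "methclones_input_error")
})

test_that("large-sample Mann-Whitney falls back to a tie-corrected normal", {
  set.seed(606)
  x <- sample(seq(0, 100, by = 10), 15, replace = TRUE)
  y <- sample(seq(20, 100, by = 10), 15, replace = TRUE)
  p_pkg <- methclones:::mw_normal_two_sided(x, y)
  p_ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE)$p.value)
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
})

test_that("Hamming distances obey metric properties on the compared counts", {
  set.seed(707)
  m <- matrix(stats::rbinom(48, 1, 0.5), 8, 6)
  d <- hamming_distances(m)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  raw <- d * 6   # unnormalized counts (complete matrix: all pairs compare 6)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(raw[i, k], raw[i, j] + raw[j, k] + 1e-9)
  }
  expect_equal(unname(hamming_distances(rbind(c(1, 0), c(0, 1)))[1, 2]), 1)
})

test_that("biclustering merges the toy clones in the expected order", {
  ds <- toy_dataset()
  bic <- hamming_bicluster(ds)
  expect_equal(bic$row_dist["clone1", "clone2"], 0)
  expect_equal(bic$row_dist["clone3", "clone4"], 0.2)
  expect_equal(bic$row_dist["clone1", "clone3"], 0.8)
  # clones 1,2 merge first (distance 0); 3,4 merge before joining {1,2}
  expect_equal(sort(bic$row_tree$merge[1, ]), c(-2, -1))
  expect_equal(sort(bic$row_tree$merge[2, ]), c(-4, -3))
  expect_equal(abs(bic$row_tree$merge[3, ]), c(1, 2))
  expect_true(which(bic$row_order == "clone1") %in%
                c(which(bic$row_order == "clone2") + 1,
                  which(bic$row_order == "clone2") - 1))
})

test_that("duplicated rows cluster flat and full disagreement scores 1", {
  flat <- meth_set(matrix(rep(c(1, 0, 1), 3), 3, byrow = TRUE),
                   c(1L, 5L, 9L))
  bic <- hamming_bicluster(flat)
  expect_true(all(bic$row_tree$height == 0))
  expect_error(
    hamming_bicluster(meth_set(rbind(c(1, NA), c(NA, 0)), c(1L, 5L))),
    "no comparable", class = "methclones_input_error")
})
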