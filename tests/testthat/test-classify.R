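test_that("the worked attractor-set comparisons map to the right classes", {
  A <- c("a1", "a2", "a3")
  expect_equal(classify_change(A, c("a1", "a2")), "not_robust_not_evolvable")
  expect_equal(classify_change(A, c("a1", "a4")), "not_robust_evolvable")
  expect_equal(classify_change(A, A), "robust_not_evolvable")
  expect_equal(classify_change(A, c("a1", "a2", "a3", "a4", "a5")),
               "robust_evolvable")
  expect_error(classify_change(A, character(0)), "nonempty")
})

test_that("classification accepts state-space analyses and checks N", {
  fig <- example_network()
  an <- find_attractors(fig)
  expect_equal(classify_change(an, an), "robust_not_evolvable")
  other <- find_attractors(identity_network(4))
  expect_error(classify_change(an, other), "incomparable")
})

test_that("the four set relations are an exhaustive, exclusive partition", {
  universe <- paste0("a", 1:6)
  withr::with_seed(19, {
    for (rep in 1:300) {
      A <- sample(universe, sample.int(6, 1))
      B <- sample(universe, sample.int(6, 1))
      cls <- classify_change(A, B)
      # recompute the relation directly
      expected <- if (setequal(A, B)) "robust_not_evolvable"
        else if (all(B %in% A)) "not_robust_not_evolvable"
        else if (all(A %in% B)) "robust_evolvable"
        else "not_robust_evolvable"
      expect_equal(cls, expected)
      expect_true(cls %in% robustness_classes())
    }
  })
})

test_that("class_distribution sums to 100 and matches per-mutant recomputation", {
  net <- generate_rbn(8, 2, seed = 3)
  co <- sample_mutants(net, 30, seed = 4)
  cd <- class_distribution(net, co)
  expect_equal(sum(cd$percentages), 100, tolerance = 1e-9)
  expect_equal(cd$n_mutants, 30L)
  # independent recomputation via the brute-force oracle
  orc_A <- oracle_attractors(net)$keys
  oracle_cls <- vapply(co, function(e) {
    orc_B <- oracle_attractors(e$network)$keys
    classify_change(orc_A, orc_B)
  }, character(1))
  expect_equal(cd$classes, oracle_cls)
  expect_error(class_distribution(net, list()), "empty")
})

test_that("mutants with identical dynamics are all robust_not_evolvable", {
  # nodes 1 and 2 carry a dummy input their tables ignore; re-pointing the
  # dummy edge changes the wiring but not the dynamics
  net <- boolean_network(list(c(1L, 2L), c(2L, 3L), 3L),
                         list(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L),
                              c(0L, 1L)))
  mutants <- list(
    apply_mutation(net, mutation("change", 1, source = 2, new_source = 3)),
    apply_mutation(net, mutation("change", 2, source = 3, new_source = 1)))
  cd <- class_distribution(net, mutants)
  expect_equal(unname(cd$percentages), c(0, 0, 100, 0))
})

test_that("cramers_v matches its definition and invariances", {
  tab <- matrix(c(10, 20, 5, 40, 8, 12), nrow = 2, byrow = TRUE)
  v <- cramers_v(tab)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(v, sqrt(unname(chi) / (sum(tab) * 1)), tolerance = 1e-12)
  # permutation and scaling invariance
  expect_equal(cramers_v(tab[, c(3, 1, 2)]), v)
  expect_equal(cramers_v(tab[c(2, 1), ]), v)
  expect_equal(cramers_v(tab * 7), v, tolerance = 1e-12)
  # independence and perfect association
  indep <- outer(c(2, 3), c(5, 10, 15))
  expect_equal(cramers_v(indep), 0, tolerance = 1e-12)
  expect_equal(cramers_v(diag(50, 2)), 1)
  expect_error(cramers_v(matrix(0, 2, 2)), "degenerate")
  expect_error(cramers_v(matrix(c(1, 2), 1, 2)), "degenerate")
  expect_error(cramers_v(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
})
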