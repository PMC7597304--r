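test_that("mutation constructor demands exactly the right parameters", {
  expect_s3_class(mutation("flip", 1, table_row = 1), "bn_mutation")
  expect_error(mutation("flip", 1), "requires exactly")
  expect_error(mutation("add", 1, source = 2), "requires exactly")
  expect_error(mutation("delete", 1, source = 2, new_source = 3),
               "requires exactly")
})

test_that("flip edits exactly one truth-table bit", {
  net <- identity_network(3)
  mut <- apply_mutation(net, mutation("flip", 2, table_row = 1))
  expect_equal(mut$truth_tables[[2]], c(1L, 1L))
  expect_identical(mut$truth_tables[[1]], net$truth_tables[[1]])
  expect_identical(mut$truth_tables[[3]], net$truth_tables[[3]])
  expect_identical(mut$inputs, net$inputs)
  expect_error(apply_mutation(net, mutation("flip", 2, table_row = 5)),
               "out of range")
})

test_that("link addition preserves the original function on the new-input-0 slice", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      net <- generate_rbn(6, 2, seed = rep)
      t <- sample.int(6, 1)
      src <- setdiff(1:6, net$inputs[[t]])[1]
      mut <- apply_mutation(net, mutation("add", t, source = src,
                                          fill_seed = rep * 31))
      expect_equal(length(mut$inputs[[t]]), 3L)
      expect_equal(length(mut$truth_tables[[t]]), 8L)
      expect_equal(mut$inputs[[t]][1], src)  # new input is the MSB
      # restricting the new input to 0 reproduces the original table
      expect_identical(mut$truth_tables[[t]][1:4], net$truth_tables[[t]])
      # and the matching delete restores the network exactly
      back <- apply_mutation(mut, mutation("delete", t, source = src))
      expect_identical(back$inputs, net$inputs)
      expect_identical(back$truth_tables, net$truth_tables)
    }
  })
})

test_that("deleting the sole input leaves the input-0 constant", {
  net <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(0L, 1L)))
  mut <- apply_mutation(net, mutation("delete", 1, source = 2))
  expect_equal(mut$inputs[[1]], integer(0))
  expect_equal(mut$truth_tables[[1]], 1L)  # original row where input was 0
})

test_that("change re-points a link without touching the table", {
  net <- generate_rbn(5, 2, seed = 8)
  t <- 1L
  src <- net$inputs[[t]][1]
  new <- setdiff(1:5, net$inputs[[t]])[1]
  mut <- apply_mutation(net, mutation("change", t, source = src,
                                      new_source = new))
  expect_identical(mut$truth_tables, net$truth_tables)
  expect_equal(sort(mut$inputs[[t]]), sort(c(setdiff(net$inputs[[t]], src), new)))
  expect_equal(lengths(mut$inputs), lengths(net$inputs))
})

test_that("inapplicable mutations raise applicability errors", {
  net <- identity_network(2)
  expect_error(apply_mutation(net, mutation("add", 1, source = 1,
                                            fill_seed = 1)),
               "already an input")
  zero_in <- boolean_network(list(integer(0), 1L), list(1L, c(0L, 1L)))
  expect_error(apply_mutation(zero_in, mutation("delete", 1, source = 1)),
               "not an input")
  expect_error(apply_mutation(net, mutation("change", 1, source = 1,
                                            new_source = 1)),
               "already an input")
})

test_that("sample_mutants balances kinds and never repeats a network", {
  net <- generate_rbn(8, 2, seed = 42)
  co <- sample_mutants(net, 6, seed = 1)
  counts <- sort(as.vector(attr(co, "kind_counts")))
  expect_equal(counts, c(1L, 1L, 2L, 2L))
  co2 <- sample_mutants(net, 40, seed = 2)
  expect_equal(as.vector(attr(co2, "kind_counts")), rep(10L, 4))
  encs <- vapply(co2, function(e) bnaf:::canonical_encoding(e$network),
                 character(1))
  expect_equal(anyDuplicated(encs), 0L)
  # N-preservation
  expect_true(all(vapply(co2, function(e) e$network$N, integer(1)) == 8L))
  # seeded reproducibility
  co3 <- sample_mutants(net, 40, seed = 2)
  expect_identical(lapply(co2, `[[`, "network"), lapply(co3, `[[`, "network"))
})

test_that("exhaustion is reported when too few distinct mutants exist", {
  net <- boolean_network(list(1L), list(c(0L, 1L)))  # N=1 self loop
  expect_error(sample_mutants(net, 50, seed = 1, max_tries = 30),
               "exhaustion")
})
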