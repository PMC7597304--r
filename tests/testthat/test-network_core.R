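test_that("constructor enforces the structural invariants", {
  expect_error(boolean_network(list(1L), list(c(0L, 1L, 0L))), "truth table")
  expect_error(boolean_network(list(3L), list(c(0L, 1L))), "out of range")
  expect_error(boolean_network(list(c(1L, 1L)), list(rep(0L, 4))),
               "parallel edges")
  net <- boolean_network(list(integer(0)), list(1L))
  expect_equal(net$N, 1L)
  expect_equal(synchronous_step(net, 0L), 1L)
})

test_that("synchronous_step follows the update map", {
  zero <- constant_zero_network(4)
  expect_equal(synchronous_step(zero, c(1L, 0L, 1L, 1L)), rep(0L, 4)) # constants
  id <- identity_network(3)
  expect_equal(synchronous_step(id, state_from_string("101")),
               state_from_string("101"))                               # fixed point
  fig <- example_network()
  expect_equal(state_to_string(synchronous_step(fig, "011")), "110")
  expect_error(synchronous_step(fig, c(0L, 1L)), "invalid state")
  # determinism
  s <- c(1L, 0L, 0L)
  expect_identical(synchronous_step(fig, s), synchronous_step(fig, s))
})

test_that("trajectory runs for the requested number of steps", {
  id <- identity_network(3)
  tr0 <- trajectory(id, "110", 0)
  expect_equal(nrow(tr0), 1L)
  tr <- trajectory(id, "110", 5)
  expect_equal(nrow(tr), 6L)
  expect_true(all(apply(tr, 1L, state_to_string) == "110"))
  expect_error(trajectory(id, "110", -1), "non-negative")
  # the example network's 100 state enters the 2-cycle {011, 110}
  fig <- example_network()
  tr <- trajectory(fig, "100", 8)
  strs <- apply(tr, 1L, state_to_string)
  hit <- which(strs %in% c("011", "110"))
  expect_true(length(hit) > 0 && hit[1] <= 8)
  tail2 <- strs[hit[1]:9]
  expect_true(all(tail2 %in% c("011", "110")))
  expect_true(all(tail2[-1] != tail2[-length(tail2)]))  # period 2
})

test_that("generate_rbn produces valid, reproducible NK networks", {
  net <- generate_rbn(3, 2, seed = 1)
  expect_true(all(lengths(net$truth_tables) == 4L))
  expect_true(all(lengths(net$inputs) == 2L))
  expect_identical(generate_rbn(10, 3, seed = 99), generate_rbn(10, 3, seed = 99))
  expect_error(generate_rbn(3, 4, seed = 1), "K <= N")
})

test_that("RBN truth-table bits are Bernoulli(bias)", {
  # 1000 networks, N=10, K=2: 40,000 i.i.d. bits, se = 0.0025
  bits <- unlist(lapply(1:1000, function(i)
    generate_rbn(10, 2, seed = i)$truth_tables))
  expect_gt(mean(bits), 0.48)
  expect_lt(mean(bits), 0.52)
})

test_that("state encoding round-trips and node 1 is the LSB", {
  expect_equal(encode_state(c(1L, 0L, 0L)), 1L)
  expect_equal(encode_state(c(0L, 0L, 1L)), 4L)
  for (code in 0:15)
    expect_equal(encode_state(decode_state(code, 4)), code)
  expect_equal(state_from_string(state_to_string(c(0L, 1L, 1L))),
               c(0L, 1L, 1L))
})
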