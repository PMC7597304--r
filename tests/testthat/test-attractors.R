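test_that("the example network has the documented attractor landscape", {
  an <- find_attractors(example_network())
  expect_equal(attractor_count(an), 4L)
  sets <- lapply(an$attractors, function(a)
    sort(vapply(a$states, function(s)
      state_to_string(decode_state(s, 3)), character(1))))
  expect_true(list("000") %in% sets)
  expect_true(list("010") %in% sets)
  expect_true(list("111") %in% sets)
  expect_true(list(c("011", "110")) %in% sets)
  expect_equal(mean_attractor_length(an), 1.25)
  # 100 and 101 drain into the 2-cycle: its basin holds 4 states
  cyc <- an$attractors[[which(vapply(an$attractors, `[[`, integer(1),
                                     "length") == 2L)]]
  expect_equal(cyc$basin_size, 4L)
})

test_that("identity and constant networks have the trivial landscapes", {
  an <- find_attractors(identity_network(2))
  expect_equal(attractor_count(an), 4L)
  expect_true(all(an$basin_sizes == 1L))
  expect_equal(mean_attractor_length(an), 1)
  expect_equal(normalized_basin_entropy(an), 1)
  zero <- find_attractors(constant_zero_network(3))
  expect_equal(attractor_count(zero), 1L)
  expect_equal(mean_attractor_length(zero), 1)
  expect_equal(normalized_basin_entropy(zero), 0)
})

test_that("the size cap is enforced by name", {
  expect_error(find_attractors(identity_network(5), cap = 4), "cap of 4")
})

test_that("attractor finder matches the brute-force oracle on random RBNs", {
  withr::with_seed(3, {
    for (rep in 1:30) {
      N <- sample(3:8, 1)
      net <- generate_rbn(N, sample.int(3, 1), seed = rep * 7)
      an <- find_attractors(net)
      orc <- oracle_attractors(net)
      got <- analysis_key_basins(an)
      expect_setequal(names(got), orc$keys)
      expect_equal(unname(got[orc$keys]), orc$basin_sizes)
      expect_equal(sum(an$basin_sizes), 2^N)                 # conservation
      expect_equal(normalized_basin_entropy(an), orc$entropy,
                   tolerance = 1e-12)
    }
  })
})

test_that("attractor identity is rotation-invariant (canonical form)", {
  # 4-cycle network: one node rotating a pattern
  net <- boolean_network(list(2L, 3L, 1L),
                         list(c(0L, 1L), c(0L, 1L), c(0L, 1L)))
  an <- find_attractors(net)
  for (a in an$attractors) {
    expect_equal(a$canonical_key, min(a$states))
    expect_equal(a$states[1], min(a$states))
    expect_equal(a$length, length(unique(a$states)))
    # successor relation holds around the cycle
    for (i in seq_along(a$states)) {
      nxt <- a$states[if (i == a$length) 1L else i + 1L]
      expect_equal(encode_state(synchronous_step(net,
        decode_state(a$states[i], net$N))), nxt)
    }
  }
})
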