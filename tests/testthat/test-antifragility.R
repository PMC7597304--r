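test_that("emergence handles the canonical endpoint and midpoint cases", {
  # constant node: no change, E_i = 0
  w <- cbind(rep(1L, 10), rep(0L, 10))
  em <- emergence(w)
  expect_equal(unname(em$E_i), c(0, 0))
  expect_equal(em$E, 0)
  expect_equal(em$C, 0)
  # half-on node: E_i = 1
  w2 <- cbind(rep(c(0L, 1L), 10))
  expect_equal(emergence(w2)$E, 1)
  expect_equal(emergence(w2)$C, 0)
  # p1 = 0.89 gives E_i = 0.5 to one decimal
  w3 <- cbind(c(rep(1L, 89), rep(0L, 11)))
  expect_equal(round(emergence(w3)$E, 1), 0.5)
  expect_equal(binary_entropy(0.89), 0.5, tolerance = 5e-4)
  expect_error(emergence(matrix(integer(0), 0, 2)), "empty")
  # p0 + p1 = 1 always, S + E = 1
  em4 <- emergence(matrix(rbinom(40, 1, 0.3), 10, 4))
  expect_equal(unname(em4$p0 + em4$p1), rep(1, 4))
  expect_equal(em4$S + em4$E, 1)
})

test_that("complexity is the normalized E*(1-E) parabola", {
  expect_equal(complexity(0.5), 1)
  expect_equal(complexity(0), 0)
  expect_equal(complexity(1), 0)
  expect_equal(round(complexity(0.612), 2), 0.95)
  expect_error(complexity(1.2), "\\[0, 1\\]")
})

test_that("delta_x normalizes perturbation intensity", {
  expect_equal(delta_x(10, 10, 1), 1)
  expect_equal(delta_x(4, 10, 1), 0.4)
  expect_equal(delta_x(0, 10, 1), 0)
  expect_equal(delta_x(4, 10, 2), 0.2)
  expect_error(delta_x(11, 10), "X <= N")
})

test_that("perturbed_window obeys the protocol", {
  net <- generate_rbn(6, 2, seed = 2)
  init <- decode_state(13, 6)
  # X = 0 equals the unperturbed trajectory's states T+1 .. 2T
  w0 <- perturbed_window(net, init, X = 0, T = 10, O = 1, seed = 1)
  tr <- trajectory(net, init, 20)
  expect_equal(unname(w0), unname(tr[12:21, , drop = FALSE]))
  # constant-zero network: post-update recording maps everything to zero
  zero <- constant_zero_network(5)
  wz <- perturbed_window(zero, rep(1L, 5), X = 3, T = 8, O = 1, seed = 4)
  expect_true(all(wz == 0L))
  expect_equal(emergence(wz)$E, 0)
  # seeded determinism
  wa <- perturbed_window(net, init, X = 2, T = 15, O = 2, seed = 9)
  wb <- perturbed_window(net, init, X = 2, T = 15, O = 2, seed = 9)
  expect_identical(wa, wb)
  expect_equal(dim(wa), c(15L, 6L))
})

test_that("single-run window agrees with the vectorised engine", {
  net <- generate_rbn(7, 2, seed = 5)
  init <- decode_state(42, 7)
  w <- perturbed_window(net, init, X = 2, T = 12, O = 1, seed = 77)
  ones <- bnaf:::run_window(net, matrix(init, nrow = 1), X = 2, T = 12,
                            O = 1, seed = 77)
  expect_equal(as.vector(ones), unname(colSums(w)))
})

test_that("fragility vanishes at X = 0 and respects its bounds", {
  net <- generate_rbn(8, 2, seed = 6)
  cfg <- perturbation_config(T = 25, s = 40, seed = 2)
  p0 <- fragility(net, 0, cfg)
  expect_equal(p0$fragility, 0)
  expect_equal(p0$delta_x, 0)
  fc <- fragility_curve(net, cfg)
  expect_equal(nrow(fc), 8L)
  expect_equal(fc$delta_x, (1:8) / 8)
  expect_true(all(fc$fragility >= -1 & fc$fragility <= 1))
  expect_true(all(fc$C >= 0 & fc$C <= 1))
  expect_true(all(fc$delta_sigma >= -1 & fc$delta_sigma <= 1))
  expect_equal(fc$fragility, -fc$delta_sigma * fc$delta_x)
  # sign semantics: complexity gain => antifragile (non-positive) value
  gained <- fc$C >= fc$C0
  expect_true(all(fc$fragility[gained] <= 0))
  # determinism of the whole curve
  expect_equal(fragility_curve(net, cfg), fc)
})

test_that("difference_curve interpolates onto the shared 30-point grid", {
  net <- generate_rbn(5, 2, seed = 9)
  cfg <- perturbation_config(T = 15, s = 20, seed = 3)
  fc <- fragility_curve(net, cfg)
  dc <- difference_curve(fc, fc)
  expect_equal(length(dc$values), 30L)
  expect_equal(dc$values, rep(0, 30))
  expect_equal(dc$grid[1], 1 / 5)
  expect_equal(dc$grid[30], 1)
  expect_true(all(diff(dc$grid) > 0))
  # closed-form check: N=2 curve (0, 1) at X=1,2; midpoint 0.75 -> 0.5
  orig <- fake_curve(1:2, c(0, 1), N = 2)
  mut <- fake_curve(1:2, c(0, 0), N = 2)
  dc3 <- difference_curve(orig, mut, points = 3)
  expect_equal(dc3$values, c(0, 0.5, 1))
  # native grid for N = 30: no interpolation error
  v <- sin(1:30)
  orig30 <- fake_curve(1:30, v, N = 30)
  mut30 <- fake_curve(1:30, rep(0, 30), N = 30)
  expect_equal(difference_curve(orig30, mut30)$values, v)
  # mismatched N is an error
  expect_error(difference_curve(orig, mut30), "incomparable")
})

test_that("perturbation draws are shared across networks (paired comparison)", {
  cfg <- perturbation_config(T = 10, s = 16, seed = 21)
  net <- generate_rbn(4, 2, seed = 1)
  # identical network object computed twice gives identical curves
  expect_equal(fragility_curve(net, cfg), fragility_curve(net, cfg))
  # a dynamics-preserving rewiring gives the identical curve under shared
  # randomness (dummy-input trick)
  base <- boolean_network(list(c(1L, 2L), 1L, 3L),
                          list(c(0L, 0L, 1L, 1L), c(0L, 1L), c(0L, 1L)))
  rewired <- apply_mutation(base, mutation("change", 1, source = 2,
                                           new_source = 3))
  expect_equal(fragility_curve(base, cfg)$fragility,
               fragility_curve(rewired, cfg)$fragility)
})
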