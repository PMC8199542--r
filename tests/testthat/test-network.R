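test_that("single-cell and diagonal grids have no crosstalk", {
  g <- matrix(0, 2, 2); g[1, 1] <- 5e-4
  expect_equal(forward_equivalent(g, 1, 1), 5e-4, tolerance = 1e-15)
  # diagonal grid: no two cells share a row-column path
  gd <- diag(c(1e-3, 2e-3, 3e-3))
  expect_equal(forward_equivalent_all(gd), gd, tolerance = 1e-15,
               ignore_attr = TRUE)
  # 1x1 degenerate grid
  g1 <- matrix(7e-4, 1, 1)
  expect_equal(forward_equivalent_all(g1), g1, tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("uniform 2x2 grid matches the series-parallel closed form", {
  # four 1 kOhm cells: direct cell in parallel with the 3-cell series path
  g <- matrix(1 / 1000, 2, 2)
  expect_equal(1 / forward_equivalent(g, 1, 1), 750, tolerance = 1e-9)
  expect_equal(forward_equivalent(g, 1, 1), 1 / 1000 + 1 / 3000,
               tolerance = 1e-12)
})

test_that("forward map matches the brute-force nodal oracle on random grids", {
  set.seed(42)
  for (case in 1:100) {
    m <- sample(1:3, 1); n <- sample(1:3, 1)
    g <- matrix(runif(m * n, 0, 1e-3), m, n)
    # sprinkle structural zeros to exercise isolated nodes
    g[runif(m * n) < 0.3] <- 0
    eq <- forward_equivalent_all(g, floor_g = 0)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      ora <- oracle_forward_equivalent(g, i, j)
      denom <- max(ora, 1e-12)
      expect_lt(abs(eq[i, j] - ora) / denom, 1e-12)
    }
  }
})

test_that("crosstalk only adds conductance and scales linearly", {
  set.seed(7)
  for (case in 1:20) {
    g <- matrix(runif(16, 0, 1e-3), 4, 4)
    eq <- forward_equivalent_all(g)
    expect_true(all(eq >= g - 1e-15))
    c0 <- runif(1, 0.1, 10)
    expect_equal(forward_equivalent_all(c0 * g), c0 * eq, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("three pressed rectangle corners make the fourth appear pressed", {
  g <- matrix(0, 4, 4)
  g[1, 1] <- 1e-3; g[1, 4] <- 1e-3; g[4, 1] <- 1e-3   # fourth corner (4,4) unpressed
  eq <- forward_equivalent_all(g)
  expect_gt(eq[4, 4], 1e-4)       # ghost: series path through the three corners
  # with a small baseline at the fourth corner the measurement still exceeds it
  g2 <- g; g2[4, 4] <- 1e-6
  expect_gt(forward_equivalent(g2, 4, 4), g2[4, 4])
})

test_that("crosstalk removal recovers random grids from their own scans", {
  set.seed(123)
  st <- inversion_settings()
  for (n in c(2, 4, 8)) {
    for (case in 1:5) {
      g <- matrix(runif(n * n, 0, 1e-3), n, n)
      g[runif(n * n) < 0.2] <- 0
      meas <- forward_equivalent_all(g)
      rec <- remove_crosstalk(meas, st)
      expect_true(attr(rec, "converged"))
      expect_lt(max(abs(rec - g)), 1e-9)
    }
  }
})

test_that("ghost corner is suppressed to tolerance after inversion", {
  g <- matrix(0, 4, 4)
  g[1, 1] <- 1e-3; g[1, 4] <- 1e-3; g[4, 1] <- 1e-3
  meas <- forward_equivalent_all(g)
  expect_gt(meas[4, 4], 1e-4)                    # non-negligible before
  rec <- remove_crosstalk(meas)
  expect_lt(rec[4, 4], inversion_settings()$tol) # negligible after
  expect_lt(max(abs(rec - g)), 1e-9)
})

test_that("single nonzero cell is a fixed point of the inversion", {
  meas <- matrix(0, 3, 3); meas[2, 3] <- 4e-4
  rec <- remove_crosstalk(meas)
  expect_equal(unclass(rec), meas, ignore_attr = TRUE, tolerance = 1e-15)
  expect_true(attr(rec, "converged"))
})

test_that("fixed-point method converges on lightly loaded grids and flags failure", {
  set.seed(5)
  g <- matrix(0, 4, 4)
  g[2, 2] <- 4e-4; g[3, 3] <- 3e-4    # sparse: weak crosstalk, contraction holds
  meas <- forward_equivalent_all(g)
  rec <- remove_crosstalk(meas, inversion_settings(damping = 0.7),
                          method = "fixed_point")
  expect_true(attr(rec, "converged"))
  expect_lt(max(abs(rec - g)), 1e-9)
  # dense uniform grid: crosstalk is not a contraction; must flag, not raise
  gd <- matrix(1e-3, 4, 4)
  md <- forward_equivalent_all(gd)
  recd <- remove_crosstalk(md, inversion_settings(max_iter = 20),
                           method = "fixed_point")
  expect_false(attr(recd, "converged"))
  expect_true(is.finite(attr(recd, "residual")))
})

test_that("constructors validate their inputs", {
  expect_error(cell_grid(matrix(-1, 2, 2)))
  expect_error(inversion_settings(damping = 0))
  expect_error(inversion_settings(tol = 0))
  expect_error(readout_circuit(v_cc = -1))
})
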