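make_seq <- function(frames, geom = NULL, fs = 10) {
  d <- dim(frames)
  if (is.null(geom)) geom <- mat_geometry(d[1], d[2], 2.0)
  pressure_sequence(seq_len(d[3]) / fs, frames, geom, units = "pressure")
}

test_that("centroid hits cell centers, symmetry points, and hand values", {
  geom <- mat_geometry(4, 4, 2.0)
  # single nonzero cell: CoP at that cell's center
  f <- array(0, c(4, 4, 1)); f[2, 3, 1] <- 5
  traj <- compute_cop(make_seq(f, geom))
  expect_equal(traj$x_ml, geom$centers_x[3])
  expect_equal(traj$y_ap, geom$centers_y[2])
  # uniform frame: geometric center
  fu <- array(1, c(4, 4, 1))
  tu <- compute_cop(make_seq(fu, geom))
  expect_equal(tu$x_ml, 0); expect_equal(tu$y_ap, 0)
  # two cells, weights 1 and 3 at x = -1 and +1: X = +0.5
  g2 <- mat_geometry(1, 2, 2.0)
  f2 <- array(c(1, 3), c(1, 2, 1))
  t2 <- compute_cop(pressure_sequence(0.1, f2, g2, units = "pressure"),
                    noise_floor = 0)
  expect_equal(t2$x_ml, 0.5)
})

test_that("centroid is invariant to proportional pressure units", {
  set.seed(10)
  f <- array(runif(4 * 4 * 5), c(4, 4, 5))
  a <- compute_cop(make_seq(f))
  b <- compute_cop(make_seq(f * 37.5))
  expect_equal(a$x_ml, b$x_ml, tolerance = 1e-12)
  expect_equal(a$y_ap, b$y_ap, tolerance = 1e-12)
})

test_that("empty frames carry the previous CoP forward and empty-first errors", {
  f <- array(0, c(2, 2, 3)); f[1, 1, 1] <- 1; f[2, 2, 3] <- 1
  expect_warning(traj <- compute_cop(make_seq(f)), "carried forward")
  expect_equal(traj$x_ml[2], traj$x_ml[1])
  f0 <- array(0, c(2, 2, 2)); f0[1, 1, 2] <- 1
  expect_error(compute_cop(make_seq(f0)), "first frame")
})

test_that("line-selection downsampling halves the grid and keeps coordinates", {
  geom <- mat_geometry(16, 16, 2.0)
  set.seed(11)
  f <- array(runif(16 * 16 * 3), c(16, 16, 3))
  seq16 <- make_seq(f, geom)
  seq8 <- downsample_grid(seq16, phase = 0)
  expect_equal(dim(seq8$frames)[1:2], c(8L, 8L))
  expect_equal(seq8$geometry$centers_x, geom$centers_x[seq(1, 16, 2)])
  expect_equal(seq8$frames[2, 3, ], f[3, 5, ])      # selected, not aggregated
  # uniform frame: CoP of the selected sub-grid is its own center of cells
  fu <- array(1, c(16, 16, 1))
  t8 <- compute_cop(downsample_grid(make_seq(fu, geom)))
  expect_equal(t8$x_ml, mean(geom$centers_x[seq(1, 16, 2)]))
  # phases of a smooth blob disagree by less than one (coarse) pitch
  foot <- foot_model()
  cop <- cop_trajectory((1:20) / 10, rep(0.7, 20), rep(-0.9, 20))
  pres <- render_pressure(cop, foot, geom)
  c0 <- compute_cop(downsample_grid(pres, 0))
  c1 <- compute_cop(downsample_grid(pres, 1))
  expect_lt(max(abs(c0$x_ml - c1$x_ml), abs(c0$y_ap - c1$y_ap)), 2 * geom$pitch)
  expect_error(downsample_grid(make_seq(array(1, c(3, 4, 1)))), "even")
})

test_that("cross-correlation alignment recovers planted lags", {
  set.seed(12)
  n <- 200
  x <- as.numeric(stats::filter(rnorm(n + 50), 0.9, method = "recursive"))
  y <- as.numeric(stats::filter(rnorm(n + 50), 0.9, method = "recursive"))
  a <- cop_trajectory((1:n) / 10, x[1:n], y[1:n])
  # identical series: lag 0
  expect_equal(align_trajectories(a, a, 20)$lag, 0L)
  # b delayed by 7 samples
  b <- cop_trajectory((1:n) / 10,
                      c(rep(x[1], 7), x[1:(n - 7)]),
                      c(rep(y[1], 7), y[1:(n - 7)]))
  al <- align_trajectories(a, b, 20)
  expect_equal(al$lag, 7L)
  expect_equal(al$b_aligned$x_ml, al$a_aligned$x_ml, tolerance = 1e-12)
  # noisy shifted white noise at SNR ~ 10 still recovers lag 3
  set.seed(13)
  wx <- rnorm(n + 3); wy <- rnorm(n + 3)
  aw <- cop_trajectory((1:n) / 10, wx[4:(n + 3)], wy[4:(n + 3)])
  bw <- cop_trajectory((1:n) / 10, wx[1:n] + rnorm(n, 0, sqrt(0.1)),
                       wy[1:n] + rnorm(n, 0, sqrt(0.1)))
  expect_equal(align_trajectories(aw, bw, 10)$lag, 3L)
  # too-short series error
  s <- cop_trajectory(1:5, rnorm(5), rnorm(5))
  expect_error(align_trajectories(s, s, 20), "short")
})

test_that("sway statistics use the population denominator and its invariances", {
  tr <- cop_trajectory(1:3, c(0, 1, 2), c(5, 5, 5))
  st <- sway_std(tr)
  expect_equal(st$sigma_ml, 0.816496580927726, tolerance = 1e-12)
  expect_equal(st$sigma_ap, 0)
  expect_equal(st$n_points, 3L)
  # translation invariance and absolute-scale equivariance
  set.seed(14)
  tr2 <- cop_trajectory(1:50, rnorm(50), rnorm(50))
  s2 <- sway_std(tr2)
  sh <- sway_std(cop_trajectory(tr2$t, tr2$x_ml + 10, tr2$y_ap - 3))
  expect_equal(sh$sigma_ml, s2$sigma_ml, tolerance = 1e-12)
  sc <- sway_std(cop_trajectory(tr2$t, -2.5 * tr2$x_ml, tr2$y_ap))
  expect_equal(sc$sigma_ml, 2.5 * s2$sigma_ml, tolerance = 1e-12)
  expect_error(sway_std(cop_trajectory(1, 0, 0)), "2")
})
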