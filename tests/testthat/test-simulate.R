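test_that("sway generator hits its targets exactly and is reproducible", {
  m <- sway_model(sigma_ml_target = 0.7, sigma_ap_target = 1.1,
                  duration = 60, fs = 10, seed = 21)
  tr <- generate_sway(m)
  expect_equal(nrow(tr), 600L)
  expect_equal(pop_sd(tr$x_ml), 0.7, tolerance = 1e-12)
  expect_equal(pop_sd(tr$y_ap), 1.1, tolerance = 1e-12)
  expect_equal(mean(tr$x_ml), 0, tolerance = 1e-12)
  tr2 <- generate_sway(m)
  expect_identical(tr, tr2)
  tr3 <- generate_sway(sway_model(seed = 22))
  expect_false(isTRUE(all.equal(tr$x_ml, tr3$x_ml)))
})

test_that("rendered frames are normalized, symmetric, and track the CoP", {
  geom <- mat_geometry()
  foot <- foot_model(load = 700)
  # centered symmetric blob: 180-degree rotation symmetry, centroid (0,0)
  pres <- render_pressure(cop_trajectory(0.1, 0, 0), foot, geom)
  fr <- pres$frames[, , 1]
  expect_equal(fr, fr[16:1, 16:1], tolerance = 1e-12)
  expect_equal(sum(fr), 700, tolerance = 1e-6)
  tc <- compute_cop(pres, noise_floor = 0)
  expect_equal(tc$x_ml, 0, tolerance = 1e-9)
  # per-frame totals renormalized to the load
  m <- sway_model(duration = 60, fs = 10, seed = 23)
  cop <- generate_sway(m)
  pres2 <- render_pressure(cop, foot, geom)
  expect_lt(max(abs(apply(pres2$frames, 3, sum) - 700)) / 700, 1e-6)
  expect_true(all(pres2$frames >= 0))
  # centroid error bounded by 5% of the pitch when spread >= 1.5 pitch
  cen <- compute_cop(pres2, noise_floor = 0)
  expect_gte(min(foot$spread_ml, foot$spread_ap), 1.5 * geom$pitch)
  expect_lt(max(abs(cen$x_ml - cop$x_ml)), 0.05 * geom$pitch)
  expect_lt(max(abs(cen$y_ap - cop$y_ap)), 0.05 * geom$pitch)
  # out-of-extent trajectory errors
  expect_error(render_pressure(cop_trajectory(0.1, 40, 0), foot, geom),
               "extent")
})

test_that("degenerate chain (no crosstalk, lag, or quantization) returns the true CoP", {
  sw <- sway_model(duration = 20, fs = 10, seed = 24)
  rec <- simulate_trial(sw, dynamics = NULL, adc_bits = Inf,
                        platform_noise_sd = 0, max_offset = 0,
                        include_crosstalk = FALSE)
  geq <- voltages_to_conductance(rec$mat_voltages, rec$circuit)
  cop <- compute_cop(geq, noise_floor = 0)
  # baseline conductance adds a small uniform pull toward the grid center;
  # with flooring at 1% it is removed and only discretization error remains
  cop_fl <- compute_cop(geq)
  expect_lt(max(abs(cop_fl$x_ml - rec$true_cop$x_ml)), 0.05 * 2.0 + 0.02)
  expect_lt(max(abs(cop_fl$y_ap - rec$true_cop$y_ap)), 0.05 * 2.0 + 0.02)
})

test_that("sensor lag shrinks the mat-derived sway below the true sway", {
  sw <- sway_model(duration = 40, fs = 10, seed = 25)
  rec <- simulate_trial(sw, dynamics = dynamics_model(0.25, 0.1),
                        adc_bits = Inf, platform_noise_sd = 0, max_offset = 0,
                        include_crosstalk = FALSE)
  geq <- voltages_to_conductance(rec$mat_voltages, rec$circuit)
  cop <- compute_cop(geq)
  burn <- 13
  st <- sway_std(cop[-(1:burn), ])
  truth <- sway_std(rec$true_cop[-(1:burn), ])
  expect_lt(st$sigma_ml, truth$sigma_ml)
  expect_lt(st$sigma_ap, truth$sigma_ap)
})

test_that("planted start offsets are recovered by alignment", {
  # sensor lag disabled: the smoother would add its own ~2-sample group delay
  sw <- sway_model(duration = 30, fs = 10, seed = 26)
  rec <- simulate_trial(sw, dynamics = NULL, max_offset = 10)
  geq <- voltages_to_conductance(rec$mat_voltages, rec$circuit)
  cop <- compute_cop(geq)
  al <- align_trajectories(rec$platform_cop, cop, max_lag = 15)
  expect_equal(al$lag, rec$start_offset)
  expect_gt(rec$start_offset, 0L)          # the draw actually planted a shift
  # with the sensor lag on, the recovered lag grows by its group delay
  rec2 <- simulate_trial(sway_model(duration = 30, fs = 10, seed = 26),
                         max_offset = 10)
  cop2 <- compute_cop(voltages_to_conductance(rec2$mat_voltages, rec2$circuit))
  al2 <- align_trajectories(rec2$platform_cop, cop2, max_lag = 15)
  expect_true(abs(al2$lag - rec2$start_offset) <= 3)
})

test_that("cohorts have the study shape and are byte-reproducible", {
  coh <- tiny_cohort(n_subjects = 3, duration = 6, master_seed = 27)
  expect_equal(length(coh$recordings), 3L)
  expect_named(coh$recordings[[1]], c("RL", "LL"))
  expect_equal(nrow(coh$subjects), 3L)
  expect_true(all(coh$subjects$sigma_ml_target > 0))
  coh2 <- tiny_cohort(n_subjects = 3, duration = 6, master_seed = 27)
  expect_identical(coh$recordings[[2]][["LL"]]$mat_voltages$frames,
                   coh2$recordings[[2]][["LL"]]$mat_voltages$frames)
  # default configuration carries the full study shape without simulating it
  cfg <- cohort_config()
  expect_equal(cfg$n_subjects, 42L)
  expect_equal(cfg$duration * cfg$fs, 600)
  expect_equal(cfg$trials, c("RL", "LL"))
})

test_that("voltages stay within the supply rails", {
  coh <- tiny_cohort(n_subjects = 2, duration = 5, master_seed = 28)
  v <- coh$recordings[[1]][["RL"]]$mat_voltages
  expect_true(all(v$frames >= 0))
  expect_true(all(v$frames <= v$v_cc))
})
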