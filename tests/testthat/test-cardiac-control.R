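test_that("normalized elastance is a valid activation waveform", {
  period <- 0.9
  shape <- mcl_params()$waveform
  # diastolic start
  expect_lt(normalized_elastance(0, period, shape), 0.01)
  # normalized peak on a dense grid
  grid <- seq(0, period, length.out = 10000)
  e <- normalized_elastance(grid, period, shape)
  expect_gte(max(e), 0.999)
  expect_lte(max(e), 1 + 1e-9)
  # end-diastolic value small
  expect_lt(normalized_elastance(period * 0.999, period, shape), 0.01)
  # periodicity
  set.seed(1)
  t <- runif(100, 0, 10)
  expect_equal(normalized_elastance(t, period, shape),
               normalized_elastance(t + period, period, shape),
               tolerance = 1e-12)
  expect_true(all(e >= 0 & e <= 1 + 1e-9))
})

test_that("Frank-Starling setpoint is linear with a zero floor", {
  expect_equal(fs_target_esp(12, 4, 20), 68)
  expect_equal(fs_target_esp(c(0, 5, 99), 0, 33), c(33, 33, 33))
  expect_equal(fs_target_esp(10, 4, -100), 0)
})

test_that("per-beat controller update moves e_max toward the target", {
  fs <- mcl_params("BVFS")$fs
  measured <- list(lap = 12, rap = 6, lvesp = 70, rvesp = 20)
  ctrl <- list(current_e_max_lv = 1.5, current_e_max_rv = 0.6,
               e_min_lv = 0.055, e_min_rv = 0.05)

  # zero error on both sides: unchanged
  fs0 <- fs
  fs0$slope_lv <- 0; fs0$intercept_lv <- 70
  fs0$slope_rv <- 0; fs0$intercept_rv <- 20
  upd <- fs_beat_update(ctrl, fs0, measured)
  expect_equal(upd$current_e_max_lv, 1.5)
  expect_equal(upd$current_e_max_rv, 0.6)

  # target above measured: e_max strictly increases
  fs_up <- fs0
  fs_up$intercept_lv <- 90
  expect_gt(fs_beat_update(ctrl, fs_up, measured)$current_e_max_lv, 1.5)
  # target below measured: decreases, but never at/below e_min
  fs_dn <- fs0
  fs_dn$intercept_lv <- 0.5
  ctrl_lo <- ctrl; ctrl_lo$current_e_max_lv <- 0.06
  expect_gte(fs_beat_update(ctrl_lo, fs_dn, measured)$current_e_max_lv,
             1.05 * ctrl$e_min_lv)
  # clipping at the configured bounds
  fs_clip <- fs0
  fs_clip$intercept_lv <- 1e5
  expect_equal(fs_beat_update(ctrl, fs_clip, measured)$current_e_max_lv,
               fs$e_max_bounds$left[2])
})

test_that("closed-loop controller converges on the normal preset", {
  st <- steady_preset("normal", "BVFS")
  expect_true(st$converged)
  tgt <- fs_target_esp(st$summary$mean[["lap"]], st$params$fs$slope_lv,
                       st$params$fs$intercept_lv)
  expect_lt(abs(st$summary$mean[["lvesp"]] - tgt), 2)
})

test_that("contractility knobs respect the configuration gating", {
  p_sv <- unit_params("SV")
  expect_error(set_contractility(p_sv, "left", "fs_slope", 3),
               "configuration error")
  # identity scaling leaves the simulation bitwise unchanged
  p1 <- set_contractility(p_sv, "left", "scale_e_max", 1)
  s1 <- mcl_simulate(p1, duration = 1)
  s0 <- mcl_simulate(p_sv, duration = 1)
  expect_identical(unclass(s1)[, ], unclass(s0)[, ])
  # halving scales both the elastance and the driver ceiling
  p2 <- set_contractility(p_sv, "left", "scale_e_max", 0.5)
  expect_equal(p2$ventricles$left$e_max, p_sv$ventricles$left$e_max / 2)
  expect_equal(p2$ventricles$left$p_drive_cap,
               p_sv$ventricles$left$p_drive_cap / 2)
  # BVFS: the knob acts on the setpoint law
  p_fs <- unit_params("BVFS")
  p3 <- set_contractility(p_fs, "left", "scale_e_max", 0.5)
  expect_equal(p3$fs$slope_lv, p_fs$fs$slope_lv / 2)
  expect_equal(p3$fs$intercept_lv, p_fs$fs$intercept_lv / 2)
  p4 <- set_contractility(p_fs, "right", "fs_slope", 2.5)
  expect_equal(p4$fs$slope_rv, 2.5)
})

test_that("halving LV contractility in SV congests the left atrium", {
  base <- steady_preset("normal", "SV")
  p_weak <- set_contractility(set_configuration(mcl_preset("normal"), "SV"),
                              "left", "scale_e_max", 0.5)
  p_weak <- configure_ecmo(p_weak, enabled = FALSE)
  weak <- find_steady_state(p_weak, state = base$state)
  expect_gt(weak$summary$mean[["lap"]], base$summary$mean[["lap"]])
  expect_lt(weak$summary$mean[["maop"]], base$summary$mean[["maop"]])
})
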