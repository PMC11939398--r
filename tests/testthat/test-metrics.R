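test_that("beat segmentation aligns to period boundaries", {
  p <- unit_params("BV")
  sim <- mcl_simulate(p, duration = 10, record_every = 10)
  w <- segment_beats(sim)
  expect_length(w, 10L)
  sim2 <- mcl_simulate(p, duration = 10.5, record_every = 10)
  expect_length(segment_beats(sim2), 10L)     # partial beat discarded
  # boundaries at exact multiples of the period, no drift
  starts <- vapply(w, function(idx) sim[idx[1], "time_s"], 0)
  expect_equal(starts, 0:9, tolerance = 1e-6)
  short <- mcl_simulate(p, duration = 0.5, record_every = 10)
  expect_length(segment_beats(short), 0L)
})

test_that("beat metrics recover synthetic closed forms", {
  # constant and sinusoidal synthetic traces through the same machinery
  n <- 2001
  tt <- seq(0, 1, length.out = n)
  traj <- matrix(0, n, length(mcloop:::.traj_colnames),
                 dimnames = list(NULL, mcloop:::.traj_colnames))
  traj[, "time_s"] <- tt
  traj[, "p_la"] <- 12
  traj[, "p_ao"] <- 10 + 5 * sin(2 * pi * tt)
  traj[, "e_norm"] <- sin(pi * tt)^2
  p <- unit_params("BV")
  m <- beat_metrics(traj, p)
  expect_equal(m$lap, 12)
  expect_equal(m$maop, 10, tolerance = 1e-6)
  expect_false(m$aortic_valve_opened)
})

test_that("stroke volume matches the volume bookkeeping oracle", {
  st <- steady_preset("normal", "BVFS")
  tr <- st$trailing
  w <- segment_beats(tr)
  beat <- tr[w[[5]], ]
  m <- beat_metrics(beat, st$params)
  open <- which(beat[, "q_aortic"] > 0)
  dv <- beat[open[1], "v_lv"] - beat[max(open), "v_lv"]
  expect_lt(abs(m$lv_stroke_volume - dv) / dv, 0.005)
})

test_that("end-systolic pressure is read at outflow-valve closure", {
  st <- steady_preset("normal", "BVFS")
  tr <- st$trailing
  beat <- tr[segment_beats(tr)[[3]], ]
  m <- beat_metrics(beat, st$params)
  open <- which(beat[, "q_aortic"] > 0)
  expect_equal(m$lvesp, beat[max(open), "p_lv"])
})

test_that("steady summary aggregates fieldwise", {
  mk <- function(lap) {
    m <- list(maop = 60, lap = lap, rap = 5, mpap = 15, lvesp = 70,
              rvesp = 20, systemic_flow = 4, ecmo_flow = 0,
              lv_outflow = 4, lv_stroke_volume = 66, rv_stroke_volume = 66,
              aortic_valve_opened = TRUE)
    class(m) <- c("beat_metrics", "list")
    m
  }
  s <- steady_summary(list(mk(10), mk(12), mk(14)))
  expect_equal(s$mean[["lap"]], 12)
  expect_equal(s$sd[["maop"]], 0)
  expect_error(steady_summary(list(mk(1), mk(2))), "at least 3")
})

test_that("aortic node balances at steady state", {
  st <- steady_preset("normal", "BVFS")
  tr <- st$trailing
  inflow <- mean(tr[, "q_aortic"])
  p_fem_free <- (tr[, "p_ao"] + tr[, "p_svc"]) / 2
  q_ub <- mean((tr[, "p_ao"] - tr[, "p_svc"]) / st$params$vascular$r_upper_body)
  q_lb <- mean((tr[, "p_ao"] - p_fem_free) / (st$params$vascular$r_lower_body / 2))
  expect_lt(abs(inflow - q_ub - q_lb) / inflow, 0.01)
})

test_that("declared steady states are steady", {
  st <- steady_preset("normal", "BVFS")
  expect_lt(max(st$summary$sd[c("maop", "lap", "rap", "mpap")]), 0.5)
  expect_lt(st$summary$sd[["systemic_flow"]], 0.05)
})
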