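test_that("zero-duration simulation returns the initial sample only", {
  p <- unit_params("BV")
  sim <- mcl_simulate(p, duration = 0)
  expect_equal(nrow(sim), 1L)
  expect_equal(unname(sim[1, mcloop:::.state_names]),
               unname(p$initial_state))
})

test_that("RK4 agrees with a refined forward-Euler integration", {
  p <- unit_params("BV")
  rk4 <- mcl_simulate(p, duration = 10, dt = 2.5e-4, record_every = 40)
  eul <- mcl_simulate(p, duration = 10, dt = 1e-5, record_every = 1000,
                      method = "euler")
  cols <- mcloop:::.state_names[1:8]
  scale <- pmax(abs(rk4[, cols]), 1)
  rel <- abs(rk4[, cols] - eul[, cols]) / scale
  expect_lt(max(rel), 5e-3)
})

test_that("halving the step leaves beat-mean pressures unchanged", {
  p <- unit_params("BV")
  m1 <- find_steady_state(p, dt = 2.5e-4)$summary$mean
  m2 <- find_steady_state(p, dt = 1.25e-4)$summary$mean
  for (k in c("maop", "lap", "rap", "mpap"))
    expect_lt(abs(m1[[k]] - m2[[k]]), 0.05)
})

test_that("fluid volume is conserved over a minute of simulation", {
  p <- configure_ecmo(unit_params("BV"), enabled = TRUE, speed = 3200)
  sim <- mcl_simulate(p, duration = 60, record_every = 200)
  tot <- rowSums(sim[, mcloop:::.state_names[1:8]])
  expect_lt(max(abs(tot - tot[1])), 0.01)
})

test_that("valve flows are never negative in a simulated trajectory", {
  p <- unit_params("BVFS")
  sim <- mcl_simulate(p, duration = 5)
  for (col in c("q_mitral", "q_aortic", "q_tricuspid", "q_pulmonary"))
    expect_gte(min(sim[, col]), 0)
})

test_that("SV and BV configurations coincide when coupling is zeroed", {
  p_bv <- unit_params("BV")
  p_bv$coupling$alpha_rl <- 0
  p_bv$coupling$alpha_lr <- 0
  p_sv <- set_configuration(p_bv, "SV")
  s_bv <- mcl_simulate(p_bv, duration = 3)
  s_sv <- mcl_simulate(p_sv, duration = 3)
  expect_identical(unclass(s_bv)[, ], unclass(s_sv)[, ])
})

test_that("a disabled ECMO branch is inert", {
  p_off <- configure_ecmo(unit_params("BV"), enabled = FALSE)
  s <- p_off$initial_state
  s[["q_ecmo"]] <- 55  # stale branch flow must be zeroed, not integrated
  sim <- mcl_simulate(p_off, state = s, duration = 2)
  expect_true(all(sim[, "q_ecmo"] == 0))
})

test_that("events mutate parameters at step boundaries", {
  p <- unit_params("BV")
  sim <- mcl_simulate(p, duration = 4, record_every = 4,
                      events = list(list(time = 2,
                                         set = list("vascular.clamp_factor" = 1000))))
  tt <- sim[, "time_s"]
  pre <- tt < 1.95; post <- tt > 3.5
  expect_gt(mean(sim[pre, "q_systemic"]), 10)
  expect_lt(mean(sim[post, "q_systemic"]), 2)
})

test_that("instability and flooding raise named errors", {
  p <- unit_params("SV")
  s <- p$initial_state
  s[["water_svc"]] <- p$chambers$svc$water_volume_ref +
    p$chambers$svc$air_volume_ref - 0.5
  expect_error(mcl_simulate(p, state = s, duration = 1), "flooded")
  expect_error(circuit_rhs(0, replace(p$initial_state, 1, NaN), p),
               "non-finite")
})

test_that("steady-state search reports convergence honestly", {
  p <- mcl_preset("normal")  # ships at its converged operating point
  st <- find_steady_state(p)
  expect_true(st$converged)
  expect_lte(st$n_beats, 15)
  st1 <- find_steady_state(p, max_beats = 10)
  expect_equal(st1$n_beats, 10)
  # steady flow continuity: beat-mean mitral inflow equals aortic outflow
  tr <- st$trailing
  q_in <- mean(tr[, "q_mitral"])
  q_out <- mean(tr[, "q_aortic"])
  expect_lt(abs(q_in - q_out) / q_out, 0.01)
})
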