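test_that("chamber pressure follows the isothermal gas law", {
  ch <- list(air_volume_ref = 1500, pressure_abs_ref = 760,
             water_volume_ref = 1000, water_volume = 1000)
  expect_equal(chamber_pressure(ch), 0)

  ch$water_volume <- 1100  # +100 mL of water compresses the air column
  expect_equal(chamber_pressure(ch), 760 * 1500 / 1400 - 760)

  # monotone in water volume
  fills <- seq(900, 1400, by = 50)
  p <- vapply(fills, function(w) {
    ch$water_volume <- w; chamber_pressure(ch)
  }, 0)
  expect_true(all(diff(p) > 0))

  # flooding the chamber is an error
  ch$water_volume <- 1000 + 1500
  expect_error(chamber_pressure(ch), "flooded")
})

test_that("small-signal chamber compliance matches the finite-difference oracle", {
  ch <- list(air_volume_ref = 1500, pressure_abs_ref = 760,
             water_volume_ref = 1000, water_volume = 1000)
  p_at <- function(w) { ch$water_volume <- w; chamber_pressure(ch) }
  dP <- (p_at(1001) - p_at(999)) / 2
  compliance_fd <- 1 / dP
  expect_equal(compliance_fd, ch$air_volume_ref / ch$pressure_abs_ref,
               tolerance = 1e-3)
})

test_that("valve flow is an ideal diode", {
  expect_equal(valve_flow(0, 5, 0.05), 0)            # closed
  expect_equal(valve_flow(10, 0, 0.05), 200)         # linear open
  # continuity at closure
  expect_equal(valve_flow(1e-12, 0, 0.05), 2e-11)
  expect_equal(valve_flow(0, 1e-12, 0.05), 0)
  expect_true(all(valve_flow(rnorm(50), rnorm(50), 0.03) >= 0))
})

test_that("ventricular pressures obey the coupled elastance law", {
  p <- mcl_params("BV")
  # SV configuration: free-wall law exactly
  p_sv <- set_configuration(p, "SV")
  s <- p$initial_state
  t <- 0.12
  vp <- ventricular_pressures(s, t, p_sv)
  period <- 60 / p$heart_rate
  en <- normalized_elastance(t, period, p$waveform)
  vl <- p$ventricles$left
  act <- min((vl$e_max - vl$e_min) * (s[["v_lv"]] - vl$v0), vl$p_drive_cap)
  expect_equal(unname(vp[["p_lv"]]),
               vl$e_min * (s[["v_lv"]] - vl$v0) + en * act)

  # additive cross-talk in the linear range: alpha_rl = 0.2,
  # p_rv_free = 10 raises p_lv by exactly 2 mmHg
  q <- p
  q$coupling$alpha_rl <- 0.2; q$coupling$alpha_lr <- 0
  base <- ventricular_pressures(s, t, p_sv)
  # choose an RV volume so the free-wall RV pressure is 10 mmHg
  vr <- q$ventricles$right
  e_rv <- vr$e_min + (vr$e_max - vr$e_min) * en
  s2 <- s; s2[["v_rv"]] <- vr$v0 + 10 / e_rv
  out <- ventricular_pressures(s2, t, q)
  free <- ventricular_pressures(s2, t, set_configuration(q, "SV"))
  expect_equal(unname(out[["p_lv"]] - free[["p_lv"]]), 0.2 * 10,
               tolerance = 1e-10)

  # raising RV volume strictly increases p_lv when alpha_rl > 0 (within
  # the linear transmission range)
  lv_at <- function(v_rv) {
    s3 <- s; s3[["v_rv"]] <- v_rv
    ventricular_pressures(s3, t, q)[["p_lv"]]
  }
  vols <- seq(20, 60, by = 10)
  expect_true(all(diff(vapply(vols, lv_at, 0)) > 0))
})

test_that("R and C++ right-hand sides agree to machine precision", {
  for (cfg in c("SV", "BV", "BVFS")) {
    p <- unit_params(cfg)
    p <- configure_ecmo(p, enabled = (cfg != "SV"), speed = 3000)
    pv <- mcloop:::.pack_params(p)
    for (seed in 1:5) {
      s <- random_state(p, seed)
      t <- runif(1, 0, 2)
      rr <- circuit_rhs(t, s, p)
      cc <- mcloop:::.mcl_core_rhs(pv, t, unname(s))
      expect_equal(unname(rr$dstate), cc$dy, tolerance = 1e-12)
    }
  }
})

test_that("volume derivatives sum to zero for random states", {
  p <- configure_ecmo(unit_params("BV"), enabled = TRUE, speed = 2600,
                      return_site = "retrograde_femoral")
  sums <- vapply(1:200, function(i) {
    s <- random_state(p, i)
    sum(circuit_rhs(runif(1, 0, 1), s, p)$dstate[1:8])
  }, 0)
  expect_lt(max(abs(sums)), 1e-9)
  p2 <- configure_ecmo(p, return_site = "antegrade_aorta")
  sums2 <- vapply(1:200, function(i) {
    s <- random_state(p2, i + 500)
    sum(circuit_rhs(runif(1, 0, 1), s, p2)$dstate[1:8])
  }, 0)
  expect_lt(max(abs(sums2)), 1e-9)
})

test_that("equilibrium states have zero derivatives", {
  # all node pressures equal and ventricles clamped at matching volumes:
  # no gradients, no flow
  p <- unit_params("SV")
  p$ventricles$left$e_max <- p$ventricles$left$e_min * 1.0001
  p$ventricles$right$e_max <- p$ventricles$right$e_min * 1.0001
  target <- 10  # mmHg everywhere
  s <- p$initial_state
  s[["v_lv"]] <- p$ventricles$left$v0 + target / p$ventricles$left$e_min
  s[["v_rv"]] <- p$ventricles$right$v0 + target / p$ventricles$right$e_min
  s[["v_la"]] <- p$vascular$v0_la + target * p$vascular$c_la
  s[["v_ra"]] <- p$vascular$v0_ra + target * p$vascular$c_ra
  w_for <- function(ch) {
    # invert the gas law for the water volume giving the target gauge
    ch$water_volume_ref + ch$air_volume_ref *
      (1 - ch$pressure_abs_ref / (target + 760))
  }
  s[["water_aoc"]] <- w_for(p$chambers$aoc)
  s[["water_svc"]] <- w_for(p$chambers$svc)
  s[["water_pac"]] <- w_for(p$chambers$pac)
  s[["water_pvc"]] <- w_for(p$chambers$pvc)
  s[["q_ecmo"]] <- 0
  d <- circuit_rhs(0, s, p)$dstate
  # elastance at e_min ~ e_max: pressures stay at target all cycle
  expect_lt(max(abs(d)), 1e-6)
})

test_that("an isolated chamber pair discharges like a two-compartment RC", {
  # isolate the pulmonary-venous chamber and the left atrium by making all
  # other connections effectively impermeable, then perturb by 1 mL: the
  # linearized two-compartment exponential is the oracle
  p <- unit_params("SV")
  p$valves$mitral <- 1e9; p$valves$aortic <- 1e9
  p$valves$tricuspid <- 1e9; p$valves$pulmonary <- 1e9
  p$vascular$r_pulmonary <- 1e9
  r <- 0.5
  p$vascular$r_pulm_venous <- r
  # both nodes at 10 mmHg, then move 1 mL from LA to PVC
  ch <- p$chambers$pvc
  w10 <- ch$water_volume_ref + ch$air_volume_ref * (1 - 760 / 770)
  s <- p$initial_state
  s[["water_pvc"]] <- w10 + 1
  s[["v_la"]] <- p$vascular$v0_la + 10 * p$vascular$c_la - 1
  sim <- mcl_simulate(p, state = s, duration = 2, dt = 5e-4)
  c_la <- p$vascular$c_la
  # chamber compliance linearized at 10 mmHg gauge
  air <- ch$air_volume_ref * 760 / 770
  c_ch <- air^2 / (760 * ch$air_volume_ref)
  tau <- r * (c_la * c_ch) / (c_la + c_ch)
  dp0 <- sim[1, "p_pvc"] - sim[1, "p_la"]
  tt <- sim[, "time_s"]
  predicted <- dp0 * exp(-tt / tau)
  observed <- sim[, "p_pvc"] - sim[, "p_la"]
  expect_equal(observed, predicted, tolerance = 5e-3)
})
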