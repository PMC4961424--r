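af <- remodeling_preset("af_remodeled")
base <- remodeling_preset("baseline")

test_that("remodeling presets carry the AF conductance multipliers", {
  expect_equal(as.numeric(af), c(0.2, 0.5, 0.6, 1.5))
  expect_equal(as.numeric(base), c(1, 1, 1, 1))
  expect_error(remodeling_params(scale_Ito = 0), "positive")
  expect_error(remodeling_params(scale_IK1 = -1), "positive")
})

test_that("resting state is a stable equilibrium and is deterministic", {
  for (rem in list(base, af)) {
    rest <- resting_state(rem)
    # integrate 5 s with no stimulus: V must drift < 0.5 mV
    out <- afsim:::cpp_crn_pace(as.numeric(rest), as.numeric(rem),
                                cl = 1e6, n_beats = 0, amp = 0, dur = 0,
                                duration = 5000, dt_max = 0.05,
                                sample_dt = 100)
    expect_lt(max(abs(out$V - rest[["V"]])), 0.5)
    gates <- as.numeric(rest)[2:16]
    expect_true(all(gates >= 0 & gates <= 1))
    expect_true(all(as.numeric(rest)[17:21] > 0))
  }
  expect_identical(resting_state(af), resting_state(af))
})

test_that("baseline resting potential matches the reference integration", {
  skip_if_not_installed("deSolve")
  parms <- list(s_to = 1, s_kur = 1, s_cal = 1, s_k1 = 1,
                stim_fun = function(t) 0)
  out <- deSolve::lsoda(ref_initial_state(), seq(0, 10000, by = 500),
                        ref_rhs, parms, rtol = 1e-8, atol = 1e-8,
                        maxsteps = 50000)
  expect_lt(abs(resting_state(base)[["V"]] - out[nrow(out), "V"]), 2)
})

test_that("ionic currents match direct evaluation of the published formulas", {
  probe <- resting_state(base)
  probe[["V"]] <- -30  # partially depolarized probe point
  probe[["d"]] <- 0.5; probe[["f"]] <- 0.7; probe[["oa"]] <- 0.3
  cur <- ionic_current(probe, base)$currents
  FRT <- 96.4867 / (8.3143 * 310)
  ek <- log(5.4 / probe[["Ki"]]) / FRT
  ena <- log(140 / probe[["Nai"]]) / FRT
  ik1_ref <- 0.09 * (probe[["V"]] - ek) / (1 + exp(0.07 * (probe[["V"]] + 80)))
  ina_ref <- 7.8 * probe[["m"]]^3 * probe[["h"]] * probe[["j"]] *
    (probe[["V"]] - ena)
  ito_ref <- 0.1652 * probe[["oa"]]^3 * probe[["oi"]] * (probe[["V"]] - ek)
  ical_ref <- 0.12375 * probe[["d"]] * probe[["f"]] * probe[["fca"]] *
    (probe[["V"]] - 65)
  expect_equal(cur[["IK1"]], ik1_ref, tolerance = 1e-6)
  expect_equal(cur[["INa"]], ina_ref, tolerance = 1e-6)
  expect_equal(cur[["Ito"]], ito_ref, tolerance = 1e-6)
  expect_equal(cur[["ICaL"]], ical_ref, tolerance = 1e-6)
})

test_that("remodeling scales currents exactly multiplicatively", {
  probe <- resting_state(base)
  probe[["V"]] <- -20
  id <- ionic_current(probe, base)$currents
  sc <- ionic_current(probe, af)$currents
  expect_equal(sc[["Ito"]], 0.2 * id[["Ito"]])
  expect_equal(sc[["IKur"]], 0.5 * id[["IKur"]])
  expect_equal(sc[["ICaL"]], 0.6 * id[["ICaL"]])
  expect_equal(sc[["IK1"]], 1.5 * id[["IK1"]])
  expect_equal(sc[["IKr"]], id[["IKr"]])     # unscaled currents untouched
  expect_equal(sc[["INaK"]], id[["INaK"]])
  zero_to <- ionic_current(probe, remodeling_params(1e-12, 1, 1, 1))$currents
  expect_equal(zero_to[["Ito"]], 0, tolerance = 1e-10)
})

test_that("step_cell honours its contracts", {
  rest <- resting_state(af)
  stepped <- step_cell(rest, af, i_stim = 0, dt = 0.05)
  expect_lt(abs(stepped[["V"]] - rest[["V"]]), 1e-3)
  expect_error(step_cell(rest, af, dt = 0.001), "0.005")
  expect_error(step_cell(rest, af, dt = 0.1), "0.05")
  bad <- rest; bad[["m"]] <- 1.5
  expect_error(step_cell(bad, af), "gating")
  # a suprathreshold 2-ms stimulus fires within 5 ms
  st <- rest
  for (k in 1:100) {  # 5 ms at dt = 0.05
    st <- step_cell(st, af, i_stim = if (k <= 40) 40 else 0, dt = 0.05)
    expect_true(all(as.numeric(st)[2:16] >= 0 & as.numeric(st)[2:16] <= 1))
  }
  expect_gt(st[["V"]], 0)
})

test_that("paced action potential matches the reference integration", {
  skip_if_not_installed("deSolve")
  amp <- 2 * stim_threshold(base)
  ref <- ref_pace(c(1, 1, 1, 1), cl = 1000, n_beats = 1, amp = amp,
                  y0 = setNames(as.numeric(resting_state(base)),
                                names(ref_initial_state())))
  tr <- pace_cell(base, 1000, 1, stim_amplitude = amp)
  expect_lt(abs(max(tr$V) - max(ref$V)), 2)            # peak V
  expect_lt(abs(tr$V[1] - ref$V[1]), 2)                # resting V
  expect_lt(abs(measure_apd90(tr) - measure_apd90(ref)), 5)
})

test_that("APD90 self-converges across the admissible step range", {
  rest <- resting_state(af)
  tr <- lapply(c(0.05, 0.005), function(dtm) {
    out <- afsim:::cpp_crn_pace(as.numeric(rest), as.numeric(af), cl = 1000,
                                n_beats = 1, amp = 25, dur = 2,
                                duration = 1000, dt_max = dtm, sample_dt = 1)
    measure_apd90(out)
  })
  expect_lt(abs(tr[[1]] - tr[[2]]), 1)
})

test_that("halving the step changes V by less than 0.01 mV over 1 ms", {
  rest <- resting_state(af)
  v_at <- function(dt) {
    st <- rest
    for (k in seq_len(round(1 / dt))) st <- step_cell(st, af, 0, dt)
    st[["V"]]
  }
  expect_lt(abs(v_at(0.05) - v_at(0.025)), 0.01)
})

test_that("pace_cell reports capture per beat", {
  tr <- pace_cell(af, 500, 2)
  expect_length(tr$captured, 2)
  expect_true(all(tr$captured))
  sub <- pace_cell(af, 500, 1, stim_amplitude = 1)  # subthreshold
  expect_false(any(sub$captured))
  expect_error(measure_apd90(sub), "undefined|action potential")
})

test_that("APD90 measurement is exact on a synthetic triangle pulse", {
  # baseline -80 mV, instant rise to +40 at t = 10, linear fall back to
  # -80 over 300 ms: the 90% level (-68 mV) is reached 270 ms after the rise
  t <- 0:400
  v <- ifelse(t < 10, -80, pmax(40 - 120 * (t - 10) / 300, -80))
  expect_equal(measure_apd90(list(t = t, V = v)), 270, tolerance = 0.02)
  expect_error(measure_apd90(list(t = t, V = rep(-81, length(t)))),
               "no action potential")
})

test_that("paced traces are deterministic", {
  t1 <- pace_cell(af, 500, 3)
  t2 <- pace_cell(af, 500, 3)
  expect_identical(t1$V, t2$V)
})

test_that("AP trace exports as a two-column CSV", {
  tr <- pace_cell(af, 1000, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ap_trace(tr, f)
  df <- read.csv(f)
  expect_named(df, c("time_ms", "V_mV"))
  expect_equal(nrow(df), length(tr$t))
})
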