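af <- remodeling_preset("af_remodeled")

test_that("diffusion operator annihilates constants and linear fields", {
  m <- make_sheet(41, 41, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.1))
  n <- nrow(m$vertices)
  expect_lt(max(abs(apply_diffusion(op, rep(7.3, n)))), 1e-10)
  x <- m$vertices[, 1]; y <- m$vertices[, 2]
  interior <- x > 2 & x < 18 & y > 2 & y < 18
  lin <- apply_diffusion(op, 2 * x - 3 * y)
  expect_lt(max(abs(lin[interior])), 1e-3 * max(abs(lin)))
  quad <- apply_diffusion(op, x^2) / 0.1
  expect_true(all(abs(quad[interior] - 2) < 0.1))   # within 5%
})

test_that("zero-flux diffusion conserves the area-weighted mean of V", {
  m <- make_sheet(21, 15, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.15))
  st <- tissue_state(op, af)
  # impose a sharp voltage blob, reaction off
  st$states[1, ] <- -80 + 60 * exp(-rowSums(
    sweep(m$vertices, 2, c(5, 3.5, 0))^2))
  total0 <- sum(m$area * st$states[1, ])
  rec <- run_simulation(op, af, duration = 50, state = st, reaction = FALSE,
                        record_interval = 5)
  fin <- attr(rec, "final_state")
  expect_equal(sum(m$area * fin$states[1, ]), total0, tolerance = 1e-6)
  # and the blob actually spread
  expect_lt(max(fin$states[1, ]), max(st$states[1, ]) - 1)
})

test_that("with D = 0 every node evolves exactly as an isolated cell", {
  m <- make_sheet(4, 3, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0))
  st <- tissue_state(op, af)
  stim <- list(stimulus_event(seq_len(nrow(m$vertices)), 0, 2, 30))
  rec <- run_simulation(op, af, duration = 300, state = st, stimuli = stim,
                        record_interval = 1)
  single <- afsim:::cpp_crn_pace(as.numeric(resting_state(af)),
                                 as.numeric(af), cl = 1000, n_beats = 1,
                                 amp = 30, dur = 2, duration = 300,
                                 dt_max = 0.05, sample_dt = 1)
  for (node in c(1, 7, 12))
    expect_equal(rec$V[node, ], single$V, tolerance = 1e-9)
})

test_that("uniform resting tissue stays at rest", {
  m <- make_sheet(6, 6, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.15))
  rec <- run_simulation(op, af, duration = 100, record_interval = 10)
  expect_lt(max(abs(rec$V - rec$V[1, 1])), 0.05)
  expect_equal(nrow(rec$events), 0)
})

test_that("a point stimulus produces radially expanding activation", {
  m <- make_sheet(31, 31, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.15))
  ctr <- which.min(rowSums(sweep(m$vertices, 2, c(7.5, 7.5, 0))^2))
  d2c <- sqrt(rowSums(sweep(m$vertices, 2, m$vertices[ctr, ])^2))
  patch <- which(d2c <= 1)
  rec <- run_simulation(op, af, duration = 80,
                        stimuli = list(stimulus_event(patch, 0, 2, 60)),
                        record_interval = 5)
  ev <- rec$events[!duplicated(rec$events$node), ]
  expect_gt(nrow(ev), 500)  # most of the sheet activates
  ct <- cor(d2c[ev$node], ev$time_ms, method = "spearman")
  expect_gt(ct, 0.95)       # activation time increases with distance
})

test_that("checkpoint/resume reproduces an uninterrupted run exactly", {
  m <- make_sheet(21, 11, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.15))
  stim <- list(stimulus_event(which(m$vertices[, 1] <= 1), 0, 2, 60))
  full <- run_simulation(op, af, duration = 60, stimuli = stim,
                         record_interval = 10)
  half1 <- run_simulation(op, af, duration = 30, stimuli = stim,
                          record_interval = 10)
  half2 <- run_simulation(op, af, duration = 30,
                          state = attr(half1, "final_state"),
                          record_interval = 10)
  vfull <- attr(full, "final_state")$states
  vres <- attr(half2, "final_state")$states
  expect_lt(max(abs(vfull - vres)), 1e-9)
})

test_that("recording windows honour the fencepost contract", {
  m <- make_sheet(5, 4, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.1))
  rec <- run_simulation(op, af, duration = 10, record_interval = 1)
  expect_length(rec$t, 11)
  expect_equal(rec$t, 0:10)
})

test_that("conduction velocity measurement and probes behave", {
  cv <- strip_cv_cached(default_diffusion())
  expect_lt(abs(cv - 0.4) / 0.4, 0.05)
  expect_error(measure_cv(list(events = data.frame(node = 1,
                                                   time_ms = 1)),
                          make_sheet(3, 3, 1), c(2, 2)), "co-located")
})

test_that("blow-up is reported with time and node", {
  m <- make_sheet(4, 4, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.1))
  st <- tissue_state(op, af)
  st$states[1, 1] <- 280  # absurd potential, still under the hard guard
  expect_error(run_simulation(op, af, duration = 5, state = st),
               "blow-up")
})
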