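la <- partition_regions(make_synthetic_la())

test_that("straight pacing reproduces the canonical ramp arithmetic", {
  p <- straight_pacing(la)
  expect_equal(p$total_ms, 4560)                       # 8 x (200+190+180)
  expect_equal(length(p$events), 24)                   # 3 CLs x 8 beats
  p1 <- straight_pacing(la, beats_per_cl = 1)
  expect_equal(p1$total_ms, 570)
  expect_equal(length(p1$events), 3)
  # patch is centered on the septum; with an 8-mm radius it may spill a
  # little into adjacent sections
  expect_gt(mean(la$region[p$site] == 1), 0.3)
  expect_error(straight_pacing(make_sheet(3, 3, 1)), "label")
})

# hand-built recordings exercise the classifier without simulation
mk_rec <- function(events, n_nodes, t0, t1, V = NULL, tt = NULL,
                   conduct = NULL) {
  structure(list(t = tt %||% numeric(0),
                 V = V %||% matrix(0, n_nodes, 0),
                 events = events, t0 = t0, t1 = t1, record_interval = 1,
                 n_nodes = n_nodes,
                 conduct = conduct %||% rep(TRUE, n_nodes)),
            class = "ap_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("activity detection counts active conducting nodes", {
  ev <- data.frame(node = c(1, 2, 2, 5), time_ms = c(100, 150, 400, 900))
  rec <- mk_rec(ev, 10, 0, 1000)
  expect_equal(detect_activity(rec, c(0, 1000)), 0.3)
  expect_equal(detect_activity(rec, c(500, 1000)), 0.1)
  expect_equal(detect_activity(rec, c(950, 1000)), 0)
  expect_error(detect_activity(rec, c(500, 500)), "empty")
})

test_that("silence classifies as QUIESCENT", {
  rec <- mk_rec(data.frame(node = 1, time_ms = 10), nrow(la$vertices),
                0, 3000)
  lab <- classify_rhythm(rec, c(0, 3000), la)
  expect_equal(lab$label, "QUIESCENT")
  expect_equal(lab$active_fraction, 0)
})

test_that("regular concordant activation classifies as AT, irregular as AF", {
  n <- nrow(la$vertices)
  # every node activates with period 250 ms (4 Hz), phase-shifted slightly
  t <- seq(0, 4000 - 1, by = 1)
  times <- as.vector(outer(seq(5, 3995, by = 250), runif(n, 0, 10), `+`))
  ev <- data.frame(node = rep(seq_len(n), each = 16), time_ms = times)
  V <- matrix(60 * sin(2 * pi * 4 * t / 1000), n, length(t), byrow = TRUE)
  rec <- mk_rec(ev, n, 0, 4000, V = V, tt = t)
  expect_equal(classify_rhythm(rec, c(0, 4000), la)$label, "AT")
  # jittered irregular intervals and discordant DFs -> AF
  set.seed(2)
  times2 <- sort(runif(16 * n, 0, 4000))
  ev2 <- data.frame(node = sample(seq_len(n), 16 * n, TRUE),
                    time_ms = times2)
  freqs <- sample(c(3, 5, 7, 9), n, TRUE)
  V2 <- 60 * sin(2 * pi * outer(freqs, t / 1000))
  rec2 <- mk_rec(ev2, n, 0, 4000, V = V2, tt = t)
  expect_equal(classify_rhythm(rec2, c(0, 4000), la)$label, "AF")
})

test_that("classification is deterministic per seed and windows validate", {
  n <- nrow(la$vertices)
  ev <- data.frame(node = rep(1:n, 3),
                   time_ms = runif(3 * n, 0, 4000))
  rec <- mk_rec(ev, n, 0, 4000)
  l1 <- classify_rhythm(rec, c(0, 4000), la, seed = 7)
  l2 <- classify_rhythm(rec, c(0, 4000), la, seed = 7)
  expect_identical(l1$probes, l2$probes)
  expect_error(classify_rhythm(rec, c(0, 1500), la), "2 s")
})

test_that("planar pacing on a sheet classifies as AT with matching DF", {
  m <- make_sheet(21, 9, 0.5)
  op <- build_diffusion_operator(m, diffusion_field(0.15))
  af <- remodeling_preset("af_remodeled")
  left <- which(m$vertices[, 1] <= 1)
  stim <- lapply(0:11, function(b) stimulus_event(left, b * 250, 2, 60))
  rec <- run_simulation(op, af, duration = 3200, stimuli = stim,
                        record_interval = 1)
  expect_equal(detect_activity(rec, c(500, 3000)), 1)  # full capture
  lab <- classify_rhythm(rec, c(1000, 3100), m)
  expect_equal(lab$label, "AT")
  expect_equal(lab$mean_cl_ms, 250, tolerance = 0.01)
  # pacing-DF identity: captured tissue shows DF = 1000/CL
  dm <- compute_df_map(rec, c(1100, 3100))
  expect_true(all(abs(dm$df - 4) < dm$resolution + 1e-9))
})

test_that("induction on a sub-wavelength sheet fails (no reentry possible)", {
  m <- make_sheet(9, 5, 0.5)   # 4 x 2 mm patch
  # region labels so straight_pacing finds a site
  m$region <- rep(1L, nrow(m$vertices))
  op <- build_diffusion_operator(m, diffusion_field(0.15))
  p <- straight_pacing(m, beats_per_cl = 2)
  ep <- induce_af(op, remodeling_preset("af_remodeled"), p,
                  follow_ms = 3000)
  expect_false(ep$induced)
  expect_false(is.na(ep$self_termination_ms))
})
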