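test_that("analysis windows are equal-length and non-overlapping", {
  w <- analysis_windows()
  expect_equal(nrow(w), 9)
  expect_equal(rownames(w), paste0("T", 1:9))
  expect_true(all(w[, 2] - w[, 1] == 6000))
  expect_true(all(diff(w[, 1]) == 30000))
  expect_true(all(w[-1, 1] >= w[-9, 2]))
  expect_error(analysis_windows(3, 5000, 4000))  # overlap
})

test_that("periodogram puts a pure tone in its exact bin", {
  fs <- 1000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  ps <- power_spectrum(sin(2 * pi * 5 * t), fs)
  expect_equal(ps$freq[2] - ps$freq[1], 1 / 6)   # 1/duration resolution
  expect_equal(ps$freq[which.max(ps$power)], 5)
  # constant signal: all-zero power after mean removal
  psc <- power_spectrum(rep(3, length(t)), fs)
  expect_lt(max(psc$power), 1e-20)
  # dominant amplitude wins: 4 Hz (amp 2) + 7 Hz (amp 1)
  ps2 <- power_spectrum(2 * sin(2 * pi * 4 * t) + sin(2 * pi * 7 * t), fs)
  expect_equal(ps2$freq[which.max(ps2$power)], 4)
})

test_that("dominant frequency matches analytic signals and handles silence", {
  fs <- 1000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  expect_equal(dominant_frequency(80 * sin(2 * pi * 5 * t), fs), 5)
  # 200-ms-period pulse train -> 5 Hz fundamental
  pulse <- ifelse((t * 1000) %% 200 < 10, 30, -80)
  expect_equal(dominant_frequency(pulse, fs), 5)
  expect_true(is.na(dominant_frequency(rep(-81, length(t)), fs)))
  expect_error(dominant_frequency(sin(t), 30, band = c(1, 20)), "Nyquist")
})

test_that("dominant frequency equals brute-force periodogram argmax", {
  # 100 random band-interior multi-tone signals
  set.seed(42)
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  for (k in 1:100) {
    nf <- sample(2:5, 1)
    fr <- round(runif(nf, 1.5, 18) * 4) / 4   # on the 0.25-Hz grid
    am <- runif(nf, 0.5, 3)
    am[sample(nf, 1)] <- 5                     # unambiguous dominant tone
    v <- colSums(am * sin(outer(2 * pi * fr, t)))
    # brute force: full unrestricted periodogram argmax
    x <- (v - mean(v)) * 0.5 * (1 - cos(2 * pi * seq_along(v) / (length(v) + 1)))
    sp <- abs(fft(x))^2
    grid <- (seq_along(v) - 1) * fs / length(v)
    brute <- grid[which.max(sp[grid <= fs / 2])]
    expect_equal(dominant_frequency(v, fs), brute)
  }
})

# a tiny synthetic "recording" with controllable per-node signals
fake_recording <- function(V, dt = 1, t0 = 0, conduct = NULL) {
  structure(list(t = t0 + (seq_len(ncol(V)) - 1) * dt, V = V,
                 events = data.frame(node = integer(0), time_ms = numeric(0)),
                 t0 = t0, t1 = t0 + ncol(V) * dt, record_interval = dt,
                 n_nodes = nrow(V),
                 conduct = conduct %||% rep(TRUE, nrow(V))),
            class = "ap_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("DF maps are computed per node with sentinels for silence", {
  t <- seq(0, 4 - 1e-3, by = 1e-3)
  V <- rbind(60 * sin(2 * pi * 4 * t),
             60 * sin(2 * pi * 6 * t),
             rep(-80, length(t)))
  rec <- fake_recording(V)
  dm <- compute_df_map(rec, c(0, 4000))
  expect_equal(dm$df[1:2], c(4, 6))
  expect_true(is.na(dm$df[3]))
  expect_equal(dm$resolution, 1 / 4)
  expect_error(compute_df_map(rec, c(10000, 16000)), "not covered")
  # stationary signal: two disjoint sub-windows give identical maps
  dm1 <- compute_df_map(rec, c(0, 2000))
  dm2 <- compute_df_map(rec, c(2000, 4000))
  expect_equal(dm1$df, dm2$df)
})

test_that("high-DF mask selects exactly the target area", {
  fake_map <- function(df) structure(
    list(df = df, window = c(0, 1), resolution = 0.5), class = "df_map")
  # clean separation: ten 8-Hz nodes among ninety 5-Hz nodes, equal areas
  df <- c(rep(8, 10), rep(5, 90))
  mask <- high_df_mask(fake_map(df), rep(1, 100), 0.10)
  expect_equal(which(mask), 1:10)
  # uniform map: lowest-index nodes win (documented tie-break)
  mu <- high_df_mask(fake_map(rep(3, 100)), rep(1, 100), 0.10)
  expect_equal(which(mu), 1:10)
  # area control within one node-area granule
  set.seed(7)
  for (k in 1:20) {
    n <- 200
    areas <- runif(n, 0.5, 2)
    df <- runif(n, 2, 9)
    fr <- sample(c(0.1, 0.15, 0.2), 1)
    m <- high_df_mask(fake_map(df), areas, fr)
    sel <- sum(areas[m])
    expect_lte(abs(sel - fr * sum(areas)), max(areas) + 1e-9)
    # nesting: smaller fraction is a subset of a larger one
    m2 <- high_df_mask(fake_map(df), areas, min(fr + 0.05, 0.9))
    expect_true(all(which(m) %in% which(m2)))
  }
  expect_error(high_df_mask(fake_map(rep(NA_real_, 5)), rep(1, 5), 0.1),
               "silent")
})

test_that("regional proportions are exact area ratios", {
  la <- partition_regions(make_synthetic_la())
  mask <- la$region == 6            # mask entirely inside R6
  rp <- regional_proportions(mask, la)
  expect_equal(unname(rp["R6"]), 100)
  expect_true(all(rp[setdiff(names(rp), "R6")] == 0))
  expect_true(all(regional_proportions(rep(TRUE, nrow(la$vertices)), la) ==
                    100))
  # identity: sum(prop * region_area)/100 == masked area
  set.seed(3)
  rmask <- runif(nrow(la$vertices)) < 0.2
  rp2 <- regional_proportions(rmask, la)
  ra <- mesh_region_areas(la)$by_region
  expect_equal(sum(rp2 * ra) / 100, sum(la$area[rmask]), tolerance = 1e-9)
})
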