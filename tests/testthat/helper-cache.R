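# Heavy simulation artifacts shared across test files (test_dir runs all
# files in one session, so this cache deduplicates expensive runs).

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# memoised strip CV (shared by calibration and scaling tests)
strip_cv_cached <- function(D, resolution = 0.25) {
  cached(paste0("cv_", D, "_", resolution),
         strip_cv(D, resolution)$cv)
}

# the desk-scale study, run once
study_report_cached <- function() {
  cached("study", {
    cfg <- study_config(n_geometries = 3, geometry_seeds = c(1, 5, 13),
                        n_windows = 3, window_length_ms = 2000,
                        window_every_ms = 3500,
                        first_window_offset_ms = 800,
                        follow_ms = 3500, seed = 1)
    run_study(cfg, keep_geometries = TRUE)
  })
}
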