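# Shared fixtures: small synthetic scenes, built once per test session.
# All fixtures are generated in code; nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small, fast scene configuration; kinetics follow the package defaults
small_config <- function(..., seed = 42L) {
  scene_config(frame_height = 100L, frame_width = 200L, fps = 2, duration = 45,
               seed = seed, ...)
}

# noiseless, motion-free small scene (exact pipeline checks)
clean_scene <- function() {
  cached("clean_scene",
         render_scene(small_config(noise_sd = 0, motion_amplitude = 0)))
}

# same scene with default noise and motion
noisy_scene <- function() {
  cached("noisy_scene", render_scene(small_config()))
}

clean_features <- function() {
  cached("clean_features",
         normalize_features(featurize_grid(build_grid_series(clean_scene()))))
}

# well-separated, noise-free zone kinetics: each zone has fixed, clearly
# distinct parameters, so classes are (nearly) linearly separable
separable_zone_params <- function() {
  list(
    good   = list(A = 150, t0 = 7,  tp = 15, alpha = 2.5, baseline = 5),
    expert = list(A = 90,  t0 = 10, tp = 20, alpha = 2.5, baseline = 5),
    poor   = list(A = 10,  t0 = 24, tp = 32, alpha = 1.6, baseline = 5)
  )
}

separable_configs <- function(n, seed = 7L, n_poor = 0) {
  sample_scene_configs(n, seed = seed, n_poor = n_poor,
                       frame_height = 100L, frame_width = 200L,
                       fps = 2, duration = 45,
                       zone_params = separable_zone_params(),
                       noise_sd = 0, motion_amplitude = 0)
}

# a hand-built features grid with known values, for line-sampling tests
constant_features <- function(nr = 20, nc = 40, value = 0.5, cell_px = 5L) {
  m <- matrix(value, nr, nc)
  structure(list(
    i_max = m, upslope = m, t_max = m, t_half = m,
    valid = matrix(TRUE, nr, nc), degenerate = matrix(FALSE, nr, nc),
    grid_shape = c(nr, nc), cell_px = cell_px,
    onset_frame = 1L, onset_time = 0, window = 30,
    window_times = seq(0, 30), normalized = TRUE,
    scaling = list(i_max = c(0, 1), upslope = c(0, 1), window = 30)
  ), class = "icgfa_features")
}

# independent brute-force weighted-KNN oracle (deliberately simple)
knn_oracle <- function(Xtr, ytr, q, k) {
  d <- sqrt(colSums((t(Xtr) - q)^2))
  nn <- order(d)[seq_len(k)]
  dd <- d[nn]; cl <- as.integer(ytr[nn])
  lv <- levels(ytr)
  if (any(dd < 1e-12)) {
    cnt <- tabulate(cl[dd < 1e-12], nbins = length(lv))
    return(factor(lv[which.max(cnt)], levels = lv))
  }
  w <- 1 / dd
  score <- vapply(seq_along(lv), function(c) sum(w[cl == c]), 0)
  best <- which(score >= max(score) - 1e-12 * max(score))
  if (length(best) > 1) {
    meand <- vapply(best, function(c) mean(dd[cl == c]), 0)
    best <- best[meand <= min(meand) + 1e-12]
  }
  factor(lv[best[1]], levels = lv)
}

# line-sample tibble from a per-line sequence list (see dataset_sequences)
seq_to_sample <- function(s) {
  tibble::tibble(position = seq_len(ncol(s$X)), col = s$cols,
                 i_max = s$X[1, ], upslope = s$X[2, ],
                 t_max = s$X[3, ], t_half = s$X[4, ])
}
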