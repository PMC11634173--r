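#' Draw scene configurations from the default synthetic study distribution
#'
#' Samples `n` scene configurations that vary the way real bowel segments
#' vary: the perfusion boundary position is uniform over 45-70% of the line,
#' and each scene draws its own zone kinetics from the ranges in
#' `zone_params` via its own seed. Optionally a number of poor-perfusion
#' segments (no boundary, whole band with poor kinetics) is included at the
#' end of the list.
#'
#' @param n Number of scenes.
#' @param seed Top-level seed; per-scene seeds are fanned out from it.
#' @param n_poor How many of the `n` scenes are poor-perfusion segments.
#' @param boundary_range Range the boundary position is drawn from.
#' @param ... Passed to [scene_config()] (e.g. `fps`, `duration`,
#'   `frame_height`).
#' @return List of `scene_config`s.
#' @export
sample_scene_configs <- function(n, seed = 1L, n_poor = 0,
                                 boundary_range = c(0.45, 0.7), ...) {
  set.seed(seed)
  bpos <- runif(n, boundary_range[1], boundary_range[2])
  seeds <- sample.int(2^30, n)
  lapply(seq_len(n), function(i) {
    scene_config(boundary_pos = bpos[i],
                 perfused = i <= n - n_poor,
                 seed = seeds[i], ...)
  })
}

#' Build a labelled dataset from rendered scenes
#'
#' Runs each scene through the pipeline (stabilisation when it has motion,
#' grid extraction, milestone features, per-recording normalisation) and
#' assembles the augmentation-line dataset with [assemble_dataset()].
#'
#' @param scenes List of `icgfa_scene`s (or `scene_config`s, which are
#'   rendered first).
#' @param n_lines,experts,height,seed Passed to [assemble_dataset()].
#' @param split Named list of video-id vectors (ids are scene indices unless
#'   scenes carry a `video_id`).
#' @param window Prediction window in seconds.
#' @return An `icgfa_dataset`.
#' @export
scenes_to_dataset <- function(scenes, n_lines = 4, experts = 1, split = NULL,
                              height = 35, window = 30, seed = 1L) {
  segments <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    if (inherits(sc, "scene_config")) sc <- render_scene(sc)
    pc <- process_scene(sc, window = window, height = height)
    out <- list(features = pc$features, annotation = sc$annotation,
                video_id = sc$video_id %||% i)
    rm(sc, pc); gc(verbose = FALSE)   # frame arrays are large; free eagerly
    out
  })
  assemble_dataset(segments, n_lines = n_lines, experts = experts,
                   split = split, height = height, seed = seed)
}
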