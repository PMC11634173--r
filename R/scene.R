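#' Configure a synthetic ICGFA scene
#'
#' Describes one synthetic bowel segment imaged under ICG fluorescence
#' angiography: a horizontal bowel band whose inflow kinetics change along its
#' length from well-perfused ("good"), through the recommended stapling band
#' ("expert"), to non-perfused ("poor") bowel, with imaging noise and
#' frame-to-frame affine camera jitter. Each pixel's near-infrared (NIR) time
#' series follows gamma-variate kinetics (see [simulate_curve()]) whose
#' parameters are drawn per zone from `zone_params` and interpolated smoothly
#' across the zone breakpoints.
#'
#' @param frame_height,frame_width Frame size in pixels; must be divisible by
#'   `cell_px`. Defaults 360x480 to match a 72x96 analysis grid of 5x5 cells.
#' @param fps Frames per second of the recording.
#' @param duration Recording length in seconds; must cover at least the 30-s
#'   inflow prediction window.
#' @param boundary_pos Position of the fluorescent/non-fluorescent boundary as
#'   a fraction of the annotated line length, in (0, 1).
#' @param expert_width Width of the expert (stapler) band in grid modules;
#'   default 12 modules, the approximate diameter of a surgical stapler head.
#' @param zone_params Named list with elements `good`, `expert`, `poor`, each
#'   a list of ranges (length-2 numeric, or a scalar) for the gamma-variate
#'   parameters `A`, `t0`, `tp`, `alpha`, `baseline`. Scene-level values are
#'   drawn uniformly from these ranges under `seed`.
#' @param noise_sd Standard deviation of additive Gaussian imaging noise on
#'   the NIR channel (8-bit intensity units).
#' @param motion_amplitude Amplitude of per-frame affine camera jitter in
#'   pixels of translation (rotation and shear scale with it); 0 disables
#'   motion.
#' @param perfused If `FALSE`, renders a poor-perfusion segment: the whole
#'   band follows "poor" kinetics and no expert band or stapler site exists.
#' @param cell_px Grid cell edge in pixels (5 px cells give the 72x96 grid on
#'   360x480 frames).
#' @param seed Integer seed; a fixed seed gives byte-identical scenes.
#'
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(frame_height = 360L, frame_width = 480L,
                         fps = 5, duration = 90,
                         boundary_pos = 0.6, expert_width = 12L,
                         zone_params = default_zone_params(),
                         noise_sd = 5, motion_amplitude = 2,
                         perfused = TRUE, cell_px = 5L, seed = 1L) {
  cfg <- list(
    frame_height = as.integer(frame_height), frame_width = as.integer(frame_width),
    fps = fps, duration = duration, boundary_pos = boundary_pos,
    expert_width = as.integer(expert_width), zone_params = zone_params,
    noise_sd = noise_sd, motion_amplitude = motion_amplitude,
    perfused = isTRUE(perfused), cell_px = as.integer(cell_px),
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
}

#' @rdname scene_config
#' @export
default_zone_params <- function() {
  list(
    good   = list(A = c(110, 150), t0 = c(6, 12),  tp = c(14, 22), alpha = c(1.8, 3.0), baseline = c(2, 8)),
    expert = list(A = c(60, 95),   t0 = c(8, 14),  tp = c(18, 26), alpha = c(1.8, 3.0), baseline = c(2, 8)),
    poor   = list(A = c(4, 18),    t0 = c(18, 28), tp = c(26, 40), alpha = c(1.2, 2.2), baseline = c(2, 8))
  )
}

range2 <- function(x) if (length(x) == 1) c(x, x) else sort(x[1:2])

validate_scene_config <- function(cfg) {
  if (cfg$frame_height %% cfg$cell_px != 0 || cfg$frame_width %% cfg$cell_px != 0)
    abort("frame dimensions must be divisible by the grid cell size")
  if (cfg$duration < 30)
    abort("`duration` must cover the 30-s prediction window")
  if (cfg$expert_width < 1) abort("`expert_width` must be >= 1")
  if (cfg$boundary_pos <= 0 || cfg$boundary_pos >= 1)
    abort("`boundary_pos` must lie in (0, 1)")
  if (cfg$fps <= 0) abort("`fps` must be positive")
  zp <- cfg$zone_params
  if (!all(c("good", "expert", "poor") %in% names(zp)))
    abort("`zone_params` needs good, expert and poor entries")
  for (z in names(zp)) for (p in c("A", "t0", "tp", "alpha", "baseline")) {
    if (is.null(zp[[z]][[p]])) abort(sprintf("zone_params$%s$%s missing", z, p))
    cfg$zone_params[[z]][[p]] <- range2(zp[[z]][[p]])
  }
  zp <- cfg$zone_params
  if (!(min(zp$good$A) > min(zp$expert$A) && min(zp$expert$A) > max(zp$poor$A)))
    abort("zone amplitudes must satisfy A_good > A_expert_min > A_poor")
  structure(cfg, class = "scene_config")
}

# geometry shared by renderer and annotation: band rows, line row, module range
scene_geometry <- function(cfg) {
  h <- cfg$frame_height; w <- cfg$frame_width; cp <- cfg$cell_px
  n_rows <- h %/% cp; n_cols <- w %/% cp
  band_mods <- max(7L, round(0.42 * n_rows))      # band height in modules
  band_top <- ((n_rows - band_mods) %/% 2L) * cp + 1L
  band_rows <- band_top:(band_top + band_mods * cp - 1L)
  margin <- 2L                                     # modules clipped at frame edge
  line_cols <- (margin + 1L):(n_cols - margin)     # modules crossed by the line
  line_row <- band_rows[1] + (band_mods %/% 2L) * cp + (cp + 1L) %/% 2L
  list(n_rows = n_rows, n_cols = n_cols, band_rows = band_rows,
       band_mods = band_mods, line_cols = line_cols, line_row = line_row)
}

draw_zone_values <- function(zone_params) {
  lapply(zone_params, function(z) lapply(z, function(r) runif(1, r[1], r[2])))
}

# smoothstep in [0,1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Per-pixel-column kinetic parameter profiles. Good kinetics hold up to the
# proximal edge of the expert band, ramp linearly to the expert values across
# the band, then drop to poor kinetics over a ~2-module smoothstep at the
# fluorescence boundary.
zone_profiles <- function(cfg, zv, geom) {
  w <- cfg$frame_width; cp <- cfg$cell_px
  x <- seq_len(w)
  pars <- c("A", "t0", "tp", "alpha", "baseline")
  if (!cfg$perfused) {
    return(lapply(setNames(pars, pars), function(p) rep(zv$poor[[p]], w)))
  }
  band <- expert_band_modules(cfg, geom)           # [start, end) in module cols
  xb <- (band[2] - 1L) * cp + 0.5                  # boundary pixel (left edge of first poor module)
  xe <- (band[1] - 1L) * cp + 0.5                  # proximal edge of expert band
  ramp <- smoothstep((x - xe) / (xb - xe))         # good -> expert across the band
  drop <- smoothstep((x - xb) / (2 * cp))          # expert -> poor at the boundary
  lapply(setNames(pars, pars), function(p) {
    g <- zv$good[[p]]; e <- zv$expert[[p]]; q <- zv$poor[[p]]
    v <- g + (e - g) * ramp
    v + (q - v) * drop
  })
}

# Expert band as a half-open interval [start, end) of 1-based grid-module
# column indices; the fluorescence boundary sits at `end`.
expert_band_modules <- function(cfg, geom) {
  lc <- geom$line_cols
  L <- length(lc)
  b_idx <- as.integer(round(cfg$boundary_pos * L)) # boundary position along the line
  b_idx <- min(max(b_idx, cfg$expert_width + 4L), L - 4L)
  boundary_col <- lc[1] + b_idx                    # first module with poor label
  as.integer(c(boundary_col - cfg$expert_width, boundary_col))
}

annotation_from_config <- function(cfg, geom) {
  lc <- geom$line_cols
  cp <- cfg$cell_px
  if (cfg$perfused) {
    band <- expert_band_modules(cfg, geom)
    labels <- ifelse(lc < band[1], "good", ifelse(lc < band[2], "expert", "poor"))
    stapler_center <- (band[1] + band[2] - 1) / 2
  } else {
    band <- NULL
    labels <- rep("poor", length(lc))
    stapler_center <- NA_real_
  }
  structure(list(
    line = tibble::tibble(
      x = (lc - 1) * cp + (cp + 1) / 2,            # pixel centre of each module
      y = rep(geom$line_row, length(lc))
    ),
    cols = lc,
    labels = zone_factor(labels),
    stapler_band = band,
    stapler_center = stapler_center,
    line_row = geom$line_row
  ), class = "icgfa_annotation")
}

#' @export
print.icgfa_annotation <- function(x, ...) {
  cat(sprintf("<icgfa_annotation> %d modules: %d good | %d expert | %d poor\n",
              length(x$cols), sum(x$labels == "good"), sum(x$labels == "expert"),
              sum(x$labels == "poor")))
  if (!is.null(x$stapler_band))
    cat(sprintf("  stapler band modules [%d, %d), centre %.1f\n",
                x$stapler_band[1], x$stapler_band[2], x$stapler_center))
  invisible(x)
}

# Static white-light tissue texture: seeded smooth grayscale noise with the
# bowel band slightly brightened and edged, so feature-based registration has
# trackable structure. Values in [0, 255].
white_light_texture <- function(cfg, geom) {
  h <- cfg$frame_height; w <- cfg$frame_width
  tex <- matrix(rnorm(h * w), h, w)
  tex <- gaussian_blur(tex, sigma = 2.5)
  tex <- (tex - min(tex)) / (max(tex) - min(tex)) # 0..1
  img <- 50 + 140 * tex
  img[geom$band_rows, ] <- img[geom$band_rows, ] + 30
  edge <- c(geom$band_rows[1] + (-1:1), tail(geom$band_rows, 1) + (-1:1))
  edge <- edge[edge >= 1 & edge <= h]
  img[edge, ] <- img[edge, ] - 60
  pmin(pmax(img, 0), 255)
}

draw_jitter <- function(cfg, n_frames) {
  a <- cfg$motion_amplitude
  ctr <- c(cfg$frame_width, cfg$frame_height) / 2
  lapply(seq_len(n_frames), function(i) {
    if (i == 1 || a == 0) return(affine_identity())
    affine_transform(dx = runif(1, -a, a), dy = runif(1, -a, a),
                     angle = runif(1, -0.3 * a, 0.3 * a),
                     shear = runif(1, -0.002 * a, 0.002 * a),
                     center = ctr)
  })
}

#' Render a synthetic ICGFA scene
#'
#' Renders the paired white-light and NIR recording described by a
#' [scene_config()], together with its ground-truth annotation (sampled line,
#' per-module zone labels, stapler band). The bowel is a horizontal band;
#' every pixel's NIR series follows its column's interpolated gamma-variate
#' kinetics, Gaussian noise is added per frame, and when `motion_amplitude >
#' 0` a random affine jitter is applied identically to both channels of each
#' frame after the first.
#'
#' @param config A [scene_config()].
#' @return An `icgfa_scene`: list with `white` and `nir`
#'   (height x width x frames arrays, 0-255), `times` (seconds), `mode`
#'   (`"native"`), `annotation`, `jitter` (per-frame true transforms),
#'   `zone_values` (the kinetic parameters drawn for this scene) and `config`.
#' @seealso [render_overlay_mode()] for the green-overlay display rendering.
#' @export
render_scene <- function(config) {
  cfg <- validate_scene_config(config)
  set.seed(cfg$seed)
  geom <- scene_geometry(cfg)
  h <- cfg$frame_height; w <- cfg$frame_width
  times <- seq(0, cfg$duration, by = 1 / cfg$fps)
  Tn <- length(times)

  zv <- draw_zone_values(cfg$zone_params)
  prof <- zone_profiles(cfg, zv, geom)
  curves <- gamma_variate_matrix(times, prof$A, prof$t0, prof$tp,
                                 prof$alpha, prof$baseline)  # w x Tn
  curves <- pmin(pmax(curves, 0), 255)

  white0 <- white_light_texture(cfg, geom)
  jitter <- draw_jitter(cfg, Tn)
  band <- geom$band_rows

  nir <- array(0, dim = c(h, w, Tn))
  white <- array(0, dim = c(h, w, Tn))
  nir_t <- matrix(0, h, w)
  for (t in seq_len(Tn)) {
    nir_t[] <- 0
    nir_t[band, ] <- matrix(curves[, t], length(band), w, byrow = TRUE)
    if (cfg$motion_amplitude > 0 && t > 1) {
      M <- jitter[[t]]
      nir[, , t] <- warp_affine(nir_t, M)
      white[, , t] <- warp_affine(white0, M)
    } else {
      nir[, , t] <- nir_t
      white[, , t] <- white0
    }
    if (cfg$noise_sd > 0) {
      nir[, , t] <- pmin(pmax(nir[, , t] + rnorm(h * w, 0, cfg$noise_sd), 0), 255)
    }
  }

  structure(list(
    white = white, nir = nir, overlay = NULL, times = times, mode = "native",
    annotation = annotation_from_config(cfg, geom),
    jitter = jitter, zone_values = zv, geometry = geom, config = cfg
  ), class = "icgfa_scene")
}

#' @export
print.icgfa_scene <- function(x, ...) {
  d <- dim(x$nir)
  cat(sprintf("<icgfa_scene> %dx%d px, %d frames @ %g fps, mode %s, %s\n",
              d[1], d[2], d[3], x$config$fps, x$mode,
              if (x$config$perfused) "perfused" else "poor perfusion"))
  print(x$annotation)
  invisible(x)
}

#' Render the green-overlay display mode of a scene
#'
#' Emulates imagers that display fluorescence as a green tint over the
#' white-light image instead of a separate grayscale NIR channel. Each output
#' pixel is the (grayscale) white-light pixel attenuated towards pure green in
#' proportion to the NIR intensity `n`:
#' `R = B = w(1 - n/255)`, `G = w(1 - n/255) + n`, so the fluorescence lives
#' entirely in the green-channel excess and [overlay_to_grayscale()] recovers
#' `n` up to 8-bit quantisation.
#'
#' @param scene An `icgfa_scene` rendered by [render_scene()].
#' @return The scene with `mode = "overlay"` and an `overlay` array
#'   (height x width x 3 x frames, integer-quantised 0-255).
#' @export
render_overlay_mode <- function(scene) {
  stopifnot(inherits(scene, "icgfa_scene"))
  nir <- scene$nir
  if (min(nir) < 0 || max(nir) > 255) {
    warn("NIR intensities outside [0, 255]; clipping before overlay rendering")
    nir <- pmin(pmax(nir, 0), 255)
  }
  d <- dim(nir)
  out <- array(0, dim = c(d[1], d[2], 3, d[3]))
  for (t in seq_len(d[3])) {
    wl <- scene$white[, , t]
    a <- nir[, , t] / 255
    rb <- round(wl * (1 - a))
    out[, , 1, t] <- rb
    out[, , 2, t] <- round(wl * (1 - a) + nir[, , t])
    out[, , 3, t] <- rb
  }
  scene$overlay <- out
  scene$mode <- "overlay"
  scene
}

# separable gaussian blur with replicate padding (helper for texture and Harris)
gaussian_kernel <- function(sigma, radius_mult = 3) {
  r <- max(1L, ceiling(radius_mult * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

conv_cols <- function(m, k) {
  # convolve each column with kernel k (odd length), replicate padding
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
  out
}

conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- ncol(m)
  pad <- cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(n, r), drop = FALSE])
  out <- matrix(0, nrow(m), n)
  for (j in seq_along(k)) out <- out + k[j] * pad[, j:(j + n - 1L), drop = FALSE]
  out
}

gaussian_blur <- function(m, sigma, radius_mult = 3) {
  k <- gaussian_kernel(sigma, radius_mult)
  conv_rows(conv_cols(m, k), k)
}
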