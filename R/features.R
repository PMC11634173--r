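#' Intensity-time curve milestones
#'
#' Summarises one fluorescence inflow curve by the four angiographic
#' milestones: maximum intensity, upslope, time to maximum and time to
#' 50%-maximum. The series is first smoothed by a centred moving average
#' (window `smooth_window` samples, partial at the ends); the baseline is the
#' mean of the first three smoothed samples. Then
#' `i_max` is the smoothed maximum, `t_max` the time of its first attainment,
#' `t_half` the first upward crossing of `baseline + 0.5 (i_max - baseline)`
#' (linearly interpolated between samples), and the upslope is
#' `(i_max - baseline) / (t_max - t_onset)` where `t_onset` is the first
#' interpolated crossing of `baseline + 0.1 (i_max - baseline)` — the
#' standard 10%-rise definition of inflow onset. All times are reported in
#' seconds from the start of the window. A flat series yields all-zero
#' features with `degenerate = TRUE`.
#'
#' @param series Numeric intensity series (>= 3 samples).
#' @param times Sample times in seconds, strictly increasing.
#' @param smooth_window Centred moving-average window in samples; 1 disables
#'   smoothing.
#' @return A one-row tibble: `i_max`, `upslope`, `t_max`, `t_half`,
#'   `t_onset`, `baseline`, `degenerate`.
#' @export
compute_milestones <- function(series, times, smooth_window = 3) {
  if (length(series) < 3) abort("need at least 3 samples")
  if (length(series) != length(times)) abort("`series` and `times` lengths differ")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  m <- milestones_matrix(matrix(series, 1), times, smooth_window)
  tibble::as_tibble(m)
}

# moving average along columns of a cells x T matrix, partial windows at ends
smooth_rows <- function(M, w) {
  if (w <= 1) return(M)
  Tn <- ncol(M)
  r <- (w - 1L) %/% 2L
  num <- M
  den <- matrix(1, nrow(M), Tn)
  for (k in seq_len(r)) {
    num[, (k + 1):Tn] <- num[, (k + 1):Tn] + M[, 1:(Tn - k)]
    den[, (k + 1):Tn] <- den[, (k + 1):Tn] + 1
    num[, 1:(Tn - k)] <- num[, 1:(Tn - k)] + M[, (k + 1):Tn]
    den[, 1:(Tn - k)] <- den[, 1:(Tn - k)] + 1
  }
  num / den
}

# first interpolated upward crossing of per-row `level`, as time from window
# start; rows that start at/above the level get 0
first_crossing <- function(sm, times, level) {
  n <- nrow(sm)
  above <- sm >= matrix(level, n, ncol(sm))
  j <- max.col(above, ties.method = "first")   # first TRUE (rows with any TRUE)
  j[!above[cbind(seq_len(n), j)]] <- NA        # no crossing at all
  tt <- rep(NA_real_, n)
  at_start <- !is.na(j) & j == 1L
  tt[at_start] <- 0
  mid <- !is.na(j) & j > 1L
  if (any(mid)) {
    jm <- j[mid]; i <- which(mid)
    s1 <- sm[cbind(i, jm - 1L)]; s2 <- sm[cbind(i, jm)]
    frac <- (level[mid] - s1) / (s2 - s1)
    frac[!is.finite(frac)] <- 0
    tt[mid] <- (times[jm - 1L] - times[1]) + frac * (times[jm] - times[jm - 1L])
  }
  tt
}

# vectorised milestone computation over the rows of a cells x T matrix;
# returns a data.frame of per-row features
milestones_matrix <- function(M, times, smooth_window = 3, degenerate_tol = 1e-8) {
  n <- nrow(M)
  sm <- smooth_rows(M, smooth_window)
  baseline <- rowMeans(sm[, 1:3, drop = FALSE])
  idx <- apply(sm, 1, which.max)
  i_max <- sm[cbind(seq_len(n), idx)]
  delta <- i_max - baseline
  t_max <- times[idx] - times[1]
  t_onset <- first_crossing(sm, times, baseline + 0.1 * delta)
  t_half <- first_crossing(sm, times, baseline + 0.5 * delta)
  # rise time can be 0 when the peak is the first sample; fall back to one
  # sample interval so the upslope stays finite
  dt_min <- min(diff(times))
  rise <- t_max - t_onset
  upslope <- delta / ifelse(rise > 0, rise, dt_min)
  degen <- delta <= degenerate_tol
  i_max[degen] <- 0; upslope[degen] <- 0; t_max[degen] <- 0
  t_half[degen] <- 0; t_onset[degen] <- 0
  data.frame(i_max = i_max, upslope = upslope, t_max = t_max, t_half = t_half,
             t_onset = t_onset, baseline = ifelse(degen, 0, baseline),
             degenerate = degen)
}

#' Detect the global ICG inflow onset of a recording
#'
#' The onset frame is the first frame at which the mean intensity over all
#' valid grid cells exceeds its pre-inflow baseline (mean of the first three
#' frames) by three baseline standard deviations (floored at 0.5 intensity
#' units so noiseless recordings behave).
#'
#' @param grid An `icgfa_grid_series`.
#' @return Integer frame index of onset.
#' @export
detect_onset <- function(grid) {
  Tn <- length(grid$times)
  gm <- vapply(seq_len(Tn), function(t) {
    v <- grid$values[, , t][grid$validity[, , t]]
    mean(v, na.rm = TRUE)
  }, 0)
  base <- mean(gm[1:3])
  s <- max(stats::sd(gm[1:3]), 0.5)
  onset <- which(gm > base + 3 * s)[1]
  if (is.na(onset))
    abort("no ICG inflow detected in the recording", class = "icgfa_no_inflow")
  onset
}

#' Compute milestone features for every grid cell
#'
#' Detects the global inflow onset (see [detect_onset()]) and computes the
#' four curve milestones per grid cell over the prediction window
#' `[onset, onset + window]`. Cells invalid in more than half of the window
#' frames are flagged invalid; isolated invalid frames within a valid cell's
#' series are filled by linear interpolation in time.
#'
#' @param grid An `icgfa_grid_series`.
#' @param window Prediction window length in seconds (default 30 s of
#'   inflow).
#' @param smooth_window Passed to the milestone computation.
#' @return An `icgfa_features` object: matrices `i_max`, `upslope`, `t_max`,
#'   `t_half` (grid shape), logical `valid` and `degenerate`, plus window
#'   metadata.
#' @export
featurize_grid <- function(grid, window = 30, smooth_window = 3) {
  onset <- detect_onset(grid)
  t_on <- grid$times[onset]
  sel <- which(grid$times >= t_on & grid$times <= t_on + window)
  if (max(grid$times) < t_on + window)
    warn(sprintf("recording ends %.1f s into the %g-s window; using available frames",
                 max(grid$times) - t_on, window))
  if (length(sel) < 3) abort("fewer than 3 frames in the prediction window")
  nr <- grid$grid_shape[1]; nc <- grid$grid_shape[2]
  V <- matrix(grid$values[, , sel], nr * nc, length(sel))
  Vd <- matrix(grid$validity[, , sel], nr * nc, length(sel))
  valid <- rowMeans(Vd) > 0.5
  V <- fill_invalid_rows(V, Vd, valid)
  feats <- milestones_matrix(V[valid, , drop = FALSE], grid$times[sel], smooth_window)
  shape_mat <- function(col, fill = NA_real_) {
    m <- matrix(fill, nr, nc)
    m[valid] <- feats[[col]]
    m
  }
  structure(list(
    i_max = shape_mat("i_max"), upslope = shape_mat("upslope"),
    t_max = shape_mat("t_max"), t_half = shape_mat("t_half"),
    valid = matrix(valid, nr, nc),
    degenerate = {m <- matrix(FALSE, nr, nc); m[valid] <- feats$degenerate; m},
    grid_shape = c(nr, nc), cell_px = grid$cell_px,
    onset_frame = onset, onset_time = t_on,
    window = window, window_times = grid$times[sel],
    normalized = FALSE, scaling = NULL,
    annotation = grid$annotation, config = grid$config
  ), class = "icgfa_features")
}

# linear interpolation in time over invalid entries of valid rows
fill_invalid_rows <- function(V, Vd, valid) {
  bad_rows <- which(valid & rowSums(!Vd) > 0)
  for (i in bad_rows) {
    ok <- Vd[i, ]
    if (sum(ok) >= 2) {
      V[i, !ok] <- stats::approx(which(ok), V[i, ok], xout = which(!ok),
                                 rule = 2)$y
    } else if (sum(ok) == 1) {
      V[i, !ok] <- V[i, ok]
    }
  }
  V
}

#' Normalise milestone features per recording
#'
#' Intensity-derived features (`i_max`, upslope) are min-max scaled to
#' \[0, 1\] over the valid cells of the recording — removing device gain and
#' illumination differences between imagers — and time features are divided
#' by the window length. The scaling is stored for exact inversion with
#' [denormalize_features()]. With zero range (a single valid cell) the scaled
#' value is 0 by convention.
#'
#' @param features An `icgfa_features` from [featurize_grid()].
#' @return The features, normalised, with a `scaling` record.
#' @export
normalize_features <- function(features) {
  if (isTRUE(features$normalized)) return(features)
  ok <- features$valid
  if (!any(ok)) abort("no valid cells to normalise")
  if (all(features$degenerate[ok])) abort("all valid cells are degenerate; cannot normalise")
  sc <- list(
    i_max = range(features$i_max[ok]),
    upslope = range(features$upslope[ok]),
    window = features$window
  )
  mm <- function(m, r) {
    if (diff(r) <= 0) return(ifelse(is.na(m), NA_real_, 0))
    (m - r[1]) / diff(r)
  }
  features$i_max <- mm(features$i_max, sc$i_max)
  features$upslope <- mm(features$upslope, sc$upslope)
  features$t_max <- features$t_max / sc$window
  features$t_half <- features$t_half / sc$window
  features$normalized <- TRUE
  features$scaling <- sc
  features
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(features) {
  if (!isTRUE(features$normalized)) return(features)
  sc <- features$scaling
  features$i_max <- features$i_max * diff(sc$i_max) + sc$i_max[1]
  features$upslope <- features$upslope * diff(sc$upslope) + sc$upslope[1]
  features$t_max <- features$t_max * sc$window
  features$t_half <- features$t_half * sc$window
  features$normalized <- FALSE
  features$scaling <- NULL
  features
}

#' @export
print.icgfa_features <- function(x, ...) {
  cat(sprintf("<icgfa_features> %dx%d grid, onset %.1f s, window %g s, %s\n",
              x$grid_shape[1], x$grid_shape[2], x$onset_time, x$window,
              if (x$normalized) "normalised" else "raw"))
  invisible(x)
}

#' @export
as_tibble.icgfa_features <- function(x, ...) {
  nr <- x$grid_shape[1]; nc <- x$grid_shape[2]
  tibble::tibble(
    row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr),
    i_max = as.vector(x$i_max), upslope = as.vector(x$upslope),
    t_max = as.vector(x$t_max), t_half = as.vector(x$t_half),
    valid = as.vector(x$valid), degenerate = as.vector(x$degenerate)
  )
}
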