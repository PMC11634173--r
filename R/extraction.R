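#' Recover fluorescence from a green-overlay display frame
#'
#' Imagers in overlay display mode show fluorescence as a green tint over the
#' white-light image. The fluorescence estimate is the green-channel excess
#' over the other channels, `F = clamp(G - max(R, B), 0, 255)`, which is
#' exactly zero on achromatic (gray/white) tissue and recovers the NIR signal
#' rendered by [render_overlay_mode()] up to 8-bit quantisation.
#'
#' @param rgb_frame Numeric height x width x 3 array (0-255).
#' @return Grayscale fluorescence matrix (0-255).
#' @export
overlay_to_grayscale <- function(rgb_frame) {
  d <- dim(rgb_frame)
  if (length(d) != 3 || d[3] != 3)
    abort("overlay frames must be height x width x 3 arrays")
  g <- matrix(rgb_frame[, , 2], d[1], d[2]) -
    pmax(matrix(rgb_frame[, , 1], d[1], d[2]),
         matrix(rgb_frame[, , 3], d[1], d[2]))
  pmin(pmax(g, 0), 255)
}

# cached block-mean aggregation matrices
.agg_cache <- new.env(parent = emptyenv())

agg_matrices <- function(h, w, cell) {
  key <- sprintf("%dx%dx%d", h, w, cell)
  m <- .agg_cache[[key]]
  if (is.null(m)) {
    nr <- h %/% cell; nc <- w %/% cell
    Rm <- matrix(0, nr, h); Cm <- matrix(0, w, nc)
    Rm[cbind(rep(seq_len(nr), each = cell), seq_len(h))] <- 1
    Cm[cbind(seq_len(w), rep(seq_len(nc), each = cell))] <- 1
    m <- list(Rm = Rm, Cm = Cm)
    .agg_cache[[key]] <- m
  }
  m
}

#' Aggregate a frame onto the analysis grid
#'
#' Divides the frame into square cells (grid modules) of `cell_px` pixels and
#' returns the mean of the valid pixels in each cell. The default 5-px cells
#' give the 72x96 grid on 360x480 frames. Cells with no valid pixel are `NaN`
#' and flagged in the `"valid"` attribute.
#'
#' @param frame Numeric matrix with dimensions divisible by `cell_px`.
#' @param validity Logical matrix of per-pixel validity (e.g. from warping);
#'   default all valid.
#' @param cell_px Cell edge in pixels.
#' @return Numeric (rows/cell) x (cols/cell) matrix with attribute `"valid"`.
#' @export
grid_aggregate <- function(frame, validity = NULL, cell_px = 5L) {
  h <- nrow(frame); w <- ncol(frame)
  if (h %% cell_px != 0 || w %% cell_px != 0)
    abort("frame dimensions must be divisible by `cell_px`")
  m <- agg_matrices(h, w, cell_px)
  if (is.null(validity)) {
    out <- (m$Rm %*% frame %*% m$Cm) / cell_px^2
    attr(out, "valid") <- matrix(TRUE, nrow(out), ncol(out))
    return(out)
  }
  v <- validity * 1
  sums <- m$Rm %*% (frame * v) %*% m$Cm
  counts <- m$Rm %*% v %*% m$Cm
  out <- sums / counts                      # 0/0 -> NaN for empty cells
  attr(out, "valid") <- counts > 0
  out
}

#' Build the per-grid-cell fluorescence time series of a sequence
#'
#' Converts a (stabilised) paired sequence into a grid intensity series: for
#' every frame the fluorescence image (native NIR, or the green-channel
#' excess of the overlay display when the scene mode is `"overlay"`) is
#' aggregated onto the analysis grid, honouring the per-pixel validity mask
#' from warping.
#'
#' @param scene An `icgfa_scene`, ideally after [stabilize_sequence()].
#' @return An `icgfa_grid_series`: `values` (rows x cols x frames, 0-255),
#'   `validity` (same shape), `times`, `grid_shape`, `cell_px`, `mode`.
#' @export
build_grid_series <- function(scene) {
  d <- dim(scene$nir)
  if (is.null(d) || d[3] < 1) abort("empty sequence")
  cp <- scene$config$cell_px %||% 5L
  if (!isTRUE(scene$stabilized) && (scene$config$motion_amplitude %||% 0) > 0)
    warn("sequence has camera motion but was not stabilised")
  Tn <- d[3]
  nr <- d[1] %/% cp; nc <- d[2] %/% cp
  values <- array(NA_real_, dim = c(nr, nc, Tn))
  valid <- array(TRUE, dim = c(nr, nc, Tn))
  overlay <- identical(scene$mode, "overlay")
  if (overlay && is.null(scene$overlay)) abort("overlay mode scene has no overlay frames")
  for (t in seq_len(Tn)) {
    f <- if (overlay) overlay_to_grayscale(scene$overlay[, , , t]) else scene$nir[, , t]
    v <- if (!is.null(scene$validity)) scene$validity[, , t] else NULL
    g <- grid_aggregate(f, v, cp)
    values[, , t] <- g
    valid[, , t] <- attr(g, "valid")
  }
  structure(list(values = values, validity = valid, times = scene$times,
                 grid_shape = c(nr, nc), cell_px = cp, mode = scene$mode,
                 annotation = scene$annotation, config = scene$config),
            class = "icgfa_grid_series")
}

#' @export
print.icgfa_grid_series <- function(x, ...) {
  cat(sprintf("<icgfa_grid_series> %dx%d grid, %d frames, mode %s\n",
              x$grid_shape[1], x$grid_shape[2], length(x$times), x$mode))
  invisible(x)
}
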