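#' Sample rectangular neighbourhoods along an annotated line
#'
#' For each coordinate of a line across the perfusion boundary, collects the
#' grid cells of a rectangle centred on the line and perpendicular to its
#' local direction. The default 35-pixel height spans 7 cells of 5 px: the
#' on-line cell plus three on each side. Cells falling outside the frame or
#' flagged invalid are omitted.
#'
#' @param features An `icgfa_features` grid (normalised or raw).
#' @param line Data frame with pixel columns `x`, `y`: one row per line
#'   coordinate, ordered proximal (perfused) to distal.
#' @param height Rectangle height in pixels; rounded to an odd multiple of
#'   the cell size. `height = 5` degenerates to the single on-line cell.
#' @return An `icgfa_line_columns` object: a coordinates tibble plus a
#'   `n_coords x n_offsets x 4` feature array with `NA` for omitted cells.
#' @export
sample_rectangle <- function(features, line, height = 35) {
  cp <- features$cell_px
  nr <- features$grid_shape[1]; nc <- features$grid_shape[2]
  x <- line$x; y <- line$y
  n <- length(x)
  if (n < 2) abort("line needs at least 2 coordinates")
  if (any(x < 1 | x > nc * cp | y < 1 | y > nr * cp))
    abort("line extends outside the frame")
  n_off <- max(1L, round(height / cp))
  if (n_off %% 2 == 0) {
    n_off <- n_off + 1L
    warn(sprintf("rectangle height rounded to %d px (odd multiple of the %d-px cell)",
                 n_off * cp, cp))
  }
  half <- (n_off - 1L) %/% 2L
  # local tangent by central differences, then unit perpendicular
  tx <- c(x[2] - x[1], (x[-(1:2)] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  ty <- c(y[2] - y[1], (y[-(1:2)] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])
  nrm <- pmax(sqrt(tx^2 + ty^2), 1e-9)
  px <- -ty / nrm; py <- tx / nrm
  feat_names <- c("i_max", "upslope", "t_max", "t_half")
  arr <- array(NA_real_, dim = c(n, n_off, 4),
               dimnames = list(NULL, NULL, feat_names))
  offs <- (-half):half
  for (j in seq_along(offs)) {
    ox <- x + offs[j] * cp * px
    oy <- y + offs[j] * cp * py
    col <- ceiling(ox / cp); row <- ceiling(oy / cp)
    ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
    idx <- cbind(row[ok], col[ok])
    ok[ok] <- features$valid[idx]
    idx <- cbind(row[ok], col[ok])
    for (k in seq_len(4)) arr[ok, j, k] <- features[[feat_names[k]]][idx]
  }
  coords <- tibble::tibble(
    position = seq_len(n), x = x, y = y,
    col = ceiling(x / cp), row = ceiling(y / cp)
  )
  structure(list(coords = coords, columns = arr, height_px = n_off * cp,
                 cell_px = cp), class = "icgfa_line_columns")
}

#' Condense rectangle columns to one feature vector per coordinate
#'
#' Reduces each coordinate's perpendicular cells independently per feature by
#' the median, condensing the rectangle back into a single linear
#' representation. Coordinates with no valid cell are filled by linear
#' interpolation from their neighbours along the line (flagged in `missing`).
#'
#' @param columns An `icgfa_line_columns` from [sample_rectangle()].
#' @return Tibble with one row per coordinate: `position`, `col`, `row`,
#'   `x`, `y`, the four median features, `n_cells`, `missing`.
#' @export
condense_median <- function(columns) {
  arr <- columns$columns
  n <- dim(arr)[1]
  feat_names <- dimnames(arr)[[3]]
  out <- columns$coords
  for (k in seq_along(feat_names)) {
    out[[feat_names[k]]] <- apply(arr[, , k, drop = FALSE], 1, median, na.rm = TRUE)
  }
  out$n_cells <- apply(arr[, , 1, drop = FALSE], 1, function(v) sum(!is.na(v)))
  out$missing <- out$n_cells == 0
  if (any(out$missing)) {
    if (all(out$missing)) abort("no coordinate has a valid cell")
    ok <- which(!out$missing)
    for (k in feat_names) {
      out[[k]][out$missing] <- stats::approx(ok, out[[k]][ok],
                                             xout = which(out$missing),
                                             rule = 2)$y
    }
  }
  out
}

#' Label line coordinates from a stapler-site annotation
#'
#' Coordinates within the stapler band are labelled `expert`; coordinates
#' proximal to it (towards well-perfused bowel) `good`, and distal ones
#' `poor`. With no band (poor-perfusion segments) every coordinate is
#' `poor`.
#'
#' @param cols Absolute grid-module column index of each line coordinate
#'   (proximal to distal).
#' @param annotation An `icgfa_annotation`, or a half-open integer interval
#'   `c(start, end)` of module columns, or `NULL` for no band.
#' @return Factor of labels (`good`, `expert`, `poor`).
#' @export
label_points <- function(cols, annotation) {
  band <- if (inherits(annotation, "icgfa_annotation")) annotation$stapler_band else annotation
  if (is.null(band)) return(zone_factor(rep("poor", length(cols))))
  if (band[1] < min(cols) || band[2] > max(cols) + 1)
    abort("stapler band lies outside the line extent")
  labels <- ifelse(cols < band[1], "good", ifelse(cols < band[2], "expert", "poor"))
  if (!any(labels == "good"))
    warn("stapler band at the proximal end of the line: no 'good' coordinates")
  if (!any(labels == "poor"))
    warn("stapler band at the distal end of the line: no 'poor' coordinates")
  zone_factor(labels)
}

#' Sample augmentation lines across the perfusion boundary of one segment
#'
#' Draws `n_lines` lines of differing lengths (+/-20% of the annotated line)
#' and perpendicular offsets (up to +/-10 modules, limited by the bowel band)
#' across the fluorescence/non-fluorescent boundary, condenses each by
#' rectangle sampling + median (see [sample_rectangle()],
#' [condense_median()]) and labels each coordinate from the annotation. Line
#' geometry is deterministic under `seed`.
#'
#' @param features An `icgfa_features` grid.
#' @param annotation The segment's `icgfa_annotation`.
#' @param n_lines Number of lines to sample.
#' @param height Rectangle height in pixels.
#' @param seed Integer seed for the line geometry.
#' @return List of `n_lines` line-sample tibbles (coordinate rows with
#'   features and `label`), each with a `line_id` column.
#' @export
augment_segment <- function(features, annotation, n_lines = 4, height = 35,
                            seed = 1L) {
  cp <- features$cell_px
  nr <- features$grid_shape[1]; nc <- features$grid_shape[2]
  base_cols <- annotation$cols
  L <- length(base_cols)
  band <- annotation$stapler_band
  set.seed(seed)
  max_off <- 10L   # perpendicular offset bound, grid modules
  samples <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    len <- max(20L, round(L * runif(1, 0.8, 1.2)))
    len <- min(len, nc - 2L)
    if (!is.null(band)) {
      # the line must cross the boundary with >= 4 modules on each side
      lo_max <- band[1] - 4L                   # latest feasible start
      hi_min <- band[2] + 4L                   # earliest feasible end
      start_min <- max(2L, hi_min - len + 1L)
      start_max <- min(lo_max, nc - len)
      if (start_min > start_max) abort("cannot place a line crossing the boundary")
      start <- if (start_min == start_max) start_min else
        sample(start_min:start_max, 1L)
    } else {
      start <- max(2L, min(base_cols[1], nc - len))
    }
    cols <- start:(start + len - 1L)
    off <- sample(-max_off:max_off, 1L)
    row_px <- annotation$line_row + off * cp
    row_px <- min(max(row_px, 3.5 * cp), nr * cp - 3.5 * cp)  # keep rectangle in frame
    line <- tibble::tibble(x = (cols - 1) * cp + (cp + 1) / 2,
                           y = rep(row_px, length(cols)))
    cond <- condense_median(sample_rectangle(features, line, height))
    cond$label <- label_points(cols, annotation)
    cond$line_id <- i
    samples[[i]] <- cond
  }
  samples
}

#' Assemble a labelled line dataset from featurised segments
#'
#' Combines the augmentation lines of many bowel segments into one tidy
#' dataset, one row per line coordinate. With `experts = 3`, two additional
#' simulated expert annotations are derived per segment by shifting the
#' stapler band by 1-2 modules (experts disagree slightly on the exact
#' transection level) and every expert's site yields its own labelled copy of
#' the lines, so the sample count is `videos x n_lines x experts`.
#'
#' @param segments List of segments, each a list with elements `features`
#'   (an `icgfa_features`), `annotation` and `video_id`.
#' @param n_lines Augmentation lines per segment.
#' @param experts 1 or 3 expert annotations per segment.
#' @param split Named list mapping split names (`train`, `validation`,
#'   `test`) to video ids; a video id must not appear in two splits.
#'   Unlisted videos go to `train`.
#' @param height Rectangle height in pixels.
#' @param seed Seed controlling line geometry and simulated expert jitter.
#' @return An `icgfa_dataset` tibble (one row per coordinate) with columns
#'   `video_id`, `expert_id`, `line_id`, `split`, `position`, `col`, the four
#'   features and `label`; attribute `class_counts` tabulates labels.
#' @export
assemble_dataset <- function(segments, n_lines = 4, experts = 1,
                             split = NULL, height = 35, seed = 1L) {
  if (length(segments) == 0) abort("no segments to assemble")
  if (!experts %in% c(1, 3)) abort("`experts` must be 1 or 3")
  split <- split %||% list()
  ids <- unlist(split)
  if (anyDuplicated(ids)) abort("a video id appears in more than one split")
  split_of <- function(vid) {
    hit <- names(split)[vapply(split, function(v) vid %in% v, TRUE)]
    if (length(hit) == 0) "train" else hit[1]
  }
  rows <- list()
  for (s in seq_along(segments)) {
    seg <- segments[[s]]
    vid <- seg$video_id %||% s
    seg_seed <- (seed + 7919L * s) %% .Machine$integer.max
    lines <- augment_segment(seg$features, seg$annotation, n_lines = n_lines,
                             height = height, seed = seg_seed)
    ann_by_expert <- list(seg$annotation)
    if (experts == 3) {
      set.seed(seg_seed + 1L)
      for (e in 2:3) {
        ann <- seg$annotation
        if (!is.null(ann$stapler_band)) {
          shift <- sample(c(-2L, -1L, 1L, 2L), 1L)
          ann$stapler_band <- ann$stapler_band + shift
          ann$stapler_center <- ann$stapler_center + shift
        }
        ann_by_expert[[e]] <- ann
      }
    }
    for (e in seq_along(ann_by_expert)) {
      for (li in seq_along(lines)) {
        ln <- lines[[li]]
        ln$label <- label_points(ln$col, ann_by_expert[[e]])
        ln$video_id <- vid
        ln$expert_id <- e
        ln$split <- split_of(vid)
        rows[[length(rows) + 1]] <- ln
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "video_id", "expert_id", "line_id", "split",
                       "position", "col", "row", "x", "y",
                       "i_max", "upslope", "t_max", "t_half",
                       "n_cells", "missing", "label")
  attr(out, "class_counts") <- table(out$label)
  attr(out, "n_samples") <- length(rows)
  class(out) <- c("icgfa_dataset", class(out))
  out
}

#' Number of line samples in a dataset
#' @param dataset An `icgfa_dataset`.
#' @param by_split Tabulate per split instead of in total.
#' @return Integer count (or a named vector with `by_split = TRUE`).
#' @export
n_line_samples <- function(dataset, by_split = FALSE) {
  key <- paste(dataset$video_id, dataset$expert_id, dataset$line_id)
  if (!by_split) return(length(unique(key)))
  vapply(base::split(key, dataset$split), function(k) length(unique(k)), 0L)
}

# split a dataset into a list of per-line sequences (feature matrix + labels)
dataset_sequences <- function(dataset, split = NULL) {
  d <- dataset
  if (!is.null(split)) d <- d[d$split %in% split, ]
  if (nrow(d) == 0) return(list())
  key <- paste(d$video_id, d$expert_id, d$line_id, sep = "\r")
  idx <- base::split(seq_len(nrow(d)), key)
  lapply(idx, function(i) {
    i <- i[order(d$position[i])]
    list(X = t(as.matrix(d[i, c("i_max", "upslope", "t_max", "t_half")])),
         y = as.integer(d$label[i]),
         cols = d$col[i],
         video_id = d$video_id[i[1]], expert_id = d$expert_id[i[1]],
         line_id = d$line_id[i[1]])
  })
}
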