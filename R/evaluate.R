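#' Extract the predicted expert (transection) zone from a label sequence
#'
#' The recommended stapling zone is the longest contiguous run of `expert`
#' labels of length at least `min_run` (default 6 modules, half a stapler
#' diameter — shorter runs are treated as noise, not a transection
#' recommendation). Ties between equally long runs are broken towards the
#' proximal end. When no run qualifies the result is an explicit
#' no-prediction, mirroring the display behaviour on poorly perfused bowel
#' where no stapling zone is shown.
#'
#' @param labels Per-coordinate labels (factor or character).
#' @param min_run Minimum qualifying run length in modules.
#' @param cols Optional absolute grid-module column per coordinate; when
#'   given, the zone also carries the absolute half-open column interval.
#' @return An `icgfa_zone`: `start`/`end` (half-open coordinate positions),
#'   `cols` (half-open absolute interval or `NULL`), `no_prediction`.
#' @export
extract_expert_zone <- function(labels, min_run = 6, cols = NULL) {
  if (length(labels) == 0) abort("empty label sequence")
  r <- rle(as.character(labels) == "expert")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_run)
  if (length(cand) == 0) {
    z <- list(start = NA_integer_, end = NA_integer_, cols = NULL,
              no_prediction = TRUE)
    return(structure(z, class = "icgfa_zone"))
  }
  best <- cand[which.max(r$lengths[cand])]   # first max = proximal tie-break
  s <- starts[best]; e <- ends[best] + 1L    # half-open [s, e)
  z <- list(start = s, end = e,
            cols = if (!is.null(cols)) c(cols[s], cols[e - 1L] + 1L) else NULL,
            no_prediction = FALSE)
  structure(z, class = "icgfa_zone")
}

#' @export
print.icgfa_zone <- function(x, ...) {
  if (x$no_prediction) cat("<icgfa_zone> no prediction\n")
  else cat(sprintf("<icgfa_zone> positions [%d, %d)%s\n", x$start, x$end,
                   if (!is.null(x$cols))
                     sprintf(", grid columns [%d, %d)", x$cols[1], x$cols[2])
                   else ""))
  invisible(x)
}

#' Pixel-level metrics for the expert label
#'
#' Binarises predictions and truth as expert-vs-rest and reports accuracy,
#' precision, recall, specificity, F1 and the DICE index
#' `2|P∩G| / (|P| + |G|)` from pooled confusion counts. For the binary set
#' formulation F1 and DICE coincide. When both expert sets are empty,
#' precision, recall, F1 and DICE are reported as 1 — vacuously perfect
#' agreement, the correct reward for predicting nothing on truly poorly
#' perfused bowel — and flagged `vacuous`.
#'
#' @param pred,truth Equal-length label vectors (factor or character).
#' @return One-row tibble of metrics plus the confusion counts.
#' @export
pixel_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("prediction and truth lengths differ")
  p <- as.character(pred) == "expert"
  g <- as.character(truth) == "expert"
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  metrics_from_counts(tp, fp, fn, tn)
}

metrics_from_counts <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  vacuous <- (tp + fp == 0) && (tp + fn == 0)
  div <- function(a, b, empty = 0) if (b == 0) empty else a / b
  tibble::tibble(
    accuracy = div(tp + tn, n),
    precision = if (vacuous) 1 else div(tp, tp + fp),
    recall = if (vacuous) 1 else div(tp, tp + fn),
    specificity = div(tn, tn + fp, empty = 1),
    f1 = if (vacuous) 1 else div(2 * tp, 2 * tp + fp + fn),
    dice = if (vacuous) 1 else div(2 * tp, 2 * tp + fp + fn),
    tp = tp, fp = fp, fn = fn, tn = tn, vacuous = vacuous
  )
}

#' Object-level hit test: does the stapler site fall in the predicted zone?
#'
#' True iff the centre of the actual stapler band lies inside the predicted
#' expert zone (half-open interval); a no-prediction never scores a hit.
#'
#' @param zone An `icgfa_zone`; use the absolute `cols` interval when
#'   present, else the coordinate positions.
#' @param stapler_center Stapler band centre, in the same coordinates.
#' @return Logical.
#' @export
object_hit <- function(zone, stapler_center) {
  if (zone$no_prediction) return(FALSE)
  iv <- zone$cols %||% c(zone$start, zone$end)
  stapler_center >= iv[1] && stapler_center < iv[2]
}

#' Render a clinical-style zone overlay on a white-light frame
#'
#' Tints the grid modules along the line by predicted class — green for
#' expert, red for good, blue for poor — alpha-blended over the white-light
#' frame as in the in-theatre display. When the prediction is a
#' no-prediction, expert tints are suppressed and only the good/poor zoning
#' is drawn (so poorly perfused bowel shows only red/blue zoning).
#'
#' @param frame Grayscale white-light frame (matrix, 0-255).
#' @param line Data frame of line pixel coordinates `x`, `y`.
#' @param labels Per-coordinate labels.
#' @param zone Optional `icgfa_zone`; its `no_prediction` flag controls
#'   expert-tint suppression.
#' @param alpha Blend factor in \[0, 1\]; 0 returns the frame unchanged.
#' @param height Tint band height in pixels, centred on the line.
#' @param cell_px Grid cell size.
#' @return An RGB array (height x width x 3, 0-255).
#' @export
render_overlay <- function(frame, line, labels, zone = NULL, alpha = 0.4,
                           height = 35, cell_px = 5L) {
  h <- nrow(frame); w <- ncol(frame)
  if (any(line$x < 1 | line$x > w | line$y < 1 | line$y > h))
    abort("line extends outside the frame")
  tint <- list(good = c(255, 0, 0), expert = c(0, 255, 0), poor = c(0, 0, 255))
  out <- array(rep(frame, 3), dim = c(h, w, 3))
  if (alpha == 0) return(out)
  suppress_expert <- !is.null(zone) && zone$no_prediction
  half <- floor(height / 2)
  labs <- as.character(labels)
  for (i in seq_along(labs)) {
    if (labs[i] == "expert" && suppress_expert) next
    cx <- ceiling(line$x[i] / cell_px)
    xs <- ((cx - 1) * cell_px + 1):(cx * cell_px)
    ys <- max(1, round(line$y[i]) - half):min(h, round(line$y[i]) + half)
    col <- tint[[labs[i]]]
    for (ch in 1:3)
      out[ys, xs, ch] <- (1 - alpha) * out[ys, xs, ch] + alpha * col[ch]
  }
  out
}

# run the full pipeline on one scene up to the condensed, labelled truth line
process_scene <- function(scene, window = 30, height = 35) {
  if ((scene$config$motion_amplitude %||% 0) > 0 && !isTRUE(scene$stabilized))
    scene <- stabilize_sequence(scene)
  grid <- build_grid_series(scene)
  feats <- normalize_features(featurize_grid(grid, window = window))
  ann <- scene$annotation
  cond <- condense_median(sample_rectangle(feats, ann$line, height))
  cond$truth <- ann$labels
  list(features = feats, line = cond, annotation = ann)
}

predict_labels <- function(model, sample) {
  if (inherits(model, "icgfa_bilstm")) return(predict_bilstm(model, sample))
  if (inherits(model, "icgfa_knn")) return(predict_knn(model, sample))
  if (is.function(model)) return(model(sample))
  abort("unsupported model type")
}

#' Evaluate a trained model over test scenes
#'
#' Runs the full pipeline per scene — stabilise, extract the grid series,
#' compute and normalise milestone features, sample and condense the
#' annotated line, predict, extract the expert zone — then pools pixel-level
#' expert-vs-rest metrics over all coordinates (micro-average) and computes
#' object-level accuracy: the fraction of segments with a stapler annotation
#' whose band centre falls inside the predicted zone. Poor-perfusion scenes
#' (no stapler site) do not enter the object-level denominator; for them the
#' correct behaviour is a no-prediction, reported per case.
#'
#' @param model An `icgfa_knn`, `icgfa_bilstm`, or a function
#'   `sample -> sample-with-label` (e.g. an oracle for testing).
#' @param scenes List of `icgfa_scene`s with ground-truth annotations.
#' @param min_run Minimum expert run length for a zone.
#' @param window Prediction window (seconds of inflow).
#' @param per_case_csv Optional path to write the per-case table.
#' @return An `icgfa_eval`: `summary` (pooled metrics + object accuracy),
#'   `per_case` tibble, and the pooled confusion counts.
#' @export
evaluate_suite <- function(model, scenes, min_run = 6, window = 30,
                           per_case_csv = NULL) {
  if (length(scenes) == 0) abort("no test scenes")
  per_case <- list()
  preds <- list(); truths <- list()
  for (s in seq_along(scenes)) {
    scene <- scenes[[s]]
    if (is.null(scene$annotation)) {
      warn(sprintf("scene %d has no annotation; skipped", s))
      next
    }
    pc <- tryCatch(process_scene(scene, window = window),
                   icgfa_no_inflow = function(e) NULL)
    gc(verbose = FALSE)
    if (is.null(pc)) {
      # no dye inflow at all: report the scene as all-poor, no prediction
      warn(sprintf("scene %d shows no ICG inflow; reported as no-prediction", s))
      ann <- scene$annotation
      pred <- tibble::tibble(position = seq_along(ann$cols), col = ann$cols,
                             label = zone_factor(rep("poor", length(ann$cols))))
      pc <- list(line = tibble::tibble(position = pred$position,
                                       truth = ann$labels),
                 annotation = ann)
    } else {
      pred <- predict_labels(model, pc$line)
    }
    zone <- extract_expert_zone(pred$label, min_run = min_run, cols = pred$col)
    ann <- pc$annotation
    has_stapler <- !is.null(ann$stapler_band)
    hit <- if (has_stapler) object_hit(zone, ann$stapler_center) else NA
    m <- pixel_metrics(pred$label, pc$line$truth)
    per_case[[length(per_case) + 1]] <- tibble::tibble(
      case = s, perfused = has_stapler,
      n_coords = nrow(pred),
      no_prediction = zone$no_prediction,
      zone_start = zone$cols[1] %||% NA_integer_,
      zone_end = zone$cols[2] %||% NA_integer_,
      stapler_center = ann$stapler_center,
      object_hit = hit,
      accuracy = m$accuracy, dice = m$dice
    )
    preds[[length(preds) + 1]] <- as.character(pred$label)
    truths[[length(truths) + 1]] <- as.character(pc$line$truth)
  }
  if (length(per_case) == 0) abort("no test scenes had annotations")
  per_case <- dplyr::bind_rows(per_case)
  pooled <- pixel_metrics(unlist(preds), unlist(truths))
  obj <- per_case$object_hit[per_case$perfused]
  summary <- dplyr::mutate(pooled,
                           object_accuracy = if (length(obj)) mean(obj) else NA_real_,
                           n_objects = length(obj),
                           n_scenes = nrow(per_case))
  if (!is.null(per_case_csv)) readr::write_csv(per_case, per_case_csv)
  structure(list(summary = summary, per_case = per_case),
            class = "icgfa_eval")
}

#' @export
print.icgfa_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<icgfa_eval> %d scenes (%d with stapler annotation)\n",
              s$n_scenes, s$n_objects))
  cat(sprintf("  pixel: acc %.3f  prec %.3f  rec %.3f  spec %.3f  F1 %.3f  DICE %.3f%s\n",
              s$accuracy, s$precision, s$recall, s$specificity, s$f1, s$dice,
              if (s$vacuous) " (vacuous)" else ""))
  cat(sprintf("  object-level accuracy: %.3f\n", s$object_accuracy))
  invisible(x)
}

#' @export
tidy.icgfa_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$summary[, c("accuracy", "precision", "recall", "specificity", "f1", "dice",
                  "object_accuracy")],
    dplyr::everything(), names_to = "metric", values_to = "value")
}

#' @export
glance.icgfa_eval <- function(x, ...) x$summary
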