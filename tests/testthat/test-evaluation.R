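lab <- function(x) factor(x, levels = c("good", "expert", "poor"))

run_labels <- function(...) {
  # build a label vector from run-length pairs: run_labels(good = 5, expert = 9)
  spec <- c(...)
  lab(rep(names(spec), spec))
}

test_that("zone extraction returns the longest qualifying expert run", {
  z <- extract_expert_zone(run_labels(good = 20))
  expect_true(z$no_prediction)
  z2 <- extract_expert_zone(run_labels(good = 3, expert = 4, good = 2,
                                       expert = 9, poor = 5))
  expect_false(z2$no_prediction)
  expect_equal(c(z2$start, z2$end), c(10, 19))
  z3 <- extract_expert_zone(run_labels(good = 35, expert = 12, poor = 10))
  expect_equal(c(z3$start, z3$end), c(36, 48))
  # below min_run -> no prediction
  z4 <- extract_expert_zone(run_labels(good = 10, expert = 5, poor = 10),
                            min_run = 6)
  expect_true(z4$no_prediction)
  expect_error(extract_expert_zone(character(0)), "empty")
})

test_that("zone extraction matches exhaustive run enumeration on random sequences", {
  set.seed(12)
  for (i in 1:60) {
    labs <- lab(sample(c("good", "expert", "poor"), 40, TRUE))
    z <- extract_expert_zone(labs, min_run = 3)
    # oracle: enumerate every maximal expert run by scanning
    runs <- list()
    s <- NA
    for (j in seq_len(41)) {
      is_e <- j <= 40 && labs[j] == "expert"
      if (is_e && is.na(s)) s <- j
      if (!is_e && !is.na(s)) { runs[[length(runs) + 1]] <- c(s, j); s <- NA }
    }
    runs <- Filter(function(r) r[2] - r[1] >= 3, runs)
    if (length(runs) == 0) {
      expect_true(z$no_prediction)
    } else {
      lens <- vapply(runs, function(r) r[2] - r[1], 0)
      best <- runs[[which.max(lens)]]   # first maximum = proximal tie-break
      expect_equal(c(z$start, z$end), best)
    }
  }
})

test_that("pixel metrics are exact on canonical cases", {
  t1 <- run_labels(good = 10, expert = 12, poor = 8)
  m <- pixel_metrics(t1, t1)
  expect_equal(m$accuracy, 1); expect_equal(m$dice, 1); expect_equal(m$f1, 1)
  # disjoint expert sets
  p <- run_labels(expert = 6, good = 24)
  g <- run_labels(good = 24, expert = 6)
  m2 <- pixel_metrics(p, g)
  expect_equal(m2$dice, 0); expect_equal(m2$recall, 0)
  # P = [0,12), G = [6,18): DICE = 2*6/24 = 0.5
  p3 <- lab(c(rep("expert", 12), rep("good", 12)))
  g3 <- lab(c(rep("good", 6), rep("expert", 12), rep("good", 6)))
  expect_equal(pixel_metrics(p3, g3)$dice, 0.5)
  expect_error(pixel_metrics(p3, g3[1:10]), "lengths differ")
})

test_that("both-empty expert sets score vacuously perfect and are flagged", {
  p <- run_labels(good = 10, poor = 10)
  m <- pixel_metrics(p, p)
  expect_true(m$vacuous)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1); expect_equal(m$dice, 1)
})

test_that("pixel metrics equal a brute-force confusion recount on random pairs", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(20:60, 1)
    p <- lab(sample(c("good", "expert", "poor"), n, TRUE))
    g <- lab(sample(c("good", "expert", "poor"), n, TRUE))
    m <- pixel_metrics(p, g)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_len(n)) {
      pe <- p[j] == "expert"; ge <- g[j] == "expert"
      if (pe && ge) tp <- tp + 1 else if (pe) fp <- fp + 1
      else if (ge) fn <- fn + 1 else tn <- tn + 1
    }
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    if (tn + fp > 0) {
      expect_equal(m$specificity, tn / (tn + fp))
      expect_equal(m$specificity + fp / (tn + fp), 1)  # spec + FPR = 1
    }
    # F1 == DICE identity for the binary set formulation
    expect_equal(m$f1, m$dice)
    expect_true(all(unlist(m[1:6]) >= 0 & unlist(m[1:6]) <= 1))
  }
})

test_that("growing the predicted zone towards truth never lowers DICE", {
  g <- run_labels(good = 10, expert = 12, poor = 10)
  last <- 0
  for (width in 1:12) {
    p <- lab(c(rep("good", 10), rep("expert", width), rep("poor", 22 - width)))
    d <- pixel_metrics(p, g)$dice
    expect_gte(d, last)
    last <- d
  }
  expect_equal(last, 1)
})

test_that("object hits use the half-open zone interval on the stapler centre", {
  z <- structure(list(start = 35L, end = 47L, cols = NULL,
                      no_prediction = FALSE), class = "icgfa_zone")
  expect_true(object_hit(z, 40))
  expect_false(object_hit(z, 47))   # end is exclusive
  expect_true(object_hit(z, 35))
  znp <- extract_expert_zone(run_labels(good = 10))
  expect_false(object_hit(znp, 40))
})

test_that("overlays tint by class and respect alpha and no-prediction", {
  sc <- clean_scene()
  frame <- sc$white[, , 1]
  ann <- sc$annotation
  labs <- ann$labels
  ov0 <- render_overlay(frame, ann$line, labs, alpha = 0)
  expect_equal(ov0[, , 1], frame)
  ov <- render_overlay(frame, ann$line, labs, alpha = 0.5)
  i_exp <- which(labs == "expert")[1]
  x <- ann$line$x[i_exp]; y <- ann$line$y[i_exp]
  expect_gt(ov[y, x, 2], ov[y, x, 1])   # expert is green-tinted
  i_good <- which(labs == "good")[1]
  xg <- ann$line$x[i_good]; yg <- ann$line$y[i_good]
  expect_gt(ov[yg, xg, 1], ov[yg, xg, 2])  # good is red-tinted
  # no-prediction suppresses the expert tint: the pixel stays untinted
  znp <- extract_expert_zone(run_labels(good = 10))
  ov2 <- render_overlay(frame, ann$line, labs, zone = znp, alpha = 0.5)
  expect_equal(ov2[y, x, ], rep(frame[y, x], 3))
  expect_error(render_overlay(frame, tibble::tibble(x = 1e4, y = 1), lab("good")),
               "outside")
})

test_that("evaluate_suite scores a perfect oracle and a useless model correctly", {
  scenes <- list(clean_scene(),
                 render_scene(small_config(noise_sd = 0, motion_amplitude = 0,
                                           seed = 77L)))
  truth_oracle <- function(sample) {
    sample$label <- label_points(sample$col, scenes[[1]]$annotation)
    sample
  }
  # both scenes share geometry (same frame size), so annotation labels match
  ev <- evaluate_suite(truth_oracle, scenes)
  expect_equal(ev$summary$object_accuracy, 1)
  expect_equal(ev$summary$accuracy, 1)
  expect_equal(ev$summary$dice, 1)
  expect_false(any(ev$per_case$no_prediction))
  all_poor <- function(sample) {
    sample$label <- lab(rep("poor", nrow(sample)))
    sample
  }
  ev2 <- evaluate_suite(all_poor, scenes)
  expect_equal(ev2$summary$object_accuracy, 0)
  expect_equal(ev2$summary$recall, 0)
  expect_true(all(ev2$per_case$no_prediction))
  expect_error(evaluate_suite(all_poor, list()), "no test scenes")
})

test_that("a scene without dye inflow is reported, not fatal", {
  sc <- render_scene(small_config(noise_sd = 0, motion_amplitude = 0,
                                  seed = 55L))
  sc$nir[] <- 5
  all_poor <- function(sample) {
    sample$label <- lab(rep("poor", nrow(sample)))
    sample
  }
  expect_warning(ev <- evaluate_suite(all_poor, list(sc)), "no ICG inflow")
  expect_true(ev$per_case$no_prediction[1])
  expect_false(ev$per_case$object_hit[1])
})

test_that("pooled metrics equal recomputation from concatenated per-scene labels", {
  scenes <- list(clean_scene())
  shifty <- function(sample) {
    truth <- label_points(sample$col, scenes[[1]]$annotation)
    sample$label <- lab(c(as.character(truth[-(1:2)]),
                          rep("poor", 2)))   # 2-module proximal shift
    sample
  }
  ev <- evaluate_suite(shifty, scenes)
  pc <- icgfa:::process_scene(scenes[[1]])
  pred <- shifty(pc$line)
  m <- pixel_metrics(pred$label, pc$line$truth)
  expect_equal(ev$summary$accuracy, m$accuracy)
  expect_equal(ev$summary$dice, m$dice)
  expect_equal(ev$summary$tp, m$tp)
})
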