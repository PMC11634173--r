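horizontal_line <- function(cols, row_px, cell_px = 5) {
  tibble::tibble(x = (cols - 1) * cell_px + (cell_px + 1) / 2,
                 y = rep(row_px, length(cols)))
}

test_that("a 35-px rectangle on a horizontal line stacks 7 cells per coordinate", {
  f <- constant_features()
  f$i_max[] <- matrix(seq_len(20 * 40) / 1000, 20, 40)  # distinct cell values
  line <- horizontal_line(5:30, row_px = 48)
  rc <- sample_rectangle(f, line, height = 35)
  expect_equal(dim(rc$columns), c(26, 7, 4))
  # offsets -3..3 rows around the line row (row 10)
  for (j in 1:7) {
    expect_equal(unname(rc$columns[1, j, "i_max"]), f$i_max[10 + j - 4, 5])
  }
})

test_that("height 5 degenerates to the single on-line cell", {
  f <- constant_features()
  f$t_max[] <- matrix(runif(800), 20, 40)
  line <- horizontal_line(3:25, row_px = 52)
  rc <- sample_rectangle(f, line, height = 5)
  expect_equal(dim(rc$columns)[2], 1L)
  expect_equal(rc$columns[, 1, "t_max"], f$t_max[11, 3:25])
})

test_that("a constant feature grid fills every rectangle entry with the constant", {
  f <- constant_features(value = 0.25)
  rc <- sample_rectangle(f, horizontal_line(4:30, 50), height = 35)
  expect_true(all(rc$columns == 0.25))
  expect_error(sample_rectangle(f, horizontal_line(4:50, 50)), "outside")
})

test_that("median condensation reduces each coordinate by the column median", {
  f <- constant_features()
  line <- horizontal_line(10:29, 48)
  rc <- sample_rectangle(f, line, height = 35)
  rc$columns[1, , "i_max"] <- 1:7
  rc$columns[2, , "i_max"] <- c(2, 2, 8, NA, NA, NA, NA)
  cond <- condense_median(rc)
  expect_equal(cond$i_max[1], 4)      # odd count
  expect_equal(cond$i_max[2], 2)      # sort oracle on {2,2,8}
  expect_equal(sort(c(2, 2, 8))[2], 2)
  # condensed values stay within the column range
  for (i in 3:nrow(cond)) {
    col <- rc$columns[i, , "upslope"]
    expect_gte(cond$upslope[i], min(col, na.rm = TRUE))
    expect_lte(cond$upslope[i], max(col, na.rm = TRUE))
  }
})

test_that("coordinates with no valid cell are interpolated from neighbours", {
  f <- constant_features()
  f$i_max[] <- 0.2
  line <- horizontal_line(5:24, 48)
  rc <- sample_rectangle(f, line, height = 5)
  rc$columns[3, , ] <- NA
  cond <- condense_median(rc)
  expect_true(cond$missing[3])
  expect_equal(cond$i_max[3], 0.2)
})

test_that("labelling a 90-module line with band [41, 53) gives 40/12/38", {
  cols <- 1:90
  labels <- label_points(cols, c(41L, 53L))
  expect_equal(as.integer(table(labels)), c(40, 12, 38))
  r <- rle(as.character(labels))
  expect_identical(r$values, c("good", "expert", "poor"))
})

test_that("band at the line start warns; band outside the line errors", {
  expect_warning(label_points(1:30, c(1L, 13L)), "proximal")
  expect_error(label_points(10:40, c(2L, 14L)), "outside")
  expect_true(all(label_points(1:20, NULL) == "poor"))
})

test_that("augmentation yields exactly n_lines labelled samples crossing the boundary", {
  f <- clean_features()
  ann <- clean_scene()$annotation
  lines <- augment_segment(f, ann, n_lines = 4, seed = 5L)
  expect_length(lines, 4)
  for (ln in lines) {
    expect_gte(nrow(ln), 20)
    counts <- table(ln$label)
    expect_equal(sum(counts), nrow(ln))       # label conservation
    expect_equal(as.integer(counts["expert"]), 12)
    r <- rle(as.character(ln$label))
    expect_identical(r$values, c("good", "expert", "poor"))
  }
  # differing geometries
  expect_gt(length(unique(vapply(lines, nrow, 0L))), 1)
  # determinism under the seed
  again <- augment_segment(f, ann, n_lines = 4, seed = 5L)
  expect_identical(lapply(lines, `[[`, "col"), lapply(again, `[[`, "col"))
  one <- augment_segment(f, ann, n_lines = 1, seed = 5L)
  expect_length(one, 1)
})

test_that("dataset assembly counts samples as videos x lines x experts", {
  f <- clean_features()
  ann <- clean_scene()$annotation
  segments <- lapply(1:3, function(i)
    list(features = f, annotation = ann, video_id = i))
  d1 <- assemble_dataset(segments, n_lines = 4, experts = 1)
  expect_equal(n_line_samples(d1), 12)
  d3 <- assemble_dataset(segments, n_lines = 4, experts = 3)
  expect_equal(n_line_samples(d3), 36)
  d2 <- assemble_dataset(segments, n_lines = 2, experts = 1,
                         split = list(train = 1:2, validation = 3))
  expect_equal(unname(n_line_samples(d2, by_split = TRUE)[c("train", "validation")]),
               c(4L, 2L))
  expect_error(assemble_dataset(list()), "no segments")
  expect_error(assemble_dataset(segments, split = list(train = 1:2, test = 2:3)),
               "more than one split")
})

test_that("simulated second and third experts shift the stapler band slightly", {
  f <- clean_features()
  ann <- clean_scene()$annotation
  segments <- list(list(features = f, annotation = ann, video_id = 1))
  d3 <- assemble_dataset(segments, n_lines = 1, experts = 3, seed = 2L)
  bands <- lapply(1:3, function(e) {
    sub <- d3[d3$expert_id == e, ]
    range(sub$col[sub$label == "expert"])
  })
  expect_equal(diff(bands[[1]]), 11)           # 12-module band
  shifts <- vapply(2:3, function(e) bands[[e]][1] - bands[[1]][1], 0)
  expect_true(all(abs(shifts) >= 1 & abs(shifts) <= 2))
})
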