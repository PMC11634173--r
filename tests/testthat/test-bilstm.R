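# tiny synthetic sequence dataset with a learnable rule, for fast tests
tiny_seq_dataset <- function(n_train = 6, n_val = 2, len = 30, seed = 21) {
  set.seed(seed)
  mk <- function(vid, split) {
    b <- sample(10:(len - 15), 1)
    lab <- rep("good", len)
    lab[b:(b + 5)] <- "expert"
    lab[(b + 6):len] <- "poor"
    x <- ifelse(lab == "good", 0.9, ifelse(lab == "expert", 0.5, 0.05)) +
      rnorm(len, 0, 0.02)
    tibble::tibble(video_id = vid, expert_id = 1L, line_id = 1L, split = split,
                   position = seq_len(len), col = seq_len(len),
                   i_max = pmin(pmax(x, 0), 1),
                   upslope = pmin(pmax(x + rnorm(len, 0, 0.02), 0), 1),
                   t_max = ifelse(lab == "poor", 0.9, 0.2),
                   t_half = ifelse(lab == "poor", 0.8, 0.15),
                   label = factor(lab, levels = c("good", "expert", "poor")))
  }
  d <- dplyr::bind_rows(
    lapply(seq_len(n_train), function(i) mk(i, "train")),
    lapply(seq_len(n_val), function(i) mk(n_train + i, "validation"))
  )
  class(d) <- c("icgfa_dataset", class(d))
  d
}

test_that("analytic gradients match numerical gradients on a tiny network", {
  set.seed(3)
  D <- 4; H <- 3; B <- 2; Tn <- 5
  params <- icgfa:::bilstm_init(D, H, 3, seed = 3)
  Xs <- lapply(1:Tn, function(t) matrix(rnorm(D * B), D, B))
  Y <- matrix(sample(1:3, B * Tn, TRUE), B, Tn)
  mask <- matrix(1, B, Tn); mask[2, 4:5] <- 0
  cw <- c(1.2, 0.8, 1.0)
  lg <- icgfa:::bilstm_loss_grad(params, Xs, Y, mask, cw)
  loss_at <- function(p) icgfa:::bilstm_loss_grad(p, Xs, Y, mask, cw,
                                                  grad = FALSE)$loss
  eps <- 1e-6
  check <- function(ana, get, set) {
    p0 <- get(params)
    idx <- seq_len(min(25, length(p0)))
    ng <- vapply(idx, function(i) {
      pa <- p0; pa[i] <- pa[i] + eps
      pb <- p0; pb[i] <- pb[i] - eps
      (loss_at(set(params, pa)) - loss_at(set(params, pb))) / (2 * eps)
    }, 0)
    expect_lt(max(abs(ana[idx] - ng)) / max(abs(ng), 1e-8), 1e-5)
  }
  check(lg$grads$fwd$W, function(p) p$fwd$W,
        function(p, v) { p$fwd$W <- matrix(v, nrow(p$fwd$W)); p })
  check(lg$grads$bwd$U, function(p) p$bwd$U,
        function(p, v) { p$bwd$U <- matrix(v, nrow(p$bwd$U)); p })
  check(lg$grads$V, function(p) p$V,
        function(p, v) { p$V <- matrix(v, nrow(p$V)); p })
  check(lg$grads$fwd$b, function(p) p$fwd$b, function(p, v) { p$fwd$b <- v; p })
})

test_that("the network has the 5-layer bi-LSTM architecture with 200 units by default", {
  d <- tiny_seq_dataset()
  m <- train_bilstm(d, epochs = 1, seed = 1L)
  expect_equal(m$hidden_units, 200)
  expect_length(m$layers, 5)
  expect_equal(nrow(m$params$fwd$W), 4 * 200)
  expect_equal(ncol(m$params$V), 2 * 200)
  expect_equal(nrow(m$params$V), 3)
  g <- glance(m)
  expect_equal(g$n_layers, 5L)
})

test_that("early stopping obeys its contract and training is reproducible", {
  d <- tiny_seq_dataset()
  m1 <- train_bilstm(d, hidden_units = 16, epochs = 30, patience = 3, seed = 5L)
  m2 <- train_bilstm(d, hidden_units = 16, epochs = 30, patience = 3, seed = 5L)
  expect_lte(m1$stop_epoch, 30)
  expect_lte(m1$best_epoch, m1$stop_epoch)
  expect_equal(m1$best_val_loss, min(m1$log$val_loss))
  expect_identical(m1$log, m2$log)
  expect_equal(m1$params, m2$params)
  # validation loss at the kept epoch is no worse than when patience started
  expect_lte(m1$best_val_loss, m1$log$val_loss[1])
  # empty validation split is a configuration error
  d_noval <- d[d$split == "train", ]
  expect_error(train_bilstm(d_noval, hidden_units = 8, epochs = 2),
               "validation")
})

test_that("posteriors are normalised per coordinate", {
  d <- tiny_seq_dataset()
  m <- train_bilstm(d, hidden_units = 16, epochs = 5, seed = 2L)
  s <- icgfa:::dataset_sequences(d, "validation")[[1]]
  pred <- predict_bilstm(m, seq_to_sample(s))
  sums <- pred$p_good + pred$p_expert + pred$p_poor
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_error(predict_bilstm(m, seq_to_sample(s)[1, ]), "2 coordinates")
})

test_that("a separable synthetic dataset is learned to high pixel accuracy", {
  d <- tiny_seq_dataset(n_train = 10, n_val = 3, seed = 31)
  m <- train_bilstm(d, hidden_units = 32, epochs = 60, patience = 8, seed = 7L)
  seqs <- icgfa:::dataset_sequences(d, "validation")
  accs <- vapply(seqs, function(s) {
    pred <- predict_bilstm(m, seq_to_sample(s))
    mean(as.integer(pred$label) == s$y)
  }, 0)
  expect_gte(mean(accs), 0.95)
  # predicted expert zones are contiguous runs on every validation line
  for (s in seqs) {
    pred <- predict_bilstm(m, seq_to_sample(s))
    z <- extract_expert_zone(pred$label, min_run = 3)
    expect_false(z$no_prediction)
  }
})

test_that("the model is direction-aware: canonical orientation matters", {
  d <- tiny_seq_dataset(n_train = 10, n_val = 3, seed = 31)
  m <- train_bilstm(d, hidden_units = 32, epochs = 40, patience = 8, seed = 7L)
  s <- icgfa:::dataset_sequences(d, "validation")[[1]]
  fwd <- predict_bilstm(m, seq_to_sample(s))
  srev <- s; srev$X <- s$X[, rev(seq_len(ncol(s$X)))]
  rev_pred <- predict_bilstm(m, seq_to_sample(srev))
  # reversing the input does not commute with reversing the output: the
  # model was trained on proximal-to-distal sequences only
  expect_false(identical(as.character(fwd$label),
                         rev(as.character(rev_pred$label))))
})
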