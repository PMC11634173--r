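# Bidirectional LSTM sequence labeller, implemented with base matrix algebra.
#
# Architecture (five layers): sequence input (4 features per coordinate) ->
# bidirectional LSTM (H hidden units per direction) -> fully connected ->
# soft-max -> classification output (3 classes). Variable-length sequences
# are padded per minibatch and masked in both the recurrence and the loss.
#
# Parameter layout per direction: W (4H x D), U (4H x H), b (4H), with gate
# row blocks ordered input / forget / output / candidate. Read-out: V (C x
# 2H), c0 (C) on the concatenated forward+backward hidden states.

sigmoid <- function(x) 1 / (1 + exp(-x))

bilstm_init <- function(D, H, C, seed) {
  set.seed(seed)
  gl <- function(nr, nc) matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr / 4 + nc)), nr, nc)
  dirp <- function() {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1          # forget-gate bias init
    list(W = gl(4 * H, D), U = gl(4 * H, H), b = b)
  }
  list(fwd = dirp(), bwd = dirp(),
       V = matrix(runif(C * 2 * H, -1, 1) * sqrt(6 / (C + 2 * H)), C, 2 * H),
       c0 = rep(0, C))
}

# One direction over a padded batch. Xs: list over t of D x B inputs; mask:
# B x Tn with 1 for real steps. Hidden/cell states carry through masked
# steps unchanged, so a reversed pass simply consumes time in reverse order.
lstm_dir_forward <- function(p, Xs, mask, reverse = FALSE, keep_cache = TRUE) {
  Tn <- length(Xs); B <- ncol(Xs[[1]]); H <- ncol(p$U)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h_prev <- matrix(0, H, B); c_prev <- matrix(0, H, B)
  hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in ord) {
    z <- p$W %*% Xs[[t]] + p$U %*% h_prev + p$b
    i <- sigmoid(z[1:H, , drop = FALSE])
    f <- sigmoid(z[(H + 1):(2 * H), , drop = FALSE])
    o <- sigmoid(z[(2 * H + 1):(3 * H), , drop = FALSE])
    g <- tanh(z[(3 * H + 1):(4 * H), , drop = FALSE])
    c_new <- f * c_prev + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- matrix(mask[, t], H, B, byrow = TRUE)
    h <- h_new * m + h_prev * (1 - m)
    cc <- c_new * m + c_prev * (1 - m)
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, o = o, g = g, tc = tc,
                         h_prev = h_prev, c_prev = c_prev, m = m)
    hs[[t]] <- h
    h_prev <- h; c_prev <- cc
  }
  list(h = hs, cache = cache)
}

lstm_dir_backward <- function(p, Xs, mask, fwdout, dh_out, reverse = FALSE) {
  Tn <- length(Xs); B <- ncol(Xs[[1]]); H <- ncol(p$U)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh_carry <- matrix(0, H, B); dc_carry <- matrix(0, H, B)
  for (t in rev(ord)) {
    cc <- fwdout$cache[[t]]
    m <- cc$m
    dh_tot <- dh_out[[t]] + dh_carry
    dh_new <- dh_tot * m
    dh_prev <- dh_tot * (1 - m)
    dc_new <- dc_carry * m
    dc_prev <- dc_carry * (1 - m)
    do <- dh_new * cc$tc
    dc_new <- dc_new + dh_new * cc$o * (1 - cc$tc^2)
    di <- dc_new * cc$g
    df <- dc_new * cc$c_prev
    dg <- dc_new * cc$i
    dc_prev <- dc_prev + dc_new * cc$f
    dz <- rbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW <- dW + tcrossprod(dz, Xs[[t]])
    dU <- dU + tcrossprod(dz, cc$h_prev)
    db <- db + rowSums(dz)
    dh_carry <- crossprod(p$U, dz) + dh_prev
    dc_carry <- dc_prev
  }
  list(W = dW, U = dU, b = db)
}

bilstm_forward <- function(params, Xs, mask, keep_cache = TRUE) {
  f <- lstm_dir_forward(params$fwd, Xs, mask, reverse = FALSE, keep_cache)
  b <- lstm_dir_forward(params$bwd, Xs, mask, reverse = TRUE, keep_cache)
  Tn <- length(Xs)
  P <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    logit <- params$V %*% rbind(f$h[[t]], b$h[[t]]) + params$c0
    logit <- sweep(logit, 2, apply(logit, 2, max))
    e <- exp(logit)
    P[[t]] <- sweep(e, 2, colSums(e), `/`)
  }
  list(P = P, fwd = f, bwd = b)
}

# masked, class-weighted cross-entropy loss and full gradient
bilstm_loss_grad <- function(params, Xs, Y, mask, cw, grad = TRUE) {
  H <- ncol(params$fwd$U)
  Tn <- length(Xs); B <- ncol(Xs[[1]])
  out <- bilstm_forward(params, Xs, mask, keep_cache = grad)
  wsum <- 0; loss <- 0
  dV <- params$V * 0; dc0 <- params$c0 * 0
  dhf <- vector("list", Tn); dhb <- vector("list", Tn)
  dlog <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    P <- out$P[[t]]
    yt <- Y[, t]
    mt <- mask[, t]
    act <- which(mt > 0)
    w <- numeric(B)
    w[act] <- cw[yt[act]]
    ll <- numeric(B)
    ll[act] <- -log(pmax(P[cbind(yt[act], act)], 1e-12))
    loss <- loss + sum(w * ll)
    wsum <- wsum + sum(w)
    if (grad) {
      G <- P
      G[cbind(yt[act], act)] <- G[cbind(yt[act], act)] - 1
      G <- sweep(G, 2, w, `*`)
      dlog[[t]] <- G
    }
  }
  loss <- loss / wsum
  if (!grad) return(list(loss = loss))
  for (t in seq_len(Tn)) {
    G <- dlog[[t]] / wsum
    hcat <- rbind(out$fwd$h[[t]], out$bwd$h[[t]])
    dV <- dV + tcrossprod(G, hcat)
    dc0 <- dc0 + rowSums(G)
    dh <- crossprod(params$V, G)
    dhf[[t]] <- dh[1:H, , drop = FALSE]
    dhb[[t]] <- dh[(H + 1):(2 * H), , drop = FALSE]
  }
  gf <- lstm_dir_backward(params$fwd, Xs, mask, out$fwd, dhf, reverse = FALSE)
  gb <- lstm_dir_backward(params$bwd, Xs, mask, out$bwd, dhb, reverse = TRUE)
  list(loss = loss, grads = list(fwd = gf, bwd = gb, V = dV, c0 = dc0))
}

flatten_grads <- function(g) c(g$fwd$W, g$fwd$U, g$fwd$b, g$bwd$W, g$bwd$U,
                               g$bwd$b, g$V, g$c0)

scale_grads <- function(g, s) {
  for (d in c("fwd", "bwd")) for (n in c("W", "U", "b")) g[[d]][[n]] <- g[[d]][[n]] * s
  g$V <- g$V * s; g$c0 <- g$c0 * s
  g
}

adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (n in names(p)) {
        r <- upd(p[[n]], g[[n]], m[[n]], v[[n]])
        out$p[[n]] <- r$p; out$m[[n]] <- r$m; out$v[[n]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# pad a list of sequences (X: D x L, y: ints) into batch tensors
pad_batch <- function(seqs) {
  D <- nrow(seqs[[1]]$X)
  B <- length(seqs)
  Tn <- max(vapply(seqs, function(s) ncol(s$X), 0L))
  Xs <- lapply(seq_len(Tn), function(t) matrix(0, D, B))
  Y <- matrix(1L, B, Tn)
  mask <- matrix(0, B, Tn)
  for (b in seq_len(B)) {
    L <- ncol(seqs[[b]]$X)
    for (t in seq_len(L)) Xs[[t]][, b] <- seqs[[b]]$X[, t]
    Y[b, seq_len(L)] <- seqs[[b]]$y
    mask[b, seq_len(L)] <- 1
  }
  list(Xs = Xs, Y = Y, mask = mask)
}

#' Train the bidirectional LSTM sequence model
#'
#' Trains the five-layer sequence network (sequence input, bidirectional LSTM
#' with `hidden_units` per direction, fully connected, soft-max,
#' classification output) on variable-length per-line feature sequences with
#' per-coordinate three-class targets. Optimised with Adam on minibatches of
#' padded sequences (loss masked on padding), inverse-frequency class weights
#' against the expert/other imbalance, and early stopping on the validation
#' loss: training stops once the validation loss has not improved for
#' `patience` epochs and the best-epoch weights are restored.
#'
#' @param dataset An `icgfa_dataset` with non-empty `train` and `validation`
#'   splits.
#' @param hidden_units LSTM hidden units per direction (default 200).
#' @param epochs Maximum epochs.
#' @param batch_size Sequences per minibatch.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param class_weights `"inverse"` for inverse-frequency weights, or a
#'   numeric vector of 3 weights (good, expert, poor).
#' @param grad_clip Global gradient-norm clip.
#' @param seed Seed for initialisation and shuffling; fixed seeds give
#'   identical runs.
#' @return An `icgfa_bilstm` model with the trained weights, the training
#'   log (per-epoch train/validation losses), `stop_epoch` and `best_epoch`.
#' @export
train_bilstm <- function(dataset, hidden_units = 200, epochs = 100,
                         batch_size = 8, lr = 1e-3, patience = 5,
                         class_weights = "inverse", grad_clip = 5,
                         seed = 1L) {
  train_seqs <- dataset_sequences(dataset, "train")
  val_seqs <- dataset_sequences(dataset, "validation")
  if (length(train_seqs) < 2) abort("need at least 2 training sequences")
  if (length(val_seqs) == 0)
    abort("validation split is empty: early stopping is impossible")
  for (s in c(train_seqs, val_seqs)) check_normalized(s$X)
  C <- 3L; D <- 4L
  y_all <- unlist(lapply(train_seqs, `[[`, "y"))
  cw <- if (identical(class_weights, "inverse")) {
    freq <- tabulate(y_all, nbins = C) / length(y_all)
    w <- ifelse(freq > 0, 1 / pmax(freq, 1e-9), 0)
    w / mean(w[freq > 0])
  } else rep_len(as.numeric(class_weights), C)

  params <- bilstm_init(D, hidden_units, C, seed)
  state <- adam_init(params)
  val_batch <- pad_batch(val_seqs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- vector("list", epochs)
  stop_epoch <- epochs
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train_seqs))
    tr_loss <- 0; nb <- 0
    for (s in seq(1, length(ord), by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, length(ord))]
      bt <- pad_batch(train_seqs[idx])
      lg <- bilstm_loss_grad(params, bt$Xs, bt$Y, bt$mask, cw)
      gn <- sqrt(sum(flatten_grads(lg$grads)^2))
      if (is.finite(gn) && gn > grad_clip)
        lg$grads <- scale_grads(lg$grads, grad_clip / gn)
      st <- adam_step(params, lg$grads, state, lr)
      params <- st$params; state <- st$state
      tr_loss <- tr_loss + lg$loss; nb <- nb + 1
    }
    val_loss <- bilstm_loss_grad(params, val_batch$Xs, val_batch$Y,
                                 val_batch$mask, cw, grad = FALSE)$loss
    improved <- val_loss < best$loss - 1e-6
    log[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / nb,
                                val_loss = val_loss, improved = improved)
    if (improved) {
      best <- list(loss = val_loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { stop_epoch <- ep; break }
    }
    stop_epoch <- ep
  }
  structure(list(
    params = best$params, hidden_units = hidden_units, classes = ZONE_LEVELS,
    class_weights = cw,
    layers = c("sequence input", "bi-LSTM", "fully connected", "soft-max",
               "classification output"),
    log = dplyr::bind_rows(log), stop_epoch = stop_epoch,
    best_epoch = best$epoch, best_val_loss = best$loss,
    config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                  patience = patience, grad_clip = grad_clip, seed = seed)
  ), class = "icgfa_bilstm")
}

#' Predict per-coordinate labels and posteriors with the sequence model
#'
#' Runs the bidirectional network over one line's feature sequence and
#' returns soft-max class posteriors and arg-max labels per coordinate.
#'
#' @param model An `icgfa_bilstm` from [train_bilstm()].
#' @param sample A line-sample tibble with the four normalised features
#'   (>= 2 coordinates).
#' @return The sample with `label`, `p_good`, `p_expert`, `p_poor` columns.
#' @export
predict_bilstm <- function(model, sample) {
  X <- t(as.matrix(sample[, c("i_max", "upslope", "t_max", "t_half")]))
  if (nrow(X) != 4) abort("expected the four curve features")
  if (ncol(X) < 2) abort("sequence must have at least 2 coordinates")
  check_normalized(X)
  L <- ncol(X)
  Xs <- lapply(seq_len(L), function(t) matrix(X[, t], 4, 1))
  mask <- matrix(1, 1, L)
  out <- bilstm_forward(model$params, Xs, mask, keep_cache = FALSE)
  P <- vapply(out$P, function(p) p[, 1], numeric(3))  # 3 x L
  sample$label <- zone_factor(model$classes[apply(P, 2, which.max)])
  sample$p_good <- P[1, ]; sample$p_expert <- P[2, ]; sample$p_poor <- P[3, ]
  sample
}

#' @export
predict.icgfa_bilstm <- function(object, newdata, ...) predict_bilstm(object, newdata)

#' @export
print.icgfa_bilstm <- function(x, ...) {
  cat(sprintf("<icgfa_bilstm> %s\n", paste(x$layers, collapse = " -> ")))
  cat(sprintf("  %d hidden units/direction, stopped at epoch %d (best %d, val loss %.4f)\n",
              x$hidden_units, x$stop_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
tidy.icgfa_bilstm <- function(x, ...) x$log

#' @export
glance.icgfa_bilstm <- function(x, ...) {
  np <- length(flatten_grads(x$params))
  tibble::tibble(hidden_units = x$hidden_units, n_layers = length(x$layers),
                 n_parameters = np, stop_epoch = x$stop_epoch,
                 best_epoch = x$best_epoch, best_val_loss = x$best_val_loss)
}
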