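#' Convolutional tile-classifier configuration
#'
#' Training protocol follows the tile-screening recipe: balanced corpus,
#' stratified 80/20 train/validation split, batch size 32, early stopping
#' that monitors validation accuracy with a patience of 10 epochs, and the
#' best checkpoint retained. The network itself is a small stack of
#' convolution blocks (3x3 convolution, ReLU, 2x max-pool — each block
#' halves the image), global average pooling and a single sigmoid output;
#' it is implemented in vectorised base R (im2col + BLAS matrix products,
#' Adam optimiser), so training the default corpus needs only a CPU.
#'
#' @param n_blocks Number of convolution blocks.
#' @param widths Channel widths per block (length `n_blocks`).
#' @param input_size Network input side length in pixels; tiles are
#'   block-mean downsampled to this size (a presence/absence screen does
#'   not need full tile resolution).
#' @param batch_size Minibatch size.
#' @param train_fraction Fraction of tiles used for training.
#' @param patience Early-stop patience, epochs without a new best
#'   validation accuracy.
#' @param max_epochs Hard epoch cap.
#' @param learning_rate Adam learning rate.
#' @param prob_threshold Probability threshold for the informative label.
#' @param seed RNG seed governing the split, initialisation and shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_blocks = 3L, widths = c(8L, 16L, 32L),
                       input_size = 32L, batch_size = 32L,
                       train_fraction = 0.8, patience = 10L,
                       max_epochs = 30L, learning_rate = 1e-3,
                       prob_threshold = 0.5, seed = 1L) {
  if (n_blocks < 1L || length(widths) != n_blocks)
    stop_invalid("widths must provide one channel count per block")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_invalid("train_fraction must lie in (0, 1)")
  if (batch_size < 1L) stop_invalid("batch_size must be >= 1")
  if (patience < 1L) stop_invalid("patience must be >= 1")
  if (input_size %% 2L^n_blocks != 0L)
    stop_invalid("input_size must be divisible by 2^n_blocks")
  structure(list(n_blocks = as.integer(n_blocks), widths = as.integer(widths),
                 input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 prob_threshold = prob_threshold, seed = seed),
            class = "cnn_config")
}

# ---- minimal CNN engine (im2col convolutions on 4D arrays H x W x C x B) ----

conv3x3_forward <- function(x, W9, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  xp <- array(0, c(H + 2L, Wd + 2L, B, C))
  xp[2:(H + 1L), 2:(Wd + 1L), , ] <- x
  P <- matrix(0, H * Wd * B, 9L * C)
  for (ci in seq_len(C)) for (k in 1:9) {
    dy <- (k - 1L) %% 3L; dx <- (k - 1L) %/% 3L
    P[, (ci - 1L) * 9L + k] <- xp[dy + seq_len(H), dx + seq_len(Wd), , ci]
  }
  out <- P %*% W9
  out <- sweep(out, 2L, b, "+")
  list(a = array(out, c(H, Wd, B, length(b))), P = P)
}

conv3x3_backward <- function(dout, P, W9, in_dim) {
  d <- dim(dout); H <- d[1]; Wd <- d[2]; B <- d[3]; cout <- d[4]
  C <- in_dim[4]
  dmat <- matrix(dout, H * Wd * B, cout)
  dW <- crossprod(P, dmat)
  db <- colSums(dmat)
  dP <- tcrossprod(dmat, W9)
  dxp <- array(0, c(H + 2L, Wd + 2L, B, C))
  for (k in 1:9) {
    dy <- (k - 1L) %% 3L; dx <- (k - 1L) %/% 3L
    cols <- (seq_len(C) - 1L) * 9L + k
    g <- array(dP[, cols], c(H, Wd, B, C))
    dxp[dy + seq_len(H), dx + seq_len(Wd), , ] <-
      dxp[dy + seq_len(H), dx + seq_len(Wd), , , drop = FALSE] + g
  }
  list(dx = dxp[2:(H + 1L), 2:(Wd + 1L), , , drop = FALSE], dW = dW, db = db)
}

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  s <- list(x[io, jo, , , drop = FALSE], x[ie, jo, , , drop = FALSE],
            x[io, je, , , drop = FALSE], x[ie, je, , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(a = m, sub = s)
}

maxpool2_backward <- function(dm, pool, out_dim) {
  s <- pool$sub; m <- pool$a
  dx <- array(0, out_dim)
  io <- seq(1L, out_dim[1], 2L); ie <- seq(2L, out_dim[1], 2L)
  jo <- seq(1L, out_dim[2], 2L); je <- seq(2L, out_dim[2], 2L)
  idx <- list(list(io, jo), list(ie, jo), list(io, je), list(ie, je))
  rem <- array(TRUE, dim(m))
  for (q in 1:4) {
    take <- (s[[q]] == m) & rem
    rem <- rem & !take
    dx[idx[[q]][[1]], idx[[q]][[2]], , ] <- dm * take
  }
  dx
}

cnn_forward <- function(x, par, keep_cache = TRUE) {
  cache <- list(); a <- x
  nb <- length(par$conv)
  for (l in seq_len(nb)) {
    cv <- conv3x3_forward(a, par$conv[[l]]$W, par$conv[[l]]$b)
    z <- cv$a
    r <- pmax(z, 0)
    pl <- maxpool2_forward(r)
    if (keep_cache)
      cache[[l]] <- list(P = cv$P, z = z, r_dim = dim(r), pool = pl,
                         in_dim = dim(a))
    a <- pl$a
  }
  d <- dim(a)  # H x W x B x C
  fmat <- t(matrix(colMeans(matrix(a, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  logits <- drop(crossprod(fmat, par$dense$w)) + par$dense$b
  p <- 1 / (1 + exp(-logits))
  list(p = p, fmat = fmat, feat_dim = d, cache = cache)
}

cnn_backward <- function(fw, y, par) {
  B <- length(y)
  dlogit <- (fw$p - y) / B
  grads <- list(dense = list(w = fw$fmat %*% dlogit, b = sum(dlogit)))
  d <- fw$feat_dim  # H x W x B x C
  dfmat <- outer(par$dense$w[, 1], dlogit)  # C x B
  da <- array(rep(as.vector(t(dfmat)), each = d[1] * d[2]) / (d[1] * d[2]), d)
  gconv <- vector("list", length(par$conv))
  for (l in rev(seq_along(par$conv))) {
    cc <- fw$cache[[l]]
    dr <- maxpool2_backward(da, cc$pool, cc$r_dim)
    dz <- dr * (cc$z > 0)
    bk <- conv3x3_backward(dz, cc$P, par$conv[[l]]$W, cc$in_dim)
    gconv[[l]] <- list(W = bk$dW, b = bk$db)
    da <- bk$dx
  }
  grads$conv <- gconv
  grads
}

cnn_init <- function(cfg) {
  cin <- 1L
  conv <- vector("list", cfg$n_blocks)
  for (l in seq_len(cfg$n_blocks)) {
    cout <- cfg$widths[l]
    conv[[l]] <- list(
      W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                 9L * cin, cout),
      b = rep(0, cout))
    cin <- cout
  }
  list(conv = conv,
       dense = list(w = matrix(stats::rnorm(cin, 0, sqrt(1 / cin)), cin, 1),
                    b = 0))
}

adam_update <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(par$conv)) {
    for (nm in c("W", "b")) {
      u <- upd(par$conv[[l]][[nm]], grads$conv[[l]][[nm]],
               state$conv[[l]][[nm]]$m, state$conv[[l]][[nm]]$v)
      par$conv[[l]][[nm]] <- u$p
      state$conv[[l]][[nm]] <- u[c("m", "v")]
    }
  }
  for (nm in c("w", "b")) {
    u <- upd(par$dense[[nm]], grads$dense[[nm]],
             state$dense[[nm]]$m, state$dense[[nm]]$v)
    par$dense[[nm]] <- u$p
    state$dense[[nm]] <- u[c("m", "v")]
  }
  list(par = par, state = state)
}

adam_init <- function(par) {
  zero_like <- function(p) list(m = p * 0, v = p * 0)
  list(conv = lapply(par$conv, function(l) lapply(l, zero_like)),
       dense = lapply(par$dense, zero_like))
}

# Downsample + normalize tiles [H0, W0, n] to network input [H, W, 1, n].
cnn_prepare <- function(tiles, input_size, norm = NULL) {
  d <- dim(tiles)
  if (is.null(d) || length(d) != 3L) stop_contract("tiles must be an [H, W, n] array")
  if (d[1] %% input_size != 0L || d[1] != d[2])
    stop_contract("tiles must be square with side a multiple of input_size")
  f <- d[1] %/% input_size
  x <- block_mean_downsample(tiles, f)
  if (is.null(norm)) norm <- list(mean = mean(x), sd = stats::sd(as.vector(x)))
  x <- (x - norm$mean) / norm$sd
  # layout H x W x B x C (single input channel)
  list(x = array(x, c(input_size, input_size, d[3], 1L)), norm = norm)
}

#' Train the convolutional tile classifier
#'
#' Trains the small CNN on a labeled tile corpus with the screening
#' protocol: stratified train/validation split, minibatch Adam with the
#' configured batch size, a per-epoch log of training/validation accuracy
#' and loss, and early stopping on validation accuracy with the configured
#' patience; the best-validation checkpoint is retained as the model.
#'
#' @param tiles Array `H x W x n` of tile images (e.g. axial MIPs), or a
#'   `tile_corpus` from [tissue_tile_corpus()] (then `labels` is taken
#'   from it).
#' @param labels Integer labels (1 = informative, 0 = non-informative).
#' @param cfg A [cnn_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `tile_cnn`: trained parameters, the
#'   normalisation constants, the training log (data frame with columns
#'   `epoch`, `train_accuracy`, `val_accuracy`, `val_loss`), `best_epoch`
#'   and `best_val_accuracy`, plus the held-out validation indices.
#' @export
train_classifier <- function(tiles, labels = NULL, cfg = cnn_config(),
                             verbose = FALSE) {
  if (inherits(tiles, "tile_corpus")) {
    labels <- tiles$labels
    tiles <- tiles$tiles
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_contract("corpus must contain both classes")
  if (dim(tiles)[3] != length(labels))
    stop_contract("labels must match the number of tiles")

  with_seed(cfg$seed, {
    # stratified split
    tr_idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
      sample(i, round(cfg$train_fraction * length(i)))
    }), use.names = FALSE)
    va_idx <- setdiff(seq_along(labels), tr_idx)

    prep <- cnn_prepare(tiles, cfg$input_size)
    x <- prep$x
    par <- cnn_init(cfg)
    state <- adam_init(par)

    eval_acc <- function(idx, chunk = 512L) {
      correct <- 0; loss <- 0
      for (s in split(idx, ceiling(seq_along(idx) / chunk))) {
        fw <- cnn_forward(x[, , s, , drop = FALSE], par, keep_cache = FALSE)
        yh <- as.integer(fw$p >= 0.5)
        correct <- correct + sum(yh == labels[s])
        pc <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
        loss <- loss + sum(-labels[s] * log(pc) - (1 - labels[s]) * log(1 - pc))
      }
      c(acc = correct / length(idx), loss = loss / length(idx))
    }

    log <- data.frame(epoch = integer(), train_accuracy = numeric(),
                      val_accuracy = numeric(), val_loss = numeric())
    best <- list(acc = -Inf, epoch = 0L, par = par)
    step <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample(tr_idx)
      n_correct <- 0L
      for (s in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
        xb <- x[, , s, , drop = FALSE]
        fw <- cnn_forward(xb, par, keep_cache = TRUE)
        grads <- cnn_backward(fw, labels[s], par)
        step <- step + 1L
        au <- adam_update(par, grads, state, cfg$learning_rate, step)
        par <- au$par; state <- au$state
        n_correct <- n_correct + sum(as.integer(fw$p >= 0.5) == labels[s])
      }
      va <- eval_acc(va_idx)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_accuracy = n_correct / length(idx),
                                   val_accuracy = va[["acc"]],
                                   val_loss = va[["loss"]]))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f loss %.4f", epoch,
                        n_correct / length(idx), va[["acc"]], va[["loss"]]))
      if (va[["acc"]] > best$acc) {
        best <- list(acc = va[["acc"]], epoch = epoch, par = par)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }

    structure(list(par = best$par, cfg = cfg, norm = prep$norm,
                   log = log, best_epoch = best$epoch,
                   best_val_accuracy = best$acc,
                   val_idx = va_idx, train_idx = tr_idx),
              class = "tile_cnn")
  })
}

#' Predict tile informativeness probabilities
#'
#' Runs the trained network on tiles and thresholds the sigmoid
#' probability into informative (1) / non-informative (0) labels.
#'
#' @param model A `tile_cnn` from [train_classifier()].
#' @param tiles Array `H x W x n` shaped like the training tiles, or a
#'   `tile_corpus`.
#' @param prob_threshold Probability threshold (default from the model's
#'   config).
#' @return A data frame of class `tile_scores`: `tile_id`, `probability`,
#'   `label`.
#' @export
predict_proba <- function(model, tiles, prob_threshold = model$cfg$prob_threshold) {
  if (!inherits(model, "tile_cnn")) stop_contract("model must be a tile_cnn")
  if (inherits(tiles, "tile_corpus")) tiles <- tiles$tiles
  prep <- cnn_prepare(tiles, model$cfg$input_size, model$norm)
  n <- dim(prep$x)[3]
  p <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / 512L))) {
    p[s] <- cnn_forward(prep$x[, , s, , drop = FALSE], model$par,
                        keep_cache = FALSE)$p
  }
  out <- data.frame(tile_id = seq_len(n), probability = p,
                    label = as.integer(p >= prob_threshold))
  class(out) <- c("tile_scores", "data.frame")
  out
}
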