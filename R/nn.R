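# A compact neural-network engine (dense / 1D and 2D convolution / max
# pooling / LSTM / dropout / softmax, trained with Adam on categorical
# cross-entropy) sufficient for the two-branch raw-signal + spectrogram
# classifier. Forward passes cache what backpropagation needs; gradients
# are verified against numerical differentiation in the test suite.
#
# Conventions: batches are the first array dimension; (B*T) x K matrices
# obtained by collapsing leading array dimensions rely on R's column-major
# layout, so collapsing and restoring with `dim<-` is exact.

sigm <- function(x) 1 / (1 + exp(-x))

# ---- layers ----------------------------------------------------------------

conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, Tn + 2L * pad, C))
  Xp[, pad + seq_len(Tn), ] <- X
  M <- array(0, c(B, Tn, k * C))
  for (o in seq_len(k)) {
    M[, , ((o - 1L) * C + 1L):(o * C)] <- Xp[, o:(o + Tn - 1L), , drop = FALSE]
  }
  dim(M) <- c(B * Tn, k * C)
  Z <- sweep(M %*% W, 2, b, `+`)
  A <- pmax(Z, 0)
  dim(A) <- c(B, Tn, ncol(W))
  list(A = A, M = M, mask = Z > 0, dims = d)
}

conv1d_backward <- function(dA, cache, W, k) {
  d <- cache$dims; B <- d[1]; Tn <- d[2]; C <- d[3]
  Fo <- ncol(W)
  dZ <- matrix(dA, B * Tn, Fo) * cache$mask
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dim(dM) <- c(B, Tn, k * C)
  pad <- (k - 1L) %/% 2L
  dXp <- array(0, c(B, Tn + 2L * pad, C))
  for (o in seq_len(k)) {
    dXp[, o:(o + Tn - 1L), ] <- dXp[, o:(o + Tn - 1L), , drop = FALSE] +
      dM[, , ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  list(dX = dXp[, pad + seq_len(Tn), , drop = FALSE], dW = dW, db = db)
}

conv2d_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Xp <- array(0, c(B, H + 2L, Wd + 2L, C))
  Xp[, 1L + seq_len(H), 1L + seq_len(Wd), ] <- X
  M <- array(0, c(B, H, Wd, 9L * C))
  o <- 0L
  for (dw in 0:2) for (dh in 0:2) {
    o <- o + 1L
    M[, , , ((o - 1L) * C + 1L):(o * C)] <-
      Xp[, dh + seq_len(H), dw + seq_len(Wd), , drop = FALSE]
  }
  dim(M) <- c(B * H * Wd, 9L * C)
  Z <- sweep(M %*% W, 2, b, `+`)
  A <- pmax(Z, 0)
  dim(A) <- c(B, H, Wd, ncol(W))
  list(A = A, M = M, mask = Z > 0, dims = d)
}

conv2d_backward <- function(dA, cache, W) {
  d <- cache$dims; B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Fo <- ncol(W)
  dZ <- matrix(dA, B * H * Wd, Fo) * cache$mask
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dim(dM) <- c(B, H, Wd, 9L * C)
  dXp <- array(0, c(B, H + 2L, Wd + 2L, C))
  o <- 0L
  for (dw in 0:2) for (dh in 0:2) {
    o <- o + 1L
    dXp[, dh + seq_len(H), dw + seq_len(Wd), ] <-
      dXp[, dh + seq_len(H), dw + seq_len(Wd), , drop = FALSE] +
      dM[, , , ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  list(dX = dXp[, 1L + seq_len(H), 1L + seq_len(Wd), , drop = FALSE],
       dW = dW, db = db)
}

pool2_forward <- function(X) {
  d <- dim(X); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- (H %/% 2L) * 2L; W2 <- (W %/% 2L) * 2L
  if (H2 == 0L || W2 == 0L) return(list(A = X, passthrough = TRUE, dims = d))
  i1 <- seq(1L, H2, 2L); i2 <- seq(2L, H2, 2L)
  j1 <- seq(1L, W2, 2L); j2 <- seq(2L, W2, 2L)
  s <- list(X[, i1, j1, , drop = FALSE], X[, i2, j1, , drop = FALSE],
            X[, i1, j2, , drop = FALSE], X[, i2, j2, , drop = FALSE])
  A <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  m1 <- s[[1]] == A
  m2 <- s[[2]] == A & !m1
  m3 <- s[[3]] == A & !m1 & !m2
  m4 <- s[[4]] == A & !m1 & !m2 & !m3
  list(A = A, masks = list(m1, m2, m3, m4), dims = d, passthrough = FALSE)
}

pool2_backward <- function(dA, cache) {
  if (isTRUE(cache$passthrough)) return(dA)
  d <- cache$dims; B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- (H %/% 2L) * 2L; W2 <- (W %/% 2L) * 2L
  i1 <- seq(1L, H2, 2L); i2 <- seq(2L, H2, 2L)
  j1 <- seq(1L, W2, 2L); j2 <- seq(2L, W2, 2L)
  dX <- array(0, d)
  dX[, i1, j1, ] <- dA * cache$masks[[1]]
  dX[, i2, j1, ] <- dA * cache$masks[[2]]
  dX[, i1, j2, ] <- dA * cache$masks[[3]]
  dX[, i2, j2, ] <- dA * cache$masks[[4]]
  dX
}

lstm_forward <- function(X, Wx, Wh, b) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; D <- d[3]
  H <- ncol(Wx) %/% 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- array(0, c(B, Tn, H))
  cache <- vector("list", Tn)
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B, D)
    Z <- Xt %*% Wx + h %*% Wh + bmat
    i <- sigm(Z[, seq_len(H), drop = FALSE])
    f <- sigm(Z[, H + seq_len(H), drop = FALSE])
    g <- tanh(Z[, 2L * H + seq_len(H), drop = FALSE])
    o <- sigm(Z[, 3L * H + seq_len(H), drop = FALSE])
    cache[[t]] <- list(Xt = Xt, hprev = h, cprev = cc, i = i, f = f, g = g, o = o)
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    cache[[t]]$tc <- tc
    Hs[, t, ] <- h
  }
  list(Hs = Hs, last = h, cache = cache, dims = d)
}

# dHs: gradient on the full sequence (B,T,H) or NULL; dlast: gradient on
# the final hidden state only (B,H) or NULL.
lstm_backward <- function(dHs, dlast, fw, Wx, Wh) {
  d <- fw$dims; B <- d[1]; Tn <- d[2]; D <- d[3]
  H <- ncol(Wx) %/% 4L
  dWx <- matrix(0, D, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, d)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    ch <- fw$cache[[t]]
    dh <- dh_next
    if (!is.null(dHs)) dh <- dh + matrix(dHs[, t, ], B, H)
    if (!is.null(dlast) && t == Tn) dh <- dh + dlast
    do <- dh * ch$tc
    dc <- dc_next + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g
    df <- dc * ch$cprev
    dg <- dc * ch$i
    dZ <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do * ch$o * (1 - ch$o))
    dWx <- dWx + crossprod(ch$Xt, dZ)
    dWh <- dWh + crossprod(ch$hprev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(Wx)
    dh_next <- dZ %*% t(Wh)
    dc_next <- dc * ch$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

dense_forward <- function(X, W, b, relu = TRUE) {
  Z <- sweep(X %*% W, 2, b, `+`)
  A <- if (relu) pmax(Z, 0) else Z
  list(A = A, X = X, mask = if (relu) Z > 0 else NULL)
}

dense_backward <- function(dA, cache, W) {
  dZ <- if (is.null(cache$mask)) dA else dA * cache$mask
  list(dX = dZ %*% t(W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(A = X, mask = NULL))
  mask <- array(stats::rbinom(length(X), 1, 1 - rate) / (1 - rate), dim(X))
  list(A = X * mask, mask = mask)
}

dropout_backward <- function(dA, cache) {
  if (is.null(cache$mask)) dA else dA * cache$mask
}

# ---- architecture ----------------------------------------------------------

#' Network hyperparameter configuration
#'
#' Defaults follow the published topology: four 1D convolution stages with
#' 64/128/512/1024 filters, two LSTM stages, three dense stages on the time
#' branch; three 3x3 2D convolution stages on the spectrogram branch; a
#' 128- and a 64-unit dense layer on top; softmax output; dropout after
#' every convolution; Adam on categorical cross-entropy, batch size 32,
#' 100 epochs. Sizes the topology leaves open (dropout rate, LSTM widths,
#' time-branch dense widths, 1D kernel length, 2D filter counts, pooling)
#' are set here and can be overridden.
#'
#' @param ... Named overrides.
#' @return Named list of hyperparameters.
#' @export
nn_config <- function(...) {
  cfg <- list(
    conv1d_filters = c(64L, 128L, 512L, 1024L),
    conv1d_kernel = 3L,
    lstm_units = c(128L, 64L),
    branch1_dense = c(256L, 128L, 64L),
    conv2d_filters = c(32L, 64L, 64L),
    pool2 = TRUE,
    head_dense = c(128L, 64L),
    dropout = 0.3,
    lr = 1e-3,
    batch_size = 32L,
    epochs = 100L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown nn_config fields: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Reduced-width profile of the network
#'
#' Same topology, smaller widths and fewer epochs; used for continuous
#' testing and the learning-sanity checks on one CPU.
#'
#' @param ... Named overrides applied on top of the reduced profile.
#' @return Named list of hyperparameters.
#' @export
nn_config_reduced <- function(...) {
  base <- nn_config(conv1d_filters = c(12L, 16L, 24L, 32L),
                    lstm_units = c(24L, 12L),
                    branch1_dense = c(32L, 16L, 16L),
                    conv2d_filters = c(4L, 6L, 8L),
                    head_dense = c(32L, 16L),
                    dropout = 0.05,
                    lr = 3e-3,
                    epochs = 30L)
  dots <- list(...)
  if (length(dots)) base[names(dots)] <- dots
  base
}

init_mat <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)

#' Build the two-branch classification network
#'
#' Branch 1 consumes 64 x 6 raw-signal windows through stacked 1D
#' convolutions, two LSTM stages and dense stages; branch 2 consumes the
#' 183 x 11 log-spectrogram image through stacked 3x3 2D convolutions; the
#' concatenated features pass through the dense head to a softmax over the
#' fall-risk classes.
#'
#' @param n_classes 2 or 6.
#' @param hyper Hyperparameters from [nn_config()] / [nn_config_reduced()].
#' @param input_time,input_channels Window shape (default 64 x 6).
#' @param img_dim Spectrogram image shape (default c(183, 11)).
#' @param seed Integer seed for weight initialisation.
#' @return A `tug_nn` model: list with `spec`, `params`, and `n_params`
#'   (total trainable parameter count).
#' @export
build_model <- function(n_classes, hyper = nn_config(), input_time = 64L,
                        input_channels = 6L, img_dim = c(183L, 11L),
                        seed = 1L) {
  if (!n_classes %in% c(2L, 6L)) stop("`n_classes` must be 2 or 6", call. = FALSE)
  k <- hyper$conv1d_kernel
  params <- list()
  with_seed(seed, {
    cin <- input_channels
    for (l in seq_along(hyper$conv1d_filters)) {
      f <- hyper$conv1d_filters[l]
      params[[paste0("c1_W", l)]] <- init_mat(k * cin, f, sqrt(2 / (k * cin)))
      params[[paste0("c1_b", l)]] <- numeric(f)
      cin <- f
    }
    din <- cin
    for (j in seq_along(hyper$lstm_units)) {
      H <- hyper$lstm_units[j]
      params[[paste0("l", j, "_Wx")]] <- init_mat(din, 4L * H, sqrt(1 / din))
      params[[paste0("l", j, "_Wh")]] <- init_mat(H, 4L * H, sqrt(1 / H))
      bb <- numeric(4L * H)
      bb[H + seq_len(H)] <- 1  # forget-gate bias
      params[[paste0("l", j, "_b")]] <- bb
      din <- H
    }
    for (l in seq_along(hyper$branch1_dense)) {
      u <- hyper$branch1_dense[l]
      params[[paste0("d1_W", l)]] <- init_mat(din, u, sqrt(2 / din))
      params[[paste0("d1_b", l)]] <- numeric(u)
      din <- u
    }
    b1_out <- din

    cin <- 1L
    for (l in seq_along(hyper$conv2d_filters)) {
      f <- hyper$conv2d_filters[l]
      params[[paste0("c2_W", l)]] <- init_mat(9L * cin, f, sqrt(2 / (9 * cin)))
      params[[paste0("c2_b", l)]] <- numeric(f)
      cin <- f
    }
    # branch-2 output shape, mirroring the forward pass (2x2 max pooling
    # floors odd dimensions; a dimension below 2 passes through)
    hw <- img_dim
    if (isTRUE(hyper$pool2)) {
      for (l in seq_along(hyper$conv2d_filters)) {
        h2 <- (hw[1] %/% 2L) * 2L; w2 <- (hw[2] %/% 2L) * 2L
        if (h2 > 0L && w2 > 0L) hw <- c(h2 %/% 2L, w2 %/% 2L)
      }
    }
    b2_out <- prod(hw) * cin

    din <- b1_out + b2_out
    for (l in seq_along(hyper$head_dense)) {
      u <- hyper$head_dense[l]
      params[[paste0("h_W", l)]] <- init_mat(din, u, sqrt(2 / din))
      params[[paste0("h_b", l)]] <- numeric(u)
      din <- u
    }
    params[["out_W"]] <- init_mat(din, n_classes, sqrt(1 / din))
    params[["out_b"]] <- numeric(n_classes)
  })
  spec <- list(n_classes = n_classes, hyper = hyper, input_time = input_time,
               input_channels = input_channels, img_dim = img_dim)
  structure(list(spec = spec, params = params,
                 n_params = sum(vapply(params, length, 0L))),
            class = "tug_nn")
}

# Forward pass. xt: (B, T, C) windows; xs: (B, H, W) spectrogram images.
nn_forward <- function(model, xt, xs, train = FALSE) {
  p <- model$params
  hy <- model$spec$hyper
  k <- hy$conv1d_kernel
  caches <- list()

  a <- xt
  for (l in seq_along(hy$conv1d_filters)) {
    cv <- conv1d_forward(a, p[[paste0("c1_W", l)]], p[[paste0("c1_b", l)]], k)
    dp <- dropout_forward(cv$A, hy$dropout, train)
    caches[[paste0("c1_", l)]] <- cv
    caches[[paste0("c1d_", l)]] <- dp
    a <- dp$A
  }
  for (j in seq_along(hy$lstm_units)) {
    lf <- lstm_forward(a, p[[paste0("l", j, "_Wx")]], p[[paste0("l", j, "_Wh")]],
                       p[[paste0("l", j, "_b")]])
    caches[[paste0("l", j)]] <- lf
    a <- if (j < length(hy$lstm_units)) lf$Hs else lf$last
  }
  for (l in seq_along(hy$branch1_dense)) {
    df <- dense_forward(a, p[[paste0("d1_W", l)]], p[[paste0("d1_b", l)]])
    caches[[paste0("d1_", l)]] <- df
    a <- df$A
  }
  b1 <- a

  s <- array(xs, c(dim(xs)[1], dim(xs)[2], dim(xs)[3], 1L))
  for (l in seq_along(hy$conv2d_filters)) {
    cv <- conv2d_forward(s, p[[paste0("c2_W", l)]], p[[paste0("c2_b", l)]])
    dp <- dropout_forward(cv$A, hy$dropout, train)
    caches[[paste0("c2_", l)]] <- cv
    caches[[paste0("c2d_", l)]] <- dp
    s <- dp$A
    if (isTRUE(hy$pool2)) {
      pl <- pool2_forward(s)
      caches[[paste0("p2_", l)]] <- pl
      s <- pl$A
    }
  }
  caches$b2_dims <- dim(s)
  b2 <- matrix(s, dim(s)[1], prod(dim(s)[-1]))

  a <- cbind(b1, b2)
  caches$b1_width <- ncol(b1)
  for (l in seq_along(hy$head_dense)) {
    df <- dense_forward(a, p[[paste0("h_W", l)]], p[[paste0("h_b", l)]])
    caches[[paste0("h_", l)]] <- df
    a <- df$A
  }
  of <- dense_forward(a, p$out_W, p$out_b, relu = FALSE)
  caches$out <- of
  logits <- of$A
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, caches = caches)
}

# Backward pass from one-hot labels; returns gradients named like params.
nn_backward <- function(model, fw, y1hot) {
  p <- model$params
  hy <- model$spec$hyper
  k <- hy$conv1d_kernel
  ca <- fw$caches
  B <- nrow(y1hot)
  g <- list()

  dlogits <- (fw$probs - y1hot) / B
  bk <- dense_backward(dlogits, ca$out, p$out_W)
  g$out_W <- bk$dW; g$out_b <- bk$db
  da <- bk$dX
  for (l in rev(seq_along(hy$head_dense))) {
    bk <- dense_backward(da, ca[[paste0("h_", l)]], p[[paste0("h_W", l)]])
    g[[paste0("h_W", l)]] <- bk$dW; g[[paste0("h_b", l)]] <- bk$db
    da <- bk$dX
  }
  b1w <- ca$b1_width
  db1 <- da[, seq_len(b1w), drop = FALSE]
  db2 <- da[, -seq_len(b1w), drop = FALSE]

  # branch 2
  ds <- array(db2, ca$b2_dims)
  for (l in rev(seq_along(hy$conv2d_filters))) {
    if (isTRUE(hy$pool2)) ds <- pool2_backward(ds, ca[[paste0("p2_", l)]])
    ds <- dropout_backward(ds, ca[[paste0("c2d_", l)]])
    bk <- conv2d_backward(ds, ca[[paste0("c2_", l)]], p[[paste0("c2_W", l)]])
    g[[paste0("c2_W", l)]] <- bk$dW; g[[paste0("c2_b", l)]] <- bk$db
    ds <- bk$dX
  }

  # branch 1
  for (l in rev(seq_along(hy$branch1_dense))) {
    bk <- dense_backward(db1, ca[[paste0("d1_", l)]], p[[paste0("d1_W", l)]])
    g[[paste0("d1_W", l)]] <- bk$dW; g[[paste0("d1_b", l)]] <- bk$db
    db1 <- bk$dX
  }
  dseq <- NULL; dlast <- db1
  for (j in rev(seq_along(hy$lstm_units))) {
    bk <- lstm_backward(dseq, dlast, ca[[paste0("l", j)]],
                        p[[paste0("l", j, "_Wx")]], p[[paste0("l", j, "_Wh")]])
    g[[paste0("l", j, "_Wx")]] <- bk$dWx
    g[[paste0("l", j, "_Wh")]] <- bk$dWh
    g[[paste0("l", j, "_b")]] <- bk$db
    dseq <- bk$dX; dlast <- NULL
  }
  da <- dseq
  for (l in rev(seq_along(hy$conv1d_filters))) {
    da <- dropout_backward(da, ca[[paste0("c1d_", l)]])
    bk <- conv1d_backward(da, ca[[paste0("c1_", l)]], p[[paste0("c1_W", l)]], k)
    g[[paste0("c1_W", l)]] <- bk$dW; g[[paste0("c1_b", l)]] <- bk$db
    da <- bk$dX
  }
  g
}

cross_entropy <- function(probs, y1hot) {
  -mean(log(pmax(rowSums(probs * y1hot), 1e-12)))
}

#' Train the two-branch network
#'
#' Adam on categorical cross-entropy over mini-batches (default size 32);
#' all shuffling, dropout and initialisation randomness runs under `seed`.
#'
#' @param model From [build_model()].
#' @param windows W x 64 x 6 array.
#' @param spectrograms W x 183 x 11 array.
#' @param labels Character/factor labels; the class set must match
#'   `model$spec$n_classes`.
#' @param epochs,batch_size,lr Training scheme; defaults come from the
#'   model's hyperparameter configuration.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss/accuracy.
#' @param early_stop Optional training-accuracy threshold; once reached,
#'   remaining epochs are skipped.
#' @return The trained model, with a `history` data.frame (epoch, loss,
#'   accuracy) attached.
#' @export
train_model <- function(model, windows, spectrograms, labels,
                        epochs = NULL, batch_size = NULL, lr = NULL,
                        seed = 1L, verbose = FALSE, early_stop = NULL) {
  hy <- model$spec$hyper
  epochs <- epochs %||% hy$epochs
  batch_size <- batch_size %||% hy$batch_size
  lr <- lr %||% hy$lr
  f <- factor(labels)
  if (nlevels(f) != model$spec$n_classes) {
    stop(sprintf("labels have %d classes; model expects %d",
                 nlevels(f), model$spec$n_classes), call. = FALSE)
  }
  classes <- levels(f)
  y1hot <- diag(length(classes))[as.integer(f), , drop = FALSE]
  n <- dim(windows)[1]

  adam_m <- lapply(model$params, function(x) x * 0)
  adam_v <- lapply(model$params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))

  for (ep in seq_len(epochs)) {
    ep_loss <- 0; ep_correct <- 0
    with_seed(child_seed(seed, ep), {
      ord <- sample(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xt <- windows[idx, , , drop = FALSE]
        xs <- spectrograms[idx, , , drop = FALSE]
        yb <- y1hot[idx, , drop = FALSE]
        fw <- nn_forward(model, xt, xs, train = TRUE)
        ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * length(idx)
        ep_correct <- ep_correct + sum(max.col(fw$probs) == max.col(yb))
        gr <- nn_backward(model, fw, yb)
        step <- step + 1L
        for (nm in names(gr)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - b1^step)
          vhat <- adam_v[[nm]] / (1 - b2^step)
          model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
    })
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         accuracy = ep_correct / n))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, ep_loss / n,
                      ep_correct / n))
    }
    if (!is.null(early_stop) && ep_correct / n >= early_stop) break
  }
  model$classes <- classes
  model$history <- history
  model
}

#' Per-window class probabilities
#'
#' @param model Trained model from [train_model()].
#' @param windows,spectrograms Input arrays.
#' @param batch_size Forward-pass batch size.
#' @return W x n_classes probability matrix (rows sum to 1), columns named
#'   by class when the model has been trained.
#' @export
predict_windows <- function(model, windows, spectrograms, batch_size = 64L) {
  n <- dim(windows)[1]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(model, windows[idx, , , drop = FALSE],
                     spectrograms[idx, , , drop = FALSE], train = FALSE)
    out <- rbind(out, fw$probs)
  }
  if (!is.null(model$classes)) colnames(out) <- model$classes
  out
}

#' Trial-level prediction by window averaging
#'
#' The trial's class probability vector is the mean softmax output over its
#' windows; the label is the argmax, with ties broken toward the lower risk
#' level (classes sorted ascending).
#'
#' @param model Trained model.
#' @param trial An `imu_trial`.
#' @param config Pipeline configuration.
#' @return List with `probs` (named numeric) and `label`.
#' @export
predict_trial <- function(model, trial, config = default_config()) {
  cw <- cohort_windows(list(trial),
                       n_classes = model$spec$n_classes, config = config)
  probs <- predict_windows(model, cw$windows, cw$spectrograms)
  avg <- colMeans(probs)
  ord <- order(colnames(probs))
  avg_sorted <- avg[ord]
  label <- names(avg_sorted)[which.max(avg_sorted)]  # first max = lowest risk
  list(probs = avg, label = label)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per grid point and scores it on a validation set; the
#' best configuration by validation accuracy is returned together with the
#' full result table.
#'
#' @param grid Data frame: one column per hyperparameter to override
#'   (epochs, lr, batch_size, dropout), one row per configuration.
#' @param train_data,val_data Lists with `windows`, `spectrograms`,
#'   `labels`.
#' @param n_classes 2 or 6.
#' @param base Hyperparameter base configuration.
#' @param seed Integer seed.
#' @return List with `best` (hyper list), `results` (one row per grid
#'   point with `val_accuracy`).
#' @export
hyper_search <- function(grid, train_data, val_data, n_classes = 2,
                         base = nn_config_reduced(), seed = 1L) {
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  acc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    hy <- base
    for (nm in names(grid)) hy[[nm]] <- grid[[nm]][r]
    model <- build_model(n_classes, hyper = hy,
                         input_time = dim(train_data$windows)[2],
                         input_channels = dim(train_data$windows)[3],
                         img_dim = dim(train_data$spectrograms)[2:3],
                         seed = child_seed(seed, r))
    model <- train_model(model, train_data$windows, train_data$spectrograms,
                         train_data$labels, seed = child_seed(seed, 100 + r))
    pr <- predict_windows(model, val_data$windows, val_data$spectrograms)
    pred <- colnames(pr)[max.col(pr)]
    acc[r] <- accuracy_score(val_data$labels, pred)
  }
  results <- cbind(grid, val_accuracy = acc)
  best <- base
  for (nm in names(grid)) best[[nm]] <- grid[[nm]][which.max(acc)]
  list(best = best, results = results)
}
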