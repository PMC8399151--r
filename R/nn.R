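# Minimal neural-network engine: 1-D convolution (im2col over BLAS matrix
# multiplies), batch normalization, max pooling, dropout, dense, LSTM, Adam,
# softmax cross-entropy. Data layout: sequence batches are (n, length,
# channels) arrays, dense batches are (n, features) matrices. Correctness is
# pinned by numerical-gradient checks in the test suite.

layer_conv1d <- function(filters, kernel, activation = "relu") {
  list(type = "conv1d", filters = filters, kernel = kernel,
       activation = activation, W = NULL, b = NULL)
}
layer_batchnorm <- function(eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", eps = eps, momentum = momentum,
       gamma = NULL, beta = NULL, run_mean = NULL, run_var = NULL)
}
layer_maxpool <- function(size = 2) {
  if (size != 2) stop("only pooling size 2 is implemented")
  list(type = "maxpool", size = size)
}
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(units, activation = "relu") {
  list(type = "dense", units = units, activation = activation,
       W = NULL, b = NULL)
}
layer_split_windows <- function(n_windows) {
  list(type = "split_windows", n_windows = n_windows)
}
layer_join_windows <- function(n_windows) {
  list(type = "join_windows", n_windows = n_windows)
}
layer_lstm <- function(units) {
  list(type = "lstm", units = units, Wx = NULL, Wh = NULL, b = NULL)
}

nn_param_names <- function(type) {
  switch(type,
         conv1d = c("W", "b"), dense = c("W", "b"),
         batchnorm = c("gamma", "beta"), lstm = c("Wx", "Wh", "b"),
         character(0))
}

# ---- shape propagation and weight initialization ---------------------------

nn_init <- function(layers, input_shape) {
  shape <- input_shape   # c(L, C) for sequences, scalar d for dense input
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    switch(ly$type,
      conv1d = {
        cin <- shape[2]
        fan_in <- ly$kernel * cin
        ly$W <- matrix(stats::rnorm(fan_in * ly$filters, 0, sqrt(2 / fan_in)),
                       fan_in, ly$filters)
        ly$b <- rep(0, ly$filters)
        shape <- c(shape[1], ly$filters)
      },
      batchnorm = {
        ch <- shape[2]
        ly$gamma <- rep(1, ch); ly$beta <- rep(0, ch)
        ly$run_mean <- rep(0, ch); ly$run_var <- rep(1, ch)
      },
      maxpool = { shape <- c(shape[1] %/% ly$size, shape[2]) },
      dropout = {},
      flatten = { shape <- shape[1] * shape[2] },
      split_windows = {
        if (shape[1] %% ly$n_windows != 0) {
          stop("sequence length ", shape[1], " not divisible into ",
               ly$n_windows, " windows")
        }
        shape <- c(shape[1] %/% ly$n_windows, shape[2])
      },
      join_windows = { shape <- c(ly$n_windows, shape) },  # (T, F)
      lstm = {
        d <- shape[2]; h <- ly$units
        ly$Wx <- matrix(stats::rnorm(d * 4 * h, 0, sqrt(1 / d)), d, 4 * h)
        ly$Wh <- matrix(stats::rnorm(h * 4 * h, 0, sqrt(1 / h)), h, 4 * h)
        ly$b <- rep(0, 4 * h)
        ly$b[(h + 1):(2 * h)] <- 1   # forget-gate bias
        shape <- h
      },
      dense = {
        d <- shape[1]
        sdv <- if (identical(ly$activation, "relu")) sqrt(2 / d) else sqrt(1 / d)
        ly$W <- matrix(stats::rnorm(d * ly$units, 0, sdv), d, ly$units)
        ly$b <- rep(0, ly$units)
        shape <- ly$units
      },
      stop("unknown layer type ", ly$type))
    layers[[i]] <- ly
  }
  list(layers = layers, output_shape = shape)
}

# ---- layer forward/backward -------------------------------------------------

act_fwd <- function(z, activation) {
  if (identical(activation, "relu")) pmax(z, 0) else z
}

im2col <- function(xp, n, L_out, k, C) {
  cols <- matrix(0, n * L_out, k * C)
  for (o in seq_len(k)) {
    sl <- xp[, o:(o + L_out - 1), , drop = FALSE]
    dim(sl) <- c(n * L_out, C)
    cols[, ((o - 1) * C + 1):(o * C)] <- sl
  }
  cols
}

fwd_conv1d <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  k <- ly$kernel
  pl <- (k - 1) %/% 2; pr <- k - 1 - pl        # "same" padding
  xp <- array(0, c(n, L + k - 1, C))
  xp[, (pl + 1):(pl + L), ] <- x
  cols <- im2col(xp, n, L, k, C)
  z <- cols %*% ly$W
  z <- sweep(z, 2, ly$b, "+")
  out <- act_fwd(z, ly$activation)
  dim(out) <- c(n, L, ly$filters)
  list(out = out, cache = list(cols = cols, z = z, n = n, L = L, C = C,
                               pl = pl, k = k), layer = ly)
}

bwd_conv1d <- function(ly, cache, dout) {
  n <- cache$n; L <- cache$L; C <- cache$C; k <- cache$k
  dz <- dout
  dim(dz) <- c(n * L, ly$filters)
  if (identical(ly$activation, "relu")) dz <- dz * (cache$z > 0)
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dcols <- dz %*% t(ly$W)
  dxp <- array(0, c(n, L + k - 1, C))
  for (o in seq_len(k)) {
    sl <- dcols[, ((o - 1) * C + 1):(o * C), drop = FALSE]
    dim(sl) <- c(n, L, C)
    dxp[, o:(o + L - 1), ] <- dxp[, o:(o + L - 1), , drop = FALSE] + sl
  }
  dx <- dxp[, (cache$pl + 1):(cache$pl + L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_batchnorm <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  x2 <- x; dim(x2) <- c(n * L, C)
  if (training) {
    mu <- colMeans(x2)
    xc <- sweep(x2, 2, mu)
    va <- colMeans(xc^2)
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * va
  } else {
    mu <- ly$run_mean; va <- ly$run_var
    xc <- sweep(x2, 2, mu)
  }
  ivar <- 1 / sqrt(va + ly$eps)
  xhat <- sweep(xc, 2, ivar, "*")
  out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, ivar = ivar, d = d,
                               training = training), layer = ly)
}

bwd_batchnorm <- function(ly, cache, dout) {
  d <- cache$d
  dout2 <- dout; dim(dout2) <- c(d[1] * d[2], d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dout2 * xhat)
  dbeta <- colSums(dout2)
  dxhat <- sweep(dout2, 2, ly$gamma, "*")
  if (cache$training) {
    N <- nrow(dout2)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dx2 <- sweep(t1 - t2, 2, cache$ivar, "*")
  } else {
    dx2 <- sweep(dxhat, 2, cache$ivar, "*")
  }
  dim(dx2) <- d
  list(dx = dx2, grads = list(gamma = dgamma, beta = dbeta))
}

fwd_maxpool <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  Lo <- L %/% ly$size
  a <- x[, seq(1, ly$size * Lo, by = 2), , drop = FALSE]
  b <- x[, seq(2, ly$size * Lo, by = 2), , drop = FALSE]
  out <- pmax(a, b)
  list(out = out, cache = list(first = a >= b, d = d, Lo = Lo), layer = ly)
}

bwd_maxpool <- function(ly, cache, dout) {
  d <- cache$d; Lo <- cache$Lo
  dx <- array(0, d)
  first <- cache$first
  dx[, seq(1, 2 * Lo, by = 2), ] <- dout * first
  dx[, seq(2, 2 * Lo, by = 2), ] <- dout * !first
  list(dx = dx, grads = NULL)
}

fwd_dropout <- function(ly, x, training) {
  if (!training || ly$rate <= 0) {
    return(list(out = x, cache = list(mask = NULL), layer = ly))
  }
  mask <- array((stats::runif(length(x)) >= ly$rate) / (1 - ly$rate), dim(x))
  list(out = x * mask, cache = list(mask = mask), layer = ly)
}

bwd_dropout <- function(ly, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = NULL)
}

fwd_flatten <- function(ly, x, training) {
  d <- dim(x)
  out <- x; dim(out) <- c(d[1], prod(d[-1]))
  list(out = out, cache = list(d = d), layer = ly)
}

bwd_flatten <- function(ly, cache, dout) {
  dx <- dout; dim(dx) <- cache$d
  list(dx = dx, grads = NULL)
}

# (n, W*Lw, C) -> (n*W, Lw, C): row r = i + (w-1)*n holds window w of sample i
fwd_split_windows <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; W <- ly$n_windows; Lw <- d[2] %/% W; C <- d[3]
  x4 <- x; dim(x4) <- c(n, Lw, W, C)
  z <- aperm(x4, c(1, 3, 2, 4))
  dim(z) <- c(n * W, Lw, C)
  list(out = z, cache = list(d = d), layer = ly)
}

bwd_split_windows <- function(ly, cache, dout) {
  d <- cache$d; n <- d[1]; W <- ly$n_windows; Lw <- d[2] %/% W; C <- d[3]
  dz <- dout; dim(dz) <- c(n, W, Lw, C)
  dx <- aperm(dz, c(1, 3, 2, 4))
  dim(dx) <- d
  list(dx = dx, grads = NULL)
}

# (n*W, F) -> (n, W, F)
fwd_join_windows <- function(ly, x, training) {
  W <- ly$n_windows
  n <- nrow(x) %/% W
  out <- x; dim(out) <- c(n, W, ncol(x))
  list(out = out, cache = list(nf = dim(x)), layer = ly)
}

bwd_join_windows <- function(ly, cache, dout) {
  dx <- dout; dim(dx) <- cache$nf
  list(dx = dx, grads = NULL)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

fwd_lstm <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; Tn <- d[2]; D <- d[3]
  H <- ly$units
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(n, D)
    a <- xt %*% ly$Wx + h %*% ly$Wh
    a <- sweep(a, 2, ly$b, "+")
    gi <- sigmoid(a[, 1:H, drop = FALSE])
    gf <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    go <- sigmoid(a[, (2 * H + 1):(3 * H), drop = FALSE])
    gg <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    steps[[t]] <- list(xt = xt, gi = gi, gf = gf, go = go, gg = gg,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = h, cache = list(steps = steps, d = d), layer = ly)
}

bwd_lstm <- function(ly, cache, dout) {
  d <- cache$d; n <- d[1]; Tn <- d[2]; D <- d[3]; H <- ly$units
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- rep(0, 4 * H)
  dx <- array(0, d)
  dh <- dout; dc <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dc <- dc + dh * st$go * (1 - st$tc^2)
    dgo <- dh * st$tc
    dgf <- dc * st$c_prev
    dgi <- dc * st$gg
    dgg <- dc * st$gi
    da <- cbind(dgi * st$gi * (1 - st$gi),
                dgf * st$gf * (1 - st$gf),
                dgo * st$go * (1 - st$go),
                dgg * (1 - st$gg^2))
    dWx <- dWx + crossprod(st$xt, da)
    dWh <- dWh + crossprod(st$h_prev, da)
    db <- db + colSums(da)
    dx[, t, ] <- da %*% t(ly$Wx)
    dh <- da %*% t(ly$Wh)
    dc <- dc * st$gf
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

fwd_dense <- function(ly, x, training) {
  z <- x %*% ly$W
  z <- sweep(z, 2, ly$b, "+")
  out <- act_fwd(z, ly$activation)
  list(out = out, cache = list(x = x, z = z), layer = ly)
}

bwd_dense <- function(ly, cache, dout) {
  dz <- dout
  if (identical(ly$activation, "relu")) dz <- dz * (cache$z > 0)
  list(dx = dz %*% t(ly$W),
       grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
                conv1d = fwd_conv1d(ly, x, training),
                batchnorm = fwd_batchnorm(ly, x, training),
                maxpool = fwd_maxpool(ly, x, training),
                dropout = fwd_dropout(ly, x, training),
                flatten = fwd_flatten(ly, x, training),
                split_windows = fwd_split_windows(ly, x, training),
                join_windows = fwd_join_windows(ly, x, training),
                lstm = fwd_lstm(ly, x, training),
                dense = fwd_dense(ly, x, training))
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    r <- switch(ly$type,
                conv1d = bwd_conv1d(ly, caches[[i]], dout),
                batchnorm = bwd_batchnorm(ly, caches[[i]], dout),
                maxpool = bwd_maxpool(ly, caches[[i]], dout),
                dropout = bwd_dropout(ly, caches[[i]], dout),
                flatten = bwd_flatten(ly, caches[[i]], dout),
                split_windows = bwd_split_windows(ly, caches[[i]], dout),
                join_windows = bwd_join_windows(ly, caches[[i]], dout),
                lstm = bwd_lstm(ly, caches[[i]], dout),
                dense = bwd_dense(ly, caches[[i]], dout))
    dout <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots for parameter-free layers
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_n_params <- function(layers) {
  sum(vapply(layers, function(ly) {
    sum(vapply(nn_param_names(ly$type), function(p) length(ly[[p]]), numeric(1)))
  }, numeric(1)))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    lapply(stats::setNames(nm = nn_param_names(ly$type)), function(p) {
      list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    })
  })
}

adam_step <- function(layers, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (p in nn_param_names(layers[[i]]$type)) {
      g <- grads[[i]][[p]]
      s <- state[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- s
    }
  }
  list(layers = layers, state = state)
}

# ---- training loop ----------------------------------------------------------

sub_batch <- function(x, idx) {
  if (length(dim(x)) == 3) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
}

# layers: initialized layer list; y: integer class in 1..k; returns layers,
# history (per-epoch mean loss and training accuracy).
nn_fit <- function(layers, x, y, k, epochs, batch_size, lr = 1e-3) {
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), y)] <- 1
  state <- adam_init(layers)
  step <- 0
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      xb <- sub_batch(x, idx)
      yb <- Y[idx, , drop = FALSE]
      fw <- nn_forward(layers, xb, training = TRUE)
      layers <- fw$layers
      p <- softmax_rows(fw$out)
      tot_loss <- tot_loss - sum(log(rowSums(p * yb) + 1e-12))
      tot_correct <- tot_correct +
        sum(max.col(p, ties.method = "first") == max.col(yb, ties.method = "first"))
      dz <- (p - yb) / nrow(yb)
      grads <- nn_backward(layers, fw$caches, dz)
      step <- step + 1
      upd <- adam_step(layers, grads, state, step, lr)
      layers <- upd$layers
      state <- upd$state
    }
    history <- rbind(history, data.frame(epoch = ep, loss = tot_loss / n,
                                         accuracy = tot_correct / n))
  }
  list(layers = layers, history = history)
}

nn_predict_proba <- function(layers, x, chunk = 256) {
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  out <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- nn_forward(layers, sub_batch(x, idx), training = FALSE)
    p <- softmax_rows(fw$out)
    out <- if (is.null(out)) p else rbind(out, p)
  }
  out
}
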