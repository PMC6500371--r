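# Minimal feed-forward engine: 1D convolution (same padding), ReLU, batch
# normalization, dropout, LSTM, global average pooling, dense, with
# reverse-mode gradients and Adam updates.  Everything is expressed as
# BLAS-level matrix products; sequences are [n, L, C] arrays (channels
# last).  Layers are plain lists; forward passes return the (possibly
# updated) layer so batch-norm running statistics thread through training.

glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

orthogonal_init <- function(nrow, ncol) {
  big <- max(nrow, ncol); small <- min(nrow, ncol)
  a <- matrix(stats::rnorm(big * small), big, small)
  qr_ <- qr(a)
  q <- qr.Q(qr_)                      # big x small with orthonormal columns
  r <- diag(qr.R(qr_))
  q <- q * rep(sign(r + (r == 0)), each = big)   # fix the QR sign ambiguity
  if (nrow < ncol) t(q) else q
}

# ---- layer constructors ----------------------------------------------------

layer_conv1d <- function(L, c_in, n_filters, kernel, l2 = 0) {
  k <- kernel
  W <- glorot_uniform(k * c_in, n_filters,
                      fan_in = k * c_in, fan_out = k * n_filters)
  idx <- as.vector(outer(seq_len(k), seq_len(L),
                         function(j, l) l + j - 1L))   # j fastest within l
  list(type = "conv1d", L = L, c_in = c_in, F = n_filters, k = k,
       pad_left = (k - 1L) %/% 2L, l2 = l2, idx = idx,
       params = list(W = W, b = numeric(n_filters)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_bn <- function(C, momentum = 0.99, eps = 1e-3) {
  # Running statistics are stored as biased exponential sums and debiased
  # by 1 - momentum^t at evaluation time, so short training runs already
  # see a faithful average of the batch statistics observed so far.
  list(type = "bn", C = C, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       running_mean = rep(0, C), running_var = rep(0, C), bn_steps = 0L)
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate,
                                     params = list())

layer_lstm <- function(c_in, units, return_sequences) {
  H <- units
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1    # forget-gate bias starts open
  list(type = "lstm", c_in = c_in, H = H,
       return_sequences = return_sequences,
       params = list(W = glorot_uniform(c_in, 4L * H),
                     U = orthogonal_init(H, 4L * H),
                     b = b))
}

layer_gap <- function() list(type = "gap", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(c_in, units) {
  list(type = "dense", c_in = c_in, units = units,
       params = list(W = glorot_uniform(c_in, units), b = numeric(units)))
}

# ---- forward ---------------------------------------------------------------

# Returns list(y, cache, layer).  `training` switches dropout on and batch
# norm to batch statistics (with running-stat updates).
nn_forward <- function(layer, x, training) {
  switch(layer$type,
    conv1d = {
      d <- dim(x); n <- d[1]; L <- layer$L; k <- layer$k; C <- layer$c_in
      xp <- array(0, c(n, L + k - 1L, C))
      xp[, layer$pad_left + seq_len(L), ] <- x
      cols <- xp[, layer$idx, , drop = FALSE]       # [n, k*L, C], j fastest
      dim(cols) <- c(n, k, L, C)
      cols <- aperm(cols, c(1, 3, 2, 4))            # [n, L, k, C]
      dim(cols) <- c(n * L, k * C)
      y <- cols %*% layer$params$W
      y <- y + rep(layer$params$b, each = n * L)
      dim(y) <- c(n, L, layer$F)
      list(y = y, cache = list(cols = cols, n = n), layer = layer)
    },
    relu = {
      y <- x; y[y < 0] <- 0
      list(y = y, cache = list(mask = x > 0), layer = layer)
    },
    bn = {
      d <- dim(x)
      xm <- x; dim(xm) <- c(prod(d[-length(d)]), d[length(d)])   # [m, C]
      m <- nrow(xm)
      if (training) {
        mu <- colMeans(xm)
        xc <- xm - rep(mu, each = m)
        v <- colMeans(xc * xc)                       # biased batch variance
        layer$running_mean <- layer$momentum * layer$running_mean +
          (1 - layer$momentum) * mu
        layer$running_var <- layer$momentum * layer$running_var +
          (1 - layer$momentum) * v
        layer$bn_steps <- layer$bn_steps + 1L
      } else {
        if (layer$bn_steps == 0L) {                  # untrained: identity stats
          mu <- rep(0, layer$C); v <- rep(1, layer$C)
        } else {
          debias <- 1 - layer$momentum^layer$bn_steps
          mu <- layer$running_mean / debias
          v <- layer$running_var / debias
        }
        xc <- xm - rep(mu, each = m)
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- xc * rep(inv_sd, each = m)
      y <- xhat * rep(layer$params$gamma, each = m) +
        rep(layer$params$beta, each = m)
      dim(y) <- d
      list(y = y,
           cache = if (training) list(xhat = xhat, inv_sd = inv_sd,
                                      m = m, d = d) else NULL,
           layer = layer)
    },
    dropout = {
      if (!training || layer$rate == 0)
        return(list(y = x, cache = NULL, layer = layer))
      keep <- 1 - layer$rate
      mask <- (stats::runif(length(x)) < keep) / keep
      dim(mask) <- dim(x) %||% NULL
      list(y = x * mask, cache = list(mask = mask), layer = layer)
    },
    lstm = {
      d <- dim(x); n <- d[1]; L <- d[2]; H <- layer$H
      W <- layer$params$W; U <- layer$params$U; b <- layer$params$b
      h <- matrix(0, n, H); cs <- matrix(0, n, H)
      steps <- vector("list", L)
      if (layer$return_sequences) ys <- array(0, c(n, L, H))
      for (t in seq_len(L)) {
        x_t <- x[, t, , drop = TRUE]
        if (is.null(dim(x_t))) dim(x_t) <- c(n, layer$c_in)
        z <- x_t %*% W + h %*% U + rep(b, each = n)
        i_g <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
        f_g <- 1 / (1 + exp(-z[, H + 1:H, drop = FALSE]))
        g_g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
        o_g <- 1 / (1 + exp(-z[, 3 * H + 1:H, drop = FALSE]))
        c_prev <- cs
        cs <- f_g * c_prev + i_g * g_g
        tc <- tanh(cs)
        h_prev <- h
        h <- o_g * tc
        steps[[t]] <- list(x_t = x_t, i = i_g, f = f_g, g = g_g, o = o_g,
                           c_prev = c_prev, tc = tc, h_prev = h_prev)
        if (layer$return_sequences) ys[, t, ] <- h
      }
      list(y = if (layer$return_sequences) ys else h,
           cache = list(steps = steps, n = n, L = L), layer = layer)
    },
    gap = {
      d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
      y <- matrix(0, n, C)
      for (cc in seq_len(C)) {
        xc <- x[, , cc, drop = FALSE]; dim(xc) <- c(n, L)
        y[, cc] <- rowMeans(xc)
      }
      list(y = y, cache = list(d = d), layer = layer)
    },
    flatten = {
      d <- dim(x)
      y <- x; dim(y) <- c(d[1], prod(d[-1]))
      list(y = y, cache = list(d = d), layer = layer)
    },
    dense = {
      n <- nrow(x)
      y <- x %*% layer$params$W + rep(layer$params$b, each = n)
      list(y = y, cache = list(x = x), layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

# ---- backward --------------------------------------------------------------

# Returns list(dx, grads) with grads matching layer$params by name.
nn_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv1d = {
      n <- cache$n; L <- layer$L; k <- layer$k
      C <- layer$c_in; F_ <- layer$F
      dim(dy) <- c(n * L, F_)
      dW <- crossprod(cache$cols, dy)
      if (layer$l2 > 0) dW <- dW + 2 * layer$l2 * layer$params$W
      db <- colSums(dy)
      dcols <- dy %*% t(layer$params$W)              # [n*L, k*C]
      dim(dcols) <- c(n, L, k, C)
      dcols <- aperm(dcols, c(1, 3, 2, 4))           # [n, k, L, C]
      dxp <- array(0, c(n, L + k - 1L, C))
      for (j in seq_len(k))
        dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), ] +
          dcols[, j, , , drop = TRUE]
      dx <- dxp[, layer$pad_left + seq_len(L), , drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dy * cache$mask, grads = list()),
    bn = {
      m <- cache$m; d <- cache$d
      dym <- dy; dim(dym) <- c(m, d[length(d)])
      xhat <- cache$xhat
      dgamma <- colSums(dym * xhat)
      dbeta <- colSums(dym)
      g_inv <- layer$params$gamma * cache$inv_sd
      dx <- rep(g_inv, each = m) *
        (dym - rep(dbeta / m, each = m) - xhat * rep(dgamma / m, each = m))
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    dropout = {
      if (is.null(cache)) return(list(dx = dy, grads = list()))
      list(dx = dy * cache$mask, grads = list())
    },
    lstm = {
      n <- cache$n; L <- cache$L; H <- layer$H
      W <- layer$params$W; U <- layer$params$U
      dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, H, 4L * H)
      db <- numeric(4L * H)
      dx <- array(0, c(n, L, layer$c_in))
      dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
      for (t in rev(seq_len(L))) {
        st <- cache$steps[[t]]
        dh <- dh_next
        if (layer$return_sequences) dh <- dh + dy[, t, , drop = TRUE]
        else if (t == L) dh <- dh + dy
        do_ <- dh * st$tc
        dc <- dc_next + dh * st$o * (1 - st$tc^2)
        di <- dc * st$g
        dg <- dc * st$i
        df <- dc * st$c_prev
        dc_next <- dc * st$f
        dz <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    dg * (1 - st$g^2),
                    do_ * st$o * (1 - st$o))
        dW <- dW + crossprod(st$x_t, dz)
        dU <- dU + crossprod(st$h_prev, dz)
        db <- db + colSums(dz)
        dx[, t, ] <- dz %*% t(W)
        dh_next <- dz %*% t(U)
      }
      list(dx = dx, grads = list(W = dW, U = dU, b = db))
    },
    gap = {
      d <- cache$d; n <- d[1]; L <- d[2]; C <- d[3]
      dx <- array(0, d)
      for (l in seq_len(L)) dx[, l, ] <- dy / L
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- dy; dim(dx) <- cache$d
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = dy %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    stop("unknown layer type: ", layer$type))
}

# ---- loss and optimizer ----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy on one-hot targets; returns loss (data term only) and
# dlogits.  y01 is the 0/1 label vector.
softmax_xent <- function(logits, y01) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  Y <- matrix(0, n, 2L); Y[idx] <- 1
  list(loss = loss, dlogits = (p - Y) / n)
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(layers, grads_list, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    gs <- grads_list[[i]]
    if (!length(gs)) next
    for (nm in names(gs)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gs[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * gs[[nm]]^2
      state[[i]][[nm]] <- st
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}

# Sum of squared conv-kernel weights times their L2 coefficients (the
# penalty term added to the training loss).
l2_penalty <- function(layers) {
  s <- 0
  for (l in layers)
    if (l$type == "conv1d" && l$l2 > 0) s <- s + l$l2 * sum(l$params$W^2)
  s
}
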