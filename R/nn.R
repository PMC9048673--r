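# A small deterministic reverse-mode neural network engine in base R.
# No R autodiff backend is available in this stack, so the layer
# vocabulary of the model definitions (conv1D, dense, max-pool,
# global-max-pool, batch-norm, dropout, ReLU, skip blocks) is
# implemented directly with vectorized matrix operations.
#
# Tensor conventions: positional activations are 3D arrays
# (batch, length, channels); flat activations are (batch, features)
# matrices. Convolutions are "valid" (no padding), stride 1, realized
# via im2col so the heavy lifting is one matrix product per layer.
#
# The backward pass takes a ReLU rule argument: "backprop" (standard),
# "guided" (pass only where forward activation > 0 AND incoming signal
# > 0), "deconv" (pass only where incoming signal > 0) and "deeplift"
# (rescale rule, multipliers from a zero-baseline reference forward
# pass). All other layers are linear or handled gradient-style, so
# multipliers propagate exactly like gradients through them.

init_layer <- function(spec, shape) {
  # shape: c(L, C) for positional input, single integer for flat
  l <- spec
  if (spec$type == "conv") {
    if (length(shape) != 2) stopf("conv layer requires positional input")
    cin <- shape[2]
    if (spec$width > shape[1])
      stopf("conv width %d exceeds input length %d", spec$width, shape[1])
    l$W <- matrix(rnorm(spec$width * cin * spec$filters) *
                    sqrt(2 / (spec$width * cin)),
                  spec$width * cin, spec$filters)
    l$b <- rep(0.1, spec$filters)   # slight positive bias guards ReLUs
    l$cin <- cin
    shape <- c(shape[1] - spec$width + 1, spec$filters)
  } else if (spec$type == "dense") {
    if (length(shape) != 1) stopf("dense layer requires flat input")
    l$W <- matrix(rnorm(shape * spec$units) * sqrt(2 / shape),
                  shape, spec$units)
    l$b <- rep(0.1, spec$units)
    shape <- spec$units
  } else if (spec$type == "max_pool") {
    if (length(shape) != 2) stopf("max_pool requires positional input")
    if (spec$width > shape[1])
      stopf("max_pool width %d exceeds input length %d", spec$width, shape[1])
    shape <- c(shape[1] %/% spec$width, shape[2])
  } else if (spec$type == "global_max_pool") {
    if (length(shape) != 2) stopf("global_max_pool requires positional input")
    shape <- shape[2]
  } else if (spec$type == "batch_norm") {
    nc <- shape[length(shape)]
    l$gamma <- rep(1, nc); l$beta <- rep(0, nc)
    l$running_mean <- rep(0, nc); l$running_var <- rep(1, nc)
    l$momentum <- 0.99; l$eps <- 1e-5
  } else if (spec$type == "flatten") {
    if (length(shape) == 2) shape <- shape[1] * shape[2]
  } else if (spec$type == "skip") {
    sub <- build_layers(spec$layers, shape)
    if (!identical(sub$shape, shape))
      stopf("skip block output shape (%s) must match its input shape (%s)",
            paste(sub$shape, collapse = "x"), paste(shape, collapse = "x"))
    l$layers <- sub$layers
  } else if (!spec$type %in% c("relu", "dropout")) {
    stopf("unknown layer type '%s'", spec$type)
  }
  list(layer = l, shape = shape)
}

build_layers <- function(specs, shape) {
  layers <- list()
  for (spec in specs) {
    # auto-insert flatten before dense layers fed a positional tensor
    if (spec$type == "dense" && length(shape) == 2) {
      fl <- init_layer(list(type = "flatten"), shape)
      layers[[length(layers) + 1]] <- fl$layer
      shape <- fl$shape
    }
    built <- init_layer(spec, shape)
    layers[[length(layers) + 1]] <- built$layer
    shape <- built$shape
  }
  list(layers = layers, shape = shape)
}

conv_forward <- function(l, X) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  w <- l$width; Lo <- L - w + 1
  Xc <- matrix(0, B * Lo, w * C)
  for (j in seq_len(w))
    Xc[, ((j - 1) * C + 1):(j * C)] <-
      matrix(X[, j:(j + Lo - 1), , drop = FALSE], B * Lo, C)
  Z <- Xc %*% l$W
  Z <- Z + rep(l$b, each = nrow(Z))
  list(out = array(Z, c(B, Lo, l$filters)),
       cache = list(Xc = Xc, B = B, L = L, Lo = Lo, C = C))
}

conv_backward <- function(l, cache, dOut) {
  dZ <- matrix(dOut, cache$B * cache$Lo, l$filters)
  gW <- crossprod(cache$Xc, dZ)
  gb <- colSums(dZ)
  dXc <- tcrossprod(dZ, l$W)
  dX <- array(0, c(cache$B, cache$L, cache$C))
  w <- l$width; C <- cache$C; Lo <- cache$Lo
  for (j in seq_len(w))
    dX[, j:(j + Lo - 1), ] <- dX[, j:(j + Lo - 1), , drop = FALSE] +
      array(dXc[, ((j - 1) * C + 1):(j * C)], c(cache$B, Lo, C))
  list(dX = dX, grads = list(W = gW, b = gb))
}

relu_backward_rule <- function(dOut, Z, rule, Z_ref = NULL) {
  switch(rule,
    backprop = dOut * (Z > 0),
    guided   = dOut * (Z > 0) * (dOut > 0),
    deconv   = dOut * (dOut > 0),
    deeplift = {
      delta <- Z - Z_ref
      m <- ifelse(abs(delta) > 1e-7,
                  (pmax(Z, 0) - pmax(Z_ref, 0)) / delta,
                  as.numeric(Z > 0))
      dOut * m
    },
    stopf("unknown ReLU backward rule '%s'", rule))
}

layer_forward <- function(l, X, training) {
  type <- l$type
  if (type == "conv") {
    r <- conv_forward(l, X)
    return(list(out = r$out, cache = r$cache, layer = l))
  }
  if (type == "dense") {
    Z <- X %*% l$W
    Z <- Z + rep(l$b, each = nrow(Z))
    return(list(out = Z, cache = list(X = X), layer = l))
  }
  if (type == "relu") {
    out <- X
    out[out < 0] <- 0
    return(list(out = out, cache = list(Z = X), layer = l))
  }
  if (type == "flatten") {
    d <- dim(X)
    return(list(out = matrix(X, d[1], prod(d[-1])),
                cache = list(dims = d), layer = l))
  }
  if (type == "max_pool") {
    d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]; p <- l$width
    Lo <- L %/% p
    out <- array(-Inf, c(B, Lo, C)); arg <- array(1L, c(B, Lo, C))
    for (j in seq_len(p)) {
      slice <- X[, seq(j, Lo * p, by = p), , drop = FALSE]
      upd <- slice > out
      out[upd] <- slice[upd]; arg[upd] <- j
    }
    return(list(out = out, cache = list(arg = arg, dims = d, Lo = Lo),
                layer = l))
  }
  if (type == "global_max_pool") {
    d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
    Xm <- matrix(aperm(X, c(2, 1, 3)), L, B * C)   # columns = (b, c) pairs
    idx <- max.col(t(Xm), ties.method = "first")
    vals <- Xm[cbind(idx, seq_len(B * C))]
    return(list(out = matrix(vals, B, C),
                cache = list(idx = idx, dims = d), layer = l))
  }
  if (type == "batch_norm") {
    flat3d <- length(dim(X)) == 3
    Xm <- if (flat3d) matrix(X, prod(dim(X)[1:2]), dim(X)[3]) else X
    if (training) {
      mu <- colMeans(Xm)
      v <- colMeans(sweep(Xm, 2, mu)^2)
      l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
      l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
    } else {
      mu <- l$running_mean; v <- l$running_var
    }
    inv_sd <- 1 / sqrt(v + l$eps)
    xhat <- sweep(sweep(Xm, 2, mu), 2, inv_sd, "*")
    outm <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
    out <- if (flat3d) array(outm, dim(X)) else outm
    return(list(out = out,
                cache = list(xhat = xhat, inv_sd = inv_sd, dims = dim(X),
                             flat3d = flat3d, training = training),
                layer = l))
  }
  if (type == "dropout") {
    if (training && l$rate > 0) {
      keep <- 1 - l$rate
      mask <- (array(runif(length(X)), dim(X) %||% length(X)) < keep) / keep
      return(list(out = X * mask, cache = list(mask = mask), layer = l))
    }
    return(list(out = X, cache = list(mask = NULL), layer = l))
  }
  if (type == "skip") {
    r <- layers_forward(l$layers, X, training)
    return(list(out = X + r$out, cache = list(sub = r$caches), layer =
                  { l$layers <- r$layers; l }))
  }
  stopf("unknown layer type '%s'", type)
}

layers_forward <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X, training)
    X <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

layer_backward <- function(l, cache, dOut, rule = "backprop",
                           ref_cache = NULL) {
  type <- l$type
  if (type == "conv") return(conv_backward(l, cache, dOut))
  if (type == "dense") {
    gW <- crossprod(cache$X, dOut)
    gb <- colSums(dOut)
    return(list(dX = tcrossprod(dOut, l$W), grads = list(W = gW, b = gb)))
  }
  if (type == "relu") {
    return(list(dX = relu_backward_rule(dOut, cache$Z, rule,
                                        if (!is.null(ref_cache)) ref_cache$Z),
                grads = NULL))
  }
  if (type == "flatten") {
    return(list(dX = array(dOut, cache$dims), grads = NULL))
  }
  if (type == "max_pool") {
    d <- cache$dims; p <- l$width; Lo <- cache$Lo
    dX <- array(0, d)
    for (j in seq_len(p))
      dX[, seq(j, Lo * p, by = p), ] <- dOut * (cache$arg == j)
    return(list(dX = dX, grads = NULL))
  }
  if (type == "global_max_pool") {
    d <- cache$dims; B <- d[1]; C <- d[3]
    dX <- array(0, d)
    bc <- seq_len(B * C)
    b <- ((bc - 1) %% B) + 1
    cc <- ((bc - 1) %/% B) + 1
    dX[cbind(b, cache$idx, cc)] <- as.vector(dOut)
    return(list(dX = dX, grads = NULL))
  }
  if (type == "batch_norm") {
    dOutm <- if (cache$flat3d)
      matrix(dOut, prod(cache$dims[1:2]), cache$dims[3]) else dOut
    dgamma <- colSums(dOutm * cache$xhat)
    dbeta <- colSums(dOutm)
    if (cache$training) {
      N <- nrow(dOutm)
      dxhat <- sweep(dOutm, 2, l$gamma, "*")
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dXm <- sweep(t1 - t2, 2, cache$inv_sd, "*")
    } else {
      dXm <- sweep(dOutm, 2, l$gamma * cache$inv_sd, "*")
    }
    dX <- if (cache$flat3d) array(dXm, cache$dims) else dXm
    return(list(dX = dX, grads = list(gamma = dgamma, beta = dbeta)))
  }
  if (type == "dropout") {
    dX <- if (is.null(cache$mask)) dOut else dOut * cache$mask
    return(list(dX = dX, grads = NULL))
  }
  if (type == "skip") {
    r <- layers_backward(l$layers, cache$sub, dOut, rule,
                         if (!is.null(ref_cache)) ref_cache$sub)
    return(list(dX = dOut + r$dX, grads = list(sub = r$grads)))
  }
  stopf("unknown layer type '%s'", type)
}

layers_backward <- function(layers, caches, dOut, rule = "backprop",
                            ref_caches = NULL) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dOut, rule,
                        if (!is.null(ref_caches)) ref_caches[[i]])
    dOut <- r$dX
    grads[i] <- list(r$grads)   # keep NULL placeholders for param-free layers
  }
  list(dX = dOut, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- optimizer ------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    st <- list()
    for (p in c("W", "b", "gamma", "beta"))
      if (!is.null(l[[p]])) st[[p]] <- list(m = l[[p]] * 0, v = l[[p]] * 0)
    if (l$type == "skip") st$sub <- adam_init(l$layers)
    st
  })
}

apply_updates <- function(layers, grads, state, lr, t, optimizer,
                          b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (layers[[i]]$type == "skip") {
      r <- apply_updates(layers[[i]]$layers, g$sub, state[[i]]$sub, lr, t,
                         optimizer, b1, b2, eps)
      layers[[i]]$layers <- r$layers
      state[[i]]$sub <- r$state
      next
    }
    for (p in names(g)) {
      if (optimizer == "sgd") {
        layers[[i]][[p]] <- layers[[i]][[p]] - lr * g[[p]]
      } else {
        st <- state[[i]][[p]]
        st$m <- b1 * st$m + (1 - b1) * g[[p]]
        st$v <- b2 * st$v + (1 - b2) * g[[p]]^2
        mhat <- st$m / (1 - b1^t)
        vhat <- st$v / (1 - b2^t)
        layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
        state[[i]][[p]] <- st
      }
    }
  }
  list(layers = layers, state = state)
}
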