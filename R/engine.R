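# Minimal CNN engine: layer-by-layer forward/backward passes over the
# RcppArmadillo kernels, Adam updates, soft-Jaccard and cross-entropy
# losses.  Inputs are H x W x C arrays; dense layers operate on the
# flattened vector.  This engine backs both the FCEDN segmenter and the
# adaptive CNN classifier, so it stays deliberately small: stride-1
# same-padding convolutions, window-stride max pooling, nearest-
# neighbour unpooling, inverted dropout, per-channel batch
# normalisation, dense layers, no autograd.

# ---- layer constructors (weights filled by engine_init) ----

layer_conv <- function(kernel_count, kernel_size, activation = "relu",
                       batchnorm = FALSE) {
  list(type = "conv", f = as.integer(kernel_count), k = as.integer(kernel_size),
       activation = activation, batchnorm = batchnorm)
}
layer_maxpool <- function(pool_size) list(type = "maxpool", p = as.integer(pool_size))
layer_upsample <- function(pool_size) list(type = "upsample", p = as.integer(pool_size))
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(units, activation = "none") {
  list(type = "dense", units = as.integer(units), activation = activation)
}

engine_model <- function(layers, input_dim, loss = c("jaccard", "softmax"),
                         eps = 1) {
  structure(
    list(layers = layers, input_dim = as.integer(input_dim),
         loss = match.arg(loss), eps = eps, initialized = FALSE),
    class = "lf_engine"
  )
}

# He-normal initialisation, fully seeded; also resolves per-layer
# input shapes so dense layers know their fan-in.
engine_init <- function(model, seed = 1L) {
  with_seed(seed, {
    dim_now <- model$input_dim            # c(H, W, C) or scalar length
    for (i in seq_along(model$layers)) {
      ly <- model$layers[[i]]
      if (ly$type == "conv") {
        cin <- dim_now[3]
        fan_in <- ly$k * ly$k * cin
        ly$W <- matrix(rnorm(fan_in * ly$f, sd = sqrt(2 / fan_in)), fan_in, ly$f)
        ly$b <- rep(0, ly$f)
        if (isTRUE(ly$batchnorm)) {
          ly$gamma <- rep(1, ly$f); ly$beta <- rep(0, ly$f)
          ly$run_mean <- rep(0, ly$f); ly$run_var <- rep(1, ly$f)
        }
        dim_now <- c(dim_now[1], dim_now[2], ly$f)
      } else if (ly$type == "maxpool") {
        if (dim_now[1] %% ly$p != 0 || dim_now[2] %% ly$p != 0) {
          lf_stop(sprintf(
            "input %dx%d not divisible by pool size %d at layer %d",
            dim_now[1], dim_now[2], ly$p, i
          ))
        }
        dim_now <- c(dim_now[1] %/% ly$p, dim_now[2] %/% ly$p, dim_now[3])
      } else if (ly$type == "upsample") {
        dim_now <- c(dim_now[1] * ly$p, dim_now[2] * ly$p, dim_now[3])
      } else if (ly$type == "flatten") {
        dim_now <- prod(dim_now)
      } else if (ly$type == "dense") {
        fan_in <- dim_now[1]
        ly$W <- matrix(rnorm(fan_in * ly$units, sd = sqrt(2 / fan_in)),
                       fan_in, ly$units)
        ly$b <- rep(0, ly$units)
        dim_now <- ly$units
      }
      model$layers[[i]] <- ly
    }
    model$output_dim <- dim_now
    model$initialized <- TRUE
    model
  })
}

apply_act <- function(z, act) {
  switch(act,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    none = z
  )
}

# forward pass; when train = TRUE dropout masks are drawn from the
# current RNG stream and caches are kept for backward()
engine_forward <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      pre <- lf_conv_fwd(x, ly$W, ly$b, ly$k)
      bn <- NULL
      if (isTRUE(ly$batchnorm)) {
        bn <- bn_forward(pre, ly, train)
        out_pre <- bn$out
      } else out_pre <- pre
      out <- apply_act(out_pre, ly$activation)
      caches[[i]] <- list(x = x, pre = out_pre, bn = bn)
      x <- out
    } else if (ly$type == "maxpool") {
      mp <- lf_maxpool_fwd(x, ly$p)
      caches[[i]] <- list(idx = mp$idx, H = dim(x)[1], W = dim(x)[2])
      x <- mp$out
    } else if (ly$type == "upsample") {
      x <- lf_upsample_fwd(x, ly$p)
    } else if (ly$type == "dropout") {
      if (train && ly$rate > 0) {
        mask <- (runif(length(x)) >= ly$rate) / (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        x <- x * array(mask, dim(x) %||% length(x))
      }
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(dims = dim(x))
      x <- as.vector(x)
    } else if (ly$type == "dense") {
      z <- as.vector(crossprod(ly$W, x)) + ly$b
      caches[[i]] <- list(x = x, pre = z)
      x <- apply_act(z, ly$activation)
    }
  }
  list(out = x, caches = caches)
}

bn_forward <- function(pre, ly, train) {
  d <- dim(pre); n <- d[1] * d[2]
  flat <- matrix(pre, n, d[3])
  if (train) {
    mu <- colMeans(flat)
    v <- colMeans(flat^2) - mu^2
  } else {
    mu <- ly$run_mean; v <- ly$run_var
  }
  xhat <- sweep(sweep(flat, 2, mu), 2, sqrt(v + 1e-5), "/")
  out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
  list(out = array(out, d), xhat = xhat, mu = mu, var = v, train = train)
}

bn_backward <- function(dout, cache, ly) {
  d <- dim(dout); n <- d[1] * d[2]
  dflat <- matrix(dout, n, d[3])
  dgamma <- colSums(dflat * cache$xhat)
  dbeta <- colSums(dflat)
  if (!cache$train) {
    dx <- sweep(sweep(dflat, 2, ly$gamma, "*"), 2, sqrt(cache$var + 1e-5), "/")
    return(list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta))
  }
  istd <- 1 / sqrt(cache$var + 1e-5)
  dxhat <- sweep(dflat, 2, ly$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, istd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

act_backward <- function(dout, out_pre, act) {
  switch(act,
    relu = dout * (out_pre > 0),
    sigmoid = {
      s <- 1 / (1 + exp(-out_pre))
      dout * s * (1 - s)
    },
    none = dout
  )
}

engine_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      cache <- caches[[i]]
      dpre <- act_backward(dout, cache$pre, ly$activation)
      g_extra <- NULL
      if (isTRUE(ly$batchnorm)) {
        bb <- bn_backward(dpre, cache$bn, ly)
        dpre <- bb$dx
        g_extra <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
      }
      bw <- lf_conv_bwd(cache$x, ly$W, dpre, ly$k)
      grads[[i]] <- c(list(dW = bw$dW, db = as.vector(bw$db)), g_extra)
      dout <- bw$dx
    } else if (ly$type == "maxpool") {
      cache <- caches[[i]]
      dout <- lf_maxpool_bwd(dout, cache$idx, cache$H, cache$W, ly$p)
    } else if (ly$type == "upsample") {
      dout <- lf_upsample_bwd(dout, ly$p)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) {
        dout <- dout * array(caches[[i]]$mask, dim(dout) %||% length(dout))
      }
    } else if (ly$type == "flatten") {
      dout <- array(dout, caches[[i]]$dims)
    } else if (ly$type == "dense") {
      cache <- caches[[i]]
      dz <- act_backward(dout, cache$pre, ly$activation)
      grads[[i]] <- list(dW = outer(cache$x, dz), db = dz)
      dout <- as.vector(ly$W %*% dz)
    }
  }
  grads
}

# ---- losses ----

# smoothed Jaccard loss for a probability map vs a binary mask;
# returns the loss and the gradient w.r.t. the probabilities
loss_soft_jaccard <- function(probs, mask, eps) {
  p <- as.vector(probs); y <- as.vector(mask)
  inter <- sum(p * y)
  uni <- sum(y) + sum(p) - inter
  j <- (eps + inter) / (eps + uni)
  dj_dp <- (y * (eps + uni) - (eps + inter) * (1 - y)) / (eps + uni)^2
  list(loss = 1 - j, dprobs = array(-dj_dp, dim(probs)), jaccard = j)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

loss_cross_entropy <- function(logits, target_index) {
  p <- softmax_vec(logits)
  dlogits <- p
  dlogits[target_index] <- dlogits[target_index] - 1
  list(loss = -log(max(p[target_index], 1e-12)), dlogits = dlogits, probs = p)
}

# ---- Adam ----

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (!ly$type %in% c("conv", "dense")) return(NULL)
    st <- list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    if (isTRUE(ly$batchnorm)) {
      st$mg <- ly$gamma * 0; st$vg <- ly$gamma * 0
      st$mB <- ly$beta * 0; st$vB <- ly$beta * 0
    }
    st
  })
}

adam_update <- function(val, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, e = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(val = val - lr * mhat / (sqrt(vhat) + e), m = m, v = v)
}

adam_step <- function(model, grads, state, lr, t) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- model$layers[[i]]; st <- state[[i]]
    up <- adam_update(ly$W, g$dW, st$mW, st$vW, lr, t)
    ly$W <- up$val; st$mW <- up$m; st$vW <- up$v
    up <- adam_update(ly$b, g$db, st$mb, st$vb, lr, t)
    ly$b <- up$val; st$mb <- up$m; st$vb <- up$v
    if (!is.null(g$dgamma)) {
      up <- adam_update(ly$gamma, g$dgamma, st$mg, st$vg, lr, t)
      ly$gamma <- up$val; st$mg <- up$m; st$vg <- up$v
      up <- adam_update(ly$beta, g$dbeta, st$mB, st$vB, lr, t)
      ly$beta <- up$val; st$mB <- up$m; st$vB <- up$v
    }
    model$layers[[i]] <- ly; state[[i]] <- st
  }
  list(model = model, state = state)
}

grads_accumulate <- function(acc, g, scale = 1) {
  if (is.null(acc)) {
    return(lapply(g, function(gi) {
      if (is.null(gi)) NULL else lapply(gi, function(x) x * scale)
    }))
  }
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (nm in names(g[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] + g[[i]][[nm]] * scale
  }
  acc
}

# update batchnorm running stats from one forward cache
bn_track <- function(model, caches, momentum = 0.1) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv" && isTRUE(ly$batchnorm) && !is.null(caches[[i]]$bn)) {
      bn <- caches[[i]]$bn
      ly$run_mean <- (1 - momentum) * ly$run_mean + momentum * bn$mu
      ly$run_var <- (1 - momentum) * ly$run_var + momentum * bn$var
      model$layers[[i]] <- ly
    }
  }
  model
}

# generic seeded SGD/Adam training loop over a list of examples.
# target_fn(output, target) must return list(loss, d_out) where d_out is
# the gradient at the network output (post-activation).
engine_train_loop <- function(model, inputs, targets, epochs, batch_size,
                              lr, seed, loss_fn) {
  if (epochs == 0) return(list(model = model, history = numeric(0)))
  state <- adam_init(model)
  history <- numeric(epochs)
  t_step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(inputs))
      losses <- numeric(0)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (b in batches) {
        acc <- NULL
        for (ix in b) {
          fw <- engine_forward(model, inputs[[ix]], train = TRUE)
          lo <- loss_fn(fw$out, targets[[ix]])
          losses <- c(losses, lo$loss)
          g <- engine_backward(model, fw$caches, lo$d_out)
          acc <- grads_accumulate(acc, g, scale = 1 / length(b))
          model <- bn_track(model, fw$caches)
        }
        t_step <- t_step + 1L
        st <- adam_step(model, acc, state, lr, t_step)
        model <- st$model; state <- st$state
      }
      history[ep] <- mean(losses)
    }
  })
  list(model = model, history = history)
}

engine_count_params <- function(model) {
  sum(vapply(model$layers, function(ly) {
    n <- 0
    if (!is.null(ly$W)) n <- n + length(ly$W) + length(ly$b)
    if (isTRUE(ly$batchnorm) && !is.null(ly$gamma)) {
      n <- n + length(ly$gamma) + length(ly$beta)
    }
    n
  }, numeric(1)))
}
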