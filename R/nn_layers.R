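# Minimal neural-network framework used by the dual-branch classifier.
#
# Conventions:
#  - 2-D feature maps are arrays dim = c(C, H, W, N) (channel fastest); 1-D
#    (waveform) stages reuse the same layout with H = 1.
#  - Vector features are (d, N) matrices.
#  - A layer is a list with members:
#      init(rng draws allowed)           -> params (possibly empty list)
#      state0()                          -> persistent state (BN running stats)
#      fwd(params, state, x, training)   -> list(y, cache, state)
#      bwd(params, cache, dy)            -> list(dx, grads)
#    Gradients mirror the parameter tree exactly.
#  - All parameter initialization draws from the current RNG stream, so model
#    construction wrapped in with_seed() is fully reproducible.
#
# Every backward pass is validated against central finite differences in the
# test suite; that numeric check is the correctness oracle for this file.

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

# ---- convolution (2-D, used for 1-D stages with kh = 1) ---------------------

nn_conv <- function(c_in, c_out, kh, kw, sh = 1L, sw = 1L, ph = 0L, pw = 0L,
                    bias = TRUE) {
  force(c_in); force(c_out); force(kh); force(kw); force(sh); force(sw)
  force(ph); force(pw); force(bias)
  list(
    type = "conv",
    init = function() {
      w <- array(he_init(c_in * kh * kw, c_in * kh * kw * c_out),
                 c(c_in, kh, kw, c_out))
      p <- list(w = w)
      if (bias) p$b <- numeric(c_out)
      p
    },
    state0 = function() list(),
    fwd = function(params, state, x, training) {
      xd <- dim(x)
      col <- .im2col_cpp(x, xd, kh, kw, sh, sw, ph, pw)
      wm <- matrix(params$w, c_in * kh * kw, c_out)
      y <- crossprod(wm, col)                      # c_out x (oH*oW*N)
      if (bias) y <- y + params$b
      oh <- (xd[2] + 2 * ph - kh) %/% sh + 1L
      ow <- (xd[3] + 2 * pw - kw) %/% sw + 1L
      dim(y) <- c(c_out, oh, ow, xd[4])
      list(y = y, cache = list(col = col, xd = xd), state = state)
    },
    bwd = function(params, cache, dy) {
      dym <- matrix(dy, c_out)
      wm <- matrix(params$w, c_in * kh * kw, c_out)
      dw <- cache$col %*% t(dym)
      dim(dw) <- c(c_in, kh, kw, c_out)
      g <- list(w = dw)
      if (bias) g$b <- rowSums(dym)
      dcol <- wm %*% dym
      dx <- .col2im_cpp(dcol, cache$xd, kh, kw, sh, sw, ph, pw)
      list(dx = dx, grads = g)
    })
}

# ---- batch normalization (per leading channel dimension) --------------------

nn_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  force(C); force(momentum); force(eps)
  list(
    type = "bn",
    init = function() list(gamma = rep(1, C), beta = numeric(C)),
    state0 = function() list(mean = numeric(C), var = rep(1, C)),
    fwd = function(params, state, x, training) {
      xd <- dim(x); if (is.null(xd)) xd <- c(length(x) %/% 1, 1)
      xm <- matrix(x, C)
      if (training) {
        m <- rowMeans(xm)
        v <- rowMeans(xm * xm) - m * m
        state$mean <- (1 - momentum) * state$mean + momentum * m
        state$var <- (1 - momentum) * state$var + momentum * v
      } else {
        m <- state$mean; v <- state$var
      }
      ivar <- 1 / sqrt(v + eps)
      xhat <- (xm - m) * ivar
      y <- params$gamma * xhat + params$beta
      dim(y) <- xd
      list(y = y,
           cache = list(xhat = xhat, ivar = ivar, xd = xd, training = training),
           state = state)
    },
    bwd = function(params, cache, dy) {
      dym <- matrix(dy, C)
      xhat <- cache$xhat
      g <- list(gamma = rowSums(dym * xhat), beta = rowSums(dym))
      dxhat <- dym * params$gamma
      if (cache$training) {
        dx <- cache$ivar *
          (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
      } else {
        dx <- dxhat * cache$ivar
      }
      dim(dx) <- cache$xd
      list(dx = dx, grads = g)
    })
}

# ---- elementwise / pooling / pooling-free layers ----------------------------

nn_relu <- function() {
  list(type = "relu", init = function() list(), state0 = function() list(),
       fwd = function(params, state, x, training) {
         mask <- x > 0
         list(y = x * mask, cache = mask, state = state)
       },
       bwd = function(params, cache, dy) list(dx = dy * cache, grads = list()))
}

nn_maxpool <- function(kh, kw, sh = kh, sw = kw, ph = 0L, pw = 0L) {
  force(kh); force(kw); force(sh); force(sw); force(ph); force(pw)
  list(type = "maxpool", init = function() list(), state0 = function() list(),
       fwd = function(params, state, x, training) {
         out <- .maxpool_cpp(x, dim(x), kh, kw, sh, sw, ph, pw)
         list(y = out$y, cache = list(argmax = out$argmax, xd = dim(x)),
              state = state)
       },
       bwd = function(params, cache, dy)
         list(dx = .maxpool_bwd_cpp(dy, cache$argmax, cache$xd), grads = list()))
}

nn_gap <- function() {
  list(type = "gap", init = function() list(), state0 = function() list(),
       fwd = function(params, state, x, training) {
         d <- dim(x); C <- d[1]; hw <- d[2] * d[3]; N <- d[4]
         xm <- array(x, c(C, hw, N))
         y <- vapply(seq_len(N), function(n) rowMeans(xm[, , n, drop = FALSE]),
                     numeric(C))
         dim(y) <- c(C, N)
         list(y = y, cache = d, state = state)
       },
       bwd = function(params, cache, dy) {
         d <- cache; hw <- d[2] * d[3]
         dx <- array(0, d)
         for (n in seq_len(d[4]))
           dx[, , , n] <- array(dy[, n] / hw, c(d[1], d[2], d[3]))
         list(dx = dx, grads = list())
       })
}

nn_dropout <- function(p = 0.5) {
  force(p)
  list(type = "dropout", init = function() list(), state0 = function() list(),
       fwd = function(params, state, x, training) {
         if (!training || p <= 0) return(list(y = x, cache = NULL, state = state))
         keep <- 1 - p
         mask <- array((runif(length(x)) < keep) / keep, dim(x) %||% length(x))
         list(y = x * mask, cache = mask, state = state)
       },
       bwd = function(params, cache, dy) {
         if (is.null(cache)) return(list(dx = dy, grads = list()))
         list(dx = dy * cache, grads = list())
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_linear <- function(d_in, d_out, bias = TRUE) {
  force(d_in); force(d_out); force(bias)
  list(type = "linear",
       init = function() {
         p <- list(w = matrix(he_init(d_in, d_in * d_out), d_out, d_in))
         if (bias) p$b <- numeric(d_out)
         p
       },
       state0 = function() list(),
       fwd = function(params, state, x, training) {
         y <- params$w %*% x
         if (bias) y <- y + params$b
         list(y = y, cache = x, state = state)
       },
       bwd = function(params, cache, dy) {
         g <- list(w = dy %*% t(cache))
         if (bias) g$b <- rowSums(dy)
         list(dx = t(params$w) %*% dy, grads = g)
       })
}

# drop the singleton H dimension: (C, 1, T, N) -> (C, T, N)
nn_squeeze <- function() {
  list(type = "squeeze", init = function() list(), state0 = function() list(),
       fwd = function(params, state, x, training) {
         d <- dim(x)
         y <- array(x, c(d[1], d[3], d[4]))
         list(y = y, cache = d, state = state)
       },
       bwd = function(params, cache, dy)
         list(dx = array(dy, cache), grads = list()))
}

# (H, T, N) sequence -> (H, N) final step
nn_take_last <- function() {
  list(type = "take_last", init = function() list(), state0 = function() list(),
       fwd = function(params, state, x, training) {
         d <- dim(x)
         list(y = array(x[, d[2], ], c(d[1], d[3])), cache = d, state = state)
       },
       bwd = function(params, cache, dy) {
         dx <- array(0, cache)
         dx[, cache[2], ] <- dy
         list(dx = dx, grads = list())
       })
}

# ---- stacked unidirectional LSTM --------------------------------------------
# Input (D, T, N) array, output full top-layer hidden sequence (H, T, N).
# Gate order within the 4H rows of W, b: input i, forget f, cell g, output o;
# pre-activations a = W %*% rbind(x_t, h_{t-1}) + b.

sigm <- function(x) 1 / (1 + exp(-x))

nn_lstm <- function(d_in, hidden, n_layers) {
  force(d_in); force(hidden); force(n_layers)
  list(
    type = "lstm",
    init = function() {
      lapply(seq_len(n_layers), function(l) {
        din_l <- if (l == 1) d_in else hidden
        s <- 1 / sqrt(hidden)
        list(w = matrix(runif(4 * hidden * (din_l + hidden), -s, s),
                        4 * hidden, din_l + hidden),
             b = numeric(4 * hidden))
      })
    },
    state0 = function() list(),
    fwd = function(params, state, x, training) {
      d <- dim(x); Tn <- d[2]; N <- d[3]; H <- hidden
      caches <- vector("list", n_layers)
      inp <- x
      for (l in seq_len(n_layers)) {
        W <- params[[l]]$w; b <- params[[l]]$b
        h <- matrix(0, H, N); cc <- matrix(0, H, N)
        steps <- vector("list", Tn)
        hseq <- array(0, c(H, Tn, N))
        for (t in seq_len(Tn)) {
          xt <- array(inp[, t, ], c(dim(inp)[1], N))
          a <- W %*% rbind(xt, h) + b
          i <- sigm(a[seq_len(H), , drop = FALSE])
          f <- sigm(a[H + seq_len(H), , drop = FALSE])
          g <- tanh(a[2 * H + seq_len(H), , drop = FALSE])
          o <- sigm(a[3 * H + seq_len(H), , drop = FALSE])
          c_prev <- cc
          cc <- f * c_prev + i * g
          tc <- tanh(cc)
          h <- o * tc
          steps[[t]] <- list(xt = xt, h_prev = if (t == 1) matrix(0, H, N) else
                               steps[[t - 1]]$h,
                             c_prev = c_prev, i = i, f = f, g = g, o = o,
                             c = cc, tc = tc, h = h)
          hseq[, t, ] <- h
        }
        caches[[l]] <- list(steps = steps, d_in_l = dim(inp)[1])
        inp <- hseq
      }
      list(y = inp, cache = list(layers = caches, Tn = Tn, N = N),
           state = state)
    },
    bwd = function(params, cache, dy) {
      Tn <- cache$Tn; N <- cache$N; H <- hidden
      grads <- vector("list", n_layers)
      dtop <- dy  # (H, T, N) gradient on the top-layer hidden sequence
      for (l in rev(seq_len(n_layers))) {
        W <- params[[l]]$w
        cl <- cache$layers[[l]]
        din_l <- cl$d_in_l
        dW <- matrix(0, 4 * H, din_l + H); db <- numeric(4 * H)
        dh_next <- matrix(0, H, N); dc_next <- matrix(0, H, N)
        dx_seq <- array(0, c(din_l, Tn, N))
        for (t in rev(seq_len(Tn))) {
          st <- cl$steps[[t]]
          dh <- array(dtop[, t, ], c(H, N)) + dh_next
          dc <- dc_next + dh * st$o * (1 - st$tc^2)
          do_ <- dh * st$tc
          di <- dc * st$g
          dg <- dc * st$i
          df <- dc * st$c_prev
          dc_next <- dc * st$f
          da <- rbind(di * st$i * (1 - st$i),
                      df * st$f * (1 - st$f),
                      dg * (1 - st$g^2),
                      do_ * st$o * (1 - st$o))
          xh <- rbind(st$xt, st$h_prev)
          dW <- dW + da %*% t(xh)
          db <- db + rowSums(da)
          dxh <- t(W) %*% da
          dx_seq[, t, ] <- dxh[seq_len(din_l), , drop = FALSE]
          dh_next <- dxh[din_l + seq_len(H), , drop = FALSE]
        }
        grads[[l]] <- list(w = dW, b = db)
        dtop <- dx_seq
      }
      list(dx = dtop, grads = grads)
    })
}

# ---- sequential composition -------------------------------------------------

nn_seq <- function(layers) {
  force(layers)
  list(
    type = "seq", layers = layers,
    init = function() lapply(layers, function(l) l$init()),
    state0 = function() lapply(layers, function(l) l$state0()),
    fwd = function(params, state, x, training) {
      caches <- vector("list", length(layers))
      for (k in seq_along(layers)) {
        out <- layers[[k]]$fwd(params[[k]], state[[k]], x, training)
        x <- out$y; caches[[k]] <- out$cache; state[[k]] <- out$state
      }
      list(y = x, cache = caches, state = state)
    },
    bwd = function(params, cache, dy) {
      grads <- vector("list", length(layers))
      for (k in rev(seq_along(layers))) {
        out <- layers[[k]]$bwd(params[[k]], cache[[k]], dy)
        dy <- out$dx; grads[[k]] <- out$grads
      }
      list(dx = dy, grads = grads)
    })
}

# ---- residual basic block ---------------------------------------------------
# Y = ReLU(BN(W2 * ReLU(BN(W1 * X))) + X), with a 1x1 projection on the skip
# path when the channel count or stride changes.

nn_resblock <- function(c_in, c_out, stride = 1L) {
  force(c_in); force(c_out); force(stride)
  main <- nn_seq(list(
    nn_conv(c_in, c_out, 3L, 3L, stride, stride, 1L, 1L, bias = FALSE),
    nn_bn(c_out), nn_relu(),
    nn_conv(c_out, c_out, 3L, 3L, 1L, 1L, 1L, 1L, bias = FALSE),
    nn_bn(c_out)))
  project <- (c_in != c_out) || (stride != 1L)
  proj <- if (project)
    nn_seq(list(nn_conv(c_in, c_out, 1L, 1L, stride, stride, 0L, 0L,
                        bias = FALSE),
                nn_bn(c_out)))
  list(
    type = "resblock",
    init = function() {
      p <- list(main = main$init())
      if (project) p$proj <- proj$init()
      p
    },
    state0 = function() {
      s <- list(main = main$state0())
      if (project) s$proj <- proj$state0()
      s
    },
    fwd = function(params, state, x, training) {
      m <- main$fwd(params$main, state$main, x, training)
      state$main <- m$state
      if (project) {
        pr <- proj$fwd(params$proj, state$proj, x, training)
        state$proj <- pr$state
        skip <- pr$y; pcache <- pr$cache
      } else {
        skip <- x; pcache <- NULL
      }
      pre <- m$y + skip
      mask <- pre > 0
      list(y = pre * mask,
           cache = list(main = m$cache, proj = pcache, mask = mask),
           state = state)
    },
    bwd = function(params, cache, dy) {
      dpre <- dy * cache$mask
      m <- main$bwd(params$main, cache$main, dpre)
      g <- list(main = m$grads)
      dx <- m$dx
      if (project) {
        pr <- proj$bwd(params$proj, cache$proj, dpre)
        g$proj <- pr$grads
        dx <- dx + pr$dx
      } else {
        dx <- dx + dpre
      }
      list(dx = dx, grads = g)
    })
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
    out
  } else f(a, b)
}

tree_sum <- function(f, tree) {
  if (is.list(tree)) sum(vapply(tree, function(t) tree_sum(f, t), numeric(1)))
  else f(tree)
}

#' Total parameter count of a parameter tree
#' @param params Nested parameter list.
#' @return Integer count.
#' @export
nn_param_count <- function(params) tree_sum(length, params)

grad_global_norm <- function(grads) sqrt(tree_sum(function(g) sum(g * g), grads))

clip_grads <- function(grads, max_norm) {
  n <- grad_global_norm(grads)
  if (is.finite(n) && n > max_norm) {
    s <- max_norm / n
    grads <- tree_map(function(g) g * s, grads)
  }
  grads
}

adam_init <- function(params)
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params), t = 0L)

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  if (weight_decay > 0)
    grads <- tree_map2(function(g, p) g + weight_decay * p, grads, params)
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), opt$m, opt$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, opt = opt)
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  tree_map2(`+`, a, b)
}
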