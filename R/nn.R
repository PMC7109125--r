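# Compact CPU training engine for the package's encoder-decoder networks.
# A model is a tape of ops over named buffers; each batch is a list of
# per-sample arrays (H, W, C) or (D1, D2, D3, C). Convolutions run through
# the im2col kernels in src/ and BLAS matrix products; gradients are
# hand-derived per op. Deliberately minimal: stride-1 convs, 2x pooling,
# 2x transposed convs - exactly what the supported architectures need.

# ---- channel-slab helpers (work for 2D and 3D feature maps) ---------------
ch_count <- function(a) dim(a)[length(dim(a))]

# ---- parameter layers ------------------------------------------------------
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_conv <- function(k, cin, cout, pad, nd) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- k; e$pad <- pad; e$nd <- nd
  e$cin <- cin; e$cout <- cout
  e$W <- he_init(c(rep(k, nd), cin, cout), k^nd * cin)
  e$b <- numeric(cout)
  e$param_names <- c("W", "b")
  e
}

new_upconv <- function(cin, cout, nd) {
  e <- new.env(parent = emptyenv())
  e$type <- "upconv"; e$nd <- nd; e$cin <- cin; e$cout <- cout
  e$W <- he_init(c(rep(2, nd), cin, cout), 2^nd * cin)
  e$b <- numeric(cout)
  e$param_names <- c("W", "b")
  e
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$gamma <- rep(1, c); e$beta <- rep(0, c)
  e$rm <- rep(0, c); e$rv <- rep(1, c)
  e$momentum <- momentum; e$eps <- eps
  e$param_names <- c("gamma", "beta")
  e
}

# ---- per-op forward/backward ----------------------------------------------
conv_fwd1 <- function(lay, x) {
  d <- dim(x); nd <- lay$nd
  Wm <- matrix(lay$W, ncol = lay$cout)
  if (nd == 2) {
    cols <- cpp_im2col2d(as.numeric(x), d[1], d[2], d[3],
                         lay$k, lay$k, lay$pad, lay$pad)
    o <- c(d[1] + 2 * lay$pad - lay$k + 1, d[2] + 2 * lay$pad - lay$k + 1)
  } else {
    cols <- cpp_im2col3d(as.numeric(x), d[1], d[2], d[3], d[4],
                         lay$k, lay$pad)
    o <- d[1:3] + 2 * lay$pad - lay$k + 1
  }
  y <- cols %*% Wm
  y <- y + rep(lay$b, each = nrow(y))
  list(y = array(y, c(o, lay$cout)), cols = cols, din = d)
}

conv_bwd1 <- function(lay, dy, cache) {
  dym <- matrix(dy, ncol = lay$cout)
  lay$dW <- lay$dW + array(crossprod(cache$cols, dym), dim(lay$W))
  lay$db <- lay$db + colSums(dym)
  dcols <- tcrossprod(dym, matrix(lay$W, ncol = lay$cout))
  d <- cache$din
  if (lay$nd == 2)
    dx <- cpp_col2im2d(dcols, d[1], d[2], d[3], lay$k, lay$k,
                       lay$pad, lay$pad)
  else
    dx <- cpp_col2im3d(dcols, d[1], d[2], d[3], d[4], lay$k, lay$pad)
  array(dx, d)
}

upconv_fwd1 <- function(lay, x) {
  d <- dim(x); nd <- lay$nd
  sp <- d[seq_len(nd)]; cin <- d[nd + 1]
  xm <- matrix(x, ncol = cin)
  y <- array(0, c(2 * sp, lay$cout))
  offs <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    Wab <- if (nd == 2)
      matrix(lay$W[o[1] + 1, o[2] + 1, , ], lay$cin, lay$cout)
    else matrix(lay$W[o[1] + 1, o[2] + 1, o[3] + 1, , ], lay$cin, lay$cout)
    contrib <- array(xm %*% Wab, c(sp, lay$cout))
    if (nd == 2)
      y[seq(o[1] + 1, 2 * sp[1], 2), seq(o[2] + 1, 2 * sp[2], 2), ] <-
        contrib
    else
      y[seq(o[1] + 1, 2 * sp[1], 2), seq(o[2] + 1, 2 * sp[2], 2),
        seq(o[3] + 1, 2 * sp[3], 2), ] <- contrib
  }
  y <- y + rep(lay$b, each = prod(2 * sp))
  list(y = y, xm = xm, sp = sp)
}

upconv_bwd1 <- function(lay, dy, cache) {
  nd <- lay$nd; sp <- cache$sp
  dxm <- matrix(0, nrow(cache$xm), lay$cin)
  offs <- as.matrix(expand.grid(rep(list(0:1), nd)))
  lay$db <- lay$db + colSums(matrix(dy, ncol = lay$cout))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sub <- if (nd == 2)
      dy[seq(o[1] + 1, 2 * sp[1], 2), seq(o[2] + 1, 2 * sp[2], 2), ,
         drop = FALSE]
    else
      dy[seq(o[1] + 1, 2 * sp[1], 2), seq(o[2] + 1, 2 * sp[2], 2),
         seq(o[3] + 1, 2 * sp[3], 2), , drop = FALSE]
    subm <- matrix(sub, ncol = lay$cout)
    Wab <- if (nd == 2)
      matrix(lay$W[o[1] + 1, o[2] + 1, , ], lay$cin, lay$cout)
    else matrix(lay$W[o[1] + 1, o[2] + 1, o[3] + 1, , ], lay$cin, lay$cout)
    dWab <- array(crossprod(cache$xm, subm), c(lay$cin, lay$cout))
    if (nd == 2)
      lay$dW[o[1] + 1, o[2] + 1, , ] <-
        lay$dW[o[1] + 1, o[2] + 1, , ] + dWab
    else
      lay$dW[o[1] + 1, o[2] + 1, o[3] + 1, , ] <-
        lay$dW[o[1] + 1, o[2] + 1, o[3] + 1, , ] + dWab
    dxm <- dxm + tcrossprod(subm, Wab)
  }
  array(dxm, c(sp, lay$cin))
}

bn_fwd <- function(lay, xs, train) {
  C <- ch_count(xs[[1]])
  xm <- do.call(rbind, lapply(xs, function(x) matrix(x, ncol = C)))
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    lay$rm <- (1 - lay$momentum) * lay$rm + lay$momentum * mu
    lay$rv <- (1 - lay$momentum) * lay$rv + lay$momentum * va
  } else {
    mu <- lay$rm; va <- lay$rv
  }
  ivar <- 1 / sqrt(va + lay$eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(ivar, each = nrow(xm))
  ym <- xhat * rep(lay$gamma, each = nrow(xm)) +
    rep(lay$beta, each = nrow(xm))
  rows <- vapply(xs, function(x) prod(dim(x)) / C, numeric(1))
  ys <- vector("list", length(xs))
  at <- 0
  for (i in seq_along(xs)) {
    ys[[i]] <- array(ym[at + seq_len(rows[i]), , drop = FALSE], dim(xs[[i]]))
    at <- at + rows[i]
  }
  list(ys = ys, xhat = xhat, ivar = ivar, rows = rows, train = train)
}

bn_bwd <- function(lay, dys, cache) {
  C <- length(lay$gamma)
  dym <- do.call(rbind, lapply(dys, function(x) matrix(x, ncol = C)))
  M <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  lay$dgamma <- lay$dgamma + dgamma
  lay$dbeta <- lay$dbeta + dbeta
  if (cache$train) {
    dxm <- (rep(lay$gamma * cache$ivar / M, each = M)) *
      (M * dym - rep(dbeta, each = M) - cache$xhat * rep(dgamma, each = M))
  } else {
    dxm <- dym * rep(lay$gamma * cache$ivar, each = M)
  }
  dxs <- vector("list", length(dys))
  at <- 0
  for (i in seq_along(dys)) {
    dxs[[i]] <- array(dxm[at + seq_len(cache$rows[i]), , drop = FALSE],
                      dim(dys[[i]]))
    at <- at + cache$rows[i]
  }
  dxs
}

# center-crop a feature map to target spatial size (valid-padding skips)
center_crop <- function(a, target_sp) {
  d <- dim(a); nd <- length(d) - 1
  off <- (d[seq_len(nd)] - target_sp) %/% 2
  if (all(off == 0)) return(list(a = a, off = off))
  idx <- lapply(seq_len(nd), function(i) off[i] + seq_len(target_sp[i]))
  a2 <- if (nd == 2) a[idx[[1]], idx[[2]], , drop = FALSE]
  else a[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  list(a = a2, off = off)
}

# ---- tape execution --------------------------------------------------------
net_forward <- function(model, xs, train = FALSE) {
  vals <- list(input = xs)
  caches <- vector("list", length(model$ops))
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    lay <- op$layer
    xin <- vals[[op$inp[1]]]
    out <- switch(op$type,
      conv = {
        cc <- lapply(xin, function(x) conv_fwd1(lay, x))
        caches[[i]] <- lapply(cc, `[`, c("cols", "din"))
        lapply(cc, `[[`, "y")
      },
      upconv = {
        cc <- lapply(xin, function(x) upconv_fwd1(lay, x))
        caches[[i]] <- lapply(cc, `[`, c("xm", "sp"))
        lapply(cc, `[[`, "y")
      },
      bn = {
        cc <- bn_fwd(lay, xin, train)
        caches[[i]] <- cc[c("xhat", "ivar", "rows", "train")]
        cc$ys
      },
      relu = {
        caches[[i]] <- lapply(xin, function(x) x > 0)
        lapply(xin, function(x) pmax(x, 0))
      },
      pool = {
        nd <- model$nd
        cc <- lapply(xin, function(x) {
          d <- dim(x)
          if (any(d[seq_len(nd)] %% 2 != 0))
            stop("pool input has odd spatial size: ",
                 paste(d, collapse = "x"))
          if (nd == 2) {
            r <- cpp_maxpool2d(as.numeric(x), d[1], d[2], d[3])
            list(y = array(r$out, c(d[1:2] %/% 2, d[3])), idx = r$idx,
                 n_in = prod(d))
          } else {
            r <- cpp_maxpool3d(as.numeric(x), d[1], d[2], d[3], d[4])
            list(y = array(r$out, c(d[1:3] %/% 2, d[4])), idx = r$idx,
                 n_in = prod(d))
          }
        })
        caches[[i]] <- cc
        lapply(cc, `[[`, "y")
      },
      unpool = {
        pc <- caches[[op$pool_id]]
        caches[[i]] <- pc
        mapply(function(x, c1) {
          d2 <- dim(vals[[model$ops[[op$pool_id]]$inp[1]]][[1]])
          y <- cpp_maxunpool2d(as.numeric(x), c1$idx, c1$n_in)
          array(y, d2)
        }, xin, pc, SIMPLIFY = FALSE)
      },
      concat = {
        skip <- vals[[op$inp[2]]]
        nd <- model$nd
        cc <- mapply(function(x, s) {
          cr <- center_crop(s, dim(x)[seq_len(nd)])
          list(y = abind_ch(cr$a, x), off = cr$off, sdim = dim(s),
               c1 = ch_count(s), c2 = ch_count(x))
        }, xin, skip, SIMPLIFY = FALSE)
        caches[[i]] <- cc
        lapply(cc, `[[`, "y")
      },
      dropout = {
        if (train) {
          cc <- lapply(xin, function(x)
            array(stats::runif(length(x)) > op$p, dim(x)))
          caches[[i]] <- cc
          mapply(function(x, m) x * m / (1 - op$p), xin, cc,
                 SIMPLIFY = FALSE)
        } else xin
      },
      stop("unknown op ", op$type))
    vals[[op$out]] <- out
  }
  list(vals = vals, caches = caches)
}

abind_ch <- function(a, b) {
  nd <- length(dim(a)) - 1
  sp <- dim(a)[seq_len(nd)]
  out <- array(0, c(sp, ch_count(a) + ch_count(b)))
  if (nd == 2) {
    out[, , seq_len(ch_count(a))] <- a
    out[, , ch_count(a) + seq_len(ch_count(b))] <- b
  } else {
    out[, , , seq_len(ch_count(a))] <- a
    out[, , , ch_count(a) + seq_len(ch_count(b))] <- b
  }
  out
}

net_backward <- function(model, fw, dscores) {
  g <- list()
  g[[model$out]] <- dscores
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    dy <- g[[op$out]]
    if (is.null(dy)) next
    lay <- op$layer
    cache <- fw$caches[[i]]
    dx <- switch(op$type,
      conv = mapply(function(d, c1) conv_bwd1(lay, d, c1), dy, cache,
                    SIMPLIFY = FALSE),
      upconv = mapply(function(d, c1) upconv_bwd1(lay, d, c1), dy, cache,
                      SIMPLIFY = FALSE),
      bn = bn_bwd(lay, dy, cache),
      relu = mapply(function(d, m) d * m, dy, cache, SIMPLIFY = FALSE),
      pool = mapply(function(d, c1) {
        dxv <- as.numeric(d)[] # pooled grads
        out <- numeric(c1$n_in)
        out[c1$idx + 1] <- dxv
        array(out, dim(fw$vals[[op$inp[1]]][[1]]))
      }, dy, cache, SIMPLIFY = FALSE),
      unpool = mapply(function(d, c1) {
        array(as.numeric(d)[c1$idx + 1], dim(fw$vals[[op$inp[1]]][[1]]))
      }, dy, cache, SIMPLIFY = FALSE),
      concat = {
        nd <- model$nd
        dskip <- mapply(function(d, c1) {
          ds_c <- if (nd == 2) d[, , seq_len(c1$c1), drop = FALSE]
          else d[, , , seq_len(c1$c1), drop = FALSE]
          full <- array(0, c1$sdim)
          sp <- dim(ds_c)[seq_len(nd)]
          idx <- lapply(seq_len(nd), function(a) c1$off[a] + seq_len(sp[a]))
          if (nd == 2) full[idx[[1]], idx[[2]], ] <- ds_c
          else full[idx[[1]], idx[[2]], idx[[3]], ] <- ds_c
          full
        }, dy, cache, SIMPLIFY = FALSE)
        g[[op$inp[2]]] <- accum_grad(g[[op$inp[2]]], dskip)
        mapply(function(d, c1) {
          if (nd == 2) d[, , c1$c1 + seq_len(c1$c2), drop = FALSE]
          else d[, , , c1$c1 + seq_len(c1$c2), drop = FALSE]
        }, dy, cache, SIMPLIFY = FALSE)
      },
      dropout = {
        if (!is.null(cache))
          mapply(function(d, m) d * m / (1 - op$p), dy, cache,
                 SIMPLIFY = FALSE)
        else dy
      })
    g[[op$inp[1]]] <- accum_grad(g[[op$inp[1]]], dx)
  }
  invisible(g)
}

accum_grad <- function(cur, add) {
  if (is.null(cur)) return(add)
  mapply(function(a, b) a + array(b, dim(a)), cur, add, SIMPLIFY = FALSE)
}

zero_grads <- function(model) {
  for (lay in model$layers) {
    for (p in lay$param_names)
      lay[[paste0("d", p)]] <- array(0, dim(as.array(lay[[p]])))
  }
}

adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (lay in model$layers) {
    lay$t_adam <- (if (is.null(lay$t_adam)) 0 else lay$t_adam) + 1
    t_ <- lay$t_adam
    for (p in lay$param_names) {
      gname <- paste0("d", p)
      g <- lay[[gname]]
      mkey <- paste0("m_", p); vkey <- paste0("v_", p)
      if (is.null(lay[[mkey]])) {
        lay[[mkey]] <- array(0, dim(as.array(g)))
        lay[[vkey]] <- array(0, dim(as.array(g)))
      }
      lay[[mkey]] <- beta1 * lay[[mkey]] + (1 - beta1) * g
      lay[[vkey]] <- beta2 * lay[[vkey]] + (1 - beta2) * g^2
      mhat <- lay[[mkey]] / (1 - beta1^t_)
      vhat <- lay[[vkey]] / (1 - beta2^t_)
      upd <- array(lr * mhat / (sqrt(vhat) + eps), dim(as.array(lay[[p]])))
      lay[[p]] <- lay[[p]] - upd
    }
  }
}

# snapshot / restore trainable parameters (for best-on-validation selection)
param_snapshot <- function(model) {
  lapply(model$layers, function(lay) {
    s <- lapply(lay$param_names, function(p) lay[[p]])
    names(s) <- lay$param_names
    if (lay$type == "bn") { s$rm <- lay$rm; s$rv <- lay$rv }
    s
  })
}

param_restore <- function(model, snap) {
  for (i in seq_along(model$layers)) {
    lay <- model$layers[[i]]
    for (p in names(snap[[i]])) lay[[p]] <- snap[[i]][[p]]
  }
  invisible(model)
}

#' Fingerprint of a model's trainable parameters
#'
#' A deterministic scalar summary (sum of all parameter values and their
#' squares) used to assert that training with zero epochs leaves a model
#' untouched.
#'
#' @param model a model built by [build_model()].
#' @return Numeric length-2 vector.
#' @export
param_fingerprint <- function(model) {
  s1 <- 0; s2 <- 0
  for (lay in model$layers)
    for (p in lay$param_names) {
      s1 <- s1 + sum(lay[[p]])
      s2 <- s2 + sum(lay[[p]]^2)
    }
  c(sum = s1, sumsq = s2)
}

# softmax canal probability from 2-channel scores
scores_to_prob <- function(s) {
  nd <- length(dim(s)) - 1
  d <- if (nd == 2) s[, , 2] - s[, , 1] else s[, , , 2] - s[, , , 1]
  array(stats::plogis(d), dim(s)[seq_len(nd)])
}

# loss and d(loss)/d(scores) for a batch
batch_loss_grad <- function(scores, targets, w, eps = 1e-7) {
  n <- length(scores)
  loss <- 0
  dscores <- vector("list", n)
  w1 <- w$weights[["canal"]]; w0 <- w$weights[["background"]]
  for (i in seq_len(n)) {
    s <- scores[[i]]
    nd <- length(dim(s)) - 1
    p <- scores_to_prob(s)
    t_ <- targets[[i]]
    V <- length(t_)
    pc <- pmin(pmax(p, eps), 1 - eps)
    loss <- loss + mean(-(w1 * t_ * log(pc) + w0 * (1 - t_) * log(1 - pc))) / n
    gd <- (w1 * t_ * (p - 1) + w0 * (1 - t_) * p) / (V * n)
    ds <- array(0, dim(s))
    if (nd == 2) { ds[, , 2] <- gd; ds[, , 1] <- -gd }
    else { ds[, , , 2] <- gd; ds[, , , 1] <- -gd }
    dscores[[i]] <- ds
  }
  list(loss = loss, dscores = dscores)
}

#' Predict per-voxel canal probability with a trained model
#'
#' @param model a model from [build_model()].
#' @param x input array `(H, W, C)` (or `(D1, D2, D3, C)` for 3D models).
#' @return Array of canal probabilities over the model's output region.
#' @export
predict_canal_prob <- function(model, x) {
  fw <- net_forward(model, list(x), train = FALSE)
  scores_to_prob(fw$vals[[model$out]][[1]])
}
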