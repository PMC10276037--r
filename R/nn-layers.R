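# Minimal neural-network layer framework.
#
# No deep-learning backend is declared by this package; the handful of layer
# types the surrogate architectures need (stride-1 convolution, batch
# normalization, 2x2 max pooling, nearest-neighbour upsampling, dropout,
# dense layers and the self-normalization output module) are implemented
# here directly.  Convolutions run as im2col + GEMM in compiled code; the
# remaining operations are vectorized R.  Every layer is a mutable
# environment exposing
#   $fw(x, mode)  forward pass; mode is "train" (batch statistics, dropout
#                 active), "eval" (running statistics, dropout off) or
#                 "mc" (running statistics, dropout active - MC dropout)
#   $bw(dy)       backward pass for the most recent training forward
# with parameters in the fields named by $param_names and gradients in the
# matching "g<name>" fields.  Activations: conv/dense tensors are
# [H, W, C, N] arrays, dense inputs [features, N] matrices.

new_layer <- function(type, out_shape = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- character(0)
  e$out_shape <- out_shape
  e
}

n_params <- function(layer) {
  if (!length(layer$param_names)) return(0L)
  sum(vapply(layer$param_names, function(p) length(layer[[p]]), 0L))
}

# Convolution GEMMs run in single precision unless the user opts into the
# double path (used by the finite-difference gradient checks).
conv_single <- function() !isTRUE(getOption("porediff.conv_double", FALSE))

layer_conv <- function(kh, kw, cin, cout, pad = 0L, act = c("relu", "linear")) {
  act <- match.arg(act)
  e <- new_layer("conv")
  sd <- if (act == "relu") sqrt(2 / (kh * kw * cin)) else sqrt(1 / (kh * kw * cin))
  e$W <- array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  e$b <- numeric(cout)
  e$param_names <- c("W", "b")
  e$pad <- as.integer(pad); e$act <- act
  e$act_flag <- if (act == "relu") 1L else 0L
  e$kh <- kh; e$kw <- kw; e$cin <- cin; e$cout <- cout
  e$fw <- function(x, mode) {
    z <- cpp_conv_fw(x, e$W, e$b, e$pad, e$act_flag, conv_single())
    if (mode %in% c("train", "tune")) { e$x <- x; e$y <- z }
    z
  }
  e$bw <- function(dy) {
    # dy is gated in place by the cached ReLU output inside the C++ call
    g <- cpp_conv_bw(e$x, e$W, dy, e$y, e$pad, e$act_flag, conv_single())
    e$gW <- g$dw; e$gb <- g$db
    e$x <- NULL; e$y <- NULL
    g$dx
  }
  e
}

layer_bnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- new_layer("bnorm")
  e$gamma <- rep(1, C); e$beta <- rep(0, C)
  e$param_names <- c("gamma", "beta")
  e$rmean <- rep(0, C); e$rvar <- rep(1, C)
  e$C <- C; e$momentum <- momentum; e$eps <- eps
  e$fw <- function(x, mode) {
    r <- cpp_bnorm_fw(x, e$gamma, e$beta, e$rmean, e$rvar, e$eps,
                      mode == "train")
    if (mode == "train") {
      e$rmean <- (1 - e$momentum) * e$rmean + e$momentum * r$mean
      e$rvar <- (1 - e$momentum) * e$rvar + e$momentum * r$var
      e$x <- x; e$bmu <- r$mean; e$istd <- r$istd; e$frozen <- FALSE
    } else if (mode == "tune") {
      # fine-tuning phase: normalize with the (frozen) running statistics,
      # but keep gradients flowing to gamma/beta and the input
      e$x <- x; e$bmu <- r$mean; e$istd <- r$istd; e$frozen <- TRUE
    }
    r$y
  }
  e$bw <- function(dy) {
    r <- if (isTRUE(e$frozen))
      cpp_bnorm_bw_frozen(e$x, dy, e$gamma, e$bmu, e$istd)
    else
      cpp_bnorm_bw(e$x, dy, e$gamma, e$bmu, e$istd)
    e$ggamma <- r$dgamma
    e$gbeta <- r$dbeta
    e$x <- NULL
    r$dx
  }
  e
}

layer_maxpool <- function() {
  e <- new_layer("maxpool")
  e$fw <- function(x, mode) {
    d <- dim(x)
    # floor pooling: an odd trailing row/column is dropped
    r1 <- seq_len(d[1] %/% 2) * 2 - 1; r2 <- r1 + 1
    c1 <- seq_len(d[2] %/% 2) * 2 - 1; c2 <- c1 + 1
    best <- x[r1, c1, , , drop = FALSE]
    idx <- array(1L, dim(best))
    k <- 1L
    for (cand in list(x[r2, c1, , , drop = FALSE],
                      x[r1, c2, , , drop = FALSE],
                      x[r2, c2, , , drop = FALSE])) {
      k <- k + 1L
      upd <- cand > best
      best[upd] <- cand[upd]
      idx[upd] <- k
    }
    if (mode %in% c("train", "tune")) { e$idx <- idx; e$d <- d }
    best
  }
  e$bw <- function(dy) {
    d <- e$d
    dx <- array(0, d)
    r1 <- seq_len(d[1] %/% 2) * 2 - 1; r2 <- r1 + 1
    c1 <- seq_len(d[2] %/% 2) * 2 - 1; c2 <- c1 + 1
    slots <- list(list(r1, c1), list(r2, c1), list(r1, c2), list(r2, c2))
    for (k in 1:4) {
      g <- dy
      g[e$idx != k] <- 0
      dx[slots[[k]][[1]], slots[[k]][[2]], , ] <- g
    }
    e$idx <- NULL
    dx
  }
  e
}

layer_upsample <- function() {
  e <- new_layer("upsample")
  e$fw <- function(x, mode) {
    d <- dim(x)
    if (mode %in% c("train", "tune")) e$d <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  }
  e$bw <- function(dy) {
    d <- dim(dy)
    r1 <- seq(1, d[1], 2); c1 <- seq(1, d[2], 2)
    dy[r1, c1, , , drop = FALSE] + dy[r1 + 1, c1, , , drop = FALSE] +
      dy[r1, c1 + 1, , , drop = FALSE] + dy[r1 + 1, c1 + 1, , , drop = FALSE]
  }
  e
}

layer_dropout <- function(p) {
  e <- new_layer("dropout")
  e$p <- p
  e$fw <- function(x, mode) {
    # dropout is active in "train" and "mc" modes, identity in "eval" and
    # in the frozen-statistics fine-tuning mode
    if (e$p <= 0 || mode %in% c("eval", "tune")) { e$mask <- NULL; return(x) }
    mask <- (stats::runif(length(x)) >= e$p) / (1 - e$p)
    if (mode == "train") e$mask <- mask
    x * mask
  }
  e$bw <- function(dy) {
    if (is.null(e$mask)) return(dy)
    g <- dy * e$mask
    e$mask <- NULL
    g
  }
  e
}

layer_flatten <- function() {
  e <- new_layer("flatten")
  e$fw <- function(x, mode) {
    d <- dim(x)
    if (mode %in% c("train", "tune")) e$d <- d
    dim(x) <- c(prod(d[1:3]), d[4])
    x
  }
  e$bw <- function(dy) { dim(dy) <- e$d; dy }
  e
}

layer_dense <- function(fin, fout, act = c("linear", "tanh", "relu")) {
  act <- match.arg(act)
  e <- new_layer("dense")
  sd <- if (act == "relu") sqrt(2 / fin) else sqrt(1 / fin)
  e$W <- matrix(stats::rnorm(fin * fout, sd = sd), fout, fin)
  e$b <- numeric(fout)
  e$param_names <- c("W", "b")
  e$act <- act
  e$fw <- function(x, mode) {
    z <- e$W %*% x + e$b
    y <- switch(e$act, linear = z, tanh = tanh(z),
                relu = { z[z < 0] <- 0; z })
    if (mode %in% c("train", "tune")) { e$x <- x; e$y <- y }
    y
  }
  e$bw <- function(dy) {
    dz <- switch(e$act,
                 linear = dy,
                 tanh = dy * (1 - e$y^2),
                 relu = dy * (e$y > 0))
    e$gW <- dz %*% t(e$x)
    e$gb <- rowSums(dz)
    dx <- crossprod(e$W, dz)
    e$x <- NULL; e$y <- NULL
    dx
  }
  e
}

# Self-normalization output module: two parallel affine maps from the last
# hidden features to 2 outputs.  The top branch is the raw response, the
# bottom branch squashes its pre-activations through 2*sigmoid() into
# multiplicative normalization factors in (0, 2); the module output is their
# element-wise product.  The factors are pulled towards 1 by the penalty
# sum_i (1 - y_i^bottom)^2, added to the per-sample loss during training.
layer_sn <- function(fin, fout = 2L) {
  e <- new_layer("sn")
  e$Wt <- matrix(stats::rnorm(fin * fout, sd = sqrt(1 / fin)), fout, fin)
  e$bt <- numeric(fout)
  e$Wb <- matrix(stats::rnorm(fin * fout, sd = sqrt(1 / fin)), fout, fin)
  e$bb <- numeric(fout)
  e$param_names <- c("Wt", "bt", "Wb", "bb")
  e$use_penalty <- TRUE
  e$fw <- function(x, mode) {
    top <- e$Wt %*% x + e$bt
    bottom <- 2 * stats::plogis(e$Wb %*% x + e$bb)
    e$bottom_last <- bottom
    if (mode %in% c("train", "tune")) { e$x <- x; e$top <- top }
    top * bottom
  }
  e$bw <- function(dy) {
    n <- ncol(dy)
    bottom <- e$bottom_last
    dtop <- dy * bottom
    dbottom <- dy * e$top
    if (isTRUE(e$use_penalty)) dbottom <- dbottom - 2 * (1 - bottom) / n
    dzb <- dbottom * bottom * (1 - bottom / 2)   # d(2 sigma)/dz
    e$gWt <- dtop %*% t(e$x);  e$gbt <- rowSums(dtop)
    e$gWb <- dzb %*% t(e$x);   e$gbb <- rowSums(dzb)
    dx <- crossprod(e$Wt, dtop) + crossprod(e$Wb, dzb)
    e$x <- NULL; e$top <- NULL
    dx
  }
  e
}

# Channel-wise concatenation used by skip connections.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(g, c1) {
  list(g[, , seq_len(c1), , drop = FALSE],
       g[, , -seq_len(c1), , drop = FALSE])
}

# Adam update over every layer with parameters.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (e in layers) {
    for (p in e$param_names) {
      g <- e[[paste0("g", p)]]
      if (is.null(g)) next
      mkey <- paste0("adam_m_", p); vkey <- paste0("adam_v_", p)
      if (is.null(e[[mkey]])) { e[[mkey]] <- g * 0; e[[vkey]] <- g * 0 }
      e[[mkey]] <- beta1 * e[[mkey]] + (1 - beta1) * g
      e[[vkey]] <- beta2 * e[[vkey]] + (1 - beta2) * g^2
      mhat <- e[[mkey]] / (1 - beta1^t)
      vhat <- e[[vkey]] / (1 - beta2^t)
      e[[p]] <- e[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
}
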