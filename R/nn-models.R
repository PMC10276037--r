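# Surrogate architectures.
#
# Three convolutional networks take the L x L binary geometry image
# (single channel, solid = 1, fluid = 0) as input:
#   C-Net      five valid-convolution blocks + two dense layers ->
#              the scalar pair (porosity, effective diffusion)
#   U-Net-Half the U-Net encoder followed by the same dense head -> (phi, D)
#   U-Net      full encoder-decoder with skip connections ->
#              the steady concentration map (same shape as the input)
# The scalar heads optionally end in the self-normalization (SN) module,
# which replaces the last hidden (10-unit) layer.

#' Declarative surrogate architecture specification
#'
#' @param kind `"CNET"`, `"UNET_HALF"` or `"UNET"`.
#' @param input_side Side length of the (square, single-channel) input image.
#' @param dropout_p Dropout probability used throughout (also drives the
#'   Monte Carlo dropout uncertainty).
#' @param sn_enabled Replace the last hidden dense layer of the scalar head
#'   with the self-normalization module?  (Scalar models only.)
#' @param blocks_per_container Convolution blocks per U-Net container.
#' @param containers Number of downsampling (and upsampling) containers.
#' @param n_kernels Kernels per U-Net convolution.
#' @param cnet_channels,cnet_kernels Kernel counts and sizes of the five
#'   C-Net convolution sections (defaults follow the reference design for
#'   128 x 128 inputs; smaller inputs need shorter chains).
#' @param fc_units Sizes of the two dense head layers (tanh, then linear).
#' @param dropout_where U-Net field models: `"all"` places a dropout layer
#'   in every convolution block (the full-scale design); `"bottleneck"`
#'   restricts dropout to the deepest encoder and decoder containers.  The
#'   reduced desk-scale configuration uses `"bottleneck"`: with only two
#'   blocks per container, block-wise dropout noise exceeds the small
#'   residual concentration signal and freezes learning, while bottleneck
#'   dropout keeps the Monte Carlo uncertainty mechanism intact.
#' @param ramp_prior Field models only: parameterize the output as a
#'   residual on the obstacle-free solution.  The prediction becomes
#'   `(unet(x) + ramp) * fluid`, where `ramp` is the linear inlet-outlet
#'   profile `(j - 1/2)/L` on the unit concentration scale and `fluid`
#'   (`1 - x`) masks solid nodes to their known value 0 — both derived from
#'   the input image, adding no parameters.  The network then learns only
#'   the local, geometry-induced deviation from the harmonic baseline,
#'   which converges far faster than rediscovering the global profile from
#'   boundary cues.
#' @return A `surrogate_spec` object.
#' @export
surrogate_spec <- function(kind = c("CNET", "UNET_HALF", "UNET"),
                           input_side = 128L, dropout_p = 0.1,
                           sn_enabled = FALSE, blocks_per_container = 4L,
                           containers = 6L, n_kernels = 64L,
                           cnet_channels = c(10L, 20L, 40L, 80L, 100L),
                           cnet_kernels = c(5L, 4L, 3L, 3L, 2L),
                           fc_units = c(400L, 10L), ramp_prior = TRUE,
                           dropout_where = c("all", "bottleneck")) {
  dropout_where <- match.arg(dropout_where)
  kind <- match.arg(kind)
  if (dropout_p < 0 || dropout_p >= 1) stop_input("`dropout_p` must lie in [0, 1)")
  if (kind %in% c("UNET", "UNET_HALF")) {
    if (input_side %% 2^containers != 0)
      stop_input("input side %d is not divisible by 2^%d poolings", input_side, containers)
  } else {
    if (length(cnet_channels) != length(cnet_kernels))
      stop_input("`cnet_channels` and `cnet_kernels` lengths differ")
    s <- input_side
    for (k in cnet_kernels) {
      s <- s - k + 1
      if (s < 2) stop_input("input side %d is incompatible with the C-Net conv/pool chain", input_side)
      s <- s %/% 2
    }
  }
  structure(list(kind = kind, input_side = as.integer(input_side),
                 dropout_p = dropout_p, sn_enabled = isTRUE(sn_enabled),
                 blocks_per_container = as.integer(blocks_per_container),
                 containers = as.integer(containers),
                 n_kernels = as.integer(n_kernels),
                 cnet_channels = as.integer(cnet_channels),
                 cnet_kernels = as.integer(cnet_kernels),
                 fc_units = as.integer(fc_units),
                 ramp_prior = isTRUE(ramp_prior),
                 dropout_where = dropout_where),
            class = "surrogate_spec")
}

new_model <- function(spec, layers, extra = list()) {
  structure(c(list(spec = spec, kind = spec$kind, layers = layers), extra),
            class = c(paste0("porediff_", tolower(spec$kind)), "porediff_model"))
}

scalar_head_layers <- function(spec, flat_len) {
  layers <- list(fc1 = layer_dense(flat_len, spec$fc_units[1], act = "tanh"),
                 head_drop = layer_dropout(spec$dropout_p))
  if (spec$sn_enabled) {
    layers$sn <- layer_sn(spec$fc_units[1])
  } else {
    layers$fc2 <- layer_dense(spec$fc_units[1], spec$fc_units[2], act = "linear")
    layers$out <- layer_dense(spec$fc_units[2], 2L, act = "linear")
  }
  layers
}

#' Build the C-Net scalar predictor
#'
#' Five sections of valid convolution (ReLU) -> batch normalization ->
#' 2x2 max pooling -> dropout, then a 400-unit tanh dense layer, dropout,
#' a 10-unit linear layer and a 2-unit output head giving `(phi, D)`.
#' With `spec$sn_enabled` the 10-unit layer is replaced by the
#' self-normalization module.
#'
#' @param spec A [surrogate_spec()] with `kind = "CNET"`.
#' @param seed Optional seed for weight initialization.
#' @return A `porediff_model`.
#' @export
build_cnet <- function(spec = surrogate_spec("CNET"), seed = NULL) {
  stopifnot(spec$kind == "CNET")
  with_seed(seed, {
    layers <- list()
    s <- spec$input_side
    cin <- 1L
    shapes <- list()
    for (i in seq_along(spec$cnet_channels)) {
      k <- spec$cnet_kernels[i]; cout <- spec$cnet_channels[i]
      layers[[paste0("conv", i)]] <- layer_conv(k, k, cin, cout, pad = 0L)
      s <- s - k + 1
      shapes[[paste0("conv", i)]] <- c(s, s, cout)
      layers[[paste0("bn", i)]] <- layer_bnorm(cout)
      layers[[paste0("pool", i)]] <- layer_maxpool()
      s <- s %/% 2
      shapes[[paste0("pool", i)]] <- c(s, s, cout)
      layers[[paste0("drop", i)]] <- layer_dropout(spec$dropout_p)
      cin <- cout
    }
    layers$flatten <- layer_flatten()
    flat_len <- s * s * cin
    layers <- c(layers, scalar_head_layers(spec, flat_len))
    for (nm in names(layers))
      if (is.null(layers[[nm]]$out_shape))
        layers[[nm]]$out_shape <- shapes[[nm]] %||% NULL
    new_model(spec, layers, list(flatten_length = flat_len, task = "scalar"))
  })
}

# Dropout placement: "all" puts p in every block; "bottleneck" only in the
# deepest encoder container and the bottleneck decoder container.
unet_dropout_p <- function(spec, container, side) {
  if (!identical(spec$dropout_where, "bottleneck")) return(spec$dropout_p)
  keep <- (side == "enc" && container == spec$containers) ||
          (side == "dec" && container == 1L)
  if (keep) spec$dropout_p else 0
}

unet_encoder_layers <- function(spec) {
  layers <- list()
  cin <- 1L
  for (k in seq_len(spec$containers)) {
    for (b in seq_len(spec$blocks_per_container)) {
      pre <- sprintf("enc%d_b%d_", k, b)
      layers[[paste0(pre, "conv")]] <- layer_conv(3, 3, cin, spec$n_kernels, pad = 1L)
      layers[[paste0(pre, "drop")]] <- layer_dropout(unet_dropout_p(spec, k, "enc"))
      layers[[paste0(pre, "bn")]] <- layer_bnorm(spec$n_kernels)
      cin <- spec$n_kernels
    }
    layers[[sprintf("enc%d_pool", k)]] <- layer_maxpool()
  }
  layers
}

#' Build the U-Net-Half scalar predictor
#'
#' The U-Net encoder (containers of convolution blocks, each followed by a
#' 2x2 max pool) flattened into the same dense head as the C-Net.
#'
#' @param spec A [surrogate_spec()] with `kind = "UNET_HALF"`.
#' @inheritParams build_cnet
#' @return A `porediff_model`.
#' @export
build_unet_half <- function(spec = surrogate_spec("UNET_HALF"), seed = NULL) {
  stopifnot(spec$kind == "UNET_HALF")
  with_seed(seed, {
    layers <- unet_encoder_layers(spec)
    bott <- spec$input_side %/% 2^spec$containers
    layers$flatten <- layer_flatten()
    flat_len <- bott * bott * spec$n_kernels
    layers <- c(layers, scalar_head_layers(spec, flat_len))
    new_model(spec, layers,
              list(flatten_length = flat_len, bottleneck = c(bott, bott),
                   task = "scalar"))
  })
}

#' Build the U-Net field-reconstruction model
#'
#' Encoder of `containers` downsampling containers (each
#' `blocks_per_container` blocks of 3x3 same-convolution (ReLU), dropout and
#' batch normalization, then a 2x2 max pool), a mirrored decoder whose
#' containers upsample by two (nearest neighbour) and concatenate the
#' matching encoder output, a final container without pooling, and a 1x1
#' output convolution producing the one-channel concentration map, same
#' shape as the input.
#'
#' @param spec A [surrogate_spec()] with `kind = "UNET"`.
#' @inheritParams build_cnet
#' @return A `porediff_model`.
#' @export
build_unet <- function(spec = surrogate_spec("UNET"), seed = NULL) {
  stopifnot(spec$kind == "UNET")
  with_seed(seed, {
    nk <- spec$n_kernels
    layers <- unet_encoder_layers(spec)
    # decoder: container 1 works on the bottleneck; containers >= 2
    # concatenate the upsampled stream with the matching encoder output.
    for (k in seq_len(spec$containers)) {
      for (b in seq_len(spec$blocks_per_container)) {
        cin <- if (b == 1 && k > 1) 2L * nk else nk
        pre <- sprintf("dec%d_b%d_", k, b)
        layers[[paste0(pre, "conv")]] <- layer_conv(3, 3, cin, nk, pad = 1L)
        layers[[paste0(pre, "drop")]] <- layer_dropout(unet_dropout_p(spec, k, "dec"))
        layers[[paste0(pre, "bn")]] <- layer_bnorm(nk)
      }
      layers[[sprintf("dec%d_up", k)]] <- layer_upsample()
    }
    for (b in seq_len(spec$blocks_per_container)) {
      cin <- if (b == 1) 2L * nk else nk
      pre <- sprintf("final_b%d_", b)
      layers[[paste0(pre, "conv")]] <- layer_conv(3, 3, cin, nk, pad = 1L)
      layers[[paste0(pre, "drop")]] <- layer_dropout(unet_dropout_p(spec, 0L, "final"))
      layers[[paste0(pre, "bn")]] <- layer_bnorm(nk)
    }
    layers$out_conv <- layer_conv(1, 1, nk, 1L, pad = 0L, act = "linear")
    if (spec$ramp_prior) layers$prior <- new_layer("ramp_prior")
    bott <- spec$input_side %/% 2^spec$containers
    new_model(spec, layers, list(bottleneck = c(bott, bott), task = "field"))
  })
}

# ---- forward / backward drivers -----------------------------------------

forward_sequential <- function(model, x, mode) {
  h <- x
  for (e in model$layers) h <- e$fw(h, mode)
  h
}

backward_sequential <- function(model, dy) {
  g <- dy
  for (e in rev(model$layers)) g <- e$bw(g)
  g
}

forward_unet <- function(model, x, mode) {
  spec <- model$spec
  C <- spec$containers; B <- spec$blocks_per_container
  L <- model$layers
  skips <- vector("list", C)
  h <- x
  for (k in seq_len(C)) {
    for (b in seq_len(B)) {
      pre <- sprintf("enc%d_b%d_", k, b)
      h <- L[[paste0(pre, "conv")]]$fw(h, mode)
      h <- L[[paste0(pre, "drop")]]$fw(h, mode)
      h <- L[[paste0(pre, "bn")]]$fw(h, mode)
    }
    skips[[k]] <- h
    h <- L[[sprintf("enc%d_pool", k)]]$fw(h, mode)
  }
  for (k in seq_len(C)) {
    if (k > 1) h <- cat_channels(h, skips[[C - k + 2]])
    for (b in seq_len(B)) {
      pre <- sprintf("dec%d_b%d_", k, b)
      h <- L[[paste0(pre, "conv")]]$fw(h, mode)
      h <- L[[paste0(pre, "drop")]]$fw(h, mode)
      h <- L[[paste0(pre, "bn")]]$fw(h, mode)
    }
    h <- L[[sprintf("dec%d_up", k)]]$fw(h, mode)
  }
  h <- cat_channels(h, skips[[1]])
  for (b in seq_len(B)) {
    pre <- sprintf("final_b%d_", b)
    h <- L[[paste0(pre, "conv")]]$fw(h, mode)
    h <- L[[paste0(pre, "drop")]]$fw(h, mode)
    h <- L[[paste0(pre, "bn")]]$fw(h, mode)
  }
  h <- L$out_conv$fw(h, mode)
  if (!is.null(L$prior)) {
    d <- dim(x)
    ramp <- array(rep((seq_len(d[2]) - 0.5) / d[2], each = d[1]),
                  c(d[1], d[2], 1, d[4]))
    fluid <- 1 - x
    if (mode %in% c("train", "tune")) L$prior$fluid <- fluid
    h <- (h + ramp) * fluid
  }
  h
}

backward_unet <- function(model, dy) {
  spec <- model$spec
  C <- spec$containers; B <- spec$blocks_per_container
  nk <- spec$n_kernels
  L <- model$layers
  skip_grads <- vector("list", C)
  if (!is.null(L$prior)) {
    dy <- dy * L$prior$fluid
    L$prior$fluid <- NULL
  }
  g <- L$out_conv$bw(dy)
  for (b in rev(seq_len(B))) {
    pre <- sprintf("final_b%d_", b)
    g <- L[[paste0(pre, "bn")]]$bw(g)
    g <- L[[paste0(pre, "drop")]]$bw(g)
    g <- L[[paste0(pre, "conv")]]$bw(g)
  }
  sp <- split_channels(g, nk)
  g <- sp[[1]]; skip_grads[[1]] <- sp[[2]]
  for (k in rev(seq_len(C))) {
    g <- L[[sprintf("dec%d_up", k)]]$bw(g)
    for (b in rev(seq_len(B))) {
      pre <- sprintf("dec%d_b%d_", k, b)
      g <- L[[paste0(pre, "bn")]]$bw(g)
      g <- L[[paste0(pre, "drop")]]$bw(g)
      g <- L[[paste0(pre, "conv")]]$bw(g)
    }
    if (k > 1) {
      sp <- split_channels(g, nk)
      g <- sp[[1]]
      skip_grads[[C - k + 2]] <- sp[[2]]
    }
  }
  for (k in rev(seq_len(C))) {
    g <- L[[sprintf("enc%d_pool", k)]]$bw(g)
    g <- g + skip_grads[[k]]
    for (b in rev(seq_len(B))) {
      pre <- sprintf("enc%d_b%d_", k, b)
      g <- L[[paste0(pre, "bn")]]$bw(g)
      g <- L[[paste0(pre, "drop")]]$bw(g)
      g <- L[[paste0(pre, "conv")]]$bw(g)
    }
  }
  g
}

model_forward <- function(model, x, mode = "eval") {
  if (model$kind == "UNET") forward_unet(model, x, mode)
  else forward_sequential(model, x, mode)
}

model_backward <- function(model, dy) {
  if (model$kind == "UNET") backward_unet(model, dy)
  else backward_sequential(model, dy)
}

as_input_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) != 4) stop_input("input must be an [H, W, 1, N] array or an H x W matrix")
  x
}

#' Deterministic forward pass of a surrogate model
#'
#' Batch normalization uses its running statistics and dropout is disabled.
#'
#' @param object A `porediff_model`.
#' @param x Input array `[H, W, 1, N]` (or a single `H x W` matrix), with
#'   solid nodes encoded as 1 and fluid nodes as 0.
#' @param ... Unused.
#' @return A `2 x N` matrix (`phi`, `D`) for scalar models, or an
#'   `[H, W, 1, N]` array for field models.
#' @export
predict.porediff_model <- function(object, x, ...) {
  out <- model_forward(object, as_input_array(x), mode = "eval")
  if (object$task == "scalar") rownames(out) <- c("phi", "D")
  out
}

#' Self-normalization transform
#'
#' Applies the SN output rule: the bottom pre-activations are squashed into
#' factors `2 sigmoid(z)` in `(0, 2)`, the output is the element-wise
#' product with the top branch, and the penalty `sum (1 - factor)^2`
#' (added to the training loss) measures how far the factors sit from 1.
#'
#' @param y_top Numeric vector (or matrix) of top-branch outputs.
#' @param bottom_preact Same-shape pre-activations of the bottom branch.
#' @return List with `output`, `factors`, and `penalty` (summed over
#'   everything, per-column when the input is a matrix).
#' @export
sn_transform <- function(y_top, bottom_preact) {
  if (!all(dim(y_top) %||% length(y_top) == (dim(bottom_preact) %||% length(bottom_preact))))
    stop_input("`y_top` and `bottom_preact` must have the same shape")
  factors <- 2 * stats::plogis(bottom_preact)
  penalty <- if (is.matrix(factors)) colSums((1 - factors)^2) else sum((1 - factors)^2)
  list(output = y_top * factors, factors = factors, penalty = penalty)
}

#' Monte Carlo dropout prediction
#'
#' Runs `M` stochastic forward passes with the dropout layers active (batch
#' normalization stays in inference mode) and summarizes them by their
#' element-wise mean (the prediction) and standard deviation (the 1-sigma
#' uncertainty).
#'
#' @param model A `porediff_model` containing dropout layers.
#' @param x Input array (see [predict.porediff_model()]).
#' @param M Number of stochastic passes.
#' @param seed Optional seed making the result bit-reproducible.
#' @return An `uncertainty_result`: list with `mean`, `sigma` (same shape),
#'   and `M`.
#' @export
mc_dropout_predict <- function(model, x, M = 20L, seed = NULL) {
  if (M < 2) stop_input("`M` must be >= 2")
  if (model$spec$dropout_p == 0)
    warning("dropout probability is 0: the MC-dropout uncertainty is identically zero",
            call. = FALSE)
  x <- as_input_array(x)
  with_seed(seed, {
    s1 <- NULL; s2 <- NULL
    for (m in seq_len(M)) {
      y <- model_forward(model, x, mode = "mc")
      if (is.null(s1)) { s1 <- y; s2 <- y^2 } else { s1 <- s1 + y; s2 <- s2 + y^2 }
    }
    mu <- s1 / M
    va <- pmax(s2 / M - mu^2, 0) * M / (M - 1)
    out <- list(mean = mu, sigma = sqrt(va), M = M)
    if (model$task == "scalar") rownames(out$mean) <- rownames(out$sigma) <- c("phi", "D")
    structure(out, class = "uncertainty_result")
  })
}

#' Structural walk of a surrogate model
#'
#' @param model A `porediff_model`.
#' @return Invisibly, a data frame of layers (type, parameter count); the
#'   walk is also printed with the total parameter count.
#' @export
model_describe <- function(model) {
  df <- data.frame(layer = names(model$layers),
                   type = vapply(model$layers, function(e) e$type, ""),
                   params = vapply(model$layers, n_params, 0),
                   row.names = NULL)
  cat(sprintf("%s surrogate, input %d x %d, dropout p = %g%s\n",
              model$kind, model$spec$input_side, model$spec$input_side,
              model$spec$dropout_p,
              if (isTRUE(model$spec$sn_enabled)) ", SN module" else ""))
  if (!is.null(model$flatten_length))
    cat(sprintf("flattened feature length: %d\n", model$flatten_length))
  if (!is.null(model$bottleneck))
    cat(sprintf("bottleneck: %d x %d\n", model$bottleneck[1], model$bottleneck[2]))
  print(df)
  cat(sprintf("total parameters: %d\n", sum(df$params)))
  invisible(df)
}
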