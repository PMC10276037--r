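# Dataset assembly, augmentation, training loops, and evaluation.

#' Split records (or a dataset) into training and validation parts
#'
#' Seeded uniform random split without replacement; the two parts are
#' disjoint and exhaustive.
#'
#' @param x A data frame of records, or a `porediff_dataset`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param rounding How to round `fraction * N` to the training size:
#'   `"floor"` (default), `"round"` or `"ceiling"`.
#' @return A list with elements `train` and `val` of the same class as `x`.
#' @export
split_dataset <- function(x, fraction = 0.7, seed = 1L,
                          rounding = c("floor", "round", "ceiling")) {
  UseMethod("split_dataset")
}

split_sizes <- function(n, fraction, rounding) {
  if (fraction <= 0 || fraction >= 1) stop_input("`fraction` must lie in (0, 1)")
  if (n < 2) stop_input("need at least 2 records to split")
  n_train <- switch(rounding,
                    floor = floor(fraction * n),
                    round = round(fraction * n),
                    ceiling = ceiling(fraction * n))
  max(1, min(n - 1, n_train))
}

#' @export
split_dataset.data.frame <- function(x, fraction = 0.7, seed = 1L,
                                     rounding = c("floor", "round", "ceiling")) {
  rounding <- match.arg(rounding)
  n <- nrow(x)
  n_train <- split_sizes(n, fraction, rounding)
  idx <- with_seed(seed, sample.int(n, n_train))
  train <- x[idx, , drop = FALSE]
  val <- x[-idx, , drop = FALSE]
  if ("split" %in% names(x)) { train$split <- "train"; val$split <- "val" }
  list(train = train, val = val)
}

#' @export
split_dataset.porediff_dataset <- function(x, fraction = 0.7, seed = 1L,
                                           rounding = c("floor", "round", "ceiling")) {
  rounding <- match.arg(rounding)
  n <- dim(x$x)[4]
  n_train <- split_sizes(n, fraction, rounding)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = subset_dataset(x, idx, "train"),
       val = subset_dataset(x, -idx, "val"))
}

#' Horizontal-flip augmentation
#'
#' Mirrors a sample left-right across the transport axis.  Porosity and the
#' effective diffusion coefficient are invariant under this flip, so scalar
#' labels pass through unchanged.  A concentration-field label must also be
#' mirrored, and, because the inlet/outlet concentrations stay attached to
#' the left/right sides, complemented on fluid nodes:
#' `c'(x, y) = (c_in + c_out) - c(L - 1 - x, y)`; solid nodes keep 0.
#'
#' @param sample A `porous_sample`, a logical grid, or a numeric geometry
#'   image (solid = 1).
#' @param label `NULL`, a scalar label (returned unchanged), or a numeric
#'   field matrix with 0 on solid nodes.
#' @param task `"scalar"` or `"field"`.
#' @param bc The [boundary_spec()] the field labels were generated under.
#' @return List with the flipped `sample` and `label`.
#' @export
augment_hflip <- function(sample, label = NULL, task = c("scalar", "field"),
                          bc = boundary_spec()) {
  task <- match.arg(task)
  if (inherits(sample, "porous_sample")) {
    flipped <- sample
    flipped$grid <- hflip_matrix(sample$grid)
    fluid <- flipped$grid
  } else {
    flipped <- hflip_matrix(sample)
    fluid <- if (is.logical(flipped)) flipped else flipped < 0.5
  }
  if (!is.null(label) && task == "field") {
    label <- hflip_matrix(label)
    label[fluid] <- (bc$c_in + bc$c_out) - label[fluid]
    label[!fluid] <- 0
  }
  list(sample = flipped, label = label)
}

# Flip a sub-batch of a [H,W,1,N] input array (and labels) in place.
hflip_batch <- function(x, y, which, task, bc) {
  W <- dim(x)[2]
  x[, , , which] <- x[, W:1, , which, drop = FALSE]
  if (task == "field") {
    yf <- y[, W:1, , which, drop = FALSE]
    solid <- x[, , , which, drop = FALSE] > 0.5
    yf <- (bc$c_in + bc$c_out) - yf
    yf[solid] <- 0
    y[, , , which] <- yf
  }
  list(x = x, y = y)
}

# Top-bottom mirror: the walls are symmetric Neumann boundaries, so the
# field mirrors without any complement.
vflip_batch <- function(x, y, which, task) {
  H <- dim(x)[1]
  x[, , , which] <- x[H:1, , , which, drop = FALSE]
  if (task == "field") y[, , , which] <- y[H:1, , , which, drop = FALSE]
  list(x = x, y = y)
}

#' Train a surrogate model
#'
#' Minimizes the mean-square error (plus the self-normalization penalty when
#' the model carries an SN module) with Adam.  The batch loop, shuffling,
#' dropout masks and augmentation coin-flips all draw from the stream seeded
#' by `seed`, so a run is bit-reproducible.
#'
#' @param model A `porediff_model` (mutated in place and returned).
#' @param train_data,val_data `porediff_dataset`s (see
#'   [make_porous_dataset()]); `val_data` may be `NULL`.
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Seed for shuffling/dropout/augmentation.
#' @param augment Apply random horizontal and vertical flips during
#'   training.  Both are exact symmetries of the steady problem: scalar
#'   labels are invariant; a field label mirrors (with the complement
#'   `c -> c_in + c_out - c` for the horizontal flip, since the Dirichlet
#'   sides stay fixed).
#' @param patience Stop early after this many epochs without validation
#'   improvement (`Inf` disables).
#' @param finetune_epochs Additional fine-tuning epochs appended after the
#'   main phase, run with frozen batch-norm statistics and dropout off
#'   (gradient noise from per-batch normalization and dropout masks
#'   otherwise floors the achievable error when the residual signal is
#'   small).
#' @param finetune_lr Learning rate of the fine-tuning phase.
#' @param verbose Print a line per epoch.
#' @return List (class `porediff_fit`) with the trained `model`, a
#'   `history` data frame (train/val loss per epoch, the phase, and the
#'   mean deviation of the SN factors from 1 when applicable), and the
#'   settings used.
#' @export
train_surrogate <- function(model, train_data, val_data = NULL,
                            epochs = 30L, batch_size = 16L, lr = 1e-3,
                            seed = 1L, augment = TRUE,
                            patience = Inf, finetune_epochs = 0L,
                            finetune_lr = lr / 10, verbose = FALSE) {
  stopifnot(inherits(train_data, "porediff_dataset"))
  task <- model$task
  bc <- train_data$bc %||% boundary_spec()
  x_all <- train_data$x
  y_all <- if (task == "scalar") train_data$y else train_data$field
  n <- dim(x_all)[4]
  sn_layer <- model$layers$sn
  history <- data.frame()
  best_val <- Inf; best_epoch <- 0L; stall <- 0L; t_adam <- 0L
  phases <- rbind(
    if (epochs > 0) data.frame(mode = "train", epochs = epochs, lr = lr),
    if (finetune_epochs > 0) data.frame(mode = "tune", epochs = finetune_epochs,
                                        lr = finetune_lr))
  if (is.null(phases)) stop_input("`epochs` and `finetune_epochs` are both 0")

  with_seed(seed, {
    epoch <- 0L
    for (ph in seq_len(nrow(phases))) {
      mode <- phases$mode[ph]
      for (e_in_ph in seq_len(phases$epochs[ph])) {
        epoch <- epoch + 1L
        ord <- sample.int(n)
        ep_loss <- 0; ep_n <- 0; sn_dev <- c()
        for (start in seq(1, n, by = batch_size)) {
          ids <- ord[start:min(start + batch_size - 1, n)]
          xb <- x_all[, , , ids, drop = FALSE]
          yb <- if (task == "scalar") y_all[, ids, drop = FALSE]
                else y_all[, , , ids, drop = FALSE]
          if (augment) {
            flip <- which(stats::runif(length(ids)) < 0.5)
            if (length(flip)) {
              fb <- hflip_batch(xb, if (task == "field") yb else NULL, flip, task, bc)
              xb <- fb$x
              if (task == "field") yb <- fb$y
            }
            vflip <- which(stats::runif(length(ids)) < 0.5)
            if (length(vflip)) {
              fb <- vflip_batch(xb, if (task == "field") yb else NULL, vflip, task)
              xb <- fb$x
              if (task == "field") yb <- fb$y
            }
          }
          pred <- model_forward(model, xb, mode = mode)
          err <- pred - yb
          loss <- mean(err^2)
          if (!is.finite(loss))
            stop("training diverged (non-finite loss) at epoch ", epoch)
          if (!is.null(sn_layer)) {
            loss <- loss + mean(colSums((1 - sn_layer$bottom_last)^2))
            sn_dev <- c(sn_dev, mean(abs(sn_layer$bottom_last - 1)))
          }
          dout <- 2 * err / length(err)
          model_backward(model, dout)
          t_adam <- t_adam + 1L
          adam_step(model$layers, phases$lr[ph], t_adam)
          ep_loss <- ep_loss + loss * length(ids); ep_n <- ep_n + length(ids)
        }
        val_loss <- NA_real_
        if (!is.null(val_data)) {
          vp <- predict(model, val_data$x)
          vy <- if (task == "scalar") val_data$y else val_data$field
          val_loss <- mean((vp - vy)^2)
        }
        history <- rbind(history, data.frame(
          epoch = epoch, phase = mode, train_loss = ep_loss / ep_n,
          val_loss = val_loss,
          sn_bottom_dev = if (length(sn_dev)) mean(sn_dev) else NA_real_))
        if (verbose)
          message(sprintf("epoch %3d [%s]  train %.5g  val %.5g", epoch,
                          mode, ep_loss / ep_n, val_loss))
        if (!is.null(val_data) && is.finite(val_loss)) {
          if (val_loss < best_val - 1e-12) {
            best_val <- val_loss; best_epoch <- epoch; stall <- 0L
          } else stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
  })
  structure(list(model = model, history = history, best_val = best_val,
                 best_epoch = best_epoch, seed = seed, lr = lr,
                 batch_size = batch_size, augment = augment),
            class = "porediff_fit")
}

#' @export
print.porediff_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<porediff_fit> %s, %d epochs (lr %g, batch %d%s)\n",
              x$model$kind, nrow(h), x$lr, x$batch_size,
              if (isTRUE(x$augment)) ", augmented" else ""))
  cat(sprintf("final train loss %.4g", utils::tail(h$train_loss, 1)))
  if (any(is.finite(h$val_loss)))
    cat(sprintf(", best val loss %.4g (epoch %d)", x$best_val, x$best_epoch))
  cat("\n")
  invisible(x)
}

# Run MC-dropout prediction over a dataset in batches to bound memory.
mc_predict_dataset <- function(model, x, M, seed, chunk = 32L) {
  n <- dim(x)[4]
  means <- NULL; sigmas <- NULL
  for (start in seq(1, n, by = chunk)) {
    ids <- start:min(start + chunk - 1, n)
    r <- mc_dropout_predict(model, x[, , , ids, drop = FALSE], M = M,
                            seed = if (is.null(seed)) NULL else seed + start)
    if (is.null(means)) { means <- list(); sigmas <- list() }
    means[[length(means) + 1]] <- r$mean
    sigmas[[length(sigmas) + 1]] <- r$sigma
  }
  if (model$task == "scalar") {
    list(mean = do.call(cbind, means), sigma = do.call(cbind, sigmas))
  } else {
    bind4 <- function(l) {
      d <- dim(l[[1]]); d[4] <- sum(vapply(l, function(a) dim(a)[4], 0))
      array(unlist(l), d)
    }
    list(mean = bind4(means), sigma = bind4(sigmas))
  }
}

#' Evaluate a scalar surrogate with MC-dropout uncertainties
#'
#' Runs `M` stochastic passes per sample, reports per-sample predictions
#' with 1-sigma uncertainties, the MSE of the mean predictions, the
#' uncertainty-weighted error [chibar2()], and the fraction of samples whose
#' true `(phi, D)` fall inside the 1- and 2-sigma bands.
#'
#' @param model A scalar `porediff_model`.
#' @param dataset A scalar-task `porediff_dataset`.
#' @param M Number of MC-dropout passes.
#' @param seed Optional seed.
#' @param sigma_floor Lower bound applied to the MC standard deviations
#'   before weighting (guards against degenerate zero spread).
#' @return List (class `scalar_evaluation`) with `per_sample`, `mse`,
#'   `chibar2`, and coverage fractions.
#' @export
evaluate_scalar <- function(model, dataset, M = 20L, seed = NULL,
                            sigma_floor = 1e-9) {
  stopifnot(model$task == "scalar")
  r <- mc_predict_dataset(model, dataset$x, M, seed)
  truth <- t(dataset$y)                       # N x 2
  pred <- t(r$mean); sig <- pmax(t(r$sigma), sigma_floor)
  per <- data.frame(sample_id = dataset$records$sample_id,
                    phi_true = truth[, 1], D_true = truth[, 2],
                    phi_pred = pred[, 1], D_pred = pred[, 2],
                    phi_sigma = sig[, 1], D_sigma = sig[, 2])
  within <- function(k) abs(pred - truth) <= k * sig
  structure(list(
    per_sample = per,
    mse = mean((pred - truth)^2),
    chibar2 = chibar2(pred, truth, sig),
    coverage1 = mean(rowSums(within(1)) == 2),
    coverage2 = mean(rowSums(within(2)) == 2),
    M = M), class = "scalar_evaluation")
}

#' Evaluate a field surrogate with MC-dropout uncertainties
#'
#' Per sample: the mean absolute reconstruction error over all nodes (and
#' over fluid nodes only) and the mean per-node 1-sigma uncertainty.
#'
#' @param model A field `porediff_model` (U-Net).
#' @param dataset A field-task `porediff_dataset`.
#' @param M Number of MC-dropout passes.
#' @param seed Optional seed.
#' @param keep_maps Also return the per-sample mean/sigma/error maps.
#' @return List (class `field_evaluation`) with `per_sample`,
#'   `mean_abs_error` (grand mean over samples of the all-node means),
#'   `mean_sigma`, and optionally `maps`.
#' @export
evaluate_field <- function(model, dataset, M = 20L, seed = NULL,
                           keep_maps = FALSE) {
  stopifnot(model$task == "field")
  r <- mc_predict_dataset(model, dataset$x, M, seed)
  n <- dim(dataset$x)[4]
  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    truth <- dataset$field[, , 1, i]
    pred <- r$mean[, , 1, i]
    fluid <- dataset$x[, , 1, i] < 0.5
    err <- abs(truth - pred)
    data.frame(sample_id = dataset$records$sample_id[i],
               mae_all = mean(err),
               mae_fluid = mean(err[fluid]),
               mean_sigma = mean(r$sigma[, , 1, i]))
  }))
  out <- list(per_sample = per,
              mean_abs_error = mean(per$mae_all),
              mean_sigma = mean(per$mean_sigma), M = M)
  if (keep_maps) out$maps <- r
  structure(out, class = "field_evaluation")
}
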