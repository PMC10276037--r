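# Serialization, manifests, and the end-to-end pipeline.

#' Save / load a porous sample
#'
#' The grid is written as a 1-bit-style grayscale PNG (white = solid,
#' black = fluid) with a JSON sidecar (`<path>.json`) carrying the
#' generator metadata, so the round trip is lossless.
#'
#' @param sample A `porous_sample`.
#' @param path PNG file path.
#' @return `save_sample` the path, invisibly; `load_sample` the
#'   reconstructed `porous_sample`.
#' @export
save_sample <- function(sample, path) {
  stopifnot(inherits(sample, "porous_sample"))
  png::writePNG(matrix(as.numeric(!sample$grid), nrow(sample$grid)), path)
  meta <- list(sample_type = sample$sample_type,
               target_porosity = sample$target_porosity,
               seed = sample$seed, side_length = sample$side_length,
               coordinate_convention = "0-based, x = column = transport axis, origin top-left",
               meta = sample$meta[setdiff(names(sample$meta), "dist_field")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_sample
#' @export
load_sample <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (nrow(img) != ncol(img))
    stop_input("corrupt sample file %s: image is not square (%d x %d)",
               path, nrow(img), ncol(img))
  grid <- img < 0.5           # black = fluid
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path)
    porous_sample(grid, sample_type = m$sample_type %||% "custom",
                  target_porosity = as.numeric(m$target_porosity %||% NA),
                  seed = as.integer(m$seed %||% NA),
                  meta = lapply(m$meta %||% list(), unlist))
  } else porous_sample(grid)
}

#' Save a concentration field as a grayscale PNG
#'
#' Fluid nodes map linearly from `[c_min, c_max]` to gray levels; solid
#' nodes are white.
#'
#' @param field A `concentration_field`.
#' @param path PNG file path.
#' @export
save_field_png <- function(field, path) {
  v <- field$values
  rng <- range(v, na.rm = TRUE)
  img <- (v - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  img[is.na(img)] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Write / read a dataset manifest
#'
#' One CSV row per sample (id, type, seed, target porosity, achieved
#' porosity, effective diffusion, split); an MD5 stamp of the content is
#' stored next to it so downstream reports can reference the exact
#' manifest they were computed from.
#'
#' @param records Data frame of sample records.
#' @param path CSV path.
#' @return The MD5 hash of the written manifest, invisibly.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  hash <- unname(tools::md5sum(path))
  writeLines(hash, paste0(path, ".md5"))
  invisible(hash)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Pipeline configuration
#'
#' Defaults describe a desk-scale run (small lattice, few samples, short
#' training) exercising every stage end to end.
#'
#' @param task `"scalar"` or `"field"`.
#' @param type Training data type, `"A"` or `"B"`.
#' @param eval_type Optional second data type for cross-type evaluation.
#' @param n_samples,L,phi_range Dataset parameters ([make_porous_dataset()]).
#' @param tolerance Solver tolerance for the labels.
#' @param epochs,batch_size,lr Training parameters.
#' @param sn_enabled Attach the SN module (scalar task).
#' @param split_fraction,seed Split and root seed.
#' @param M MC-dropout passes at evaluation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(task = c("scalar", "field"), type = c("A", "B"),
                            eval_type = NULL, n_samples = 20L, L = 32L,
                            phi_range = NULL, tolerance = 1e-10,
                            epochs = 5L, batch_size = 8L, lr = 1e-3,
                            sn_enabled = FALSE, split_fraction = 0.7,
                            seed = 1L, M = 10L) {
  structure(list(task = match.arg(task), type = match.arg(type),
                 eval_type = eval_type, n_samples = as.integer(n_samples),
                 L = as.integer(L), phi_range = phi_range,
                 tolerance = tolerance, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 sn_enabled = sn_enabled, split_fraction = split_fraction,
                 seed = as.integer(seed), M = as.integer(M)),
            class = "pipeline_config")
}

# Reduced scalar / field architectures sized for a given lattice side.
scaled_scalar_spec <- function(L, sn_enabled = FALSE, dropout_p = 0.1) {
  if (L >= 128)
    return(surrogate_spec("CNET", input_side = L, dropout_p = dropout_p,
                          sn_enabled = sn_enabled))
  if (L >= 64)
    surrogate_spec("CNET", input_side = L, dropout_p = dropout_p,
                   sn_enabled = sn_enabled,
                   cnet_channels = c(8L, 16L, 32L), cnet_kernels = c(5L, 3L, 3L),
                   fc_units = c(64L, 10L))
  else
    surrogate_spec("CNET", input_side = L, dropout_p = dropout_p,
                   sn_enabled = sn_enabled,
                   cnet_channels = c(8L, 16L), cnet_kernels = c(5L, 3L),
                   fc_units = c(32L, 10L))
}

scaled_field_spec <- function(L, dropout_p = 0.1) {
  containers <- if (L >= 64) 3L else 2L
  surrogate_spec("UNET", input_side = L, dropout_p = dropout_p,
                 containers = containers, blocks_per_container = 2L,
                 n_kernels = 32L, dropout_where = "bottleneck")
}

#' Run the full pipeline
#'
#' Generate -> solve -> label -> split -> train -> evaluate, writing a
#' manifest, sample PNGs, the dataset, the training history and the
#' evaluation report under `out_dir`.  Re-running with the same config and
#' an existing manifest skips regeneration unless `force = TRUE`.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param force Regenerate everything even when outputs exist.
#' @return Invisibly, a list with the dataset, fit, evaluation(s), Archie
#'   fit, and the artifact paths.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "samples"), showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  ds_path <- file.path(out_dir, "dataset.rds")
  task <- config$task

  if (file.exists(ds_path) && !force) {
    message("[dataset] reusing ", ds_path)
    ds <- readRDS(ds_path)
  } else {
    t0 <- proc.time()[3]
    message(sprintf("[dataset] generating %d type-%s samples at L = %d (seed %d)",
                    config$n_samples, config$type, config$L, config$seed))
    ds <- make_porous_dataset(config$n_samples, config$type, config$L,
                              phi_range = config$phi_range, seed = config$seed,
                              task = if (task == "field") "both" else "scalar",
                              solver = solver_config(tolerance = config$tolerance),
                              keep_samples = TRUE)
    for (i in seq_len(config$n_samples))
      save_sample(ds$samples[[i]],
                  file.path(out_dir, "samples",
                            paste0(ds$records$sample_id[i], ".png")))
    saveRDS(ds, ds_path)
    message(sprintf("[dataset] done in %.1f s", proc.time()[3] - t0))
  }

  sp <- split_dataset(ds, config$split_fraction,
                      seed = sub_seed(config$seed, "split"))
  recs <- rbind(sp$train$records, sp$val$records)
  hash <- write_manifest(recs, manifest_path)
  message("[manifest] ", nrow(recs), " rows, md5 ", hash)

  message("[train] task ", task, ", ", config$epochs, " epochs")
  model <- if (task == "scalar")
    build_cnet(scaled_scalar_spec(config$L, config$sn_enabled),
               seed = sub_seed(config$seed, "init"))
  else
    build_unet(scaled_field_spec(config$L), seed = sub_seed(config$seed, "init"))
  fit <- train_surrogate(model, sp$train, sp$val, epochs = config$epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = sub_seed(config$seed, "train"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  message("[evaluate] M = ", config$M)
  evaluation <- if (task == "scalar")
    evaluate_scalar(model, sp$val, M = config$M,
                    seed = sub_seed(config$seed, "mc"))
  else
    evaluate_field(model, sp$val, M = config$M,
                   seed = sub_seed(config$seed, "mc"))
  metrics <- if (task == "scalar")
    list(mse = evaluation$mse, chibar2 = evaluation$chibar2,
         coverage1 = evaluation$coverage1, coverage2 = evaluation$coverage2)
  else
    list(mean_abs_error = evaluation$mean_abs_error,
         mean_sigma = evaluation$mean_sigma)
  archie <- tryCatch(fit_archie(ds$records), error = function(e) NULL,
                     warning = function(w) suppressWarnings(fit_archie(ds$records)))
  if (!is.null(archie)) metrics$archie_n <- archie$n
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  cross <- NULL
  if (!is.null(config$eval_type)) {
    message("[evaluate] cross-type on type ", config$eval_type)
    ds2 <- make_porous_dataset(max(10L, config$n_samples %/% 2),
                               config$eval_type, config$L,
                               seed = sub_seed(config$seed, "cross"),
                               task = if (task == "field") "both" else "scalar",
                               solver = solver_config(tolerance = config$tolerance))
    cross <- if (task == "scalar")
      evaluate_scalar(model, ds2, M = config$M)
    else evaluate_field(model, ds2, M = config$M)
  }

  invisible(list(dataset = ds, fit = fit, evaluation = evaluation,
                 cross_evaluation = cross, archie = archie,
                 paths = list(manifest = manifest_path, dataset = ds_path),
                 manifest_hash = hash))
}
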