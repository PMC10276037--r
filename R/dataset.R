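# Labeled dataset assembly: generate geometries, solve the steady diffusion
# problem, and package (image, label) pairs for surrogate training.

#' Generate a labeled porous-media dataset
#'
#' Draws `n_samples` target porosities uniformly from `phi_range`, generates
#' a percolating sample per target (type A or B), solves each to steady
#' state, and assembles the training tensors: geometry images `x`
#' (`[L, L, 1, n]`, solid = 1, fluid = 0), scalar labels `y` (2 x n matrix
#' of porosity and effective diffusion) and, for the field task, the
#' concentration maps `field` (`[L, L, 1, n]`, 0 on solid nodes).
#'
#' @param n_samples Number of samples.
#' @param type `"A"` (overlapping grains) or `"B"` (Voronoi channels).
#' @param L Side length in nodes.
#' @param phi_range Range the target porosities are drawn from; defaults to
#'   `c(0.45, 0.95)` for type A (above the percolation floor) and
#'   `c(0.15, 0.7)` for type B.
#' @param seed Root seed; every sample derives its own sub-seed.
#' @param task `"scalar"`, `"field"`, or `"both"`.
#' @param solver [solver_config()] used for the labels.
#' @param bc [boundary_spec()].
#' @param normalization Flux normalization for the diffusion label, see
#'   [effective_diffusion()]; the default `"total"` (superficial average)
#'   is the convention under which `D = phi^(n-1)` Archie fits describe
#'   these media.
#' @param n_points,width_step,block_size Generator parameters.
#' @param keep_samples Keep the `porous_sample` objects in the result.
#' @param verbose Progress messages.
#' @return A `porediff_dataset`: list with `x`, `y`, `field` (or `NULL`),
#'   `records` (data frame: sample_id, type, seed, target_phi, phi, D,
#'   split), `task`, `L`, `bc`.
#' @export
make_porous_dataset <- function(n_samples, type = c("A", "B"), L = 64L,
                                phi_range = NULL, seed = 1L,
                                task = c("scalar", "field", "both"),
                                solver = solver_config(tolerance = 1e-10),
                                bc = boundary_spec(),
                                normalization = "total",
                                n_points = 50L, width_step = 0.25,
                                block_size = 3L, keep_samples = FALSE,
                                verbose = FALSE) {
  type <- match.arg(type); task <- match.arg(task)
  phi_range <- phi_range %||% if (type == "A") c(0.45, 0.95) else c(0.15, 0.7)
  x <- array(0, c(L, L, 1L, n_samples))
  fld <- if (task != "scalar") array(0, c(L, L, 1L, n_samples)) else NULL
  y <- matrix(0, 2L, n_samples, dimnames = list(c("phi", "D"), NULL))
  samples <- if (keep_samples) vector("list", n_samples) else NULL
  recs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    si <- sub_seed(seed, paste0("gen", type), i)
    tgt <- with_seed(si, stats::runif(1, phi_range[1], phi_range[2]))
    s <- if (type == "A")
      generate_type_a(L, generator_config_a(tgt, block_size = block_size), seed = si)
    else
      generate_type_b(L, generator_config_b(tgt, n_points = n_points,
                                            width_step = width_step), seed = si)
    f <- solve_steady(s, bc, solver)
    D <- effective_diffusion(f, s, bc, normalization = normalization)
    x[, , 1, i] <- 1 - s$grid           # solid = 1
    y[, i] <- c(porosity(s), D)
    if (!is.null(fld)) {
      cmap <- f$values; cmap[is.na(cmap)] <- 0
      fld[, , 1, i] <- cmap
    }
    if (keep_samples) samples[[i]] <- s
    recs[[i]] <- data.frame(sample_id = sprintf("%s%04d", type, i), type = type,
                            seed = si, target_phi = tgt, phi = y[1, i],
                            D = y[2, i], split = NA_character_)
    if (verbose && i %% 25 == 0) message("generated ", i, "/", n_samples)
  }
  structure(list(x = x, y = y, field = fld,
                 records = do.call(rbind, recs), task = task, L = L, bc = bc,
                 samples = samples, normalization = normalization),
            class = "porediff_dataset")
}

subset_dataset <- function(ds, idx, split = NA_character_) {
  out <- ds
  out$x <- ds$x[, , , idx, drop = FALSE]
  out$y <- ds$y[, idx, drop = FALSE]
  if (!is.null(ds$field)) out$field <- ds$field[, , , idx, drop = FALSE]
  if (!is.null(ds$samples)) out$samples <- ds$samples[idx]
  out$records <- ds$records[idx, , drop = FALSE]
  if (!is.na(split)) out$records$split <- split
  rownames(out$records) <- NULL
  out
}

#' @export
print.porediff_dataset <- function(x, ...) {
  cat(sprintf("<porediff_dataset> %d type-%s samples, L = %d, task %s\n",
              dim(x$x)[4], x$records$type[1], x$L, x$task))
  invisible(x)
}
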