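# Shared fixtures, built lazily and cached for the whole test run.
# The heavier labeled datasets (used by several acceptance checks) are
# generated once at the spec's scaled study conditions: L = 64, solver
# tolerance 1e-10, type-A targets uniform in [0.45, 0.95], type-B targets
# uniform in [0.15, 0.7].

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(build)
  .fixture_cache[[name]]
}

# n-sample labeled dataset of a given type (superficial-D labels + fields)
scaled_dataset <- function(type, n, seed, task = "both") {
  fixture(paste("ds", type, n, seed, task, sep = "_"),
          make_porous_dataset(n, type, L = 64L, seed = seed, task = task,
                              solver = solver_config(tolerance = 1e-10)))
}

# independent flood-fill percolation oracle: iterative reachability by
# 4-neighbour dilation from the left column
percolates_oracle <- function(grid) {
  reach <- grid & col(grid) == 1
  repeat {
    grown <- reach
    nr <- nrow(grid)
    grown[-1, ] <- grown[-1, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    nc <- ncol(grid)
    grown[, -1] <- grown[, -1] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown <- grown & grid
    if (identical(grown, reach)) break
    reach <- grown
  }
  any(reach[, ncol(grid)])
}

# Three independent 40-sample type-A replicate batches (scalar labels),
# also pooled into the scaled type-A training set.
typeA_replicates <- function() {
  fixture("typeA_reps", lapply(1:3, function(r)
    make_porous_dataset(40, "A", L = 64L, seed = sub_seed(1, "archieA", r),
                        task = "scalar",
                        solver = solver_config(tolerance = 1e-10))))
}

pool_datasets <- function(lst) {
  out <- lst[[1]]
  out$x <- array(unlist(lapply(lst, `[[`, "x")),
                 c(dim(lst[[1]]$x)[1:3], sum(vapply(lst, function(d) dim(d$x)[4], 0))))
  out$y <- do.call(cbind, lapply(lst, `[[`, "y"))
  if (!is.null(lst[[1]]$field))
    out$field <- array(unlist(lapply(lst, `[[`, "field")), dim(out$x))
  out$records <- do.call(rbind, lapply(lst, `[[`, "records"))
  rownames(out$records) <- NULL
  out
}

# 150 type-B (geometry, phi, D, concentration-map) pairs; its records are
# also consumed as three 50-sample replicate batches.
typeB_field_150 <- function() {
  fixture("typeB150",
          make_porous_dataset(150, "B", L = 64L, seed = 2024, task = "both",
                              solver = solver_config(tolerance = 1e-10)))
}

typeA_field_20 <- function() {
  fixture("typeA20",
          make_porous_dataset(20, "A", L = 64L, seed = 3025, task = "both",
                              solver = solver_config(tolerance = 1e-10)))
}

linear_profile <- function(L, c_in = 0, c_out = 1)
  matrix(rep(c_in + (c_out - c_in) * (seq_len(L) - 0.5) / L, each = L), L, L)

solve_and_D <- function(sample, tol = 1e-10, normalization = "pore") {
  f <- solve_steady(sample, cfg = solver_config(tolerance = tol))
  effective_diffusion(f, sample, normalization = normalization)
}
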