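# Porous-geometry generation and measurement.
#
# A porous sample is an L x L boolean lattice: TRUE marks a fluid (pore)
# node, FALSE a solid node.  Columns run along the transport axis x (the
# left boundary is column 1), rows along y.  Two generator families are
# provided: type A stamps overlapping 3x3 solid grains into an all-fluid
# domain (granular media such as sand packings); type B grows fluid channels
# of uniform width around the Voronoi-edge network of a random point set
# (extracellular-space-like tissue geometries).

#' Construct a porous sample
#'
#' Wraps an `L x L` logical grid (`TRUE` = fluid node, `FALSE` = solid node)
#' together with its generator provenance.  Columns run along the transport
#' axis; column 1 is the inlet side.
#'
#' @param grid Square logical matrix, `TRUE` for fluid nodes; `L >= 8`.
#' @param sample_type One of `"A"`, `"B"`, `"custom"`.
#' @param target_porosity Porosity the generator aimed for (or `NA`).
#' @param seed Integer seed used by the generator (or `NA`).
#' @param meta Optional named list of extra generator metadata.
#' @return An object of class `porous_sample`.
#' @examples
#' s <- porous_sample(matrix(TRUE, 16, 16))
#' porosity(s)
#' @export
porous_sample <- function(grid, sample_type = c("custom", "A", "B"),
                          target_porosity = NA_real_, seed = NA_integer_,
                          meta = list()) {
  sample_type <- match.arg(sample_type)
  if (!is.matrix(grid) || !is.logical(grid))
    stop_input("`grid` must be a logical matrix")
  if (nrow(grid) != ncol(grid))
    stop_input("`grid` must be square (got %d x %d)", nrow(grid), ncol(grid))
  if (nrow(grid) < 8)
    stop_input("side length must be at least 8 nodes (got %d)", nrow(grid))
  if (anyNA(grid))
    stop_input("`grid` must not contain missing values")
  structure(
    list(grid = grid, side_length = nrow(grid), sample_type = sample_type,
         target_porosity = target_porosity, seed = seed, meta = meta),
    class = "porous_sample")
}

#' @export
print.porous_sample <- function(x, ...) {
  cat(sprintf("<porous_sample> type %s, L = %d, porosity = %.4f",
              x$sample_type, x$side_length, porosity(x)))
  if (!is.na(x$target_porosity))
    cat(sprintf(" (target %.3f)", x$target_porosity))
  cat("\n")
  invisible(x)
}

as_grid <- function(x) {
  if (inherits(x, "porous_sample")) return(x$grid)
  if (is.matrix(x) && is.logical(x)) return(x)
  stop_input("expected a `porous_sample` or a logical matrix")
}

#' Porosity of a sample
#'
#' The pore fraction \eqn{\varphi = |D_f| / L^2}, the ratio of the number of
#' fluid nodes to the total number of lattice nodes.
#'
#' @param sample A `porous_sample` or a logical matrix (`TRUE` = fluid).
#' @return Porosity in `[0, 1]`.
#' @export
porosity <- function(sample) {
  g <- as_grid(sample)
  if (length(g) == 0) stop_input("empty grid")
  mean(g)
}

#' Left-right percolation test
#'
#' `TRUE` when a path of 4-neighbour (von Neumann) adjacent fluid nodes
#' connects some fluid node of the first column to some fluid node of the
#' last column.  Diagonal-only contact does not carry axis-aligned diffusive
#' streaming and is not counted as connected.
#'
#' @inheritParams porosity
#' @return Logical scalar.
#' @export
percolates <- function(sample) {
  cpp_percolates(as_grid(sample))
}

#' Generator configuration for type-A (granular) samples
#'
#' @param target_porosity Target pore fraction; must exceed the percolation
#'   floor of randomly deposited overlapping square grains (about 0.4 for
#'   3x3 blocks).
#' @param block_size Side of the square solid grains, in nodes.
#' @param max_rejections How many non-percolating configurations to resample
#'   before giving up.
#' @return A `generator_config_a` list.
#' @export
generator_config_a <- function(target_porosity, block_size = 3L,
                               max_rejections = 200L) {
  if (block_size < 1) stop_input("`block_size` must be >= 1")
  if (!is.numeric(target_porosity) || target_porosity <= 0 || target_porosity > 1)
    stop_input("`target_porosity` must lie in (0, 1]")
  structure(list(block_size = as.integer(block_size),
                 target_porosity = target_porosity,
                 max_rejections = as.integer(max_rejections)),
            class = "generator_config_a")
}

#' Generator configuration for type-B (channel-network) samples
#'
#' @param target_porosity Target pore fraction in (0, 1].
#' @param n_points Number of Voronoi seed points placed in the domain.
#' @param width_step Increment of the channel half-width per widening step,
#'   in lattice units.
#' @return A `generator_config_b` list.
#' @export
generator_config_b <- function(target_porosity, n_points = 50L,
                               width_step = 0.25) {
  if (n_points < 3) stop_input("`n_points` must be >= 3")
  if (!is.numeric(width_step) || width_step <= 0)
    stop_input("`width_step` must be > 0")
  if (!is.numeric(target_porosity) || target_porosity <= 0 || target_porosity > 1)
    stop_input("`target_porosity` must lie in (0, 1]")
  structure(list(n_points = as.integer(n_points),
                 target_porosity = target_porosity,
                 width_step = width_step),
            class = "generator_config_b")
}

#' Generate a type-A (overlapping-grain) sample
#'
#' Solid `block_size x block_size` squares are stamped at integer positions
#' drawn uniformly in `[0, L)` (overlap allowed; blocks protruding past the
#' boundary are clipped) until the porosity first drops to or below the
#' target.  Configurations that fail the left-right percolation test are
#' rejected and regenerated from a derived sub-seed, so generation at a fixed
#' seed is bit-reproducible.
#'
#' @param L Side length in nodes.
#' @param cfg A [generator_config_a()].
#' @param seed Integer seed.
#' @return A percolating `porous_sample` with
#'   `target - block_size^2/L^2 <= porosity <= target`.
#' @export
generate_type_a <- function(L = 128L, cfg, seed) {
  stopifnot(inherits(cfg, "generator_config_a"))
  target <- cfg$target_porosity
  if (target <= 0.4 && target < 1)
    stop_generation(paste0(
      "target porosity %.3f is at or below the percolation threshold of ",
      "randomly deposited overlapping %dx%d blocks (~0.4): such samples ",
      "cannot percolate between the left and right boundaries"),
      target, cfg$block_size, cfg$block_size)
  bs <- cfg$block_size
  n_nodes <- as.numeric(L)^2
  for (attempt in seq_len(cfg$max_rejections)) {
    grid <- with_seed(sub_seed(seed, "typeA", attempt), {
      g <- matrix(TRUE, L, L)
      n_fluid <- n_nodes
      while (n_fluid / n_nodes > target) {
        x <- sample.int(L, 1L) - 1L   # column offset, 0-based
        y <- sample.int(L, 1L) - 1L   # row offset
        rows <- (y + 1L):min(y + bs, L)
        cols <- (x + 1L):min(x + bs, L)
        n_fluid <- n_fluid - sum(g[rows, cols])
        g[rows, cols] <- FALSE
      }
      g
    })
    if (cpp_percolates(grid))
      return(porous_sample(grid, "A", target, as.integer(seed),
                           meta = list(attempts = attempt)))
  }
  stop_generation(paste0(
    "no percolating configuration found in %d attempts at target porosity ",
    "%.3f: the target is too close to the ~0.4 percolation threshold of ",
    "overlapping %dx%d blocks"),
    cfg$max_rejections, target, bs, bs)
}

# Fluid mask of a type-B sample at channel half-width w.
channel_mask <- function(dist_field, w) dist_field <= w

#' Generate a type-B (Voronoi channel-network) sample
#'
#' `n_points` seed points are drawn uniformly in `[0, L)^2` and replicated
#' into the eight neighbouring period images to suppress boundary effects.
#' The edges of the Voronoi tessellation of the tiled set are the channel
#' centrelines.  Starting from an all-solid grid, a node becomes fluid when
#' its centre lies within distance `w` of any centreline segment; `w` grows
#' in steps of `cfg$width_step` until the porosity reaches the target (and,
#' if a one-node-wide discretized channel happens to be 4-disconnected, until
#' the mask also percolates).
#'
#' @param L Side length in nodes.
#' @param cfg A [generator_config_b()].
#' @param seed Integer seed.
#' @param keep_distance Keep the centreline distance field in `meta`
#'   (useful for width-monotonicity checks).
#' @return A percolating `porous_sample` with porosity `>=` target; the
#'   achieved channel half-width and the porosity one step earlier are stored
#'   in `meta`.
#' @export
generate_type_b <- function(L = 128L, cfg, seed, keep_distance = FALSE) {
  stopifnot(inherits(cfg, "generator_config_b"))
  target <- cfg$target_porosity
  for (attempt in 1:25) {
    pts <- with_seed(sub_seed(seed, "typeB", attempt),
                     matrix(stats::runif(2 * cfg$n_points, 0, L), ncol = 2))
    if (min(stats::dist(pts)) > 1e-8 * L) break
    message("degenerate type-B point set (duplicate points); regenerating ",
            "with perturbed sub-seed")
  }
  offs <- as.matrix(expand.grid(x = c(-L, 0, L), y = c(-L, 0, L)))
  tiled <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(pts[, 1] + offs[i, 1], pts[, 2] + offs[i, 2])))
  edges <- cpp_voronoi_edges(tiled, -2.5 * L, 3.5 * L)
  dist_field <- cpp_segment_distance_field(edges, as.integer(L))

  step <- cfg$width_step
  k <- max(1L, ceiling(min(dist_field) / step))  # first width with any fluid
  repeat {
    w <- k * step
    g <- channel_mask(dist_field, w)
    if (mean(g) >= target && cpp_percolates(g)) break
    k <- k + 1L
  }
  phi_prev <- mean(channel_mask(dist_field, (k - 1L) * step))
  meta <- list(width = w, width_step = step, phi_prev = phi_prev,
               widened_for_percolation = phi_prev >= target)
  if (keep_distance) meta$dist_field <- dist_field
  porous_sample(g, "B", target, as.integer(seed), meta = meta)
}

# Mirror a grid (or field matrix) left-right across the transport axis.
hflip_matrix <- function(m) m[, ncol(m):1, drop = FALSE]
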