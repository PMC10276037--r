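# Steady diffusion on a porous sample with a D2Q5 lattice kinetic solver.
#
# The concentration field obeys dc/dt = div(D0 grad c) inside the pore
# space, with zero normal flux on solid surfaces and on the top/bottom
# walls, and fixed concentrations on faces half a node outside the first
# and last columns (so the inlet-outlet distance equals the node count L).
# The scheme is a two-relaxation-time (TRT) D2Q5 lattice Boltzmann update;
# the odd relaxation time sets the bulk diffusivity D0 = c_s^2 (tau - 1/2)
# with c_s^2 = 1/3, and the even relaxation time is tied to the "magic"
# product Lambda = 1/4, for which the converged field coincides with the
# 5-point finite-volume discretization assembled by [laplace_oracle()].

#' Solver configuration
#'
#' @param tolerance Convergence threshold on the maximum node-wise change of
#'   the concentration between two consecutive iterations.
#' @param max_iterations Iteration cap.
#' @param D0 Bulk diffusivity in lattice units; the odd relaxation time is
#'   derived from it as `tau = 1/2 + 3 D0`.
#' @param relaxation_time Odd (flux) relaxation time; must be consistent
#'   with `D0` if both are given.
#' @param check_interval Convergence is tested every this many iterations.
#' @param lambda_trt Magic product of the two relaxation offsets; `1/4`
#'   makes the steady state coincide with the 5-point finite-volume solution.
#' @return A `solver_config` list.
#' @export
solver_config <- function(tolerance = 1e-13, max_iterations = 1e6,
                          D0 = 1, relaxation_time = NULL,
                          check_interval = 10L, lambda_trt = 0.25) {
  if (tolerance <= 0) stop_input("`tolerance` must be > 0")
  if (D0 <= 0) stop_input("`D0` must be > 0")
  tau <- 0.5 + 3 * D0
  if (!is.null(relaxation_time)) {
    if (relaxation_time <= 0.5)
      stop_input("`relaxation_time` must be > 1/2")
    if (abs((relaxation_time - 0.5) / 3 - D0) > 1e-12)
      stop_input("`relaxation_time` %.4f is inconsistent with D0 = %g (need tau = 1/2 + 3 D0)",
                 relaxation_time, D0)
    tau <- relaxation_time
  }
  structure(list(tolerance = tolerance, max_iterations = max_iterations,
                 relaxation_time = tau, D0 = D0,
                 check_interval = as.integer(check_interval),
                 lambda_trt = lambda_trt),
            class = "solver_config")
}

#' Boundary specification
#'
#' Fixed concentrations on the inlet (left) and outlet (right) faces;
#' reflecting (zero normal flux) conditions on the top/bottom walls and on
#' all solid-fluid interfaces are implied.
#'
#' @param c_in Concentration on the left face (default 0).
#' @param c_out Concentration on the right face (default 1).
#' @return A `boundary_spec` list.
#' @export
boundary_spec <- function(c_in = 0, c_out = 1) {
  if (c_in == c_out) stop_input("`c_in` and `c_out` must differ")
  structure(list(c_in = c_in, c_out = c_out), class = "boundary_spec")
}

new_concentration_field <- function(values, iterations, final_delta,
                                    converged, method = "lbm") {
  structure(list(values = values, iterations_run = iterations,
                 final_delta = final_delta, converged = converged,
                 method = method),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> %d x %d (%s), iterations = %s, final delta = %.3g, converged: %s\n",
              nrow(x$values), ncol(x$values), x$method,
              format(x$iterations_run), x$final_delta, x$converged))
  invisible(x)
}

#' Solve the steady diffusion problem on a porous sample
#'
#' Iterates the D2Q5 collision-streaming update (half-way bounce-back at
#' reflecting surfaces, anti-bounce-back fixed-concentration closure at the
#' inlet/outlet faces) until the maximum concentration change between two
#' consecutive iterations falls below `cfg$tolerance`, or the iteration cap
#' is reached.  Fluid pockets not connected to either face keep the initial
#' value `bc$c_in` (their enclosure is flux-free).
#'
#' @param sample A `porous_sample` or logical matrix (`TRUE` = fluid).
#' @param bc A [boundary_spec()].
#' @param cfg A [solver_config()].
#' @return A `concentration_field`: the `L x L` field (`NA` on solid nodes)
#'   plus iteration diagnostics.
#' @export
solve_steady <- function(sample, bc = boundary_spec(), cfg = solver_config()) {
  grid <- as_grid(sample)
  if (!cpp_percolates(grid))
    warning("sample does not percolate between the left and right boundaries; ",
            "the steady field is piecewise constant and D = 0", call. = FALSE)
  res <- cpp_lbm_solve(grid, bc$c_in, bc$c_out,
                       cfg$relaxation_time, cfg$lambda_trt,
                       cfg$tolerance, cfg$max_iterations,
                       cfg$check_interval, bc$c_in)
  new_concentration_field(res$c, res$iterations, res$final_delta, res$converged)
}

#' Maximum concentration change between two iterates
#'
#' @param c_now,c_prev Same-shape numeric matrices.
#' @param fluid_mask Logical matrix; only fluid nodes enter the maximum.
#' @return `max |c_now - c_prev|` over fluid nodes.
#' @export
convergence_delta <- function(c_now, c_prev, fluid_mask) {
  if (!all(dim(c_now) == dim(c_prev)) || !all(dim(c_now) == dim(fluid_mask)))
    stop_input("field/mask shapes differ")
  if (!any(fluid_mask)) return(0)
  max(abs(c_now[fluid_mask] - c_prev[fluid_mask]))
}

#' Effective diffusion coefficient from a converged field
#'
#' Discrete Fick's-law estimator
#' \deqn{D = \frac{L}{N (c_{out} - c_{in})} \sum_{r_i \in D_f}
#'       \left(\partial c / \partial x\right)\big|_{r_i}.}
#' The gradient uses a central difference over fluid x-neighbours, a
#' one-sided difference when one neighbour is solid, zero when both are,
#' and the face value (`c_in` / `c_out` at half a node spacing) in the
#' first and last columns.
#'
#' Two flux-normalization conventions are supported through `N`:
#' `"pore"` divides by the number of fluid nodes (an intrinsic,
#' pore-space-averaged coefficient: exactly `D0` for straight channels at
#' any porosity), while `"total"` divides by all `L^2` nodes (the
#' superficial, Darcy-style coefficient: smaller by a factor `phi`, and the
#' convention under which the Archie relation `D = phi^(n-1)` describes the
#' porosity dependence of these media).  Both equal `D0` on an
#' obstacle-free domain.
#'
#' @param field A `concentration_field` from [solve_steady()] or
#'   [laplace_oracle()].
#' @param sample The sample the field was solved on.
#' @param bc The boundary specification used.
#' @param D0 Bulk diffusivity the solver was calibrated to (default 1).
#' @param normalization `"pore"` (default) or `"total"`, see above.
#' @return Effective diffusion coefficient in units of `D0`.
#' @export
effective_diffusion <- function(field, sample, bc = boundary_spec(), D0 = 1,
                                normalization = c("pore", "total")) {
  normalization <- match.arg(normalization)
  grid <- as_grid(sample)
  v <- field$values
  if (!all(dim(v) == dim(grid))) stop_input("field/sample shapes differ")
  L <- ncol(v)
  if (sum(grid) == 0) stop_input("sample has no fluid nodes")
  N <- if (normalization == "pore") sum(grid) else length(grid)

  lv <- cbind(NA_real_, v[, -L, drop = FALSE]); ld <- matrix(1, nrow(v), L)
  rv <- cbind(v[, -1, drop = FALSE], NA_real_); rd <- matrix(1, nrow(v), L)
  lv[, 1] <- bc$c_in;  ld[, 1] <- 0.5
  rv[, L] <- bc$c_out; rd[, L] <- 0.5

  grad <- matrix(0, nrow(v), L)
  both <- !is.na(lv) & !is.na(rv)
  onlyl <- !is.na(lv) & is.na(rv)
  onlyr <- is.na(lv) & !is.na(rv)
  grad[both] <- (rv[both] - lv[both]) / (ld[both] + rd[both])
  grad[onlyl] <- (v[onlyl] - lv[onlyl]) / ld[onlyl]
  grad[onlyr] <- (rv[onlyr] - v[onlyr]) / rd[onlyr]

  D0 * L / (N * (bc$c_out - bc$c_in)) * sum(grad[grid])
}

#' Direct sparse finite-volume solution of the steady diffusion problem
#'
#' Independent verification oracle for [solve_steady()]: assembles the
#' 5-point finite-volume Laplacian on fluid nodes (unit conductance on
#' fluid-fluid links, zero-flux faces at solid/wall interfaces, Dirichlet
#' faces of conductance 2 half a node outside the first/last columns) and
#' solves the linear system exactly.  Fluid components touching neither
#' Dirichlet face make the system singular; they are excluded, set to the
#' solver's initial value `bc$c_in`, and flagged in the result.
#'
#' @inheritParams solve_steady
#' @return A `concentration_field` (method `"laplace"`); the number of
#'   Dirichlet-free components is stored in attribute `isolated_components`.
#' @export
laplace_oracle <- function(sample, bc = boundary_spec()) {
  grid <- as_grid(sample)
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- cpp_components(grid)
  touching <- unique(c(lab[, 1], lab[, nc]))
  touching <- touching[touching > 0]
  solvable <- grid & (lab %in% touching)
  dim(solvable) <- dim(grid)
  n_iso <- length(setdiff(unique(lab[lab > 0]), touching))

  values <- matrix(NA_real_, nr, nc)
  values[grid] <- bc$c_in   # isolated pockets keep the initial value
  n <- sum(solvable)
  if (n > 0) {
    id <- matrix(NA_integer_, nr, nc)
    id[solvable] <- seq_len(n)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    diag_w <- numeric(n)
    b <- numeric(n)
    # fluid-fluid links, vertical and horizontal
    link <- function(ida, idb) {
      ok <- !is.na(ida) & !is.na(idb)
      a <- ida[ok]; bb <- idb[ok]
      ii <<- c(ii, a, bb); jj <<- c(jj, bb, a); xx <<- c(xx, rep(-1, 2 * length(a)))
      tab <- tabulate(c(a, bb), nbins = n)
      diag_w <<- diag_w + tab
    }
    link(id[-nr, , drop = FALSE], id[-1, , drop = FALSE])
    link(id[, -nc, drop = FALSE], id[, -1, drop = FALSE])
    # Dirichlet faces at half spacing: conductance 2
    left <- id[, 1][!is.na(id[, 1])]
    right <- id[, nc][!is.na(id[, nc])]
    diag_w[left] <- diag_w[left] + 2
    diag_w[right] <- diag_w[right] + 2
    b[left] <- b[left] + 2 * bc$c_in
    b[right] <- b[right] + 2 * bc$c_out
    A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                              x = c(xx, diag_w), dims = c(n, n))
    sol <- as.numeric(Matrix::solve(A, b))
    values[!is.na(id)] <- sol[id[!is.na(id)]]
  }
  out <- new_concentration_field(values, NA_real_, 0, TRUE, method = "laplace")
  attr(out, "isolated_components") <- n_iso
  out
}
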