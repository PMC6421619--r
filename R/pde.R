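# Method-of-lines discretisation: second-order conservative finite
# differences on a uniform grid over the scaled defect thickness x in [0, 1],
# boundary conditions assembled by ghost-node elimination, and stiff time
# integration through deSolve.

#' Uniform spatial grid on the scaled defect
#'
#' @param n_nodes number of nodes (>= 3), endpoints included. `x = 0` is the
#'   subchondral bone side, `x = 1` the interface with healthy cartilage.
#' @return An object of class `cart_grid` with fields `n_nodes`, `x`
#'   (coordinates) and `h` (spacing `1/(n_nodes - 1)`).
#' @export
make_grid <- function(n_nodes = 101L) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 3L)
  h <- 1 / (n_nodes - 1L)
  structure(
    list(n_nodes = n_nodes, x = seq(0, 1, length.out = n_nodes), h = h),
    class = "cart_grid"
  )
}

#' Construct a spatial state of the six fields
#'
#' @param grid a `cart_grid`.
#' @param cs,cc,n,m,g,b field profiles; scalars are recycled over the grid.
#' @return An object of class `cart_state`: a named list of numeric vectors
#'   of length `grid$n_nodes` in the order `cs`, `cc`, `n`, `m`, `g`, `b`.
#' @export
make_state <- function(grid, cs = 0, cc = 0, n = 1, m = 0, g = 0, b = 0) {
  stopifnot(inherits(grid, "cart_grid"))
  vals <- list(cs = cs, cc = cc, n = n, m = m, g = g, b = b)
  out <- lapply(vals, function(v) {
    if (length(v) == 1L) v <- rep(v, grid$n_nodes)
    if (length(v) != grid$n_nodes) {
      stop("field length does not match grid (", grid$n_nodes, " nodes)",
           call. = FALSE)
    }
    as.numeric(v)
  })
  structure(out, class = "cart_state")
}

pack_state <- function(state) unlist(state[FIELDS], use.names = FALSE)

unpack_state <- function(y, n_nodes) {
  out <- split(y, rep(seq_along(FIELDS), each = n_nodes))
  names(out) <- FIELDS
  out
}

# Flux-form second-order Laplacian with ghost-node boundary closures.
# `Dface` is the diffusivity at the N-1 interior faces (scalar or vector);
# the left end is always reflected (no flux); `right` selects the closure at
# x = 1. For the Robin closure the ghost node satisfies a flux balance
# -D du/dx = robin_coef * u, giving an extra sink 2*robin_coef*u[N]/h.
diffuse_1d <- function(u, Dface, h, right = c("reflect", "robin"),
                       robin_coef = 0) {
  right <- match.arg(right)
  N <- length(u)
  G <- Dface * diff(u)              # D * (u[i+1] - u[i]) at faces
  du <- numeric(N)
  du[2:(N - 1)] <- G[2:(N - 1)] - G[1:(N - 2)]
  du[1] <- 2 * G[1]
  du[N] <- -2 * G[N - 1]
  du <- du / h^2
  if (right == "robin") du[N] <- du[N] - 2 * robin_coef * u[N] / h
  du
}

rhs_core <- function(t, y, parms) {
  N <- parms$n_nodes
  p <- parms$p
  h <- parms$h
  s <- unpack_state(y, N)
  r <- reaction_rates(s, p, parms$eps)
  m <- s$m
  mf <- 0.5 * (m[-1] + m[-N])       # matrix density at cell faces
  mob <- mf / (mf * mf + p$m1^2)
  dcs <- r$dcs + diffuse_1d(s$cs, p$ds0 * mob, h)
  dcc <- r$dcc + diffuse_1d(s$cc, p$dc0 * mob, h)
  dm <- r$dm + diffuse_1d(m, p$dm, h)
  if (parms$bc_mode == "paper") {
    dn <- r$dn + diffuse_1d(s$n, p$dn, h)
    dn[N] <- 0                      # nutrient reservoir pins n = 1 at x = 1
    dg <- r$dg + diffuse_1d(s$g, p$dg, h, right = "robin",
                            robin_coef = p$gamma)
    db <- r$db + diffuse_1d(s$b, p$db, h, right = "robin",
                            robin_coef = p$chi)
  } else {
    dn <- r$dn + diffuse_1d(s$n, p$dn, h)
    dg <- r$dg + diffuse_1d(s$g, p$dg, h)
    db <- r$db + diffuse_1d(s$b, p$db, h)
  }
  list(c(dcs, dcc, dn, dm, dg, db))
}

#' Assemble the semi-discrete right-hand side
#'
#' Evaluates the spatially discretised time derivative of the flattened
#' state: conservative second-order fluxes of the (matrix-dependent)
#' diffusion terms, with interface motilities evaluated at the arithmetic
#' mean of the matrix density on adjacent nodes, plus the local
#' [reaction_rates()]. Boundary closures in `bc_mode = "paper"`: no flux for
#' every field at `x = 0`; at `x = 1` no flux for cells and matrix, the
#' nutrient pinned at its reservoir value 1 (its derivative at the boundary
#' node is forced to zero), and Robin outflow `-D du/dx = coef * u` for both
#' growth factors. `bc_mode = "all_no_flux"` reflects every field at both
#' ends (a closed domain, used for solver verification against well-mixed
#' dynamics).
#'
#' @param t time (unused by the autonomous model; part of the solver
#'   contract).
#' @param y flattened state, fields concatenated in the order `cs`, `cc`,
#'   `n`, `m`, `g`, `b`, each of length `grid$n_nodes`.
#' @param grid a `cart_grid`.
#' @param p a `cart_params` object.
#' @param eps gate smoothing width.
#' @param bc_mode `"paper"` or `"all_no_flux"`.
#' @return Numeric vector `dy/dt` of the same length as `y`.
#' @export
assemble_rhs <- function(t, y, grid, p, eps = 1e-2,
                         bc_mode = c("paper", "all_no_flux")) {
  bc_mode <- match.arg(bc_mode)
  stopifnot(inherits(grid, "cart_grid"))
  if (length(y) != 6L * grid$n_nodes) {
    stop("state vector has length ", length(y), ", expected ",
         6L * grid$n_nodes, " (6 fields x ", grid$n_nodes, " nodes)",
         call. = FALSE)
  }
  parms <- list(n_nodes = grid$n_nodes, h = grid$h, p = p, eps = eps,
                bc_mode = bc_mode)
  rhs_core(t, y, parms)[[1L]]
}

#' Integrate the semi-discrete model in time
#'
#' Method-of-lines integration of [assemble_rhs()] with an implicit stiff
#' integrator (`deSolve::ode.1D`, default `lsoda`, which switches to BDF on
#' the stiff transients and exploits the banded Jacobian of the
#' nearest-neighbour coupling).
#'
#' @param state0 initial `cart_state` on `grid`.
#' @param t_eval increasing vector of dimensionless output times starting
#'   at 0.
#' @param grid a `cart_grid`.
#' @param p a `cart_params` object.
#' @param eps gate smoothing width.
#' @param bc_mode boundary-condition mode, see [assemble_rhs()].
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method a stiff-capable `deSolve` method name.
#' @return An object of class `cart_trajectory`: a list with `times`, a
#'   `fields` list of time-by-node matrices (one per field), the `grid`, the
#'   parameter snapshot `params`, and `solver_meta` (tolerances, grid size,
#'   `eps`, `bc_mode`, method, integrator step statistics).
#' @export
integrate_pde <- function(state0, t_eval, grid, p, eps = 1e-2,
                          bc_mode = c("paper", "all_no_flux"),
                          rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  bc_mode <- match.arg(bc_mode)
  stopifnot(inherits(state0, "cart_state"), inherits(grid, "cart_grid"))
  if (length(state0$cs) != grid$n_nodes) {
    stop("initial state is not on the supplied grid", call. = FALSE)
  }
  t_eval <- as.numeric(t_eval)
  if (length(t_eval) < 2L || t_eval[1L] != 0 || any(diff(t_eval) <= 0)) {
    stop("'t_eval' must increase strictly from 0", call. = FALSE)
  }
  parms <- list(n_nodes = grid$n_nodes, h = grid$h, p = p, eps = eps,
                bc_mode = bc_mode)
  out <- deSolve::ode.1D(
    y = pack_state(state0), times = t_eval, func = rhs_core, parms = parms,
    nspec = 6L, dimens = grid$n_nodes, method = method,
    rtol = rtol, atol = atol
  )
  if (nrow(out) < length(t_eval)) {
    last_t <- out[nrow(out), 1L]
    stop("integrator failed at t = ", format(last_t), " (reached ",
         nrow(out) - 1L, " of ", length(t_eval) - 1L, " output times)",
         call. = FALSE)
  }
  sol <- out[, -1L, drop = FALSE]
  N <- grid$n_nodes
  fields <- lapply(seq_along(FIELDS), function(k) {
    mat <- sol[, ((k - 1L) * N + 1L):(k * N), drop = FALSE]
    dimnames(mat) <- NULL
    mat
  })
  names(fields) <- FIELDS
  diagn <- attr(out, "istate")
  structure(
    list(
      times = t_eval,
      fields = fields,
      grid = grid,
      params = p,
      solver_meta = list(
        method = method, rtol = rtol, atol = atol, eps = eps,
        bc_mode = bc_mode, n_nodes = N,
        n_steps = if (!is.null(diagn)) diagn[3L] else NA_integer_
      )
    ),
    class = "cart_trajectory"
  )
}

#' Extract one field profile or full state from a trajectory
#'
#' @param traj a `cart_trajectory`.
#' @param i time index (row).
#' @return `get_state`: a `cart_state`; `get_profile`: a numeric vector.
#' @export
get_state <- function(traj, i) {
  stopifnot(inherits(traj, "cart_trajectory"))
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= length(traj$times))
  out <- lapply(traj$fields, function(mat) mat[i, ])
  structure(out, class = "cart_state")
}

#' @rdname get_state
#' @param field one of `"cs"`, `"cc"`, `"n"`, `"m"`, `"g"`, `"b"`.
#' @export
get_profile <- function(traj, field, i) {
  stopifnot(inherits(traj, "cart_trajectory"))
  field <- match.arg(field, FIELDS)
  traj$fields[[field]][as.integer(i), ]
}

#' @export
print.cart_trajectory <- function(x, ...) {
  cat("<cart_trajectory> ", length(x$times), " states on ",
      x$grid$n_nodes, " nodes, t = [", format(min(x$times)), ", ",
      format(max(x$times)), "]", sep = "")
  if (!is.null(x$scenario)) cat(", scenario '", x$scenario, "'", sep = "")
  cat("\n")
  invisible(x)
}

#' Observed spatial order of accuracy
#'
#' Runs the same scenario on a sequence of grids (each refining the last by
#' a factor 2 in spacing), restricts the solutions to the common coarse
#' nodes, and estimates the convergence order from the ratio of successive
#' solution differences (Richardson estimate on the matrix profile at the
#' final time by default). Time-integration tolerances are tightened so the
#' spatial error dominates.
#'
#' @param spec a scenario specification, see [scenario_spec()].
#' @param n_nodes three grid sizes; each `n - 1` must double the previous.
#' @param t_months evaluation time in months (scenario is run to this time).
#' @param field field whose profile is compared.
#' @param rtol,atol tightened time-integration tolerances.
#' @return A list with the estimated `order`, the successive-difference
#'   norms `err_coarse` and `err_fine`, and the grid sizes.
#' @export
convergence_order <- function(spec, n_nodes = c(51L, 101L, 201L),
                              t_months = 2, field = "m",
                              rtol = 1e-9, atol = 1e-12) {
  stopifnot(length(n_nodes) == 3L)
  n_nodes <- as.integer(n_nodes)
  if (any((n_nodes[-1L] - 1L) != 2L * (n_nodes[-3L] - 1L))) {
    stop("each grid must halve the spacing of the previous one",
         call. = FALSE)
  }
  field <- match.arg(field, FIELDS)
  profiles <- lapply(n_nodes, function(N) {
    sp <- spec
    sp$n_nodes <- N
    sp$duration_months <- t_months
    sp$cadence_months <- t_months
    sp$rtol <- rtol
    sp$atol <- atol
    traj <- run_scenario(sp)
    traj$fields[[field]][length(traj$times), ]
  })
  coarse <- function(u, N_from) u[seq(1L, N_from, by = (N_from - 1L) %/%
                                        (n_nodes[1L] - 1L))]
  u1 <- profiles[[1L]]
  u2 <- coarse(profiles[[2L]], n_nodes[2L])
  u3 <- coarse(profiles[[3L]], n_nodes[3L])
  err_coarse <- sqrt(mean((u1 - u2)^2))
  err_fine <- sqrt(mean((u2 - u3)^2))
  if (!(err_coarse > err_fine && err_fine > 0)) {
    stop("non-monotone error sequence (", format(err_coarse), " vs ",
         format(err_fine), "); order estimate unreliable", call. = FALSE)
  }
  list(order = log2(err_coarse / err_fine),
       err_coarse = err_coarse, err_fine = err_fine, n_nodes = n_nodes)
}
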