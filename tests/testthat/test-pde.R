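# Spatial discretisation, boundary assembly and stiff time integration.

test_that("the grid is uniform on [0, 1] with consistent spacing", {
  g <- make_grid(101)
  expect_equal(g$x[1], 0)
  expect_equal(g$x[g$n_nodes], 1)
  expect_lt(max(abs(diff(g$x) - g$h)), 1e-14)
  expect_error(make_grid(2))
  expect_error(make_state(g, cs = rep(1, 5)), "length")
})

test_that("diffusion vanishes for uniform profiles and conforms to the grid", {
  p <- default_dimensionless()
  grid <- make_grid(21)
  s <- make_state(grid, cs = 0.2, cc = 0.1, n = 0.8, m = 0.3, g = 0.05,
                  b = 0.02)
  dy <- assemble_rhs(0, pack_state_for_test(s), grid, p,
                     bc_mode = "all_no_flux")
  r <- reaction_rates(lapply(s, function(v) v[1]), p)
  expect_equal(dy, rep(unlist(r, use.names = FALSE), each = 21),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(assemble_rhs(0, rep(0, 10), grid, p), "length")
})

test_that("with no cells and a full nutrient column the nutrient is stationary", {
  p <- default_dimensionless()
  grid <- make_grid(31)
  s <- make_state(grid, cs = 0, cc = 0, n = 1, m = 1e-4, g = 0, b = 0)
  dy <- assemble_rhs(0, pack_state_for_test(s), grid, p, bc_mode = "paper")
  dn <- dy[(2 * 31 + 1):(3 * 31)]
  expect_equal(dn, rep(0, 31))
})

test_that("the flux-form Laplacian conserves mass under no-flux closures", {
  # single interior spike in the matrix field, no cells anywhere: every
  # reaction term is zero and the trapezoid integral of dm must vanish
  p <- default_dimensionless()
  grid <- make_grid(41)
  m <- rep(1e-3, 41); m[15] <- 0.5
  s <- make_state(grid, cs = 0, cc = 0, n = 1, m = m, g = 0, b = 0)
  dy <- assemble_rhs(0, pack_state_for_test(s), grid, p,
                     bc_mode = "all_no_flux")
  dm <- dy[(3 * 41 + 1):(4 * 41)]
  w <- c(0.5, rep(1, 39), 0.5) * grid$h
  expect_equal(sum(w * dm), 0, tolerance = 1e-12)
  # same property for a stem-cell spike moving by matrix-dependent motility
  pq <- dimensionless_params(p10 = 0, p2 = 0, p3 = 0)
  cs <- rep(0, 41); cs[20] <- 0.3
  s <- make_state(grid, cs = cs, cc = 0, n = 1, m = 0.1, g = 0, b = 0)
  dy <- assemble_rhs(0, pack_state_for_test(s), grid, pq,
                     bc_mode = "all_no_flux")
  dcs <- dy[1:41]
  expect_equal(sum(w * dcs), 0, tolerance = 1e-12)
})

test_that("integration reproduces closed-form growth-factor decay", {
  p <- default_dimensionless()
  grid <- make_grid(11)
  s <- make_state(grid, cs = 0, cc = 0, n = 1, m = 1e-4, g = p$g_init,
                  b = 0)
  tr <- integrate_pde(s, c(0, 0.5, 1), grid, p, bc_mode = "all_no_flux",
                      rtol = 1e-10, atol = 1e-14)
  for (i in 2:3) {
    expect_equal(get_profile(tr, "g", i),
                 rep(p$g_init * exp(-p$p11 * tr$times[i]), 11),
                 tolerance = 1e-6)
  }
})

test_that("the stiff solver agrees with an independent 0-D RK4 oracle", {
  p <- dimensionless_params(ds0 = 0, dc0 = 0, dn = 0, dm = 0, dg = 0,
                            db = 0, .force = TRUE)
  eps <- 1e-2
  s0 <- list(cs = 0.1, cc = 0.01, n = 0.9, m = 0.05, g = 0.02, b = 0.01)
  oracle <- rk4_kinetics(s0, p, eps, t_end = 1, dt = 1e-4)
  grid <- make_grid(11)
  st <- do.call(make_state, c(list(grid), s0))
  tr <- integrate_pde(st, c(0, 1), grid, p, eps = eps,
                      bc_mode = "all_no_flux", rtol = 1e-10, atol = 1e-14)
  end <- get_state(tr, 2)
  for (f in names(s0)) {
    # uniform dynamics: every node must match the well-mixed solution
    expect_equal(end[[f]], rep(oracle[[f]], 11),
                 tolerance = 1e-4, label = paste("field", f))
    rel <- abs(end[[f]][1] - oracle[[f]]) / max(abs(oracle[[f]]), 1e-6)
    expect_lt(rel, 1e-4)
  }
})

test_that("all-no-flux transport without reactions conserves every field", {
  pq <- dimensionless_params(p10 = 0, p2 = 0, p3 = 0, p40 = 0, p400 = 0,
                             p5 = 0, p6 = 0, p7 = 0, p9 = 0, p11 = 0,
                             p12 = 0, p13 = 0)
  grid <- make_grid(41)
  x <- grid$x
  s <- make_state(grid, cs = 0.2 * exp(-(x / 0.2)^2), cc = 0,
                  n = 0.5 + 0.4 * x, m = 0.1 + 0.05 * sin(pi * x),
                  g = 0.1 * (1 - x), b = 0.05 * x)
  tr <- integrate_pde(s, c(0, 1, 2), grid, pq, bc_mode = "all_no_flux",
                      rtol = 1e-10, atol = 1e-13)
  w <- c(0.5, rep(1, 39), 0.5) * grid$h
  for (f in c("cs", "n", "m", "g", "b")) {
    tot0 <- sum(w * tr$fields[[f]][1, ])
    for (i in 2:3) {
      expect_equal(sum(w * tr$fields[[f]][i, ]), tot0, tolerance = 1e-8,
                   label = paste("integral of", f, "at output", i))
    }
  }
})

test_that("pure diffusion of a cosine mode decays at second order in space", {
  # g-field eigenmode cos(pi x) under no-flux ends: exact solution
  # g(x, t) = exp(-dg pi^2 t) cos(pi x)
  pq <- dimensionless_params(p9 = 0, p11 = 0)
  t_end <- 0.1
  errs <- sapply(c(26L, 51L), function(N) {
    grid <- make_grid(N)
    s <- make_state(grid, cs = 0, cc = 0, n = 1, m = 1e-4,
                    g = 0.5 * (1 + cos(pi * grid$x)), b = 0)
    tr <- integrate_pde(s, c(0, t_end), grid, pq, bc_mode = "all_no_flux",
                        rtol = 1e-10, atol = 1e-13)
    exact <- 0.5 + 0.5 * exp(-pq$dg * pi^2 * t_end) * cos(pi * grid$x)
    max(abs(get_profile(tr, "g", 2) - exact))
  })
  order <- log2(errs[1] / errs[2])
  expect_gt(order, 1.8)
  expect_lt(order, 2.2)
})

test_that("uniform reaction-free states are integrated exactly on any grid", {
  pq <- dimensionless_params(p10 = 0, p2 = 0, p3 = 0, p40 = 0, p400 = 0,
                             p5 = 0, p6 = 0, p7 = 0, p9 = 0, p11 = 0,
                             p12 = 0, p13 = 0)
  for (N in c(11L, 21L)) {
    grid <- make_grid(N)
    # no chondrocytes: matrix deposition (not a zeroable rate constant)
    # would otherwise proceed
    s <- make_state(grid, cs = 0.1, cc = 0, n = 0.7, m = 0.2, g = 0.1,
                    b = 0.1)
    tr <- integrate_pde(s, c(0, 1), grid, pq, bc_mode = "all_no_flux")
    for (f in c("cs", "cc", "n", "m", "g", "b")) {
      expect_equal(get_profile(tr, f, 2), get_profile(tr, f, 1),
                   tolerance = 1e-9)
    }
  }
})
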