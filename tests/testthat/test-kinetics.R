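# Pointwise reaction kinetics: gates, closures, rates and their invariants.

test_that("smooth Heaviside is a symmetric saturating switch", {
  for (eps in c(1e-1, 1e-2, 1e-3)) {
    expect_equal(smooth_heaviside(0, eps), 0.5)
    expect_equal(smooth_heaviside(10 * eps, eps), 1, tolerance = 1e-8)
    expect_equal(smooth_heaviside(-10 * eps, eps), 0, tolerance = 1e-8)
  }
  expect_error(smooth_heaviside(0, eps = 0))
})

test_that("BMP-2 lowers the differentiation threshold from cs0max to cs0min", {
  p <- default_dimensionless()
  expect_equal(threshold_cs0(0, p), 0.35)
  expect_equal(threshold_cs0(1e6, p), 0.315)
  # hand evaluation at alpha = 100, b = 0.01
  expect_equal(threshold_cs0(0.01, p), 0.315 + 0.035 * exp(-1))
  expect_equal(threshold_cs0(0.01, p), 0.32788, tolerance = 2e-5)
  b <- seq(0, 0.2, length.out = 50)
  th <- threshold_cs0(b, p)
  expect_true(all(diff(th) < 0))
  expect_true(all(th >= p$cs0min & th <= p$cs0max))
})

test_that("matrix-dependent closures match hand evaluations", {
  p <- default_dimensionless()
  # motility peaks at m = m1 with value ds0/(2*m1)
  cl <- closures(m = 0.1, g = 0, cs = 0, cc = 0, p)
  expect_equal(cl$DS, 5 * p$ds0)
  expect_equal(cl$DC, 5 * p$dc0)
  m_grid <- seq(0.01, 0.99, by = 0.01)
  DS_all <- closures(m_grid, 0, 0, 0, p)$DS
  expect_equal(max(DS_all), 5 * p$ds0, tolerance = 1e-12)
  # pristine defect: full matrix production rate
  expect_equal(closures(0, 0, 0, 0, p)$p8, 1)
  # chondrocyte proliferation with saturated FGF-1 contribution
  cl <- closures(m = 0.1, g = 1, cs = 0, cc = 0, p)
  expect_equal(cl$p4, 0.012 * 5 + 0.012 * 0.5)
  # crowding factors floor at zero instead of going negative
  cl <- closures(m = 0.5, g = 0, cs = 0.4, cc = 0.3, p)
  expect_equal(cl$p1, 0)   # cs above cs_max = 0.3
  expect_equal(cl$p4, 0)   # cc above cc_max = 0.2
  cl <- closures(m = 1, g = 0, cs = 0.1, cc = 0.1, p)
  expect_equal(cl$p1, 0)
  expect_true(is.finite(cl$p4))
})

test_that("reaction rates reproduce elementary balances", {
  p <- default_dimensionless()
  zero <- list(cs = 0, cc = 0, n = 0, m = 0, g = 0, b = 0)
  expect_equal(unlist(reaction_rates(zero, p)), rep(0, 6),
               ignore_attr = TRUE)
  # pure exponential decay of FGF-1 when no cells are present
  s <- list(cs = 0, cc = 0, n = 1, m = 0, g = p$g_init, b = 0)
  expect_equal(reaction_rates(s, p)$dg, -p$p11 * p$g_init)
  # differentiation transfers cells one-to-one
  pq <- dimensionless_params(p10 = 0, p40 = 0, p400 = 0, p3 = 0, p5 = 0)
  s <- list(cs = 0.5, cc = 0.1, n = 1, m = 0.1, g = 0, b = 0)
  r <- reaction_rates(s, pq, eps = 1e-2)
  expect_equal(r$dcs, -pq$p2 * 0.5, tolerance = 1e-8)
  expect_identical(r$dcs + r$dcc, 0)
  expect_error(reaction_rates(list(cs = NaN, cc = 0, n = 0, m = 0, g = 0,
                                   b = 0), p), "cs")
})

test_that("cell number is conserved under pure differentiation", {
  pq <- dimensionless_params(p10 = 0, p40 = 0, p400 = 0, p3 = 0, p5 = 0)
  set.seed(42)
  for (i in 1:200) {
    s <- list(cs = runif(1, 0, 0.8), cc = runif(1, 0, 0.8),
              n = runif(1, 0, 1), m = runif(1, 0, 0.99),
              g = runif(1, 0, 2), b = runif(1, 0, 0.1))
    r <- reaction_rates(s, pq, eps = 10^runif(1, -4, -1))
    expect_identical(r$dcs + r$dcc, 0)
  }
})

test_that("rates respect the model's monotonicity structure", {
  p <- default_dimensionless()
  set.seed(7)
  for (i in 1:100) {
    s <- list(cs = runif(1, 0, 0.6), cc = runif(1, 0, 0.3),
              n = runif(1, 0, 1), m = runif(1, 0, 0.9),
              g = runif(1, 0, 2), b = runif(1, 0, 0.05))
    r <- reaction_rates(s, p)
    # nutrient is only consumed
    expect_lte(r$dn, 0)
    # matrix deposition grows with nutrient and with chondrocyte density
    s_up <- s; s_up$n <- min(1, s$n + 0.1)
    expect_gte(reaction_rates(s_up, p)$dm, r$dm)
    s_up <- s; s_up$cc <- s$cc + 0.05
    expect_gte(reaction_rates(s_up, p)$dm, r$dm)
    # FGF-1 speeds chondrocyte proliferation below the crowding cap
    cl <- closures(s$m, s$g, s$cs, s$cc, p)
    if (s$cc < cl$cc_max) {
      cl_up <- closures(s$m, s$g + 0.5, s$cs, s$cc, p)
      expect_gt(cl_up$p4, cl$p4)
    }
  }
})

test_that("smoothed gates converge to the sharp-switch rates away from thresholds", {
  p <- default_dimensionless()
  sharp_rates <- function(s, p) {
    # independent sharp-Heaviside evaluation of the same kinetics
    H <- function(z) as.numeric(z > 0)
    cl <- closures(s$m, s$g, s$cs, s$cc, p)
    upt <- s$n / (s$n + p$n0)
    tr <- p$p2 * s$cs * H(s$cs - threshold_cs0(s$b, p))
    list(
      dcs = cl$p1 * upt * s$cs * H(s$n - p$n1) - tr -
        p$p3 * s$cs * H(p$n1 - s$n),
      dcc = cl$p4 * upt * s$cc * H(s$n - p$n1) + tr -
        p$p5 * s$cc * H(p$n1 - s$n),
      dn = -upt * (p$p6 * s$cs + p$p7 * s$cc),
      dm = cl$p8 * upt * s$cc,
      dg = p$p9 * s$cs - p$p11 * s$g,
      db = p$p12 * s$cc - p$p13 * s$b
    )
  }
  set.seed(11)
  states <- replicate(50, list(
    cs = runif(1, 0, 0.8), cc = runif(1, 0, 0.5), n = runif(1, 0, 1),
    m = runif(1, 0, 0.9), g = runif(1, 0, 1), b = runif(1, 0, 0.05)
  ), simplify = FALSE)
  worst <- sapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    errs <- sapply(states, function(s) {
      # only judge states well away from every switching surface
      margin <- min(abs(s$n - p$n1), abs(s$cs - threshold_cs0(s$b, p)))
      if (margin < 10 * eps) return(0)
      max(abs(unlist(reaction_rates(s, p, eps)) - unlist(sharp_rates(s, p))))
    })
    max(errs)
  })
  expect_true(all(diff(worst) < 0))
  expect_lt(worst[3], 1e-6)
})
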