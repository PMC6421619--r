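# Pointwise reaction kinetics of the dimensionless model: everything on the
# right-hand side of the six field equations except the diffusion operators.
# All functions are vectorised over nodes so the same code serves the PDE
# solver and a 0-D (well-mixed) integration.

FIELDS <- c("cs", "cc", "n", "m", "g", "b")

#' Smooth Heaviside switch
#'
#' `0.5 * (1 + tanh(z / eps))`: a smooth regularisation of the unit step,
#' equal to 1/2 at `z = 0` and saturating to 0/1 within a few multiples of
#' `eps`. The model gates stem-cell differentiation, proliferation and
#' nutrient-starvation death on field thresholds; the smooth form keeps the
#' right-hand side differentiable for the stiff implicit integrator. One
#' width `eps` is used for every gate.
#'
#' @param z signed distance from the switching threshold.
#' @param eps smoothing width (> 0); default `1e-2`.
#' @return Values in (0, 1), same shape as `z`.
#' @export
smooth_heaviside <- function(z, eps = 1e-2) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0)
  0.5 * (1 + tanh(z / eps))
}

#' BMP-2-modulated differentiation threshold
#'
#' The stem-cell density above which differentiation into chondrocytes
#' switches on. BMP-2 (produced by chondrocytes) lowers the threshold
#' exponentially from `cs0max` (no BMP-2) towards the floor `cs0min`:
#' `(cs0max - cs0min) * exp(-alpha * b) + cs0min`.
#'
#' @param b dimensionless BMP-2 concentration (>= 0), vectorised.
#' @param p a `cart_params` object.
#' @return Threshold density in `[cs0min, cs0max]`, strictly decreasing in `b`.
#' @export
threshold_cs0 <- function(b, p) {
  (p$cs0max - p$cs0min) * exp(-p$alpha * b) + p$cs0min
}

#' Matrix- and growth-factor-dependent closures
#'
#' Evaluates the nonlinear coefficient functions of the model at given local
#' matrix density `m`, FGF-1 level `g` and cell densities:
#' * cell motilities `DS`, `DC` proportional to `m / (m^2 + m1^2)`
#'   (cells need some matrix to crawl on, excess matrix blocks them);
#' * density caps `cs_max = cs_max0 * (1 - m)`, `cc_max = cc_max0 * (1 - m)`
#'   (matrix displaces room for cells);
#' * proliferation rates `p1` (stem) and `p4` (chondrocyte), each a
#'   matrix-mediated rate times logistic crowding `1 - c / c_max(m)`; the
#'   chondrocyte rate gains an FGF-1 term `p400 * g / (g + 1)`;
#' * matrix synthesis rate `p8 = (1 - p81 * m) * (1 + p800 * g / (g + 1))`.
#'
#' The logistic crowding factors are floored at 0 once the local density
#' reaches (or the cap falls below) zero room, so no negative proliferation
#' is produced in the fully-packed regime.
#'
#' @param m,g,cs,cc dimensionless local fields (vectorised, equal length).
#' @param p a `cart_params` object.
#' @return A list with elements `DS`, `DC`, `p1`, `p4`, `p8`, `cs_max`,
#'   `cc_max`.
#' @export
closures <- function(m, g, cs, cc, p) {
  mob <- m / (m * m + p$m1^2)
  amp <- m / (m * m + p$m2^2)
  cs_max <- p$cs_max0 * (1 - m)
  cc_max <- p$cc_max0 * (1 - m)
  room_s <- ifelse(cs_max > 0, pmax(0, 1 - cs / cs_max), 0)
  room_c <- ifelse(cc_max > 0, pmax(0, 1 - cc / cc_max), 0)
  gf_sat <- g / (g + 1)
  list(
    DS = p$ds0 * mob,
    DC = p$dc0 * mob,
    p1 = p$p10 * amp * room_s,
    p4 = (p$p40 * amp + p$p400 * gf_sat) * room_c,
    p8 = (1 - p$p81 * m) * (1 + p$p800 * gf_sat),
    cs_max = cs_max,
    cc_max = cc_max
  )
}

#' Local reaction rates of the six fields
#'
#' The full reaction (non-diffusive) right-hand side of the dimensionless
#' model, per unit dimensionless time:
#' * stem cells: nutrient-limited logistic proliferation (gated on
#'   `n > n1`), minus differentiation at rate `p2` (gated on the stem density
#'   exceeding the BMP-2-lowered threshold), minus starvation death at rate
#'   `p3` (gated on `n < n1`);
#' * chondrocytes: their own nutrient-limited proliferation (FGF-1
#'   augmented), plus the differentiation source (one-to-one transfer from
#'   the stem pool), minus starvation death;
#' * nutrient: Michaelis-Menten uptake by both cell types (always <= 0);
#' * matrix: deposition by chondrocytes at rate `p8(m, g)`, nutrient-limited;
#' * FGF-1: production by stem cells at `p9`, first-order decay at `p11`;
#' * BMP-2: production by chondrocytes at `p12`, first-order decay at `p13`.
#'
#' All threshold gates use [smooth_heaviside()] with the same width `eps`.
#'
#' @param s named list of dimensionless fields `cs`, `cc`, `n`, `m`, `g`,
#'   `b`, scalars or equal-length vectors.
#' @param p a `cart_params` object.
#' @param eps gate smoothing width.
#' @return A list with rates `dcs`, `dcc`, `dn`, `dm`, `dg`, `db`.
#' @export
reaction_rates <- function(s, p, eps = 1e-2) {
  for (f in FIELDS) {
    v <- s[[f]]
    if (is.null(v)) stop("state is missing field '", f, "'", call. = FALSE)
    if (anyNA(v) || any(!is.finite(v))) {
      i <- which(!is.finite(v))[1L]
      stop("non-finite value in field '", f, "' (element ", i, ": ",
           v[i], ")", call. = FALSE)
    }
  }
  cs <- s$cs; cc <- s$cc; n <- s$n; m <- s$m; g <- s$g; b <- s$b
  cl <- closures(m, g, cs, cc, p)
  upt <- n / (n + p$n0)                       # Michaelis-Menten saturation
  h_grow <- smooth_heaviside(n - p$n1, eps)   # enough nutrient to proliferate
  h_die <- smooth_heaviside(p$n1 - n, eps)    # starvation
  h_diff <- smooth_heaviside(cs - threshold_cs0(b, p), eps)
  transfer <- p$p2 * cs * h_diff              # stem -> chondrocyte flux
  list(
    dcs = cl$p1 * upt * cs * h_grow - transfer - p$p3 * cs * h_die,
    dcc = cl$p4 * upt * cc * h_grow + transfer - p$p5 * cc * h_die,
    dn = -upt * (p$p6 * cs + p$p7 * cc),
    dm = cl$p8 * upt * cc,
    dg = p$p9 * cs - p$p11 * g,
    db = p$p12 * cc - p$p13 * b
  )
}
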