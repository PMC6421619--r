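# Named simulation scenarios: growth-factor configurations, the implanted
# stem-cell seeding profile, and one-at-a-time parameter sweeps.

GF_CONFIGS <- c("none", "fgf_only", "bmp_only", "both")

#' Specify a simulation scenario
#'
#' A scenario bundles the growth-factor configuration, the stem-cell seeding
#' profile, the simulated duration and the solver settings. The four named
#' configurations toggle the two growth-factor feedback loops:
#' `"none"` zeroes both production constants and both initial concentrations
#' (the baseline, stem cells only); `"fgf_only"` keeps FGF-1 but zeroes the
#' BMP-2 pair; `"bmp_only"` the converse; `"both"` keeps the full model.
#' Zeroing both the production constant and the initial concentration of an
#' excluded factor prevents residual effects of the initial pulse.
#'
#' @param gf_config one of `"none"`, `"fgf_only"`, `"bmp_only"`, `"both"`.
#' @param name scenario identifier; defaults to `gf_config`.
#' @param seeding_width dimensionless width of the implanted stem-cell layer
#'   at the subchondral bone, in (0, 0.5].
#' @param duration_months simulated duration (> 0).
#' @param param_overrides named list of dimensionless parameter overrides,
#'   applied before the growth-factor toggles.
#' @param n_nodes spatial grid size.
#' @param eps gate smoothing width.
#' @param rtol,atol integration tolerances.
#' @param cadence_months output sampling interval in months.
#' @param force_params logical; pass `.force` to parameter validation
#'   (needed for sweeps that leave the physiological ranges).
#' @return An object of class `cart_scenario` (a validated list of the
#'   above).
#' @export
scenario_spec <- function(gf_config = c("none", "fgf_only", "bmp_only",
                                        "both"),
                          name = NULL,
                          seeding_width = 0.1,
                          duration_months = 24,
                          param_overrides = list(),
                          n_nodes = 101L,
                          eps = 1e-2,
                          rtol = 1e-6,
                          atol = 1e-9,
                          cadence_months = 1,
                          force_params = FALSE) {
  gf_config <- match.arg(gf_config)
  if (is.null(name)) name <- gf_config
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(seeding_width) && length(seeding_width) == 1L &&
        seeding_width > 0 && seeding_width <= 0.5)) {
    stop("'seeding_width' must lie in (0, 0.5]", call. = FALSE)
  }
  stopifnot(duration_months > 0, cadence_months > 0,
            cadence_months <= duration_months)
  if (length(param_overrides)) {
    bad <- setdiff(names(param_overrides), DLESS_FIELDS)
    if (length(bad)) {
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(name = name, gf_config = gf_config, seeding_width = seeding_width,
         duration_months = duration_months,
         param_overrides = param_overrides, n_nodes = as.integer(n_nodes),
         eps = eps, rtol = rtol, atol = atol,
         cadence_months = cadence_months, force_params = force_params),
    class = "cart_scenario"
  )
}

#' Resolve the dimensionless parameters of a scenario
#'
#' Applies the scenario's overrides to [default_dimensionless()] and then
#' the growth-factor toggles (toggles win, so an excluded factor stays
#' excluded).
#'
#' @param spec a `cart_scenario`.
#' @return A `cart_params` object.
#' @export
scenario_params <- function(spec) {
  stopifnot(inherits(spec, "cart_scenario"))
  p <- do.call(
    dimensionless_params,
    c(spec$param_overrides, list(.force = spec$force_params))
  )
  if (spec$gf_config %in% c("none", "bmp_only")) {
    p$p9 <- 0
    p$g_init <- 0
  }
  if (spec$gf_config %in% c("none", "fgf_only")) {
    p$p12 <- 0
    p$b_init <- 0
  }
  p
}

#' Initial state after stem-cell implantation
#'
#' Stem cells are implanted against the subchondral bone (`x = 0`) as a
#' Gaussian layer `cs_init * exp(-(x / w)^2)` of peak `cs_init` and width
#' `w`; a small uniform chondrocyte density `cc_init` and matrix density
#' `m3` pre-exist throughout the defect (they seed the growth-factor and
#' matrix dynamics), the nutrient is at its reservoir value 1 everywhere,
#' and the growth factors start at their (scenario-dependent) initial
#' levels.
#'
#' @param grid a `cart_grid`.
#' @param p a `cart_params` object.
#' @param w seeding width in (0, 0.5].
#' @return A `cart_state`.
#' @export
initial_state <- function(grid, p, w = 0.1) {
  if (!(is.numeric(w) && length(w) == 1L && w > 0 && w <= 0.5)) {
    stop("seeding width 'w' must lie in (0, 0.5]", call. = FALSE)
  }
  make_state(
    grid,
    cs = p$cs_init * exp(-(grid$x / w)^2),
    cc = p$cc_init,
    n = 1,
    m = p$m3,
    g = p$g_init,
    b = p$b_init
  )
}

#' Run a scenario
#'
#' Builds the parameter set and initial state, converts the duration to
#' dimensionless time (see [months_to_tbar()]), and integrates the model,
#' sampling the state every `cadence_months`. The model is deterministic:
#' identical specifications produce identical trajectories.
#'
#' @param spec a `cart_scenario`.
#' @param verbose print the run configuration (grid, timescale,
#'   month-to-scaled-time conversion, tolerances) before solving.
#' @return A `cart_trajectory` with additional elements `months` (the output
#'   stamps in months) and `scenario` (the scenario name; the full
#'   specification is stored as `spec`).
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "cart_scenario"))
  p <- scenario_params(spec)
  grid <- make_grid(spec$n_nodes)
  tpm <- tbar_per_month()
  months <- seq(0, spec$duration_months, by = spec$cadence_months)
  if (months[length(months)] < spec$duration_months) {
    months <- c(months, spec$duration_months)
  }
  if (verbose) {
    message(sprintf(
      "scenario '%s': grid %d, eps %.3g, rtol %.1g/atol %.1g; 1 month = %.4f time units (timescale %.1f h)",
      spec$name, spec$n_nodes, spec$eps, spec$rtol, spec$atol, tpm,
      matrix_timescale_hours()
    ))
  }
  traj <- tryCatch(
    integrate_pde(initial_state(grid, p, spec$seeding_width),
                  t_eval = months * tpm, grid = grid, p = p,
                  eps = spec$eps, bc_mode = "paper",
                  rtol = spec$rtol, atol = spec$atol),
    error = function(e) {
      stop("scenario '", spec$name, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  traj$months <- months
  traj$scenario <- spec$name
  traj$spec <- spec
  traj
}

#' One-at-a-time parameter sweep
#'
#' Re-runs `base` once per value of a single dimensionless parameter,
#' everything else held fixed.
#'
#' @param base a `cart_scenario`.
#' @param param name of a dimensionless parameter field.
#' @param values numeric vector of values to sweep over.
#' @param force_params allow out-of-range values (default `TRUE`: sweeps
#'   deliberately explore beyond the fitted ranges).
#' @return A named list of `cart_trajectory` objects, keyed by value.
#' @export
sweep_parameter <- function(base, param, values, force_params = TRUE) {
  stopifnot(inherits(base, "cart_scenario"))
  if (!(is.character(param) && length(param) == 1L &&
        param %in% DLESS_FIELDS)) {
    stop("unknown parameter name '", param, "'", call. = FALSE)
  }
  out <- lapply(values, function(v) {
    sp <- base
    sp$param_overrides[[param]] <- v
    sp$force_params <- sp$force_params || force_params
    sp$name <- paste0(base$name, "_", param, "=", format(v))
    run_scenario(sp)
  })
  names(out) <- as.character(values)
  out
}
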