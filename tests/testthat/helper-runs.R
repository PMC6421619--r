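# Shared scenario runs (cached across test files; the model is
# deterministic, so each configuration is integrated once) and an
# independent fixed-step RK4 integrator used as the 0-D oracle.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, spec) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, run_scenario(spec), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

gf_run4 <- function(config) {
  cached_run(paste0(config, "_4mo"),
             scenario_spec(config, duration_months = 4,
                           cadence_months = 0.25))
}

gf_run2 <- function(config) {
  cached_run(paste0(config, "_2mo"),
             scenario_spec(config, duration_months = 2,
                           cadence_months = 0.5))
}

baseline_run6 <- function() {
  cached_run("none_6mo",
             scenario_spec("none", duration_months = 6,
                           cadence_months = 0.5))
}

baseline_run24 <- function() {
  cached_run("none_24mo", scenario_spec("none", duration_months = 24))
}

pack_state_for_test <- function(s) unlist(s, use.names = FALSE)

# Fixed-step classical RK4 on the pointwise kinetics: deliberately naive and
# independent of the deSolve path it cross-checks.
rk4_kinetics <- function(s0, p, eps, t_end, dt = 1e-4) {
  y <- unlist(s0)
  nm <- names(y)
  f <- function(v) {
    unlist(reaction_rates(as.list(stats::setNames(v, nm)), p, eps),
           use.names = FALSE)
  }
  nstep <- round(t_end / dt)
  for (i in seq_len(nstep)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(y, nm)
}

# Minimal hand-built trajectory for metric unit tests.
fake_trajectory <- function(months, profiles_by_field, n_nodes = 11L) {
  grid <- make_grid(n_nodes)
  fields <- lapply(stats::setNames(nm = c("cs", "cc", "n", "m", "g", "b")),
                   function(f) {
    if (!is.null(profiles_by_field[[f]])) {
      profiles_by_field[[f]]
    } else {
      matrix(0, nrow = length(months), ncol = n_nodes)
    }
  })
  structure(
    list(times = months_to_tbar(months), months = months, fields = fields,
         grid = grid, params = default_dimensionless(),
         solver_meta = list(atol = 1e-9)),
    class = "cart_trajectory"
  )
}
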