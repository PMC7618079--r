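#' Run configurations as YAML
#'
#' A run configuration names an engine (`"wellmixed"` or `"vertex"`) and
#' per-type parameters, either dimensional (death threshold, signal
#' strength, G1/G2 durations) or dimensionless (`beta`, `eta`, with `t_G`
#' and `c`), which are expanded with [expand_dimensionless()]. The two
#' specifications are mutually exclusive per type; the expansion is the
#' exact inverse of [nondimensionalise()]. Every config embeds an explicit
#' seed, so identical config plus seed yields identical event logs.
#'
#' @param engine `"wellmixed"` or `"vertex"`.
#' @param types Named list; each entry is either a
#'   [death_clock_params()] or a list with `beta`, `eta` and optional
#'   `t_G`, `c`.
#' @param seed Integer seed.
#' @param ... Further engine options (e.g. `end_time`, `n_cells`,
#'   `arrangement`, `init`, `init_counts`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(engine = c("wellmixed", "vertex"), types, seed = 1L,
                       ...) {
  engine <- match.arg(engine)
  stopifnot(is.list(types), length(types) >= 1L, !is.null(names(types)))
  types <- lapply(types, function(tp) {
    if (inherits(tp, "death_clock_params")) return(tp)
    stopifnot(is.list(tp))
    if (!is.null(tp$beta)) {
      if (!is.null(tp$death_threshold)) {
        stop("give either dimensionless (beta, eta) or dimensional ",
             "parameters, not both")
      }
      return(expand_dimensionless(tp$beta, tp$eta,
                                  t_G = if (is.null(tp$t_G)) 1 else tp$t_G,
                                  c = if (is.null(tp$c)) 1 else tp$c))
    }
    do.call(death_clock_params, tp)
  })
  structure(list(engine = engine, types = types, seed = as.integer(seed),
                 options = list(...)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(
    engine = config$engine, seed = config$seed,
    types = lapply(config$types, function(tp) {
      list(death_threshold = tp$death_threshold,
           signal_strength = tp$signal_strength,
           g1_mean = tp$g1_mean, g2_duration = tp$g2_duration,
           g1_family = tp$g1_family)
    }),
    options = config$options)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, c(
    list(engine = obj$engine,
         types = lapply(obj$types, function(tp) do.call(death_clock_params, tp)),
         seed = obj$seed),
    obj$options))
}

#' Execute a run configuration
#'
#' Dispatches to [run_wellmixed()] or [run_vertex()].
#'
#' @param config A [run_config()].
#' @return An [event_log()].
#' @export
execute_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  opts <- config$options
  if (config$engine == "wellmixed") {
    counts <- opts$init_counts
    if (is.null(counts)) {
      counts <- stats::setNames(rep(50L, length(config$types)),
                                names(config$types))
    }
    cfg <- wellmixed_config(
      config$types, unlist(counts)[names(config$types)],
      end_time = if (is.null(opts$end_time)) 20 else opts$end_time,
      seed = config$seed,
      init = if (is.null(opts$init)) "newborn" else opts$init,
      max_population = if (is.null(opts$max_population)) 1e5
                       else opts$max_population,
      max_events = if (is.null(opts$max_events)) Inf else opts$max_events)
    run_wellmixed(cfg)
  } else {
    mech <- if (is.null(opts$mech_params)) vertex_params() else
      opts$mech_params
    cfg <- vertex_config(
      config$types, mech,
      n_cells = if (is.null(opts$n_cells)) 36L else opts$n_cells,
      arrangement = if (is.null(opts$arrangement)) "homotypic"
                    else opts$arrangement,
      end_time = if (is.null(opts$end_time)) 250 else opts$end_time,
      seed = config$seed,
      death_clock = if (is.null(opts$death_clock)) TRUE
                    else opts$death_clock,
      init = if (is.null(opts$init)) "newborn" else opts$init)
    run_vertex(cfg)
  }
}

#' Ready-made scenario configurations
#'
#' Named run configurations encoding the standard study conditions:
#' a 3x3 homotypic viability grid for the well-mixed model; heterotypic
#' parameter cross sections fixing the competitor at
#' (beta_B, eta_B) = (0.2, 0.2) ("cross-section-I"; always-viable
#' competitor), (0.8, 0.2) ("cross-section-II"; viable, eliminable) and
#' (0.4, 0.1) ("cross-section-III"; homotypically nonviable competitor);
#' a segregated-versus-random vertex comparison; and a small mechanical
#' sweep smoke configuration. All fixtures embed explicit seeds.
#'
#' @param seed Base seed embedded in the configs.
#' @return Named list of [run_config()]s (and for the grid, a data frame
#'   of (beta, eta) points under `$homotypic_grid_points`).
#' @export
fixture_scenarios <- function(seed = 1L) {
  grid <- expand.grid(beta = c(0.3, 0.5, 0.7), eta = c(0.1, 0.2, 0.3))
  cs <- list(
    "cross-section-I" = c(beta = 0.2, eta = 0.2),
    "cross-section-II" = c(beta = 0.8, eta = 0.2),
    "cross-section-III" = c(beta = 0.4, eta = 0.1))
  out <- list(homotypic_grid_points = grid)
  for (nm in names(cs)) {
    out[[nm]] <- run_config(
      "wellmixed",
      types = list(A = list(beta = 0.5, eta = 0.3),
                   B = list(beta = cs[[nm]][["beta"]],
                            eta = cs[[nm]][["eta"]])),
      seed = seed, end_time = 20, init = "staggered",
      init_counts = list(A = 50L, B = 50L))
  }
  out[["segregated-vs-random"]] <- run_config(
    "vertex",
    types = list(A = list(beta = 0.4, eta = 0.4, t_G = 100),
                 B = list(beta = 0.6, eta = 0.1, t_G = 100)),
    seed = seed, end_time = 150, arrangement = "random",
    n_cells = 36L)
  out[["sweep-smoke"]] <- run_config(
    "wellmixed",
    types = list(A = list(beta = 0.4, eta = 0.3),
                 B = list(beta = 0.6, eta = 0.3)),
    seed = seed, end_time = 15, init = "staggered",
    init_counts = list(A = 25L, B = 25L))
  out
}
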