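#' Configuration for the vertex-based simulator
#'
#' The vertex-based engine advances tissue mechanics with a fixed explicit
#' Euler step and checks cell-cycle and death-clock events once per step.
#' Each cell carries the two-phase cycle (stochastic G1, fixed G2) and,
#' when `death_clock = TRUE`, a death clock driven by the local G2 signal:
#' the fraction of edge-adjacent neighbours in G2 phase ([local_g2_fraction()]).
#' A G1 cell whose clock reaches its threshold triggers apoptosis
#' ([trigger_apoptosis()]): its target area shrinks to zero and it is
#' eventually extruded by a T2 swap. With `death_clock = FALSE` the engine
#' is the purely mechanical model; cells then die only passively, by T2
#' extrusion under crowding, and such extrusions are logged as deaths.
#'
#' @param type_params Named list of [death_clock_params()] per type label
#'   (e.g. `list(A = ..., B = ...)`); supplies the cycle durations and, for
#'   death-clock runs, `signal_strength` and `death_threshold`.
#' @param mech_params A [vertex_params()] object.
#' @param n_cells Initial cell count (hexagonal patch).
#' @param arrangement Initial type arrangement, see [init_tissue()].
#' @param end_time Simulation end time.
#' @param seed Integer seed.
#' @param death_clock Enable the death-clock mechanism.
#' @param init `"newborn"` (all initial cells age 0) or `"staggered"`
#'   (phases sampled from stationary cycle occupancy).
#' @param max_cells Population cap (run stops, flagged truncated).
#' @param record_g1exit Log `g1exit` events.
#' @return An object of class `vertex_config`.
#' @seealso [run_vertex()]
#' @export
vertex_config <- function(type_params, mech_params = vertex_params(),
                          n_cells = 36L, arrangement = "homotypic",
                          end_time = 250, seed = 1L, death_clock = TRUE,
                          init = c("newborn", "staggered"),
                          max_cells = 1000L, record_g1exit = FALSE) {
  init <- match.arg(init)
  stopifnot(is.list(type_params), length(type_params) >= 1L,
            all(vapply(type_params, inherits, TRUE, "death_clock_params")),
            inherits(mech_params, "vertex_params"), end_time > 0)
  structure(
    list(type_params = type_params, mech_params = mech_params,
         n_cells = as.integer(n_cells), arrangement = arrangement,
         end_time = end_time, seed = as.integer(seed),
         death_clock = isTRUE(death_clock), init = init,
         max_cells = as.integer(max_cells),
         record_g1exit = isTRUE(record_g1exit)),
    class = "vertex_config"
  )
}

#' Run the vertex-based simulator
#'
#' Time loop: each step first processes biology — advance death clocks with
#' the local G2 signal, trigger apoptosis for G1 cells whose clock reached
#' the threshold (a death tied with the G1-to-G2 transition resolves to
#' death), transition cells out of G1, divide cells whose age reached
#' `t* + t_G2` ([divide_cell()]) — then advances mechanics by one Euler
#' step with T1/T2 rearrangements ([advance_mesh()]). Deaths are logged at
#' the apoptosis trigger; passive T2 extrusions of non-dying cells are also
#' logged as deaths.
#'
#' @param config A [vertex_config()].
#' @param return_mesh Attach the final mesh as attribute `"mesh"`.
#' @return An [event_log()] (events: `division`, `death`, `g1exit`,
#'   `t1swap`, `t2swap`).
#' @export
#' @examples
#' p <- expand_dimensionless(beta = 0.5, eta = 0.5, t_G = 40)
#' cfg <- vertex_config(list(A = p), n_cells = 4L, end_time = 10, seed = 1)
#' run_vertex(cfg)
run_vertex <- function(config, return_mesh = FALSE) {
  stopifnot(inherits(config, "vertex_config"))
  set.seed(config$seed)
  labels <- names(config$type_params)
  if (is.null(labels)) labels <- c("A", "B")[seq_along(config$type_params)]
  mesh <- init_tissue(config$n_cells, config$arrangement)
  mesh$labels <- labels
  tp <- config$type_params
  cvec_t <- vapply(tp, `[[`, 0, "signal_strength")
  Td_t <- vapply(tp, `[[`, 0, "death_threshold")
  tG2_t <- vapply(tp, `[[`, 0, "g2_duration")
  beta_t <- vapply(tp, function(p) {
    tg <- p$g1_mean + p$g2_duration
    if (tg > 0) p$g1_mean / tg else 0
  }, 0)
  nc0 <- length(mesh$cells)
  for (k in seq_along(tp)) {
    sel <- mesh$type == k
    mesh$tstar[sel] <- sample_g1(tp[[k]], sum(sel))
  }
  mesh$S0 <- config$mech_params$S0[mesh$type]
  if (config$init == "staggered") {
    in_g2 <- stats::runif(nc0) < (1 - beta_t[mesh$type])
    resid <- stats::runif(nc0) * tG2_t[mesh$type]
    mesh$birth[in_g2] <- -(mesh$tstar[in_g2] + tG2_t[mesh$type[in_g2]] -
                             resid[in_g2])
  }

  dt <- config$mech_params$dt
  nsteps <- ceiling(config$end_time / dt)
  times <- numeric(); events <- character(); ids <- integer()
  tys <- character()
  push <- function(tt, ee, ii, kk) {
    times[length(times) + 1L] <<- tt
    events[length(events) + 1L] <<- ee
    ids[length(ids) + 1L] <<- ii
    tys[length(tys) + 1L] <<- kk
  }
  truncated <- FALSE
  t <- 0
  for (step in seq_len(nsteps)) {
    t <- step * dt
    if (!length(mesh$cells)) break
    if (length(mesh$cells) >= config$max_cells) {
      truncated <- TRUE
      break
    }
    age <- t - mesh$birth
    # death clocks driven by the local G2 fraction over this step
    if (config$death_clock && any(cvec_t > 0)) {
      g <- local_g2_fraction(mesh, t - dt)
      live <- !mesh$dying
      mesh$tau[live] <- mesh$tau[live] +
        cvec_t[mesh$type[live]] * g[live] * dt
      vulnerable <- live & (age - dt) < mesh$tstar
      hit <- which(vulnerable & mesh$tau >= Td_t[mesh$type])
      for (ci in hit) {
        push(t, "death", mesh$cell_id[ci], labels[mesh$type[ci]])
        trigger_apoptosis(mesh, ci)
      }
    }
    if (config$record_g1exit) {
      ex <- which(!mesh$dying & (age - dt) < mesh$tstar & age >= mesh$tstar)
      for (ci in ex) push(t, "g1exit", mesh$cell_id[ci],
                          labels[mesh$type[ci]])
    }
    # divisions
    ready <- which(!mesh$dying & age >= mesh$tstar + tG2_t[mesh$type])
    for (ci in ready) {
      push(t, "division", mesh$cell_id[ci], labels[mesh$type[ci]])
      newci <- divide_cell(mesh, ci)
      k <- mesh$type[ci]
      mesh$birth[ci] <- t; mesh$tau[ci] <- 0
      mesh$tstar[ci] <- sample_g1(tp[[k]])
      mesh$S0[ci] <- config$mech_params$S0[k]
      if (!is.na(newci)) {
        mesh$birth[newci] <- t
        mesh$tstar[newci] <- sample_g1(tp[[k]])
        mesh$S0[newci] <- config$mech_params$S0[k]
      }
    }
    # mechanics + rearrangements
    rearr <- advance_mesh(mesh, config$mech_params, dt)
    for (ev in rearr) {
      if (ev$kind == "t1swap") {
        push(t, "t1swap", 0L, "")
      } else {
        push(t, "t2swap", ev$cell_id, labels[ev$type])
        if (!ev$dying) {
          # passive extrusion counts as a death
          push(t, "death", ev$cell_id, labels[ev$type])
        }
      }
    }
  }
  log <- event_log(times, events, ids, tys, truncated = truncated,
                   meta = list(n_initial = nc0,
                               n_final = length(mesh$cells),
                               seed = config$seed, end_time = config$end_time,
                               time_reached = t))
  if (return_mesh) attr(log, "mesh") <- mesh
  log
}

#' Relax a mesh mechanically
#'
#' Runs pure mechanics (no cell cycle, no death clock) for a number of
#' steps and records the tissue energy after each step. Used to verify
#' that the force implementation descends the energy landscape.
#'
#' @param mesh A vertex mesh (modified in place).
#' @param params A [vertex_params()] object.
#' @param steps Number of Euler steps.
#' @return Numeric vector of energies (initial energy first, then one per
#'   step).
#' @export
relax_mesh <- function(mesh, params, steps = 100L) {
  if (all(is.na(mesh$S0))) mesh$S0 <- params$S0[mesh$type]
  E <- numeric(steps + 1L)
  E[1L] <- energy(mesh, params)
  for (s in seq_len(steps)) {
    advance_mesh(mesh, params)
    E[s + 1L] <- energy(mesh, params)
  }
  E
}
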