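#' Configuration for the well-mixed simulator
#'
#' In the well-mixed G2 death-signal model every cell's extracellular
#' environment consists of all other cells: the death signal received by a
#' cell is \eqn{f = c\,g} with \eqn{g} the fraction of the *other* cells
#' currently in G2 phase (0 when the cell is alone). Between discrete
#' events (G1 exits, divisions, deaths) \eqn{g} is constant for every cell,
#' so the simulator is exactly event-driven: clock-threshold crossing times
#' are computed in closed form and no integration error is incurred.
#'
#' @param type_params Named list of [death_clock_params()], one per cell
#'   type (names are the type labels, e.g. `list(A = ..., B = ...)`).
#' @param init_counts Named integer vector of initial cell counts per type
#'   (names matching `type_params`).
#' @param end_time Simulation end time, > 0.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param init Initialisation convention: `"newborn"` starts every cell at
#'   age 0 with a fresh G1 draw; `"staggered"` samples each initial cell's
#'   phase from the stationary cycle occupancy (G2 with probability
#'   \eqn{1-\beta}, with uniformly distributed residual G2 time), which
#'   removes most of the synchronised-start transient.
#' @param max_population Population cap; the run stops (flagged truncated)
#'   if reached. Survival frequencies remain valid for the logged events.
#' @param max_events Optional cap on logged division+death events; the run
#'   stops (flagged truncated) once reached. Useful for fixing the
#'   statistical resolution of survival-frequency estimates.
#' @param record_g1exit Log `g1exit` events (set `FALSE` to keep logs small).
#' @return An object of class `wellmixed_config`.
#' @seealso [run_wellmixed()]
#' @export
wellmixed_config <- function(type_params, init_counts, end_time, seed = 1L,
                             init = c("newborn", "staggered"),
                             max_population = 1e5, max_events = Inf,
                             record_g1exit = FALSE) {
  init <- match.arg(init)
  stopifnot(is.list(type_params), length(type_params) >= 1L,
            !is.null(names(type_params)), all(nzchar(names(type_params))),
            all(vapply(type_params, inherits, TRUE, "death_clock_params")),
            is.numeric(init_counts), all(init_counts >= 0),
            setequal(names(init_counts), names(type_params)),
            is.numeric(end_time), end_time > 0)
  structure(
    list(type_params = type_params,
         init_counts = init_counts[names(type_params)],
         end_time = end_time, seed = as.integer(seed), init = init,
         max_population = max_population, max_events = max_events,
         record_g1exit = record_g1exit),
    class = "wellmixed_config"
  )
}

# G2 fraction seen by each cell: (# other cells in G2) / (# other cells).
# `phase` is integer (1 = G1, 2 = G2).
wellmixed_g <- function(phase) {
  n <- length(phase)
  if (n <= 1L) return(rep(0, n))
  nG2 <- sum(phase == 2L)
  (nG2 - (phase == 2L)) / (n - 1L)
}

#' G2 death-signal fraction seen by one cell of a well-mixed population
#'
#' The proportion of the *other* cells that are in G2 phase, or 0 when the
#' focal cell has no neighbours. This is the \eqn{g} in the received death
#' signal \eqn{f = c\,g}.
#'
#' @param phases Character or integer phases of all cells (`"G1"`/`"G2"` or
#'   1/2).
#' @param focal Index of the focal cell.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
g2_signal_fraction <- function(phases, focal) {
  if (is.character(phases)) phases <- ifelse(phases == "G2", 2L, 1L)
  stopifnot(focal >= 1L, focal <= length(phases))
  wellmixed_g(phases)[focal]
}

#' Run the event-driven well-mixed simulator
#'
#' Simulates the well-mixed G2 death-signal population exactly: at each
#' step the next event is the minimum over all cells of (a) G1 exit at
#' `birth + t*`, (b) division at `birth + t* + t_G2`, and (c) clock
#' threshold crossing at `t + (T+ - tau) / (c g)` for G1 cells receiving a
#' positive signal. Clocks advance by exactly `c g dt` between events, with
#' the signal recomputed after every event. Cells in G2 phase keep
#' integrating their clock but are impervious to death; daughters are born
#' with a zero clock and a fresh G1 draw. Simultaneous events are processed
#' in (time, cell id) order, and a death tied with a G1 exit wins.
#'
#' @param config A [wellmixed_config()].
#' @return An [event_log()] with metadata (`n_initial`, `n_final`,
#'   `extinct`, `seed`, `end_time`) and truncation flag.
#' @export
#' @examples
#' p <- expand_dimensionless(beta = 0.5, eta = 0.2)
#' cfg <- wellmixed_config(list(A = p), c(A = 20), end_time = 5, seed = 1)
#' log <- run_wellmixed(cfg)
#' survival_frequency(log, "A")
run_wellmixed <- function(config) {
  stopifnot(inherits(config, "wellmixed_config"))
  set.seed(config$seed)
  labels <- names(config$type_params)
  cvec_t <- vapply(config$type_params, `[[`, 0, "signal_strength")
  Td_t <- vapply(config$type_params, `[[`, 0, "death_threshold")
  tG2_t <- vapply(config$type_params, `[[`, 0, "g2_duration")
  beta_t <- vapply(config$type_params, function(p) {
    tg <- p$g1_mean + p$g2_duration
    if (tg > 0) p$g1_mean / tg else 0
  }, 0)

  # state vectors
  type <- rep(seq_along(labels), times = config$init_counts)
  n0 <- length(type)
  id <- seq_len(n0)
  next_id <- n0 + 1L
  tstar <- numeric(n0)
  for (k in seq_along(labels)) {
    sel <- type == k
    tstar[sel] <- sample_g1(config$type_params[[k]], sum(sel))
  }
  birth <- numeric(n0)
  tau <- numeric(n0)
  phase <- ifelse(tstar > 0, 1L, 2L)
  if (config$init == "staggered" && n0 > 0) {
    in_g2 <- stats::runif(n0) < (1 - beta_t[type])
    # G2 cells: residual G2 time uniform on (0, t_G2); backdate the birth
    resid <- stats::runif(n0) * tG2_t[type]
    birth[in_g2] <- -(tstar[in_g2] + tG2_t[type[in_g2]] - resid[in_g2])
    phase[in_g2] <- 2L
    # G1 cells keep age 0: exponential G1 is memoryless, clock approximated
    # as fresh (affects only the first generation)
  }
  phase0 <- phase
  type0 <- type

  # preallocated log
  cap <- 4096L
  lt <- numeric(cap); lev <- character(cap); lid <- integer(cap)
  lty <- integer(cap); nlog <- 0L
  push <- function(tt, ee, ii, kk) {
    nlog <<- nlog + 1L
    if (nlog > cap) {
      cap <<- cap * 2L
      length(lt) <<- cap; length(lev) <<- cap
      length(lid) <<- cap; length(lty) <<- cap
    }
    lt[nlog] <<- tt; lev[nlog] <<- ee; lid[nlog] <<- ii; lty[nlog] <<- kk
  }

  t <- 0
  truncated <- FALSE
  n_fate <- 0L  # divisions + deaths
  repeat {
    n <- length(id)
    if (n == 0L) break
    if (n >= config$max_population || n_fate >= config$max_events) {
      truncated <- TRUE
      break
    }
    g <- wellmixed_g(phase)
    rate <- cvec_t[type] * g
    is_g1 <- phase == 1L
    t_exit <- ifelse(is_g1, birth + tstar, Inf)
    t_div <- ifelse(is_g1, Inf, birth + tstar + tG2_t[type])
    t_death <- ifelse(is_g1 & rate > 0, t + (Td_t[type] - tau) / rate, Inf)
    cand <- pmin(t_exit, t_div, t_death)
    # numerical guard: events cannot precede current time
    cand[cand < t] <- t
    te <- min(cand)
    if (te > config$end_time) {
      tau <- tau + rate * (config$end_time - t)
      t <- config$end_time
      break
    }
    due <- which(cand == te)
    i <- due[which.min(id[due])]
    # advance all clocks over [t, te] with the signal that held
    tau <- tau + rate * (te - t)
    t <- te
    if (t_death[i] <= te) {
      # threshold crossing (ties with G1 exit resolve to death)
      push(t, "death", id[i], type[i])
      keep <- -i
      id <- id[keep]; type <- type[keep]; birth <- birth[keep]
      tstar <- tstar[keep]; tau <- tau[keep]; phase <- phase[keep]
      n_fate <- n_fate + 1L
    } else if (is_g1[i]) {
      phase[i] <- 2L
      if (config$record_g1exit) push(t, "g1exit", id[i], type[i])
    } else {
      push(t, "division", id[i], type[i])
      n_fate <- n_fate + 1L
      # mother slot becomes daughter 1, append daughter 2
      k <- type[i]
      ts1 <- sample_g1(config$type_params[[k]])
      ts2 <- sample_g1(config$type_params[[k]])
      birth[i] <- t; tau[i] <- 0; tstar[i] <- ts1
      phase[i] <- if (ts1 > 0) 1L else 2L
      id <- c(id, next_id); next_id <- next_id + 1L
      type <- c(type, k); birth <- c(birth, t); tau <- c(tau, 0)
      tstar <- c(tstar, ts2); phase <- c(phase, if (ts2 > 0) 1L else 2L)
    }
  }

  keep <- seq_len(nlog)
  event_log(lt[keep], lev[keep], lid[keep], labels[lty[keep]],
            truncated = truncated,
            meta = list(n_initial = n0, n_final = length(id),
                        extinct = length(id) == 0L, seed = config$seed,
                        end_time = config$end_time, time_reached = t,
                        initial_phase = c("G1", "G2")[phase0],
                        initial_type = labels[type0],
                        final_g2_fraction = if (length(id))
                          mean(phase == 2L) else NA_real_,
                        final_counts = stats::setNames(
                          tabulate(type, nbins = length(labels)), labels)))
}

#' Fixed-timestep integrator for the well-mixed model
#'
#' Reference integrator used to cross-validate the event-driven simulator:
#' clocks are advanced with explicit steps of size `dt` and cycle/death
#' events are processed once per step. As `dt` shrinks, event counts
#' converge to the event-driven run under the same seed discipline (G1
#' draws are consumed in the same order as long as no two events share a
#' step).
#'
#' @param config A [wellmixed_config()].
#' @param dt Time step, > 0.
#' @return An [event_log()].
#' @export
run_wellmixed_fixedstep <- function(config, dt) {
  stopifnot(inherits(config, "wellmixed_config"), dt > 0)
  set.seed(config$seed)
  labels <- names(config$type_params)
  cvec_t <- vapply(config$type_params, `[[`, 0, "signal_strength")
  Td_t <- vapply(config$type_params, `[[`, 0, "death_threshold")
  tG2_t <- vapply(config$type_params, `[[`, 0, "g2_duration")

  type <- rep(seq_along(labels), times = config$init_counts)
  n0 <- length(type)
  id <- seq_len(n0); next_id <- n0 + 1L
  tstar <- numeric(n0)
  for (k in seq_along(labels)) {
    sel <- type == k
    tstar[sel] <- sample_g1(config$type_params[[k]], sum(sel))
  }
  birth <- numeric(n0); tau <- numeric(n0)
  phase <- ifelse(tstar > 0, 1L, 2L)

  times <- numeric(); events <- character(); ids <- integer(); tys <- integer()
  t <- 0
  while (t < config$end_time && length(id) > 0L &&
         length(id) < config$max_population) {
    g <- wellmixed_g(phase)
    tau <- tau + cvec_t[type] * g * dt
    t <- t + dt
    # deaths: G1 cells whose clock reached the threshold
    dying <- which(phase == 1L & tau >= Td_t[type])
    if (length(dying)) {
      for (i in dying) {
        times <- c(times, t); events <- c(events, "death")
        ids <- c(ids, id[i]); tys <- c(tys, type[i])
      }
      keep <- setdiff(seq_along(id), dying)
      id <- id[keep]; type <- type[keep]; birth <- birth[keep]
      tstar <- tstar[keep]; tau <- tau[keep]; phase <- phase[keep]
    }
    # G1 exits
    ex <- which(phase == 1L & (t - birth) >= tstar)
    phase[ex] <- 2L
    # divisions
    dv <- which(phase == 2L & (t - birth) >= tstar + tG2_t[type])
    for (i in dv) {
      times <- c(times, t); events <- c(events, "division")
      ids <- c(ids, id[i]); tys <- c(tys, type[i])
      k <- type[i]
      ts1 <- sample_g1(config$type_params[[k]])
      ts2 <- sample_g1(config$type_params[[k]])
      birth[i] <- t; tau[i] <- 0; tstar[i] <- ts1
      phase[i] <- if (ts1 > 0) 1L else 2L
      id <- c(id, next_id); next_id <- next_id + 1L
      type <- c(type, k); birth <- c(birth, t); tau <- c(tau, 0)
      tstar <- c(tstar, ts2); phase <- c(phase, if (ts2 > 0) 1L else 2L)
    }
  }
  event_log(times, events, ids, labels[tys],
            truncated = length(id) >= config$max_population,
            meta = list(n_initial = n0, n_final = length(id), dt = dt))
}
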