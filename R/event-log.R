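#' Event logs
#'
#' Both simulators record a tabular event log: one row per discrete event,
#' with columns `time`, `event` (`"division"`, `"death"`, `"g1exit"`,
#' `"t1swap"`, `"t2swap"`), `cell_id` and `cell_type`. Times are
#' non-decreasing. Survival frequencies and viability classification are
#' computed from these logs.
#'
#' @param time,event,cell_id,cell_type Column vectors of equal length.
#' @param truncated Whether the run was stopped by a population/event cap.
#' @param meta Optional named list of run metadata (seed, end time, counts).
#' @return A `data.frame` of class `event_log`.
#' @export
event_log <- function(time = numeric(), event = character(),
                      cell_id = integer(), cell_type = character(),
                      truncated = FALSE, meta = list()) {
  stopifnot(length(time) == length(event),
            length(time) == length(cell_id),
            length(time) == length(cell_type))
  if (length(time) > 1L && any(diff(time) < 0)) {
    stop("event times must be non-decreasing")
  }
  out <- data.frame(time = as.numeric(time), event = as.character(event),
                    cell_id = as.integer(cell_id),
                    cell_type = as.character(cell_type),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_log", "data.frame")
  attr(out, "truncated") <- isTRUE(truncated)
  attr(out, "meta") <- meta
  out
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log: %d events", nrow(x)))
  if (nrow(x) > 0) cat(sprintf(" over [%g, %g]", min(x$time), max(x$time)))
  if (isTRUE(attr(x, "truncated"))) cat(" (truncated)")
  cat("\n")
  tab <- table(x$event)
  if (length(tab)) print(tab)
  invisible(x)
}

#' Write / read an event log as CSV
#'
#' Plain CSV with header `time,event,cell_id,cell_type`.
#'
#' @param log An [event_log()].
#' @param path File path.
#' @return `read_event_log` returns an [event_log()]; `write_event_log`
#'   returns `path` invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_log(df$time, df$event, df$cell_id, df$cell_type)
}

#' Survival frequency of a cell type
#'
#' The empirical viability statistic: the fraction of "cell fate decisions"
#' that were divisions,
#' \deqn{\hat\lambda = \frac{\#\mathrm{divisions}}
#'   {\#\mathrm{divisions} + \#\mathrm{deaths}},}
#' computed per cell type from an event log. A value below one half means
#' the population declined over the run; at or above one half it grew or
#' held steady. When a burn-in is given, only events at `time >= burnin`
#' are counted, which suppresses the initial-condition transient.
#'
#' @param log An [event_log()].
#' @param type Cell type label; `NULL` pools all types.
#' @param burnin Discard events before this time.
#' @return Survival frequency in \eqn{[0, 1]}, or `NA` when the log holds
#'   no divisions or deaths for that type (the population persisted
#'   unchanged).
#' @export
survival_frequency <- function(log, type = NULL, burnin = 0) {
  stopifnot(inherits(log, "event_log"))
  keep <- log$time >= burnin
  if (!is.null(type)) keep <- keep & log$cell_type == type
  ndiv <- sum(keep & log$event == "division")
  ndeath <- sum(keep & log$event == "death")
  if (ndiv + ndeath == 0L) return(NA_real_)
  ndiv / (ndiv + ndeath)
}

#' Cohort survival frequency of the initial G1 cells
#'
#' Survival frequency restricted to the cells that were in G1 phase at the
#' start of the run: the fraction of those cells whose first recorded fate
#' is a division rather than a death. With a large population initialised
#' at the stationary cycle occupancy (`init = "staggered"`), each such cell
#' is a fresh G1 cell with a zero clock embedded in an environment whose
#' G2 signal is close to its ergodic value, so this cohort fraction is a
#' direct Monte-Carlo estimate of the survival probability — it avoids the
#' age-structure drift that a growing (or collapsing) population develops
#' over longer horizons.
#'
#' With `born_before > 0` the cohort additionally includes every cell born
#' (by a logged division) before that time; each division/death is then a
#' trial whose birth time is the previous event of the same cell id (a
#' mother's slot is reused by one daughter, so consecutive events of one id
#' are consecutive cell generations).
#'
#' @param log An [event_log()] produced by [run_wellmixed()] (the run
#'   metadata must carry the initial phases).
#' @param type Restrict to one cell type label (`NULL` pools).
#' @param born_before Also count trials of cells born before this time.
#' @return List with `frequency`, `divisions`, `deaths` (cohort cells whose
#'   fate fell inside the simulated window).
#' @export
cohort_survival_frequency <- function(log, type = NULL, born_before = 0) {
  stopifnot(inherits(log, "event_log"))
  meta <- attr(log, "meta")
  if (is.null(meta$initial_phase)) {
    stop("log has no initial-phase metadata")
  }
  fate <- log[log$event %in% c("division", "death"), , drop = FALSE]
  if (!is.null(type)) fate <- fate[fate$cell_type == type, , drop = FALSE]
  first <- !duplicated(fate$cell_id)
  # birth time of each trial: previous event of the same id; 0 for the
  # first occurrence (an initial cell)
  prev_time <- numeric(nrow(fate))
  last_seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(fate))) {
    key <- as.character(fate$cell_id[r])
    prev <- last_seen[[key]]
    prev_time[r] <- if (is.null(prev)) 0 else prev
    last_seen[[key]] <- fate$time[r]
  }
  # first occurrences of fresh ids are daughters whose birth time the log
  # does not carry (the mother id differs); their co-daughters in the
  # reused mother slots are exchangeable, so dropping them is unbiased
  initial <- first & fate$cell_id <= meta$n_initial
  started_g1 <- initial &
    meta$initial_phase[pmin(fate$cell_id, meta$n_initial)] == "G1"
  keep <- (initial & started_g1) |
    (!first & prev_time <= born_before)
  ndiv <- sum(keep & fate$event == "division")
  ndeath <- sum(keep & fate$event == "death")
  list(frequency = if (ndiv + ndeath > 0) ndiv / (ndiv + ndeath)
                   else NA_real_,
       divisions = ndiv, deaths = ndeath)
}

#' Division/death event counts backing a survival frequency
#'
#' @inheritParams survival_frequency
#' @return Integer vector `c(divisions = , deaths = )`.
#' @export
event_counts <- function(log, type = NULL, burnin = 0) {
  stopifnot(inherits(log, "event_log"))
  keep <- log$time >= burnin
  if (!is.null(type)) keep <- keep & log$cell_type == type
  c(divisions = sum(keep & log$event == "division"),
    deaths = sum(keep & log$event == "death"))
}
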