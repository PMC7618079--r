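#' Piecewise-constant death signal
#'
#' Represents a non-negative, piecewise-constant death signal \eqn{f(t)} as
#' breakpoints and segment values, together with its running integral
#' \eqn{F(t) = \int_0^t f(t')\,dt'}. Both cell-based simulators only ever
#' change the death signal at discrete events, so this representation makes
#' threshold-crossing times exact (no ODE-solver tolerance is involved).
#'
#' @param breakpoints Strictly increasing times starting at 0; segment `k`
#'   spans `[breakpoints[k], breakpoints[k+1])`, the last segment extends to
#'   infinity.
#' @param values Non-negative signal value on each segment (same length as
#'   `breakpoints`).
#' @return An object of class `signal_primitive`.
#' @seealso [signal_cumulative()], [signal_pseudoinverse()],
#'   [survival_probability()]
#' @export
#' @examples
#' sig <- signal_primitive(c(0, 1, 2), c(1, 0, 1))
#' signal_cumulative(sig, c(0.5, 1.5, 2.5))
signal_primitive <- function(breakpoints, values) {
  stopifnot(is.numeric(breakpoints), is.numeric(values),
            length(breakpoints) == length(values),
            length(breakpoints) >= 1L)
  if (breakpoints[1L] != 0) stop("first breakpoint must be 0")
  if (any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing")
  }
  if (any(values < 0) || any(!is.finite(values))) {
    stop("signal values must be finite and non-negative")
  }
  seg <- diff(breakpoints)
  cum <- c(0, cumsum(values[-length(values)] * seg))
  structure(list(t = breakpoints, f = values, Fcum = cum),
            class = "signal_primitive")
}

#' Constant death signal
#'
#' Convenience constructor for \eqn{f(t) \equiv c}.
#'
#' @param value Constant signal value, >= 0.
#' @return A [signal_primitive()] object.
#' @export
constant_signal <- function(value) signal_primitive(0, value)

#' Cumulative death signal F(t)
#'
#' Evaluates \eqn{F(t) = \int_0^t f(t')\,dt'}; continuous, non-decreasing,
#' with \eqn{F(0) = 0}.
#'
#' @param signal A [signal_primitive()] object.
#' @param t Times (vectorised), >= 0.
#' @return Numeric vector of accumulated signal.
#' @export
signal_cumulative <- function(signal, t) {
  stopifnot(inherits(signal, "signal_primitive"), all(t >= 0))
  k <- findInterval(t, signal$t)
  signal$Fcum[k] + signal$f[k] * (t - signal$t[k])
}

#' Pseudoinverse of the cumulative death signal
#'
#' Returns \eqn{F^{-1}(\tau) = \min\{t \ge 0 : F(t) = \tau\}}, the first
#' time the accumulated signal reaches `tau`, or `Inf` when the signal
#' never accumulates that much. This is the time at which a death clock
#' driven by `signal` would reach the value `tau`.
#'
#' @param signal A [signal_primitive()] object.
#' @param tau Clock value to invert, >= 0 (scalar).
#' @return A single time, possibly `Inf`.
#' @export
#' @examples
#' sig <- signal_primitive(c(0, 1, 2), c(1, 0, 1))
#' signal_pseudoinverse(sig, 1.5)  # 2.5: 1 accrued on [0,1], rest after t=2
signal_pseudoinverse <- function(signal, tau) {
  stopifnot(inherits(signal, "signal_primitive"),
            is.numeric(tau), length(tau) == 1L)
  if (!is.finite(tau) || tau < 0) stop("`tau` must be finite and >= 0")
  if (tau == 0) return(0)
  n <- length(signal$t)
  for (k in seq_len(n)) {
    end_cum <- if (k < n) signal$Fcum[k + 1L] else Inf
    if (signal$f[k] > 0 && tau <= end_cum) {
      return(signal$t[k] + (tau - signal$Fcum[k]) / signal$f[k])
    }
    # zero-valued segment: F is flat; tau can only be met if already reached,
    # which an earlier segment would have caught
  }
  Inf
}

#' Survival probability for a prescribed death signal
#'
#' Probability \eqn{\theta} that a cell born at signal-time 0 completes G1
#' phase before its death clock reaches the threshold, for a fixed
#' (deterministic) death signal. Writing \eqn{\Psi} for the G1-duration CDF,
#' \eqn{\theta = \Psi(F^{-1}(T_\dagger))}; if the accumulated signal never
#' reaches the threshold, \eqn{\theta = 1}. For the constant signal
#' \eqn{f \equiv c} and exponential G1 durations this reduces to
#' \eqn{\theta = 1 - \exp(-T_\dagger / (c\, t_{G1}))}.
#'
#' @param signal A [signal_primitive()] object (the signal experienced by
#'   the cell from birth onwards).
#' @param params A [death_clock_params()] object. The signal values already
#'   include any strength factor; `params$signal_strength` is not reapplied.
#' @return Survival probability in \eqn{[0, 1]}.
#' @export
survival_probability <- function(signal, params) {
  stopifnot(inherits(params, "death_clock_params"))
  t_hit <- signal_pseudoinverse(signal, params$death_threshold)
  if (!is.finite(t_hit)) return(1)
  if (params$g1_family == "fixed" || params$g1_mean == 0) {
    # survival condition is strict: t* < F^{-1}(T+)
    return(as.numeric(params$g1_mean < t_hit))
  }
  g1_cdf(params, t_hit)
}

#' Single-cell record
#'
#' State carried by one cell in the death-clock framework: the clock value
#' \eqn{\tau}, the sampled G1 duration \eqn{t^*}, the birth time, the cell
#' phase, a type label, and the cell-type parameters. The clock is zero at
#' birth and non-decreasing thereafter; the phase is G2 exactly when the
#' cell's age has reached \eqn{t^*}.
#'
#' @param params A [death_clock_params()] object.
#' @param birth_time Birth time of the cell.
#' @param sampled_g1 Sampled G1 duration \eqn{t^*}; drawn via [sample_g1()]
#'   when `NULL`.
#' @param type_label Cell type label (e.g. `"A"` or `"B"`).
#' @param clock Current clock value, >= 0.
#' @param age Current age of the cell (time since birth), >= 0.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(params, birth_time = 0, sampled_g1 = NULL,
                        type_label = "A", clock = 0, age = 0) {
  stopifnot(inherits(params, "death_clock_params"), clock >= 0, age >= 0)
  if (is.null(sampled_g1)) sampled_g1 <- sample_g1(params)
  structure(
    list(clock = clock, sampled_g1 = sampled_g1, birth_time = birth_time,
         age = age, phase = if (age >= sampled_g1) "G2" else "G1",
         type_label = type_label, params = params),
    class = "cell_record"
  )
}

#' Check the survival condition for a completed G1 phase
#'
#' A cell survives G1 phase if its death clock is still strictly below the
#' death threshold when the sampled G1 duration elapses:
#' \eqn{\tau(t^*) < T_\dagger}. The clock reaching the threshold exactly
#' counts as death, making the survival condition and the apoptosis rule
#' complementary. Since the death signal is non-negative the clock is
#' non-decreasing, so this is equivalent to the clock never having reached
#' the threshold during G1.
#'
#' @param cell A [cell_record()] whose `clock` holds \eqn{\tau(t^*)}, or a
#'   numeric clock value.
#' @param death_threshold Threshold; taken from `cell$params` when `cell` is
#'   a `cell_record`.
#' @return `TRUE` if the cell survives G1, `FALSE` if apoptosis triggered.
#' @export
check_survival <- function(cell, death_threshold = NULL) {
  if (inherits(cell, "cell_record")) {
    tau <- cell$clock
    if (is.null(death_threshold)) death_threshold <- cell$params$death_threshold
  } else {
    tau <- cell
    if (is.null(death_threshold)) stop("`death_threshold` required")
  }
  tau < death_threshold
}
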