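#' Death-clock parameters for one cell type
#'
#' Bundles the parameters governing a single cell's cycle and death clock:
#' the death threshold \eqn{T_\dagger}, the death-signal strength \eqn{c},
#' the mean G1 duration \eqn{t_{G1}}, the fixed G2 duration \eqn{t_{G2}},
#' and the G1 duration distribution family. The clock \eqn{\tau(t)}
#' integrates the received death signal \eqn{f(t) \ge 0}; apoptosis is
#' initiated when \eqn{\tau} reaches \eqn{T_\dagger} while the cell is in G1
#' phase.
#'
#' @param death_threshold Death threshold \eqn{T_\dagger} (signal units),
#'   strictly positive.
#' @param signal_strength Death-signal strength \eqn{c} (signal units per
#'   time), non-negative.
#' @param g1_mean Mean G1 duration \eqn{t_{G1}} (time), non-negative.
#' @param g2_duration Fixed G2 duration \eqn{t_{G2}} (time), non-negative.
#'   "G2" lumps together the S, G2 and M phases of the cell cycle.
#' @param g1_family G1 duration distribution family: `"exponential"` (mean
#'   `g1_mean`) or `"fixed"` (degenerate at `g1_mean`).
#' @return An object of class `death_clock_params`.
#' @seealso [sample_g1()], [survival_probability()], [expand_dimensionless()]
#' @export
#' @examples
#' p <- death_clock_params(death_threshold = 0.2, signal_strength = 1,
#'                         g1_mean = 0.5, g2_duration = 0.5)
#' sample_g1(p, n = 3)
death_clock_params <- function(death_threshold, signal_strength, g1_mean,
                               g2_duration,
                               g1_family = c("exponential", "fixed")) {
  g1_family <- match.arg(g1_family)
  if (!is.numeric(death_threshold) || length(death_threshold) != 1L ||
      !is.finite(death_threshold) || death_threshold <= 0) {
    stop("`death_threshold` must be a single positive number")
  }
  if (!is.numeric(signal_strength) || length(signal_strength) != 1L ||
      !is.finite(signal_strength) || signal_strength < 0) {
    stop("`signal_strength` must be a single non-negative number")
  }
  if (!is.numeric(g1_mean) || length(g1_mean) != 1L || !is.finite(g1_mean) ||
      g1_mean < 0) {
    stop("`g1_mean` must be a single non-negative number")
  }
  if (!is.numeric(g2_duration) || length(g2_duration) != 1L ||
      !is.finite(g2_duration) || g2_duration < 0) {
    stop("`g2_duration` must be a single non-negative number")
  }
  structure(
    list(death_threshold = death_threshold,
         signal_strength = signal_strength,
         g1_mean = g1_mean,
         g2_duration = g2_duration,
         g1_family = g1_family),
    class = "death_clock_params"
  )
}

#' @export
print.death_clock_params <- function(x, ...) {
  cat("Death-clock parameters\n")
  cat(sprintf("  death threshold T+ : %g\n", x$death_threshold))
  cat(sprintf("  signal strength c  : %g\n", x$signal_strength))
  cat(sprintf("  G1 mean t_G1       : %g (%s)\n", x$g1_mean, x$g1_family))
  cat(sprintf("  G2 duration t_G2   : %g\n", x$g2_duration))
  invisible(x)
}

#' Sample G1 phase durations
#'
#' Draws stochastic G1 durations \eqn{t^*} from the configured G1
#' distribution family. The family is constrained to have support on
#' \eqn{[0, \infty)} and mean `g1_mean`: the exponential family draws with
#' rate \eqn{1/t_{G1}}, the fixed family returns \eqn{t_{G1}} exactly. A
#' zero mean degenerates to 0 for both families.
#'
#' Draws use the current R random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param params A [death_clock_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative durations.
#' @export
sample_g1 <- function(params, n = 1L) {
  stopifnot(inherits(params, "death_clock_params"))
  if (params$g1_mean == 0) return(rep(0, n))
  switch(params$g1_family,
         exponential = stats::rexp(n, rate = 1 / params$g1_mean),
         fixed = rep(params$g1_mean, n))
}

#' G1 duration cumulative distribution function
#'
#' \eqn{\Psi(t) = P(t^* \le t)} for the configured family. Used by
#' [survival_probability()]; survival requires \eqn{t^* < F^{-1}(T_\dagger)},
#' and for the continuous exponential family the boundary has probability
#' zero so the CDF applies directly.
#'
#' @param params A [death_clock_params()] object.
#' @param t Time(s) at which to evaluate (vectorised).
#' @return Probabilities in \eqn{[0, 1]}.
#' @keywords internal
g1_cdf <- function(params, t) {
  if (params$g1_mean == 0) return(as.numeric(t >= 0))
  switch(params$g1_family,
         exponential = stats::pexp(t, rate = 1 / params$g1_mean),
         fixed = as.numeric(t >= params$g1_mean))
}

#' Expand dimensionless cell-type parameters to dimensional ones
#'
#' The G2 death-signal theory is governed by two dimensionless parameters
#' per cell type: \eqn{\beta}, the mean fraction of the cell cycle spent in
#' G1 phase, and \eqn{\eta = T_\dagger / (c\, t_G)}, the normalised death
#' threshold. Given \eqn{(\beta, \eta)}, a total cell cycle duration
#' \eqn{t_G} and signal strength \eqn{c}, this returns the dimensional
#' parameter set \eqn{t_{G1} = \beta t_G}, \eqn{t_{G2} = (1-\beta) t_G},
#' \eqn{T_\dagger = \eta c t_G}. The signal strength is a free scale
#' absorbed by \eqn{\eta}; the default is \eqn{c = 1}.
#'
#' @param beta G1 fraction of the cell cycle, in (0, 1).
#' @param eta Normalised death threshold, > 0.
#' @param t_G Total cell cycle duration (time), > 0.
#' @param c Signal strength, > 0.
#' @param g1_family Passed to [death_clock_params()].
#' @return A [death_clock_params()] object.
#' @seealso [nondimensionalise()] for the inverse map.
#' @export
#' @examples
#' expand_dimensionless(beta = 0.5, eta = 0.2)
expand_dimensionless <- function(beta, eta, t_G = 1, c = 1,
                                 g1_family = "exponential") {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0, beta < 1,
            is.numeric(eta), length(eta) == 1L, eta > 0,
            is.numeric(t_G), length(t_G) == 1L, t_G > 0,
            is.numeric(c), length(c) == 1L, c > 0)
  death_clock_params(death_threshold = eta * c * t_G,
                     signal_strength = c,
                     g1_mean = beta * t_G,
                     g2_duration = (1 - beta) * t_G,
                     g1_family = g1_family)
}

#' Nondimensionalise death-clock parameters
#'
#' Inverse of [expand_dimensionless()]: maps a dimensional parameter set to
#' \eqn{(\beta, \eta, t_G)} with \eqn{\beta = t_{G1}/t_G},
#' \eqn{\eta = T_\dagger/(c\,t_G)} and \eqn{t_G = t_{G1} + t_{G2}}.
#'
#' @param params A [death_clock_params()] object with positive
#'   `signal_strength` and positive total cycle time.
#' @return A list with elements `beta`, `eta`, `t_G`.
#' @export
nondimensionalise <- function(params) {
  stopifnot(inherits(params, "death_clock_params"))
  t_G <- params$g1_mean + params$g2_duration
  if (t_G <= 0) stop("total cell cycle duration must be positive")
  if (params$signal_strength <= 0) {
    stop("signal strength must be positive to nondimensionalise")
  }
  list(beta = params$g1_mean / t_G,
       eta = params$death_threshold / (params$signal_strength * t_G),
       t_G = t_G)
}
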