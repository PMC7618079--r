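#' Dimensionless cell-type parameters
#'
#' The G2 death-signal theory characterises a cell type by two dimensionless
#' numbers: `beta`, the mean fraction of the cell cycle spent in G1 phase
#' (when cells are vulnerable to death signals and emit none), and `eta`,
#' the normalised death threshold \eqn{\eta = T_\dagger/(c\,t_G)}. The ratio
#' \eqn{\eta/\beta} acts as the cell's *tolerance* to death signals and
#' \eqn{1-\beta} as its *emission* rate (time spent signalling in G2).
#'
#' @param beta G1 fraction, in (0, 1).
#' @param eta Normalised death threshold, > 0.
#' @param t_G Total cell cycle duration (time); used only to check that two
#'   types being compared share a cycle duration.
#' @return An object of class `dimensionless_type`.
#' @export
dimensionless_type <- function(beta, eta, t_G = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0, beta < 1,
            is.numeric(eta), length(eta) == 1L, eta > 0,
            is.numeric(t_G), length(t_G) == 1L, t_G > 0)
  structure(list(beta = beta, eta = eta, t_G = t_G),
            class = "dimensionless_type")
}

#' @export
print.dimensionless_type <- function(x, ...) {
  cat(sprintf("Cell type: beta = %g, eta = %g (t_G = %g)\n",
              x$beta, x$eta, x$t_G))
  invisible(x)
}

as_type <- function(x) {
  if (inherits(x, "dimensionless_type")) return(x)
  if (inherits(x, "death_clock_params")) {
    nd <- nondimensionalise(x)
    return(dimensionless_type(nd$beta, nd$eta, nd$t_G))
  }
  stop("expected a dimensionless_type or death_clock_params object")
}

check_common_tG <- function(a, b, override = FALSE) {
  if (!override && abs(a$t_G - b$t_G) > 1e-12 * max(a$t_G, b$t_G)) {
    stop("winner/loser analysis assumes equal total cycle durations; ",
         "set `override_t_G = TRUE` to compare anyway")
  }
}

#' Homotypic survival probability
#'
#' Closed form for the exponential cell cycle model under the ergodic,
#' well-mixed approximation (the fraction of cells in G2 equals the mean G2
#' fraction of the cycle, \eqn{1-\beta}):
#' \deqn{\lambda(\beta, \eta) = 1 - \exp\!\left(-\frac{\eta}
#'   {\beta(1-\beta)}\right).}
#' The homotypic viability curve \eqn{\lambda = 1/2} is
#' \eqn{\eta = \ln(2)\,\beta(1-\beta)}.
#'
#' @param beta G1 fractions in (0, 1) (vectorised), or a
#'   [dimensionless_type()] (in which case `eta` is ignored).
#' @param eta Normalised death thresholds, > 0 (vectorised).
#' @return Survival probabilities in (0, 1).
#' @export
#' @examples
#' homotypic_lambda(0.3, log(2) * 0.3 * 0.7)  # exactly 1/2 on the curve
homotypic_lambda <- function(beta, eta = NULL) {
  if (inherits(beta, "dimensionless_type")) {
    eta <- beta$eta; beta <- beta$beta
  }
  if (any(beta <= 0 | beta >= 1)) stop("beta must lie in (0, 1)")
  if (any(eta <= 0)) stop("eta must be positive")
  1 - exp(-eta / (beta * (1 - beta)))
}

#' Generic-family homotypic survival probability
#'
#' \eqn{\lambda = \Psi\!\left(T_\dagger / (c (1-\beta))\right)} for an
#' arbitrary G1-duration family, via [survival_probability()] with the
#' ergodic constant signal \eqn{f \equiv c(1-\beta)}.
#'
#' @param params A [death_clock_params()] object.
#' @return Survival probability.
#' @export
homotypic_lambda_general <- function(params) {
  stopifnot(inherits(params, "death_clock_params"))
  nd <- nondimensionalise(params)
  survival_probability(
    constant_signal(params$signal_strength * (1 - nd$beta)), params)
}

#' Population-weighted mean G2 occupancy (ergodic death signal)
#'
#' Under the ergodic approximation each subpopulation contributes its mean
#' cycle G2 fraction, weighted by abundance:
#' \deqn{\langle 1-\beta\rangle = \frac{n_A(1-\beta_A) + n_B(1-\beta_B)}
#'   {n_A + n_B}.}
#' This is the well-mixed approximation to the G2 fraction \eqn{g(t)}
#' driving every cell's death clock. With one type absent it reduces to the
#' other type's homotypic value.
#'
#' @param n_A,n_B Cell counts, >= 0, not both zero.
#' @param beta_A,beta_B G1 fractions.
#' @return The weighted average in \eqn{[\min(1-\beta), \max(1-\beta)]}.
#' @export
ergodic_signal <- function(n_A, n_B, beta_A, beta_B) {
  stopifnot(all(n_A >= 0), all(n_B >= 0))
  if (any(n_A + n_B == 0)) stop("population must be non-empty")
  (n_A * (1 - beta_A) + n_B * (1 - beta_B)) / (n_A + n_B)
}

#' Instantaneous heterotypic survival probability
#'
#' For a cell type with parameters \eqn{(\beta, \eta)} exposed to the
#' population-weighted G2 occupancy `signal` \eqn{= \langle 1-\beta\rangle}:
#' \deqn{\xi = 1 - \exp\!\left(-\frac{\eta}{\beta\,\langle 1-\beta\rangle}
#'   \right).}
#' With `signal = 0` no death signal is received and \eqn{\xi = 1}; with
#' `signal` equal to the type's own \eqn{1-\beta} it reduces to
#' [homotypic_lambda()].
#'
#' @param type A [dimensionless_type()] (or `beta` as a number).
#' @param signal Weighted G2 occupancy \eqn{\langle 1-\beta\rangle} in
#'   \eqn{[0, 1]} (vectorised).
#' @param eta Normalised death threshold when `type` is given as a number.
#' @return Survival probabilities in (0, 1].
#' @export
heterotypic_xi <- function(type, signal, eta = NULL) {
  if (inherits(type, "dimensionless_type")) {
    beta <- type$beta; eta <- type$eta
  } else {
    beta <- type
  }
  stopifnot(all(signal >= 0), all(signal <= 1))
  out <- ifelse(signal == 0, 1, 1 - exp(-eta / (beta * pmax(signal, 1e-300))))
  as.numeric(out)
}

sgn_tol <- function(x, tol) as.integer(sign(ifelse(abs(x) <= tol, 0, x)))

#' Sign of the heterotypic survival difference
#'
#' The heterotypic survival difference \eqn{\Delta^{\ne}_{A|B} =
#' \xi_{A|B} - \xi_{B|A}} determines winner/loser status. Its sign is
#' independent of the population state:
#' \deqn{\mathrm{sgn}(\Delta^{\ne}_{A|B}) =
#'   \mathrm{sgn}(\eta_A/\beta_A - \eta_B/\beta_B),}
#' i.e. the more death-signal-tolerant type wins. `+1` means A wins, `-1`
#' means B wins, `0` is coexistence (the coexistence curve
#' \eqn{\eta_A/\beta_A = \eta_B/\beta_B}).
#'
#' @param type_A,type_B [dimensionless_type()] objects.
#' @param tol Absolute tolerance for detecting the analytic boundary.
#' @return Integer in \eqn{\{-1, 0, +1\}}.
#' @export
heterotypic_difference_sign <- function(type_A, type_B, tol = 1e-12) {
  a <- as_type(type_A); b <- as_type(type_B)
  sgn_tol(a$eta / a$beta - b$eta / b$beta, tol)
}

#' Sign of the homotypic survival difference
#'
#' The homotypic survival difference \eqn{\Delta^{=}_{A|B} = \xi_{A|B} -
#' \lambda_A} compares a type's fitness in heterotypic versus homotypic
#' conditions. In a genuinely mixed population (both counts positive) its
#' sign is state-independent:
#' \deqn{\mathrm{sgn}(\Delta^{=}_{A|B}) = \mathrm{sgn}(\beta_B - \beta_A),}
#' i.e. a type gains from competing against a lower-emission
#' (higher-\eqn{\beta}) type. Antisymmetric under label swap: one type's
#' loss is the other's gain, so a mutualistic interaction is impossible.
#' The zero set \eqn{\beta_A = \beta_B} is the neutral competition curve.
#'
#' @inheritParams heterotypic_difference_sign
#' @return Integer in \eqn{\{-1, 0, +1\}} (the sign for type A relative to
#'   B; negate for B relative to A).
#' @export
homotypic_difference_sign <- function(type_A, type_B, tol = 1e-12) {
  a <- as_type(type_A); b <- as_type(type_B)
  sgn_tol(b$beta - a$beta, tol)
}

#' Asymptotic heterotypic survival probabilities
#'
#' As the winner type comes to dominate, the weighted G2 occupancy
#' approaches the winner's own \eqn{1-\beta_W}, so the winner's asymptotic
#' survival probability equals its homotypic \eqn{\lambda_W}, and the
#' loser's is
#' \deqn{\xi^{\infty}_{L|W} = 1 - \exp\!\left(-\frac{\eta_L}
#'   {\beta_L (1-\beta_W)}\right).}
#'
#' @inheritParams heterotypic_difference_sign
#' @param override_t_G Allow differing total cycle durations (the
#'   winner/loser ordering assumes they are equal).
#' @return A list with `winner`, `loser` (labels `"A"`/`"B"`),
#'   `xi_winner` (\eqn{= \lambda_W}) and `xi_loser`
#'   (\eqn{= \xi^{\infty}_{L|W}}).
#' @export
asymptotic_survival <- function(type_A, type_B, tol = 1e-12,
                                override_t_G = FALSE) {
  a <- as_type(type_A); b <- as_type(type_B)
  check_common_tG(a, b, override_t_G)
  s <- heterotypic_difference_sign(a, b, tol)
  if (s == 0L) {
    stop("types are on the coexistence curve; no asymptotic winner exists")
  }
  w <- if (s > 0L) a else b
  l <- if (s > 0L) b else a
  list(winner = if (s > 0L) "A" else "B",
       loser = if (s > 0L) "B" else "A",
       xi_winner = homotypic_lambda(w$beta, w$eta),
       xi_loser = heterotypic_xi(l, 1 - w$beta))
}

#' Classify the competitive interaction (sign pattern)
#'
#' Classifies the interaction between two cell types from the signs of the
#' heterotypic and homotypic survival differences into one of nine cells /
#' five named categories: neutral coexistence (both zero), coexistence
#' (only the heterotypic difference zero), neutral competition (only the
#' homotypic difference zero), indirect competition (opposite signs: the
#' loser gains absolute fitness, the winner loses some), and direct
#' competition (same signs: winners gain, losers lose).
#'
#' @inheritParams heterotypic_difference_sign
#' @return A list with `category`, the two signs (`delta_het`, `delta_hom`
#'   for A relative to B), and `winner`/`loser` labels (`NA` when no winner
#'   emerges).
#' @export
classify_interaction <- function(type_A, type_B, tol = 1e-12) {
  s_het <- heterotypic_difference_sign(type_A, type_B, tol)
  s_hom <- homotypic_difference_sign(type_A, type_B, tol)
  winner <- if (s_het > 0L) "A" else if (s_het < 0L) "B" else NA_character_
  loser <- if (s_het > 0L) "B" else if (s_het < 0L) "A" else NA_character_
  category <-
    if (s_het == 0L && s_hom == 0L) "neutral coexistence"
    else if (s_het == 0L) "coexistence"
    else if (s_hom == 0L) "neutral competition"
    else if (s_het == s_hom) "direct competition"
    else "indirect competition"
  list(category = category, delta_het = s_het, delta_hom = s_hom,
       winner = winner, loser = loser)
}

#' Classify the competition regime
#'
#' Combines homotypic viability (\eqn{\lambda > 1/2} viable in this
#' analytic layer), the winner/loser ordering, the loser's asymptotic
#' survival probability, and the homotypic survival difference into the
#' most specific named competition regime:
#'
#' * `"homotypic nonviability"` — at least one type homotypically nonviable
#'   (outside the homotypic viability regime);
#' * `"neutral coexistence"`, `"coexistence"` — no winner emerges;
#' * `"complete cell competition"` — loser eliminated,
#'   \eqn{\xi^\infty_{L|W} < 1/2};
#' * `"critical cell competition"` — threshold case
#'   \eqn{\xi^\infty_{L|W} = 1/2};
#' * `"incomplete cell competition"` — loser survives but loses fitness;
#' * `"neutral competition"` — loser survives with unchanged fitness;
#' * `"indirect competition"` — loser survives and gains fitness.
#'
#' Boundary equalities are detected with absolute tolerance `tol`.
#'
#' @inheritParams asymptotic_survival
#' @return A list of class `regime_label` with `regime`, `winner`, `loser`,
#'   `lambda_A`, `lambda_B`, `delta_het_sign`, `xi_loser` (NA when no
#'   winner), and `competitive` (`TRUE` for complete/critical cell
#'   competition, i.e. the loser-elimination regime).
#' @export
classify_regime <- function(type_A, type_B, tol = 1e-12,
                            override_t_G = FALSE) {
  a <- as_type(type_A); b <- as_type(type_B)
  check_common_tG(a, b, override_t_G)
  lam_A <- homotypic_lambda(a$beta, a$eta)
  lam_B <- homotypic_lambda(b$beta, b$eta)
  s_het <- heterotypic_difference_sign(a, b, tol)
  out <- list(lambda_A = lam_A, lambda_B = lam_B, delta_het_sign = s_het,
              winner = NA_character_, loser = NA_character_,
              xi_loser = NA_real_, competitive = FALSE)
  viable_A <- lam_A > 0.5 + tol
  viable_B <- lam_B > 0.5 + tol
  if (!viable_A || !viable_B) {
    out$regime <- "homotypic nonviability"
    class(out) <- "regime_label"
    return(out)
  }
  if (s_het == 0L) {
    s_hom <- homotypic_difference_sign(a, b, tol)
    out$regime <- if (s_hom == 0L) "neutral coexistence" else "coexistence"
    class(out) <- "regime_label"
    return(out)
  }
  asym <- asymptotic_survival(a, b, tol, override_t_G)
  out$winner <- asym$winner
  out$loser <- asym$loser
  out$xi_loser <- asym$xi_loser
  # homotypic survival difference of the loser relative to the winner
  s_hom_loser <- if (s_het > 0L) homotypic_difference_sign(b, a, tol)
                 else homotypic_difference_sign(a, b, tol)
  if (abs(asym$xi_loser - 0.5) <= tol) {
    out$regime <- "critical cell competition"
    out$competitive <- TRUE
  } else if (asym$xi_loser < 0.5) {
    out$regime <- "complete cell competition"
    out$competitive <- TRUE
  } else if (s_hom_loser == 0L) {
    out$regime <- "neutral competition"
  } else if (s_hom_loser < 0L) {
    out$regime <- "incomplete cell competition"
  } else {
    out$regime <- "indirect competition"
  }
  class(out) <- "regime_label"
  out
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s\n", x$regime))
  cat(sprintf("  lambda_A = %.4f, lambda_B = %.4f\n", x$lambda_A, x$lambda_B))
  if (!is.na(x$winner)) {
    cat(sprintf("  winner %s, loser %s, loser xi_inf = %.4f\n",
                x$winner, x$loser, x$xi_loser))
  }
  invisible(x)
}

#' Tolerance and emission of a cell type
#'
#' The transformed parameters
#' \deqn{\tilde\eta = \frac{\eta}{\ln(2)\,\beta}, \qquad d = 1 - \beta,}
#' interpreted as the cell's tolerance to, and emission of, death signals.
#' Homotypic viability is \eqn{d < \tilde\eta} (cells must tolerate their
#' own signal); loser elimination is \eqn{\tilde\eta_L < d_W} (winners emit
#' more than losers tolerate); complete cell competition is the chain
#' \eqn{d_L < \tilde\eta_L < d_W < \tilde\eta_W}.
#'
#' @param type A [dimensionless_type()].
#' @return A list with `tolerance` and `emission`.
#' @export
tolerance_emission <- function(type) {
  x <- as_type(type)
  list(tolerance = x$eta / (log(2) * x$beta), emission = 1 - x$beta)
}

#' Competition regime via tolerance-emission inequality chains
#'
#' Independent reformulation of [classify_regime()] purely in terms of the
#' tolerance \eqn{\tilde\eta} and emission \eqn{d} of the two types:
#' homotypic viability of X is \eqn{d_X < \tilde\eta_X}; the winner is the
#' type with the larger tolerance; then
#' complete (\eqn{d_L < \tilde\eta_L < d_W < \tilde\eta_W}), critical
#' (\eqn{\tilde\eta_L = d_W}), incomplete
#' (\eqn{d_L < d_W < \tilde\eta_L < \tilde\eta_W}), neutral
#' (\eqn{d_L = d_W}) and indirect
#' (\eqn{d_W < d_L < \tilde\eta_L < \tilde\eta_W}) competition.
#'
#' @inheritParams classify_regime
#' @return Regime name (character), matching `classify_regime()$regime`.
#' @export
regime_from_tolerance_emission <- function(type_A, type_B, tol = 1e-12) {
  a <- as_type(type_A); b <- as_type(type_B)
  te_a <- tolerance_emission(a); te_b <- tolerance_emission(b)
  viable <- function(te) te$emission < te$tolerance - tol
  if (!viable(te_a) || !viable(te_b)) return("homotypic nonviability")
  dtol <- te_a$tolerance - te_b$tolerance
  if (abs(dtol) <= tol) {
    if (abs(te_a$emission - te_b$emission) <= tol) return("neutral coexistence")
    return("coexistence")
  }
  w <- if (dtol > 0) te_a else te_b
  l <- if (dtol > 0) te_b else te_a
  if (abs(l$tolerance - w$emission) <= tol) return("critical cell competition")
  if (l$tolerance < w$emission) return("complete cell competition")
  if (abs(l$emission - w$emission) <= tol) return("neutral competition")
  if (l$emission < w$emission) return("incomplete cell competition")
  "indirect competition"
}

#' Regime-boundary curves of a parameter cross section
#'
#' For a fixed competitor type B, the hypersurfaces separating the
#' heterotypic proliferation regimes become curves in
#' \eqn{(\beta_A, \eta_A)}-space:
#' * coexistence curve: \eqn{\eta_A = (\eta_B/\beta_B)\,\beta_A};
#' * A winner viability curve: \eqn{\eta_A = \ln(2)\,\beta_A(1-\beta_A)}
#'   (the homotypic viability curve of A);
#' * B loser viability curve: the vertical line
#'   \eqn{\beta_A = 1 - \eta_B/(\ln(2)\beta_B)}, absent when
#'   \eqn{\eta_B/\beta_B > \ln 2};
#' * A loser viability curve: \eqn{\eta_A = \ln(2)(1-\beta_B)\,\beta_A}.
#'
#' @param type_B A [dimensionless_type()] fixing the cross section.
#' @return A list with functions `coexistence(beta_A)`,
#'   `winner_viability(beta_A)`, `loser_viability_A(beta_A)` (each returning
#'   \eqn{\eta_A}), and the scalar `loser_viability_B_beta` (\eqn{\beta_A}
#'   of the vertical B loser curve, `NA` when absent).
#' @export
cross_section_curves <- function(type_B) {
  b <- as_type(type_B)
  ratio_B <- b$eta / b$beta
  beta_Bloser <- if (ratio_B > log(2)) NA_real_ else 1 - b$eta / (log(2) * b$beta)
  list(
    coexistence = function(beta_A) ratio_B * beta_A,
    winner_viability = function(beta_A) log(2) * beta_A * (1 - beta_A),
    loser_viability_A = function(beta_A) log(2) * (1 - b$beta) * beta_A,
    loser_viability_B_beta = beta_Bloser
  )
}

#' Predicted viability outcome for a heterotypic pairing
#'
#' Theory-side prediction of the four viability booleans measured by
#' simulation: homotypic viability from \eqn{\lambda > 1/2}, heterotypic
#' viability from the asymptotic survival probabilities (winner viable iff
#' homotypically viable; if the winner is nonviable both types are
#' eliminated; the loser additionally requires
#' \eqn{\xi^\infty_{L|W} > 1/2}). On the coexistence curve both types keep
#' their homotypic viability (their survival probabilities are identical
#' functions of the shared signal).
#'
#' @inheritParams classify_regime
#' @return A list with logicals `hom_A`, `hom_B`, `het_A`, `het_B`.
#' @export
predict_viability <- function(type_A, type_B, tol = 1e-12,
                              override_t_G = FALSE) {
  a <- as_type(type_A); b <- as_type(type_B)
  check_common_tG(a, b, override_t_G)
  lam_A <- homotypic_lambda(a$beta, a$eta)
  lam_B <- homotypic_lambda(b$beta, b$eta)
  s <- heterotypic_difference_sign(a, b, tol)
  hom_A <- lam_A >= 0.5
  hom_B <- lam_B >= 0.5
  if (s == 0L) {
    return(list(hom_A = hom_A, hom_B = hom_B, het_A = hom_A, het_B = hom_B))
  }
  asym <- asymptotic_survival(a, b, tol, override_t_G)
  w_viable <- asym$xi_winner >= 0.5
  l_viable <- w_viable && asym$xi_loser >= 0.5
  if (asym$winner == "A") {
    list(hom_A = hom_A, hom_B = hom_B, het_A = w_viable, het_B = l_viable)
  } else {
    list(hom_A = hom_A, hom_B = hom_B, het_A = l_viable, het_B = w_viable)
  }
}
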