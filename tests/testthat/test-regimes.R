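# Closed-form theory: survival probabilities, survival differences,
# interaction and regime classifiers, tolerance-emission.

test_that("homotypic survival probability and its viability curve", {
  # on the curve eta = ln(2) beta (1 - beta) the probability is exactly 1/2
  for (b in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(homotypic_lambda(b, log(2) * b * (1 - b)), 0.5)
  }
  expect_equal(homotypic_lambda(0.4, 0.1), 1 - exp(-0.1 / 0.24))
  expect_lt(homotypic_lambda(0.4, 0.1), 0.5)
  # large threshold: certain survival in the limit
  expect_gt(homotypic_lambda(0.5, 50), 1 - 1e-10)
  expect_error(homotypic_lambda(1.2, 0.1), "beta")
  # generic-family route agrees with the closed form
  p <- expand_dimensionless(0.35, 0.22)
  expect_equal(homotypic_lambda_general(p), homotypic_lambda(0.35, 0.22))
})

test_that("ergodic signal is the abundance-weighted G2 occupancy", {
  expect_equal(ergodic_signal(5, 0, 0.3, 0.9), 0.7)   # B absent
  expect_equal(ergodic_signal(10, 10, 0.2, 0.8), 0.5)
  set.seed(2)
  for (r in 1:20) {
    nA <- sample(0:50, 1); nB <- sample(0:50, 1)
    if (nA + nB == 0) nB <- 1
    bA <- runif(1, 0.01, 0.99); bB <- runif(1, 0.01, 0.99)
    s <- ergodic_signal(nA, nB, bA, bB)
    expect_gte(s, min(1 - bA, 1 - bB) - 1e-12)
    expect_lte(s, max(1 - bA, 1 - bB) + 1e-12)
  }
  expect_error(ergodic_signal(0, 0, 0.5, 0.5), "non-empty")
})

test_that("heterotypic survival probability generalises the homotypic one", {
  tA <- dimensionless_type(0.3, 0.25)
  expect_equal(heterotypic_xi(tA, 1 - 0.3), homotypic_lambda(0.3, 0.25))
  expect_equal(heterotypic_xi(dimensionless_type(0.8, 0.2), 0.8),
               1 - exp(-0.2 / (0.8 * 0.8)))
  expect_identical(heterotypic_xi(tA, 0), 1)   # no signal, no death
})

test_that("survival-difference signs depend only on tolerance and emission", {
  A <- dimensionless_type(0.2, 0.4)   # tolerance 2
  B <- dimensionless_type(0.8, 0.2)   # tolerance 0.25
  expect_identical(heterotypic_difference_sign(A, B), 1L)
  expect_identical(heterotypic_difference_sign(B, A), -1L)
  expect_identical(heterotypic_difference_sign(A, A), 0L)
  # the sign matches the actual difference at any composition
  for (s in c(0.2, 0.5, 0.8)) {
    expect_gt(heterotypic_xi(A, s) - heterotypic_xi(B, s), 0)
  }
  # homotypic difference: emission ordering, antisymmetric
  expect_identical(homotypic_difference_sign(A, B), 1L)  # beta_B > beta_A
  expect_identical(homotypic_difference_sign(B, A), -1L)
  expect_identical(homotypic_difference_sign(A, A), 0L)
})

test_that("asymptotic survival: winner keeps lambda, loser gets squeezed", {
  A <- dimensionless_type(0.2, 0.4)
  B <- dimensionless_type(0.8, 0.2)
  asym <- asymptotic_survival(A, B)
  expect_identical(asym$winner, "A")
  expect_equal(asym$xi_winner, homotypic_lambda(0.2, 0.4))
  expect_equal(asym$xi_loser, 1 - exp(-0.2 / (0.8 * (1 - 0.2))))
  expect_lt(asym$xi_loser, 0.5)
  # the loser's asymptotic survival never beats the winner's, anywhere
  set.seed(4)
  for (r in 1:60) {
    a <- dimensionless_type(runif(1, 0.05, 0.95), runif(1, 0.02, 1))
    b <- dimensionless_type(runif(1, 0.05, 0.95), runif(1, 0.02, 1))
    if (heterotypic_difference_sign(a, b) == 0L) next
    as <- asymptotic_survival(a, b)
    expect_lt(as$xi_loser, as$xi_winner + 1e-12)
  }
  expect_error(asymptotic_survival(A, A), "coexistence")
})

test_that("interaction classification covers the nine sign patterns", {
  mk <- function(b, e) dimensionless_type(b, e)
  # direct competition: A more tolerant and higher emission
  d <- classify_interaction(mk(0.2, 0.4), mk(0.8, 0.2))
  expect_identical(d$category, "direct competition")
  expect_identical(d$winner, "A")
  # neutral coexistence at identical parameters
  expect_identical(classify_interaction(mk(0.5, 0.3), mk(0.5, 0.3))$category,
                   "neutral coexistence")
  # coexistence: equal tolerance, different emission
  expect_identical(classify_interaction(mk(0.2, 0.2), mk(0.4, 0.4))$category,
                   "coexistence")
  # neutral competition: equal emission, different tolerance
  expect_identical(classify_interaction(mk(0.5, 0.4), mk(0.5, 0.2))$category,
                   "neutral competition")
  # indirect: A wins on tolerance but B has lower emission
  ind <- classify_interaction(mk(0.6, 0.9), mk(0.2, 0.1))
  expect_identical(ind$category, "indirect competition")
  expect_identical(ind$winner, "A")
})

test_that("regime classification returns the most specific label", {
  W <- dimensionless_type(0.2, 0.4)
  L <- dimensionless_type(0.8, 0.2)
  r <- classify_regime(W, L)
  expect_identical(r$regime, "complete cell competition")
  expect_true(r$competitive)
  expect_identical(r$winner, "A")
  # identical types: neutral coexistence
  expect_identical(classify_regime(W, W)$regime, "neutral coexistence")
  # homotypically nonviable partner takes the pair out of the regime grid
  N <- dimensionless_type(0.4, 0.1)
  expect_identical(classify_regime(W, N)$regime, "homotypic nonviability")
  expect_false(classify_regime(W, N)$competitive)
  # incomplete competition: loser survives but is suppressed
  r2 <- classify_regime(dimensionless_type(0.3, 0.6),
                        dimensionless_type(0.35, 0.3))
  expect_identical(r2$regime, "incomplete cell competition")
  expect_false(r2$competitive)
})

test_that("tolerance-emission reformulation agrees with the regime chains", {
  te <- tolerance_emission(dimensionless_type(0.2, 0.2))
  expect_equal(te$tolerance, 1 / log(2))
  expect_equal(te$emission, 0.8)
  # homotypic viability iff emission < tolerance
  expect_true(te$emission < te$tolerance)
  expect_gt(homotypic_lambda(0.2, 0.2), 0.5)
  # dense-grid agreement between the two classifier routes
  betas <- seq(0.15, 0.85, by = 0.1)
  etas <- seq(0.05, 0.65, by = 0.1)
  for (bA in betas) for (eA in etas) {
    A <- dimensionless_type(bA, eA)
    B <- dimensionless_type(0.45, 0.35)
    expect_identical(classify_regime(A, B)$regime,
                     regime_from_tolerance_emission(A, B))
  }
})

test_that("regime classification is equivariant under label swap", {
  set.seed(9)
  for (r in 1:50) {
    A <- dimensionless_type(runif(1, 0.1, 0.9), runif(1, 0.05, 0.8))
    B <- dimensionless_type(runif(1, 0.1, 0.9), runif(1, 0.05, 0.8))
    rAB <- classify_regime(A, B)
    rBA <- classify_regime(B, A)
    expect_identical(rAB$regime, rBA$regime)
    if (!is.na(rAB$winner)) {
      expect_identical(rBA$winner, c(A = "B", B = "A")[[rAB$winner]])
      expect_equal(rAB$xi_loser, rBA$xi_loser)
    }
  }
})

test_that("cross-section curves follow the analytic formulas", {
  # always-viable competitor: tolerance ratio above ln 2, no loser curve
  csI <- cross_section_curves(dimensionless_type(0.2, 0.2))
  expect_true(is.na(csI$loser_viability_B_beta))
  # eliminable competitor: vertical loser curve at 1 - eta_B/(ln2 beta_B)
  csII <- cross_section_curves(dimensionless_type(0.8, 0.2))
  expect_equal(csII$loser_viability_B_beta, 1 - 0.2 / (log(2) * 0.8))
  expect_equal(csII$loser_viability_B_beta, 0.6393, tolerance = 1e-4)
  # the coexistence curve passes through the neutral coexistence point
  expect_equal(csII$coexistence(0.8), 0.2)
  # coexistence curve slope is the competitor's tolerance ratio
  expect_equal(csI$coexistence(0.6), 0.6)
  # the A-side curves at the competitor's beta
  expect_equal(csII$winner_viability(0.5), log(2) * 0.25)
  expect_equal(csII$loser_viability_A(0.5), log(2) * 0.2 * 0.5)
})

test_that("viability predictions match the asymptotic theory", {
  # A eliminates B (complete competition)
  pv <- predict_viability(dimensionless_type(0.3, 0.4),
                          dimensionless_type(0.8, 0.2))
  expect_identical(unlist(pv), c(hom_A = TRUE, hom_B = TRUE,
                                 het_A = TRUE, het_B = FALSE))
  # nonviable winner drags both down
  pv2 <- predict_viability(dimensionless_type(0.3, 0.08),
                           dimensionless_type(0.4, 0.1))
  expect_false(pv2$het_A)
  expect_false(pv2$het_B)
  # mismatched cycle durations are refused unless overridden
  expect_error(predict_viability(dimensionless_type(0.3, 0.4, t_G = 1),
                                 dimensionless_type(0.5, 0.2, t_G = 2)),
               "cycle durations")
})
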