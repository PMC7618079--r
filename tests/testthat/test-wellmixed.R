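# Event-driven well-mixed simulator: signal fractions, scheduling,
# determinism, bookkeeping and agreement with the closed-form theory.

test_that("G2 signal fraction counts the other cells", {
  expect_equal(g2_signal_fraction(c("G1", "G2", "G1", "G1"), 1), 1 / 3)
  expect_equal(g2_signal_fraction("G1", 1), 0)           # alone: no signal
  expect_equal(g2_signal_fraction(c("G1", "G2", "G2", "G2"), 1), 1)
  # a G2 cell does not count itself
  expect_equal(g2_signal_fraction(c("G2", "G2", "G1"), 1), 1 / 2)
})

test_that("runs are deterministic given the seed", {
  cfg <- wellmixed_config(list(A = dp(0.5, 0.2)), c(A = 30), end_time = 6,
                          seed = 123)
  l1 <- run_wellmixed(cfg)
  l2 <- run_wellmixed(cfg)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  l3 <- run_wellmixed(wellmixed_config(list(A = dp(0.5, 0.2)), c(A = 30),
                                       end_time = 6, seed = 124))
  expect_false(identical(as.data.frame(l1), as.data.frame(l3)))
})

test_that("population bookkeeping is exact", {
  log <- quick_hom_run(0.4, 0.2, n0 = 60, end_time = 8, seed = 9)
  meta <- attr(log, "meta")
  ndiv <- sum(log$event == "division")
  ndeath <- sum(log$event == "death")
  expect_identical(ndiv - ndeath, meta$n_final - meta$n_initial)
})

test_that("zero signal strength gives a pure branching process", {
  p <- death_clock_params(death_threshold = 1, signal_strength = 0,
                          g1_mean = 0.5, g2_duration = 0.5)
  log <- run_wellmixed(wellmixed_config(list(A = p), c(A = 20),
                                        end_time = 5, seed = 2))
  expect_identical(sum(log$event == "death"), 0L)
  expect_gt(sum(log$event == "division"), 0L)
})

test_that("cells in G2 are impervious: deaths only strike G1 cells", {
  # fixed G1 of zero: every cell is always in G2, so no deaths can occur
  p <- death_clock_params(death_threshold = 0.01, signal_strength = 50,
                          g1_mean = 0, g2_duration = 1, g1_family = "fixed")
  log <- run_wellmixed(wellmixed_config(list(A = p), c(A = 10),
                                        end_time = 3, seed = 4))
  expect_identical(sum(log$event == "death"), 0L)
})

test_that("simultaneous events are processed in cell-id order", {
  # fixed family, no deaths: both initial cells divide at exactly t = 2
  p <- death_clock_params(1, 0, g1_mean = 1, g2_duration = 1,
                          g1_family = "fixed")
  log <- run_wellmixed(wellmixed_config(list(A = p), c(A = 2),
                                        end_time = 2.5, seed = 1))
  div <- log[log$event == "division", ]
  expect_equal(div$time[1:2], c(2, 2))
  expect_identical(div$cell_id[1:2], c(1L, 2L))
})

test_that("homotypic survival frequency matches the closed form", {
  log <- run_wellmixed(wellmixed_config(
    list(A = dp(0.5, 0.2)), c(A = 400), end_time = 4, seed = 42,
    init = "staggered", max_population = 5e4))
  cs <- cohort_survival_frequency(log, "A", born_before = 1)
  lam <- homotypic_lambda(0.5, 0.2)
  n <- cs$divisions + cs$deaths
  expect_gt(n, 300)
  expect_lt(abs(cs$frequency - lam), 3 * binom_se(lam, n))
})

test_that("the population is ergodic: G2 occupancy tracks 1 - beta", {
  log <- run_wellmixed(wellmixed_config(
    list(A = dp(0.4, 0.15)), c(A = 600), end_time = 6, seed = 8,
    init = "staggered", max_population = 5e4))
  meta <- attr(log, "meta")
  expect_gt(meta$n_final, 100)
  expect_lt(abs(meta$final_g2_fraction - (1 - 0.4)), 0.05)
})

test_that("fixed-step integration converges to the event-driven log", {
  cfg <- wellmixed_config(list(A = dp(0.5, 0.3)), c(A = 10), end_time = 4,
                          seed = 5)
  ev <- run_wellmixed(cfg)
  fx <- run_wellmixed_fixedstep(cfg, dt = 0.002)
  expect_identical(sum(ev$event == "division"), sum(fx$event == "division"))
  expect_identical(sum(ev$event == "death"), sum(fx$event == "death"))
})

test_that("lethal parameters collapse the population to a remnant", {
  # strong signal, tiny threshold: the population declines steeply, but
  # full extinction is impossible (the last survivor is always a G2 cell,
  # impervious and committed to division), so a small remnant lingers
  p <- expand_dimensionless(0.9, 0.005)
  log <- run_wellmixed(wellmixed_config(list(A = p), c(A = 30),
                                        end_time = 50, seed = 3))
  meta <- attr(log, "meta")
  expect_lt(meta$n_final, 10L)
  expect_lt(survival_frequency(log, "A"), 0.5)
  # population cap flags truncation
  p2 <- death_clock_params(1, 0, 0.2, 0.2)
  log2 <- run_wellmixed(wellmixed_config(list(A = p2), c(A = 10),
                                         end_time = 50, seed = 3,
                                         max_population = 50))
  expect_true(attr(log2, "truncated"))
})

test_that("event logs round-trip through CSV", {
  log <- quick_hom_run(0.5, 0.2, n0 = 20, end_time = 3, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log),
               ignore_attr = TRUE)
  unlink(path)
})
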