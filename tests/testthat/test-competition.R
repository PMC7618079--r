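# Survival frequencies, viability classification, the viability matrix and
# the significance protocol.

mk_log <- function(ndiv, ndeath, type = "A") {
  nn <- ndiv + ndeath
  event_log(seq_len(nn), c(rep("division", ndiv), rep("death", ndeath)),
            seq_len(nn), rep(type, nn))
}

test_that("survival frequency is divisions over fate decisions", {
  expect_equal(survival_frequency(mk_log(3, 1), "A"), 0.75)
  expect_equal(survival_frequency(mk_log(0, 5), "A"), 0)
  expect_identical(survival_frequency(mk_log(0, 0), "A"), NA_real_)
  # burn-in drops early events
  log <- event_log(c(1, 10), c("death", "division"), 1:2, c("A", "A"))
  expect_equal(survival_frequency(log, "A", burnin = 5), 1)
})

test_that("viability classification applies the competition criteria", {
  # both homotypically viable, only A heterotypically viable: competitive
  o <- classify_viability(c(0.6, 0.7, 0.8, 0.2))
  expect_true(o$competitive)
  expect_identical(o$winner, "A")
  expect_identical(o$col, 4L)
  expect_identical(o$row, 2L)
  # all viable: diagonal cell, not competitive
  o2 <- classify_viability(c(0.6, 0.7, 0.8, 0.9))
  expect_false(o2$competitive)
  expect_identical(c(o2$row, o2$col), c(4L, 4L))
  # loser rescue: A homotypically nonviable, both heterotypically viable
  o3 <- classify_viability(c(0.3, 0.7, 0.8, 0.9))
  expect_false(o3$competitive)
  expect_identical(c(o3$row, o3$col), c(4L, 3L))
  # threshold is >= 1/2
  expect_true(classify_viability(c(0.5, 0.5, 0.5, 0.5))$hom_A)
  # undefined frequencies count as viable, with a warning
  expect_warning(o4 <- classify_viability(c(NA, 0.7, 0.8, 0.2)),
                 "undefined")
  expect_true(o4$hom_A)
})

test_that("competitive flag equals the criteria conjunction on all 16 cells", {
  for (hom_A in c(0, 1)) for (hom_B in c(0, 1)) {
    for (het_A in c(0, 1)) for (het_B in c(0, 1)) {
      o <- classify_viability(c(0.1 + 0.8 * hom_A, 0.1 + 0.8 * hom_B,
                                0.1 + 0.8 * het_A, 0.1 + 0.8 * het_B))
      expect_identical(o$competitive,
                       hom_A == 1 && hom_B == 1 && xor(het_A == 1,
                                                       het_B == 1))
    }
  }
})

test_that("label swap mirrors matrix cells and preserves competitiveness", {
  set.seed(5)
  for (r in 1:40) {
    f <- runif(4)
    o <- classify_viability(f)
    s <- swap_labels(o)
    swap_idx <- c(1L, 3L, 2L, 4L)   # middle row/col pair exchanges
    expect_identical(s$row, swap_idx[o$row])
    expect_identical(s$col, swap_idx[o$col])
    expect_identical(s$competitive, o$competitive)
    if (o$competitive) {
      expect_identical(s$winner, c(A = "B", B = "A")[[o$winner]])
    }
  }
})

test_that("tabulation and label swap act consistently on outcome sets", {
  set.seed(6)
  outcomes <- lapply(1:30, function(i) classify_viability(runif(4)))
  m <- tabulate_viability_matrix(outcomes)
  expect_identical(sum(m), 30L)
  swapped <- tabulate_viability_matrix(lapply(outcomes, swap_labels))
  swap_idx <- c(1L, 3L, 2L, 4L)
  expect_identical(unname(unclass(swapped)[swap_idx, swap_idx]),
                   unname(unclass(m)[1:4, 1:4]))
  # empty input gives the zero matrix
  expect_identical(sum(tabulate_viability_matrix(list())), 0L)
})

test_that("the reference sweep tabulation reproduces its printed aggregates", {
  path <- system.file("extdata", "mechanical_sweep_viability_counts.csv",
                      package = "deathclock")
  m <- read_viability_matrix(path)
  st <- viability_matrix_stats(m)
  expect_identical(st$total, 2786L)
  expect_identical(st$competitive, 20L)
  expect_identical(st$antidiagonal_bottom_left, 4L)
  expect_equal(st$rescue_bottom_middle_pct, 8.4, tolerance = 0.01)
  expect_equal(st$suppress_top_middle_pct, 1.0, tolerance = 0.01)
  expect_gt(st$diagonal_plus_rescue_pct, 98)
})

test_that("the significance protocol rejects clear cases only", {
  mkfreq <- function(a, b, xa, xb) {
    counts <- rbind(lambda_A = a, lambda_B = b, xi_A = xa, xi_B = xb)
    colnames(counts) <- c("divisions", "deaths")
    structure(list(lambda_A = NA, lambda_B = NA, xi_A = NA, xi_B = NA,
                   counts = counts),
              class = "survival_frequencies")
  }
  # strong competitive signal: A wins, B crushed (2 divisions, 98 deaths)
  strong <- mkfreq(c(80, 20), c(75, 25), c(85, 15), c(2, 98))
  st <- significance_test(list(strong), winner = "A", alpha = 0.05)
  expect_true(st$significant)
  expect_lt(st$p_values[["het_loser"]], 1e-10)
  # frequencies hovering at one half: nothing rejects
  flat <- mkfreq(c(50, 50), c(51, 49), c(49, 51), c(50, 50))
  expect_false(significance_test(list(flat), "A")$significant)
  # alpha = 1 accepts any point estimates satisfying the criteria
  mild <- mkfreq(c(60, 40), c(60, 40), c(60, 40), c(40, 60))
  expect_true(significance_test(list(mild), "A", alpha = 1)$significant)
  # zero events in a condition: inconclusive
  empty <- mkfreq(c(0, 0), c(60, 40), c(60, 40), c(40, 60))
  st2 <- significance_test(list(empty), "A")
  expect_true(st2$inconclusive)
  expect_identical(st2$significant, NA)
  # pooling across replicates adds counts
  st3 <- significance_test(list(mild, mild, mild, mild), "A", alpha = 0.05)
  expect_true(st3$significant)
})
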