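#' Orthogonal-array Latin hypercube sweep design
#'
#' Defines a parameter sweep over `k` factors with bounds, sampled with an
#' orthogonal-array-based Latin hypercube: a strength-2 orthogonal array
#' OA(q^2, k, q, 2) over the prime field GF(q) spreads the q^2 runs so
#' that every pair of factors sees each of the q x q coarse cells exactly
#' once, and a per-level randomised fine stratification refines each
#' one-dimensional projection so that each factor's q^2 equal bins contain
#' exactly one point.
#'
#' @param factors Data frame with columns `name`, `lower`, `upper`.
#' @param q Number of levels; must be prime, with `nrow(factors) <= q + 1`.
#' @param seed Integer seed making the design reproducible.
#' @return An object of class `sweep_design`.
#' @seealso [oa_lhs_sample()], [default_mechanical_design()]
#' @export
sweep_design <- function(factors, q, seed = 1L) {
  stopifnot(is.data.frame(factors),
            all(c("name", "lower", "upper") %in% names(factors)),
            nrow(factors) >= 1L)
  if (any(factors$lower >= factors$upper)) {
    stop("each factor needs lower < upper")
  }
  q <- as.integer(q)
  if (!is_prime(q)) stop("q must be prime")
  if (nrow(factors) > q + 1L) {
    stop("at most q + 1 factors are supported by the OA construction")
  }
  structure(list(factors = factors, q = q, seed = as.integer(seed)),
            class = "sweep_design")
}

is_prime <- function(q) {
  q <- as.integer(q)
  if (q < 2L) return(FALSE)
  if (q < 4L) return(TRUE)
  all(q %% 2:floor(sqrt(q)) != 0L)
}

#' Sample an OA-based Latin hypercube design
#'
#' Builds the strength-2 orthogonal array from the finite-field
#' construction (runs indexed by \eqn{(a, b) \in GF(q)^2}; columns
#' \eqn{a}, \eqn{b}, and \eqn{a + m b \bmod q} for
#' \eqn{m = 1, \dots, q-1}), refines each column into a Latin hypercube by
#' assigning, within every coarse level, a random permutation of the q
#' fine bins, jitters uniformly within bins, and scales to the factor
#' bounds.
#'
#' @param design A [sweep_design()].
#' @return Data frame with q^2 rows and one column per factor, plus
#'   attribute `"levels"` (the integer OA, for property checks).
#' @export
#' @examples
#' d <- sweep_design(data.frame(name = c("x", "y"), lower = 0, upper = 1),
#'                   q = 3, seed = 1)
#' oa_lhs_sample(d)
oa_lhs_sample <- function(design) {
  stopifnot(inherits(design, "sweep_design"))
  q <- design$q
  if (!is_prime(q)) stop("q must be prime")
  k <- nrow(design$factors)
  set.seed(design$seed)
  a <- rep(0:(q - 1L), each = q)
  b <- rep(0:(q - 1L), times = q)
  cols <- vector("list", q + 1L)
  cols[[1L]] <- a
  cols[[2L]] <- b
  for (m in seq_len(q - 1L)) cols[[m + 2L]] <- (a + m * b) %% q
  oa <- do.call(cbind, cols[seq_len(k)])
  n <- q * q
  pts <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lev <- oa[, j]
    fine <- integer(n)
    for (l in 0:(q - 1L)) {
      sel <- which(lev == l)
      fine[sel] <- l * q + sample.int(q) - 1L  # one point per fine bin
    }
    u <- (fine + stats::runif(n)) / n
    lo <- design$factors$lower[j]; hi <- design$factors$upper[j]
    pts[, j] <- lo + u * (hi - lo)
  }
  out <- as.data.frame(pts)
  names(out) <- design$factors$name
  attr(out, "levels") <- oa
  attr(out, "design") <- design
  out
}

#' Sweep bounds for the mechanical model
#'
#' The 13-factor design over the mechanical and cell-cycle parameters of a
#' cell-type pair: target areas and elasticities in [0.5, 1.5],
#' contractilities in [0.01, 0.07], the three line tensions in
#' [0.06, 0.18], mean G1 durations in [0, 60] and G2 durations in
#' [40, 100]. With q = 53 levels the OA-LHS design has 53^2 = 2809
#' parameter sets.
#'
#' @param q Number of levels (prime), default 53.
#' @param seed Integer seed.
#' @return A [sweep_design()].
#' @export
default_mechanical_design <- function(q = 53L, seed = 1L) {
  factors <- data.frame(
    name = c("S0_A", "S0_B", "K_A", "K_B", "Gamma_A", "Gamma_B",
             "Lambda_AA", "Lambda_AB", "Lambda_BB",
             "tG1_A", "tG1_B", "tG2_A", "tG2_B"),
    lower = c(0.5, 0.5, 0.5, 0.5, 0.01, 0.01, 0.06, 0.06, 0.06, 0, 0, 40, 40),
    upper = c(1.5, 1.5, 1.5, 1.5, 0.07, 0.07, 0.18, 0.18, 0.18,
              60, 60, 100, 100),
    stringsAsFactors = FALSE)
  sweep_design(factors, q = q, seed = seed)
}

# derive a per-set seed from the sweep seed and the set index (kept below
# 2^31)
set_seed_for <- function(seed, index, run) {
  (as.numeric(seed) * 1009 + index * 131 + run * 7) %% 2147483647
}

sweep_params_wellmixed <- function(row, base) {
  # cycle factors from the design; death-clock scale from the base config
  list(
    A = death_clock_params(base$death_threshold, base$signal_strength,
                           row[["tG1_A"]], row[["tG2_A"]]),
    B = death_clock_params(base$death_threshold, base$signal_strength,
                           row[["tG1_B"]], row[["tG2_B"]]))
}

sweep_params_vertex <- function(row) {
  vertex_params(K = c(row[["K_A"]], row[["K_B"]]),
                S0 = c(row[["S0_A"]], row[["S0_B"]]),
                Gamma = c(row[["Gamma_A"]], row[["Gamma_B"]]),
                lambda_AA = row[["Lambda_AA"]],
                lambda_AB = row[["Lambda_AB"]],
                lambda_BB = row[["Lambda_BB"]])
}

#' Run a viability sweep over a parameter design
#'
#' For each parameter set (row) runs three simulations — two homotypic
#' (one per cell type) and one heterotypic with an equal random split —
#' computes the four survival frequencies and classifies the viability
#' outcome. Engine failures are caught, recorded, and excluded from the
#' tabulation. Per-set seeds are derived deterministically from the sweep
#' seed and the row index.
#'
#' The `"wellmixed"` engine uses the cycle factors (`tG1_*`, `tG2_*`) with
#' the death-clock scale fixed by `base` (signal strength and death
#' threshold); the `"vertex"` engine runs the mechanical model (no death
#' clock; deaths are passive T2 extrusions) with the mechanical factors.
#'
#' @param samples Data frame from [oa_lhs_sample()] (or any data frame
#'   with the same columns).
#' @param engine `"wellmixed"` or `"vertex"`.
#' @param seed Sweep-level seed.
#' @param base List of engine options: for `wellmixed`,
#'   `signal_strength`, `death_threshold`, `n0` (cells per type),
#'   `end_time`, `max_events`; for `vertex`, `n_cells`, `end_time`.
#' @param arrangement Heterotypic initial arrangement (vertex engine).
#' @return List with `outcomes` (per-set [classify_viability()] results or
#'   `NULL` for failed sets), `frequencies` (per-set
#'   [survival_frequencies()]), `errors` (character messages, `NA` when
#'   OK), and `matrix` (the [tabulate_viability_matrix()] of the non-failed
#'   sets).
#' @export
run_sweep <- function(samples, engine = c("wellmixed", "vertex"), seed = 1L,
                      base = list(), arrangement = "random") {
  engine <- match.arg(engine)
  defaults <- if (engine == "wellmixed") {
    list(signal_strength = 1, death_threshold = 30, n0 = 50L,
         end_time = 250, max_events = 400L)
  } else {
    list(n_cells = 36L, end_time = 250)
  }
  base <- utils::modifyList(defaults, base)
  n <- nrow(samples)
  outcomes <- vector("list", n)
  freqs <- vector("list", n)
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    row <- samples[i, , drop = FALSE]
    res <- tryCatch({
      if (engine == "wellmixed") {
        tp <- sweep_params_wellmixed(row, base)
        run3 <- function(counts, run) {
          run_wellmixed(wellmixed_config(
            tp, counts, end_time = base$end_time,
            seed = set_seed_for(seed, i, run), init = "staggered",
            max_events = base$max_events))
        }
        hom_A <- run3(c(A = base$n0, B = 0L), 1L)
        hom_B <- run3(c(A = 0L, B = base$n0), 2L)
        het <- run3(c(A = base$n0 %/% 2L, B = base$n0 %/% 2L), 3L)
      } else {
        mp <- sweep_params_vertex(row)
        # homotypic B run needs B's mechanics in slot 1
        mp_B <- vertex_params(K = row[["K_B"]], S0 = row[["S0_B"]],
                              Gamma = row[["Gamma_B"]],
                              lambda_AA = row[["Lambda_BB"]])
        # mechanical model: no death clock; dummy threshold, zero signal
        tpv <- list(
          A = death_clock_params(1, 0, row[["tG1_A"]], row[["tG2_A"]]),
          B = death_clock_params(1, 0, row[["tG1_B"]], row[["tG2_B"]]))
        runv <- function(arr, run, tp2, mech) {
          run_vertex(vertex_config(
            tp2, mech, n_cells = base$n_cells, arrangement = arr,
            end_time = base$end_time, seed = set_seed_for(seed, i, run),
            death_clock = FALSE))
        }
        hom_A <- runv("homotypic", 1L, list(A = tpv$A), mp)
        hom_B <- runv("homotypic", 2L, list(A = tpv$B), mp_B)
        # relabel the second homotypic run as type B
        hom_B$cell_type <- rep("B", nrow(hom_B))
        het <- runv(arrangement, 3L, tpv, mp)
      }
      survival_frequencies(hom_A, hom_B, het)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      freqs[[i]] <- res
      outcomes[[i]] <- suppressWarnings(classify_viability(res))
    }
  }
  list(outcomes = outcomes, frequencies = freqs, errors = errors,
       matrix = tabulate_viability_matrix(outcomes))
}

#' Re-test flagged parameter sets for significant competition
#'
#' Runs `n_replicates` additional simulation trios for each parameter set
#' (typically those that satisfied the cell competition criteria in a
#' sweep) and applies [significance_test()] to the pooled division/death
#' counts. With `arrangement = "segregated"` the heterotypic runs start
#' from two contiguous half-tissues instead of a random mixture (vertex
#' engine only).
#'
#' @inheritParams run_sweep
#' @param n_replicates Replicate trios per set; fewer than 2 is flagged
#'   inconclusive.
#' @param alpha Familywise significance level.
#' @return List of per-set reports: `significant`, `p_values`, `winner`,
#'   `inconclusive`.
#' @export
targeted_retest <- function(samples, engine = c("wellmixed", "vertex"),
                            n_replicates = 4L, alpha = 0.05, seed = 99L,
                            base = list(), arrangement = "random") {
  engine <- match.arg(engine)
  n <- nrow(samples)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_replicates < 2L) {
      reports[[i]] <- list(significant = NA, inconclusive = TRUE,
                           p_values = NULL, winner = NA_character_)
      next
    }
    reps <- lapply(seq_len(n_replicates), function(r) {
      res <- run_sweep(samples[i, , drop = FALSE], engine,
                       seed = seed + 7919 * r, base = base,
                       arrangement = arrangement)
      res$frequencies[[1L]]
    })
    reps <- Filter(Negate(is.null), reps)
    if (!length(reps)) {
      reports[[i]] <- list(significant = NA, inconclusive = TRUE,
                           p_values = NULL, winner = NA_character_)
      next
    }
    # claimed winner from the pooled point estimates
    pooled <- Reduce(`+`, lapply(reps, `[[`, "counts"))
    xiA <- pooled["xi_A", 1L] / max(1L, sum(pooled["xi_A", ]))
    xiB <- pooled["xi_B", 1L] / max(1L, sum(pooled["xi_B", ]))
    winner <- if (xiA >= xiB) "A" else "B"
    st <- significance_test(reps, winner = winner, alpha = alpha)
    reports[[i]] <- list(significant = st$significant,
                         p_values = st$p_values, winner = winner,
                         inconclusive = st$inconclusive)
  }
  reports
}
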