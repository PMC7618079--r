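#' Survival frequencies of a cell-type pairing
#'
#' Collects the four empirical survival frequencies needed by the cell
#' competition criteria — \eqn{\hat\lambda_A, \hat\lambda_B} from two
#' homotypic runs and \eqn{\hat\xi_{A|B}, \hat\xi_{B|A}} from one
#' heterotypic run — together with the division/death counts backing each.
#'
#' @param hom_A,hom_B [event_log()]s of the homotypic runs (A resp. B).
#' @param het [event_log()] of the heterotypic run.
#' @param labels Type labels, default `c("A", "B")`.
#' @param burnin Discard events before this time in every log.
#' @return An object of class `survival_frequencies`: list with `lambda_A`,
#'   `lambda_B`, `xi_A`, `xi_B` (each possibly `NA` when no events) and a
#'   `counts` matrix.
#' @export
survival_frequencies <- function(hom_A, hom_B, het, labels = c("A", "B"),
                                 burnin = 0) {
  counts <- rbind(
    lambda_A = event_counts(hom_A, labels[1L], burnin),
    lambda_B = event_counts(hom_B, labels[2L], burnin),
    xi_A = event_counts(het, labels[1L], burnin),
    xi_B = event_counts(het, labels[2L], burnin))
  freq <- ifelse(rowSums(counts) > 0, counts[, 1L] / rowSums(counts),
                 NA_real_)
  structure(
    list(lambda_A = freq[["lambda_A"]], lambda_B = freq[["lambda_B"]],
         xi_A = freq[["xi_A"]], xi_B = freq[["xi_B"]], counts = counts),
    class = "survival_frequencies"
  )
}

#' @export
print.survival_frequencies <- function(x, ...) {
  cat(sprintf("lambda_A = %.3f  lambda_B = %.3f  xi_A|B = %.3f  xi_B|A = %.3f\n",
              x$lambda_A, x$lambda_B, x$xi_A, x$xi_B))
  invisible(x)
}

#' Classify a viability outcome
#'
#' Applies the viability threshold (frequency \eqn{\ge 1/2} means the
#' population grew or held steady, hence viable) to the four survival
#' frequencies, locates the outcome in the 4x4 viability matrix, and
#' applies the cell competition criteria: an outcome is *competitive* when
#' both types are homotypically viable and exactly one remains
#' heterotypically viable; that type is the winner.
#'
#' An undefined frequency (no divisions or deaths logged) is treated as
#' viable with a warning — the population persisted unchanged.
#'
#' The matrix layout puts homotypic outcomes on columns in the order
#' (neither viable, only A, only B, both) and heterotypic outcomes on rows
#' in the same order, so the main diagonal collects outcomes whose
#' heterotypic viability matches the homotypic one.
#'
#' @param freqs A [survival_frequencies()] object, or a numeric vector of
#'   the four frequencies `c(lambda_A, lambda_B, xi_A, xi_B)`.
#' @return An object of class `viability_outcome`: list with logicals
#'   `hom_A`, `hom_B`, `het_A`, `het_B`, integer `row`/`col` in 1..4,
#'   `competitive`, and `winner` (`"A"`, `"B"` or `NA`).
#' @export
classify_viability <- function(freqs) {
  if (inherits(freqs, "survival_frequencies")) {
    v <- c(freqs$lambda_A, freqs$lambda_B, freqs$xi_A, freqs$xi_B)
  } else {
    stopifnot(is.numeric(freqs), length(freqs) == 4L)
    v <- freqs
  }
  if (anyNA(v)) {
    warning("undefined survival frequency (no events); treating as viable")
    v[is.na(v)] <- 1
  }
  viable <- v >= 0.5
  hom_A <- viable[1L]; hom_B <- viable[2L]
  het_A <- viable[3L]; het_B <- viable[4L]
  col <- 1L + hom_A + 2L * hom_B
  row <- 1L + het_A + 2L * het_B
  competitive <- hom_A && hom_B && xor(het_A, het_B)
  winner <- if (!competitive) NA_character_ else if (het_A) "A" else "B"
  structure(
    list(hom_A = hom_A, hom_B = hom_B, het_A = het_A, het_B = het_B,
         row = row, col = col, competitive = competitive, winner = winner),
    class = "viability_outcome"
  )
}

#' @export
print.viability_outcome <- function(x, ...) {
  lab <- function(b) if (b) "viable" else "nonviable"
  cat(sprintf("Homotypic: A %s, B %s; heterotypic: A %s, B %s\n",
              lab(x$hom_A), lab(x$hom_B), lab(x$het_A), lab(x$het_B)))
  cat(sprintf("Matrix cell (row %d, col %d); %s\n", x$row, x$col,
              if (x$competitive) paste0("competitive, winner ", x$winner)
              else "not competitive"))
  invisible(x)
}

#' Swap the cell-type labels of a viability outcome
#'
#' Relabelling A as B maps each viability-matrix cell to its mirror cell
#' (columns/rows 2 and 3 exchange) and preserves the competitive flag with
#' the winner relabelled.
#'
#' @param outcome A [classify_viability()] result.
#' @return The relabelled `viability_outcome`.
#' @export
swap_labels <- function(outcome) {
  stopifnot(inherits(outcome, "viability_outcome"))
  classify_viability(c(as.numeric(outcome$hom_B), as.numeric(outcome$hom_A),
                       as.numeric(outcome$het_B), as.numeric(outcome$het_A)))
}

viability_matrix_dimnames <- function() {
  hom <- c("homA<1/2,homB<1/2", "homA>=1/2,homB<1/2",
           "homA<1/2,homB>=1/2", "homA>=1/2,homB>=1/2")
  het <- c("hetA<1/2,hetB<1/2", "hetA>=1/2,hetB<1/2",
           "hetA<1/2,hetB>=1/2", "hetA>=1/2,hetB>=1/2")
  list(heterotypic = het, homotypic = hom)
}

#' Tabulate viability outcomes into the 4x4 viability matrix
#'
#' Counts outcomes per viability-matrix cell. Rows index the heterotypic
#' outcome, columns the homotypic outcome, both ordered (neither, A only, B
#' only, both viable); the main diagonal therefore holds outcomes with no
#' viability change between conditions, and the cells (row 2, col 4) and
#' (row 3, col 4) are the competitive outcomes.
#'
#' @param outcomes A list of [classify_viability()] results (entries that
#'   are `NULL` or carry an `error` attribute are skipped).
#' @return A 4x4 integer matrix of class `viability_matrix`.
#' @export
tabulate_viability_matrix <- function(outcomes) {
  m <- matrix(0L, 4L, 4L, dimnames = viability_matrix_dimnames())
  for (o in outcomes) {
    if (is.null(o) || !inherits(o, "viability_outcome")) next
    m[o$row, o$col] <- m[o$row, o$col] + 1L
  }
  class(m) <- c("viability_matrix", class(m))
  m
}

#' Aggregate statistics of a viability matrix
#'
#' Summary quantities used to interpret a sweep: the number of competitive
#' outcomes (middle rows of the last column), the "loser rescue" cells
#' (bottom row middle: one type homotypically nonviable but both
#' heterotypically viable), the "mutual suppression" cells (top row middle:
#' both heterotypically nonviable), the bottom-left antidiagonal cell (both
#' nonviable types rescuing each other), the main diagonal (no viability
#' change), and percentages of the total.
#'
#' @param m A [tabulate_viability_matrix()] result (any 4x4 count matrix).
#' @return Named list of counts and percentages.
#' @export
viability_matrix_stats <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  total <- sum(m)
  diag_count <- sum(diag(m))
  competitive <- m[2L, 4L] + m[3L, 4L]
  rescue <- m[4L, 2L] + m[4L, 3L]
  suppress <- m[1L, 2L] + m[1L, 3L]
  anti_bl <- m[4L, 1L]
  list(total = total,
       competitive = competitive,
       competitive_pct = 100 * competitive / total,
       rescue_bottom_middle = rescue,
       rescue_bottom_middle_pct = 100 * rescue / total,
       suppress_top_middle = suppress,
       suppress_top_middle_pct = 100 * suppress / total,
       antidiagonal_bottom_left = anti_bl,
       diagonal = diag_count,
       diagonal_pct = 100 * diag_count / total,
       diagonal_plus_rescue_pct = 100 * (diag_count + rescue) / total)
}

#' Write / read a viability matrix as CSV
#'
#' @param m A viability matrix.
#' @param path File path.
#' @export
write_viability_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_viability_matrix
#' @export
read_viability_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  dimnames(m) <- viability_matrix_dimnames()
  class(m) <- c("viability_matrix", class(m))
  m
}

#' Significance test for a competitive classification
#'
#' Tests whether a competitive classification (both types homotypically
#' viable, winner heterotypically viable, loser heterotypically nonviable)
#' is statistically significant, using pooled division/death counts across
#' replicate runs. Four one-sided exact binomial tests are performed on the
#' pooled counts:
#' * homotypic A and homotypic B: reject `frequency < 1/2`
#'   (alternative "greater");
#' * winner heterotypic: reject `frequency < 1/2` (alternative "greater");
#' * loser heterotypic: reject `frequency >= 1/2` (alternative "less");
#'
#' and the classification is deemed significant when all four reject after
#' Bonferroni correction across the four tests at level `alpha`. A
#' condition with zero pooled events renders the test inconclusive.
#'
#' @param freq_list List of [survival_frequencies()] objects (replicates of
#'   the same condition trio).
#' @param winner `"A"` or `"B"`: the claimed winner.
#' @param alpha Significance level (familywise).
#' @return List with `significant` (logical, `NA` when inconclusive),
#'   `p_values` (named, raw), `alpha`, `pooled` counts matrix.
#' @export
significance_test <- function(freq_list, winner = c("A", "B"), alpha = 0.05) {
  winner <- match.arg(winner)
  stopifnot(is.list(freq_list), length(freq_list) >= 1L,
            all(vapply(freq_list, inherits, TRUE, "survival_frequencies")))
  pooled <- Reduce(`+`, lapply(freq_list, `[[`, "counts"))
  het_w <- if (winner == "A") "xi_A" else "xi_B"
  het_l <- if (winner == "A") "xi_B" else "xi_A"
  spec <- list(
    hom_A = list(row = "lambda_A", alternative = "greater"),
    hom_B = list(row = "lambda_B", alternative = "greater"),
    het_winner = list(row = het_w, alternative = "greater"),
    het_loser = list(row = het_l, alternative = "less"))
  p <- vapply(spec, function(s) {
    x <- pooled[s$row, "divisions"]
    n <- sum(pooled[s$row, ])
    if (n == 0L) return(NA_real_)
    stats::binom.test(x, n, p = 0.5, alternative = s$alternative)$p.value
  }, 0)
  inconclusive <- anyNA(p)
  significant <- if (inconclusive) NA else all(p <= alpha / length(p))
  list(significant = significant, p_values = p, alpha = alpha,
       pooled = pooled, inconclusive = inconclusive)
}
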