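# Mechanics of the vertex-based epithelium: tissue energy, its analytic
# gradient, and the explicit Euler step with mesh rearrangements.

edge_lambda <- function(mesh, params, cache) {
  interior <- cache$edge_c2 > 0L
  lam <- numeric(length(cache$edge_a))
  t1 <- mesh$type[cache$edge_c1]
  lam[!interior] <- params$lambda_bdy[t1[!interior]]
  t2 <- mesh$type[pmax(cache$edge_c2, 1L)]
  lam[interior] <- params$lambda[cbind(t1[interior], t2[interior])]
  lam
}

# per-cell current target areas: engine sets mesh$S0 (0 for dying cells);
# fall back to the per-type default when unset
current_S0 <- function(mesh, params) {
  s0 <- mesh$S0
  miss <- is.na(s0)
  if (any(miss)) s0[miss] <- params$S0[mesh$type[miss]]
  s0
}

#' Tissue mechanical energy
#'
#' Evaluates the epithelium energy: area elasticity
#' \eqn{\sum_\alpha K_\alpha/2\,(S_\alpha - S^0_\alpha)^2}, perimeter
#' contractility \eqn{\sum_\alpha \Gamma_\alpha/2\, L_\alpha^2}, and line
#' tension \eqn{\sum \Lambda_{ij} \ell_{ij}} with the tension resolved by
#' the edge type (A-A, A-B, B-B, or boundary).
#'
#' @param mesh A vertex mesh.
#' @param params A [vertex_params()] object.
#' @return Scalar energy.
#' @export
energy <- function(mesh, params) {
  ch <- mesh_cache(mesh)
  S <- cell_areas(mesh)
  L <- cell_perimeters(mesh)
  s0 <- current_S0(mesh, params)
  x <- mesh$pos[, 1L]; y <- mesh$pos[, 2L]
  el <- sqrt((x[ch$edge_a] - x[ch$edge_b])^2 +
             (y[ch$edge_a] - y[ch$edge_b])^2)
  lam <- edge_lambda(mesh, params, ch)
  sum(params$K[mesh$type] / 2 * (S - s0)^2) +
    sum(params$Gamma[mesh$type] / 2 * L^2) +
    sum(lam * el)
}

#' Forces on mesh vertices
#'
#' Analytic negative gradient of [energy()] with respect to every vertex
#' position, so that free relaxation decreases the energy. For a vertex
#' with cyclic neighbours \eqn{r_p, r_n} within a cell, the area gradient
#' is \eqn{\partial S/\partial r_i = ((y_n - y_p)/2, (x_p - x_n)/2)} and
#' the perimeter gradient is the sum of unit vectors away from the two
#' neighbours; edge tension pulls each endpoint toward the other.
#'
#' @inheritParams energy
#' @return Matrix (vertices x 2) of forces; rows of unreferenced vertices
#'   are zero.
#' @export
vertex_forces <- function(mesh, params) {
  ch <- mesh_cache(mesh)
  nc <- length(mesh$cells)
  V <- nrow(mesh$pos)
  x <- mesh$pos[, 1L]; y <- mesh$pos[, 2L]
  v <- ch$v; vn <- ch$vn; vp <- ch$vp; cid <- ch$cid

  cr <- x[v] * y[vn] - x[vn] * y[v]
  S <- rowsum_into(cr, cid, nc) / 2
  elx <- x[vn] - x[v]; ely <- y[vn] - y[v]
  el <- sqrt(elx^2 + ely^2)
  L <- rowsum_into(el, cid, nc)
  s0 <- current_S0(mesh, params)
  coefA <- (params$K[mesh$type] * (S - s0))[cid]
  coefP <- (params$Gamma[mesh$type] * L)[cid]

  gx <- coefA * 0.5 * (y[vn] - y[vp])
  gy <- coefA * 0.5 * (x[vp] - x[vn])
  lpx <- x[v] - x[vp]; lpy <- y[v] - y[vp]
  lp <- sqrt(lpx^2 + lpy^2); lp[lp < 1e-12] <- 1
  ln <- el; ln[ln < 1e-12] <- 1
  gx <- gx + coefP * (lpx / lp - elx / ln)
  gy <- gy + coefP * (lpy / lp - ely / ln)
  grad_x <- rowsum_into(gx, v, V)
  grad_y <- rowsum_into(gy, v, V)

  lam <- edge_lambda(mesh, params, ch)
  dx <- x[ch$edge_a] - x[ch$edge_b]
  dy <- y[ch$edge_a] - y[ch$edge_b]
  dl <- sqrt(dx^2 + dy^2); dl[dl < 1e-12] <- 1
  tx <- lam * dx / dl; ty <- lam * dy / dl
  grad_x <- grad_x + rowsum_into(tx, ch$edge_a, V) -
    rowsum_into(tx, ch$edge_b, V)
  grad_y <- grad_y + rowsum_into(ty, ch$edge_a, V) -
    rowsum_into(ty, ch$edge_b, V)

  cbind(-grad_x, -grad_y)
}

#' Advance the mesh by one mechanical step
#'
#' Explicit Euler update \eqn{r_i \leftarrow r_i + (dt/\mu) F_i}, followed
#' by mesh rearrangements: T1 swaps on interior edges shorter than the T1
#' threshold (neighbour exchange) and T2 extrusion of cells whose area has
#' fallen below the T2 threshold. Cell-cycle and death-clock events are
#' handled by [run_vertex()], which calls this every step.
#'
#' @inheritParams energy
#' @param dt Timestep (defaults to `params$dt`).
#' @return A list of rearrangement records, each
#'   `list(kind = "t1swap"|"t2swap", cell_id =, cell_index =, dying =)`;
#'   T2 records describe the removed cell (by its stable id).
#' @export
advance_mesh <- function(mesh, params, dt = params$dt) {
  stopifnot(dt > 0)
  F <- vertex_forces(mesh, params)
  mesh$pos <- mesh$pos + (dt / params$mu) * F
  events <- list()
  # T1 swaps: one at a time, re-examining after each (topology changes)
  for (iter in 1:100) {
    ch <- mesh_cache(mesh)
    x <- mesh$pos[, 1L]; y <- mesh$pos[, 2L]
    el <- sqrt((x[ch$edge_a] - x[ch$edge_b])^2 +
               (y[ch$edge_a] - y[ch$edge_b])^2)
    short <- which(ch$edge_c2 > 0L & el < params$t1_threshold)
    if (!length(short)) break
    done <- FALSE
    for (e in short[order(el[short])]) {
      if (do_t1(mesh, params, ch$edge_a[e], ch$edge_b[e])) {
        events[[length(events) + 1L]] <-
          list(kind = "t1swap", cell_id = NA_integer_,
               cell_index = NA_integer_, dying = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done) break  # all short edges currently unswappable
  }
  # T2 extrusions
  repeat {
    S <- cell_areas(mesh)
    small <- which(S < params$t2_threshold)
    if (!length(small)) break
    ci <- small[1L]
    events[[length(events) + 1L]] <-
      list(kind = "t2swap", cell_id = mesh$cell_id[ci], cell_index = ci,
           dying = mesh$dying[ci], type = mesh$type[ci])
    do_t2(mesh, ci)
    if (!length(mesh$cells)) break
  }
  if (length(mesh$cells)) {
    S <- cell_areas(mesh)
    if (any(S <= 0) || any(!is.finite(mesh$pos))) {
      stop("simulation error: degenerate mesh (timestep too large?)")
    }
  }
  events
}
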