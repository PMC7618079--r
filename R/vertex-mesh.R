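# Vertex meshes are environments: the simulation engine mutates them in
# place (positions every step, topology at rearrangements) and keeps a
# derived topology cache that is invalidated whenever cell connectivity
# changes.

#' Mechanical parameters of the vertex-based model
#'
#' Parameters of the standard area-elasticity / contractility / line-tension
#' epithelium energy
#' \deqn{E = \sum_\alpha \frac{K_\alpha}{2}(S_\alpha - S^0_\alpha)^2 +
#'  \sum_\alpha \frac{\Gamma_\alpha}{2} L_\alpha^2 +
#'  \sum_{\langle i,j\rangle} \Lambda_{ij}\,\ell_{ij},}
#' with per-type elasticity `K`, target area `S0` and contractility `Gamma`,
#' and per-edge line tension resolved by the types of the cells sharing the
#' edge (`lambda_AA`, `lambda_AB`, `lambda_BB`; boundary edges use
#' `lambda_bdy_A`/`lambda_bdy_B`, defaulting to the homotypic tensions).
#' Vertices obey overdamped dynamics \eqn{\mu\,\dot r_i = F_i} with
#' \eqn{F_i = -\nabla_i E}.
#'
#' Defaults follow common practice for this energy: `K = 1`, `S0 = 1`,
#' `Gamma = 0.04`, `lambda = 0.12`, `mu = 1`, timestep `dt = 0.05`,
#' T1 threshold length 0.1 (new edge 1.05x the threshold to avoid immediate
#' re-triggering) and T2 area threshold 0.01.
#'
#' @param K,S0,Gamma Per-type vectors (length 1 or 2; recycled to 2).
#' @param lambda_AA,lambda_AB,lambda_BB Line tensions by edge type.
#' @param lambda_bdy_A,lambda_bdy_B Boundary-edge tensions.
#' @param mu Friction coefficient, > 0.
#' @param dt Timestep for the explicit Euler update.
#' @param t1_threshold Edge length below which a T1 swap fires.
#' @param t1_new_factor New edge length after a T1, as a multiple of
#'   `t1_threshold`.
#' @param t2_threshold Cell area below which the cell is extruded (T2).
#' @return An object of class `vertex_params`.
#' @export
vertex_params <- function(K = 1, S0 = 1, Gamma = 0.04,
                          lambda_AA = 0.12, lambda_AB = 0.12,
                          lambda_BB = 0.12,
                          lambda_bdy_A = lambda_AA,
                          lambda_bdy_B = lambda_BB,
                          mu = 1, dt = 0.05,
                          t1_threshold = 0.1, t1_new_factor = 1.05,
                          t2_threshold = 0.01) {
  stopifnot(mu > 0, dt > 0, t1_threshold > 0, t2_threshold > 0,
            t1_new_factor > 1)
  lam <- matrix(c(lambda_AA, lambda_AB, lambda_AB, lambda_BB), 2L, 2L)
  structure(
    list(K = rep_len(K, 2L), S0 = rep_len(S0, 2L),
         Gamma = rep_len(Gamma, 2L), lambda = lam,
         lambda_bdy = c(lambda_bdy_A, lambda_bdy_B), mu = mu, dt = dt,
         t1_threshold = t1_threshold, t1_new_factor = t1_new_factor,
         t2_threshold = t2_threshold),
    class = "vertex_params"
  )
}

new_vertex_mesh <- function(pos, cells, type, labels = c("A", "B")) {
  mesh <- new.env(parent = emptyenv())
  mesh$pos <- pos
  mesh$cells <- cells
  mesh$type <- as.integer(type)
  mesh$labels <- labels
  n <- length(cells)
  mesh$cell_id <- seq_len(n)
  mesh$next_cell_id <- n + 1L
  mesh$birth <- numeric(n)
  mesh$tstar <- rep(NA_real_, n)
  mesh$tau <- numeric(n)
  mesh$dying <- logical(n)
  mesh$S0 <- rep(NA_real_, n)  # per-cell current target area (set by engine)
  mesh$cache <- NULL
  class(mesh) <- "vertex_mesh"
  mesh
}

#' @export
print.vertex_mesh <- function(x, ...) {
  cat(sprintf("Vertex mesh: %d cells, %d vertices\n",
              length(x$cells), nrow(x$pos)))
  tab <- table(x$labels[x$type])
  print(tab)
  invisible(x)
}

#' Number of cells in a mesh
#' @param mesh A vertex mesh.
#' @return Integer count.
#' @export
n_cells <- function(mesh) length(mesh$cells)

invalidate_cache <- function(mesh) mesh$cache <- NULL

# Topology cache: flattened cell cycles (cid/v with next and previous
# vertex in each cell's cycle) and the undirected edge table with incident
# cells (c2 = 0 for boundary edges).
mesh_cache <- function(mesh) {
  if (!is.null(mesh$cache)) return(mesh$cache)
  cells <- mesh$cells
  len <- lengths(cells)
  if (any(len < 3L)) stop("mesh error: cell with fewer than 3 vertices")
  cid <- rep.int(seq_along(cells), len)
  v <- unlist(cells, use.names = FALSE)
  # next/prev within each cycle
  offs <- cumsum(c(0L, len[-length(len)]))
  pos_in_cell <- sequence(len)
  nxt_pos <- ifelse(pos_in_cell == len[cid], 1L, pos_in_cell + 1L)
  prv_pos <- ifelse(pos_in_cell == 1L, len[cid], pos_in_cell - 1L)
  vn <- v[offs[cid] + nxt_pos]
  vp <- v[offs[cid] + prv_pos]
  # undirected edges
  a <- pmin(v, vn); b <- pmax(v, vn)
  key <- a * (nrow(mesh$pos) + 1) + b
  first <- !duplicated(key)
  ukey <- key[first]
  idx <- match(key, ukey)
  ne <- length(ukey)
  c1 <- integer(ne); c2 <- integer(ne)
  c1[idx[first]] <- cid[first]
  second <- duplicated(key)
  c2[idx[second]] <- cid[second]
  if (any(tabulate(idx, ne) > 2L)) {
    stop("mesh error: edge incident to more than two cells")
  }
  mesh$cache <- list(cid = cid, v = v, vn = vn, vp = vp,
                     edge_a = a[first], edge_b = b[first],
                     edge_c1 = c1, edge_c2 = c2)
  mesh$cache
}

rowsum_into <- function(w, idx, n) {
  out <- numeric(n)
  r <- rowsum(w, idx)
  out[as.integer(rownames(r))] <- r
  out
}

#' Cell areas and perimeters
#'
#' Areas by the shoelace rule (positive for the counter-clockwise cell
#' polygons maintained by the package) and perimeters as the sum of edge
#' lengths.
#'
#' @param mesh A vertex mesh.
#' @return Numeric vector, one entry per cell.
#' @export
cell_areas <- function(mesh) {
  ch <- mesh_cache(mesh)
  x <- mesh$pos[, 1L]; y <- mesh$pos[, 2L]
  cr <- x[ch$v] * y[ch$vn] - x[ch$vn] * y[ch$v]
  rowsum_into(cr, ch$cid, length(mesh$cells)) / 2
}

#' @rdname cell_areas
#' @export
cell_perimeters <- function(mesh) {
  ch <- mesh_cache(mesh)
  x <- mesh$pos[, 1L]; y <- mesh$pos[, 2L]
  el <- sqrt((x[ch$vn] - x[ch$v])^2 + (y[ch$vn] - y[ch$v])^2)
  rowsum_into(el, ch$cid, length(mesh$cells))
}

cell_centroid <- function(mesh, ci) {
  cyc <- mesh$cells[[ci]]
  p <- mesh$pos[cyc, , drop = FALSE]
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

# interior-edge adjacency: matrix with one row per interior edge (c1, c2)
cell_adjacency <- function(mesh) {
  ch <- mesh_cache(mesh)
  keep <- ch$edge_c2 > 0L
  cbind(ch$edge_c1[keep], ch$edge_c2[keep])
}

#' Fraction of edge-adjacent neighbours in G2 phase
#'
#' The local G2 death-signal fraction of the vertex-based model: the
#' proportion of a cell's edge-sharing neighbours currently in G2 phase,
#' or 0 when the cell has no neighbours. Dying (apoptotic) cells are
#' excluded from both numerator and denominator: they no longer progress
#' through the cycle and are being extruded.
#'
#' @param mesh A vertex mesh with cycle state (as produced by
#'   [run_vertex()] / [init_tissue()] + engine initialisation).
#' @param time Current simulation time (phases derive from cell ages).
#' @return Numeric vector of fractions, one per cell.
#' @export
local_g2_fraction <- function(mesh, time) {
  nc <- length(mesh$cells)
  adj <- cell_adjacency(mesh)
  age <- time - mesh$birth
  in_g2 <- !mesh$dying & age >= mesh$tstar
  ok <- !mesh$dying
  num <- numeric(nc); den <- numeric(nc)
  # accumulate over both directions of each interior edge
  for (k in 1:2) {
    from <- adj[, k]; to <- adj[, 3L - k]
    w_ok <- as.numeric(ok[to])
    den <- den + rowsum_into(w_ok, from, nc)
    num <- num + rowsum_into(w_ok * in_g2[to], from, nc)
  }
  ifelse(den > 0, num / den, 0)
}

#' Build an initial hexagonal tissue
#'
#' Constructs a rectangular patch of regular hexagonal cells (area
#' `hex_area` each) and assigns cell types: `"homotypic"` makes every cell
#' type A; `"random"` splits the population equally and places the two
#' types uniformly at random; `"segregated"` assigns two contiguous
#' half-tissues (left half A, right half B, split by column).
#'
#' Type assignment for `"random"` uses the current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n_cells Number of cells; factorised into the most square
#'   rows-by-columns patch (36 gives 6x6).
#' @param arrangement `"homotypic"`, `"random"` or `"segregated"`.
#' @param hex_area Initial area of each hexagon.
#' @return A `vertex_mesh` with types assigned and cycle state unset.
#' @export
#' @examples
#' mesh <- init_tissue(36, "homotypic")
#' n_cells(mesh)
init_tissue <- function(n_cells = 36L,
                        arrangement = c("homotypic", "random", "segregated"),
                        hex_area = 1) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_cells >= 1L, hex_area > 0)
  R <- floor(sqrt(n_cells))
  while (R > 1L && n_cells %% R != 0L) R <- R - 1L
  C <- n_cells %/% R
  a <- sqrt(2 * hex_area / (3 * sqrt(3)))
  vert_key <- character(0)
  pos <- matrix(0, 0L, 2L)
  cells <- vector("list", n_cells)
  ang <- pi / 6 + (0:5) * pi / 3
  ci <- 0L
  vkey_env <- new.env(parent = emptyenv())
  get_vertex <- function(x, y) {
    key <- paste(round(x * 1e6), round(y * 1e6))
    hit <- vkey_env[[key]]
    if (!is.null(hit)) return(hit)
    pos <<- rbind(pos, c(x, y))
    vkey_env[[key]] <- nrow(pos)
    nrow(pos)
  }
  col_of <- integer(n_cells)
  for (r in 0:(R - 1L)) {
    for (cc in 0:(C - 1L)) {
      ci <- ci + 1L
      cx <- sqrt(3) * a * (cc + 0.5 * (r %% 2))
      cy <- 1.5 * a * r
      cyc <- vapply(seq_along(ang), function(k) {
        get_vertex(cx + a * cos(ang[k]), cy + a * sin(ang[k]))
      }, 0L)
      cells[[ci]] <- cyc
      col_of[ci] <- cc
    }
  }
  type <- rep(1L, n_cells)
  if (arrangement == "random") {
    if (n_cells %% 2L != 0L) {
      stop("random arrangement needs an even cell count")
    }
    type[sample.int(n_cells, n_cells %/% 2L)] <- 2L
  } else if (arrangement == "segregated") {
    type[col_of >= C / 2] <- 2L
  }
  new_vertex_mesh(pos, cells, type)
}

# deep copy (meshes are environments)
#' Copy a vertex mesh
#' @param mesh A vertex mesh.
#' @return An independent copy.
#' @export
mesh_copy <- function(mesh) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(mesh, all.names = TRUE)) assign(nm, get(nm, mesh), out)
  class(out) <- "vertex_mesh"
  out
}

#' Export mesh geometry as a plain list (for snapshots / JSON)
#'
#' @param mesh A vertex mesh.
#' @return List with `vertices` (matrix) and `cells` (list of index
#'   vectors), `type` labels and cycle state.
#' @export
mesh_snapshot <- function(mesh) {
  list(vertices = mesh$pos, cells = mesh$cells,
       type = mesh$labels[mesh$type], cell_id = mesh$cell_id,
       dying = mesh$dying, areas = cell_areas(mesh))
}
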