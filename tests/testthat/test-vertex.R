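# Vertex-based epithelium: tissue construction, mechanics, rearrangements,
# division and the death-clock extension.

mp_default <- vertex_params()

test_that("initial tissues have the requested composition", {
  mesh <- init_tissue(36, "homotypic")
  expect_identical(n_cells(mesh), 36L)
  expect_true(all(mesh$type == 1L))
  # all cells hexagonal with unit area
  expect_equal(cell_areas(mesh), rep(1, 36), tolerance = 1e-9)

  set.seed(1)
  rnd <- init_tissue(36, "random")
  expect_identical(sum(rnd$type == 1L), 18L)
  expect_identical(sum(rnd$type == 2L), 18L)

  seg <- init_tissue(36, "segregated")
  expect_identical(sum(seg$type == 1L), 18L)
  # segregated: heterotypic contact confined to one interface, far fewer
  # heterotypic neighbour pairs than under random mixing
  adj <- deathclock:::cell_adjacency(seg)
  het <- sum(seg$type[adj[, 1L]] != seg$type[adj[, 2L]])
  adj_r <- deathclock:::cell_adjacency(rnd)
  het_r <- sum(rnd$type[adj_r[, 1L]] != rnd$type[adj_r[, 2L]])
  expect_gt(het, 0L)
  expect_lt(het, het_r / 2)
  # homotypic: no heterotypic edges at all
  hom_adj <- deathclock:::cell_adjacency(mesh)
  expect_identical(sum(mesh$type[hom_adj[, 1L]] != mesh$type[hom_adj[, 2L]]),
                   0L)
})

test_that("tissue energy matches a symbolic evaluation", {
  # single regular hexagon, side 1: S = 3 sqrt(3) / 2, L = 6, all edges
  # are boundary edges
  ang <- pi / 6 + (0:5) * pi / 3
  mesh <- deathclock:::new_vertex_mesh(cbind(cos(ang), sin(ang)),
                                       list(1:6), 1L)
  mesh$S0 <- 1
  E <- energy(mesh, vertex_params(K = 1, S0 = 1, Gamma = 0.04,
                                  lambda_AA = 0.12))
  expect_equal(E, 0.5 * (3 * sqrt(3) / 2 - 1)^2 + 0.02 * 36 + 0.12 * 6)
  # relaxed configuration with no contractility or tension has zero energy
  mesh$S0 <- 3 * sqrt(3) / 2
  expect_equal(energy(mesh, vertex_params(K = 1, S0 = 3 * sqrt(3) / 2,
                                          Gamma = 0, lambda_AA = 0,
                                          lambda_bdy_A = 0)), 0)
})

test_that("heterotypic edges use the A-B line tension", {
  mesh <- init_tissue(4, "segregated")   # 2 x 2 patch, split into A | B
  mesh$S0 <- rep(1, 4)
  base <- vertex_params(lambda_AA = 0.1, lambda_AB = 0.1, lambda_BB = 0.1,
                        lambda_bdy_A = 0, lambda_bdy_B = 0)
  bump <- vertex_params(lambda_AA = 0.1, lambda_AB = 0.3, lambda_BB = 0.1,
                        lambda_bdy_A = 0, lambda_bdy_B = 0)
  ch <- deathclock:::mesh_cache(mesh)
  interior <- ch$edge_c2 > 0L
  het <- interior & mesh$type[ch$edge_c1] != mesh$type[pmax(ch$edge_c2, 1L)]
  x <- mesh$pos[, 1L]; y <- mesh$pos[, 2L]
  het_len <- sum(sqrt((x[ch$edge_a] - x[ch$edge_b])^2 +
                      (y[ch$edge_a] - y[ch$edge_b])^2)[het])
  expect_gt(het_len, 0)
  expect_equal(energy(mesh, bump) - energy(mesh, base), 0.2 * het_len)
})

test_that("analytic forces match central finite differences", {
  set.seed(1)
  mesh <- init_tissue(9, "homotypic")
  mesh$S0 <- rep(1, 9)
  mesh$pos <- mesh$pos + matrix(rnorm(length(mesh$pos), 0, 0.05), ncol = 2)
  F <- vertex_forces(mesh, mp_default)
  h <- 1e-6
  maxrel <- 0
  for (vi in seq_len(nrow(mesh$pos))) {
    for (d in 1:2) {
      m2 <- mesh_copy(mesh); m2$pos[vi, d] <- m2$pos[vi, d] + h
      m3 <- mesh_copy(mesh); m3$pos[vi, d] <- m3$pos[vi, d] - h
      fd <- -(energy(m2, mp_default) - energy(m3, mp_default)) / (2 * h)
      maxrel <- max(maxrel, abs(F[vi, d] - fd) / max(abs(fd), 1))
    }
  }
  expect_lt(maxrel, 1e-6)
})

test_that("pure line tension pulls along incident edge directions", {
  ang <- pi / 6 + (0:5) * pi / 3
  mesh <- deathclock:::new_vertex_mesh(cbind(cos(ang), sin(ang)),
                                       list(1:6), 1L)
  mesh$S0 <- 3 * sqrt(3) / 2
  lam <- 0.25
  par <- vertex_params(K = 0, S0 = 3 * sqrt(3) / 2, Gamma = 0,
                       lambda_AA = lam, lambda_bdy_A = lam)
  F <- vertex_forces(mesh, par)
  # hand derivation: force on vertex i is -lambda * sum of unit vectors
  # pointing from each neighbour towards i
  unit_to <- function(from, to) {
    d <- mesh$pos[to, ] - mesh$pos[from, ]
    d / sqrt(sum(d^2))
  }
  for (vi in 1:6) {
    prev <- if (vi == 1) 6 else vi - 1
    nxt <- if (vi == 6) 1 else vi + 1
    expected <- -lam * (unit_to(prev, vi) + unit_to(nxt, vi))
    expect_equal(F[vi, ], expected, tolerance = 1e-12)
  }
})

test_that("relaxation of a perturbed lattice descends the energy", {
  set.seed(2)
  mesh <- init_tissue(16, "homotypic")
  mesh$pos <- mesh$pos + matrix(rnorm(length(mesh$pos), 0, 0.08), ncol = 2)
  E <- relax_mesh(mesh, mp_default, steps = 150)
  expect_true(all(diff(E) <= 1e-8))
  expect_lt(E[length(E)], E[1L])
})

test_that("division conserves area, adds one cell and inherits the type", {
  set.seed(3)
  mesh <- init_tissue(9, "homotypic")
  mesh$S0 <- rep(1, 9)
  mesh$type[5L] <- 2L
  A0 <- cell_areas(mesh)[5L]
  n0 <- n_cells(mesh)
  newci <- divide_cell(mesh, 5L, angle = 0.7)
  expect_false(is.na(newci))
  expect_identical(n_cells(mesh), n0 + 1L)
  A <- cell_areas(mesh)
  expect_equal(A[5L] + A[newci], A0, tolerance = 1e-12)
  expect_identical(mesh$type[newci], 2L)
  # mesh stays conforming: cache rebuild succeeds and areas are positive
  expect_true(all(cell_areas(mesh) > 0))
})

test_that("a shrinking edge triggers a T1 swap that exchanges neighbours", {
  mesh <- init_tissue(9, "homotypic")
  mesh$S0 <- rep(1, 9)
  ch <- deathclock:::mesh_cache(mesh)
  # find an interior edge whose endpoints both touch three cells
  cand <- which(ch$edge_c2 > 0L)
  pick <- NA
  for (e in cand) {
    ci <- deathclock:::cells_with_vertex(mesh, ch$edge_a[e])
    cj <- deathclock:::cells_with_vertex(mesh, ch$edge_b[e])
    if (length(ci) == 3L && length(cj) == 3L) { pick <- e; break }
  }
  expect_false(is.na(pick))
  i <- ch$edge_a[pick]; j <- ch$edge_b[pick]
  m <- (mesh$pos[i, ] + mesh$pos[j, ]) / 2
  mesh$pos[i, ] <- m + 0.01 * (mesh$pos[i, ] - m)
  mesh$pos[j, ] <- m + 0.01 * (mesh$pos[j, ] - m)
  before <- nrow(deathclock:::cell_adjacency(mesh))
  ok <- deathclock:::do_t1(mesh, mp_default, i, j)
  expect_true(ok)
  # mesh remains valid and the edge is now longer than the threshold
  ch2 <- deathclock:::mesh_cache(mesh)
  len <- sqrt(sum((mesh$pos[i, ] - mesh$pos[j, ])^2))
  expect_equal(len, 1.05 * mp_default$t1_threshold, tolerance = 1e-12)
  expect_true(all(cell_areas(mesh) > 0))
})

test_that("a tiny cell is extruded by a T2 swap", {
  mesh <- init_tissue(9, "homotypic")
  mesh$S0 <- rep(1, 9)
  ctr <- deathclock:::cell_centroid(mesh, 5L)
  cyc <- mesh$cells[[5L]]
  mesh$pos[cyc, ] <- sweep(0.05 * sweep(mesh$pos[cyc, ], 2, ctr), 2, ctr,
                           FUN = "+")
  ev <- advance_mesh(mesh, mp_default, dt = 1e-9)
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_true("t2swap" %in% kinds)
  expect_identical(n_cells(mesh), 8L)
  expect_true(all(cell_areas(mesh) > 0))
})

test_that("apoptosis shrinks the target area until extrusion", {
  mesh <- init_tissue(9, "homotypic")
  mesh$S0 <- rep(1, 9)
  mesh$tstar <- rep(1e9, 9)   # park the cycle
  trigger_apoptosis(mesh, 5L)
  expect_true(mesh$dying[5L])
  expect_identical(mesh$S0[5L], 0)
  areas <- numeric()
  for (s in 1:2000) {
    advance_mesh(mesh, mp_default)
    if (n_cells(mesh) < 9L) break
    areas <- c(areas, cell_areas(mesh)[5L])
  }
  expect_lt(n_cells(mesh), 9L)          # eventually extruded
  expect_lt(min(areas), 0.2)            # shrank substantially first
  # dying cells are excluded from the G2 signal of their neighbours
  mesh2 <- init_tissue(4, "homotypic")
  mesh2$tstar <- c(1e9, 0, 1e9, 1e9)    # only cell 2 is in G2
  mesh2$S0 <- rep(1, 4)
  g_before <- local_g2_fraction(mesh2, time = 1)
  expect_true(any(g_before[-2L] > 0))   # neighbours feel its signal
  trigger_apoptosis(mesh2, 2L)
  g_after <- local_g2_fraction(mesh2, time = 1)
  expect_true(all(g_after[-2L] == 0))   # dropped from the signal entirely
})

test_that("the vertex engine runs a death-clock tissue reproducibly", {
  p <- dp(0.5, 0.3, t_G = 30)
  cfg <- vertex_config(list(A = p), vertex_params(), n_cells = 9L,
                       arrangement = "homotypic", end_time = 30, seed = 5,
                       init = "staggered")
  l1 <- run_vertex(cfg)
  l2 <- run_vertex(cfg)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  ndiv <- sum(l1$event == "division")
  ndeath <- sum(l1$event == "death")
  meta <- attr(l1, "meta")
  expect_identical(ndiv - ndeath, meta$n_final - meta$n_initial)
  expect_gt(ndiv + ndeath, 0L)
})
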