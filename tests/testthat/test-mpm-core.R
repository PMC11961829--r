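# Solver core: kernel weights, particle-grid transfers, grid update,
# frame finalization and the assembled frame loop.

test_that("quadratic B-spline weights have the kernel identities", {
  dx <- 0.005
  # particle exactly on a node: per-axis weights (1/8, 3/4, 1/8)
  w <- kernel_weights(c(2 * dx, 3 * dx), dx)
  expect_equal(w$axis_weights[1, ], c(0.125, 0.75, 0.125))
  expect_equal(w$axis_weights[2, ], c(0.125, 0.75, 0.125))
  set.seed(5)
  for (i in 1:50) {
    x <- runif(2, 0.01, 0.05)
    w <- kernel_weights(x, dx)
    # partition of unity and zero first moment
    expect_lt(abs(sum(w$weights) - 1), 1e-12)
    m1 <- colSums(w$weights * sweep(w$positions, 2L, x))
    expect_lt(max(abs(m1)), 1e-12)
  }
  # mirror symmetry: reflecting the offset about a node reverses the weights
  node <- 4 * dx
  delta <- 0.3 * dx
  wp <- kernel_weights(c(node + delta, node), dx)
  wm <- kernel_weights(c(node - delta, node), dx)
  expect_equal(wp$axis_weights[1, ], rev(wm$axis_weights[1, ]), tolerance = 1e-12)
})

test_that("p2g conserves mass exactly and momentum to rounding", {
  st <- tiny_slab_state(all_free = TRUE)
  st$p$v[, 1] <- 0.1 * st$p$x[, 2]   # some nontrivial velocity field
  st$p$v[, 2] <- -0.05
  st <- p2g(st)
  expect_equal(sum(st$grid$mass), sum(st$p$m), tolerance = 1e-12)
  # total grid momentum equals total particle momentum: the affine and
  # stress terms annihilate under the zero-first-moment kernel identity
  expect_equal(colSums(st$grid$mom), colSums(st$p$v * st$p$m),
               tolerance = 1e-10)
})

test_that("a resting particle scatters mass but no momentum", {
  st <- tiny_slab_state(all_free = TRUE)
  keep <- 40L  # one interior particle
  for (f in c("x", "v", "C", "F", "vpre", "rel", "dv", "P")) {
    st$p[[f]] <- st$p[[f]][keep, , drop = FALSE]
  }
  for (f in c("Jp", "J", "Je", "m", "V0")) st$p[[f]] <- st$p[[f]][keep]
  st$p$status <- st$p$status[keep]
  st$p$n <- 1L
  st <- p2g(st)
  expect_equal(sum(st$grid$mass), st$p$m)
  expect_equal(max(abs(st$grid$mom)), 0)
})

test_that("grid update divides momentum by mass and applies slip BC", {
  st <- tiny_slab_state(all_free = TRUE)
  st$p$v[, 1] <- 0.2
  st <- p2g(st)
  st <- grid_update(st)
  act <- which(st$grid$active)
  expect_equal(st$grid$vel[act, ],
               st$grid$mom[act, ] / st$grid$mass[act])
  # slip boundary: inward components zeroed, tangential kept
  cfg <- st$cfg
  g <- st$grid
  g$mass[] <- 0
  g$mom[] <- 0
  low_node <- which(g$coords[, 1] == 1L & g$coords[, 2] == 8L)  # in lower-x margin
  g$mass[low_node] <- 1
  g$mom[low_node, ] <- c(-0.3, 0.4)   # moving into the face, plus tangential
  st$grid <- g
  st <- grid_update(st)
  expect_equal(st$grid$vel[low_node, ], c(0, 0.4))
  # moving away from the face is untouched
  st$grid$mom[low_node, ] <- c(0.3, 0.4)
  st <- grid_update(st)
  expect_equal(st$grid$vel[low_node, ], c(0.3, 0.4))
})

test_that("g2p reproduces uniform and linear grid velocity fields", {
  st <- tiny_slab_state(all_free = TRUE)
  st <- p2g(st)
  st <- grid_update(st)
  N <- prod(st$cfg$nn)
  # uniform field: v~ = u, C = 0
  u <- c(0.3, -0.2)
  st$grid$vel <- matrix(u, N, 2, byrow = TRUE)
  gp <- g2p(st)
  expect_equal(gp$v_tilde, matrix(u, st$p$n, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_lt(max(abs(gp$state$p$C)), 1e-9)
  # linear field v = A x: recovered affine matrix equals A
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  pos <- st$grid$coords * st$cfg$dx
  st$grid$vel <- pos %*% t(A)
  gp <- g2p(st)
  C <- gp$state$p$C
  for (r in 1:2) for (c in 1:2) {
    expect_equal(C[, (c - 1) * 2 + r], rep(A[r, c], st$p$n),
                 tolerance = 1e-6)
  }
  # all grid velocities zero: positions do not move
  st$grid$vel <- matrix(0, N, 2)
  gp <- g2p(st)
  expect_identical(gp$x_tilde, st$p$x)
})

test_that("finalize_frame reproduces a brute-force scatter of dv", {
  st <- tiny_slab_state(all_free = TRUE)
  st <- p2g(st)
  st <- grid_update(st)
  gp <- g2p(st)
  n <- st$p$n
  # no collisions: dv is identically zero and so is the grid increment field
  st0 <- finalize_frame(gp$state, gp$x_tilde, gp$v_tilde)
  expect_identical(st0$p$dv, matrix(0, n, 2))
  expect_identical(st0$grid$dv, matrix(0, prod(st0$cfg$nn), 2))

  # synthetic displacements on a few particles, against a double-loop oracle
  set.seed(9)
  altered <- rep(FALSE, n)
  altered[sample(n, 12)] <- TRUE
  x_new <- gp$x_tilde
  x_new[altered, ] <- x_new[altered, ] + 1e-4 * matrix(runif(24), 12, 2)
  st1 <- finalize_frame(gp$state, x_new, gp$v_tilde, altered)
  # single displaced particle velocity follows (x^{n+1} - x^n) / dt
  i <- which(altered)[1]
  expect_equal(st1$p$v[i, ],
               (x_new[i, ] - gp$state$p$x[i, ]) / st1$cfg$dt)
  # oracle: explicit loop over particles and their 9 stencil nodes
  oracle <- matrix(0, prod(st1$cfg$nn), 2)
  dt <- st1$cfg$dt; dx <- st1$cfg$dx; nn <- st1$cfg$nn
  for (ip in which(altered)) {
    xp <- gp$state$p$x[ip, ]
    dvp <- (x_new[ip, ] - xp) / dt - gp$v_tilde[ip, ]
    kw <- kernel_weights(xp, dx)
    for (o in seq_len(nrow(kw$offsets))) {
      id <- kw$offsets[o, 1] + 1L + nn[1] * kw$offsets[o, 2]
      oracle[id, ] <- oracle[id, ] + kw$weights[o] * st1$p$m[ip] * dvp
    }
  }
  nz <- st1$grid$mass > 0
  oracle[nz, ] <- oracle[nz, ] / st1$grid$mass[nz]
  oracle[!nz, ] <- 0
  expect_equal(st1$grid$dv, oracle, tolerance = 1e-12)
})

test_that("a resting slab stays exactly at rest over 100 frames", {
  st <- tiny_slab_state(all_free = TRUE)
  x0 <- st$p$x
  for (k in 1:100) {
    out <- advance_frame(st)
    st <- out$state
    expect_identical(out$force, c(0, 0))
  }
  expect_lt(max(abs(st$p$x - x0)), 1e-8)
  expect_lt(max(abs(st$p$F - pm_identity_pub(st$p$n))), 1e-8)
})

test_that("a uniformly translating slab stays stress-free", {
  st <- tiny_slab_state(all_free = TRUE)
  u <- 0.4
  st$p$v[, 1] <- u
  com0 <- colMeans(st$p$x)
  for (k in 1:100) st <- advance_frame(st)$state
  expect_equal(colMeans(st$p$x) - com0, c(u * 100 * st$cfg$dt, 0),
               tolerance = 1e-10)
  expect_lt(max(abs(st$p$F - pm_identity_pub(st$p$n))), 1e-8)
  expect_lt(max(abs(st$p$P)), 1e-6)
})

test_that("the frame loop is deterministic and mirror-symmetric", {
  run_once <- function(flip = FALSE) {
    cfg <- tiny_cfg(nn = c(64, 64))
    spec <- specimen_spec(extents = c(0.05, 0.01), particles_per_cell = 4)
    p <- make_slab(spec, cfg, seed = 2L)
    st <- mpm_state(p, cfg, material_params())
    st$p$status[] <- 0L
    mid <- (cfg$nn[2] - 1) * cfg$dx / 2
    if (flip) st$p$x[, 2] <- 2 * mid - st$p$x[, 2]
    st$p$v[, 2] <- if (flip) -0.1 else 0.1
    forces <- matrix(0, 20, 2)
    for (k in 1:20) {
      out <- advance_frame(st)
      st <- out$state
      forces[k, ] <- out$force
    }
    list(st = st, forces = forces, mid = mid)
  }
  a <- run_once(FALSE)
  b <- run_once(FALSE)
  # bit-identical trajectories for identical inputs
  expect_identical(a$st$p$x, b$st$p$x)
  expect_identical(a$st$p$F, b$st$p$F)
  # mirrored scene gives mirrored state
  m <- run_once(TRUE)
  expect_equal(m$st$p$x[, 1], a$st$p$x[, 1], tolerance = 1e-10)
  expect_equal(m$st$p$x[, 2], 2 * a$mid - a$st$p$x[, 2], tolerance = 1e-10)
})

test_that("particles leaving the domain raise a frame-tagged error", {
  st <- tiny_slab_state(all_free = TRUE)
  st$p$x[1, 1] <- 1e6
  expect_error(advance_frame(st), "frame 0.*domain")
})

test_that("the solver also runs in three dimensions", {
  cfg <- sim_config(d = 3, nn = c(32, 12, 12), dx = 0.004)
  spec <- specimen_spec(extents = c(0.04, 0.012, 0.012),
                        particles_per_cell = 8)
  p <- make_slab(spec, cfg)
  p$status[] <- 0L
  st <- mpm_state(p, cfg, material_params())
  expect_equal(sum(p$m), spec$density * prod(spec$extents), tolerance = 1e-10)
  x0 <- st$p$x
  for (k in 1:20) st <- advance_frame(st)$state
  expect_lt(max(abs(st$p$x - x0)), 1e-10)
  st$p$v[, 2] <- 0.2
  for (k in 1:20) st <- advance_frame(st)$state
  expect_lt(max(abs(st$p$F - pm_identity_pub(st$p$n, 3L))), 1e-8)
  st <- p2g(st)
  expect_equal(sum(st$grid$mass), sum(st$p$m), tolerance = 1e-12)
})
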