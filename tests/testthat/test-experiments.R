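# Specimen generation and the three characterization experiments, run on
# small slabs so the default suite stays fast; the full-size protocols run
# in test-acceptance.R.

test_that("slab sampling is a deterministic lattice with exact mass", {
  cfg <- tiny_cfg()
  spec <- specimen_spec(extents = c(0.05, 0.01), particles_per_cell = 4)
  p <- make_slab(spec, cfg, seed = 3L)
  # jitter = 0: regular lattice with spacing dx / sqrt(ppc)
  xs <- sort(unique(p$x[, 1]))
  expect_equal(diff(xs), rep(0.001, length(xs) - 1), tolerance = 1e-12)
  # total mass is the closed-form slab mass
  expect_equal(sum(p$m), spec$density * 0.05 * 0.01, tolerance = 1e-10)
  expect_equal(sum(p$V0), 0.05 * 0.01, tolerance = 1e-10)
  # determinism, with and without jitter
  p2 <- make_slab(spec, cfg, seed = 3L)
  expect_identical(p$x, p2$x)
  specj <- specimen_spec(extents = c(0.05, 0.01), particles_per_cell = 4,
                         jitter = 0.3)
  j1 <- make_slab(specj, cfg, seed = 3L)
  j2 <- make_slab(specj, cfg, seed = 3L)
  expect_identical(j1$x, j2$x)
  expect_false(identical(j1$x, p$x))
  # rest state and bands
  expect_true(all(j1$Jp == 1))
  expect_gt(sum(p$status == 1L), 0)
  expect_gt(length(attr(p, "load_idx")), 0)
  # a slab too large for the domain is refused
  expect_error(make_slab(specimen_spec(extents = c(10, 0.01)), cfg), "fit")
})

test_that("single-element stateful recursion decays geometrically", {
  # hold a homogeneous element at constant stretch beyond the extension
  # limit; the elastic volume excess must decay with ratio (1 - k_s) per
  # frame (closed form), and the plastic volume ratio must ratchet so that
  # J_E * J_P = J at every step
  params <- material_params(k_s = 0.05)
  F <- sqrt(1.3) * diag(2)      # J = 1.3, beyond 1 + theta_s = 1.1
  Jp <- 1
  excess <- numeric(60)
  for (k in 1:60) {
    s <- split_deformation(F, Jp, params)
    Jp <- s$J_P
    excess[k] <- s$J_E - 1.1
  }
  excess0 <- (1.3 - 1.1) * (1 - params$k_s)   # after the first application
  analytic <- excess0 * (1 - params$k_s)^(0:59)
  expect_equal(excess, analytic, tolerance = 1e-6)
  # stress follows the decay monotonically
  stresses <- numeric(30)
  Jp <- 1
  for (k in 1:30) {
    s <- split_deformation(F, Jp, params)
    Jp <- s$J_P
    stresses[k] <- pk_stress(s, params)[1, 1]
  }
  expect_true(all(diff(stresses) < 0))

  # stateless mode: no memory, no decay
  ps <- material_params(k_s = 0.05, plasticity_mode = "stateless")
  s1 <- split_deformation(F, 1, ps)
  s2 <- split_deformation(F, s1$J_P, ps)
  expect_identical(s1$J_E, s2$J_E)

  # faster viscosity constant = faster plastic accumulation (creep rate)
  accumulate <- function(k_s) {
    p <- material_params(k_s = k_s)
    Jp <- 1
    for (k in 1:20) Jp <- split_deformation(F, Jp, p)$J_P
    Jp
  }
  expect_gt(accumulate(0.1), accumulate(0.05))
})

test_that("relaxation run holds strain and relaxes stress (stateful only)", {
  cfg <- tiny_cfg(nn = c(96, 16))
  spec <- specimen_spec(extents = c(0.06, 0.01), particles_per_cell = 4)
  cur <- run_relaxation(spec, cfg, material_params(), target_strain = 0.11,
                        hold_duration = 0.06, record_every = 20L)
  hs <- attr(cur, "hold_start")
  hold <- cur[cur$time > hs + 1e-12, ]
  expect_gt(nrow(hold), 10)
  expect_lt(diff(range(hold$strain)), 1e-6)
  expect_true(all(diff(hold$stress) <= 1e-8 * max(abs(hold$stress))))
  expect_lt(tail(hold$stress, 1), hold$stress[1])

  # a hold inside the elastic range relaxes nothing
  cur_el <- run_relaxation(spec, cfg, material_params(), target_strain = 0.03,
                           hold_duration = 0.02, record_every = 20L)
  hse <- attr(cur_el, "hold_start")
  he <- cur_el[cur_el$time > hse + 1e-12, ]
  expect_equal(tail(he$stress, 1), he$stress[1], tolerance = 1e-10)

  # stateless material: no decay during the hold either
  cur_sl <- run_relaxation(spec, cfg,
                           material_params(plasticity_mode = "stateless"),
                           target_strain = 0.11, hold_duration = 0.02,
                           record_every = 20L)
  hss <- attr(cur_sl, "hold_start")
  hsl <- cur_sl[cur_sl$time > hss + 1e-12, ]
  expect_equal(tail(hsl$stress, 1), hsl$stress[1], tolerance = 1e-10)
})

test_that("creep strain grows monotonically with a decreasing rate", {
  cfg <- tiny_cfg(nn = c(96, 16))
  spec <- specimen_spec(extents = c(0.06, 0.01), particles_per_cell = 4)
  cur <- run_creep(spec, cfg, material_params(), applied_stress = 500,
                   duration = 0.2, record_every = 20L)
  n <- nrow(cur)
  tr <- n %/% 8
  expect_true(all(diff(cur$strain[tr:n]) > -1e-4))
  q <- n %/% 4
  rate_first <- (cur$strain[q] - cur$strain[1]) / (cur$time[q] - cur$time[1])
  rate_last <- (cur$strain[n] - cur$strain[n - q]) /
    (cur$time[n] - cur$time[n - q])
  expect_lt(rate_last, rate_first)

  # zero load: nothing moves at all
  cur0 <- run_creep(spec, cfg, material_params(), applied_stress = 0,
                    duration = 0.02, record_every = 20L)
  expect_lt(max(abs(cur0$strain)), 1e-8)
  expect_lt(max(abs(cur0$stress)), 1e-8)
})

test_that("zero pull rate leaves the tear specimen unstressed", {
  cfg <- tiny_cfg(nn = c(96, 16))
  spec <- specimen_spec(extents = c(0.06, 0.01), particles_per_cell = 4)
  cur <- run_tear(spec, cfg, material_params(), pull_rate = 0,
                  duration = 0.02, record_every = 20L)
  expect_lt(max(abs(cur$stress)), 1e-8)
  expect_lt(max(abs(cur$strain)), 1e-8)
})

test_that("stage segmentation recovers constructed breakpoints", {
  # purely linear curve: a single elastic stage
  lin <- data.frame(strain = seq(0, 1, 0.01), stress = 3 * seq(0, 1, 0.01))
  seg <- segment_stages(lin, smooth = 1L)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$label, "elastic")

  # piecewise linear -> flat -> drop with known corners at 0.40, 0.70, ~0.79
  strain <- seq(0, 1, 0.01)
  stress <- ifelse(strain <= 0.4, 3 * strain,
                   ifelse(strain <= 0.7, 1.2,
                          pmax(1.2 - 11.8 * (strain - 0.7), 0.02)))
  seg2 <- segment_stages(data.frame(strain = strain, stress = stress),
                         smooth = 1L)
  expect_equal(nrow(seg2), 4L)
  expect_equal(seg2$label, c("elastic", "plastic", "tearing", "broken"))
  bp <- attr(seg2, "breakpoints")
  expect_lt(abs(bp[1] - 0.40), 0.021)   # within 2 samples
  expect_lt(abs(bp[2] - 0.70), 0.021)
  expect_lt(abs(bp[3] - 0.791), 0.021)  # stress crosses 10% of peak at 0.7915

  # degenerate inputs are refused with a clear message
  expect_error(segment_stages(lin[1:10, ]), "too short")
  expect_error(segment_stages(data.frame(strain = 1:30)), "columns")
})

test_that("experiment curves enforce their invariants", {
  expect_error(npsim:::experiment_curve(c(0, 1, 1), 1:3, 1:3, 1:3, "tear"),
               "increasing")
  cur <- npsim:::experiment_curve(1:3, c(0, 0.1, 0.2), c(0, 5, 10), 0:2, "tear")
  expect_s3_class(cur, "experiment_curve")
  expect_identical(attr(cur, "experiment"), "tear")
})
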