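test_that("movement is exact for a constant force on a free vertex", {
  # no membrane forces: RK4 on a constant field gives zeta * f * dt exactly
  p <- spine_params(P = 0, tau = 0, kappa = 0)
  m <- as_spine_mesh(rbind(c(0, 0), c(1, 0), c(0.5, 0.8)),
                     fixed = c(TRUE, TRUE, FALSE))
  f <- rbind(c(0, 0), c(0, 0), c(0.3, -0.2))
  m2 <- move_membrane(m, f, p)
  expect_equal(unname(m2$positions[3, ] - m$positions[3, ]),
               p$zeta * f[3, ] * p$dt, tolerance = 1e-10)
  expect_identical(m2$positions[1:2, ], m$positions[1:2, ])
  expect_identical(move_membrane(m, f * 0, p)$positions, m$positions)
})

test_that("fixed vertices never move, whatever the load", {
  p <- spine_params()
  m <- init_spine_mesh(p)
  f <- matrix(50, nrow(m$positions), 2)
  m2 <- move_membrane(m, f, p)
  expect_identical(m2$positions[m$fixed, ], m$positions[m$fixed, ])
  expect_false(identical(m2$positions[!m$fixed, ], m$positions[!m$fixed, ]))
})

test_that("a zero-duration run contains only the initial record", {
  p <- spine_params()
  rest <- default_rest()
  tr <- run_simulation(p, 0, seed = 31, mesh = rest$mesh, A_s = rest$A_s)
  expect_length(tr$area, 1)
  expect_gt(tr$area[1], 0)
  expect_equal(tr$n_f[1], p$n_f0)
})

test_that("seeded runs are bitwise reproducible", {
  p <- spine_params()
  rest <- default_rest()
  tr1 <- run_simulation(p, 15, seed = 32, mesh = rest$mesh, A_s = rest$A_s)
  tr2 <- run_simulation(p, 15, seed = 32, mesh = rest$mesh, A_s = rest$A_s)
  expect_identical(tr1$area, tr2$area)
  expect_identical(tr1$n_f, tr2$n_f)
  expect_identical(tr1$final_state$mesh$positions,
                   tr2$final_state$mesh$positions)
  tr3 <- run_simulation(p, 15, seed = 33, mesh = rest$mesh, A_s = rest$A_s)
  expect_false(identical(tr1$area, tr3$area))
})

test_that("without foci or nucleation the area stays at the resting value", {
  p <- spine_params(gamma_f = 0, n_f0 = 0L)
  rest <- default_rest()
  tr <- run_simulation(p, 30, seed = 34, mesh = rest$mesh, A_s = rest$A_s)
  expect_equal(tr$n_f, rep(0L, length(tr$n_f)))
  expect_lt(max(abs(tr$area - rest$A_s)), 0.01)
})

test_that("trace bookkeeping: record count, snapshots, lifetime log", {
  p <- spine_params()
  rest <- default_rest()
  tr <- run_simulation(p, 30, seed = 35, snapshot_interval = 10,
                       mesh = rest$mesh, A_s = rest$A_s)
  expect_length(tr$area, 30 / p$dt + 1)
  expect_true(all(tr$area > 0))
  expect_equal(names(tr$snapshots), c("0", "10", "20", "30"))
  if (nrow(tr$lifetimes) > 0) {
    expect_equal(tr$lifetimes$lifetime,
                 tr$lifetimes$death - tr$lifetimes$birth)
    expect_true(all(tr$lifetimes$lifetime > 0))
  }
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  rt <- read_trace_csv(path)
  expect_equal(rt$area, tr$area)
  expect_equal(rt$n_f, tr$n_f)
})

test_that("focus centres survive remeshing", {
  p <- spine_params()
  rest <- default_rest()
  set.seed(36)
  foci <- NULL
  for (i in 1:3) foci <- rbind(foci, nucleate_focus(rest$mesh, p, id = i))
  st <- spine_state(rest$mesh, p, foci = foci)
  for (s in 1:40) {
    st <- simulation_step(st)
    if (nrow(st$foci) > 0) {
      expect_true(all(st$foci$center >= 1 &
                        st$foci$center <= nrow(st$mesh$positions)))
    }
  }
  expect_equal(st$t, 5)
})

test_that("a single-value sweep reduces to summarised replicates", {
  p <- spine_params()
  tab <- run_sweep(p, "phi", 75, n_replicates = 2, replicate_duration = 10,
                   seeds = c(41, 42))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$param, c("phi", "phi"))
  expect_true(all(tab$mean_area > 0))
  expect_true(all(is.finite(tab$sd_area)))
})
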