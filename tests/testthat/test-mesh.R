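test_that("initial mesh projects PSD and neck vertices onto the plateaus", {
  p <- spine_params()
  m <- init_spine_mesh(p)
  expect_equal(m$h_PSD, sqrt(0.5^2 - 0.3571^2), tolerance = 1e-12)
  expect_equal(m$h_PSD, 0.34997, tolerance = 1e-4)
  expect_equal(m$h_neck, -sqrt(0.5^2 - 0.0995^2), tolerance = 1e-12)
  expect_equal(m$h_neck, -0.48999, tolerance = 1e-4)
  expect_equal(nrow(m$positions), round(2 * pi * p$r_s / p$delta_s))
  ys <- m$positions[m$fixed, 2]
  expect_true(all(ys == m$h_PSD | ys == m$h_neck))
  free_y <- m$positions[!m$fixed, 2]
  expect_true(all(free_y < m$h_PSD & free_y > m$h_neck))
  expect_gt(compute_geometry(m)$area_enclosed, 0)  # counterclockwise
})

test_that("vanishing PSD and neck radii leave an almost free circle", {
  p <- spine_params(r_PSD = 1e-6, r_neck = 1e-6)
  m <- init_spine_mesh(p)
  expect_lte(sum(m$fixed), 2)
  expect_equal(compute_geometry(m)$area_enclosed, pi * 0.25,
               tolerance = 1e-3)
})

test_that("geometry report matches closed forms", {
  sq <- as_spine_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- compute_geometry(sq)
  expect_equal(g$area_enclosed, 1)
  expect_equal(g$boundary_length, 4)

  g100 <- compute_geometry(regular_polygon_mesh(100, 0.5))
  expect_equal(g100$area_enclosed, (100 / 2) * 0.25 * sin(2 * pi / 100),
               tolerance = 1e-12)

  g1k <- compute_geometry(regular_polygon_mesh(1000, 0.5))
  expect_equal(g1k$curvature, rep(2, 1000), tolerance = 1e-6)
  expect_equal(sum(g1k$ds), g1k$boundary_length, tolerance = 1e-12)
})

test_that("degenerate vertex configurations are handled", {
  # collinear triple: zero curvature at the middle vertex, not an error
  m <- as_spine_mesh(rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(compute_geometry(m)$curvature[2], 0)
  dup <- as_spine_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  dup$positions[2, ] <- dup$positions[1, ]
  expect_error(compute_geometry(dup), "duplicate")
})

test_that("remesh splits long edges at their midpoint", {
  p <- spine_params()
  m <- regular_polygon_mesh(105, 0.5)       # edges ~0.0299, in band
  drop <- m$positions[-7, ]                 # removing a vertex makes a ~0.06 edge
  m2 <- as_spine_mesh(drop)
  r <- remesh(m2, p)
  expect_equal(nrow(r$positions), 105)      # midpoint restored
  mid <- (drop[6, ] + drop[7, ]) / 2
  d <- sqrt(colSums((t(r$positions) - mid)^2))
  expect_lt(min(d), 1e-12)
  g <- compute_geometry(r)
  expect_true(all(g$edge_lengths >= p$d_min & g$edge_lengths <= p$d_max))
})

test_that("remesh collapses short edges by dropping the second free vertex", {
  p <- spine_params()
  m <- regular_polygon_mesh(105, 0.5)
  pos <- m$positions
  extra <- pos[10, ] + 0.01 * (pos[11, ] - pos[10, ]) /
    sqrt(sum((pos[11, ] - pos[10, ])^2))
  m2 <- as_spine_mesh(rbind(pos[1:10, ], extra, pos[11:105, ]))
  r <- remesh(m2, p)
  # the inserted vertex is second in cyclic order on the short edge -> gone
  d <- sqrt(colSums((t(r$positions) - extra)^2))
  expect_gt(min(d), 1e-6)
  g <- compute_geometry(r)
  expect_true(all(g$edge_lengths >= p$d_min & g$edge_lengths <= p$d_max))
})

test_that("remesh leaves in-band meshes untouched and is idempotent", {
  p <- spine_params()
  m <- regular_polygon_mesh(105, 0.5)
  expect_identical(remesh(m, p)$positions, m$positions)

  set.seed(7)
  th <- sort(runif(80, 0, 2 * pi))
  rr <- 0.5 + runif(80, -0.03, 0.03)
  jag <- as_spine_mesh(cbind(rr * cos(th), rr * sin(th)))
  r1 <- remesh(jag, p)
  r2 <- remesh(r1, p)
  expect_identical(r1$positions, r2$positions)
  expect_lt(abs(compute_geometry(r1)$area_enclosed -
                  compute_geometry(jag)$area_enclosed), 1e-3)
})

test_that("remesh preserves fixed vertices bitwise and fixes plateau midpoints", {
  p <- spine_params()
  m <- init_spine_mesh(p)
  r <- remesh(m, p)
  fixed_in <- m$positions[m$fixed, , drop = FALSE]
  fixed_out <- r$positions[r$fixed, , drop = FALSE]
  for (i in seq_len(nrow(fixed_in))) {
    hit <- which(fixed_out[, 1] == fixed_in[i, 1] &
                   fixed_out[, 2] == fixed_in[i, 2])
    expect_length(hit, 1)
  }
  # stretch a plateau edge beyond d_max: its midpoint must come back fixed
  psd <- which(m$fixed & m$positions[, 2] == m$h_PSD)
  wide <- as_spine_mesh(rbind(c(-0.05, 0.35), c(-0.06, 0.2), c(0, 0.1),
                              c(0.06, 0.2), c(0.05, 0.35)),
                        fixed = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                        h_PSD = 0.35)
  rw <- remesh(wide, p)
  new_on_plateau <- rw$positions[, 2] == 0.35
  expect_true(all(rw$fixed[new_on_plateau]))
  expect_gt(sum(new_on_plateau), 2)
})

test_that("remesh refuses to reduce a polygon below three vertices", {
  p <- spine_params()
  tri <- as_spine_mesh(0.005 * rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  expect_error(remesh(tri, p), "below 3")
})

test_that("mesh snapshots round-trip through CSV", {
  m <- init_spine_mesh(spine_params())
  path <- tempfile(fileext = ".csv")
  write_mesh_csv(m, path)
  m2 <- read_mesh_csv(path)
  expect_equal(m2$positions, m$positions, ignore_attr = TRUE)
  expect_equal(m2$fixed, m$fixed)
  expect_equal(m2$h_PSD, m$h_PSD)
})
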