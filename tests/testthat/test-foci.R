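test_that("nucleation candidates respect the membrane/PSD shell and weighting", {
  p <- spine_params()
  rest <- default_rest()
  set.seed(21)
  cand <- nucleation_candidates(rest$mesh, p)
  expect_gt(nrow(cand$points), 0)
  expect_equal(sum(cand$weights), 1, tolerance = 1e-12)

  # flat weighting when the distance scale is huge
  pl <- spine_params(lam = 1e9)
  set.seed(21)
  cl <- nucleation_candidates(rest$mesh, pl)
  expect_lt(diff(range(cl$weights)) / mean(cl$weights), 1e-6)

  # nearly all mass on the PSD-nearest candidate when the scale is tiny
  ps <- spine_params(lam = 1e-9)
  set.seed(21)
  cs <- nucleation_candidates(rest$mesh, ps)
  expect_gt(cs$weights[which.min(cs$d_psd)], 1 - 1e-9)
})

test_that("nucleated foci satisfy the geometric constraints", {
  p <- spine_params()
  rest <- default_rest()
  seg <- psd_segment(rest$mesh)
  set.seed(22)
  n_ok <- 0
  for (i in 1:300) {
    f <- nucleate_focus(rest$mesh, p, t = 0, id = i)
    # rare NULLs are legitimate: a nucleation point close to the shell
    # boundary may have no mesh vertex within the shell radius
    if (is.null(f)) next
    n_ok <- n_ok + 1
    xn <- cbind(f$xn_x, f$xn_y)
    expect_true(spinesim:::points_in_polygon_cpp(rest$mesh$positions, xn))
    expect_lte(spinesim:::dist_to_boundary_cpp(rest$mesh$positions, xn),
               p$nucleation_shell + 1e-12)
    expect_gt(spinesim:::dist_to_segment_cpp(xn, seg[1, 1], seg[1, 2],
                                             seg[2, 1], seg[2, 2]),
              p$nucleation_shell)
    cpos <- rest$mesh$positions[f$center, ]
    expect_lte(sqrt(sum((cpos - xn)^2)), p$nucleation_shell)
    expect_equal(f$m_c, 1L)
    expect_equal(f$m_u, 0L)
  }
  expect_gt(n_ok, 250)
})

test_that("nucleation returns nothing when the shell filter empties", {
  # a polygon so small that every interior point is within the shell of the PSD
  p <- spine_params()
  sq <- as_spine_mesh(rbind(c(-0.05, -0.05), c(0.05, -0.05),
                            c(0.05, 0.05), c(-0.05, 0.05)),
                      fixed = c(FALSE, FALSE, TRUE, TRUE), h_PSD = 0.05)
  set.seed(23)
  expect_null(nucleate_focus(sq, p))
})

test_that("the actin force field matches the Gaussian kernel", {
  p <- spine_params()
  w0 <- p$alpha / (p$sigma * sqrt(2 * pi))
  expect_equal(w0, 5.0533, tolerance = 1e-4)

  # polygon containing vertex 1 at the origin and vertex 2 at distance sigma
  m <- as_spine_mesh(rbind(c(0, 0), c(p$sigma, 0), c(p$sigma, 1),
                           c(-1, 1), c(-1, -0.5), c(0, -0.5)))
  # focus centred on vertex 1, nucleated far left so directions align with +x
  f <- data.frame(id = 1L, xn_x = -5, xn_y = 0, center = 1L,
                  m_c = 3L, m_u = 0L, birth = 0)
  F <- actin_force_field(m, f, p)
  expect_equal(F[1, ], c(3 * w0, 0), tolerance = 1e-9)
  expect_equal(F[2, 1] / F[1, 1], exp(-0.5), tolerance = 1e-6)

  # additivity and the kernel bound
  f2 <- data.frame(id = 2L, xn_x = 0, xn_y = -3, center = 3L,
                   m_c = 2L, m_u = 1L, birth = 0)
  Fa <- actin_force_field(m, f2, p)
  Fsum <- actin_force_field(m, rbind(f, f2), p)
  expect_equal(Fsum, F + Fa, tolerance = 1e-12)
  expect_true(all(sqrt(rowSums(Fsum^2)) <= (3 + 3) * w0 + 1e-9))

  # no foci, no force; a vertex coinciding with X_n contributes nothing
  expect_equal(actin_force_field(m, NULL, p), matrix(0, 6, 2))
  f3 <- data.frame(id = 3L, xn_x = 0, xn_y = 0, center = 2L,
                   m_c = 1L, m_u = 0L, birth = 0)
  expect_equal(actin_force_field(m, f3, p)[1, ], c(0, 0))
})

test_that("dead or out-of-range foci are rejected by the force field", {
  p <- spine_params()
  m <- pentagon_mesh()
  dead <- data.frame(id = 1L, xn_x = 0, xn_y = 0, center = 1L,
                     m_c = 0L, m_u = 0L, birth = 0)
  expect_error(actin_force_field(m, dead, p), "dead")
  bad <- data.frame(id = 1L, xn_x = 0, xn_y = 0, center = 99L,
                    m_c = 1L, m_u = 0L, birth = 0)
  expect_error(actin_force_field(m, bad, p), "range")
})
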