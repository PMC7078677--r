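# Shared fixtures.  The default resting shape is expensive to compute, so it
# is relaxed once per test session and cached.

.spine_cache <- new.env(parent = emptyenv())

default_rest <- function() {
  if (is.null(.spine_cache$rest)) {
    p <- spine_params()
    .spine_cache$rest <- relax_to_rest(init_spine_mesh(p), p)
  }
  .spine_cache$rest
}

regular_polygon_mesh <- function(n, r = 0.5) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  as_spine_mesh(cbind(r * cos(th), r * sin(th)))
}

# irregular convex-ish pentagon used as a gradient fixture
pentagon_mesh <- function() {
  as_spine_mesh(rbind(c(0.31, 0.02), c(0.06, 0.30), c(-0.25, 0.13),
                      c(-0.19, -0.20), c(0.16, -0.28)))
}

# central finite-difference gradient of the membrane energy (oracle for the
# analytic force)
numeric_membrane_gradient <- function(mesh, params, h = 1e-6) {
  n <- nrow(mesh$positions)
  g <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    for (d in 1:2) {
      mp <- mesh
      mm <- mesh
      mp$positions[k, d] <- mp$positions[k, d] + h
      mm$positions[k, d] <- mm$positions[k, d] - h
      g[k, d] <- (membrane_energy(mp, params) -
                    membrane_energy(mm, params)) / (2 * h)
    }
  }
  -g
}

# Eq.-style recursive area series generated directly from known parameters;
# oracle for the estimator fit
recursive_area_series <- function(m, b, Phi, A0, A_s, foci) {
  out <- numeric(length(foci))
  prev <- A0
  for (j in seq_along(foci)) {
    prev <- prev - Phi * (prev - A_s) + m * foci[j] + b
    out[j] <- prev
  }
  out
}
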