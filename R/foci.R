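#' Polymerization foci
#'
#' Active actin polymerization foci are tracked in a plain data frame with
#' one row per focus and columns `id`, `xn_x`, `xn_y` (nucleation point,
#' fixed for the focus lifetime), `center` (index of the membrane vertex
#' acting as focus centre), `m_c`, `m_u` (filament counts by minus-end
#' state), and `birth` (nucleation time, s).  A focus is alive while
#' `m_c + m_u > 0`.
#'
#' @name foci
NULL

empty_foci <- function() {
  data.frame(id = integer(), xn_x = numeric(), xn_y = numeric(),
             center = integer(), m_c = integer(), m_u = integer(),
             birth = numeric())
}

#' Nucleation candidate points
#'
#' Draws `n_cand` uniform points inside the membrane polygon (rejection
#' sampling in the bounding box) and filters them to the nucleation-permitted
#' shell: within `nucleation_shell` of the membrane boundary and farther than
#' `nucleation_shell` from the PSD segment.  Returns the surviving points
#' with their PSD distances and normalized selection weights
#' `p_j` proportional to `exp(-d_j / lam)`.
#'
#' @param mesh A `spine_mesh` object.
#' @param params A [spine_params()] object.
#' @param n_cand Number of uniform candidates to draw (default 1000).
#' @return A list with `points` (m x 2 matrix), `d_psd`, `weights`; all of
#'   length zero when no candidate survives the filter.
#' @export
nucleation_candidates <- function(mesh, params, n_cand = 1000L) {
  assert_mesh(mesh)
  seg <- psd_segment(mesh)
  if (is.null(seg)) {
    # no PSD plateau: only the membrane-proximity filter applies
    seg <- matrix(c(Inf, Inf, Inf, Inf), 2, 2)
  }
  cand <- candidate_points_cpp(mesh$positions, as.integer(n_cand),
                               seg[1, 1], seg[1, 2], seg[2, 1], seg[2, 2])
  keep <- cand$d_membrane <= params$nucleation_shell &
    cand$d_psd > params$nucleation_shell
  pts <- cand$points[keep, , drop = FALSE]
  d_psd <- cand$d_psd[keep]
  if (nrow(pts) == 0L) {
    return(list(points = pts, d_psd = numeric(), weights = numeric()))
  }
  logw <- -(d_psd - min(d_psd)) / params$lam
  w <- exp(logw)
  list(points = pts, d_psd = d_psd, weights = w / sum(w))
}

#' Nucleate a new polymerization focus
#'
#' Implements the two-step nucleation rule: a nucleation point `X_n` is
#' selected among membrane-proximal, PSD-distal candidate points with
#' probability proportional to `exp(-d_j / lam)` in its PSD distance `d_j`
#' (small `lam` favours nucleation near the PSD); then the focus centre is a
#' membrane vertex drawn uniformly among those within `nucleation_shell` of
#' `X_n`.  The new focus starts with `initial_filaments` filaments in the
#' minus-capped class.
#'
#' @param mesh A `spine_mesh` object.
#' @param params A [spine_params()] object.
#' @param t Nucleation time recorded on the focus (s).
#' @param id Identifier for the new focus.
#' @param initial_filaments Number of seed filaments (default 1).
#' @param n_cand Number of uniform candidate points (default 1000).
#' @return A one-row foci data frame, or `NULL` when no candidate point or no
#'   nearby centre vertex survives.
#' @export
nucleate_focus <- function(mesh, params, t = 0, id = 1L,
                           initial_filaments = 1L, n_cand = 1000L) {
  cand <- nucleation_candidates(mesh, params, n_cand)
  if (nrow(cand$points) == 0L) return(NULL)
  j <- sample.int(nrow(cand$points), 1L, prob = cand$weights)
  xn <- cand$points[j, ]
  d <- sqrt((mesh$positions[, 1] - xn[1])^2 + (mesh$positions[, 2] - xn[2])^2)
  near <- which(d <= params$nucleation_shell)
  if (length(near) == 0L) return(NULL)
  center <- if (length(near) == 1L) near else near[sample.int(length(near), 1L)]
  data.frame(id = as.integer(id), xn_x = xn[1], xn_y = xn[2],
             center = as.integer(center),
             m_c = as.integer(initial_filaments), m_u = 0L, birth = t)
}

#' Actin force field on the mesh
#'
#' Converts the active foci into per-vertex pushing forces.  Each focus `i`
#' contributes at vertex `k`
#' \deqn{W(\|x^k - X_c^i\|)\, B^i\, V_{i,k}, \qquad
#'   W(x) = \frac{\alpha}{\sigma\sqrt{2\pi}} e^{-x^2/2\sigma^2},}
#' where `X_c` is the current position of the focus centre vertex, `B` the
#' focus barbed-end count, and \eqn{V_{i,k} = (x^k - X_n^i)/\|x^k - X_n^i\|}
#' the outward direction away from the (fixed) nucleation point.  Distances
#' are straight-line distances in the plane.  A vertex coinciding with a
#' nucleation point receives no contribution from that focus.
#'
#' @param mesh A `spine_mesh` object.
#' @param foci A foci data frame (see [nucleate_focus()]); may be empty.
#' @param params A [spine_params()] object.
#' @return An `n x 2` matrix of force vectors (pN).
#' @export
actin_force_field <- function(mesh, foci, params) {
  assert_mesh(mesh)
  n <- nrow(mesh$positions)
  if (is.null(foci) || nrow(foci) == 0L) return(matrix(0, n, 2))
  B <- foci$m_c + foci$m_u
  if (any(B <= 0)) stop("dead focus in force-field evaluation", call. = FALSE)
  if (any(foci$center < 1L | foci$center > n))
    stop("focus centre vertex out of range", call. = FALSE)
  centers <- mesh$positions[foci$center, , drop = FALSE]
  xn <- cbind(foci$xn_x, foci$xn_y)
  actin_force_cpp(mesh$positions, centers, xn, as.integer(B), params$alpha,
                  params$sigma)
}

# Re-map focus centre indices after remeshing: each focus centre is moved to
# the vertex of the new mesh nearest to its previous centre position.
remap_focus_centers <- function(foci, old_positions, new_mesh) {
  if (nrow(foci) == 0L) return(foci)
  for (i in seq_len(nrow(foci))) {
    old <- old_positions[foci$center[i], ]
    d2 <- (new_mesh$positions[, 1] - old[1])^2 +
      (new_mesh$positions[, 2] - old[2])^2
    foci$center[i] <- which.min(d2)
  }
  foci
}
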