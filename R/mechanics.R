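#' Helfrich-type membrane energy of a mesh
#'
#' Evaluates the discretised membrane energy
#' \deqn{E = P \Omega + \tau S + 2\kappa \sum_k H_k^2 \, ds_k,}
#' where \eqn{\Omega} is the enclosed area, \eqn{S} the boundary length,
#' \eqn{H_k} the signed discrete curvature at vertex \eqn{k} and \eqn{ds_k}
#' its arc-length weight (see [compute_geometry()]).  `P` is the pressure
#' difference, `tau` the line tension, and `kappa` the bending modulus.
#'
#' @param mesh A `spine_mesh` object.
#' @param params A [spine_params()] object.
#' @return The scalar energy (model units).
#' @export
membrane_energy <- function(mesh, params) {
  assert_mesh(mesh)
  g <- compute_geometry(mesh)  # validates non-degenerate edges
  params$P * g$area_enclosed + params$tau * g$boundary_length +
    2 * params$kappa * sum(g$curvature^2 * g$ds)
}

#' Membrane force field
#'
#' Per-vertex force `F_mem = -dE/dx`, the negative gradient of the
#' discretised membrane energy with respect to each vertex position.  The
#' pressure and tension gradients are analytic; the bending gradient is a
#' local central finite difference of the discretised bending term, which
#' coincides with the global finite-difference gradient of
#' [membrane_energy()] because the bending energy is local in the mesh.
#' Forces are reported at every vertex, including fixed ones (which do not
#' move but whose local membrane load enters the branching rate).
#'
#' @param mesh A `spine_mesh` object.
#' @param params A [spine_params()] object.
#' @return An `n x 2` matrix of force vectors (pN).
#' @export
membrane_force <- function(mesh, params) {
  assert_mesh(mesh)
  membrane_force_cpp(mesh$positions, params$P, params$tau, params$kappa)
}

#' Relax a mesh to the resting shape
#'
#' Integrates the mobility-limited gradient flow of the membrane energy with
#' no actin force (fixed vertices immobile), remeshing each step, until the
#' largest free-vertex displacement per step drops below `max_disp_tol`.
#' Because only membrane forces act, the spine shrinks onto its resting
#' shape, whose enclosed area `A_s` is the baseline of all area fluctuations.
#'
#' @param mesh A `spine_mesh` object with fixed PSD and neck vertices.
#' @param params A [spine_params()] object.
#' @param max_disp_tol Convergence tolerance on the per-step maximum
#'   free-vertex displacement (um).
#' @param max_iter Iteration cap.
#' @return A list with elements `mesh` (the relaxed `spine_mesh`), `A_s`
#'   (resting area, um^2), `iterations`, and `converged`.
#' @export
relax_to_rest <- function(mesh, params, max_disp_tol = 1e-6,
                          max_iter = 100000L) {
  assert_mesh(mesh)
  out <- relax_cpp(mesh$positions, mesh$fixed, params$P, params$tau,
                   params$kappa, params$zeta, params$dt, params$d_tol,
                   params$d_min, params$d_max, max_disp_tol,
                   as.integer(max_iter), 25L)
  if (!out$converged) {
    stop(sprintf(
      "resting-shape relaxation did not converge in %d iterations (last displacement %.3g um)",
      out$iterations, out$max_disp), call. = FALSE)
  }
  relaxed <- new_spine_mesh(out$positions, out$fixed, h_PSD = mesh$h_PSD,
                            h_neck = mesh$h_neck, delta_s = mesh$delta_s)
  list(mesh = relaxed, A_s = compute_geometry(relaxed)$area_enclosed,
       iterations = out$iterations, converged = out$converged)
}
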