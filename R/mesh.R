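#' Membrane mesh: a closed polygon with fixed PSD and neck plateaus
#'
#' The spine membrane is represented by a cyclically ordered, counterclockwise
#' polygon of 2D vertices.  Vertices on the post-synaptic density (PSD)
#' plateau at the top and on the neck plateau at the bottom are flagged fixed
#' and never move.
#'
#' @name spine_mesh
NULL

new_spine_mesh <- function(positions, fixed, h_PSD = NA_real_,
                           h_neck = NA_real_, delta_s = NA_real_) {
  stopifnot(is.matrix(positions), ncol(positions) == 2,
            length(fixed) == nrow(positions))
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions, fixed = as.logical(fixed),
                 h_PSD = h_PSD, h_neck = h_neck, delta_s = delta_s),
            class = "spine_mesh")
}

#' Initialize the spine membrane mesh
#'
#' Samples a circle of radius `r_s` centred at the origin at arc spacing
#' approximately `delta_s`, then imposes the two morphological constraints of
#' a mature spine: vertices with `y >= h_PSD` are projected onto the PSD
#' plateau `y = h_PSD` and vertices with `y <= h_neck` onto the neck plateau
#' `y = h_neck`; both groups are flagged fixed.  The plateau levels are the
#' circle heights at the PSD and neck radii,
#' `h_PSD = sqrt(r_s^2 - r_PSD^2)` and `h_neck = -sqrt(r_s^2 - r_neck^2)`,
#' so the initial shape is a flat-topped, flat-bottomed disk.
#'
#' @param params A [spine_params()] object.
#' @return A `spine_mesh` object (counterclockwise vertex order).
#' @examples
#' m <- init_spine_mesh(spine_params())
#' m$h_PSD   # ~0.350
#' @export
init_spine_mesh <- function(params) {
  stopifnot(inherits(params, "spine_params"))
  h_PSD <- sqrt(params$r_s^2 - params$r_PSD^2)
  h_neck <- -sqrt(params$r_s^2 - params$r_neck^2)
  n <- max(3L, round(2 * pi * params$r_s / params$delta_s))
  theta <- 2 * pi * (seq_len(n) - 1L) / n  # counterclockwise
  pos <- cbind(params$r_s * cos(theta), params$r_s * sin(theta))
  fixed <- rep(FALSE, n)
  top <- pos[, 2] >= h_PSD
  pos[top, 2] <- h_PSD
  bottom <- pos[, 2] <= h_neck
  pos[bottom, 2] <- h_neck
  fixed[top | bottom] <- TRUE
  new_spine_mesh(pos, fixed, h_PSD = h_PSD, h_neck = h_neck,
                 delta_s = params$delta_s)
}

#' Build a membrane mesh from raw coordinates
#'
#' Constructor for custom polygons (fixtures, analytic test shapes, meshes
#' read from external sources).  Vertices must be in counterclockwise order
#' (positive shoelace area).
#'
#' @param positions `n x 2` numeric matrix of vertex coordinates (um).
#' @param fixed Logical vector flagging immobile vertices (default: none).
#' @param h_PSD,h_neck Plateau levels (um), when the mesh has them.
#' @param delta_s Target edge length (um).
#' @return A `spine_mesh` object.
#' @export
as_spine_mesh <- function(positions, fixed = rep(FALSE, nrow(positions)),
                          h_PSD = NA_real_, h_neck = NA_real_,
                          delta_s = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 3L || anyNA(positions))
    stop("'positions' must be an n x 2 matrix (n >= 3) without NAs",
         call. = FALSE)
  m <- new_spine_mesh(positions, fixed, h_PSD = h_PSD, h_neck = h_neck,
                      delta_s = delta_s)
  if (geom_report_cpp(positions)$area <= 0)
    stop("polygon must be counterclockwise (positive signed area)",
         call. = FALSE)
  m
}

assert_mesh <- function(mesh) {
  if (!inherits(mesh, "spine_mesh")) stop("not a 'spine_mesh'", call. = FALSE)
  if (nrow(mesh$positions) < 3L)
    stop("mesh must have at least 3 vertices", call. = FALSE)
  invisible(mesh)
}

#' Geometric measurements of a membrane mesh
#'
#' Computes the enclosed area (shoelace formula), boundary length, per-vertex
#' signed discrete curvature and arc-length weight, and per-edge lengths.
#' The curvature at a vertex is the inverse circumradius of the triangle
#' formed with its two neighbours, signed by the turn direction (positive
#' where the counterclockwise polygon is locally convex); three collinear
#' points give zero curvature.  The arc-length weight `ds` is half the sum of
#' the two adjacent edge lengths, so that `sum(ds)` equals the boundary
#' length.
#'
#' @param mesh A `spine_mesh` object.
#' @return A list with elements `area_enclosed`, `boundary_length`,
#'   `curvature`, `ds`, and `edge_lengths`.
#' @export
compute_geometry <- function(mesh) {
  assert_mesh(mesh)
  rep <- geom_report_cpp(mesh$positions)
  if (any(rep$edge_lengths == 0))
    stop("duplicate consecutive vertices in mesh", call. = FALSE)
  list(area_enclosed = rep$area, boundary_length = rep$boundary_length,
       curvature = rep$curvature, ds = rep$ds,
       edge_lengths = rep$edge_lengths)
}

#' Remesh a membrane polygon to the target edge-length band
#'
#' Recursively splits edges longer than `d_max` at their midpoint and removes
#' one endpoint of edges shorter than `d_min`, until every edge not joining
#' two fixed vertices lies in `[d_min, d_max]`.  A vertex inserted between two
#' fixed vertices is itself fixed (it lies on the same plateau); fixed
#' vertices are never removed, and an edge between two fixed vertices is
#' exempt from the collapse rule.  When both endpoints of a short edge are
#' free, the second in cyclic order is removed.
#'
#' @param mesh A `spine_mesh` object.
#' @param params A [spine_params()] object supplying `d_min` and `d_max`.
#' @return The remeshed `spine_mesh`.
#' @export
remesh <- function(mesh, params) {
  assert_mesh(mesh)
  out <- remesh_cpp(mesh$positions, mesh$fixed, params$d_min, params$d_max)
  new_spine_mesh(out$positions, out$fixed, h_PSD = mesh$h_PSD,
                 h_neck = mesh$h_neck, delta_s = mesh$delta_s)
}

#' The PSD segment of a mesh
#'
#' Returns the chord occupied by the fixed PSD plateau: the segment at
#' `y = h_PSD` spanning the x-range of the fixed vertices on that plateau.
#'
#' @param mesh A `spine_mesh` object.
#' @return A 2x2 matrix with the two segment endpoints as rows, or `NULL`
#'   when no vertex lies on the PSD plateau.
#' @export
psd_segment <- function(mesh) {
  assert_mesh(mesh)
  if (is.na(mesh$h_PSD)) return(NULL)
  on_psd <- mesh$fixed & abs(mesh$positions[, 2] - mesh$h_PSD) < 1e-12
  if (!any(on_psd)) return(NULL)
  xs <- range(mesh$positions[on_psd, 1])
  rbind(c(xs[1], mesh$h_PSD), c(xs[2], mesh$h_PSD))
}

#' Write a mesh snapshot as CSV
#'
#' Writes columns `x`, `y`, `fixed` (0/1), coordinates in micrometres.
#'
#' @param mesh A `spine_mesh` object.
#' @param path Output file path.
#' @export
write_mesh_csv <- function(mesh, path) {
  assert_mesh(mesh)
  df <- data.frame(x = mesh$positions[, 1], y = mesh$positions[, 2],
                   fixed = as.integer(mesh$fixed))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mesh snapshot written by [write_mesh_csv()]
#'
#' @param path CSV file with columns `x`, `y`, `fixed`.
#' @param delta_s Target edge length to attach to the mesh (um).
#' @return A `spine_mesh` object.  Plateau levels are recovered from the
#'   fixed vertices when present.
#' @export
read_mesh_csv <- function(path, delta_s = NA_real_) {
  df <- utils::read.csv(path)
  fixed <- as.logical(df$fixed)
  ys <- df$y[fixed]
  h_PSD <- if (any(fixed) && any(ys > 0)) max(ys) else NA_real_
  h_neck <- if (any(fixed) && any(ys < 0)) min(ys) else NA_real_
  new_spine_mesh(cbind(df$x, df$y), fixed, h_PSD = h_PSD, h_neck = h_neck,
                 delta_s = delta_s)
}

#' @export
print.spine_mesh <- function(x, ...) {
  g <- compute_geometry(x)
  cat(sprintf("<spine_mesh> %d vertices (%d fixed), area %.4f um^2, boundary %.4f um\n",
              nrow(x$positions), sum(x$fixed), g$area_enclosed,
              g$boundary_length))
  invisible(x)
}

#' @export
plot.spine_mesh <- function(x, ..., asp = 1) {
  pos <- rbind(x$positions, x$positions[1, , drop = FALSE])
  graphics::plot(pos, type = "l", asp = asp, xlab = "x (um)", ylab = "y (um)",
                 ...)
  graphics::points(x$positions[x$fixed, , drop = FALSE], pch = 16, cex = 0.4)
  invisible(x)
}
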