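#' Construct a polygonal cell agent
#'
#' A cell is an organising centre plus `N` vertices joined to it by
#' Kelvin-Voigt (spring + dashpot) segments representing actin bundles.
#' Angular springs between consecutive segments resist shape changes, and a
#' constant contraction force of magnitude `F_co` pulls every vertex
#' towards the centre (myosin activity).  Three geometries are supported:
#'
#' * `"elongated"`: two collinear segments (`N = 2`), natural angle pi;
#' * `"round"`: `n_vertices` vertices equally spaced on a circle of radius
#'   `size`;
#' * `"fan"`: `n_vertices - 1` vertices spanning a half-disc of radius
#'   `size` (the leading edge) plus one rear vertex at half radius.
#'
#' Rest lengths and natural angles are taken from the constructed geometry,
#' so a freshly made cell is at mechanical equilibrium.
#'
#' @param shape_tag `"elongated"`, `"round"` or `"fan"`.
#' @param centre 2-vector, organising-centre position (um).
#' @param size radius (round/fan) or total length (elongated), um.
#' @param orientation rotation of the shape, radians.
#' @param n_vertices vertex count for round/fan shapes.
#' @param k_seg segment elastic constant, pN/um.
#' @param gamma_seg segment viscous constant, pN s/um.
#' @param k_ang angular stiffness, pN um/rad.
#' @param F_co contraction force magnitude per vertex, pN.
#' @param eta damping coefficient of cell nodes, pN s/um.
#' @return an object of class `cell`.
#' @export
make_cell <- function(shape_tag, centre, size, orientation = 0,
                      n_vertices = 8L, k_seg = 1e4, gamma_seg = 1000,
                      k_ang = 5e4, F_co = 0, eta = 1000) {
  if (size <= 0) stopf("size must be positive")
  centre <- as.numeric(centre)
  rot <- function(a) cbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  R <- rot(orientation)
  if (shape_tag == "elongated") {
    local <- rbind(c(-size / 2, 0), c(size / 2, 0))
  } else if (shape_tag == "round") {
    ang <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    local <- size * cbind(cos(ang), sin(ang))
  } else if (shape_tag == "fan") {
    if (n_vertices < 4L) stopf("fan cells need at least 4 vertices")
    lead <- n_vertices - 1L
    ang <- seq(-pi / 2, pi / 2, length.out = lead)
    local <- rbind(size * cbind(cos(ang), sin(ang)),
                   c(-size / 2, 0))
  } else {
    stopf("unknown shape_tag '%s'", shape_tag)
  }
  vertices <- sweep(local %*% t(R), 2, centre, "+")
  cl <- structure(list(
    centre = centre, vertices = vertices,
    segment_rest_lengths = row_norms(sweep(vertices, 2, centre)),
    natural_angles = NULL,
    k_seg = k_seg, gamma_seg = gamma_seg, k_ang = k_ang,
    F_co = F_co, eta = eta, shape_tag = shape_tag
  ), class = "cell")
  cl$natural_angles <- cell_angles(cl)
  validate_cell(cl)
  cl
}

validate_cell <- function(cell) {
  n <- nrow(cell$vertices)
  if (n < 2L) stopf("a cell needs at least 2 vertices")
  if ((cell$shape_tag == "elongated") != (n == 2L))
    stopf("elongated cells must have exactly 2 vertices")
  if (any(cell$segment_rest_lengths <= 0)) stopf("rest lengths must be > 0")
  if (cell$k_seg < 0 || cell$k_ang < 0 || cell$gamma_seg < 0)
    stopf("stiffnesses must be non-negative")
  if (n >= 3L) {
    s <- sum(cell$natural_angles)
    if (abs(s - 2 * pi) > 1e-8)
      stopf("natural angles of a closed cell must sum to 2*pi (got %.6f)", s)
  }
  invisible(cell)
}

#' @export
print.cell <- function(x, ...) {
  cat(sprintf("<cell> %s, %d vertices, F_co = %.3g pN\n",
              x$shape_tag, nrow(x$vertices), x$F_co))
  invisible(x)
}

# Index pairs (i, j) of consecutive segments bounding each angle.  Closed
# shapes (N >= 3) are cyclic; elongated cells have the single pair (1, 2).
angle_pairs <- function(n) {
  if (n == 2L) cbind(1L, 2L) else cbind(seq_len(n), c(seq_len(n)[-1], 1L))
}

# Signed interior angles at the centre, in [0, 2*pi).
cell_angles <- function(cell, vertices = NULL, centre = NULL) {
  vertices <- vertices %||% cell$vertices
  centre <- centre %||% cell$centre
  d <- sweep(vertices, 2, centre)
  phi <- atan2(d[, 2], d[, 1])
  ap <- angle_pairs(nrow(vertices))
  th <- (phi[ap[, 2]] - phi[ap[, 1]]) %% (2 * pi)
  th
}

#' Structural (Kelvin-Voigt + angular) forces of a cell
#'
#' Per vertex, the force is the sum of
#' * a spring term `-k_seg * (len - L0)` along the segment axis,
#' * a viscous term `-gamma_seg * d(len)/dt` along the segment axis (the
#'   elongation rate is the relative vertex-centre velocity projected on
#'   the axis, keeping the Kelvin-Voigt element one-dimensional), and
#' * angular terms: each consecutive-segment angle theta carries a harmonic
#'   potential `1/2 k_ang (theta - theta0)^2` whose exact analytic gradient
#'   is distributed over the two vertices and the centre.
#'
#' The centre reaction is the exact negative of the vertex sum, so a cell's
#' internal forces always cancel.
#'
#' @param cell a [make_cell()] object.
#' @param vertex_velocities numeric matrix (N x 2), um/s (zero allowed).
#' @param centre_velocity 2-vector, um/s.
#' @param vertices,centre optional positions overriding the cell's own.
#' @return list with `vertices` (N x 2 matrix, pN) and `centre` (2-vector,
#'   pN; the reaction `-colSums(vertices)`).
#' @export
structural_forces <- function(cell, vertex_velocities = NULL,
                              centre_velocity = c(0, 0),
                              vertices = NULL, centre = NULL) {
  vertices <- vertices %||% cell$vertices
  centre <- centre %||% cell$centre
  n <- nrow(vertices)
  if (is.null(vertex_velocities)) vertex_velocities <- matrix(0, n, 2)
  d <- sweep(vertices, 2, centre)
  len <- row_norms(d)
  if (any(len == 0)) stopf("zero-length cell segment")
  u <- d / len
  Fv <- matrix(0, n, 2)
  # Kelvin-Voigt: spring + dashpot along the segment
  relv <- sweep(vertex_velocities, 2, centre_velocity)
  dlen <- rowSums(relv * u)
  mag <- -cell$k_seg * (len - cell$segment_rest_lengths) -
    cell$gamma_seg * dlen
  Fv <- Fv + mag * u
  # angular forces: gradient of 1/2 k (theta - theta0)^2 with
  # theta = atan2 difference; grad_vi theta = -perp(d_i)/|d_i|^2,
  # grad_vj theta = +perp(d_j)/|d_j|^2, grad_c theta = -(sum of both)
  if (cell$k_ang > 0 && n >= 2L) {
    ap <- angle_pairs(n)
    th <- cell_angles(cell, vertices, centre)
    dev <- th - cell$natural_angles
    pi_ <- ap[, 1]; pj_ <- ap[, 2]
    perp_i <- cbind(-d[pi_, 2], d[pi_, 1]) / len[pi_]^2
    perp_j <- cbind(-d[pj_, 2], d[pj_, 1]) / len[pj_]^2
    Fi <- (cell$k_ang * dev) * perp_i    # = -k dev * grad_vi
    Fj <- -(cell$k_ang * dev) * perp_j   # = -k dev * grad_vj
    for (a in seq_len(nrow(ap))) {
      Fv[pi_[a], ] <- Fv[pi_[a], ] + Fi[a, ]
      Fv[pj_[a], ] <- Fv[pj_[a], ] + Fj[a, ]
    }
  }
  list(vertices = Fv, centre = -colSums(Fv))
}

#' Active contraction forces of a cell
#'
#' Each vertex receives a constant force of magnitude `F_co` directed from
#' the vertex towards the organising centre; the centre receives the exact
#' negative of the sum (internal force pair).
#'
#' @inheritParams structural_forces
#' @return list with `vertices` (N x 2, pN) and `centre` (2-vector, pN).
#' @export
contraction_forces <- function(cell, vertices = NULL, centre = NULL) {
  vertices <- vertices %||% cell$vertices
  centre <- centre %||% cell$centre
  d <- sweep(vertices, 2, centre)
  len <- row_norms(d)
  if (any(len == 0)) stopf("vertex coincides with the cell centre")
  Fv <- -cell$F_co * d / len
  list(vertices = Fv, centre = -colSums(Fv))
}

#' Elastic energy of a cell (springs + angles + contraction potential)
#'
#' Used for finite-difference validation of the analytic forces: the
#' structural + contraction forces are minus the gradient of this energy
#' (viscous forces have no potential).
#'
#' @inheritParams structural_forces
#' @param include_contraction include the contraction potential
#'   `F_co * sum(len)` whose negative gradient is [contraction_forces()].
#' @return scalar energy, pN um.
#' @export
cell_energy <- function(cell, vertices = NULL, centre = NULL,
                        include_contraction = FALSE) {
  vertices <- vertices %||% cell$vertices
  centre <- centre %||% cell$centre
  len <- row_norms(sweep(vertices, 2, centre))
  e <- sum(0.5 * cell$k_seg * (len - cell$segment_rest_lengths)^2)
  th <- cell_angles(cell, vertices, centre)
  e <- e + sum(0.5 * cell$k_ang * (th - cell$natural_angles)^2)
  if (include_contraction) e <- e + cell$F_co * sum(len)
  e
}
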