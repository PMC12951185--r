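# Closed-form quasi-static E-field inside the homogeneous two-sphere head
# model, and field-operator assembly.
#
# The induced field of an external current element I*dl at q, evaluated at an
# interior point r, is
#   E(r) = (mu0 * omega * I / 4pi) * [ -dl/a + G dl + (r.dl) grad G ],
# with a = |r - q| and G(r) = int_0^1 dt/|t r - q| (closed form in C++).
# The field has no radial component at any interior point, is independent of
# the conductivity and of the sphere radius, and is reported as the amplitude
# at the peak of the sinusoidal drive p(t) = sin(omega t).

#' Spherical head model
#'
#' Two concentric spheres centered at the origin: a brain sphere and an outer
#' (scalp) sphere. The conductivity is informational only; the magnetically
#' induced field in a spherical conductor does not depend on it. The default
#' coil placement is at \code{r_c = c(0, 0, 0.09)} m with the coil axis
#' \code{n_c} pointing into the head and the design target field direction
#' \code{t_hat} along y. Depth is measured from the brain surface along the
#' depth line \code{s(l) = r_c + l * n_c}.
#'
#' @param brain_radius brain sphere radius (m).
#' @param outer_radius scalp sphere radius (m).
#' @param sigma conductivity (S/m), informational.
#' @param r_c coil center (m).
#' @param n_c inward unit coil axis.
#' @param t_hat target field direction at depth.
#' @param freq_hz drive frequency (Hz).
#' @export
head_model <- function(brain_radius = 0.070, outer_radius = 0.085,
                       sigma = 0.33, r_c = c(0, 0, 0.09),
                       n_c = c(0, 0, -1), t_hat = c(0, 1, 0),
                       freq_hz = 3000) {
  if (!(brain_radius > 0 && brain_radius < outer_radius &&
        outer_radius < sqrt(sum(r_c^2)))) {
    stop("need 0 < brain radius < outer radius < |r_c|")
  }
  n_c <- n_c / sqrt(sum(n_c^2))
  t_hat <- t_hat / sqrt(sum(t_hat^2))
  structure(list(brain_radius = brain_radius, outer_radius = outer_radius,
                 sigma = sigma, r_c = r_c, n_c = n_c, t_hat = t_hat,
                 omega = 2 * pi * freq_hz,
                 # distance from coil center to the cortex along the axis
                 C = sqrt(sum(r_c^2)) - brain_radius),
            class = "head_model")
}

#' Point on the depth line at depth d below the brain surface
#' @param head a \code{head_model}
#' @param d depth below the cortical surface (m), scalar or vector
#' @return matrix of points (one row per depth)
#' @export
depth_point <- function(head, d) {
  l <- head$C + d
  t(sapply(l, function(li) head$r_c + li * head$n_c))
}

check_points_inside <- function(points, head, margin = 0) {
  r <- sqrt(rowSums(points^2))
  if (any(r >= head$outer_radius - margin)) {
    stop("field evaluation points must lie strictly inside the outer sphere")
  }
}

check_sources_outside <- function(pos, head, clearance = 1e-3) {
  r <- sqrt(rowSums(pos^2))
  if (any(r < head$outer_radius + clearance)) {
    stop(sprintf(
      "source geometry must stay at least %.0f mm outside the outer sphere",
      clearance * 1000))
  }
}

#' Field operator of the surface-current basis
#'
#' Assembles the dense linear map from internal-node weights \code{lambda} to
#' stacked E-field vectors (x, y, z per point, point-major rows) at a fixed
#' point set, in V/m per unit weight (A) at the peak of the drive cycle.
#' Each triangle's constant current is represented by \code{order} point
#' current elements (edge midpoints for order 3).
#'
#' @param mesh a \code{coil_mesh}, strictly outside the outer sphere.
#' @param head a \code{head_model}.
#' @param points n x 3 matrix of interior points.
#' @param order element quadrature order per triangle (1 or 3).
#' @return \code{field_operator}: list with \code{matrix} (3n x n_internal),
#'   \code{points}, \code{omega}.
#' @export
efield_basis_operator <- function(mesh, head, points, order = 3) {
  points <- as_points(points)
  check_points_inside(points, head)
  check_sources_outside(mesh$vertices, head)
  el <- current_elements(mesh, order)
  tris <- mesh$triangles
  internal <- mesh$internal_nodes
  col_of <- integer(nrow(mesh$vertices))
  col_of[internal] <- seq_along(internal)
  # entries: element e of triangle t contributes, for each internal node of t,
  # vector J_{i,t} * A_t / order
  ent_elem <- integer(0); ent_col <- integer(0); ent_vec <- NULL
  ee <- vector("list", 3L)
  for (loc in 1:3) {
    nodes <- tris[, loc]
    keep <- col_of[nodes] > 0L
    j <- tris[, (loc %% 3) + 1L]
    k <- tris[, ((loc + 1L) %% 3) + 1L]
    Jt <- (mesh$vertices[k, , drop = FALSE] -
           mesh$vertices[j, , drop = FALSE]) / (2 * mesh$areas)
    # replicate per element of the triangle
    tkeep <- which(keep)
    el_ids <- which(el$tri %in% tkeep)
    # mapping: element row -> triangle
    tri_of_el <- el$tri
    sel <- tri_of_el %in% tkeep
    ids <- which(sel)
    ee[[loc]] <- list(elem = ids, col = col_of[nodes[tri_of_el[ids]]],
                      vec = Jt[tri_of_el[ids], , drop = FALSE] *
                        el$weight[ids])
  }
  ent_elem <- unlist(lapply(ee, `[[`, "elem"))
  ent_col <- unlist(lapply(ee, `[[`, "col"))
  ent_vec <- do.call(rbind, lapply(ee, `[[`, "vec"))
  M <- efield_operator_cpp(points, el$pos, as.integer(ent_elem),
                           as.integer(ent_col), ent_vec, length(internal))
  M <- M * (1e-7 * head$omega) # mu0/(4 pi) * omega
  structure(list(matrix = M, points = points, omega = head$omega,
                 ncol = length(internal), kind = "basis"),
            class = "field_operator")
}

#' Field operator of discrete wire loops
#'
#' One column per loop: the E-field per unit loop current (V/m per A) at the
#' drive peak. Polylines are subdivided to at most \code{max_seg} segment
#' length and each segment is represented by a midpoint current element.
#'
#' @param loops list of closed polylines (n x 3 matrices) or a
#'   \code{winding_set}.
#' @param head a \code{head_model}.
#' @param points interior evaluation points.
#' @param max_seg maximum segment length (m).
#' @export
efield_wire_operator <- function(loops, head, points, max_seg = 0.002) {
  points <- as_points(points)
  check_points_inside(points, head)
  polys <- as_loop_list(loops)
  ent_elem <- integer(0); ent_col <- integer(0)
  pos <- NULL; vec <- NULL
  for (k in seq_along(polys)) {
    P <- close_loop(polys[[k]])
    check_sources_outside(P, head)
    sg <- subdivide_polyline(P, max_seg)
    pos <- rbind(pos, sg$mid)
    vec <- rbind(vec, sg$vec)
    ent_col <- c(ent_col, rep(k, nrow(sg$mid)))
  }
  ent_elem <- seq_len(nrow(pos))
  M <- efield_operator_cpp(points, pos, as.integer(ent_elem),
                           as.integer(ent_col), vec, length(polys))
  M <- M * (1e-7 * head$omega)
  structure(list(matrix = M, points = points, omega = head$omega,
                 ncol = length(polys), kind = "wire"),
            class = "field_operator")
}

#' Evaluate the field of a field operator
#' @param op a \code{field_operator}
#' @param x weights (lambda or per-loop currents)
#' @return n x 3 matrix of E vectors (V/m)
#' @export
field_at <- function(op, x) {
  v <- op$matrix %*% x
  matrix(v, ncol = 3, byrow = TRUE)
}

# direct (matrix-free) field evaluation of a lambda current at many points
efield_lambda_points <- function(mesh, head, lambda, points, order = 3) {
  points <- as_points(points)
  check_points_inside(points, head)
  Sr <- full_stream(mesh, lambda)
  J <- triangle_currents(mesh, Sr)
  el <- current_elements(mesh, order)
  evec <- J[el$tri, , drop = FALSE] * el$weight
  E <- efield_elements_cpp(points, el$pos, evec)
  E * (1e-7 * head$omega)
}

# direct field of a winding (list of loops + currents) at many points
efield_wire_points <- function(loops, currents, head, points, max_seg = 0.002) {
  points <- as_points(points)
  check_points_inside(points, head)
  polys <- as_loop_list(loops)
  stopifnot(length(currents) == length(polys))
  pos <- NULL; vec <- NULL
  for (k in seq_along(polys)) {
    P <- close_loop(polys[[k]])
    sg <- subdivide_polyline(P, max_seg)
    pos <- rbind(pos, sg$mid)
    vec <- rbind(vec, sg$vec * currents[k])
  }
  E <- efield_elements_cpp(points, pos, vec)
  E * (1e-7 * head$omega)
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

as_loop_list <- function(loops) {
  if (inherits(loops, "winding_set")) {
    lapply(loops$loops, `[[`, "path")
  } else if (is.matrix(loops)) list(loops) else loops
}

close_loop <- function(P, tol = 1e-6) {
  gap <- sqrt(sum((P[1, ] - P[nrow(P), ])^2))
  if (gap > tol) {
    stop(sprintf("loop does not close: endpoint gap %.2e m exceeds %.0e m",
                 gap, tol))
  }
  if (gap > 0) P[nrow(P), ] <- P[1, ]
  P
}

subdivide_polyline <- function(P, max_seg) {
  A <- P[-nrow(P), , drop = FALSE]
  B <- P[-1, , drop = FALSE]
  len <- sqrt(rowSums((B - A)^2))
  keep <- len > 1e-12
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  len <- len[keep]
  nsub <- pmax(1L, as.integer(ceiling(len / max_seg)))
  idx <- rep(seq_along(nsub), nsub)
  frac_start <- unlist(lapply(nsub, function(n) (seq_len(n) - 1L) / n))
  frac_end <- unlist(lapply(nsub, function(n) seq_len(n) / n))
  S <- A[idx, , drop = FALSE] + (B - A)[idx, , drop = FALSE] * frac_start
  E <- A[idx, , drop = FALSE] + (B - A)[idx, , drop = FALSE] * frac_end
  list(start = S, end = E, mid = (S + E) / 2, vec = E - S)
}

#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' @param radius sphere radius (m).
#' @param n number of points (>= 12).
#' @return n x 3 matrix; attribute \code{weight} holds the per-point area.
#' @export
sample_shell <- function(radius, n) {
  if (n < 12) stop("need at least 12 shell samples")
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  P <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  attr(P, "weight") <- rep(4 * pi * radius^2 / n, n)
  P
}

#' Cartesian voxel grid covering the brain sphere
#'
#' @param head a \code{head_model}.
#' @param spacing grid spacing (m); each point carries voxel volume
#'   \code{spacing^3}.
#' @param zmin optional lower z bound to restrict the grid (m).
#' @return list: \code{points} (n x 3), \code{voxel_volume}.
#' @export
sample_brain_grid <- function(head, spacing, zmin = NULL) {
  R <- head$brain_radius
  if (spacing > R / 10) stop("grid spacing must be at most brain radius / 10")
  g1 <- seq(-R + spacing / 2, R, by = spacing)
  gz <- if (is.null(zmin)) g1 else g1[g1 >= zmin]
  pts <- expand.grid(x = g1, y = g1, z = gz)
  keep <- pts$x^2 + pts$y^2 + pts$z^2 < R^2
  list(points = as.matrix(pts[keep, ]), voxel_volume = spacing^3)
}
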