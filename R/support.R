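# Coil support meshes and the divergence-free nodal current basis.

MU0 <- 4e-7 * pi

#' Build a parametric coil support mesh
#'
#' Constructs a triangle mesh for one of the four supported coil surfaces,
#' positioned in the head frame: the support center is at
#' \code{c(0, 0, 0.09)} m and the coil axis points along \code{-z} (into the
#' head). Triangle normals are oriented away from the head.
#'
#' Shapes:
#' \describe{
#'   \item{square}{Flat square of side \code{size} in the plane z = 0.09.}
#'   \item{half_sphere}{Spherical dome of radius \code{size} whose pole is at
#'     z = 0.09 (for the default 0.09 m it is concentric with the head).}
#'   \item{sphere}{Closed sphere of radius \code{size} with pole at z = 0.09.}
#'   \item{hat}{Radially symmetric surface with a spherical-cap crown of
#'     radius \code{size} blended C1 into a flaring annular brim of width
#'     \code{brim_width}. This is a two-parameter stand-in for head-conformal
#'     hat formers; it is an approximation, not a reconstruction of any
#'     MRI-derived surface.}
#' }
#'
#' @param shape one of "square", "half_sphere", "sphere", "hat".
#' @param size side length (square) or radius (others), meters.
#' @param resolution target edge length, meters.
#' @param brim_width hat brim width (m), hat only.
#' @param cap_angle polar half-angle of the hat crown, radians.
#' @return an object of class \code{coil_mesh}: vertices, triangles, areas,
#'   normals, boundary and internal node indices.
#' @export
build_support <- function(shape = c("hat", "square", "half_sphere", "sphere"),
                          size = NULL, resolution = 0.008,
                          brim_width = 0.04, cap_angle = pi / 4) {
  shape <- match.arg(shape)
  if (is.null(size)) {
    size <- switch(shape, square = 0.18, half_sphere = 0.09,
                   sphere = 0.09, hat = 0.095)
  }
  if (!is.finite(size) || size <= 0) {
    stop("degenerate size parameter: support must have positive extent")
  }
  if (!is.finite(resolution) || resolution <= 0) {
    stop("resolution must be positive")
  }
  mesh <- switch(shape,
    square      = mesh_square(size, resolution),
    half_sphere = mesh_half_sphere(size, resolution),
    sphere      = mesh_sphere(size, resolution),
    hat         = mesh_hat(size, brim_width, cap_angle, resolution))
  mesh$shape <- shape
  mesh$params <- list(size = size, resolution = resolution,
                      brim_width = brim_width, cap_angle = cap_angle)
  mesh
}

# --- shape generators -------------------------------------------------------

mesh_square <- function(side, h) {
  n <- max(4L, as.integer(ceiling(side / h)) + 1L)
  xs <- seq(-side / 2, side / 2, length.out = n)
  V <- as.matrix(expand.grid(x = xs, y = xs))
  V <- cbind(V, z = 0.09)
  idx <- function(i, j) (j - 1L) * n + i
  tris <- vector("list", 2L * (n - 1L)^2)
  k <- 1L
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      if ((i + j) %% 2L == 0L) {
        tris[[k]] <- c(a, b, c_); tris[[k + 1L]] <- c(a, c_, d)
      } else {
        tris[[k]] <- c(a, b, d); tris[[k + 1L]] <- c(b, c_, d)
      }
      k <- k + 2L
    }
  }
  finish_mesh(V, do.call(rbind, tris), orient = "z")
}

# rings of nodes (angle-sorted) stitched into triangles
stitch_rings <- function(inner_idx, inner_ang, outer_idx, outer_ang) {
  ni <- length(inner_idx); no <- length(outer_idx)
  tris <- matrix(0L, ni + no, 3L)
  k <- 0L
  i <- 1L; j <- 1L
  # walk around both rings in angle order
  ai <- c(inner_ang, inner_ang[1] + 2 * pi)
  aj <- c(outer_ang, outer_ang[1] + 2 * pi)
  while (i <= ni || j <= no) {
    adv_inner <- if (i > ni) FALSE else if (j > no) TRUE else ai[i + 1L] <= aj[j + 1L]
    k <- k + 1L
    ii <- inner_idx[(i - 1L) %% ni + 1L]
    jj <- outer_idx[(j - 1L) %% no + 1L]
    if (adv_inner) {
      i2 <- inner_idx[i %% ni + 1L]
      tris[k, ] <- c(ii, jj, i2)
      i <- i + 1L
    } else {
      j2 <- outer_idx[j %% no + 1L]
      tris[k, ] <- c(ii, jj, j2)
      j <- j + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# generic surface of revolution: rings at radii rho (>=0), heights z(rho)
mesh_revolution <- function(rho, z, h, close_center = TRUE) {
  stopifnot(length(rho) == length(z))
  V <- NULL; ring_idx <- list(); ring_ang <- list()
  nv <- 0L
  for (k in seq_along(rho)) {
    if (rho[k] < 1e-12) {
      V <- rbind(V, c(0, 0, z[k]))
      ring_idx[[k]] <- nv + 1L; ring_ang[[k]] <- 0
      nv <- nv + 1L
    } else {
      nk <- max(8L, as.integer(round(2 * pi * rho[k] / h)))
      ang <- 2 * pi * (seq_len(nk) - 1L) / nk + (k %% 2L) * pi / nk
      V <- rbind(V, cbind(rho[k] * cos(ang), rho[k] * sin(ang), z[k]))
      ring_idx[[k]] <- nv + seq_len(nk); ring_ang[[k]] <- ang
      nv <- nv + nk
    }
  }
  tris <- NULL
  for (k in seq_len(length(rho) - 1L)) {
    if (length(ring_idx[[k]]) == 1L) {
      ctr <- ring_idx[[k]]
      out <- ring_idx[[k + 1L]]
      no <- length(out)
      tris <- rbind(tris, cbind(ctr, out, out[c(2:no, 1L)]))
    } else if (length(ring_idx[[k + 1L]]) == 1L) {
      ctr <- ring_idx[[k + 1L]]
      inn <- ring_idx[[k]]
      ni <- length(inn)
      tris <- rbind(tris, cbind(ctr, inn[c(2:ni, 1L)], inn))
    } else {
      tris <- rbind(tris, stitch_rings(ring_idx[[k]], ring_ang[[k]],
                                       ring_idx[[k + 1L]], ring_ang[[k + 1L]]))
    }
  }
  list(V = V, tris = tris)
}

mesh_half_sphere <- function(R, h) {
  c0 <- c(0, 0, 0.09 - R)
  nth <- max(4L, as.integer(ceiling((pi / 2) * R / h)))
  th <- seq(0, pi / 2, length.out = nth + 1L)
  m <- mesh_revolution(R * sin(th), c0[3] + R * cos(th), h)
  finish_mesh(m$V, m$tris, orient = "radial", center = c0)
}

mesh_sphere <- function(R, h) {
  c0 <- c(0, 0, 0.09 - R)
  nth <- max(8L, as.integer(ceiling(pi * R / h)))
  th <- seq(0, pi, length.out = nth + 1L)
  m <- mesh_revolution(R * sin(th), c0[3] + R * cos(th), h)
  finish_mesh(m$V, m$tris, orient = "radial", center = c0)
}

# hat height profile: spherical cap crown, C1 quadratic flaring brim
hat_profile <- function(rho, crown_radius, brim_width, cap_angle) {
  z0 <- 0.09 - crown_radius
  rho0 <- crown_radius * sin(cap_angle)
  s0 <- -tan(cap_angle)                 # crown slope at rho0
  kappa <- (-0.2 - s0) / brim_width     # flatten to slope -0.2 at the rim
  ifelse(rho <= rho0,
         z0 + sqrt(pmax(crown_radius^2 - pmin(rho, rho0)^2, 0)),
         z0 + crown_radius * cos(cap_angle) + s0 * (rho - rho0) +
           0.5 * kappa * (rho - rho0)^2)
}

mesh_hat <- function(crown_radius, brim_width, cap_angle, h) {
  rho0 <- crown_radius * sin(cap_angle)
  rho_max <- rho0 + brim_width
  # ring spacing along arc length of the crown, then along the brim
  n1 <- max(3L, as.integer(ceiling(cap_angle * crown_radius / h)))
  n2 <- max(2L, as.integer(ceiling(brim_width * 1.3 / h)))
  rho <- c(crown_radius * sin(seq(0, cap_angle, length.out = n1 + 1L)),
           seq(rho0, rho_max, length.out = n2 + 1L)[-1L])
  z <- hat_profile(rho, crown_radius, brim_width, cap_angle)
  m <- mesh_revolution(rho, z, h)
  finish_mesh(m$V, m$tris, orient = "z")
}

# --- mesh bookkeeping -------------------------------------------------------

tri_geometry <- function(V, tris) {
  p1 <- V[tris[, 1], , drop = FALSE]
  p2 <- V[tris[, 2], , drop = FALSE]
  p3 <- V[tris[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(cr^2))
  list(normals = cr / nn, areas = nn / 2)
}

finish_mesh <- function(V, tris, orient = c("z", "radial"), center = c(0, 0, 0)) {
  orient <- match.arg(orient)
  dimnames(V) <- NULL
  storage.mode(tris) <- "integer"
  g <- tri_geometry(V, tris)
  ctr <- (V[tris[, 1], ] + V[tris[, 2], ] + V[tris[, 3], ]) / 3
  ref <- if (orient == "z") {
    matrix(rep(c(0, 0, 1), each = nrow(tris)), ncol = 3)
  } else {
    d <- sweep(ctr, 2, center)
    d / sqrt(rowSums(d^2))
  }
  flip <- rowSums(g$normals * ref) < 0
  if (any(flip)) {
    tmp <- tris[flip, 2L]
    tris[flip, 2L] <- tris[flip, 3L]
    tris[flip, 3L] <- tmp
    g <- tri_geometry(V, tris)
  }
  if (any(g$areas <= 0) || any(!is.finite(g$areas))) {
    stop("mesh contains degenerate triangles")
  }
  boundary <- boundary_nodes(tris, nrow(V))
  if (length(boundary) == 0L) {
    # closed surface: the lowest vertex serves as the stream-function gauge
    boundary <- which.min(V[, 3])
  }
  internal <- sort(setdiff(seq_len(nrow(V)), boundary))
  structure(list(vertices = V, triangles = tris, normals = g$normals,
                 areas = g$areas, boundary_nodes = boundary,
                 internal_nodes = internal),
            class = "coil_mesh")
}

# vertices incident to edges used by exactly one triangle; for closed surfaces
# (no boundary) the lowest vertex is designated as the stream-function gauge
# node and reported here so that weights remain defined up to that gauge.
boundary_nodes <- function(tris, nv) {
  ed <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  open_edges <- names(cnt)[cnt == 1L]
  if (length(open_edges) == 0L) return(integer(0))
  sort(unique(as.integer(unlist(strsplit(open_edges, " ")))))
}

#' @export
print.coil_mesh <- function(x, ...) {
  cat(sprintf("coil_mesh: %s | %d vertices, %d triangles, %d internal nodes\n",
              x$shape %||% "custom", nrow(x$vertices), nrow(x$triangles),
              length(x$internal_nodes)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nodal finite-element gradients on a triangle mesh
#'
#' Returns, per triangle, the (constant) gradients of the three linear nodal
#' shape functions. Within each triangle the shape functions sum to one and
#' their gradients sum to zero.
#'
#' @param mesh a \code{coil_mesh}.
#' @param area_tol triangles with area below \code{area_tol} times the mean
#'   area are reported as slivers.
#' @return list with \code{grads}: an nt x 3 x 3 array (triangle, local node,
#'   xyz component).
#' @export
nodal_basis <- function(mesh, area_tol = 1e-6) {
  V <- mesh$vertices; tris <- mesh$triangles
  bad <- which(mesh$areas < area_tol * mean(mesh$areas))
  if (length(bad)) {
    stop(sprintf("sliver triangle(s) below area tolerance: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  nt <- nrow(tris)
  grads <- array(0, c(nt, 3, 3))
  n <- mesh$normals
  for (loc in 1:3) {
    j <- tris[, (loc %% 3) + 1L]
    k <- tris[, ((loc + 1L) %% 3) + 1L]
    e <- V[k, , drop = FALSE] - V[j, , drop = FALSE] # edge opposite local node
    # grad N_i = n x e / (2A)
    g <- cbind(n[, 2] * e[, 3] - n[, 3] * e[, 2],
               n[, 3] * e[, 1] - n[, 1] * e[, 3],
               n[, 1] * e[, 2] - n[, 2] * e[, 1]) / (2 * mesh$areas)
    grads[, loc, ] <- g
  }
  list(grads = grads)
}

#' Seed current of one internal node
#'
#' The divergence-free basis current \eqn{J_i = -n \times \nabla N_i}
#' associated with internal node \code{i}: a piecewise-constant tangential
#' field supported on the triangles incident to the node, circulating around
#' it with unit stream-function peak (1 A).
#'
#' @param mesh a \code{coil_mesh}.
#' @param node vertex index (must be an internal node).
#' @return data frame: triangle index and the three current components (A/m).
#' @export
seed_current <- function(mesh, node) {
  if (!(node %in% mesh$internal_nodes)) {
    stop("seed currents are defined for internal nodes only")
  }
  tris <- mesh$triangles
  hit <- which(tris[, 1] == node | tris[, 2] == node | tris[, 3] == node)
  J <- matrix(0, length(hit), 3)
  for (r in seq_along(hit)) {
    t <- hit[r]
    loc <- which(tris[t, ] == node)
    j <- tris[t, (loc %% 3) + 1L]
    k <- tris[t, ((loc + 1L) %% 3) + 1L]
    # J_i = -n x grad N_i = (p_k - p_j) / (2A): the opposite edge vector
    J[r, ] <- (mesh$vertices[k, ] - mesh$vertices[j, ]) / (2 * mesh$areas[t])
  }
  data.frame(triangle = hit, Jx = J[, 1], Jy = J[, 2], Jz = J[, 3])
}

#' Stream function and surface current for a weight vector
#'
#' Given weights over the internal nodes, returns the nodal stream-function
#' values (zero on the boundary), the per-triangle surface current
#' \eqn{I = -n \times \nabla Sr} (A/m), and its maximum magnitude.
#'
#' @param mesh a \code{coil_mesh}.
#' @param lambda numeric vector over \code{mesh$internal_nodes} (A).
#' @return list: \code{Sr} (per vertex, A), \code{I} (nt x 3, A/m),
#'   \code{max_I}.
#' @export
stream_function <- function(mesh, lambda) {
  ni <- length(mesh$internal_nodes)
  if (length(lambda) != ni) {
    stop(sprintf("lambda has length %d, expected %d internal nodes",
                 length(lambda), ni))
  }
  Sr <- numeric(nrow(mesh$vertices))
  Sr[mesh$internal_nodes] <- lambda
  I <- triangle_currents(mesh, Sr)
  list(Sr = Sr, I = I, max_I = if (nrow(I)) max(sqrt(rowSums(I^2))) else 0)
}

# per-triangle current from full nodal stream function values
triangle_currents <- function(mesh, Sr) {
  tris <- mesh$triangles
  V <- mesh$vertices
  I <- matrix(0, nrow(tris), 3)
  for (loc in 1:3) {
    j <- tris[, (loc %% 3) + 1L]
    k <- tris[, ((loc + 1L) %% 3) + 1L]
    e <- V[k, , drop = FALSE] - V[j, , drop = FALSE]
    I <- I + Sr[tris[, loc]] * e / (2 * mesh$areas)
  }
  I
}

# map lambda (internal nodes) to full nodal vector
full_stream <- function(mesh, lambda) {
  Sr <- numeric(nrow(mesh$vertices))
  Sr[mesh$internal_nodes] <- lambda
  Sr
}

# current elements for field evaluation: per triangle, `order` point elements
# carrying vector J_t * A_t / order. order 3 uses edge midpoints, 1 centroid.
current_elements <- function(mesh, order = 3) {
  V <- mesh$vertices; tris <- mesh$triangles
  nt <- nrow(tris)
  p1 <- V[tris[, 1], , drop = FALSE]
  p2 <- V[tris[, 2], , drop = FALSE]
  p3 <- V[tris[, 3], , drop = FALSE]
  if (order == 1) {
    pos <- (p1 + p2 + p3) / 3
    tri_of <- seq_len(nt)
  } else if (order == 3) {
    pos <- rbind((p1 + p2) / 2, (p2 + p3) / 2, (p3 + p1) / 2)
    tri_of <- rep(seq_len(nt), 3)
  } else stop("element quadrature order must be 1 or 3")
  list(pos = pos, tri = tri_of, weight = mesh$areas[tri_of] / order)
}

#' Drive waveform
#'
#' Time-harmonic drive current scale \eqn{p(t) = sin(\omega t)}. Reported
#' fields are amplitudes at the peak of the cycle.
#'
#' @param freq_hz drive frequency, default 3000 Hz.
#' @export
drive_waveform <- function(freq_hz = 3000) {
  if (freq_hz <= 0) stop("drive frequency must be positive")
  list(omega = 2 * pi * freq_hz, freq_hz = freq_hz)
}
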