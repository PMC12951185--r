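# Magnetic energy of surface currents, inductance and resistance of windings.

#' Magnetic energy matrix of the surface-current basis
#'
#' Assembles the symmetric positive-definite matrix \eqn{W} over internal
#' nodes such that the stored magnetic energy of the current with weights
#' \code{lambda} at the drive peak is \eqn{W(\lambda) = \lambda^T W \lambda}
#' (joules):
#' \deqn{W(\lambda) = \frac{\mu_0}{8\pi}\int_\Omega\int_\Omega
#'   \frac{I(r;\lambda) \cdot I(r';\lambda)}{\|r - r'\|}\,dA\,dA'.}
#' The double surface integral over each triangle pair uses an analytic inner
#' (single-layer potential) integral and a 3-point interior outer rule, which
#' is singularity-safe for self and adjacent pairs.
#'
#' @param mesh a \code{coil_mesh}.
#' @return list: \code{W} (n_internal x n_internal, J per A^2), \code{K}
#'   (triangle-pair kernel, retained for reuse).
#' @export
energy_matrix <- function(mesh) {
  tris <- mesh$triangles
  V <- mesh$vertices
  verts <- cbind(V[tris[, 1], , drop = FALSE], V[tris[, 2], , drop = FALSE],
                 V[tris[, 3], , drop = FALSE])
  K <- tri_pair_kernel_cpp(verts, mesh$areas)
  if (any(!is.finite(K))) {
    bad <- which(!is.finite(K), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite energy kernel entry for triangle pair (%d, %d)",
                 bad[1], bad[2]))
  }
  internal <- mesh$internal_nodes
  ni <- length(internal)
  nt <- nrow(tris)
  # J[, t] components of seed current of each internal node on triangle t
  col_of <- integer(nrow(V)); col_of[internal] <- seq_len(ni)
  Jx <- matrix(0, ni, nt); Jy <- matrix(0, ni, nt); Jz <- matrix(0, ni, nt)
  for (loc in 1:3) {
    nodes <- tris[, loc]
    keep <- which(col_of[nodes] > 0L)
    j <- tris[keep, (loc %% 3) + 1L]
    k <- tris[keep, ((loc + 1L) %% 3) + 1L]
    Jt <- (V[k, , drop = FALSE] - V[j, , drop = FALSE]) / (2 * mesh$areas[keep])
    rows <- col_of[nodes[keep]]
    idx <- cbind(rows, keep)
    Jx[idx] <- Jx[idx] + Jt[, 1]
    Jy[idx] <- Jy[idx] + Jt[, 2]
    Jz[idx] <- Jz[idx] + Jt[, 3]
  }
  W <- Jx %*% K %*% t(Jx) + Jy %*% K %*% t(Jy) + Jz %*% K %*% t(Jz)
  W <- (W + t(W)) / 2 * (MU0 / (8 * pi))
  list(W = W, K = K)
}

#' Stored magnetic energy of a weight vector
#' @param em result of \code{\link{energy_matrix}} (or the matrix itself)
#' @param lambda weights (A)
#' @return energy in joules at the drive peak
#' @export
current_energy <- function(em, lambda) {
  W <- if (is.list(em)) em$W else em
  drop(crossprod(lambda, W %*% lambda))
}

#' Inductance of a discrete winding
#'
#' Neumann double line integral over all segment pairs of the winding
#' (filament centerlines), plus the external partial self-inductance
#' \eqn{(\mu_0/2\pi) l (\ln(2l/a) - 1)} of each straight segment of a round
#' wire of radius \code{wire_radius}.
#'
#' @param winding a \code{winding_set}, a list of polylines, or one polyline.
#' @param wire_radius wire radius (m); for rectangular cross-sections use the
#'   radius of equal area.
#' @param max_seg segment subdivision length (m).
#' @param use_serial_path if TRUE and a serial path is available, the path is
#'   used (includes inter-loop connections); otherwise loops are summed as
#'   closed turns.
#' @return inductance in henries.
#' @export
winding_inductance <- function(winding, wire_radius, max_seg = 0.004,
                               use_serial_path = TRUE) {
  if (wire_radius <= 0) {
    stop("wire radius must be positive: the filament self-term diverges")
  }
  polys <- if (inherits(winding, "winding_set")) {
    if (use_serial_path && !is.null(winding$serial_path)) {
      list(winding$serial_path)
    } else {
      lapply(winding$loops, `[[`, "path")
    }
  } else if (is.matrix(winding)) list(winding) else winding
  S <- NULL; E <- NULL
  for (P in polys) {
    sg <- subdivide_polyline(P, max_seg)
    S <- rbind(S, sg$start); E <- rbind(E, sg$end)
  }
  neumann_inductance_cpp(S, E, wire_radius)
}

#' Stored pulse energy of a coil
#' @param L inductance (H)
#' @param I_peak peak current (A)
#' @return \eqn{W = L I^2 / 2} in joules
#' @export
pulse_energy <- function(L, I_peak) {
  if (L <= 0) stop("inductance must be positive")
  0.5 * L * I_peak^2
}

#' DC resistance of the winding wire
#'
#' \eqn{R = \rho \ell / A}. The DC value is reported; a warning is issued when
#' the wire diameter exceeds twice the skin depth at the drive frequency,
#' where the true AC resistance is appreciably higher.
#'
#' @param length wire length (m)
#' @param cross_section conductor cross-sectional area (m^2)
#' @param resistivity conductor resistivity (Ohm m); copper at 20 C default
#' @param freq_hz drive frequency for the skin-depth advisory (Hz)
#' @export
estimate_resistance <- function(length, cross_section,
                                resistivity = 1.68e-8, freq_hz = 3000) {
  if (cross_section <= 0) stop("cross-section must be positive")
  if (length < 0) stop("length must be non-negative")
  skin <- sqrt(resistivity / (pi * freq_hz * MU0))
  diam <- 2 * sqrt(cross_section / pi)
  if (diam > 2 * skin) {
    warning(sprintf(
      "wire diameter %.1f mm exceeds twice the skin depth %.2f mm at %g Hz; DC value reported",
      diam * 1000, skin * 1000, freq_hz))
  }
  resistivity * length / cross_section
}

#' Total wire length of a winding
#' @param winding a \code{winding_set} or list of polylines
#' @param use_serial_path measure the serial path if present
#' @export
wire_length <- function(winding, use_serial_path = TRUE) {
  polys <- if (inherits(winding, "winding_set")) {
    if (use_serial_path && !is.null(winding$serial_path)) {
      list(winding$serial_path)
    } else lapply(winding$loops, `[[`, "path")
  } else if (is.matrix(winding)) list(winding) else winding
  sum(vapply(polys, function(P) {
    sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
  }, 0))
}
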