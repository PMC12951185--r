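# Coil evaluation, shell field maps, probe averaging, fixtures.

# field function closure for either a lambda-on-mesh current or a winding
coil_field_fun <- function(coil, head, current = 1) {
  if (inherits(coil, "winding_set")) {
    paths <- lapply(coil$loops, `[[`, "path")
    cur <- rep(current, length(paths))
    function(points) efield_wire_points(paths, cur, head, points)
  } else if (is.list(coil) && !is.null(coil$mesh) && !is.null(coil$lambda)) {
    function(points) {
      efield_lambda_points(coil$mesh, head, coil$lambda * current, points)
    }
  } else stop("coil must be a winding_set or list(mesh=, lambda=)")
}

# field-magnitude evaluation on a fine brain grid with coarse-pass pruning:
# a coarse grid locates the candidate suprathreshold region (relative to the
# peak); the fine grid is evaluated only inside its padded bounding box.
# Returns magnitudes on the fine grid restricted to the box plus the
# guarantee bound from the coarse pass.
pruned_grid_magnitudes <- function(fieldfun, head, spacing,
                                   coarse_spacing = 0.004, frac = 0.35,
                                   pad = 0.008) {
  cg <- sample_brain_grid(head, coarse_spacing)
  Ec <- sqrt(rowSums(fieldfun(cg$points)^2))
  peak <- max(Ec)
  sel <- Ec >= frac * peak
  box_lo <- apply(cg$points[sel, , drop = FALSE], 2, min) - pad
  box_hi <- apply(cg$points[sel, , drop = FALSE], 2, max) + pad
  fg <- sample_brain_grid(head, spacing)
  inbox <- fg$points[, 1] >= box_lo[1] & fg$points[, 1] <= box_hi[1] &
           fg$points[, 2] >= box_lo[2] & fg$points[, 2] <= box_hi[2] &
           fg$points[, 3] >= box_lo[3] & fg$points[, 3] <= box_hi[3]
  pts <- fg$points[inbox, , drop = FALSE]
  Ef <- sqrt(rowSums(fieldfun(pts)^2))
  list(Emag = Ef, grid = list(points = pts, voxel_volume = fg$voxel_volume),
       outside_bound = frac * peak * 1.35) # coarse-grid safety information
}

#' Evaluate a coil: full merit report
#'
#' Computes the scale-independent half-maximum metrics (for \code{alpha} and
#' \code{sqrt(2)}), the drive scaling that puts the target field at the design
#' depth, the stored energy at that drive, depth-swept volume/spread/energy
#' curves, and scalp exposure metrics.
#'
#' @param coil a \code{winding_set} or \code{list(mesh =, lambda =)}.
#' @param head a \code{head_model}.
#' @param spec a \code{design_spec}.
#' @param grid_spacing brain grid spacing (m) for the volume metrics.
#' @param depth_grid depths for the swept curves (m).
#' @param n_scalp scalp sample count.
#' @param fine use coarse-pass pruning to evaluate on the fine grid.
#' @param energy_matrix precomputed \code{\link{energy_matrix}} for lambda
#'   coils (computed on demand otherwise).
#' @param wire_radius wire radius for winding inductance (defaults to the
#'   equal-area radius of the winding cross-section).
#' @return object of class \code{merit_report}.
#' @export
evaluate_coil <- function(coil, head, spec, grid_spacing = 0.002,
                          depth_grid = NULL, n_scalp = 2000, fine = FALSE,
                          energy_matrix = NULL, wire_radius = NULL) {
  ff <- coil_field_fun(coil, head)
  # line profile at 0.1 mm
  d <- seq(0, head$brain_radius - head$C - 1e-6, by = 1e-4)
  lp <- depth_point(head, d)
  keep <- sqrt(rowSums(lp^2)) < head$brain_radius
  d <- d[keep]; lp <- lp[keep, , drop = FALSE]
  El <- ff(lp)
  Et <- drop(El %*% head$t_hat)
  sp <- sample_shell(head$brain_radius * 0.9995, 2500)
  ax <- head$r_c / sqrt(sum(head$r_c^2))
  sp <- sp[drop(sp %*% ax) > 0, , drop = FALSE]
  surface_peak <- max(sqrt(rowSums(ff(sp)^2)))
  if (fine) {
    pg <- pruned_grid_magnitudes(ff, head, grid_spacing)
    profiles <- list(grid = pg$grid, Emag = pg$Emag, d = d, Et = Et,
                     Eline_mag = sqrt(rowSums(El^2)),
                     surface_peak = surface_peak)
  } else {
    grid <- sample_brain_grid(head, grid_spacing, zmin = 0)
    Eg <- ff(grid$points)
    profiles <- list(grid = grid, Emag = sqrt(rowSums(Eg^2)), d = d, Et = Et,
                     Eline_mag = sqrt(rowSums(El^2)),
                     surface_peak = surface_peak)
  }
  hm2 <- half_max_metrics(profiles, spec$alpha)
  hmr2 <- half_max_metrics(profiles, sqrt(2))
  # drive scaling for E_targ at the design depth
  Et_at <- stats::approx(d, Et, xout = spec$depth, rule = 2)$y
  unit_scale <- if (Et_at > 0) spec$E_targ / Et_at else NA_real_
  # energy at unit drive
  if (inherits(coil, "winding_set")) {
    wr <- wire_radius %||% sqrt(prod(coil$wire_cross_section) / pi)
    L <- winding_inductance(coil, wr)
    energy_unit <- 0.5 * L
    electrical <- list(
      L = L,
      wire_length = wire_length(coil),
      R = suppressWarnings(estimate_resistance(
        wire_length(coil), prod(coil$wire_cross_section))))
  } else {
    em <- energy_matrix %||% energy_matrix(coil$mesh)
    energy_unit <- current_energy(em, coil$lambda)
    electrical <- NULL
  }
  if (is.null(depth_grid)) {
    depth_grid <- seq(0.002, min(0.03, head$brain_radius - head$C), by = 0.002)
  }
  swept <- depth_swept_metrics(profiles, energy_unit, spec, depth_grid)
  # scalp metrics at the design drive
  scalp_pts <- sample_shell(head$outer_radius * 0.995, n_scalp)
  Es <- sqrt(rowSums(ff(scalp_pts)^2)) * unit_scale
  sm <- scalp_metrics(Es, attr(scalp_pts, "weight"), spec$E_targ)
  structure(list(
    V = hm2$V, d = hm2$d, S = hm2$S, peak_unit = hm2$peak,
    half_max = list(alpha = hm2, sqrt2 = hmr2),
    drive_scale = unit_scale,
    W = unit_scale^2 * energy_unit,
    energy_unit = energy_unit,
    peak_ratio = unit_scale * hm2$peak / spec$E_targ,
    scalp = sm, swept = swept, electrical = electrical,
    spec = spec), class = "merit_report")
}

#' @export
print.merit_report <- function(x, ...) {
  cat(sprintf("merit_report: V_1/a = %.2f cm^3, d_1/a = %.2f cm, S_1/a = %.2f cm^2\n",
              x$V * 1e6, x$d * 100, x$S * 1e4))
  cat(sprintf("  drive for E_targ at design depth: %.0f A-equiv, W = %.1f J\n",
              x$drive_scale, x$W))
  if (!is.null(x$electrical)) {
    cat(sprintf("  L = %.2f uH, wire %.1f m, R(DC) = %.1f mOhm\n",
                x$electrical$L * 1e6, x$electrical$wire_length,
                x$electrical$R * 1000))
  }
  cat(sprintf("  scalp: area >= E_targ %.1f cm^2, peak ratio %.2f\n",
              x$scalp$area * 1e4, x$scalp$peak_ratio))
  invisible(x)
}

#' Shell field maps with the half-maximum iso-region
#'
#' @param coil coil object (see \code{\link{evaluate_coil}}).
#' @param head a \code{head_model}.
#' @param radii shell radii (m).
#' @param n samples per shell.
#' @param iso_alpha iso-region divisor (sqrt(2) outlines the region above
#'   peak/sqrt(2)).
#' @return list per radius: points, E (n x 3), Emag, iso (logical mask).
#' @export
shell_maps <- function(coil, head, radii = c(0.07, 0.06), n = 2000,
                       iso_alpha = sqrt(2)) {
  ff <- coil_field_fun(coil, head)
  out <- list()
  for (r in radii) {
    if (r > head$brain_radius) stop("shell radius must be inside the brain")
    P <- sample_shell(r * 0.999, n)
    E <- ff(P)
    m <- sqrt(rowSums(E^2))
    out[[sprintf("r%.0fmm", r * 1000)]] <-
      list(radius = r, points = P, E = E, Emag = m,
           iso = m >= max(m) / iso_alpha)
  }
  out
}

#' Probe reading: average directional field along a probe base
#'
#' Models a triangle-probe measurement: the mean of \code{E . direction} over
#' a straight base segment of the given width centered at the point.
#'
#' @param fieldfun function(points) -> n x 3 field matrix.
#' @param point base center (3-vector).
#' @param direction base direction (normalized internally).
#' @param width base width (m); defaults per the 4 and 5 mm probes.
#' @param n_quad quadrature points along the base.
#' @export
probe_average <- function(fieldfun, point, direction, width = 0.004,
                          n_quad = 21) {
  u <- direction / sqrt(sum(direction^2))
  if (width <= 0) return(sum(fieldfun(matrix(point, 1)) * u))
  s <- seq(-width / 2, width / 2, length.out = n_quad)
  P <- t(sapply(s, function(si) point + si * u))
  mean(drop(fieldfun(P) %*% u))
}

#' Export the primary E-field on a voxel grid as NIfTI
#'
#' Samples the free-space (primary) E-field per unit drive on a Cartesian
#' grid and stores it as a 4D NIfTI volume (x, y, z, component), with the
#' affine mapping voxel indices to meters.
#'
#' @param coil coil object.
#' @param head a \code{head_model} (for the drive frequency).
#' @param file output path (.nii).
#' @param box list(lo, hi) corners in meters.
#' @param spacing voxel edge (m).
#' @return the written array (invisibly), with attribute \code{affine}.
#' @export
export_nifti_grid <- function(coil, head, file,
                              box = list(lo = c(-0.08, -0.08, 0),
                                         hi = c(0.08, 0.08, 0.08)),
                              spacing = 0.005) {
  if (spacing <= 0) stop("spacing must be positive")
  gx <- seq(box$lo[1], box$hi[1], by = spacing)
  gy <- seq(box$lo[2], box$hi[2], by = spacing)
  gz <- seq(box$lo[3], box$hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  E <- primary_field(coil, head, pts)
  arr <- array(0, c(length(gx), length(gy), length(gz), 3))
  for (k in 1:3) arr[, , , k] <- array(E[, k], c(length(gx), length(gy), length(gz)))
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4] <- c(gx[1], gy[1], gz[1])
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, file)
  attr(arr, "affine") <- affine
  invisible(arr)
}

# free-space primary field -dA/dt (peak amplitude) of a coil at arbitrary
# points (no conductor): used for voxel-grid exports consumed by FEM tools.
primary_field <- function(coil, head, points, current = 1) {
  points <- as_points(points)
  if (inherits(coil, "winding_set")) {
    pos <- NULL; vec <- NULL
    for (l in coil$loops) {
      sg <- subdivide_polyline(close_loop(l$path), 0.002)
      pos <- rbind(pos, sg$mid); vec <- rbind(vec, sg$vec * current)
    }
  } else {
    Sr <- full_stream(coil$mesh, coil$lambda * current)
    J <- triangle_currents(coil$mesh, Sr)
    el <- current_elements(coil$mesh, 3)
    pos <- el$pos; vec <- J[el$tri, , drop = FALSE] * el$weight
  }
  E <- matrix(0, nrow(points), 3)
  for (k in seq_len(nrow(pos))) {
    a <- sqrt(colSums((t(points) - pos[k, ])^2))
    E <- E - outer(1 / a, vec[k, ])
  }
  E * (1e-7 * head$omega)
}

#' Canonical test fixtures
#'
#' Deterministic reference inputs: \code{"figure8"} — a two-loop circular
#' figure-8 coil with 70 mm loop diameter at the default coil plane;
#' \code{"hat_coarse"}/\code{"hat_fine"}/\code{"square_coarse"} — support
#' meshes; \code{"synthetic_stream"} — a stream function with a figure-8
#' core, two biasing and four cancellation extrema on a coarse hat mesh.
#'
#' @param which fixture name.
#' @export
make_fixtures <- function(which = c("figure8", "hat_coarse", "hat_fine",
                                    "square_coarse", "synthetic_stream")) {
  which <- match.arg(which)
  if (which == "figure8") {
    th <- seq(0, 2 * pi, length.out = 121)
    r <- 0.035
    right <- cbind(r * cos(th) + r, r * sin(th), 0.09)
    left <- cbind(r * cos(-th) - r, r * sin(-th), 0.09) # opposite sense
    loops <- list(list(path = right, level = 1, basin = 1L,
                       region = "figure8", layer = 0L, sense = 1),
                  list(path = left, level = -1, basin = 2L,
                       region = "figure8", layer = 0L, sense = -1))
    return(new_winding_set(loops, serial_path = connect_serial(loops),
                           wire_cross_section = c(0.002, 0.002)))
  }
  if (which == "hat_coarse") return(build_support("hat", resolution = 0.012))
  if (which == "hat_fine") return(build_support("hat", resolution = 0.006))
  if (which == "square_coarse") {
    return(build_support("square", resolution = 0.012))
  }
  # synthetic_stream: 2 + 2 + 4 extrema on a coarse hat
  mesh <- build_support("hat", resolution = 0.012)
  V <- mesh$vertices
  bump <- function(cx, cy, s, amp) {
    amp * exp(-((V[, 1] - cx)^2 + (V[, 2] - cy)^2) / (2 * s^2))
  }
  # centers sit slightly off the mesh symmetry axes so every lobe has a
  # unique extremal node
  Sr <- bump(0.0183, 0.0011, 0.011, 1) + bump(-0.0177, 0.0007, 0.011, -0.82) +
    bump(0.0683, 0.0009, 0.013, 0.45) + bump(-0.0677, 0.0013, 0.013, -0.45) +
    bump(0.0203, 0.0443, 0.009, -0.18) + bump(-0.0197, 0.0437, 0.009, 0.18) +
    bump(0.0197, -0.0443, 0.009, -0.18) + bump(-0.0203, -0.0437, 0.009, 0.18)
  Sr[mesh$boundary_nodes] <- 0
  list(mesh = mesh, Sr = Sr, lambda = Sr[mesh$internal_nodes])
}

#' Read and validate a pipeline configuration file
#'
#' Configurations are nested key/value YAML; missing keys fall back to the
#' packaged defaults (\code{inst/extdata/default_config.yaml}), unknown keys
#' and non-positive dimensions are rejected.
#'
#' @param file path to a YAML configuration, or NULL for the defaults.
#' @return nested list with sections head, design, support, winding.
#' @export
read_config <- function(file = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "focalcoil"))
  cfg <- defaults
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    for (sec in names(user)) {
      if (!sec %in% names(defaults)) stop("unknown config section: ", sec)
      for (k in names(user[[sec]])) {
        if (!k %in% names(defaults[[sec]])) {
          stop(sprintf("unknown config key: %s.%s", sec, k))
        }
        cfg[[sec]][[k]] <- user[[sec]][[k]]
      }
    }
  }
  with(cfg$head, {
    if (!(brain_radius > 0 && brain_radius < outer_radius)) {
      stop("config: need 0 < brain_radius < outer_radius")
    }
  })
  if (cfg$design$alpha <= 1) stop("config: alpha must exceed 1")
  if (cfg$design$E_targ <= 0) stop("config: E_targ must be positive")
  if (cfg$winding$wire_width <= 0 || cfg$winding$wire_height <= 0) {
    stop("config: wire dimensions must be positive")
  }
  cfg
}
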