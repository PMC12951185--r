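# Figures of merit: stimulated volume, stimulation depth, spread,
# half-maximum metrics, depth-swept curves, scalp exposure.

#' Design specification
#'
#' Parameters of a coil design target. The absolute target field strength
#' \code{E_targ} is a convention (energies scale with its square); 100 V/m is
#' the package default.
#'
#' @param E_targ target field strength at the design depth (V/m).
#' @param alpha peak-cap ratio: fields above \code{alpha * E_targ} anywhere in
#'   the brain are inadmissible (> 1).
#' @param depth target stimulation depth below the cortical surface (m).
#' @param energy_budget maximum stored magnetic energy (J).
#' @param wire_width wire width for the wire-fit constraint (m).
#' @param wire_height wire height (m).
#' @param M number of equispaced contour intervals for winding extraction.
#' @export
design_spec <- function(E_targ = 100, alpha = 2, depth = 0.0131,
                        energy_budget = 200, wire_width = 0.003,
                        wire_height = 0.003, M = 12) {
  stopifnot(alpha > 1, E_targ > 0, depth > 0, energy_budget > 0)
  structure(list(E_targ = E_targ, alpha = alpha, depth = depth,
                 energy_budget = energy_budget, wire_width = wire_width,
                 wire_height = wire_height, M = M),
            class = "design_spec")
}

#' Stimulated volume
#'
#' Volume of the brain region where the field magnitude meets or exceeds the
#' threshold (ties count as stimulated).
#'
#' @param Emag field magnitudes at brain-grid points (V/m).
#' @param grid result of \code{\link{sample_brain_grid}} (or a voxel volume).
#' @param E_targ threshold (V/m).
#' @return volume in m^3
#' @export
stimulated_volume <- function(Emag, grid, E_targ) {
  vv <- if (is.list(grid)) grid$voxel_volume else grid
  if (length(Emag) == 0) stop("empty brain grid")
  sum(Emag >= E_targ) * vv
}

#' Stimulation depth along the coil axis
#'
#' The depth of the deepest point on the depth line where the directional
#' field component \code{E . t_hat} meets or exceeds the threshold, with
#' linear interpolation at the threshold crossing. Returns 0 when no point is
#' above threshold.
#'
#' @param Et directional field component at the line samples (V/m).
#' @param d depths of the samples below the cortical surface (m), increasing.
#' @param E_targ threshold (V/m).
#' @export
stimulation_depth <- function(Et, d, E_targ) {
  above <- Et >= E_targ
  if (!any(above)) return(0)
  i <- max(which(above))
  if (i == length(d) || Et[i] == E_targ) return(d[i])
  # interpolate to the crossing below sample i
  frac <- (Et[i] - E_targ) / (Et[i] - Et[i + 1])
  d[i] + frac * (d[i + 1] - d[i])
}

#' Spread of the stimulated region
#'
#' Average transverse area \eqn{S = V / d_M} of the suprathreshold region.
#'
#' @param V stimulated volume (m^3)
#' @param d_M stimulation depth (m)
#' @return spread in m^2, or NA with a message when d_M = 0
#' @export
spread <- function(V, d_M) {
  if (d_M <= 0) {
    return(NA_real_)
  }
  V / d_M
}

# helper: field of a source at brain grid + depth line + cortical surface.
# `fieldfun(points)` must return an n x 3 matrix of E vectors. The peak brain
# field sits on the cortical surface, between voxel centers, so the surface is
# sampled separately for the peak reference.
eval_field_profiles <- function(fieldfun, head, grid_spacing = 0.002,
                                line_step = 1e-4, grid = NULL,
                                n_surface = 2500) {
  if (is.null(grid)) grid <- sample_brain_grid(head, grid_spacing)
  Eg <- fieldfun(grid$points)
  d <- seq(0, head$brain_radius - 1e-6, by = line_step)
  lp <- depth_point(head, d)
  # clamp to inside brain
  keep <- sqrt(rowSums(lp^2)) < head$brain_radius
  d <- d[keep]; lp <- lp[keep, , drop = FALSE]
  El <- fieldfun(lp)
  surface_peak <- if (n_surface > 0) {
    sp <- sample_shell(head$brain_radius * 0.9995, n_surface)
    ax <- head$r_c / sqrt(sum(head$r_c^2))
    sp <- sp[drop(sp %*% ax) > 0, , drop = FALSE] # hemisphere facing the coil
    max(sqrt(rowSums(fieldfun(sp)^2)))
  } else 0
  list(grid = grid, Emag = sqrt(rowSums(Eg^2)),
       d = d, Et = drop(El %*% head$t_hat),
       Eline_mag = sqrt(rowSums(El^2)), surface_peak = surface_peak)
}

#' Half-maximum (1/alpha) focality metrics
#'
#' Scale-independent metrics: the threshold is the peak brain field magnitude
#' divided by \code{alpha}. Volume uses the field magnitude; depth uses the
#' directional component along the depth line (a configuration switch allows
#' magnitude-based depth for sensitivity checks).
#'
#' @param profiles result of \code{eval_field_profiles}-style list with
#'   \code{Emag}, \code{grid}, \code{d}, \code{Et}, \code{Eline_mag}.
#' @param alpha threshold divisor (2 for half-maximum).
#' @param depth_uses_magnitude use |E| instead of E.t for the depth criterion.
#' @return list: V, d, S (m^3, m, m^2), peak (V/m).
#' @export
half_max_metrics <- function(profiles, alpha = 2, depth_uses_magnitude = FALSE) {
  peak <- max(max(profiles$Emag), profiles$surface_peak %||% 0)
  if (peak <= 0) stop("field is identically zero")
  thr <- peak / alpha
  V <- stimulated_volume(profiles$Emag, profiles$grid, thr)
  comp <- if (depth_uses_magnitude) profiles$Eline_mag else profiles$Et
  d <- stimulation_depth(comp, profiles$d, thr)
  list(V = V, d = d, S = spread(V, d), peak = peak)
}

#' Depth-swept volume, spread, and energy curves
#'
#' For each target depth the drive is scaled so the directional field at that
#' depth equals \code{E_targ}; the stimulated volume, spread, and energy at
#' that scaling are recorded. Depths whose scaling pushes the peak brain field
#' above \code{alpha * E_targ} are marked unreachable, as are depths where the
#' directional field is non-positive.
#'
#' @param profiles field profiles of the coil at unit drive.
#' @param energy_unit stored energy at unit drive (J).
#' @param spec a \code{design_spec}.
#' @param depths depth grid (m).
#' @return data frame: d, scale, V, S, W, reachable.
#' @export
depth_swept_metrics <- function(profiles, energy_unit, spec, depths) {
  Et_at <- stats::approx(profiles$d, profiles$Et, xout = depths, rule = 2)$y
  peak_unit <- max(max(profiles$Emag), profiles$surface_peak %||% 0)
  out <- data.frame(d = depths, scale = NA_real_, V = NA_real_, S = NA_real_,
                    W = NA_real_, reachable = FALSE)
  for (i in seq_along(depths)) {
    if (Et_at[i] <= 0) next
    sc <- spec$E_targ / Et_at[i]
    out$scale[i] <- sc
    reach <- sc * peak_unit <= spec$alpha * spec$E_targ + 1e-9
    out$reachable[i] <- reach
    out$V[i] <- stimulated_volume(profiles$Emag, profiles$grid,
                                  spec$E_targ / sc)
    out$S[i] <- spread(out$V[i], depths[i])
    out$W[i] <- sc^2 * energy_unit
  }
  out
}

#' Scalp exposure metrics
#'
#' Area of the outer-sphere (scalp) surface where the field magnitude meets or
#' exceeds the target field, and the peak scalp field relative to the target.
#'
#' @param Emag field magnitudes at scalp samples.
#' @param weights per-sample area weights (m^2).
#' @param E_targ target field (V/m).
#' @return list: area (m^2), peak_ratio.
#' @export
scalp_metrics <- function(Emag, weights, E_targ) {
  list(area = sum(weights[Emag >= E_targ]),
       peak_ratio = max(Emag) / E_targ)
}
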