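# Optimal surface currents: minimum stored energy subject to target-field
# equalities, peak-field caps, focality bounds outside a candidate region,
# and optional wire-fit constraints.
#
# The solver minimizes the quadratic energy lambda' W lambda over the span of
# energy-whitened field modes (generalized eigenvectors of the field Gram
# matrix against W). Magnitude constraints ||E|| <= b are imposed as 16
# half-plane constraints in the tangent plane of each constrained point (the
# induced field has no radial component), activated lazily so the active-set
# QP stays small. The 16-gon is an edge-tangent over-approximation: feasible
# fields satisfy ||E|| <= b / cos(pi/16).
#
# Two equalities pin the field profile: the directional field at the target
# depth equals E_targ, and the directional field at the cortical point under
# the coil equals alpha * E_targ. The second pin makes the peak-field cap
# bind, which aligns the half-maximum threshold (peak/alpha) with the
# focality bound E_targ outside the candidate region; without it the
# energy-minimal current leaves the cap slack and the half-maximum region
# spills beyond the candidate region.

COS16 <- cos(pi / 16)

# --- constraint sampling ----------------------------------------------------

# Sample points where field magnitude bounds are enforced: the cortical
# surface (region facing the coil) plus two interior guard shells.
design_samples <- function(head, n_cortex = 1200, n_inner = 300) {
  Rb <- head$brain_radius
  ax <- -head$n_c # outward axis (toward coil)
  keepcap <- function(P, frac) {
    proj <- drop(P %*% ax) / sqrt(rowSums(P^2))
    P[proj > frac, , drop = FALSE]
  }
  rbind(keepcap(sample_shell(Rb * 0.999, n_cortex), -0.1),
        keepcap(sample_shell(Rb * 0.9, n_inner), 0.1),
        keepcap(sample_shell(Rb * 0.75, n_inner), 0.2))
}

# in-plane coordinates of points transverse to the depth line: u along the
# target direction t_hat, v along n_c x t_hat
transverse_coords <- function(points, head) {
  d <- sweep(points, 2, head$r_c)
  along <- drop(d %*% head$n_c)
  perp <- d - outer(along, head$n_c)
  u <- drop(perp %*% head$t_hat)
  e2 <- c(head$n_c[2] * head$t_hat[3] - head$n_c[3] * head$t_hat[2],
          head$n_c[3] * head$t_hat[1] - head$n_c[1] * head$t_hat[3],
          head$n_c[1] * head$t_hat[2] - head$n_c[2] * head$t_hat[1])
  v <- drop(perp %*% e2)
  cbind(u = u, v = v)
}

# transverse distance from the depth line
axis_distance <- function(points, head) {
  tc <- transverse_coords(points, head)
  sqrt(rowSums(tc^2))
}

#' Assemble a reusable design problem
#'
#' Precomputes the energy matrix, the field operator at the constraint sample
#' points, the target and cortical-apex points, and the energy-whitened field
#' modes used to reduce the optimization dimension.
#'
#' @param mesh a \code{coil_mesh}.
#' @param head a \code{head_model}.
#' @param spec a \code{design_spec}.
#' @param n_modes number of field modes retained (default \code{min(250, n)}).
#' @param n_cortex,n_inner constraint sample counts.
#' @return a \code{design_problem} list.
#' @export
design_problem <- function(mesh, head, spec, n_modes = NULL,
                           n_cortex = 1200, n_inner = 300) {
  em <- energy_matrix(mesh)
  samples <- design_samples(head, n_cortex, n_inner)
  target <- depth_point(head, spec$depth)
  # cortical point nearest the coil center
  apex <- matrix(head$r_c / sqrt(sum(head$r_c^2)) *
                   head$brain_radius * 0.9995, 1, 3)
  op <- efield_basis_operator(mesh, head, rbind(target, apex, samples))
  ni <- ncol(em$W)
  if (is.null(n_modes)) n_modes <- min(250L, ni)
  n_modes <- min(n_modes, ni)
  Rch <- tryCatch(chol(em$W), error = function(e) {
    chol(em$W + diag(mean(diag(em$W)) * 1e-10, ni))
  })
  Fg <- crossprod(op$matrix)
  Mw <- backsolve(Rch, t(backsolve(Rch, Fg, transpose = TRUE)))
  eg <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
  Vm <- backsolve(Rch, eg$vectors[, seq_len(n_modes), drop = FALSE])
  # columns satisfy v' W v = 1: energy of lambda = V y is ||y||^2
  structure(list(mesh = mesh, head = head, spec = spec, em = em,
                 samples = samples, target = target, apex = apex,
                 op_target = op$matrix[1:3, , drop = FALSE],
                 op_apex = op$matrix[4:6, , drop = FALSE],
                 op_samples = op$matrix[-(1:6), , drop = FALSE],
                 modes = Vm, mode_gain = eg$values[seq_len(n_modes)]),
            class = "design_problem")
}

# tangent-plane 16-gon rows for point p (3-row operator block op3), bound b
polygon_rows <- function(op3, p, b, ngon = 16) {
  rhat <- p / sqrt(sum(p^2))
  e1 <- c(-rhat[2], rhat[1], 0)
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
  e1 <- e1 - sum(e1 * rhat) * rhat
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(rhat[2] * e1[3] - rhat[3] * e1[2],
          rhat[3] * e1[1] - rhat[1] * e1[3],
          rhat[1] * e1[2] - rhat[2] * e1[1])
  ang <- 2 * pi * (seq_len(ngon) - 1) / ngon
  U <- outer(cos(ang), e1) + outer(sin(ang), e2) # ngon x 3
  list(G = U %*% op3, h = rep(b, ngon))
}

# --- minimum-norm active-set QP --------------------------------------------
# minimize ||y||^2 subject to Aeq y = beq and G y <= h.
# Lazy primal active set on the rows of G; all solves are min-norm solutions
# of the active system via a rank-revealing SVD.
solve_min_norm_qp <- function(Aeq, beq, G, h, max_iter = 600, tol = 1e-9) {
  if (is.null(dim(Aeq))) Aeq <- matrix(Aeq, 1)
  ne <- nrow(Aeq)
  act <- integer(0)
  m <- if (is.null(G)) 0L else nrow(G)
  y <- NULL
  for (it in seq_len(max_iter)) {
    A <- rbind(Aeq, if (length(act)) G[act, , drop = FALSE])
    b <- c(beq, if (length(act)) h[act])
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-11
    Ub <- drop(crossprod(sv$u[, pos, drop = FALSE], b))
    y <- drop(sv$v[, pos, drop = FALSE] %*% (Ub / sv$d[pos]))
    nu <- drop(sv$u[, pos, drop = FALSE] %*% (Ub / sv$d[pos]^2))
    if (max(abs(A %*% y - b)) > 1e-6 * max(abs(b))) {
      return(list(status = "infeasible", y = y, active = act))
    }
    if (length(act)) {
      lam <- -nu[-seq_len(ne)]
      neg <- which(lam < -tol * max(1, max(abs(lam))))
      if (length(neg)) {
        act <- act[-neg[which.min(lam[neg])]]
        next
      }
    }
    if (m > 0) {
      s <- drop(G %*% y) - h
      cand <- setdiff(which(s > tol * max(1, max(abs(h)))), act)
      if (length(cand)) {
        act <- c(act, cand[which.max(s[cand])])
        next
      }
    }
    return(list(status = "optimal", y = y, active = act))
  }
  list(status = "maxiter", y = y, active = act)
}

# per-sample magnitude bounds for an elliptical candidate region
region_bounds <- function(prob, rho, aspect, alpha_design = NULL) {
  alpha_design <- alpha_design %||% prob$spec$alpha
  tc <- transverse_coords(prob$samples, prob$head)
  inside <- (tc[, "v"] / rho)^2 + (tc[, "u"] / (rho * aspect))^2 <= 1
  ifelse(inside, alpha_design * prob$spec$E_targ, prob$spec$E_targ)
}

# core loop shared by design entry points: given per-sample bounds, solve the
# lazily-constrained min-energy QP
solve_design <- function(prob, bounds, pin_peak = TRUE, extra_G = NULL,
                         extra_h = NULL, max_outer = 80,
                         alpha_design = NULL) {
  spec <- prob$spec; head <- prob$head
  alpha_design <- alpha_design %||% spec$alpha
  Vm <- prob$modes
  Aeq <- matrix(drop(crossprod(head$t_hat, prob$op_target) %*% Vm), 1)
  beq <- spec$E_targ
  if (pin_peak) {
    Aeq <- rbind(Aeq, drop(crossprod(head$t_hat, prob$op_apex) %*% Vm))
    beq <- c(beq, alpha_design * spec$E_targ)
  }
  G <- NULL; h <- numeric(0)
  if (!is.null(extra_G)) {
    G <- extra_G %*% Vm
    h <- extra_h
  }
  active_pts <- integer(0)
  sol <- NULL
  for (outer in seq_len(max_outer)) {
    sol <- solve_min_norm_qp(Aeq, beq, G, h)
    if (sol$status != "optimal") break
    lam <- drop(Vm %*% sol$y)
    E <- matrix(prob$op_samples %*% lam, ncol = 3, byrow = TRUE)
    mag <- sqrt(rowSums(E^2))
    viol <- mag / (bounds / COS16)
    viol[active_pts] <- 0
    w <- which(viol > 1 + 1e-7)
    if (!length(w)) {
      return(list(lambda = lam, energy = sum(sol$y^2), status = "optimal",
                  achieved = drop(crossprod(head$t_hat, prob$op_target %*% lam)),
                  mag = mag, n_active_points = length(active_pts), y = sol$y,
                  constraints = list(Aeq = Aeq, beq = beq, G = G, h = h)))
    }
    w <- w[order(viol[w], decreasing = TRUE)]
    w <- utils::head(w, 12)
    for (p in w) {
      pr <- polygon_rows(
        prob$op_samples[(3 * p - 2):(3 * p), , drop = FALSE] %*% Vm,
        prob$samples[p, ], bounds[p])
      G <- rbind(G, pr$G); h <- c(h, pr$h)
    }
    active_pts <- c(active_pts, w)
  }
  status <- if (!is.null(sol) && sol$status == "infeasible") "infeasible"
            else "not_converged"
  list(lambda = NULL, energy = NA_real_, status = status,
       achieved = NA_real_, n_active_points = length(active_pts))
}

#' Design an optimal surface current
#'
#' Minimizes the stored magnetic energy subject to: the directional field
#' at the target depth equals \code{E_targ}; the directional field at the
#' cortical apex equals \code{alpha * E_targ} (when \code{pin_peak}); the
#' field magnitude at most \code{alpha * E_targ} inside and \code{E_targ}
#' outside an elliptical candidate cylinder around the depth line (semi-axis
#' \code{rho} across the target direction and \code{rho * aspect} along it).
#' With \code{refine = TRUE} the admissible region is subsequently shrunk
#' greedily (lowest-field samples first) while the energy stays within the
#' budget, a sequential convex approximation of direct volume minimization.
#'
#' @param prob a \code{design_problem}.
#' @param rho candidate-region transverse semi-axis (m).
#' @param aspect ratio of the semi-axis along \code{t_hat} to \code{rho}.
#' @param pin_peak pin the cortical apex field to the cap (default TRUE).
#' @param refine greedily shrink the admissible region within the budget.
#' @param budget energy budget for refinement (J), default from the spec.
#' @param core_radius samples within this transverse distance are never
#'   removed from the candidate region during refinement (m).
#' @param extra_G,extra_h additional linear constraint rows (lambda space).
#' @param max_outer maximum constraint-activation sweeps.
#' @return list: \code{lambda}, \code{energy} (J), \code{status},
#'   \code{achieved}, \code{n_active_points}.
#' @export
design_current <- function(prob, rho, aspect = 1, pin_peak = TRUE,
                           refine = FALSE, budget = NULL,
                           core_radius = 0.008, extra_G = NULL,
                           extra_h = NULL, max_outer = 80,
                           alpha_design = NULL) {
  bounds <- region_bounds(prob, rho, aspect, alpha_design)
  des <- solve_design(prob, bounds, pin_peak, extra_G, extra_h, max_outer,
                      alpha_design)
  if (!refine || des$status != "optimal") return(des)
  budget <- budget %||% prob$spec$energy_budget
  if (des$energy > budget) return(des)
  core <- axis_distance(prob$samples, prob$head) <= core_radius
  E_T <- prob$spec$E_targ
  repeat {
    ins <- which(bounds > E_T & !core)
    if (!length(ins)) break
    flip <- ins[order(des$mag[ins])]
    flip <- utils::head(flip, max(1L, as.integer(0.1 * length(ins))))
    nb <- bounds; nb[flip] <- E_T
    cand <- solve_design(prob, nb, pin_peak, extra_G, extra_h, max_outer,
                         alpha_design)
    if (cand$status != "optimal" || cand$energy > budget) break
    bounds <- nb; des <- cand
  }
  des
}

#' Energy-versus-spread Pareto sweep
#'
#' Solves the design over a grid of candidate-region shapes, evaluates the
#' half-maximum spread of each feasible design, and returns the
#' Pareto-filtered energy/spread trade-off curve.
#'
#' @param prob a \code{design_problem}.
#' @param rho_grid transverse semi-axes (m).
#' @param aspect_grid along-target aspect ratios.
#' @param grid_spacing brain grid spacing for the spread evaluation (m).
#' @param pin_peak,refine passed to \code{\link{design_current}}.
#' @param keep_lambda retain the weight vectors (attribute \code{lambdas}).
#' @param pareto_filter drop dominated points.
#' @return data frame of feasible designs sorted by energy.
#' @export
pareto_sweep <- function(prob, rho_grid = NULL, aspect_grid = c(1, 1.5),
                         grid_spacing = 0.0025, pin_peak = TRUE,
                         refine = FALSE, keep_lambda = TRUE,
                         pareto_filter = TRUE, alpha_design = NULL) {
  if (is.null(rho_grid)) {
    rho_grid <- exp(seq(log(0.014), log(0.04), length.out = 6))
  }
  if (!length(rho_grid)) stop("empty radius grid")
  head <- prob$head; spec <- prob$spec
  grid <- sample_brain_grid(head, grid_spacing, zmin = 0)
  rows <- list(); lambdas <- list()
  for (aspect in aspect_grid) {
    for (rho in rho_grid) {
      des <- design_current(prob, rho, aspect, pin_peak = pin_peak,
                            refine = refine, alpha_design = alpha_design)
      if (des$status != "optimal") next
      ff <- function(pts) efield_lambda_points(prob$mesh, head, des$lambda, pts)
      profiles <- eval_field_profiles(ff, head, grid = grid)
      hm <- half_max_metrics(profiles, spec$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        rho = rho, aspect = aspect, W = des$energy, S = hm$S, d = hm$d,
        V = hm$V, peak_ratio = hm$peak / spec$E_targ)
      lambdas[[length(rows)]] <- des$lambda
    }
  }
  if (!length(rows)) stop("all candidate regions were infeasible")
  out <- do.call(rbind, rows)
  ord <- order(out$W)
  out <- out[ord, ]; lambdas <- lambdas[ord]
  if (pareto_filter) {
    keep <- !logical(nrow(out))
    best <- Inf
    for (i in seq_len(nrow(out))) {
      if (out$S[i] < best - 1e-12) best <- out$S[i] else keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    lambdas <- lambdas[keep]
  }
  if (keep_lambda) attr(out, "lambdas") <- lambdas
  class(out) <- c("pareto_curve", class(out))
  out
}

#' Select the most focal design within the energy budget
#'
#' Runs \code{\link{pareto_sweep}} and returns the design with the smallest
#' half-maximum spread among feasible designs whose continuous-current energy
#' is within the budget.
#'
#' @param prob a \code{design_problem}.
#' @param budget energy budget (J); default from the spec.
#' @param ... passed to \code{\link{pareto_sweep}}.
#' @return list: \code{lambda}, \code{row} (the selected sweep row),
#'   \code{curve}.
#' @export
design_for_target <- function(prob, budget = NULL, ...) {
  budget <- budget %||% prob$spec$energy_budget
  pc <- pareto_sweep(prob, pareto_filter = FALSE, ...)
  ok <- which(pc$W <= budget)
  if (!length(ok)) stop("no feasible design within the energy budget")
  sel <- ok[which.min(pc$S[ok])]
  list(lambda = attr(pc, "lambdas")[[sel]], row = pc[sel, ], curve = pc)
}

#' Wire-fit constrained design iteration
#'
#' Enforces that the extracted windings of the design fit a wire of width
#' \code{wire_width}: the minimum contour spacing of a stream function with M
#' uniform intervals is \code{dist_min = Delta_sr(M) / max||I||}, so the
#' constraint is \code{max||I|| <= Delta_sr(M) / wire_width}. The bound uses
#' \code{Delta_sr} of the previous iterate and is imposed as 16-gon
#' constraints on the triangle currents where the condition is violated,
#' re-solving until satisfied (at most \code{max_iter} sweeps).
#'
#' @param prob a \code{design_problem}.
#' @param rho,aspect candidate-region shape.
#' @param max_iter maximum constraint sweeps.
#' @return design list as \code{\link{design_current}} plus
#'   \code{iterations}, \code{max_I}, \code{dist_min}.
#' @export
wire_fit_iteration <- function(prob, rho, aspect = 1, max_iter = 10) {
  mesh <- prob$mesh; spec <- prob$spec
  extra_G <- NULL; extra_h <- numeric(0)
  bound_tris <- integer(0)
  for (it in seq_len(max_iter)) {
    des <- design_current(prob, rho, aspect, extra_G = extra_G,
                          extra_h = extra_h)
    if (des$status != "optimal") {
      stop("wire-fit iteration: design became ", des$status)
    }
    sf <- stream_function(mesh, des$lambda)
    delta <- (max(sf$Sr) - min(sf$Sr)) / spec$M
    cap <- delta / spec$wire_width
    Imag <- sqrt(rowSums(sf$I^2))
    viol <- which(Imag > (1 + 1e-3) * cap)
    if (!length(viol)) {
      return(c(des, list(iterations = it, max_I = max(Imag),
                         dist_min = delta / max(Imag))))
    }
    if (it == max_iter) {
      stop(sprintf(
        "wire-fit did not converge in %d iterations: max||I|| = %.3g, cap = %.3g",
        max_iter, max(Imag), cap))
    }
    new_tris <- setdiff(viol[order(Imag[viol], decreasing = TRUE)], bound_tris)
    new_tris <- utils::head(new_tris, 40)
    for (t in new_tris) {
      rows <- triangle_current_rows(mesh, t)
      pg <- polygon_rows_plane(rows, mesh$normals[t, ], cap)
      extra_G <- rbind(extra_G, pg$G)
      extra_h <- c(extra_h, pg$h)
    }
    # refresh bounds of previously constrained triangles to the new cap
    if (length(bound_tris)) {
      extra_h[seq_len(16 * length(bound_tris))] <- cap
    }
    bound_tris <- c(bound_tris, new_tris)
  }
}

# 3 x n_internal rows mapping lambda to the current vector of triangle t
triangle_current_rows <- function(mesh, t) {
  internal <- mesh$internal_nodes
  col_of <- integer(nrow(mesh$vertices)); col_of[internal] <- seq_along(internal)
  R <- matrix(0, 3, length(internal))
  tri <- mesh$triangles[t, ]
  for (loc in 1:3) {
    node <- tri[loc]
    if (col_of[node] == 0L) next
    j <- tri[(loc %% 3) + 1L]; k <- tri[((loc + 1L) %% 3) + 1L]
    R[, col_of[node]] <- R[, col_of[node]] +
      (mesh$vertices[k, ] - mesh$vertices[j, ]) / (2 * mesh$areas[t])
  }
  R
}

# 16-gon rows in an arbitrary plane with normal nrm
polygon_rows_plane <- function(rows3, nrm, b, ngon = 16) {
  nrm <- nrm / sqrt(sum(nrm^2))
  e1 <- c(-nrm[2], nrm[1], 0)
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
  e1 <- e1 - sum(e1 * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  ang <- 2 * pi * (seq_len(ngon) - 1) / ngon
  U <- outer(cos(ang), e1) + outer(sin(ang), e2)
  list(G = U %*% rows3, h = rep(b, ngon))
}
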