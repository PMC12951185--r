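test_that("min-norm active-set QP agrees with brute force and pracma", {
  set.seed(3)
  for (rep in 1:5) {
    ae <- rnorm(3); be <- 1
    G <- matrix(rnorm(24), 8, 3); h <- runif(8, 0.5, 1.5)
    sol <- focalcoil:::solve_min_norm_qp(ae, be, G, h)
    if (sol$status != "optimal") next
    # brute force on a grid restricted to the equality plane
    gr <- seq(-3, 3, length.out = 121)
    best <- Inf
    for (a in gr) for (b in gr) {
      # param: y = y0 + a t1 + b t2 with t1, t2 spanning the null space
      ns <- svd(matrix(ae, 1), nv = 3)$v[, 2:3]
      y0 <- ae * be / sum(ae^2)
      y <- y0 + ns[, 1] * a + ns[, 2] * b
      if (all(G %*% y <= h + 1e-9)) best <- min(best, sum(y^2))
    }
    # the solver point is feasible, and no grid point beats it (the finite
    # grid can only overestimate the optimum, or miss the feasible set)
    expect_true(all(G %*% sol$y <= h + 1e-8))
    expect_equal(drop(ae %*% sol$y), be, tolerance = 1e-8)
    if (is.finite(best)) {
      expect_lte(sum(sol$y^2), best + 1e-9)
      expect_equal(sum(sol$y^2), best, tolerance = 0.02)
    }
    # independent solver: pracma::quadprog
    qp <- pracma::quadprog(2 * diag(3), c(0, 0, 0), A = G, b = h,
                           Aeq = matrix(ae, 1), beq = be)
    expect_equal(sum(sol$y^2), sum(qp$xmin^2), tolerance = 1e-6)
  }
})

test_that("optimal design meets the target with certified magnitude bounds", {
  prob <- design_fixture()
  des <- design_current(prob, rho = 0.03)
  expect_equal(des$status, "optimal")
  expect_equal(des$achieved, 100, tolerance = 1e-6)
  # 16-gon over-approximation: no sample exceeds bound / cos(pi/16)
  bounds <- focalcoil:::region_bounds(prob, 0.03, 1)
  expect_true(all(des$mag <= bounds / cos(pi / 16) * (1 + 1e-6)))
  # final active constraint set re-solved by an independent QP
  cn <- des$constraints
  if (!is.null(cn$G)) {
    qp <- pracma::quadprog(2 * diag(ncol(prob$modes)),
                           numeric(ncol(prob$modes)),
                           A = cn$G, b = cn$h, Aeq = cn$Aeq, beq = cn$beq)
    expect_equal(des$energy, sum(qp$xmin^2), tolerance = 1e-4)
  }
})

test_that("feasible-set monotonicity: larger regions need no more energy", {
  prob <- design_fixture()
  d30 <- design_current(prob, 0.030)
  d40 <- design_current(prob, 0.040)
  expect_equal(d30$status, "optimal")
  expect_equal(d40$status, "optimal")
  expect_lte(d40$energy, d30$energy * (1 + 1e-6))
  # removing the focality bound altogether (huge region) never costs more
  dfree <- design_current(prob, 0.2)
  expect_lte(dfree$energy, d40$energy * (1 + 1e-6))
})

test_that("infeasible candidate regions are reported, not relaxed", {
  prob <- design_fixture()
  des <- design_current(prob, rho = 0.004)
  expect_true(des$status %in% c("infeasible", "not_converged"))
  expect_true(is.null(des$lambda) || des$status != "optimal")
})

test_that("pareto sweep returns an energy-sorted non-dominated curve", {
  prob <- design_fixture()
  pc <- pareto_sweep(prob, rho_grid = c(0.022, 0.03, 0.045), aspect_grid = 1,
                     grid_spacing = 0.004)
  expect_true(all(diff(pc$W) >= 0))
  expect_true(all(diff(pc$S) <= 1e-12))
  expect_true(all(pc$peak_ratio <= 2 / cos(pi / 16) + 1e-6))
})

test_that("wire-fit iteration terminates and certifies contour spacing", {
  prob <- design_fixture()
  spec <- prob$spec
  # already satisfying: a generous wire width is a fixed point
  base <- design_current(prob, 0.03)
  sf <- stream_function(prob$mesh, base$lambda)
  delta <- diff(range(sf$Sr)) / spec$M
  prob_easy <- prob
  prob_easy$spec$wire_width <- 0.5 * delta / sf$max_I
  easy <- wire_fit_iteration(prob_easy, 0.03)
  expect_equal(easy$iterations, 1)
  expect_equal(easy$lambda, base$lambda, tolerance = 1e-9)

  # binding case: converges within the documented 2-5 sweeps
  prob_hard <- prob
  prob_hard$spec$wire_width <- 1.35 * delta / sf$max_I
  hard <- wire_fit_iteration(prob_hard, 0.03)
  expect_lte(hard$iterations, 5)
  expect_gte(hard$dist_min, prob_hard$spec$wire_width / (1 + 2e-3))

  # geometric audit: adjacent uniform-level contours of the converged design
  # are at least 0.95 wire widths apart
  sfh <- stream_function(prob$mesh, hard$lambda)
  lv <- uniform_levels(sfh$Sr, spec$M)$levels
  worst <- Inf
  for (k in seq_len(length(lv) - 1)) {
    la <- extract_contours(prob$mesh, sfh$Sr, lv[k])
    lb <- extract_contours(prob$mesh, sfh$Sr, lv[k + 1])
    for (a in la) for (b in lb) {
      worst <- min(worst,
                   focalcoil:::polyline_min_dist_cpp(a$path, b$path))
    }
  }
  expect_gte(worst, 0.95 * prob_hard$spec$wire_width)
})
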