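test_that("triangle single-layer potential matches brute-force quadrature", {
  v1 <- c(0, 0, 0); v2 <- c(0.01, 0, 0); v3 <- c(0.002, 0.012, 0)
  P <- rbind(c(0.004, 0.003, 0), # inside, in plane
             c(0.004, 0.003, 0.005), # above
             c(0.05, 0.04, 0.001)) # far
  Ia <- focalcoil:::tri_potential_cpp(P, v1, v2, v3)
  A <- 0.5 * abs((v2[1] - v1[1]) * (v3[2] - v1[2]) -
                 (v3[1] - v1[1]) * (v2[2] - v1[2]))
  for (i in 1:3) {
    # dense Monte Carlo over the triangle (robust near the singularity)
    set.seed(5)
    n <- 4e5
    u <- runif(n); v <- runif(n)
    a <- 1 - sqrt(u); b <- sqrt(u) * (1 - v); cc <- sqrt(u) * v
    x <- a * v1[1] + b * v2[1] + cc * v3[1]
    y <- a * v1[2] + b * v2[2] + cc * v3[2]
    val <- mean(1 / sqrt((P[i, 1] - x)^2 + (P[i, 2] - y)^2 + P[i, 3]^2)) * A
    expect_equal(Ia[i], val, tolerance = 0.01)
  }
})

test_that("energy matrix is symmetric positive definite with quadratic scaling", {
  hat <- small_hat()
  em <- energy_matrix(hat)
  expect_equal(em$W, t(em$W), tolerance = 1e-12)
  ev <- eigen(em$W, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  lam <- rand_lambda(hat)
  expect_equal(current_energy(em, 2 * lam), 4 * current_energy(em, lam),
               tolerance = 1e-12)
  expect_equal(current_energy(em, 0 * lam), 0)
  expect_gt(current_energy(em, lam), 0)
})

test_that("surface-current ring energy matches the strip-loop inductance", {
  # a plateau stream function on a flat mesh drives a uniform circular current
  # band; its energy is L I^2 / 2 with the closed-form inductance of a flat
  # strip loop (GMD of a strip of width w is 0.22313 w)
  m <- build_support("square", size = 0.12, resolution = 0.006)
  rho <- sqrt(rowSums(m$vertices[m$internal_nodes, 1:2]^2))
  R0 <- 0.04; w <- 0.015
  lam <- pmin(1, pmax(0, (R0 - rho) / w))
  em <- energy_matrix(m)
  W <- current_energy(em, lam)
  Rm <- R0 - w / 2
  Lstrip <- 4e-7 * pi * Rm * (log(8 * Rm / (0.22313 * w)) - 2)
  expect_equal(W, 0.5 * Lstrip, tolerance = 0.05)
})

test_that("Neumann inductance reproduces the circular-loop closed form", {
  R <- 0.05; a <- 0.001
  loop <- circle_loop(R, z = 0, n = 157)
  L <- winding_inductance(loop, a, max_seg = 0.002)
  Lref <- 4e-7 * pi * R * (log(8 * R / a) - 2)
  expect_lt(abs(L / Lref - 1), 0.02)
  expect_error(winding_inductance(loop, 0), "positive")
})

test_that("mutual coupling: far coaxial loops add; opposing less than aiding", {
  a <- 0.001
  l1 <- circle_loop(0.04, z = 0)
  l2 <- circle_loop(0.04, z = 1.0) # far apart: mutual term vanishes
  Lsingle <- winding_inductance(l1, a)
  Lfar <- winding_inductance(list(l1, l2), a)
  expect_equal(Lfar, 2 * Lsingle, tolerance = 0.01)

  l2near <- circle_loop(0.04, z = 0.01)
  Laid <- winding_inductance(list(l1, l2near), a)
  Lopp <- winding_inductance(list(l1, l2near[nrow(l2near):1, ]), a)
  expect_lt(Lopp, Laid)

  # invariance under rigid motion and traversal reversal
  shift <- l1; shift[, 1] <- shift[, 1] + 0.3; shift[, 3] <- shift[, 3] + 0.2
  expect_equal(winding_inductance(shift, a), Lsingle, tolerance = 1e-6)
  expect_equal(winding_inductance(l1[nrow(l1):1, ], a), Lsingle,
               tolerance = 1e-9)
})

test_that("inductance is converged at the 2 mm segment default", {
  loop <- circle_loop(0.05, z = 0, n = 157)
  L2 <- winding_inductance(loop, 0.001, max_seg = 0.002)
  L1 <- winding_inductance(loop, 0.001, max_seg = 0.001)
  expect_lt(abs(L2 / L1 - 1), 0.005)
})

test_that("pulse energy and DC resistance arithmetic", {
  expect_equal(pulse_energy(10e-6, 5000), 125)
  expect_equal(pulse_energy(10e-6, 10000), 4 * pulse_energy(10e-6, 5000))
  expect_error(pulse_energy(0, 1), "positive")

  expect_warning(r <- estimate_resistance(10, 8e-6), "skin depth")
  expect_equal(r, 1.68e-8 * 10 / 8e-6, tolerance = 1e-12) # ~21 mOhm
  expect_equal(r, 0.021, tolerance = 0.01)
  expect_equal(suppressWarnings(estimate_resistance(20, 8e-6)), 2 * r,
               tolerance = 1e-12)
  expect_equal(suppressWarnings(estimate_resistance(0, 8e-6)), 0)
})

test_that("winding stored energy is consistent with the surface-current energy", {
  # matched continuous/discrete pair on the synthetic stream fixture
  fx <- make_fixtures("synthetic_stream")
  head <- default_head()
  em <- energy_matrix(fx$mesh)
  W_cont <- current_energy(em, fx$lambda)
  part <- partition_subcoils(fx$mesh, fx$Sr)
  bl <- focalcoil:::initial_basin_levels(fx$mesh, fx$Sr, 24, part)
  loops <- focalcoil:::extract_basin_loops(fx$mesh, fx$Sr, bl, part)
  # least-squares drive matching the continuous field on a shell
  shell <- sample_shell(0.0699, 1200)
  Ei <- focalcoil:::efield_lambda_points(fx$mesh, head, fx$lambda, shell)
  Eu <- focalcoil:::winding_unit_field(loops, head, shell)
  s <- sum(Eu * Ei) / sum(Eu * Eu)
  L <- winding_inductance(lapply(loops, `[[`, "path"), 0.0015)
  expect_equal(0.5 * L * s^2, W_cont, tolerance = 0.25)
})
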