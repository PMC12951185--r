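test_that("interior field has no radial component and is linear in the source", {
  hat <- small_hat()
  head <- default_head()
  set.seed(7)
  pts <- matrix(rnorm(60), 20, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(20, 0.005, 0.069)
  op <- efield_basis_operator(hat, head, pts)
  l1 <- rand_lambda(hat, 1); l2 <- rand_lambda(hat, 2)
  E <- field_at(op, l1)
  rad <- rowSums(E * pts) / sqrt(rowSums(pts^2))
  expect_lt(max(abs(rad)), 1e-10 * max(sqrt(rowSums(E^2))))
  # linearity to machine precision
  expect_equal(field_at(op, l1 + l2), field_at(op, l1) + field_at(op, l2),
               tolerance = 1e-12)
  expect_equal(max(abs(field_at(op, 0 * l1))), 0)
})

test_that("closed form matches the independent quadrature oracle", {
  set.seed(11)
  epos <- matrix(rnorm(30), 10, 3)
  epos <- epos / sqrt(rowSums(epos^2)) * runif(10, 0.09, 0.16)
  evec <- matrix(rnorm(30), 10, 3) * 0.01
  pts <- matrix(rnorm(30), 10, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(10, 0.002, 0.069)
  E <- focalcoil:::efield_elements_cpp(pts, epos, evec)
  E_or <- oracle_efield(pts, epos, evec)
  expect_lt(max(abs(E - E_or)) / max(abs(E_or)), 1e-3 * 1e-3) # < 0.1% * 0.001
})

test_that("axisymmetric sources induce no field on the axis; reversal negates", {
  head <- default_head()
  loop <- circle_loop(0.04)
  axis_pts <- cbind(0, 0, c(0.02, 0.05, 0.065))
  op <- efield_wire_operator(list(loop), head, axis_pts)
  E <- field_at(op, 1)
  expect_lt(max(abs(E)), 1e-10)
  # off-axis: reversing traversal negates the field
  p <- matrix(c(0.02, 0.01, 0.05), 1)
  Ef <- field_at(efield_wire_operator(list(loop), head, p), 1)
  Er <- field_at(efield_wire_operator(list(loop[nrow(loop):1, ]), head, p), 1)
  expect_equal(Er, -Ef, tolerance = 1e-10)
  # open polylines are rejected
  expect_error(efield_wire_operator(list(loop[1:100, ]), head, p),
               "does not close")
})

test_that("figure-8 field peaks under the coil center along the lobe axis", {
  head <- default_head()
  f8 <- make_fixtures("figure8")
  sm <- shell_maps(f8, head, radii = 0.07, n = 3000)[[1]]
  imax <- which.max(sm$Emag)
  p <- sm$points[imax, ]
  # peak within a few sampling steps of the apex (0, 0, 0.07)
  expect_lt(sqrt(p[1]^2 + p[2]^2), 0.012)
  # field there is parallel to the line joining the loop centers rotated 90
  # degrees: the lobes sit along x, so E is along y
  Edir <- sm$E[imax, ] / sm$Emag[imax]
  expect_gt(abs(Edir[2]), 0.99)
})

test_that("Fibonacci shell sampling is quasi-uniform", {
  P <- sample_shell(0.07, 46532)
  expect_equal(nrow(P), 46532)
  expect_true(all(abs(sqrt(rowSums(P^2)) - 0.07) < 1e-12))

  P2 <- sample_shell(0.05, 100)
  expect_lt(max(abs(colMeans(P2))), 1e-3 * 0.05)

  P3 <- sample_shell(0.07, 500)
  D <- as.matrix(dist(P3))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  expect_gt(min(nn), 0)
  expect_lt(sd(nn) / mean(nn), 0.25)
})

test_that("brain grid covers the sphere with consistent voxel volumes", {
  head <- default_head()
  g <- sample_brain_grid(head, 0.005)
  vol <- nrow(g$points) * g$voxel_volume
  vref <- 4 / 3 * pi * 0.07^3
  expect_lt(abs(vol - vref) / vref, 0.05)
  g2 <- sample_brain_grid(head, 0.0025)
  vol2 <- nrow(g2$points) * g2$voxel_volume
  expect_lt(abs(vol2 - vref), abs(vol - vref))

  # independent lattice count: integer points of the offset lattice in the ball
  s <- 0.005
  ax <- seq(-0.07 + s / 2, 0.07, by = s)
  cnt <- 0L
  for (x in ax) for (y in ax) {
    z2 <- 0.07^2 - x^2 - y^2
    if (z2 > 0) cnt <- cnt + sum(ax^2 < z2)
  }
  expect_equal(nrow(g$points), cnt)

  expect_error(sample_brain_grid(head, 0.02), "spacing")
})

test_that("segment subdivision is converged at the 2 mm default", {
  head <- default_head()
  loop <- circle_loop(0.035, center = c(0.02, 0.01))
  pts <- rbind(c(0.01, 0.0, 0.055), c(-0.02, 0.015, 0.04))
  E2 <- field_at(efield_wire_operator(list(loop), head, pts, max_seg = 0.002), 1)
  E1 <- field_at(efield_wire_operator(list(loop), head, pts, max_seg = 0.001), 1)
  expect_lt(max(abs(E2 - E1)) / max(abs(E1)), 1e-4)
})

test_that("placement contracts are enforced", {
  hat <- small_hat()
  head <- default_head()
  expect_error(efield_basis_operator(hat, head, matrix(c(0, 0, 0.09), 1)),
               "inside")
  bad <- hat
  bad$vertices[, 3] <- bad$vertices[, 3] - 0.02 # dips into the scalp sphere
  expect_error(efield_basis_operator(bad, head, matrix(c(0, 0, 0.05), 1)),
               "outside")
})
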