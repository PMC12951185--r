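test_that("uniform contour levels follow the half-offset rule", {
  expect_equal(uniform_levels(c(0, 10), 10)$levels, seq(0.5, 9.5, by = 1))
  expect_equal(uniform_levels(c(0, 10), 2)$levels, c(2.5, 7.5))
  expect_error(uniform_levels(c(3, 3), 4), "constant")
  # antisymmetric range with even M: levels symmetric about 0, none at 0
  lv <- uniform_levels(c(-8, 8), 8)$levels
  expect_equal(lv, -rev(lv))
  expect_true(all(abs(lv) > 1e-12))
})

test_that("extracted contours are closed circles on a radial stream function", {
  sq <- tiny_square()
  Sr <- numeric(nrow(sq$vertices))
  rho <- sqrt(rowSums(sq$vertices[, 1:2]^2))
  Sr <- pmax(0, 0.05 - rho)
  Sr[sq$boundary_nodes] <- 0
  loops <- extract_contours(sq, Sr, 0.02)
  expect_equal(length(loops), 1L)
  P <- loops[[1]]$path
  expect_equal(P[1, ], P[nrow(P), ], tolerance = 1e-12)
  rr <- sqrt(rowSums(P[, 1:2]^2))
  # contour of 0.05 - rho at level 0.02: circle of radius 0.03, with error
  # bounded by the mesh edge length
  expect_lt(max(abs(rr - 0.03)), 0.02)
  expect_lt(sd(rr), 0.002)
  expect_error(extract_contours(sq, Sr, 1), "strictly between")
})

test_that("contour orientation follows the surface current", {
  sq <- tiny_square()
  rho <- sqrt(rowSums(sq$vertices[, 1:2]^2))
  Sr <- pmax(0, 0.05 - rho)
  Sr[sq$boundary_nodes] <- 0
  lp <- extract_contours(sq, Sr, 0.02)[[1]]
  # I = -n x grad Sr: for grad Sr = -rho_hat and n = +z, I = -(z x -rho_hat)
  # = +z x rho_hat rotated: counterclockwise seen from +z
  P <- lp$path
  area2 <- sum(P[-nrow(P), 1] * P[-1, 2] - P[-1, 1] * P[-nrow(P), 2])
  expect_gt(area2, 0)
})

test_that("the synthetic stream function partitions into 2/2/4 basins", {
  fx <- make_fixtures("synthetic_stream")
  part <- partition_subcoils(fx$mesh, fx$Sr)
  tab <- table(part$info$region)
  expect_equal(unname(tab["figure8"]), 2L)
  expect_equal(unname(tab["biasing"]), 2L)
  expect_equal(unname(tab["cancellation"]), 4L)
  # invariance under a global sign flip
  part2 <- partition_subcoils(fx$mesh, -fx$Sr)
  expect_equal(table(part2$info$region), tab)
  # a pure figure-8 (2 extrema) has no biasing or cancellation basins
  sq <- tiny_square()
  x <- sq$vertices[, 1]; y <- sq$vertices[, 2]
  Sr8 <- x * exp(-(x^2 + y^2) / (2 * 0.025^2))
  Sr8[sq$boundary_nodes] <- 0
  p8 <- partition_subcoils(sq, Sr8)
  expect_setequal(p8$info$region, "figure8")
})

test_that("layer assignment is round-robin with head-side innermost", {
  fx <- make_fixtures("synthetic_stream")
  part <- partition_subcoils(fx$mesh, fx$Sr)
  bl <- focalcoil:::initial_basin_levels(fx$mesh, fx$Sr, 18, part)
  loops <- focalcoil:::extract_basin_loops(fx$mesh, fx$Sr, bl, part)
  one <- assign_layers(loops, fx$mesh, function(b) 1L, 0.003)
  expect_true(all(vapply(one, function(l) l$layer, 0L) == 0L))
  # with 3 layers the innermost (largest |level|) loop of each basin is on
  # layer 0 and consecutive concentric loops cycle 0,1,2
  three <- assign_layers(loops, fx$mesh, function(b) 3L, 0.003)
  basins <- vapply(three, function(l) as.integer(l$basin), 1L)
  for (b in unique(basins)) {
    ids <- which(basins == b)
    ids <- ids[order(abs(vapply(three[ids], `[[`, 0, "level")),
                     decreasing = TRUE)]
    lay <- vapply(three[ids], function(l) as.integer(l$layer), 1L)
    expect_equal(lay, (seq_along(ids) - 1L) %% 3L)
  }
  # offsets move along +normal (away from the head) by layer * wire height
  l1 <- three[[which(vapply(three, function(l) l$layer, 0L) == 1L)[1]]]
  match0 <- loops[[which(vapply(three, function(l) l$layer, 0L) == 1L)[1]]]
  dz <- l1$path[, 3] - match0$path[, 3]
  expect_gt(mean(dz), 0.002) # mostly upward on the near-flat crown
})

test_that("serial connection visits every loop once and conserves length", {
  fx <- make_fixtures("synthetic_stream")
  part <- partition_subcoils(fx$mesh, fx$Sr)
  bl <- focalcoil:::initial_basin_levels(fx$mesh, fx$Sr, 12, part)
  loops <- focalcoil:::extract_basin_loops(fx$mesh, fx$Sr, bl, part)
  loops <- assign_layers(loops, fx$mesh, function(b) 1L, 0.003)
  path <- connect_serial(loops)
  per <- sum(vapply(loops, function(l) {
    P <- l$path
    sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
  }, 0))
  plen <- sum(sqrt(rowSums(diff(path)^2)))
  expect_gte(plen, per)
  # jogs, bridges, return and closing leads stay short relative to the winding
  expect_lt(plen - per, 0.5 * per)

  # single loop: the path is the loop opened at one vertex
  single <- connect_serial(loops[1])
  expect_equal(sum(sqrt(rowSums(diff(single)^2))),
               sum(sqrt(rowSums(diff(loops[[1]]$path)^2))), tolerance = 1e-9)

  # serial path field matches per-loop superposition at the shell peak
  head <- default_head()
  shell <- sample_shell(0.0699, 400)
  Esum <- focalcoil:::winding_unit_field(loops, head, shell)
  sg <- focalcoil:::subdivide_polyline(path, 0.002)
  Eser <- focalcoil:::efield_elements_cpp(shell, sg$mid, sg$vec) *
    (1e-7 * head$omega)
  i <- which.max(sqrt(rowSums(Esum^2)))
  expect_lt(sqrt(sum((Eser[i, ] - Esum[i, ])^2)) / sqrt(sum(Esum[i, ]^2)),
            0.03)
})

test_that("reported spacing equals a brute-force minimum distance", {
  fx <- make_fixtures("synthetic_stream")
  part <- partition_subcoils(fx$mesh, fx$Sr)
  bl <- focalcoil:::initial_basin_levels(fx$mesh, fx$Sr, 16, part)
  loops <- focalcoil:::extract_basin_loops(fx$mesh, fx$Sr, bl, part)
  loops <- assign_layers(loops, fx$mesh, function(b) 1L, 0)
  sp <- focalcoil:::min_adjacent_spacing(loops)
  # brute force: all same-basin same-layer adjacent pairs via dense sampling
  basins <- vapply(loops, function(l) as.integer(l$basin), 1L)
  worst <- Inf
  for (b in unique(basins)) {
    ids <- which(basins == b)
    ids <- ids[order(abs(vapply(loops[ids], `[[`, 0, "level")),
                     decreasing = TRUE)]
    if (length(ids) < 2) next
    for (k in seq_len(length(ids) - 1)) {
      A <- loops[[ids[k]]]$path; B <- loops[[ids[k + 1]]]$path
      dmin <- min(apply(A, 1, function(p) {
        min(sqrt(colSums((t(B) - p)^2)))
      }))
      worst <- min(worst, dmin)
    }
  }
  expect_lte(sp, worst + 1e-12) # segment distance <= vertex distance
  expect_gt(sp, worst * 0.8)
})

test_that("field mismatch of the discretized winding decreases with M", {
  dc <- designed_current()
  head <- default_head()
  shell <- sample_shell(0.0699, 1000)
  Ei <- focalcoil:::efield_lambda_points(dc$mesh, head, dc$lambda, shell)
  mis <- sapply(c(4, 8, 16, 32), function(M) {
    lv <- uniform_levels(dc$Sr, M)$levels
    loops <- list()
    for (l in lv) {
      for (lp in extract_contours(dc$mesh, dc$Sr, l)) {
        loops[[length(loops) + 1]] <- lp
      }
    }
    Eu <- focalcoil:::winding_unit_field(loops, head, shell)
    s <- sum(Eu * Ei) / sum(Eu * Eu)
    sqrt(sum((s * Eu - Ei)^2)) / sqrt(sum(Ei^2))
  })
  expect_true(all(diff(mis) < 0))
})

test_that("hybrid level optimization descends and respects spacing", {
  fx <- make_fixtures("synthetic_stream")
  head <- default_head()
  part <- partition_subcoils(fx$mesh, fx$Sr)
  bl <- focalcoil:::initial_basin_levels(fx$mesh, fx$Sr, 14, part)
  bl <- focalcoil:::repair_spacing(fx$mesh, fx$Sr, bl, part, function(b) 1L,
                                   0.002, 0.0022)
  res <- optimize_hybrid_levels(fx$mesh, head, fx$lambda, part, bl,
                                function(b) 1L, wire = c(0.002, 0.002),
                                shell_n = 800, min_spacing = 0.0022,
                                maxit = 40)
  expect_lte(res$objective, res$objective_start * (1 + 1e-9))
  expect_gte(res$spacing, 0.0022)
  expect_s3_class(res$winding, "winding_set")
  # zero-iteration call returns the start point
  res0 <- optimize_hybrid_levels(fx$mesh, head, fx$lambda, part, bl,
                                 function(b) 1L, wire = c(0.002, 0.002),
                                 shell_n = 800, min_spacing = 0.0022,
                                 maxit = 0)
  expect_equal(res0$objective, res0$objective_start)
})
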