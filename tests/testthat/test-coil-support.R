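test_that("parametric supports have the prescribed geometry", {
  sq <- tiny_square()
  expect_true(all(abs(sq$vertices[, 3] - 0.09) < 1e-12))

  hs <- build_support("half_sphere", size = 0.09, resolution = 0.02)
  r <- sqrt(rowSums(hs$vertices^2)) # centered at the origin for R = 0.09
  expect_true(all(abs(r - 0.09) < 1e-9))

  hat <- build_support("hat", size = 0.095, brim_width = 0.04,
                       resolution = 0.015)
  # no overhangs: every facet normal points within 90 deg of the coil axis,
  # i.e. the head-side normal is within 90 deg of -z
  expect_true(all(hat$normals[, 3] > 0))
  # the crown apex sits at the coil center height
  expect_equal(max(hat$vertices[, 3]), 0.09, tolerance = 1e-6)

  expect_error(build_support("square", size = 0), "positive extent")
})

test_that("boundary nodes are exactly the vertices on single-use edges", {
  sq <- tiny_square()
  n <- sqrt(nrow(sq$vertices))
  on_rim <- which(abs(abs(sq$vertices[, 1]) - 0.06) < 1e-12 |
                  abs(abs(sq$vertices[, 2]) - 0.06) < 1e-12)
  expect_setequal(sq$boundary_nodes, on_rim)
  expect_setequal(sq$internal_nodes, setdiff(seq_len(nrow(sq$vertices)), on_rim))

  # closed sphere: a single gauge node stands in for the boundary
  sp <- build_support("sphere", size = 0.09, resolution = 0.03)
  expect_length(sp$boundary_nodes, 1L)
})

test_that("nodal basis gradients match closed forms", {
  # unit right triangle, hat function of the right-angle corner
  m <- raw_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(1:3, 1))
  nb <- nodal_basis(m)
  expect_equal(sqrt(sum(nb$grads[1, 1, ]^2)), sqrt(2), tolerance = 1e-12)
  # partition of unity: gradients sum to zero in every triangle
  expect_equal(apply(nb$grads, c(1, 3), sum), matrix(0, 1, 3),
               tolerance = 1e-12)

  # equilateral triangle of side a: |grad N| = 2 / (a sqrt(3))
  a <- 0.37
  me <- raw_mesh(rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0)),
                 matrix(1:3, 1))
  g <- nodal_basis(me)$grads
  for (k in 1:3) {
    expect_equal(sqrt(sum(g[1, k, ]^2)), 2 / (a * sqrt(3)), tolerance = 1e-10)
  }

  # sliver rejection
  ms <- raw_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1e-9, 0),
                       c(0.5, 0.5, 0)),
                 rbind(1:3, c(1, 2, 4)))
  expect_error(nodal_basis(ms), "sliver")
})

test_that("seed currents are tangential, local, and carry unit circulation", {
  sq <- tiny_square()
  node <- sq$internal_nodes[3]
  sc <- seed_current(sq, node)
  expect_true(all(abs(sc$Jz) < 1e-14)) # tangent to the flat mesh
  # supported only on incident triangles
  inc <- apply(sq$triangles, 1, function(tr) node %in% tr)
  expect_setequal(sc$triangle, which(inc))
  expect_error(seed_current(sq, sq$boundary_nodes[1]), "internal")

  # discrete flux audit: the current crossing a straight cut from the node to
  # the boundary equals 1 A (unit stream-function peak)
  lam <- numeric(length(sq$internal_nodes))
  lam[match(node, sq$internal_nodes)] <- 1
  sf <- stream_function(sq, lam)
  p0 <- sq$vertices[node, 1:2]
  p1 <- c(0.06, p0[2] + 1e-5) # cut to the +x rim, off vertex lines
  nseg <- 4000
  ts <- (seq_len(nseg) - 0.5) / nseg
  pts <- cbind(p0[1] + ts * (p1[1] - p0[1]), p0[2] + ts * (p1[2] - p0[2]))
  dl <- sqrt(sum((p1 - p0)^2)) / nseg
  nrm <- c(-(p1[2] - p0[2]), p1[1] - p0[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  # locate containing triangle by barycentric coordinates
  tris <- sq$triangles; V <- sq$vertices
  flux <- 0
  for (i in seq_len(nseg)) {
    p <- pts[i, ]
    for (t in seq_len(nrow(tris))) {
      A <- V[tris[t, 1], 1:2]; B <- V[tris[t, 2], 1:2]; C <- V[tris[t, 3], 1:2]
      det <- (B[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (B[2] - A[2])
      l1 <- ((B[1] - p[1]) * (C[2] - p[2]) - (C[1] - p[1]) * (B[2] - p[2])) / det
      l2 <- ((C[1] - p[1]) * (A[2] - p[2]) - (A[1] - p[1]) * (C[2] - p[2])) / det
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-12 && l2 >= -1e-12 && l3 >= -1e-12) {
        flux <- flux + sum(sf$I[t, 1:2] * nrm) * dl
        break
      }
    }
  }
  expect_equal(abs(flux), 1, tolerance = 0.01)
})

test_that("stream function currents: uniformity, linearity, closure", {
  sq <- tiny_square()
  # Sr linear in x -> uniform current along -(z x x) = -y
  lam <- sq$vertices[sq$internal_nodes, 1]
  sf <- stream_function(sq, lam)
  # triangles whose three nodes are internal carry exactly grad Sr = x_hat
  all_int <- apply(sq$triangles, 1, function(tr) {
    all(tr %in% sq$internal_nodes)
  })
  I_int <- sf$I[all_int, , drop = FALSE]
  expect_true(all(abs(I_int[, 1]) < 1e-10))
  expect_true(all(abs(I_int[, 2] + 1) < 1e-10))

  expect_equal(stream_function(sq, 2 * lam)$max_I, 2 * sf$max_I,
               tolerance = 1e-12)
  expect_error(stream_function(sq, lam[-1]), "internal nodes")

  # zero weights -> zero current
  expect_equal(stream_function(sq, 0 * lam)$max_I, 0)
})

test_that("currents are discretely divergence-free (edge-flux consistency)", {
  hat <- small_hat()
  lam <- rand_lambda(hat)
  sf <- stream_function(hat, lam)
  # the current crossing an interior edge equals the difference of nodal
  # stream values, computed identically from both adjacent triangles
  tris <- hat$triangles
  ed <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  tri_of <- rep(seq_len(nrow(tris)), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  dup <- split(seq_len(nrow(ed)), key)
  V <- hat$vertices
  checked <- 0
  worst <- 0
  for (g in dup) {
    if (length(g) != 2) next
    a <- ed[g[1], 1]; b <- ed[g[1], 2]
    ev <- V[b, ] - V[a, ]
    for (gi in g) {
      t <- tri_of[gi]
      n <- hat$normals[t, ]
      perp <- c(n[2] * ev[3] - n[3] * ev[2],
                n[3] * ev[1] - n[1] * ev[3],
                n[1] * ev[2] - n[2] * ev[1])
      flux <- sum(sf$I[t, ] * perp)
      worst <- max(worst, abs(flux - (sf$Sr[a] - sf$Sr[b])))
    }
    checked <- checked + 1
    if (checked > 200) break
  }
  expect_gt(checked, 100)
  expect_lt(worst, 1e-9 * max(abs(sf$Sr)))
})

test_that("field of an antisymmetric stream function is mirror-symmetric", {
  sq <- tiny_square()
  head <- default_head()
  x <- sq$vertices[sq$internal_nodes, 1]
  y <- sq$vertices[sq$internal_nodes, 2]
  lam <- x * exp(-(x^2 + y^2) / (2 * 0.03^2)) # odd in x: figure-8
  pts <- rbind(c(0.02, 0.013, 0.05), c(-0.02, 0.013, 0.05),
               c(0.035, -0.01, 0.04), c(-0.035, -0.01, 0.04))
  E <- focalcoil:::efield_lambda_points(sq, head, lam, pts)
  # Ey is even under x -> -x for this source
  expect_equal(E[1, 2], E[2, 2], tolerance = 1e-8)
  expect_equal(E[3, 2], E[4, 2], tolerance = 1e-8)
})

test_that("mesh and weight serialization round-trips", {
  sq <- tiny_square()
  tf <- tempfile(fileext = ".obj")
  write_mesh(sq, tf)
  back <- read_mesh(tf)
  expect_equal(back$vertices, sq$vertices, tolerance = 1e-9)
  expect_equal(nrow(back$triangles), nrow(sq$triangles))

  tf2 <- tempfile(fileext = ".stl")
  write_mesh(sq, tf2)
  back2 <- read_mesh(tf2)
  expect_equal(nrow(back2$vertices), nrow(sq$vertices))
  expect_equal(sum(back2$areas), sum(sq$areas), tolerance = 1e-9)

  lam <- rand_lambda(sq)
  tf3 <- tempfile(fileext = ".json")
  write_weights(sq, lam, tf3)
  w <- read_weights(tf3, mesh = sq)
  expect_equal(w$values, lam, tolerance = 1e-12)
  expect_error(read_weights(tf3, mesh = small_hat()), "hash")
})
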