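# Shared fixtures, built once per test session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

tiny_square <- function() {
  fixture("tiny_square", function() {
    build_support("square", size = 0.12, resolution = 0.02)
  })
}

small_hat <- function() {
  fixture("small_hat", function() build_support("hat", resolution = 0.014))
}

default_head <- function() head_model()

# a bare triangle mesh (bypassing the parametric generators)
raw_mesh <- function(V, tris) focalcoil:::finish_mesh(V, tris, orient = "z")

# random weights with a fixed seed
rand_lambda <- function(mesh, seed = 42, scale = 1) {
  set.seed(seed)
  scale * rnorm(length(mesh$internal_nodes))
}

# independent quadrature oracle for the sphere E-field of point current
# elements: E = -dA/dt - grad phi, with phi(r) = -r . int_0^1 dA/dt(t r) dt
# evaluated by 64-point Gauss-Legendre and grad phi by central differences.
oracle_efield <- function(points, epos, evec) {
  gl <- pracma::gaussLegendre(64, 0, 1)
  Afun <- function(r) {
    s <- c(0, 0, 0)
    for (j in seq_len(nrow(epos))) {
      s <- s + evec[j, ] / sqrt(sum((r - epos[j, ])^2))
    }
    s
  }
  phi <- function(r) {
    s <- 0
    for (k in seq_len(64)) s <- s + gl$w[k] * sum(r * Afun(gl$x[k] * r))
    -s
  }
  t(apply(points, 1, function(r) {
    h <- 1e-6
    g <- sapply(1:3, function(d) {
      e <- numeric(3); e[d] <- h
      (phi(r + e) - phi(r - e)) / (2 * h)
    })
    -Afun(r) - g
  }))
}

circle_loop <- function(radius, z = 0.095, n = 120, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(radius * cos(th) + center[1], radius * sin(th) + center[2], z)
}

# a reusable design problem and an optimized current on the small hat
design_fixture <- function() {
  fixture("design_prob", function() {
    design_problem(small_hat(), default_head(), design_spec(depth = 0.0131),
                   n_modes = 120, n_cortex = 600, n_inner = 150)
  })
}

designed_current <- function() {
  fixture("designed_current", function() {
    prob <- design_fixture()
    des <- design_current(prob, 0.03)
    list(mesh = prob$mesh, lambda = des$lambda,
         Sr = focalcoil:::full_stream(prob$mesh, des$lambda))
  })
}
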