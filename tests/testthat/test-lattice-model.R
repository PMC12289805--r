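test_that("local map vanishes at equilibria and reduces to F_p on the diagonal", {
  p <- ref_params(q = 0.5)
  b <- equilibrium_branches(0.5, 16)
  for (x in c(b$x_d, b$x_m, b$x_u))
    expect_lt(abs(local_map(x, x, x, p)), 1e-10)
  vs <- seq(-0.2, 1.2, by = 0.1)
  expect_equal(local_map(vs, vs, vs, p), raw_Fp(vs, 16, 0.5, 0.1),
               tolerance = 1e-14)
  expect_equal(bistable_reaction(vs, p), raw_Fp(vs, 16, 0.5, 0.1),
               tolerance = 1e-14)
})

test_that("the lattice coupling is cooperative (positive partials in u and w)", {
  p <- ref_params(q = 0.5)
  set.seed(1234)
  h <- 1e-6
  for (i in 1:10) {
    u <- runif(1); v <- runif(1); w <- runif(1)
    du <- (local_map(u + h, v, w, p) - local_map(u - h, v, w, p)) / (2 * h)
    dw <- (local_map(u, v, w + h, p) - local_map(u, v, w - h, p)) / (2 * h)
    expect_gt(du, 0)
    expect_gt(dw, 0)
    # dN/dw = q S'(w) exactly
    expect_equal(dw, p$q * sigmoid_deriv(w, p), tolerance = 1e-6)
  }
})

test_that("scalar_rhs applies the boundary closures of the finite network", {
  p <- ref_params(q = 0.5)
  b <- equilibrium_branches(0.5, 16)
  prot <- input_protocol("constant", s0 = b$x_d)
  expect_lt(max(abs(scalar_rhs(rep(b$x_d, 10), 0, prot, p))), 1e-12)
  # interior layer delegates to local_map
  v <- c(0.2, 0.7, 0.4)
  d <- scalar_rhs(v, 0, input_protocol("constant", s0 = 0.9), p)
  expect_equal(d[2], local_map(v[1], v[2], v[3], p))
  expect_equal(d[1], local_map(0.9, v[1], v[2], p))
  # layer J: feedback term absent (independently coded top-layer equation)
  top <- (1 - p$p - p$q) * (raw_S(v[2], 16, 0.5) - v[3]) +
    p$p * raw_Sp(v[3], 16, 0.5) * (v[2] - raw_S(v[3], 16, 0.5))
  expect_equal(d[3], top, tolerance = 1e-14)
  expect_error(scalar_rhs(0.5, 0, prot, p), "at least")
})

test_that("interior dynamics is translation equivariant", {
  p <- ref_params(q = 0.4)
  set.seed(1234)
  v <- runif(12)
  d <- local_map(v[1:10], v[2:11], v[3:12], p)
  vs <- c(v[4:12], runif(3))
  ds <- local_map(vs[1:10], vs[2:11], vs[3:12], p)
  expect_equal(d[4:10], ds[1:7], tolerance = 1e-15)
})

test_that("vector model reduces exactly to the scalar model at identity weights", {
  p <- ref_params(q = 0.5)
  vp <- vector_model_params(diag(1), diag(1),
                            hyper_params(p$p, 1 - p$p - p$q, p$q),
                            ref_sigmoid())
  prot <- input_protocol("constant", s0 = 0.8)
  set.seed(1234)
  v <- runif(15)
  expect_equal(drop(vector_rhs(matrix(v, 1), 3, prot, vp)),
               scalar_rhs(v, 3, prot, p), tolerance = 1e-14)
  # equilibrium of the map => zero derivative everywhere
  b <- equilibrium_branches(0.5, 16)
  expect_lt(max(abs(vector_rhs(matrix(b$x_u, 1, 8), 0,
                               input_protocol("constant", s0 = b$x_u),
                               vp))), 1e-12)
  expect_error(vector_rhs(matrix(v, 3), 0, prot, vp), "rows")
})

test_that("multi-population RHS matches an independent per-layer loop", {
  set.seed(1234)
  d <- 2; J <- 6
  Wf <- matrix(rnorm(4, sd = 0.5), d) + diag(d)
  Wb <- matrix(rnorm(4, sd = 0.5), d) + diag(d)
  hy <- hyper_params(0.4, 1.2, 0.8)
  sg <- ref_sigmoid()
  vp <- vector_model_params(Wf, Wb, hy, sg)
  V <- matrix(runif(d * J), d)
  s0 <- 0.7
  prot <- input_protocol("constant", s0 = s0)
  got <- vector_rhs(V, 0, prot, vp)
  # oracle: direct transcription of the three layer cases
  Sv <- function(X) matrix(raw_S(X, 16, 0.5), nrow = d)
  oracle <- matrix(0, d, J)
  for (j in 1:J) {
    prev <- if (j == 1) matrix(rep(s0, d)) else V[, j - 1, drop = FALSE]
    vj <- V[, j, drop = FALSE]
    term <- hy$beta * (Wf %*% Sv(prev) - vj) +
      hy$alpha * diag(raw_Sp(drop(vj), 16, 0.5), d) %*%
        (t(Wb) %*% (prev - Wb %*% Sv(vj)))
    if (j < J)
      term <- term + hy$lambda * (Wb %*% Sv(V[, j + 1, drop = FALSE]) - vj)
    oracle[, j] <- term
  }
  expect_equal(got, oracle, tolerance = 1e-13)
})

test_that("diagonal weights reproduce the decoupled scalar equation", {
  hy <- hyper_params(0.4, 1.2, 0.8)
  w <- diagonal_weights(0.8, 1.3)
  set.seed(1234)
  v <- runif(8)
  s0 <- 0.6
  got <- diagonal_rhs(v, 0, input_protocol("constant", s0 = s0), w, hy,
                      ref_sigmoid())
  u <- c(s0, v[-8])
  oracle <- hy$beta * (w$omega_f * raw_S(u, 16, 0.5) - v) +
    hy$alpha * raw_Sp(v, 16, 0.5) * w$omega_b *
      (u - w$omega_b * raw_S(v, 16, 0.5))
  lam <- hy$lambda * (w$omega_b * raw_S(c(v[-1], 0), 16, 0.5) - v)
  lam[8] <- 0
  oracle <- oracle + lam
  expect_equal(got, oracle, tolerance = 1e-13)
  # (1, 1) recovers the base model
  r <- hyperparams_to_pq(hy)
  base <- diagonal_rhs(v, 0, input_protocol("constant", s0 = s0),
                       diagonal_weights(1, 1), hy, ref_sigmoid())
  expect_equal(base,
               r$time_scale *
                 scalar_rhs(v, 0, input_protocol("constant", s0 = s0),
                            model_params(0.5, 16, r$p, r$q)),
               tolerance = 1e-13)
})

test_that("adaptation reduces to the base model at gamma = 0 and shifts equilibria", {
  p <- ref_params(q = 0.5)
  prot <- input_protocol("constant", s0 = 0.7)
  set.seed(1234)
  v <- runif(9); a <- runif(9)
  r0 <- adaptation_rhs(v, a, 0, prot, p, adaptation_params(0, 5))
  expect_equal(r0$dv, scalar_rhs(v, 0, prot, p), tolerance = 1e-15)
  expect_equal(r0$da, (v - a) / 5)
  expect_error(adaptation_params(0.1, 0), "tau_a")
  # stationary homogeneous states solve F_p(v) = gamma v (with a = v)
  eq <- adaptation_equilibria(p, 0.005)
  expect_length(eq, 3L)
  for (v0 in eq) {
    expect_lt(abs(bistable_reaction(v0, p) - 0.005 * v0), 1e-10)
    # interior layers only: the layer-J closure assumes x = S(x), which
    # adaptation-shifted equilibria do not satisfy
    r <- adaptation_rhs(rep(v0, 5), rep(v0, 5), 0,
                        input_protocol("constant", s0 = v0), p,
                        adaptation_params(0.005, 10))
    expect_lt(max(abs(c(r$dv[1:4], r$da))), 1e-9)
  }
  # strong adaptation leaves only the down state
  n_roots <- vapply(c(0.001, 0.05, 0.2, 0.5),
                    function(g) length(adaptation_equilibria(p, g)),
                    integer(1))
  expect_equal(n_roots[1], 3L)
  expect_equal(n_roots[length(n_roots)], 1L)
  expect_true(all(diff(n_roots) <= 0))
})
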