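test_that("hyper-parameters reduce to (p, q) with the right time scale", {
  r <- hyperparams_to_pq(hyper_params(1, 1, 2))
  expect_equal(r[c("p", "q", "time_scale")], list(p = 0.25, q = 0.5,
                                                  time_scale = 4))
  r2 <- hyperparams_to_pq(hyper_params(0, 1, 0))
  expect_equal(c(r2$p, r2$q), c(0, 0))
  expect_error(hyper_params(0, 0, 0), "degenerate")
})

test_that("model_params enforces the three-branch admissibility conditions", {
  expect_error(model_params(0.5, 3, 0.1, 0.5), "mu")
  expect_error(model_params(0.5, 16, 0.3, 0.5), "4/\\(4\\+mu\\)")
  expect_error(model_params(0.5, 16, 0.1, 1.2), "q")
  expect_error(model_params(0.5, 16, 0.15, 0.9), "p \\+ q")
  expect_true(model_params(0.5, 16, 0.1, 0.5)$bistable)
  expect_false(model_params(0.9, 16, 0.1, 0.5)$bistable)
})

test_that("theta_of_x matches the closed form and its symmetry", {
  expect_equal(theta_of_x(0.5, 16), 0.5)
  expect_equal(theta_of_x(0.5, 7.3), 0.5)
  xs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(theta_of_x(xs, 16) + theta_of_x(1 - xs, 16), rep(1, 10))
  # value at the lower fold abscissa of mu = 16
  xs16 <- 0.5 - sqrt(0.25 - 1 / 16)
  expect_equal(theta_of_x(xs16, 16), xs16 + log((1 - xs16) / xs16) / 16)
  expect_equal(theta_of_x(xs16, 16), 0.2316, tolerance = 1e-4)
  expect_error(theta_of_x(0, 16), "inside")
  expect_error(theta_of_x(1.2, 16), "inside")
})

test_that("fold points match the printed closed forms", {
  fp <- fold_points(16)
  expect_equal(fp$x_star, 0.5 - sqrt(0.25 - 1 / 16))
  expect_equal(fp$x_star_upper, 0.5 + sqrt(0.25 - 1 / 16))
  expect_equal(fp$x_star, 0.066987, tolerance = 1e-5)
  expect_equal(fp$x_star_upper, 0.933013, tolerance = 1e-5)
  expect_equal(fp$theta_star, 0.2316, tolerance = 1e-4)
  expect_equal(fp$theta_star_upper, 0.7684, tolerance = 1e-4)
  expect_equal(fp$theta_star + fp$theta_star_upper, 1)
  # degenerate fold as mu -> 4+
  fp4 <- fold_points(4 + 1e-10)
  expect_equal(fp4$x_star, 0.5, tolerance = 1e-4)
  expect_equal(fp4$x_star_upper, 0.5, tolerance = 1e-4)
  expect_error(fold_points(4), "mu")
})

test_that("equilibrium branches solve x = S(x) on their monotonicity intervals", {
  b <- equilibrium_branches(0.5, 16)
  expect_true(b$bistable)
  expect_equal(b$x_m, 0.5)
  expect_equal(b$x_d, 1 - b$x_u, tolerance = 1e-12)
  # independent oracle: plain bisection of x = S(x) on (0, x_star)
  oracle <- uniroot(function(x) x - raw_S(x, 16, 0.5),
                    c(1e-12, 0.5 - sqrt(0.25 - 1 / 16)), tol = 1e-14)$root
  expect_equal(b$x_d, oracle, tolerance = 1e-10)
  expect_equal(b$x_d, 3.4e-4, tolerance = 1e-2)
  # residuals and ordering across the window
  sp <- ref_sigmoid()
  for (th in seq(0.25, 0.75, by = 0.05)) {
    bt <- equilibrium_branches(th, 16)
    vals <- c(bt$x_d, bt$x_m, bt$x_u)
    expect_true(all(abs(vals - sigmoid(vals, sigmoid_params(16, th)))
                    < 1e-10))
    expect_true(bt$x_d < bt$x_star && bt$x_star < bt$x_m &&
                bt$x_m < bt$x_star_upper && bt$x_star_upper < bt$x_u)
  }
})

test_that("branches collapse at the folds and obey the x -> 1 - x symmetry", {
  fp <- fold_points(16)
  bf <- equilibrium_branches(fp$theta_star, 16)
  expect_false(bf$bistable)
  expect_equal(bf$x_d, fp$x_star)           # merged double root
  expect_true(is.na(bf$x_m))
  # outside the window only one branch survives
  b_lo <- equilibrium_branches(0.1, 16)
  expect_true(is.na(b_lo$x_d) && is.na(b_lo$x_m) && !is.na(b_lo$x_u))
  b_hi <- equilibrium_branches(0.9, 16)
  expect_true(!is.na(b_hi$x_d) && is.na(b_hi$x_m) && is.na(b_hi$x_u))
  # mirror symmetry
  for (th in c(0.3, 0.4, 0.45)) {
    a <- equilibrium_branches(th, 16)
    m <- equilibrium_branches(1 - th, 16)
    expect_equal(a$x_d, 1 - m$x_u, tolerance = 1e-10)
    expect_equal(a$x_m, 1 - m$x_m, tolerance = 1e-10)
    expect_equal(a$x_u, 1 - m$x_d, tolerance = 1e-10)
  }
})

test_that("spectrum matches the printed real part and peaks at phi = 0", {
  p <- ref_params(q = 0.5)
  b <- equilibrium_branches(0.5, 16)
  # S'(x_m) = 4, so Re nu(0) = (4 - 1)(1 - 0.1 - 0.4) = 1.5
  expect_equal(Re(spectrum_nu(b$x_m, p, 0)), 1.5)
  phis <- seq(-pi, pi, length.out = 41)
  for (x in c(b$x_d, b$x_m, b$x_u)) {
    sp <- sigmoid_deriv(x, p)
    re <- Re(spectrum_nu(x, p, phis))
    expect_equal(re, sp * (cos(phis) - 1) +
                   (sp - 1) * (1 - p$p - p$p * sp), tolerance = 1e-12)
    expect_true(all(re <= Re(spectrum_nu(x, p, 0)) + 1e-12))
  }
  expect_error(spectrum_nu(0.3, p, 0), "not an equilibrium")
})

test_that("stability classification follows the sign of Re nu(0)", {
  p <- ref_params(q = 0.5)
  b <- equilibrium_branches(0.5, 16)
  expect_identical(classify_stability("x_d", b, p), "stable")
  expect_identical(classify_stability("x_m", b, p), "unstable")
  expect_identical(classify_stability("x_u", b, p), "stable")
  # fold: merged branch has S'(x) = 1, marginal
  fp <- fold_points(16)
  bf <- equilibrium_branches(fp$theta_star, 16)
  pf <- model_params(fp$theta_star, 16, 0.1, 0.5)
  expect_identical(classify_stability("x_d", bf, pf), "marginal")
  expect_error(classify_stability("x_m", bf, pf), "absent")
})

test_that("classification agrees with nonlinear simulation of homogeneous perturbations", {
  p <- ref_params(q = 0.5)
  b <- equilibrium_branches(0.5, 16)
  for (x0 in c(b$x_d, b$x_u)) {
    for (s in c(-1, 1)) {
      tr <- simulate_semi(p, input_protocol("constant", s0 = x0),
                          "bottom_up", J = 71, t_final = 50,
                          init = rep(x0 + s * 1e-3, 71))
      expect_lt(max(abs(tr$values[, ncol(tr$values)] - x0)), 1e-6)
    }
  }
  # middle branch departs
  tr <- simulate_semi(p, input_protocol("constant", s0 = b$x_m),
                      "bottom_up", J = 71, t_final = 50,
                      init = rep(b$x_m + 1e-3, 71))
  expect_gt(max(abs(tr$values[, ncol(tr$values)] - b$x_m)), 1e-2)
})
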