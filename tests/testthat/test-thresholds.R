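test_that("constant sub-separatrix input stagnates; strong input propagates", {
  p <- model_params(0.35, 16, 0.1, 0.35)
  b <- equilibrium_branches(0.35, 16)
  tr <- simulate_semi(p, input_protocol("constant",
                                        s0 = (b$x_d + b$x_m) / 2),
                      "bottom_up", J = 100, t_final = 300)
  expect_identical(classify_outcome(tr), "stagnation")
  tr2 <- simulate_semi(p, input_protocol("constant", s0 = 0.95),
                       "bottom_up", J = 100, t_final = 300)
  expect_identical(classify_outcome(tr2), "front_propagation")
})

test_that("stationary profiles satisfy the stationary equations", {
  p <- model_params(0.35, 16, 0.1, 0.35)
  b <- equilibrium_branches(0.35, 16)
  # anchored at the down state: the homogeneous down state itself
  sd <- stationary_profile(p, b$x_d, "down", "bottom_up", J = 100)
  expect_lt(max(abs(sd$values - b$x_d)), 1e-6)
  # generic sub-separatrix anchor: non-constant decaying entrance profile
  s0 <- (b$x_d + b$x_m) / 2
  sg <- stationary_profile(p, s0, "down", "bottom_up", J = 100)
  expect_lt(sg$residual, 1e-8)
  expect_gt(sg$values[1], b$x_d + 1e-4)              # entrance lifted
  expect_lt(abs(sg$values[100] - b$x_d), 1e-4)       # down tail
  expect_true(all(diff(sg$values[1:50]) < 1e-12))    # monotone decay
  # up tail anchored at the down state (c_ud > 0 regime)
  su <- stationary_profile(p, b$x_d, "up", "bottom_up", J = 100)
  expect_lt(su$residual, 1e-8)
  expect_lt(abs(su$values[100] - b$x_u), 1e-4)
})

test_that("s0* bisection satisfies its dichotomy and sits above x_m", {
  p <- model_params(0.35, 16, 0.1, 0.35)
  b <- equilibrium_branches(0.35, 16)
  th <- find_s0_star(p, "bottom_up")
  expect_gte(th$value, b$x_m)
  expect_lte(th$bracket[["hi"]] - th$bracket[["lo"]], 2 * th$tol)
  # outcomes flip across the threshold
  lab <- function(s0) classify_outcome(
    simulate_semi(p, input_protocol("constant", s0 = s0), "bottom_up",
                  J = 100, t_final = 300))
  expect_identical(lab(th$value - 10 * th$tol), "stagnation")
  expect_identical(lab(th$value + 10 * th$tol), "front_propagation")
  # adverse regime: c_ud < 0, no bottom-up threshold
  expect_error(find_s0_star(ref_params(q = 0.8), "bottom_up"),
               "undefined")
})

test_that("tau* dichotomy, monotone response, and orientation ordering", {
  p <- model_params(0.28, 16, 0.1, 0.35)
  bu <- find_tau_star(p, "bottom_up", J = 75, t_final = 350)
  expect_lte(bu$bracket[["hi"]] - bu$bracket[["lo"]], 2 * bu$tol)
  b <- equilibrium_branches(0.28, 16)
  lab <- function(tau) classify_outcome(
    simulate_semi(p, input_protocol("flashed", s0 = b$x_u, tau = tau,
                                    baseline = b$x_d),
                  "bottom_up", J = 75, t_final = 350))
  expect_identical(lab(bu$value - 10 * bu$tol), "propagation_failure")
  lab_hi <- lab(bu$value + 10 * bu$tol)
  expect_true(lab_hi %in% c("stacked_propagation", "front_propagation",
                            "pulse_propagation"))
  # monotone in tau: much longer flashes still propagate
  expect_true(lab(bu$value + 5) %in%
                c("stacked_propagation", "front_propagation",
                  "pulse_propagation"))
  # feedback strength q = 0.35 favours the bottom-up direction
  td <- find_tau_star(p, "top_down", J = 75, t_final = 400)
  expect_lt(bu$value, td$value)
})

test_that("tau* takes comparable values in both orientations at q = 0.5", {
  p <- model_params(0.28, 16, 0.1, 0.5)
  bu <- find_tau_star(p, "bottom_up", J = 75, t_final = 350)
  td <- find_tau_star(p, "top_down", J = 75, t_final = 350)
  expect_lt(abs(bu$value - td$value) / max(bu$value, td$value), 0.25)
})

test_that("the pinning boundary is consistent with the speed estimator", {
  p <- model_params(0.4, 16, 0.1, 0.65)
  th <- find_pinning_boundary(p, "theta", "bottom_up", tol = 2e-3,
                              J = 300, t_final = 120)
  expect_identical(th$kind, "theta0")
  # just on the moving side: a clearly positive speed; just inside: pinned
  below <- estimate_speed(model_params(th$value - 5e-3, 16, 0.1, 0.65),
                          "u_to_d", J = 300, t_final = 120)
  above <- estimate_speed(model_params(th$value + 5e-3, 16, 0.1, 0.65),
                          "u_to_d", J = 300, t_final = 120)
  expect_gt(below$c, 5e-3)
  expect_true(above$pinned || above$c < 5e-3)
  expect_error(find_pinning_boundary(p, "theta", "bottom_up",
                                     bracket = c(0.26, 0.30),
                                     J = 300, t_final = 120),
               "sign change")
})

test_that("boundaries mirror through the c_ud(theta) = c_du(1-theta) identity", {
  # smallest theta with c_du = 0 at q = 0.65 equals 1 minus the upper edge
  # of the c_ud pinned interval (test-local bisection for the latter)
  p <- model_params(0.4, 16, 0.1, 0.65)
  td <- find_pinning_boundary(p, "theta", "top_down",
                              bracket = c(0.58, 0.70), tol = 2e-3,
                              J = 300, t_final = 120)
  c_of <- function(th) estimate_speed(model_params(th, 16, 0.1, 0.65),
                                      "u_to_d", J = 300, t_final = 120,
                                      on_margin = "truncate")
  lo <- 0.365; hi <- 0.42                # pinned vs negative-moving
  expect_true(c_of(lo)$pinned)
  expect_lt(c_of(hi)$c, -5e-3)
  while (hi - lo > 4e-3) {
    mid <- (lo + hi) / 2
    est <- c_of(mid)
    if (est$pinned) lo <- mid else hi <- mid
  }
  upper_edge <- (lo + hi) / 2
  expect_lt(abs(td$value - (1 - upper_edge)), 2 * (2e-3 + 4e-3))
})

test_that("the regime map recovers all four joint outcomes", {
  rm <- regime_map(q = c(0.35, 0.5, 0.8), s0 = c(0.25, 1.0),
                   theta = 0.35, mu = 16, p = 0.1)
  expect_true(all(rm$label[rm$s0 == 0.25] == "both_stagnate"))
  expect_identical(rm$label[rm$q == 0.35 & rm$s0 == 1], "bottom_up_only")
  expect_identical(rm$label[rm$q == 0.5 & rm$s0 == 1], "both_propagate")
  expect_identical(rm$label[rm$q == 0.8 & rm$s0 == 1], "top_down_only")
  expect_setequal(unique(rm$label),
                  c("both_stagnate", "bottom_up_only", "both_propagate",
                    "top_down_only"))
  expect_true(all(rm$normal_regime == (rm$label == "both_propagate")))
  # single node reduces to two classifications
  one <- regime_map(q = 0.5, s0 = 1.0, theta = 0.35, mu = 16, p = 0.1)
  expect_identical(one$bottom_up, "front_propagation")
  expect_identical(one$label, "both_propagate")
})
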