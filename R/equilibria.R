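# Stationary homogeneous solutions of the lattice: the down/middle/up
# branches x_d < x_m < x_u solving x = S(x), the fold points where branches
# collide, and the linear stability spectrum of each branch.

#' Threshold as a function of the fixed-point abscissa
#'
#' Solving \eqn{x = S(x)} for the threshold gives the explicit
#' parametrization \eqn{\theta = f(x) = x + \log((1-x)/x)/\mu} on
#' \eqn{x \in (0,1)}. Its level sets define the three equilibrium branches:
#' \eqn{f} is decreasing on \eqn{(0, x_*)} and \eqn{(x^*, 1)} and increasing
#' on \eqn{(x_*, x^*)} once \eqn{\mu > 4}.
#'
#' @param x Numeric vector in (0, 1).
#' @param mu Sigmoid slope (`> 0`).
#' @return \eqn{f(x)}, same length as `x`.
#' @examples
#' theta_of_x(0.5, 16)                       # 0.5 for any mu
#' theta_of_x(0.2, 16) + theta_of_x(0.8, 16) # 1: log antisymmetry
#' @export
theta_of_x <- function(x, mu) {
  stopifnot(is.numeric(x), is.numeric(mu), length(mu) == 1L, mu > 0)
  if (any(x <= 0) || any(x >= 1))
    stop("`x` must lie strictly inside (0, 1)")
  x + log((1 - x) / x) / mu
}

#' Fold points of the equilibrium branches
#'
#' The critical points of \eqn{f(x) = x + \log((1-x)/x)/\mu} are explicit:
#' \eqn{x_*(\mu) = 1/2 - \sqrt{1/4 - 1/\mu}} and
#' \eqn{x^*(\mu) = 1/2 + \sqrt{1/4 - 1/\mu}}, with fold thresholds
#' \eqn{\theta_* = f(x_*)} and \eqn{\theta^* = f(x^*)}. By the sigmoid
#' symmetry, \eqn{\theta_* + \theta^* = 1}. The bistable window is
#' \eqn{\theta \in (\theta_*, \theta^*)}.
#'
#' @param mu Sigmoid slope, `> 4` (at `mu = 4` the folds merge at 1/2 and
#'   the window is empty).
#' @return A list with `x_star`, `x_star_upper`, `theta_star`,
#'   `theta_star_upper`.
#' @examples
#' fold_points(16)  # x_star ~ 0.0670, theta_star ~ 0.2316
#' @export
fold_points <- function(mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (mu <= 4)
    stop("`mu` must exceed 4: no bistable window for mu = ", mu)
  r <- sqrt(0.25 - 1 / mu)
  x_star <- 0.5 - r
  x_star_upper <- 0.5 + r
  list(x_star = x_star,
       x_star_upper = x_star_upper,
       theta_star = theta_of_x(x_star, mu),
       theta_star_upper = theta_of_x(x_star_upper, mu))
}

# Solve f(x) = theta on one monotonicity interval by Brent bracketing, then
# polish on g(x) = x - S(x) with damped Newton (g' = 1 - S'), which sharpens
# the fixed-point residual below 1e-12 away from the folds.
solve_branch <- function(theta, mu, lower, upper) {
  sp <- sigmoid_params(mu, theta)
  h <- function(x) theta_of_x(x, mu) - theta
  hl <- h(lower); hu <- h(upper)
  if (!is.finite(hl) || !is.finite(hu) || hl * hu > 0) return(NA_real_)
  x <- stats::uniroot(h, c(lower, upper), tol = 1e-13)$root
  for (i in 1:4) {
    g <- x - sigmoid(x, sp)
    dg <- 1 - sigmoid_deriv(x, sp)
    if (abs(dg) < 1e-8) break
    step <- g / dg
    xn <- x - step
    if (xn <= lower || xn >= upper) break
    x <- xn
    if (abs(step) < 1e-15) break
  }
  x
}

#' Equilibrium branches of the lattice
#'
#' Computes the stationary homogeneous solutions of the lattice at
#' `(theta, mu)`: the roots of \eqn{x = S(x)}, found by bracketed
#' root-finding on each monotonicity interval of the parametrization
#' \eqn{f}. Inside the bistable window \eqn{(\theta_*, \theta^*)} all three
#' branches \eqn{x_d < x_m < x_u} exist (down state, unstable separatrix,
#' up state); outside, only the surviving branch(es) are reported and
#' `bistable` is `FALSE`. Within `1e-10` of a fold the merged double root is
#' reported once on the surviving slot and `bistable` is `FALSE` (double
#' roots break bracketing).
#'
#' @param theta Sigmoid threshold.
#' @param mu Sigmoid slope (`> 4`).
#' @return An object of class `pcl_branches`: fields `x_d`, `x_m`, `x_u`
#'   (`NA` when absent), the four fold quantities, `bistable`, `theta`,
#'   `mu`. Serializes to a flat record via `as.list()`/`unclass()`.
#' @examples
#' b <- equilibrium_branches(0.5, 16)
#' b$x_m  # exactly 0.5 by symmetry
#' @export
equilibrium_branches <- function(theta, mu) {
  fp <- fold_points(mu)
  eps <- 1e-14
  fold_tol <- 1e-10
  at_lower_fold <- abs(theta - fp$theta_star) < fold_tol
  at_upper_fold <- abs(theta - fp$theta_star_upper) < fold_tol
  x_d <- x_m <- x_u <- NA_real_
  if (at_lower_fold) {
    # x_d and x_m merge at x_star; x_u survives
    x_d <- fp$x_star
    x_u <- solve_branch(theta, mu, fp$x_star_upper, 1 - eps)
  } else if (at_upper_fold) {
    x_u <- fp$x_star_upper
    x_d <- solve_branch(theta, mu, eps, fp$x_star)
  } else {
    if (theta > fp$theta_star)
      x_d <- solve_branch(theta, mu, eps, fp$x_star)
    if (theta > fp$theta_star && theta < fp$theta_star_upper)
      x_m <- solve_branch(theta, mu, fp$x_star, fp$x_star_upper)
    if (theta < fp$theta_star_upper)
      x_u <- solve_branch(theta, mu, fp$x_star_upper, 1 - eps)
  }
  structure(
    list(x_d = x_d, x_m = x_m, x_u = x_u,
         x_star = fp$x_star, x_star_upper = fp$x_star_upper,
         theta_star = fp$theta_star,
         theta_star_upper = fp$theta_star_upper,
         bistable = !at_lower_fold && !at_upper_fold &&
           !is.na(x_d) && !is.na(x_m) && !is.na(x_u),
         theta = theta, mu = mu),
    class = "pcl_branches")
}

#' @export
print.pcl_branches <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.8g", v)
  cat(sprintf("equilibria at (theta, mu) = (%g, %g):\n", x$theta, x$mu))
  cat(sprintf("  x_d = %s, x_m = %s, x_u = %s  [%s]\n",
              fmt(x$x_d), fmt(x$x_m), fmt(x$x_u),
              if (x$bistable) "bistable" else "not bistable"))
  cat(sprintf("  window: theta in (%.6g, %.6g)\n",
              x$theta_star, x$theta_star_upper))
  invisible(x)
}

check_branches <- function(branches) {
  if (!inherits(branches, "pcl_branches"))
    stop("`branches` must come from equilibrium_branches()")
  branches
}

#' Linear stability spectrum around a homogeneous equilibrium
#'
#' Plane-wave perturbations \eqn{u_j(t) = e^{\nu t + i\varphi j}} of a
#' stationary homogeneous state \eqn{x = S(x)} grow or decay according to
#' \deqn{\nu(\varphi) = (1-q) S'(x) e^{-i\varphi} - (1-p) - p S'(x)^2
#'   + q S'(x) e^{i\varphi},}
#' whose real part is \eqn{S'(x)(\cos\varphi - 1) +
#' (S'(x)-1)(1 - p - p S'(x))} and is maximal at \eqn{\varphi = 0}.
#'
#' @param x Equilibrium value; must satisfy `|x - S(x)| < 1e-8` (loose
#'   enough to admit simulated fixed points).
#' @param params A [model_params()] object.
#' @param phi Wavenumber(s) in `[-pi, pi]`.
#' @return Complex vector \eqn{\nu(\varphi)}, same length as `phi`.
#' @export
spectrum_nu <- function(x, params, phi = 0) {
  check_model_params(params)
  stopifnot(is.numeric(x), length(x) == 1L, is.numeric(phi))
  if (abs(x - sigmoid(x, params)) >= 1e-8)
    stop("`x` is not an equilibrium: |x - S(x)| = ",
         format(abs(x - sigmoid(x, params))))
  sp <- sigmoid_deriv(x, params)
  (1 - params$q) * sp * exp(-1i * phi) - (1 - params$p) - params$p * sp^2 +
    params$q * sp * exp(1i * phi)
}

#' Classify the linear stability of an equilibrium branch
#'
#' The decisive quantity is \eqn{\max_\varphi \mathrm{Re}\,\nu(\varphi) =
#' \mathrm{Re}\,\nu(0) = (S'(x)-1)(1-p-pS'(x))}, which vanishes iff
#' \eqn{S'(x) = 1}, i.e. exactly at the folds. Inside the bistable window
#' the down and up branches are stable and the middle branch is unstable.
#'
#' @param branch One of `"x_d"`, `"x_m"`, `"x_u"`.
#' @param branches A [equilibrium_branches()] result containing that branch.
#' @param params A [model_params()] object (its `theta`, `mu` should match
#'   `branches`).
#' @return `"stable"`, `"unstable"`, or `"marginal"` when
#'   \eqn{|\mathrm{Re}\,\nu(0)|} is below 1e-10 (fold degeneracy: the
#'   linearization cannot classify the branch).
#' @export
classify_stability <- function(branch = c("x_d", "x_m", "x_u"),
                               branches, params) {
  branch <- match.arg(branch)
  check_branches(branches)
  check_model_params(params)
  x <- branches[[branch]]
  if (is.na(x)) stop("branch `", branch, "` is absent at these parameters")
  re0 <- Re(spectrum_nu(x, params, 0))
  if (abs(re0) < 1e-10) return("marginal")
  if (re0 < 0) "stable" else "unstable"
}
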