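# Logistic activation S(x) = 1 / (1 + exp(-mu * (x - theta))) and friends.
# Every other module evaluates the lattice nonlinearity through these.

#' Sigmoid parameters
#'
#' Container for the two parameters of the logistic activation
#' \eqn{S(x) = 1 / (1 + e^{-\mu (x - \theta)})}: the slope \eqn{\mu > 0} and
#' the threshold \eqn{\theta \ge 0}. The analysis modules additionally
#' require \eqn{\mu > 4} (three intervals of monotony of the branch
#' parametrization); that stricter condition is enforced by
#' [model_params()], not here.
#'
#' @param mu Slope of the sigmoid (dimensionless, `> 0`).
#' @param theta Activation threshold (dimensionless, `>= 0`).
#' @return An object of class `pcl_sigmoid` with fields `mu` and `theta`.
#' @examples
#' sp <- sigmoid_params(mu = 16, theta = 0.5)
#' sigmoid(0.5, sp)  # 0.5 at the symmetry point
#' @export
sigmoid_params <- function(mu, theta) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (mu <= 0) stop("`mu` must be positive, got ", mu)
  if (theta < 0) stop("`theta` must be non-negative, got ", theta)
  structure(list(mu = mu, theta = theta), class = "pcl_sigmoid")
}

check_sigmoid_params <- function(params) {
  if (!inherits(params, "pcl_sigmoid"))
    stop("`params` must be created by sigmoid_params() or model_params()")
  params
}

#' Logistic activation and its derivatives
#'
#' `sigmoid()` evaluates \eqn{S(x) = 1/(1 + e^{-\mu (x - \theta)})} through
#' [stats::plogis()], whose exp(-|z|) branch never overflows, so arguments
#' far outside \eqn{[0, 1]} (transient lattice states) are safe.
#' `sigmoid_deriv()` returns \eqn{S'(x) = \mu S(x)(1 - S(x))} and
#' `sigmoid_deriv2()` returns \eqn{S''(x) = \mu^2 S(1-S)(1-2S)}.
#'
#' @param x Numeric vector of membrane-potential-like activities (finite).
#' @param params A [sigmoid_params()] (or [model_params()]) object.
#' @return Numeric vector of the same length as `x`; `sigmoid()` values lie
#'   strictly in (0, 1) and are strictly increasing in `x`.
#' @examples
#' sp <- sigmoid_params(16, 0.5)
#' sigmoid_deriv(0.5, sp)  # mu / 4 = 4 at the inflection point
#' @export
sigmoid <- function(x, params) {
  check_sigmoid_params(params)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric")
  stats::plogis(x, location = params$theta, scale = 1 / params$mu)
}

#' @rdname sigmoid
#' @export
sigmoid_deriv <- function(x, params) {
  s <- sigmoid(x, params)
  params$mu * s * (1 - s)
}

#' @rdname sigmoid
#' @export
sigmoid_deriv2 <- function(x, params) {
  s <- sigmoid(x, params)
  params$mu^2 * s * (1 - s) * (1 - 2 * s)
}

# one-shot warning state for the inverse clipping guard
.pcl_state <- new.env(parent = emptyenv())
.pcl_state$inverse_clip_warned <- FALSE

#' Inverse sigmoid
#'
#' \eqn{S^{-1}(y) = \theta + \log(y / (1 - y)) / \mu}, used by the top
#' boundary closure of the finite network, where the last layer's artificial
#' neighbour is \eqn{v_{J+1} = S^{-1}(v_J)}. Arguments within `guard` of 0
#' or 1 are clipped to `[guard, 1 - guard]` before inversion (the top layer
#' saturates numerically toward the up state); the clip emits a warning once
#' per session. Values outside \eqn{[0, 1]} beyond the guard are a domain
#' error.
#'
#' @param y Numeric vector in (0, 1).
#' @param params A [sigmoid_params()] object.
#' @param guard Clipping guard width (default `1e-12`).
#' @return Numeric vector with `sigmoid(sigmoid_inverse(y)) == y` to 1e-12
#'   relative tolerance for `y` in `[guard, 1 - guard]`.
#' @export
sigmoid_inverse <- function(y, params, guard = 1e-12) {
  check_sigmoid_params(params)
  if (!is.numeric(y) || anyNA(y)) stop("`y` must be numeric without NA")
  if (any(y <= -guard) || any(y >= 1 + guard))
    stop("`y` outside the domain (0, 1) of the inverse sigmoid")
  lo <- y < guard
  hi <- y > 1 - guard
  if (any(lo) || any(hi)) {
    if (!.pcl_state$inverse_clip_warned) {
      warning("sigmoid_inverse(): argument clipped to [", guard, ", 1 - ",
              guard, "] (warning shown once per session)", call. = FALSE)
      .pcl_state$inverse_clip_warned <- TRUE
    }
    y[lo] <- guard
    y[hi] <- 1 - guard
  }
  stats::qlogis(y, location = params$theta, scale = 1 / params$mu)
}
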