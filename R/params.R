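# Model parameter containers: the rescaled tuple Lambda = (theta, mu, p, q)
# and the raw hyper-parameters (alpha, beta, lambda).

#' Lattice model parameters
#'
#' The rescaled parameter tuple \eqn{\Lambda = (\theta, \mu, p, q)} of the
#' scalar predictive-coding lattice. `p` is the relative strength of the
#' feedforward error correction, `q` the relative strength of the feedback
#' error correction, and `1 - p - q` the relative strength of the
#' instantaneous feedforward drive. Admissibility requires \eqn{\mu > 4},
#' \eqn{0 \le p < 4/(4+\mu)} (so that exactly three stationary homogeneous
#' branches coexist), \eqn{0 \le q \le 1} and \eqn{p + q \le 1}. The
#' bistable set additionally requires
#' \eqn{\theta_*(\mu) < \theta < \theta^*(\mu)}; the constructor records
#' that membership in the `bistable` field rather than failing, so the same
#' container can describe monostable regimes.
#'
#' @param theta Sigmoid threshold (`>= 0`).
#' @param mu Sigmoid slope (`> 4`).
#' @param p Relative feedforward error-correction strength, in
#'   `[0, 4/(4+mu))`.
#' @param q Relative feedback error-correction strength, in `[0, 1]` with
#'   `p + q <= 1`.
#' @return An object of class `c("pcl_params", "pcl_sigmoid")` with fields
#'   `theta`, `mu`, `p`, `q` and a logical `bistable` flag.
#' @examples
#' model_params(theta = 0.5, mu = 16, p = 0.1, q = 0.5)
#' @export
model_params <- function(theta, mu, p, q) {
  for (v in list(theta, mu, p, q))
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (mu <= 4)
    stop("`mu` must exceed 4 (otherwise no bistable window exists), got ", mu)
  if (theta < 0) stop("`theta` must be non-negative, got ", theta)
  pmax_ <- 4 / (4 + mu)
  if (p < 0 || p >= pmax_)
    stop(sprintf("`p` must satisfy 0 <= p < 4/(4+mu) = %.6g, got %g",
                 pmax_, p))
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1], got ", q)
  if (p + q > 1) stop("`p + q` must not exceed 1, got ", p + q)
  fp <- fold_points(mu)
  structure(
    list(theta = theta, mu = mu, p = p, q = q,
         bistable = theta > fp$theta_star && theta < fp$theta_star_upper),
    class = c("pcl_params", "pcl_sigmoid"))
}

check_model_params <- function(params) {
  if (!inherits(params, "pcl_params"))
    stop("`params` must be created by model_params()")
  params
}

# require membership in the bistable set P
check_bistable <- function(params) {
  check_model_params(params)
  if (!params$bistable)
    stop(sprintf(paste0("parameters lie outside the bistable window: theta ",
                        "= %g not in (theta_star, theta_star_upper) = ",
                        "(%.6g, %.6g) for mu = %g"),
                 params$theta, fold_points(params$mu)$theta_star,
                 fold_points(params$mu)$theta_star_upper, params$mu))
  params
}

#' @export
print.pcl_params <- function(x, ...) {
  cat(sprintf(
    "lattice parameters: theta = %g, mu = %g, p = %g, q = %g (%s)\n",
    x$theta, x$mu, x$p, x$q,
    if (x$bistable) "bistable" else "outside the bistable window"))
  invisible(x)
}

#' Hyper-parameters of the unscaled model
#'
#' The raw gains of the continuous-time predictive-coding model:
#' `alpha` (feedforward error correction), `beta` (instantaneous feedforward
#' drive) and `lambda` (feedback error correction), all non-negative with a
#' positive sum (the all-zero case yields trivial constant dynamics and is
#' rejected).
#'
#' @param alpha,beta,lambda Non-negative gains with `alpha+beta+lambda > 0`.
#' @return An object of class `pcl_hyper`.
#' @export
hyper_params <- function(alpha, beta, lambda) {
  for (v in list(alpha, beta, lambda))
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (alpha < 0 || beta < 0 || lambda < 0)
    stop("hyper-parameters must be non-negative")
  if (alpha + beta + lambda <= 0)
    stop("degenerate dynamics: alpha + beta + lambda must be positive")
  structure(list(alpha = alpha, beta = beta, lambda = lambda),
            class = "pcl_hyper")
}

#' Reduce hyper-parameters to the rescaled pair (p, q)
#'
#' After rescaling time by \eqn{t \leftrightarrow t(\alpha+\beta+\lambda)},
#' the model depends only on \eqn{p = \alpha/(\alpha+\beta+\lambda)} and
#' \eqn{q = \lambda/(\alpha+\beta+\lambda)}. The sum itself is returned as
#' `time_scale`: one rescaled time unit equals `1/time_scale` physical
#' units.
#'
#' @param h A [hyper_params()] object.
#' @return A list with fields `p`, `q` and `time_scale`.
#' @examples
#' hyperparams_to_pq(hyper_params(1, 1, 2))  # p = 0.25, q = 0.5
#' @export
hyperparams_to_pq <- function(h) {
  if (!inherits(h, "pcl_hyper")) stop("`h` must come from hyper_params()")
  s <- h$alpha + h$beta + h$lambda
  list(p = h$alpha / s, q = h$lambda / s, time_scale = s)
}
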