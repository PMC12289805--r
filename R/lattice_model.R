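# Right-hand sides of the model family: the local lattice map N, the
# finite-J scalar system with its boundary closures, truncated bi-infinite
# lattices, the d-population vector model, and the adaptation extension.

#' Local lattice map
#'
#' The nonlinear coupling applied at every interior layer,
#' \deqn{\mathcal{N}(u, v, w) = (1-p-q)(S(u) - v) + p S'(v)(u - S(v))
#'   + q (S(w) - v),}
#' where `u` is the layer below (feedforward side), `v` the layer itself and
#' `w` the layer above (feedback side). On the diagonal it reduces to the
#' bistable reaction term: \eqn{\mathcal{N}(v,v,v) = F_p(v) =
#' (-v + S(v))(1 - p - p S'(v))}. Both partial derivatives
#' \eqn{\partial_u \mathcal{N} = (1-p-q)S'(u) + pS'(v)} and
#' \eqn{\partial_w \mathcal{N} = q S'(w)} are positive on admissible
#' parameters: the lattice is cooperative, which is what makes monotone
#' front theory applicable.
#'
#' @param u,v,w Numeric vectors (recycled to a common length): activities of
#'   the lower neighbour, the layer, and the upper neighbour.
#' @param params A [model_params()] object.
#' @return Numeric vector of time-derivatives.
#' @export
local_map <- function(u, v, w, params) {
  check_model_params(params)
  (1 - params$p - params$q) * (sigmoid(u, params) - v) +
    params$p * sigmoid_deriv(v, params) * (u - sigmoid(v, params)) +
    params$q * (sigmoid(w, params) - v)
}

#' Bistable reaction term
#'
#' \eqn{F_p(v) = (-v + S(v)) (1 - p - p S'(v))}: the on-diagonal reduction
#' of [local_map()], whose roots are the stationary homogeneous states.
#'
#' @param v Numeric vector.
#' @param params A [model_params()] object.
#' @export
bistable_reaction <- function(v, params) {
  check_model_params(params)
  (-v + sigmoid(v, params)) *
    (1 - params$p - params$p * sigmoid_deriv(v, params))
}

#' Scalar finite-network right-hand side
#'
#' The J-layer system with the two boundary rules of the finite network:
#' the first layer sees the external input \eqn{v_0(t) = s_0(t)} as its
#' lower neighbour, and the last layer's artificial upper neighbour is
#' \eqn{v_{J+1} = S^{-1}(v_J)}, under which the feedback term
#' \eqn{q(S(v_{J+1}) - v_J) = q(v_J - v_J)} vanishes identically. The
#' cancellation is implemented symbolically (the term is omitted) rather
#' than through `sigmoid(sigmoid_inverse(.))`, avoiding clipping artifacts
#' near saturation.
#'
#' @param state Numeric vector of layer activities `v_1..v_J`, `J >= 2`.
#' @param t Time (passed to the protocol).
#' @param protocol An [input_protocol()] object supplying `s_0(t)`.
#' @param params A [model_params()] object.
#' @return Vector of time-derivatives, same length as `state`.
#' @export
scalar_rhs <- function(state, t, protocol, params) {
  check_model_params(params)
  J <- length(state)
  if (J < 2) stop("the finite network needs at least J = 2 layers")
  s0 <- protocol_value(protocol, t)
  u <- c(s0, state[-J])
  w <- state[-1]
  p <- params$p; q <- params$q
  su <- sigmoid(u, params)
  sv <- sigmoid(state, params)
  dv <- (1 - p - q) * (su - state) +
    p * sigmoid_deriv(state, params) * (u - sv)
  dv[-J] <- dv[-J] + q * (sigmoid(w, params) - state[-J])
  dv
}

# Truncated bi-infinite lattice: both ghost ends clamped to the exact
# asymptotic equilibrium values (fronts converge exponentially to the
# equilibria, so clamping is the faithful truncation).
clamped_rhs <- function(state, params, left, right) {
  J <- length(state)
  u <- c(left, state[-J])
  w <- c(state[-1], right)
  local_map(u, state, w, params)
}

# Truncated top-down semi-infinite lattice in mirrored (depth) coordinates:
# w_k := v_{-k}, k = 1..J, so w_k' = N(w_{k+1}, w_k, w_{k-1}) with
# w_0 = s_0(t) entering through the feedback slot. The far-end ghost
# w_{J+1} on the feedforward slot is closed by S^-1(w_J): the drive term
# (1-p-q)(S(w_{J+1}) - w_J) then cancels symbolically and only the
# error-correction term p S'(w_J)(S^-1(w_J) - S(w_J)) remains, which is
# exact at any homogeneous equilibrium.
topdown_rhs <- function(state, t, protocol, params) {
  J <- length(state)
  if (J < 2) stop("the truncated top-down network needs at least 2 layers")
  s0 <- protocol_value(protocol, t)
  p <- params$p; q <- params$q
  u <- c(state[-1], NA_real_)           # deeper neighbour w_{k+1}
  w <- c(s0, state[-J])                 # shallower neighbour w_{k-1}
  sv <- sigmoid(state, params)
  dv <- q * (sigmoid(w, params) - state)
  dv[-J] <- dv[-J] + (1 - p - q) * (sigmoid(u[-J], params) - state[-J]) +
    p * sigmoid_deriv(state[-J], params) * (u[-J] - sv[-J])
  ghost <- sigmoid_inverse(min(max(state[J], 1e-12), 1 - 1e-12), params)
  dv[J] <- dv[J] + p * sigmoid_deriv(state[J], params) * (ghost - sv[J])
  dv
}

#' Vector (d-population) model parameters
#'
#' The full model couples `d` populations per layer through a feedforward
#' weight matrix `W_f` and a feedback weight matrix `W_b`, with raw
#' hyper-parameter gains (no time rescaling is applied for `d > 1`; the
#' scalar reduction at identity weights equals [scalar_rhs()] up to the
#' factor `alpha + beta + lambda`).
#'
#' @param W_f,W_b `d x d` finite numeric matrices.
#' @param hyper A [hyper_params()] object.
#' @param sigmoid A [sigmoid_params()] object.
#' @return An object of class `pcl_vector_params`.
#' @export
vector_model_params <- function(W_f, W_b, hyper, sigmoid) {
  W_f <- as.matrix(W_f); W_b <- as.matrix(W_b)
  if (!all(is.finite(W_f)) || !all(is.finite(W_b)))
    stop("weight matrices must be finite")
  d <- nrow(W_f)
  if (ncol(W_f) != d || !all(dim(W_b) == d))
    stop("W_f and W_b must be square matrices of the same size")
  if (!inherits(hyper, "pcl_hyper")) stop("`hyper` must be hyper_params()")
  check_sigmoid_params(sigmoid)
  structure(list(d = d, W_f = W_f, W_b = W_b, hyper = hyper,
                 sigmoid = sigmoid),
            class = "pcl_vector_params")
}

#' Diagonal connection weights
#'
#' When `W_f` and `W_b` are scalar multiples of the identity the vector
#' model decouples into scalar equations with two extra weights
#' `(omega_f, omega_b)`; `(1, 1)` recovers the base scalar model.
#'
#' @param omega_f,omega_b Finite real weights.
#' @return An object of class `pcl_diag_weights`.
#' @export
diagonal_weights <- function(omega_f, omega_b) {
  stopifnot(is.numeric(omega_f), length(omega_f) == 1L, is.finite(omega_f),
            is.numeric(omega_b), length(omega_b) == 1L, is.finite(omega_b))
  structure(list(omega_f = omega_f, omega_b = omega_b),
            class = "pcl_diag_weights")
}

#' Vector-model right-hand side
#'
#' The d-population network in physical time,
#' \deqn{V_j' = \beta (W_f \mathcal{S}(V_{j-1}) - V_j)
#'   + \alpha D\mathcal{S}(V_j) W_b^T (V_{j-1} - W_b \mathcal{S}(V_j))
#'   + \lambda (W_b \mathcal{S}(V_{j+1}) - V_j),}
#' with the external input \eqn{V_0 = S_0(t)} at the first layer and no
#' feedback term at the last layer (no incoming top-down signal).
#'
#' @param state `d x J` matrix of activities (`d = 1` input may be a
#'   vector).
#' @param t Time.
#' @param protocol An [input_protocol()] object; its amplitude is recycled
#'   across the `d` populations.
#' @param vparams A [vector_model_params()] object.
#' @return `d x J` matrix of derivatives.
#' @export
vector_rhs <- function(state, t, protocol, vparams) {
  if (!inherits(vparams, "pcl_vector_params"))
    stop("`vparams` must come from vector_model_params()")
  if (is.null(dim(state))) state <- matrix(state, nrow = vparams$d)
  d <- vparams$d
  if (nrow(state) != d)
    stop("`state` must have d = ", d, " rows, got ", nrow(state))
  J <- ncol(state)
  if (J < 2) stop("the vector network needs at least 2 layers")
  sp <- vparams$sigmoid
  a <- vparams$hyper$alpha; b <- vparams$hyper$beta
  l <- vparams$hyper$lambda
  s0 <- matrix(rep_len(protocol_value(protocol, t), d), nrow = d)
  Vprev <- cbind(s0, state[, -J, drop = FALSE])
  SV <- matrix(sigmoid(as.vector(state), sp), nrow = d)
  Sprev <- matrix(sigmoid(as.vector(Vprev), sp), nrow = d)
  E <- Vprev - vparams$W_b %*% SV
  dv <- b * (vparams$W_f %*% Sprev - state) +
    a * matrix(sigmoid_deriv(as.vector(state), sp), nrow = d) *
      (t(vparams$W_b) %*% E)
  if (l > 0) {
    Snext <- matrix(sigmoid(as.vector(state[, -1, drop = FALSE]), sp),
                    nrow = d)
    fb <- l * (cbind(vparams$W_b %*% Snext,
                     matrix(0, d, 1)) - state)
    fb[, J] <- 0
    dv <- dv + fb
  }
  dv
}

#' Scalar diagonal-weight right-hand side
#'
#' Convenience reduction of [vector_rhs()] for `d = 1` with
#' `W_f = omega_f`, `W_b = omega_b`:
#' \deqn{v_j' = \beta(\omega_f S(v_{j-1}) - v_j)
#'   + \alpha S'(v_j)\,\omega_b (v_{j-1} - \omega_b S(v_j))
#'   + \lambda(\omega_b S(v_{j+1}) - v_j).}
#'
#' @param state Numeric vector of layer activities.
#' @inheritParams vector_rhs
#' @param weights A [diagonal_weights()] object.
#' @param hyper A [hyper_params()] object.
#' @param sigmoid A [sigmoid_params()] object.
#' @export
diagonal_rhs <- function(state, t, protocol, weights, hyper, sigmoid) {
  if (!inherits(weights, "pcl_diag_weights"))
    stop("`weights` must come from diagonal_weights()")
  vp <- vector_model_params(matrix(weights$omega_f), matrix(weights$omega_b),
                            hyper, sigmoid)
  drop(vector_rhs(matrix(state, nrow = 1), t, protocol, vp))
}

#' Adaptation parameters
#'
#' Spike-frequency adaptation adds a linear recovery variable per layer:
#' `gamma` scales how strongly adaptation pulls activity down and `tau_a`
#' is its (slow) timescale. `gamma = 0` recovers the base model.
#'
#' @param gamma Adaptation strength, `>= 0`.
#' @param tau_a Adaptation timescale, `> 0` (named to avoid a clash with
#'   the flash duration `tau`).
#' @return An object of class `pcl_adapt`.
#' @export
adaptation_params <- function(gamma, tau_a) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(tau_a), length(tau_a) == 1L, is.finite(tau_a))
  if (gamma < 0) stop("`gamma` must be non-negative")
  if (tau_a <= 0) stop("`tau_a` must be positive")
  structure(list(gamma = gamma, tau_a = tau_a), class = "pcl_adapt")
}

#' Right-hand side with spike-frequency adaptation
#'
#' \deqn{v_j' = \mathcal{N}(v_{j-1}, v_j, v_{j+1}) - \gamma a_j, \qquad
#'   a_j' = (v_j - a_j)/\tau_a.}
#' Spatially homogeneous stationary states solve \eqn{F_p(v) = \gamma v}
#' with \eqn{a = v}; see [adaptation_equilibria()].
#'
#' @param v,a Layer vectors of activity and adaptation.
#' @inheritParams scalar_rhs
#' @param ap An [adaptation_params()] object.
#' @return A list with components `dv` and `da`.
#' @export
adaptation_rhs <- function(v, a, t, protocol, params, ap) {
  if (!inherits(ap, "pcl_adapt"))
    stop("`ap` must come from adaptation_params()")
  if (length(a) != length(v)) stop("`v` and `a` must have equal length")
  list(dv = scalar_rhs(v, t, protocol, params) - ap$gamma * a,
       da = (v - a) / ap$tau_a)
}

#' Homogeneous equilibria of the adaptation model
#'
#' Roots of \eqn{F_p(v) - \gamma v = 0} located by a sign-change scan on a
#' fine grid followed by bracketed root-finding. For small `gamma` three
#' roots survive (down/middle/up); past a critical strength only the down
#' state remains.
#'
#' @param params A [model_params()] object.
#' @param gamma Adaptation strength.
#' @param grid_n Scan resolution (default 4001 points on `[-0.25, 1.25]`).
#' @return Sorted numeric vector of equilibrium activities `v` (each paired
#'   with `a = v`).
#' @export
adaptation_equilibria <- function(params, gamma, grid_n = 4001) {
  check_model_params(params)
  g <- function(v) bistable_reaction(v, params) - gamma * v
  xs <- seq(-0.25, 1.25, length.out = grid_n)
  gv <- g(xs)
  idx <- which(gv[-grid_n] * gv[-1] <= 0 & is.finite(gv[-grid_n]))
  roots <- sort(vapply(idx, function(i)
    stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-14)$root, numeric(1)))
  roots[c(TRUE, diff(roots) > 1e-8)]
}
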