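# Time integration: input protocols, step initial conditions, the adaptive
# Dormand-Prince 5(4) integrator, and the high-level simulation drivers.

#' Input protocol at the first layer
#'
#' The external input \eqn{s_0(t)} presented at layer 0. Three kinds:
#' `"none"` (no input layer; used by truncated bi-infinite runs),
#' `"constant"` (\eqn{s_0(t) = s_0} for all `t`), and `"flashed"`
#' (\eqn{s_0(t) = s_0} on `[0, tau]`, then reset to `baseline`, normally
#' the down state \eqn{x_d}).
#'
#' @param kind One of `"none"`, `"constant"`, `"flashed"`.
#' @param s0 Input amplitude (required unless `kind = "none"`).
#' @param tau Flash duration, `> 0` (flashed only).
#' @param baseline Post-flash value (flashed only; must be below `s0`).
#' @return An object of class `pcl_protocol`.
#' @examples
#' input_protocol("constant", s0 = 0.8)
#' input_protocol("flashed", s0 = 0.9, tau = 10, baseline = 1e-3)
#' @export
input_protocol <- function(kind = c("none", "constant", "flashed"),
                           s0 = NULL, tau = NULL, baseline = NULL) {
  kind <- match.arg(kind)
  if (kind != "none") {
    stopifnot(is.numeric(s0), length(s0) == 1L, is.finite(s0))
  }
  if (kind == "flashed") {
    stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
    if (tau <= 0) stop("flashed input requires `tau` > 0")
    stopifnot(is.numeric(baseline), length(baseline) == 1L,
              is.finite(baseline))
    if (s0 <= baseline)
      stop("flashed input requires `s0` above the post-flash baseline")
  }
  structure(list(kind = kind, s0 = s0, tau = tau, baseline = baseline),
            class = "pcl_protocol")
}

# evaluate s_0(t); the flash switches exactly at t = tau (integration is
# split there so the discontinuity never sits inside a step)
protocol_value <- function(protocol, t) {
  if (!inherits(protocol, "pcl_protocol"))
    stop("`protocol` must come from input_protocol()")
  switch(protocol$kind,
         none = stop("protocol 'none' provides no input value"),
         constant = protocol$s0,
         flashed = if (t <= protocol$tau) protocol$s0 else protocol$baseline)
}

# time points at which the rhs is discontinuous
protocol_breaks <- function(protocol) {
  if (protocol$kind == "flashed") protocol$tau else numeric(0)
}

#' Step and homogeneous initial conditions
#'
#' Builds the initial layer vector from the bistable equilibria: a
#' down-to-up or up-to-down step with the interface at layer
#' `interface_index` (state `x_u` on the low-index side for `"u_to_d"`,
#' mirrored for `"d_to_u"`), or the homogeneous down/up states. Step data
#' require a bistable branch set and an interface at least `margin` layers
#' from both ends.
#'
#' @param direction One of `"u_to_d"`, `"d_to_u"`, `"all_down"`,
#'   `"all_up"`.
#' @param branches A bistable [equilibrium_branches()] result.
#' @param J Number of layers.
#' @param interface_index Layer index of the last `x_u` (`"u_to_d"`) or
#'   last `x_d` (`"d_to_u"`) layer, in the coordinates of `layers`.
#' @param layers Integer vector of layer labels (default `1:J`; bi-infinite
#'   runs use an index range centred on 0).
#' @param margin Minimal distance (layers) between the interface and either
#'   boundary (default 20).
#' @return Numeric vector of length `J` with attribute `layers`.
#' @export
make_initial <- function(direction = c("u_to_d", "d_to_u", "all_down",
                                       "all_up"),
                         branches, J, interface_index = 0,
                         layers = seq_len(J), margin = 20) {
  direction <- match.arg(direction)
  check_branches(branches)
  stopifnot(length(layers) == J)
  if (direction %in% c("u_to_d", "d_to_u")) {
    if (!branches$bistable)
      stop("step initial data need a bistable branch set")
    if (interface_index < layers[1] + margin ||
        interface_index > layers[J] - margin)
      stop("interface_index must sit at least ", margin,
           " layers from both boundaries")
    lowside <- layers <= interface_index
    v <- if (direction == "u_to_d")
      ifelse(lowside, branches$x_u, branches$x_d)
    else
      ifelse(lowside, branches$x_d, branches$x_u)
  } else if (direction == "all_down") {
    if (is.na(branches$x_d)) stop("down state absent at these parameters")
    v <- rep(branches$x_d, J)
  } else {
    if (is.na(branches$x_u)) stop("up state absent at these parameters")
    v <- rep(branches$x_u, J)
  }
  attr(v, "layers") <- layers
  v
}

# Dormand-Prince 5(4) tableau (shared by all integrations)
.dp5 <- list(
  A = list(c(1 / 5),
           c(3 / 40, 9 / 40),
           c(44 / 45, -56 / 15, 32 / 9),
           c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
           c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
             -5103 / 18656),
           c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)),
  b5 = c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0),
  e  = c(35 / 384 - 5179 / 57600, 0, 500 / 1113 - 7571 / 16695,
         125 / 192 - 393 / 640, -2187 / 6784 + 92097 / 339200,
         11 / 84 - 187 / 2100, -1 / 40))

# integrate one smooth segment, landing exactly on each requested output
# time; returns the filled columns of `out` plus the final state
dp5_segment <- function(f, y, t, t_end, outs, out, oi, rtol, atol, h0,
                        stats_env) {
  A <- .dp5$A; b5 <- .dp5$b5; ecoef <- .dp5$e
  h <- h0
  k1 <- f(t, y)
  n <- length(y)
  K <- matrix(0, n, 7)
  while (t < t_end - 1e-13) {
    tout <- if (oi <= length(outs) && outs[oi] <= t_end + 1e-13)
      outs[oi] else t_end
    hs <- min(h, tout - t)
    if (hs < 1e-12)
      stop("integrator step underflow at t = ", format(t))
    K[, 1] <- k1
    for (i in 1:6)
      K[, i + 1] <- f(t + hs * sum(A[[i]]),
                      y + hs * drop(K[, 1:i, drop = FALSE] %*% A[[i]]))
    y5 <- y + hs * drop(K[, 1:6] %*% b5[1:6])
    err <- hs * drop(K %*% ecoef)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    en <- sqrt(mean((err / sc)^2))
    if (is.na(en)) stop("integrator failure (non-finite state) at t = ",
                        format(t))
    if (en <= 1) {
      t <- t + hs
      y <- y5
      k1 <- K[, 7]                       # FSAL
      stats_env$n_accept <- stats_env$n_accept + 1L
      if (abs(t - tout) < 1e-12 && oi <= length(outs) &&
          abs(tout - outs[oi]) < 1e-12) {
        out[, oi] <- y
        oi <- oi + 1L
      }
    } else stats_env$n_reject <- stats_env$n_reject + 1L
    fac <- if (en > 0) 0.9 * en^(-0.2) else 5
    h <- min(max(hs * min(max(fac, 0.2), 5), 1e-10), 2)
  }
  list(y = y, out = out, oi = oi, h = h)
}

#' Adaptive time integration of a lattice right-hand side
#'
#' Explicit Dormand-Prince 5(4) pair with FSAL and standard error-based
#' step control (the lattice RHS is smooth and bounded, so a non-stiff
#' method is appropriate). Output is sampled on the uniform grid
#' `seq(0, t_final, by = output_dt)` by forcing steps onto the output
#' times; integration is split at `breaks` (protocol discontinuities) so no
#' step straddles a jump. Fully deterministic for identical inputs.
#'
#' @param rhs Function `rhs(t, y)` returning `dy/dt`.
#' @param initial Initial state vector (its `layers` attribute, if present,
#'   is carried into the trajectory).
#' @param t_final Final rescaled time, `> 0`.
#' @param output_dt Output sampling interval (default 0.5).
#' @param rtol,atol Relative / absolute tolerances (defaults `1e-8`,
#'   `1e-10`).
#' @param breaks Interior times at which the RHS jumps.
#' @return An object of class `pcl_trajectory`: `times`, `values` (layers
#'   by times matrix, first column the initial condition), `layers`, and
#'   `solver` (tolerances and step statistics). Metadata fields `params`,
#'   `protocol` and `truncation` are filled by the drivers.
#' @export
integrate_lattice <- function(rhs, initial, t_final, output_dt = 0.5,
                              rtol = 1e-8, atol = 1e-10,
                              breaks = numeric(0)) {
  stopifnot(is.numeric(initial), t_final > 0, output_dt > 0)
  outs <- seq(0, t_final, by = output_dt)
  if (abs(outs[length(outs)] - t_final) > 1e-12)
    outs <- c(outs, t_final)
  out <- matrix(NA_real_, length(initial), length(outs))
  out[, 1] <- initial
  stats_env <- new.env()
  stats_env$n_accept <- 0L
  stats_env$n_reject <- 0L
  seg_ends <- sort(unique(c(breaks[breaks > 0 & breaks < t_final], t_final)))
  y <- as.numeric(initial)
  t <- 0; oi <- 2L; h <- min(0.05, output_dt)
  for (te in seg_ends) {
    res <- dp5_segment(rhs, y, t, te, outs, out, oi, rtol, atol, h,
                       stats_env)
    y <- res$y; out <- res$out; oi <- res$oi; h <- res$h; t <- te
    # land the output sample exactly at a segment end if requested there
    if (oi <= length(outs) && abs(outs[oi] - te) < 1e-12) {
      out[, oi] <- y
      oi <- oi + 1L
    }
  }
  structure(
    list(times = outs, values = out,
         layers = attr(initial, "layers") %||% seq_along(y),
         params = NULL, protocol = NULL, truncation = NULL,
         solver = list(rtol = rtol, atol = atol,
                       n_accept = stats_env$n_accept,
                       n_reject = stats_env$n_reject)),
    class = "pcl_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcl_trajectory <- function(x, ...) {
  cat(sprintf(
    "lattice trajectory: %d layers x %d times on [0, %g] (%d/%d steps ok)\n",
    nrow(x$values), length(x$times), max(x$times),
    x$solver$n_accept, x$solver$n_accept + x$solver$n_reject))
  invisible(x)
}

#' Simulate a truncated bi-infinite lattice from step initial data
#'
#' `J` layers centred on the interface, both ghost ends clamped to the
#' exact asymptotic equilibrium values of the step. This is the workhorse
#' behind front-speed estimation.
#'
#' @param params A bistable [model_params()] object.
#' @param direction `"u_to_d"` or `"d_to_u"`.
#' @param J Number of layers (default 400).
#' @param t_final Final rescaled time (default 200).
#' @param output_dt,rtol,atol Passed to [integrate_lattice()].
#' @return A `pcl_trajectory` with layer labels centred on 0.
#' @export
simulate_front <- function(params, direction = c("u_to_d", "d_to_u"),
                           J = 400, t_final = 200, output_dt = 0.5,
                           rtol = 1e-8, atol = 1e-10) {
  direction <- match.arg(direction)
  check_bistable(params)
  br <- equilibrium_branches(params$theta, params$mu)
  layers <- seq_len(J) - (J %/% 2)      # interface between 0 and 1
  init <- make_initial(direction, br, J, interface_index = 0,
                       layers = layers)
  ends <- if (direction == "u_to_d") c(br$x_u, br$x_d) else
    c(br$x_d, br$x_u)
  rhs <- function(t, y) clamped_rhs(y, params, ends[1], ends[2])
  traj <- integrate_lattice(rhs, init, t_final, output_dt, rtol, atol)
  traj$params <- params
  traj$protocol <- input_protocol("none")
  traj$truncation <- list(J = J, boundary = "clamped-equilibria",
                          direction = direction)
  traj
}

#' Simulate a truncated semi-infinite lattice with external input
#'
#' Bottom-up runs integrate layers `1..J` with the input as the lower
#' neighbour of layer 1 and the `S^-1` closure at the top;
#' top-down runs integrate layers `-1..-J` in mirrored depth coordinates
#' (the input enters through the feedback slot). Layer labels are positive
#' bottom-up and negative top-down.
#'
#' @param params A [model_params()] object.
#' @param protocol An [input_protocol()] of kind `"constant"` or
#'   `"flashed"`.
#' @param orientation `"bottom_up"` or `"top_down"`.
#' @param J Number of layers (default 100).
#' @param t_final Final rescaled time (default 300).
#' @param init Initial condition: `"all_down"`, `"all_up"`, or a numeric
#'   vector of length `J`.
#' @param output_dt,rtol,atol Passed to [integrate_lattice()].
#' @return A `pcl_trajectory`.
#' @export
simulate_semi <- function(params, protocol,
                          orientation = c("bottom_up", "top_down"),
                          J = 100, t_final = 300, init = "all_down",
                          output_dt = 0.5, rtol = 1e-8, atol = 1e-10) {
  orientation <- match.arg(orientation)
  check_model_params(params)
  if (!inherits(protocol, "pcl_protocol") || protocol$kind == "none")
    stop("semi-infinite runs need a constant or flashed input protocol")
  br <- equilibrium_branches(params$theta, params$mu)
  if (protocol$kind == "constant" && !is.na(br$x_d) &&
      protocol$s0 < br$x_d - 1e-12)
    stop("constant input requires s0 >= x_d (standing assumption)")
  layers <- if (orientation == "bottom_up") seq_len(J) else -seq_len(J)
  if (is.character(init)) {
    init <- make_initial(match.arg(init, c("all_down", "all_up")), br, J,
                         layers = layers)
  } else {
    stopifnot(is.numeric(init), length(init) == J)
    attr(init, "layers") <- layers
  }
  rhs <- if (orientation == "bottom_up")
    function(t, y) scalar_rhs(y, t, protocol, params)
  else
    function(t, y) topdown_rhs(y, t, protocol, params)
  traj <- integrate_lattice(rhs, init, t_final, output_dt, rtol, atol,
                            breaks = protocol_breaks(protocol))
  traj$params <- params
  traj$protocol <- protocol
  traj$truncation <- list(J = J,
                          boundary = if (orientation == "bottom_up")
                            "input + S^-1 closure" else
                            "input + mirrored S^-1 closure",
                          orientation = orientation)
  traj
}

# Named scenario presets. Figure-caption parameters are used where printed
# ((theta, mu, p) = (0.5, 16, 0.1) with q = 0.6 / 0.4 for the front runs);
# the semi-infinite presets encode representative parameter values chosen
# once to satisfy each case's defining speed-sign conditions.
scenario_presets <- function() {
  P <- function(theta, q) model_params(theta, 16, 0.1, q)
  list(
    fig2a = list(kind = "front", params = P(0.5, 0.6), direction = "u_to_d"),
    fig2c = list(kind = "front", params = P(0.5, 0.4), direction = "u_to_d"),
    fig2d = list(kind = "front", params = P(0.5, 0.6), direction = "d_to_u"),
    fig2f = list(kind = "front", params = P(0.5, 0.4), direction = "d_to_u"),
    # constant input, bottom-up: below / above the propagation threshold
    fig6a = list(kind = "semi", params = P(0.35, 0.35),
                 orientation = "bottom_up", s0 = 0.30),
    fig6b = list(kind = "semi", params = P(0.35, 0.35),
                 orientation = "bottom_up", s0 = 0.95),
    # flashed input, bottom-up: failure / stacked / front morphologies
    fig9a = list(kind = "semi", params = P(0.55, 0.30),
                 orientation = "bottom_up", flash = 20),
    fig9b = list(kind = "semi", params = P(0.45, 0.30),
                 orientation = "bottom_up", flash = 20),
    fig9c = list(kind = "semi", params = P(0.35, 0.55),
                 orientation = "bottom_up", flash = 20),
    # flashed input at equal positive speeds: traveling pulse
    fig10 = list(kind = "semi", params = P(0.50, 0.20),
                 orientation = "bottom_up", flash = 10),
    # constant input, top-down: below / above threshold
    fig12a = list(kind = "semi", params = P(0.35, 0.80),
                  orientation = "top_down", s0 = 0.30),
    fig12b = list(kind = "semi", params = P(0.35, 0.80),
                  orientation = "top_down", s0 = 0.95),
    # flashed input, top-down: failure / stacked / front morphologies
    fig15a = list(kind = "semi", params = P(0.55, 0.70),
                  orientation = "top_down", flash = 20),
    fig15b = list(kind = "semi", params = P(0.45, 0.80),
                  orientation = "top_down", flash = 20),
    fig15c = list(kind = "semi", params = P(0.35, 0.65),
                  orientation = "top_down", flash = 20))
}

#' Run a named scenario preset
#'
#' Presets encode the parameter tuples of the reference experiments:
#' `fig2a/c/d/f` (bi-infinite step data at `(theta, mu, p) =
#' (0.5, 16, 0.1)` with `q = 0.6` or `0.4`), `fig6a/b` and `fig12a/b`
#' (constant input below/above the propagation threshold, bottom-up and
#' top-down), `fig9a/b/c` and `fig15a/b/c` (flashed input in the three
#' speed-sign regimes), and `fig10` (flashed input at equal positive
#' speeds, yielding a traveling pulse).
#'
#' @param name Preset name; unknown names raise an error listing all
#'   presets.
#' @param J,t_final Optional overrides of the preset truncation/horizon.
#' @param ... Further arguments passed to [simulate_front()] or
#'   [simulate_semi()].
#' @return A `pcl_trajectory`.
#' @export
run_scenario <- function(name, J = NULL, t_final = NULL, ...) {
  presets <- scenario_presets()
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: ", paste(names(presets), collapse = ", "))
  ps <- presets[[name]]
  if (ps$kind == "front") {
    simulate_front(ps$params, ps$direction, J = J %||% 400,
                   t_final = t_final %||% 200, ...)
  } else {
    br <- equilibrium_branches(ps$params$theta, ps$params$mu)
    protocol <- if (!is.null(ps$flash))
      input_protocol("flashed", s0 = br$x_u, tau = ps$flash,
                     baseline = br$x_d)
    else
      input_protocol("constant", s0 = ps$s0)
    simulate_semi(ps$params, protocol, ps$orientation,
                  J = J %||% 100, t_final = t_final %||% 300, ...)
  }
}
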