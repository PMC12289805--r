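# Semi-infinite network experiments: stagnation/propagation classification,
# stationary profiles, and bisection searches for the input-amplitude
# threshold s0*, the flash-duration threshold tau*, and pinning boundaries.

undetermined <- function(msg) {
  stop(structure(class = c("pcl_undetermined", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# depth-coordinate view of a semi-infinite trajectory: depth 1 is the layer
# adjacent to the input, depth J the far end, for both orientations
semi_rhs_fun <- function(traj) {
  orientation <- traj$truncation$orientation
  if (is.null(orientation))
    stop("trajectory does not come from simulate_semi()")
  params <- traj$params
  protocol <- traj$protocol
  if (orientation == "bottom_up")
    function(t, y) scalar_rhs(y, t, protocol, params)
  else
    function(t, y) topdown_rhs(y, t, protocol, params)
}

#' Classify the long-time outcome of a semi-infinite run
#'
#' Operational rules on a truncated semi-infinite trajectory started from
#' the down state (depth coordinates: depth 1 adjacent to the input):
#' \itemize{
#' \item `front_propagation`: the sentinel layer (depth `J - 20`) exceeds
#'   `(x_m + x_u)/2` before the horizon and remains above it at the end.
#' \item `stagnation` (constant input): the time-derivative sup-norm at the
#'   final state is below `1e-8` and every layer deeper than 20 is below
#'   `x_m` (both required, to distinguish stagnation from slow fronts).
#' \item flashed protocols, classified after the flash end: `propagation_failure`
#'   when the sup-norm distance to the homogeneous down state falls below
#'   `1e-3` before the sentinel is reached; when the sentinel is reached
#'   and a trailing interface (the up-crossing of `x_m` behind the
#'   plateau) also advances by at least 5 layers, `pulse_propagation` if
#'   the two interfaces travel at the same speed (difference below
#'   `pin_tol`, width constant to one layer over the last half window)
#'   and `stacked_propagation` otherwise; `front_propagation` when the
#'   trailing interface does not advance.
#' }
#' If none of the rules fire by the horizon the run is `undetermined` and
#' an error of class `pcl_undetermined` is raised, prompting a longer
#' horizon (the search drivers double it once automatically).
#'
#' @param traj A [simulate_semi()] trajectory (all-down initial data).
#' @param branches Optional [equilibrium_branches()] result (recomputed
#'   from `traj$params` when omitted).
#' @param pin_tol Pinning tolerance used by the pulse rule (default 5e-3).
#' @return One of the regime labels above, as a character scalar.
#' @export
classify_outcome <- function(traj, branches = NULL, pin_tol = 5e-3) {
  if (!inherits(traj, "pcl_trajectory")) stop("`traj` must be a trajectory")
  protocol <- traj$protocol
  if (is.null(protocol) || protocol$kind == "none")
    stop("classification needs a constant or flashed input protocol")
  br <- branches %||% equilibrium_branches(traj$params$theta,
                                           traj$params$mu)
  check_branches(br)
  if (!br$bistable) stop("classification requires the bistable regime")
  V <- traj$values
  J <- nrow(V)
  if (J < 71) stop("truncation too small: sentinel needs >= 50 layers ",
                   "between input and boundary")
  times <- traj$times
  n_t <- length(times)
  sentinel <- J - 20L
  up_level <- (br$x_m + br$x_u) / 2
  above <- V[sentinel, ] > up_level
  t_reach <- if (any(above)) times[which(above)[1]] else Inf
  reached_and_stays <- any(above) && above[n_t]

  if (protocol$kind == "constant") {
    if (reached_and_stays) return("front_propagation")
    rhs <- semi_rhs_fun(traj)
    dmax <- max(abs(rhs(times[n_t], V[, n_t])))
    deep_quiet <- all(V[seq.int(21L, J), n_t] < br$x_m)
    if (dmax < 1e-8 && deep_quiet) return("stagnation")
    undetermined(paste0("outcome undetermined at t = ", times[n_t],
                        " (|dv/dt| = ", format(dmax),
                        "); increase t_final"))
  }

  # flashed: only the post-flash dynamics is classified (the trailing
  # interface exists only after the reset)
  post <- which(times > protocol$tau)
  if (length(post) < 4L)
    stop("horizon barely exceeds the flash; increase t_final")
  dist_down <- apply(abs(V[, post, drop = FALSE] - br$x_d), 2, max)
  collapsed <- dist_down < 1e-3
  t_collapse <- if (any(collapsed)) times[post[which(collapsed)[1]]] else Inf
  if (t_collapse < t_reach) return("propagation_failure")

  if (any(above)) {
    # the sentinel was reached: front morphology if it stays up, stacked or
    # pulse when a trailing interface also invades (the plateau then passes
    # the sentinel, which later returns to the down state)
    cps <- lapply(post, function(i) {
      v <- V[, i]
      attr(v, "layers") <- seq_len(J)
      crossing_positions(v, br$x_m)
    })
    two <- vapply(cps, function(x) length(x) >= 2L, logical(1))
    if (any(two)) {
      trail <- vapply(cps[two], min, numeric(1))
      lead <- vapply(cps[two], max, numeric(1))
      tt <- times[post[two]]
      advance <- trail[length(trail)] - trail[1]
      if (advance >= 5) {
        half <- tt >= tt[1] + (tt[length(tt)] - tt[1]) / 2
        fitv <- function(y) unname(stats::lm.fit(cbind(1, tt[half]),
                                                 y[half])$coefficients[2])
        dspeed <- abs(fitv(lead) - fitv(trail))
        width <- lead[half] - trail[half]
        if (dspeed < pin_tol && (max(width) - min(width)) <= 2)
          return("pulse_propagation")
        return("stacked_propagation")
      }
    }
    if (reached_and_stays) return("front_propagation")
  }
  undetermined(paste0("flashed outcome undetermined at t = ", times[n_t],
                      "; increase t_final"))
}

# classify with a single automatic horizon doubling on "undetermined"
classify_with_retry <- function(params, protocol, orientation, J, t_final,
                                branches, ...) {
  run <- function(tf) {
    traj <- simulate_semi(params, protocol, orientation, J = J,
                          t_final = tf, ...)
    classify_outcome(traj, branches)
  }
  tryCatch(run(t_final),
           pcl_undetermined = function(e) run(2 * t_final))
}

#' Stationary profile of the semi-infinite network
#'
#' Computes a stationary solution anchored at the input value `s0` with the
#' prescribed asymptotic tail (`"down"` to the down state, `"up"` to the up
#' state). Time integration from all-down (down tail) or all-up (up tail)
#' initial data brings the state into the basin of the profile; once the
#' derivative sup-norm falls below `1e-5` the stationary system is solved
#' directly by damped Newton iteration (finite-difference Jacobian), which
#' removes the slow entrance-layer relaxation mode and drives the residual
#' to near machine precision. The returned profile satisfies the
#' stationary equations to well below `1e-8` per layer.
#'
#' @param params A bistable [model_params()] object.
#' @param s0 Input anchor value.
#' @param tail `"down"` or `"up"`.
#' @param orientation `"bottom_up"` or `"top_down"`.
#' @param J Truncation depth (default 150).
#' @param chunk,t_cap Integration chunk length and total time cap of the
#'   pre-Newton phase.
#' @return An object of class `pcl_stationary`: `values` (with `layers`
#'   attribute), `anchor`, `tail`, `orientation`, `residual` (sup-norm),
#'   `time_to_converge`.
#' @export
stationary_profile <- function(params, s0, tail = c("down", "up"),
                               orientation = c("bottom_up", "top_down"),
                               J = 150, chunk = 100, t_cap = 2000) {
  tail <- match.arg(tail)
  orientation <- match.arg(orientation)
  check_bistable(params)
  protocol <- input_protocol("constant", s0 = s0)
  init <- if (tail == "down") "all_down" else "all_up"
  elapsed <- 0
  state <- NULL
  rhs <- NULL
  repeat {
    traj <- simulate_semi(params, protocol, orientation, J = J,
                          t_final = chunk, init = state %||% init,
                          output_dt = chunk / 4)
    rhs <- semi_rhs_fun(traj)
    state <- traj$values[, ncol(traj$values)]
    elapsed <- elapsed + chunk
    if (max(abs(rhs(elapsed, state))) < 1e-5) break
    if (elapsed >= t_cap)
      stop("stationary profile did not reach the Newton basin within t = ",
           t_cap)
  }
  g <- function(x) rhs(0, x)
  for (iter in 1:25) {
    gv <- g(state)
    if (max(abs(gv)) < 1e-12) break
    h <- 1e-7
    Jac <- vapply(seq_len(J), function(k) {
      xp <- state; xp[k] <- xp[k] + h
      (g(xp) - gv) / h
    }, numeric(J))
    step <- solve(Jac, -gv)
    # damp so the Newton step never leaves the trapping region
    lam <- 1
    repeat {
      cand <- state + lam * step
      if (max(abs(g(cand))) < max(abs(gv)) || lam < 1 / 64) break
      lam <- lam / 2
    }
    state <- state + lam * step
  }
  resid <- max(abs(g(state)))
  if (resid >= 1e-10)
    stop("stationary profile did not converge (residual ", format(resid),
         ")")
  layers <- if (orientation == "bottom_up") seq_len(J) else -seq_len(J)
  attr(state, "layers") <- layers
  structure(list(values = state, anchor = s0, tail = tail,
                 orientation = orientation, residual = resid,
                 time_to_converge = elapsed, params = params),
            class = "pcl_stationary")
}

new_threshold <- function(kind, value, bracket, tol, orientation, params,
                          extra = list()) {
  structure(c(list(kind = kind, value = value,
                   bracket = c(lo = bracket[1], hi = bracket[2]),
                   tol = tol, direction = orientation, params = params),
              extra),
            class = "pcl_threshold")
}

#' @export
print.pcl_threshold <- function(x, ...) {
  cat(sprintf("%s (%s): %.6g  [bracket %.6g .. %.6g, tol %g]\n",
              x$kind, x$direction, x$value, x$bracket[1], x$bracket[2],
              x$tol))
  invisible(x)
}

# speed relevant to an orientation: the invading front must move into the
# network, i.e. c_{u->d} > 0 bottom-up, c_{d->u} < 0 top-down
orientation_speed <- function(params, orientation, speed_opts) {
  dir <- if (orientation == "bottom_up") "u_to_d" else "d_to_u"
  do.call(estimate_speed,
          c(list(params = params, direction = dir, on_margin = "truncate"),
            speed_opts))
}

#' Minimal constant input amplitude for propagation
#'
#' Bisects the amplitude of a constant input between stagnation (below) and
#' propagation (above). The threshold exists only where the relevant front
#' invades the network (`c_{u->d} > 0` bottom-up, `c_{d->u} < 0`
#' top-down); that speed-sign precondition is verified first. The search
#' bracket starts at the separatrix `x_m` (stagnation is guaranteed on
#' `[x_d, x_m]` by the comparison principle) and the upper end grows
#' geometrically until propagation is observed, up to `s0_cap`; hitting the
#' cap is reported as divergence, consistent with the threshold blowing up
#' near the pinning boundary.
#'
#' @param params A bistable [model_params()] object.
#' @param orientation `"bottom_up"` or `"top_down"`.
#' @param J,t_final Truncation and horizon of each classification run.
#' @param tol Bisection tolerance on the amplitude (default 1e-3).
#' @param s0_cap Upper amplitude cap (default 10).
#' @param speed_opts Options for the precondition speed estimate.
#' @return A `pcl_threshold` of kind `"s0_star"`; its value always
#'   satisfies `value >= x_m`.
#' @export
find_s0_star <- function(params, orientation = c("bottom_up", "top_down"),
                         J = 100, t_final = 300, tol = 1e-3, s0_cap = 10,
                         speed_opts = list(J = 300, t_final = 120)) {
  orientation <- match.arg(orientation)
  check_bistable(params)
  est <- orientation_speed(params, orientation, speed_opts)
  ok <- if (orientation == "bottom_up") !est$pinned && est$c > 0
        else !est$pinned && est$c < 0
  if (!ok)
    stop("threshold undefined (pinned/adverse regime): ",
         sprintf("c = %.4g%s", est$c, if (est$pinned) " [pinned]" else ""))
  br <- equilibrium_branches(params$theta, params$mu)
  outcome <- function(s0)
    classify_with_retry(params, input_protocol("constant", s0 = s0),
                        orientation, J, t_final, br)
  lo <- br$x_m                          # stagnation guaranteed
  hi <- NA_real_
  step <- 0.25
  repeat {
    cand <- br$x_m + step
    if (cand > s0_cap)
      stop("no propagation up to s0 = ", s0_cap,
           ": threshold diverges (pinning boundary nearby)")
    if (outcome(cand) != "stagnation") { hi <- cand; break }
    lo <- cand
    step <- 2 * step
  }
  while (hi - lo > 2 * tol) {
    mid <- (lo + hi) / 2
    if (outcome(mid) == "stagnation") lo <- mid else hi <- mid
  }
  new_threshold("s0_star", (lo + hi) / 2, c(lo, hi), tol, orientation,
                params,
                extra = list(outcome_lo = "stagnation",
                             outcome_hi = "propagation"))
}

#' Minimal flash duration for propagation
#'
#' For a flashed input of amplitude `s0` (the up state by default) followed
#' by a reset to the down state, bisects the presentation time between
#' propagation failure (below) and propagation in any form (stacked, front
#' or pulse, above). The regime must admit propagation for long flashes:
#' bottom-up requires `c_{u->d} > 0` and `c_{d->u} < c_{u->d}`; top-down
#' requires `c_{d->u} < 0` and `c_{d->u} < c_{u->d}`.
#'
#' @inheritParams find_s0_star
#' @param s0 Flash amplitude (default: the up state).
#' @param tol Bisection tolerance on the duration (default 1e-2).
#' @param tau_cap Maximal tested duration (default 200).
#' @return A `pcl_threshold` of kind `"tau_star"`.
#' @export
find_tau_star <- function(params, orientation = c("bottom_up", "top_down"),
                          s0 = NULL, J = 120, t_final = 350, tol = 1e-2,
                          tau_cap = 200,
                          speed_opts = list(J = 300, t_final = 120)) {
  orientation <- match.arg(orientation)
  check_bistable(params)
  br <- equilibrium_branches(params$theta, params$mu)
  s0 <- s0 %||% br$x_u
  est_ud <- do.call(estimate_speed,
                    c(list(params = params, direction = "u_to_d",
                           on_margin = "truncate"), speed_opts))
  est_du <- do.call(estimate_speed,
                    c(list(params = params, direction = "d_to_u",
                           on_margin = "truncate"), speed_opts))
  ok <- if (orientation == "bottom_up")
    est_ud$c > 0 && est_du$c < est_ud$c
  else
    est_du$c < 0 && est_du$c < est_ud$c
  if (!ok)
    stop(sprintf(paste0("flash threshold undefined in this regime: ",
                        "c_ud = %.4g, c_du = %.4g"), est_ud$c, est_du$c))
  outcome <- function(tau)
    classify_with_retry(params,
                        input_protocol("flashed", s0 = s0, tau = tau,
                                       baseline = br$x_d),
                        orientation, J, t_final, br)
  lo <- 0                               # zero presentation: failure
  hi <- NA_real_
  tau_try <- 5
  repeat {
    if (tau_try > tau_cap)
      stop("no propagation for any tested flash duration up to ", tau_cap)
    if (outcome(tau_try) != "propagation_failure") { hi <- tau_try; break }
    lo <- tau_try
    tau_try <- 2 * tau_try
  }
  while (hi - lo > 2 * tol) {
    mid <- (lo + hi) / 2
    if (outcome(mid) == "propagation_failure") lo <- mid else hi <- mid
  }
  new_threshold("tau_star", (lo + hi) / 2, c(lo, hi), tol, orientation,
                params,
                extra = list(s0 = s0, outcome_lo = "propagation_failure",
                             outcome_hi = "propagation"))
}

#' Pinning boundary in a single parameter
#'
#' Bisects one free parameter (`theta` or `q`) against the moving/pinned
#' predicate of the front-speed estimator, locating the edge of the pinning
#' region of the orientation-relevant speed: bottom-up tracks
#' `c_{u->d}` ("moving" means `c > pin_tol`), top-down tracks `c_{d->u}`
#' ("moving" means `c < -pin_tol`). The standard boundary definitions are
#' recovered by the bracket orientation: the smallest `theta` (or `q`)
#' with `c_{u->d} = 0` has the moving side at the lower bracket end; the
#' largest `q` with `c_{d->u} = 0` has it at the upper end. Exactly one
#' bracket end must be on the moving side.
#'
#' @param params A [model_params()] object providing the fixed parameters
#'   (its free coordinate is overwritten during the search).
#' @param free `"theta"` or `"q"`.
#' @param orientation `"bottom_up"` (tracks `c_{u->d}`) or `"top_down"`
#'   (tracks `c_{d->u}`).
#' @param bracket Numeric length-2 search interval. Default for
#'   `free = "theta"`, bottom-up: `c(theta_star + 0.05, 0.5)`; all other
#'   combinations require an explicit bracket.
#' @param tol Bisection tolerance (default 1e-3).
#' @param J,t_final,pin_tol Speed-estimation controls (defaults 400, 200,
#'   5e-3). Fast bracket ends are handled by the truncated-fit mode of
#'   [estimate_speed()].
#' @return A `pcl_threshold` of kind `"theta0"` or `"q0"`.
#' @export
find_pinning_boundary <- function(params, free = c("theta", "q"),
                                  orientation = c("bottom_up", "top_down"),
                                  bracket = NULL, tol = 1e-3,
                                  J = 400, t_final = 200, pin_tol = 5e-3) {
  free <- match.arg(free)
  orientation <- match.arg(orientation)
  check_model_params(params)
  direction <- if (orientation == "bottom_up") "u_to_d" else "d_to_u"
  if (is.null(bracket)) {
    if (free == "theta" && orientation == "bottom_up") {
      fp <- fold_points(params$mu)
      bracket <- c(fp$theta_star + 0.05, 0.5)
    } else {
      stop("an explicit `bracket` is required for free = ", free,
           ", orientation = ", orientation)
    }
  }
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  with_free <- function(x) {
    if (free == "theta")
      model_params(x, params$mu, params$p, params$q)
    else
      model_params(params$theta, params$mu, params$p, x)
  }
  moving <- function(x) {
    est <- estimate_speed(with_free(x), direction, J = J,
                          t_final = t_final, pin_tol = pin_tol,
                          on_margin = "truncate")
    if (orientation == "bottom_up") !est$pinned && est$c > pin_tol
    else !est$pinned && est$c < -pin_tol
  }
  m_lo <- moving(bracket[1])
  m_hi <- moving(bracket[2])
  if (m_lo == m_hi)
    stop("no moving/pinned sign change in the bracket [", bracket[1], ", ",
         bracket[2], "]")
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > 2 * tol) {
    mid <- (lo + hi) / 2
    if (moving(mid) == m_lo) lo <- mid else hi <- mid
  }
  new_threshold(if (free == "theta") "theta0" else "q0",
                (lo + hi) / 2, c(lo, hi), tol, orientation, params,
                extra = list(free = free, moving_at = if (m_lo) "lo"
                             else "hi"))
}

#' Joint bottom-up/top-down regime map under constant input
#'
#' Classifies the constant-input outcome of both orientations on a
#' `(q, s0)` grid at fixed `(theta, mu, p)` and labels each node
#' `both_propagate` (the normal working regime), `both_stagnate`,
#' `bottom_up_only`, `top_down_only`, or `undetermined`.
#'
#' @param q,s0 Grid vectors.
#' @param theta,mu,p Fixed parameters.
#' @param J,t_final Classification run controls (defaults 100, 300).
#' @return A `data.frame` of class `pcl_regimemap` with columns `q`, `s0`,
#'   `bottom_up`, `top_down`, `label`, `normal_regime`.
#' @export
regime_map <- function(q, s0, theta, mu, p, J = 100, t_final = 300) {
  grid <- expand.grid(q = q, s0 = s0, KEEP.OUT.ATTRS = FALSE)
  br <- equilibrium_branches(theta, mu)
  one <- function(qi, s0i, orientation) {
    tryCatch({
      params <- model_params(theta, mu, p, qi)
      classify_with_retry(params, input_protocol("constant", s0 = s0i),
                          orientation, J, t_final, br)
    }, error = function(e) "undetermined")
  }
  bu <- mapply(one, grid$q, grid$s0, MoreArgs = list("bottom_up"))
  td <- mapply(one, grid$q, grid$s0, MoreArgs = list("top_down"))
  lab <- ifelse(bu == "undetermined" | td == "undetermined", "undetermined",
         ifelse(bu != "stagnation" & td != "stagnation", "both_propagate",
         ifelse(bu == "stagnation" & td == "stagnation", "both_stagnate",
         ifelse(bu != "stagnation", "bottom_up_only", "top_down_only"))))
  out <- cbind(grid, data.frame(bottom_up = bu, top_down = td, label = lab,
                                normal_regime = lab == "both_propagate",
                                stringsAsFactors = FALSE))
  class(out) <- c("pcl_regimemap", class(out))
  out
}
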