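# Front tracking: interface positions, least-squares wave-speed estimates,
# pinning detection, co-moving profiles, and speed sign maps.

#' Interface position of a monotone front snapshot
#'
#' Locates the single crossing of `level` by linear interpolation between
#' the two bracketing layers. The snapshot must cross the level exactly
#' once (monotone transition region); zero crossings mean the front never
#' formed or left the window, multiple crossings mean the state is not a
#' single front.
#'
#' @param snapshot Numeric layer vector, optionally with a `layers`
#'   attribute giving the layer labels (default `seq_along(snapshot)`).
#' @param level Crossing level, normally the separatrix `x_m`.
#' @return Fractional layer position of the crossing.
#' @examples
#' v <- c(rep(1, 10), rep(0, 10))
#' interface_position(v, 0.5)  # 10.5
#' @export
interface_position <- function(snapshot, level) {
  pos <- crossing_positions(snapshot, level)
  if (length(pos) == 0L)
    stop("no crossing of level ", level,
         ": front left the window or never formed")
  if (length(pos) > 1L)
    stop("snapshot crosses level ", level, " ", length(pos),
         " times; expected a single monotone interface")
  pos
}

# all fractional crossing positions of `level`, in layer coordinates;
# exact hits on the level resolve to the layer itself
crossing_positions <- function(snapshot, level) {
  layers <- attr(snapshot, "layers") %||% seq_along(snapshot)
  d <- as.numeric(snapshot) - level
  n <- length(d)
  i <- which(d[-n] * d[-1] < 0)
  pos <- layers[i] + d[i] / (d[i] - d[i + 1]) * (layers[i + 1] - layers[i])
  exact <- which(d == 0)
  sort(c(pos, layers[exact]))
}

#' Front-speed estimate from step initial data
#'
#' Simulates the truncated bi-infinite lattice from the requested step
#' initial condition, tracks the interface (crossing of the separatrix
#' `x_m`) through time, discards the initial transient, and fits position
#' against time by ordinary least squares; solutions from step data
#' converge exponentially to a translating front, so the late-time slope
#' estimates the wave speed. The estimate is flagged `pinned` when the
#' total displacement over the fit window is below one layer AND the
#' fitted `|c|` is below `pin_tol` (both required: this separates true
#' pinning from slow fronts).
#'
#' @param params A bistable [model_params()] object.
#' @param direction `"u_to_d"` (front connecting up state on the left to
#'   down state on the right) or `"d_to_u"`.
#' @param J,t_final,output_dt,rtol,atol Simulation controls; see
#'   [simulate_front()].
#' @param transient_frac Fraction of the horizon discarded before the fit
#'   (default 0.25).
#' @param pin_tol Pinning tolerance in layers per rescaled time unit
#'   (default 5e-3).
#' @param margin Sentinel margin: the run aborts (or is truncated, see
#'   `on_margin`) once the interface comes within `margin` layers of a
#'   boundary.
#' @param on_margin `"error"` (default): abort advising a larger `J` or a
#'   shorter `t_final`; `"truncate"`: drop the post-breach samples and fit
#'   on the valid window (used internally by fast bracket ends of the
#'   pinning-boundary search).
#' @return An object of class `pcl_speed`: `c`, `stderr`, `window`,
#'   `pinned`, `positions` (time series), `times`, `direction`, `params`.
#' @export
estimate_speed <- function(params, direction = c("u_to_d", "d_to_u"),
                           J = 400, t_final = 200, output_dt = 0.5,
                           rtol = 1e-8, atol = 1e-10,
                           transient_frac = 0.25, pin_tol = 5e-3,
                           margin = 50, on_margin = c("error", "truncate")) {
  direction <- match.arg(direction)
  on_margin <- match.arg(on_margin)
  traj <- simulate_front(params, direction, J, t_final, output_dt,
                         rtol, atol)
  br <- equilibrium_branches(params$theta, params$mu)
  pos <- vapply(seq_along(traj$times), function(i) {
    v <- traj$values[, i]
    attr(v, "layers") <- traj$layers
    tryCatch(interface_position(v, br$x_m),
             error = function(e) NA_real_)   # front left the window
  }, numeric(1))
  lo <- traj$layers[1] + margin
  hi <- traj$layers[length(traj$layers)] - margin
  breach <- which(is.na(pos) | pos < lo | pos > hi)
  times <- traj$times
  if (length(breach) > 0L) {
    if (on_margin == "error")
      stop("front reached the sentinel margin (", margin,
           " layers from the boundary) at t = ", times[breach[1]],
           "; increase J or decrease t_final")
    keep <- seq_len(breach[1] - 1L)
    if (length(keep) < 8L)
      stop("front reached the sentinel margin almost immediately; ",
           "increase J")
    pos <- pos[keep]
    times <- times[keep]
  }
  t_end <- times[length(times)]
  sel <- times >= transient_frac * t_end
  fit <- stats::lm.fit(cbind(1, times[sel]), pos[sel])
  cc <- unname(fit$coefficients[2])
  dof <- sum(sel) - 2L
  se <- if (dof > 0) {
    s2 <- sum(fit$residuals^2) / dof
    sqrt(s2 / sum((times[sel] - mean(times[sel]))^2))
  } else NA_real_
  disp <- abs(pos[length(pos)] - pos[which(sel)[1]])
  structure(
    list(c = cc, intercept = unname(fit$coefficients[1]), stderr = se,
         window = c(t_start = times[which(sel)[1]], t_end = t_end),
         pinned = (disp < 1) && (abs(cc) < pin_tol),
         displacement = disp,
         positions = pos, times = times,
         direction = direction, params = params,
         truncated = length(breach) > 0L,
         trajectory = traj),
    class = "pcl_speed")
}

#' @export
print.pcl_speed <- function(x, ...) {
  cat(sprintf(
    "front speed %s: c = %.6g +/- %.2g layers/unit time%s (window [%g, %g])\n",
    x$direction, x$c, x$stderr, if (x$pinned) " [PINNED]" else "",
    x$window[1], x$window[2]))
  invisible(x)
}

#' Co-moving wave profile
#'
#' Reconstructs the traveling profile \eqn{\Phi(\xi)}, \eqn{\xi = j - ct},
#' by pooling the lattice samples of all late-time snapshots in the frame
#' moving with the fitted speed: as \eqn{ct \bmod 1} sweeps through the
#' unit cell, the union of points \eqn{(j - ct, v_j(t))} samples the
#' profile densely, which a single snapshot (one point per layer) cannot
#' do across the steep interface. Alignment uses the fitted position line,
#' not the per-snapshot crossing, so measurement jitter does not enter the
#' phase.
#'
#' @param est A [estimate_speed()] result with `pinned = FALSE` and fit
#'   standard error below `stderr_gate`.
#' @param offsets Co-moving coordinate grid (default `seq(-30, 30, 0.25)`).
#' @param stderr_gate Quality gate on the fit standard error (default
#'   1e-3).
#' @return An object of class `pcl_profile`: `offsets`, `values`,
#'   `direction`, and `collapse`, the sup-norm distance between the
#'   profiles rebuilt from the \eqn{[T/2, T]} and \eqn{[3T/4, T]} time
#'   windows (a convergence diagnostic).
#' @export
extract_profile <- function(est, offsets = seq(-30, 30, by = 0.25),
                            stderr_gate = 1e-3) {
  if (!inherits(est, "pcl_speed")) stop("`est` must come from estimate_speed()")
  if (est$pinned) stop("no traveling profile: the front is pinned")
  if (!is.na(est$stderr) && est$stderr > stderr_gate)
    stop("fit standard error ", format(est$stderr),
         " exceeds the quality gate ", stderr_gate)
  traj <- est$trajectory
  t_end <- est$times[length(est$times)]
  pool <- function(from) {
    keep <- which(est$times >= from)
    xi <- unlist(lapply(keep, function(i)
      traj$layers - (est$intercept + est$c * est$times[i])))
    vv <- as.vector(traj$values[, keep])
    ok <- order(xi)
    stats::approx(xi[ok], vv[ok], xout = offsets, ties = mean, rule = 1)$y
  }
  half <- pool(t_end / 2)
  quarter <- pool(3 * t_end / 4)
  ok <- !is.na(half) & !is.na(quarter)
  structure(
    list(offsets = offsets, values = half,
         direction = est$direction,
         collapse = max(abs(half[ok] - quarter[ok]))),
    class = "pcl_profile")
}

#' Sign map of the wave speeds over a parameter grid
#'
#' Estimates both front speeds on every node of a two-parameter grid and
#' maps them to `{-1, 0, +1}` with the pinning tolerance (0 when pinned).
#' Exactly two of `theta`, `q`, `p` must be vectors (the grid axes); the
#' rest are fixed. Inadmissible nodes (outside the bistable window or the
#' three-branch regime) are marked missing rather than fatal. Nodes are
#' independent: results are identical however they are scheduled.
#'
#' @param theta,q,p Scalars or grid vectors (exactly two vectors).
#' @param mu Fixed sigmoid slope.
#' @param ... Simulation controls passed to [estimate_speed()].
#' @param pin_tol Pinning tolerance (default 5e-3).
#' @return A `data.frame` of class `pcl_signmap` with columns `theta`, `q`,
#'   `p`, `mu`, `c_ud`, `c_ud_stderr`, `pinned_ud`, `c_du`, `c_du_stderr`,
#'   `pinned_du`, `sign_ud`, `sign_du`.
#' @export
sign_map <- function(theta, q, p, mu, ..., pin_tol = 5e-3) {
  axes <- c(theta = length(theta) > 1L, q = length(q) > 1L,
            p = length(p) > 1L)
  if (sum(axes) > 2L)
    stop("at most two of theta, q, p may be grid vectors")
  grid <- expand.grid(theta = theta, q = q, p = p, mu = mu,
                      KEEP.OUT.ATTRS = FALSE)
  one_dir <- function(row, direction) {
    est <- tryCatch(
      estimate_speed(model_params(row$theta, row$mu, row$p, row$q),
                     direction, ..., pin_tol = pin_tol),
      error = function(e) NULL)
    if (is.null(est)) return(c(NA_real_, NA_real_, NA))
    c(est$c, est$stderr, est$pinned)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    ok <- tryCatch({
      pp <- model_params(row$theta, row$mu, row$p, row$q)
      pp$bistable
    }, error = function(e) FALSE)
    if (!ok) return(rep(NA_real_, 6))
    c(one_dir(row, "u_to_d"), one_dir(row, "d_to_u"))
  })
  res <- do.call(rbind, res)
  colnames(res) <- c("c_ud", "c_ud_stderr", "pinned_ud",
                     "c_du", "c_du_stderr", "pinned_du")
  out <- cbind(grid, as.data.frame(res))
  sgn <- function(c, pinned) ifelse(is.na(c), NA_real_,
                                    ifelse(pinned == 1, 0, sign(c)))
  out$sign_ud <- sgn(out$c_ud, out$pinned_ud)
  out$sign_du <- sgn(out$c_du, out$pinned_du)
  class(out) <- c("pcl_signmap", class(out))
  out
}
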