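#' Fixed-step RK4 integration of an ODE
#'
#' Classical 4th-order Runge-Kutta with step `dt_integrate`, sampling the
#' solution every `dt_sample` (which must be an integer multiple of the
#' step).  Deterministic: identical inputs give bitwise-identical output.
#' This R-level integrator takes an arbitrary right-hand side and is meant
#' for oracles, cross-checks and small systems; the neuron simulations use
#' the compiled equivalents [simulate_neuron()] and [simulate_pair()].
#'
#' @param rhs function `rhs(t, y, ...)` returning the derivative vector.
#' @param y0 named initial state.
#' @param t_span total integration time (ms), > 0.
#' @param dt_integrate integration step (ms).
#' @param dt_sample sampling interval (ms), integer multiple of
#'   `dt_integrate`.
#' @param ... passed on to `rhs`.
#' @return A [new_trace()] object.
#' @export
integrate_ode <- function(rhs, y0, t_span, dt_integrate, dt_sample = dt_integrate,
                          ...) {
  check_steps(t_span, dt_integrate, dt_sample)
  every <- round(dt_sample / dt_integrate)
  nstep <- round(t_span / dt_integrate)
  nm <- names(y0)
  if (is.null(nm)) nm <- paste0("y", seq_along(y0))
  out <- matrix(NA_real_, nstep %/% every + 1, length(y0),
                dimnames = list(NULL, nm))
  y <- as.numeric(y0)
  out[1, ] <- y
  isamp <- 1L
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt_integrate
    k1 <- rhs(t, y, ...)
    k2 <- rhs(t + dt_integrate / 2, y + dt_integrate / 2 * k1, ...)
    k3 <- rhs(t + dt_integrate / 2, y + dt_integrate / 2 * k2, ...)
    k4 <- rhs(t + dt_integrate, y + dt_integrate * k3, ...)
    y <- y + dt_integrate / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)))
      stop(sprintf("integration diverged at t = %g ms", s * dt_integrate))
    if (s %% every == 0) {
      isamp <- isamp + 1L
      out[isamp, ] <- y
    }
  }
  new_trace(out, dt_sample,
            meta = list(dt_integrate = dt_integrate, t_span = t_span))
}

check_steps <- function(t_span, dt_integrate, dt_sample) {
  if (t_span <= 0) stop("t_span must be > 0")
  if (dt_integrate <= 0) stop("dt_integrate must be > 0")
  r <- dt_sample / dt_integrate
  if (abs(r - round(r)) > 1e-8 || round(r) < 1)
    stop("dt_sample must be an integer multiple of dt_integrate")
  if (round(t_span / dt_integrate) < 1) stop("zero-length integration request")
  invisible(TRUE)
}

#' Fixed-step method-of-steps integration of a DDE
#'
#' RK4 method of steps for delay differential equations with constant
#' delays.  Delayed states are interpolated from the stored solution by
#' cubic Hermite interpolation (values and derivatives at the integration
#' grid); before `t = 0` the initial history function is used.  With all
#' lags zero the scheme reduces exactly to [integrate_ode()].
#'
#' @param rhs function `rhs(t, y, ylag, ...)`; `ylag` is a matrix with one
#'   row per lag (in the order of `lags`).
#' @param y0 named initial state at `t = 0`.
#' @param history function of `t <= 0` returning the state; defaults to the
#'   constant history `y0`.
#' @param lags numeric vector of delays (ms, >= 0).
#' @inheritParams integrate_ode
#' @return A [new_trace()] object.
#' @export
integrate_dde <- function(rhs, y0, lags, history = NULL, t_span, dt_integrate,
                          dt_sample = dt_integrate, ...) {
  check_steps(t_span, dt_integrate, dt_sample)
  if (any(lags < 0)) stop("delays must be >= 0")
  if (is.null(history)) history <- function(t) as.numeric(y0)
  every <- round(dt_sample / dt_integrate)
  nstep <- round(t_span / dt_integrate)
  nv <- length(y0)
  nm <- names(y0)
  if (is.null(nm)) nm <- paste0("y", seq_along(y0))
  Y <- matrix(NA_real_, nstep + 1, nv)   # solution at integration grid
  D <- matrix(NA_real_, nstep + 1, nv)   # derivatives for Hermite
  lookup <- function(tq, kmax) {
    # state at time tq using history (tq <= 0) or Hermite on segment
    if (tq <= 0) return(history(tq))
    if (kmax < 1)  # first step with lag < dt: linear Taylor from the node
      return(Y[1, ] + tq * D[1, ])
    x <- tq / dt_integrate
    k <- max(0, min(floor(x), kmax - 1))  # mild extrapolation for lag < dt
    u <- x - k
    h00 <- (1 + 2 * u) * (1 - u)^2; h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u); h11 <- u^2 * (u - 1)
    h00 * Y[k + 1, ] + h10 * dt_integrate * D[k + 1, ] +
      h01 * Y[k + 2, ] + h11 * dt_integrate * D[k + 2, ]
  }
  eval_rhs <- function(t, y, kmax, ...) {
    ylag <- do.call(rbind, lapply(lags, function(tau) {
      if (tau == 0) y else lookup(t - tau, kmax)
    }))
    rhs(t, y, ylag, ...)
  }
  y <- as.numeric(y0)
  Y[1, ] <- y
  D[1, ] <- eval_rhs(0, y, kmax = 0, ...)
  out <- matrix(NA_real_, nstep %/% every + 1, nv, dimnames = list(NULL, nm))
  out[1, ] <- y
  isamp <- 1L
  dt <- dt_integrate
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    kmax <- s - 1
    k1 <- eval_rhs(t, y, kmax, ...)
    k2 <- eval_rhs(t + dt / 2, y + dt / 2 * k1, kmax, ...)
    k3 <- eval_rhs(t + dt / 2, y + dt / 2 * k2, kmax, ...)
    k4 <- eval_rhs(t + dt, y + dt * k3, kmax, ...)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)))
      stop(sprintf("integration diverged at t = %g ms", s * dt))
    Y[s + 1, ] <- y
    D[s + 1, ] <- eval_rhs(s * dt, y, kmax = s, ...)
    if (s %% every == 0) {
      isamp <- isamp + 1L
      out[isamp, ] <- y
    }
  }
  new_trace(out, dt_sample,
            meta = list(dt_integrate = dt_integrate, t_span = t_span,
                        lags = lags))
}

#' Simulate the single PBC neuron
#'
#' Compiled fixed-step RK4 integration of the five model equations.
#'
#' @param params a [pbc_params()] object.
#' @param I_exc stimulus current.
#' @param y0 initial state `(V, n, h, Ca, l)`; default [default_state()].
#' @param t_end run length (ms).
#' @param dt_integrate integration step (ms); default 0.02 resolves the
#'   ~1 ms spike upstrokes.
#' @param dt_sample sampling interval (ms); default 1.
#' @return A [new_trace()] with columns `V`, `n`, `h`, `Ca`, `l`.
#' @examples
#' \donttest{
#' tr <- simulate_neuron(pbc_params(), I_exc = 8.5, t_end = 2e4)
#' }
#' @export
simulate_neuron <- function(params, I_exc, y0 = default_state(params),
                            t_end = 2e5, dt_integrate = 0.02, dt_sample = 1) {
  stopifnot(inherits(params, "pbc_params"), length(y0) == 5)
  check_steps(t_end, dt_integrate, dt_sample)
  m <- cpp_simulate_single(unclass(params), I_exc, as.numeric(y0), t_end,
                           dt_integrate, dt_sample)
  states <- m[, -1, drop = FALSE]
  colnames(states) <- c("V", "n", "h", "Ca", "l")
  new_trace(states, dt_sample,
            meta = list(params = params, I_exc = I_exc, y0 = y0,
                        dt_integrate = dt_integrate))
}

#' Simulate the delay-coupled two-neuron network
#'
#' Compiled RK4 method-of-steps integration of the eight coupled equations
#' (two somatic compartments, one shared calcium subsystem).  Delayed
#' voltages are interpolated from the integration-resolution history by
#' cubic Hermite interpolation; the initial history is constant, equal to
#' the initial state.  With `tau1 = tau2 = 0` the integration is exactly
#' the plain RK4 solution of the 8-dimensional ODE.
#'
#' @param params a [pbc_params()] object.
#' @param net a [network_config()] object.
#' @param y0 initial state `(V1, n1, h1, V2, n2, h2, Ca, l)`; default
#'   [default_pair_state()].
#' @inheritParams simulate_neuron
#' @return A [new_trace()] with columns `V1 ... l`.
#' @export
simulate_pair <- function(params, net, y0 = default_pair_state(params),
                          t_end = 2e5, dt_integrate = 0.02, dt_sample = 1) {
  stopifnot(inherits(params, "pbc_params"), inherits(net, "pbc_network"),
            length(y0) == 8)
  if (net$tau1 < 0 || net$tau2 < 0) stop("delays must be >= 0")
  check_steps(t_end, dt_integrate, dt_sample)
  m <- cpp_simulate_pair(unclass(params), unclass(net), as.numeric(y0), t_end,
                         dt_integrate, dt_sample)
  states <- m[, -1, drop = FALSE]
  colnames(states) <- c("V1", "n1", "h1", "V2", "n2", "h2", "Ca", "l")
  new_trace(states, dt_sample,
            meta = list(params = params, net = net, y0 = y0,
                        dt_integrate = dt_integrate))
}
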