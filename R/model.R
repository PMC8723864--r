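#' Steady-state gating function (Boltzmann)
#'
#' `x_inf(V) = 1 / (1 + exp((V - V_half) / slope))`.  Negative slopes give
#' activation curves (increasing in `V`), positive slopes inactivation
#' curves.
#'
#' @param V membrane potential (mV); vectorized.
#' @param V_half half-activation voltage (mV).
#' @param slope gating slope (mV); must be nonzero.
#' @return Values in (0, 1).
#' @export
gate_inf <- function(V, V_half, slope) {
  if (slope == 0) stop("gating slope must be nonzero")
  1 / (1 + exp((V - V_half) / slope))
}

#' Voltage-dependent gating time constant
#'
#' `tau(V) = tau_bar / cosh((V - V_half) / (2 * slope))`; maximal at
#' `V = V_half`, even around it.
#'
#' @param V membrane potential (mV); vectorized.
#' @param tau_bar maximal time constant (ms); must be positive.
#' @inheritParams gate_inf
#' @return Time constants in `(0, tau_bar]` (ms).
#' @export
gate_tau <- function(V, tau_bar, V_half, slope) {
  if (slope == 0) stop("gating slope must be nonzero")
  if (tau_bar <= 0) stop("tau_bar must be > 0")
  tau_bar / cosh((V - V_half) / (2 * slope))
}

#' CAN current calcium activation
#'
#' Hill activation `f(Ca) = 1 / (1 + (K_CAN / Ca)^n_CAN)` scaled by
#' `params$can_scale` (see [pbc_params()]).
#'
#' @param Ca intracellular calcium (uM), > 0.
#' @param params a [pbc_params()] object.
#' @export
can_activation <- function(Ca, params) {
  if (any(Ca <= 0)) stop("invalid state: Ca must be > 0")
  params$can_scale / (1 + (params$K_CAN / Ca)^params$n_CAN)
}

#' Ionic currents of the somatic compartment
#'
#' Evaluates the five membrane currents at a somatic state and calcium
#' level:
#' `I_Na = g_Na m_inf(V)^3 (1 - n) (V - V_Na)`,
#' `I_NaP = g_NaP mp_inf(V) h (V - V_Na)`,
#' `I_CAN = g_CAN f(Ca) (V - V_Na)`,
#' `I_K = g_K n^4 (V - V_K)`, and `I_L = g_L (V - V_L)`.
#'
#' @param state named numeric vector with `V`, `n`, `h`.
#' @param Ca intracellular calcium (uM), > 0.
#' @param params a [pbc_params()] object.
#' @return Named list with `I_Na`, `I_NaP`, `I_CAN`, `I_K`, `I_L`.
#' @export
ionic_currents <- function(state, Ca, params) {
  p <- params
  V <- state[["V"]]; n <- state[["n"]]; h <- state[["h"]]
  if (Ca <= 0) stop("invalid state: Ca must be > 0")
  m <- gate_inf(V, p$V_m, p$s_m)
  mp <- gate_inf(V, p$V_p, p$s_mp)
  list(
    I_Na = p$g_Na * m^3 * (1 - n) * (V - p$V_Na),
    I_NaP = p$g_NaP * mp * h * (V - p$V_Na),
    I_CAN = p$g_CAN * can_activation(Ca, p) * (V - p$V_Na),
    I_K = p$g_K * n^4 * (V - p$V_K),
    I_L = p$g_L * (V - p$V_L)
  )
}

#' Right-hand side of the single-neuron model
#'
#' The five model equations: the somatic voltage equation
#' `C_m dV/dt = -I_Na - I_NaP - I_CAN - I_K - I_L - I_exc`, first-order
#' gating kinetics for `n` and `h`, and the elliptic calcium subsystem
#' `dCa/dt = -eps * d * (l - l_c)`, `dl/dt = (eps / d) * (Ca - Ca_c)`.
#'
#' @param state numeric vector `(V, n, h, Ca, l)`.
#' @param I_exc stimulus current.
#' @param params a [pbc_params()] object.
#' @return Numeric vector of the five time derivatives.
#' @export
rhs_single <- function(state, I_exc, params) {
  p <- params
  V <- state[[1]]; n <- state[[2]]; h <- state[[3]]
  Ca <- state[[4]]; l <- state[[5]]
  cur <- ionic_currents(c(V = V, n = n, h = h), Ca, p)
  dV <- (-cur$I_Na - cur$I_NaP - cur$I_CAN - cur$I_K - cur$I_L - I_exc) / p$C_m
  dn <- (gate_inf(V, p$V_n, p$s_n) - n) / gate_tau(V, p$tau_n_bar, p$V_n, p$s_n)
  dh <- (gate_inf(V, p$V_h, p$s_h) - h) / gate_tau(V, p$tau_h_bar, p$V_h, p$s_h)
  c(dV, dn, dh,
    -p$eps * p$d * (l - p$l_c),
    (p$eps / p$d) * (Ca - p$Ca_c))
}

#' Right-hand side of the delay-coupled pair
#'
#' Two somatic compartments sharing one calcium subsystem; neuron `i`
#' additionally receives the electrical coupling current
#' `I_ci = g_c * (V_j(t - tau_i) - V_i)`, subtracted on the right-hand side
#' of its voltage equation.  Delays are resolved by the caller: the delayed
#' voltages are passed in.
#'
#' @param state numeric vector `(V1, n1, h1, V2, n2, h2, Ca, l)`.
#' @param delayed_V numeric vector `(V2(t - tau1), V1(t - tau2))`.
#' @param net a [network_config()] object.
#' @param params a [pbc_params()] object.
#' @return Numeric vector of the eight time derivatives.
#' @export
rhs_coupled <- function(state, delayed_V, net, params) {
  p <- params
  Ca <- state[[7]]; l <- state[[8]]
  Ic1 <- net$g_c * (delayed_V[[1]] - state[[1]])
  Ic2 <- net$g_c * (delayed_V[[2]] - state[[4]])
  d1 <- rhs_single(c(state[1:3], Ca, l), net$I_exc1 + Ic1, p)
  d2 <- rhs_single(c(state[4:6], Ca, l), net$I_exc2 + Ic2, p)
  c(d1[1:3], d2[1:3], d1[4], d1[5])
}

#' Default initial state of the single neuron
#'
#' Somatic state `(V, n, h) = (-50, 0, 0.5)` with calcium starting on the
#' ellipse at `Ca = Ca_c + ellipse_amplitude`, `l = l_c`.  The default
#' amplitude 0 pins the calcium subsystem at its center, making the CAN
#' drive constant.
#'
#' @param params a [pbc_params()] object.
#' @param ellipse_amplitude initial calcium displacement from the ellipse
#'   center (uM); the resulting ellipse has `E(0) = amplitude^2 / d`.
#' @return Named numeric state vector of length 5.
#' @export
default_state <- function(params, ellipse_amplitude = 0) {
  if (params$Ca_c + ellipse_amplitude <= 0)
    stop("ellipse amplitude places Ca at or below 0")
  c(V = -50, n = 0, h = 0.5,
    Ca = params$Ca_c + ellipse_amplitude, l = params$l_c)
}

#' Default initial state of the coupled pair
#'
#' Both neurons start from [default_state()]; neuron 2's voltage is
#' perturbed by `+0.01` mV so that complete synchronization shows up as
#' convergence rather than a trivial identity.
#'
#' @inheritParams default_state
#' @param perturb_V2 initial voltage offset of neuron 2 (mV).
#' @return Named numeric state vector of length 8.
#' @export
default_pair_state <- function(params, ellipse_amplitude = 0,
                               perturb_V2 = 0.01) {
  s <- default_state(params, ellipse_amplitude)
  c(V1 = s[["V"]], n1 = s[["n"]], h1 = s[["h"]],
    V2 = s[["V"]] + perturb_V2, n2 = s[["n"]], h2 = s[["h"]],
    Ca = s[["Ca"]], l = s[["l"]])
}

#' Calcium ellipse invariant
#'
#' `E(Ca, l) = (Ca - Ca_c)^2 / d + d * (l - l_c)^2` is conserved along the
#' calcium subsystem; its time derivative along the flow is identically
#' zero.
#'
#' @param Ca,l calcium state (vectorized).
#' @param params a [pbc_params()] object.
#' @export
ellipse_invariant <- function(Ca, l, params) {
  (Ca - params$Ca_c)^2 / params$d + params$d * (l - params$l_c)^2
}
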