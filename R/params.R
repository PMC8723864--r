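#' Biophysical parameters of the modified PBC neuron model
#'
#' Constructs the parameter set of the modified Toporikova-Butera
#' pre-Botzinger complex (PBC) neuron: a somatic compartment with fast
#' sodium, delayed-rectifier potassium, persistent sodium (NaP), leak and
#' calcium-activated nonspecific cation (CAN) currents, driven by a calcium
#' subsystem that traces an ellipse in the (`Ca`, `l`) plane around the
#' center (`Ca_c`, `l_c`).
#'
#' Defaults are the published values of the model.  Two points deserve
#' note:
#'
#' * `tau_n_bar = 10` ms and `tau_h_bar = 10000` ms follow the canonical
#'   Butera-family assignment (fast potassium activation `n`, slow NaP
#'   inactivation `h`).  This assignment is the one consistent with the
#'   model's published somatic Jacobian; see the package vignette.
#' * `can_scale` multiplies the CAN activation function.  The default 1 is
#'   the plain Hill form `1 / (1 + (K_CAN/Ca)^n_CAN)`.  The published
#'   fixed-point analysis of the somatic subsystem implies an effective CAN
#'   activation about 0.58 times the Hill value at the operating calcium;
#'   [calibrate_can_scale()] computes that factor in closed form, and the
#'   vignette discusses the discrepancy.
#'
#' @param ... named overrides of any default field (see Details).
#'
#' @details Fields (units): `C_m` membrane capacitance; `g_Na`, `g_K`,
#'   `g_L`, `g_NaP`, `g_CAN` maximal conductances (nS); `V_Na`, `V_K`,
#'   `V_L` reversal potentials (mV); `V_m`, `V_n`, `V_p`, `V_h`
#'   half-activation voltages (mV); `s_m`, `s_n`, `s_h`, `s_mp` gating
#'   slopes (mV); `tau_n_bar`, `tau_h_bar` maximal gating time constants
#'   (ms); `n_CAN`, `K_CAN` CAN Hill exponent and half-activation calcium
#'   (uM); `eps` angular speed of the calcium ellipse (1/ms); `d` ellipse
#'   aspect ratio; `Ca_c`, `l_c` ellipse center; `can_scale` CAN activation
#'   scaling (dimensionless).
#'
#' @return An object of class `pbc_params` (a validated named list).
#' @seealso [calibrate_can_scale()], [write_params_yaml()],
#'   [network_config()]
#' @examples
#' p <- pbc_params()
#' p$g_NaP
#' p2 <- pbc_params(g_NaP = 2.5) # overrides by name
#' @export
pbc_params <- function(...) {
  p <- list(
    C_m = 21, g_Na = 28, g_K = 11.2, g_L = 2.3, g_NaP = 2, g_CAN = 0.7,
    V_Na = 50, V_K = -85, V_L = -58,
    V_m = -34, V_n = -29, V_p = -40, V_h = -48,
    s_m = -5, s_n = -4, s_h = 5, s_mp = -6,
    tau_n_bar = 10, tau_h_bar = 10000,
    n_CAN = 0.97, K_CAN = 0.74,
    eps = 0.09, d = 0.5, Ca_c = 0.1, l_c = 0.9,
    can_scale = 1
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_params(p)
  structure(p, class = "pbc_params")
}

validate_params <- function(p) {
  num1 <- function(f) is.numeric(p[[f]]) && length(p[[f]]) == 1 && is.finite(p[[f]])
  for (f in names(p)) if (!num1(f)) stop("parameter '", f, "' must be a finite scalar")
  for (f in c("g_Na", "g_K", "g_L", "g_NaP", "g_CAN"))
    if (p[[f]] < 0) stop("conductance '", f, "' must be >= 0")
  if (p$C_m <= 0) stop("C_m must be > 0")
  if (p$eps <= 0) stop("eps must be > 0")
  if (p$d <= 0) stop("d must be > 0")
  if (p$Ca_c <= 0) stop("Ca_c must be > 0")
  if (p$l_c <= 0 || p$l_c >= 1) stop("l_c must be in (0, 1)")
  for (f in c("s_m", "s_n", "s_h", "s_mp"))
    if (p[[f]] == 0) stop("gating slope '", f, "' must be nonzero")
  if (p$tau_n_bar <= 0 || p$tau_h_bar <= 0) stop("gating time constants must be > 0")
  if (p$can_scale < 0) stop("can_scale must be >= 0")
  invisible(p)
}

#' @export
print.pbc_params <- function(x, ...) {
  cat("<pbc_params> modified Toporikova-Butera PBC neuron\n")
  v <- unlist(x)
  cat(paste(sprintf("  %-10s %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Calibrate the CAN activation scale to the published somatic equilibrium
#'
#' The published fixed-point analysis of the somatic subsystem (calcium
#' fixed at the ellipse center) reports a Hopf point with equilibrium
#' membrane potential `V_eq` at stimulus current `I_exc`.  With every other
#' current fixed by the standard functional forms, the current balance
#' `sum(I) + I_exc = 0` at that point determines the effective CAN
#' conductance, hence the scaling of the Hill activation.  This function
#' solves that balance in closed form and returns the params object with
#' `can_scale` replaced.
#'
#' @param params a [pbc_params()] object.
#' @param V_eq equilibrium membrane potential at the reference Hopf point
#'   (mV); default the published value -51.8239.
#' @param I_exc stimulus current at the reference Hopf point; default the
#'   published 8.073.
#' @param Ca calcium concentration at which the balance is solved (uM);
#'   default the ellipse center.
#' @return A `pbc_params` object with calibrated `can_scale`.
#' @export
calibrate_can_scale <- function(params, V_eq = -51.8239, I_exc = 8.073,
                                Ca = params$Ca_c) {
  p <- params
  n <- gate_inf(V_eq, p$V_n, p$s_n)
  h <- gate_inf(V_eq, p$V_h, p$s_h)
  m <- gate_inf(V_eq, p$V_m, p$s_m)
  mp <- gate_inf(V_eq, p$V_p, p$s_mp)
  I_Na <- p$g_Na * m^3 * (1 - n) * (V_eq - p$V_Na)
  I_NaP <- p$g_NaP * mp * h * (V_eq - p$V_Na)
  I_K <- p$g_K * n^4 * (V_eq - p$V_K)
  I_L <- p$g_L * (V_eq - p$V_L)
  g_can_f <- (-I_Na - I_NaP - I_K - I_L - I_exc) / (V_eq - p$V_Na)
  f_hill <- 1 / (1 + (p$K_CAN / Ca)^p$n_CAN)
  p$can_scale <- g_can_f / (p$g_CAN * f_hill)
  validate_params(p)
  structure(p, class = "pbc_params")
}

#' Two-neuron network configuration
#'
#' Coupling and drive configuration for the electrically coupled pair.  The
#' coupling current entering neuron `i` is
#' `I_ci = g_c * (V_j(t - tau_i) - V_i(t))`, subtracted on the right-hand
#' side of the voltage equation, where `j` is the other neuron.
#'
#' @param g_c coupling strength (nS); negative values synchronize.
#' @param tau1,tau2 transmission delays of the two directions (ms, >= 0).
#' @param I_exc1,I_exc2 stimulus currents of neurons 1 and 2.
#' @return An object of class `pbc_network`.
#' @examples
#' network_config(g_c = -0.4)
#' @export
network_config <- function(g_c = 0, tau1 = 0, tau2 = 0,
                           I_exc1 = 8.5, I_exc2 = 8.5) {
  if (tau1 < 0 || tau2 < 0) stop("delays must be >= 0")
  structure(list(g_c = g_c, tau1 = tau1, tau2 = tau2,
                 I_exc1 = I_exc1, I_exc2 = I_exc2),
            class = "pbc_network")
}

#' @export
print.pbc_network <- function(x, ...) {
  cat(sprintf(
    "<pbc_network> g_c = %g, tau = (%g, %g) ms, I_exc = (%g, %g)%s\n",
    x$g_c, x$tau1, x$tau2, x$I_exc1, x$I_exc2,
    if (x$tau1 == x$tau2 && x$I_exc1 == x$I_exc2) " [identical, symmetric]" else ""
  ))
  invisible(x)
}

#' Read / write model parameters as YAML
#'
#' Parameters serialize to a flat YAML mapping keyed by the published
#' parameter names.  The file shipped at
#' `system.file("extdata", "table1.yaml", package = "pbcsync")` holds the
#' canonical defaults.
#'
#' @param path file path.
#' @param params a `pbc_params` object.
#' @return `read_params_yaml` returns a `pbc_params` object;
#'   `write_params_yaml` returns `path` invisibly.
#' @export
read_params_yaml <- function(path) {
  do.call(pbc_params, yaml::read_yaml(path))
}

#' @rdname read_params_yaml
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "pbc_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
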