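# Somatic-subsystem analysis at fixed calcium: equilibria, analytic
# Jacobian and higher-order derivative tensors, Hopf location, first
# Lyapunov coefficient, and Benettin maximal-Lyapunov estimation.

# stimulus current that makes V an equilibrium of the somatic subsystem
# (n and h at steady state, calcium fixed)
balance_current <- function(V, params, Ca = params$Ca_c) {
  p <- params
  n <- gate_inf(V, p$V_n, p$s_n)
  h <- gate_inf(V, p$V_h, p$s_h)
  cur <- ionic_currents(c(V = V, n = n, h = h), Ca, p)
  -(cur$I_Na + cur$I_NaP + cur$I_CAN + cur$I_K + cur$I_L)
}

somatic_rhs <- function(state, I_exc, params, Ca) {
  rhs_single(c(state, Ca, params$l_c), I_exc, params)[1:3]
}

#' Equilibria of the somatic subsystem
#'
#' Solves the somatic subsystem `(V, n, h)` at fixed calcium for its
#' equilibria.  At an equilibrium `n = n_inf(V)` and `h = h_inf(V)`, so the
#' problem reduces to the scalar current balance in `V`; all roots in the
#' search box are returned (the equilibrium curve over the stimulus
#' current is cubic, so there may be one to three).
#'
#' @param params a [pbc_params()] object.
#' @param I_exc stimulus current.
#' @param Ca_fixed calcium level (uM); default the ellipse center.
#' @param V_range search box for `V` (mV).
#' @param n_grid scan resolution for root bracketing.
#' @return Matrix with columns `V`, `n`, `h`, one row per equilibrium,
#'   ordered by increasing `V`.  Error if none exists in the box.
#' @export
find_equilibrium <- function(params, I_exc, Ca_fixed = params$Ca_c,
                             V_range = c(-80, 20), n_grid = 2000) {
  g <- function(V) balance_current(V, params, Ca_fixed) - I_exc
  Vs <- seq(V_range[1], V_range[2], length.out = n_grid)
  gv <- vapply(Vs, g, numeric(1))
  sign_flip <- which(gv[-1] * gv[-length(gv)] <= 0 & is.finite(gv[-1]))
  if (!length(sign_flip))
    stop("no equilibrium found in the search box")
  roots <- vapply(sign_flip, function(i) {
    uniroot(g, c(Vs[i], Vs[i + 1]), tol = 1e-13)$root
  }, numeric(1))
  roots <- sort(unique(roots))
  cbind(V = roots,
        n = gate_inf(roots, params$V_n, params$s_n),
        h = gate_inf(roots, params$V_h, params$s_h))
}

#' Analytic Jacobian of the somatic subsystem
#'
#' Exact partial derivatives of the somatic right-hand side `(dV, dn, dh)`
#' with respect to `(V, n, h)` at a given state and fixed calcium.  The
#' entries (2,3) and (3,2) are structurally zero: the `n` kinetics do not
#' involve `h` and vice versa.
#'
#' @param params a [pbc_params()] object.
#' @param eq state `(V, n, h)` (typically an equilibrium row from
#'   [find_equilibrium()]).
#' @param Ca_fixed calcium level (uM).
#' @return 3x3 Jacobian matrix.
#' @export
jacobian_somatic <- function(params, eq, Ca_fixed = params$Ca_c) {
  p <- params
  V <- eq[[1]]; n <- eq[[2]]; h <- eq[[3]]
  dl <- derivs_logistic
  m <- dl(V, p$V_m, p$s_m)
  mp <- dl(V, p$V_p, p$s_mp)
  ninf <- dl(V, p$V_n, p$s_n)
  hinf <- dl(V, p$V_h, p$s_h)
  k <- p$g_CAN * can_activation(Ca_fixed, p)
  # P = m^3 (V - V_Na), Q = mp (V - V_Na)
  dV <- V - p$V_Na
  P1 <- 3 * m$y^2 * m$y1 * dV + m$y^3
  Q1 <- mp$y1 * dV + mp$y
  rn <- derivs_invtau(V, p$V_n, p$s_n, p$tau_n_bar)
  rh <- derivs_invtau(V, p$V_h, p$s_h, p$tau_h_bar)
  J <- matrix(0, 3, 3)
  J[1, 1] <- -(p$g_Na * (1 - n) * P1 + p$g_NaP * h * Q1 + k +
                 p$g_K * n^4 + p$g_L) / p$C_m
  J[1, 2] <- (p$g_Na * m$y^3 * dV - 4 * p$g_K * n^3 * (V - p$V_K)) / p$C_m
  J[1, 3] <- -p$g_NaP * mp$y * dV / p$C_m
  J[2, 1] <- ninf$y1 * rn$y + (ninf$y - n) * rn$y1
  J[2, 2] <- -rn$y
  J[3, 1] <- hinf$y1 * rh$y + (hinf$y - h) * rh$y1
  J[3, 3] <- -rh$y
  J
}

# logistic sigma(V) = 1/(1 + exp((V - V0)/s)) with derivatives to 3rd order
derivs_logistic <- function(V, V0, s) {
  y <- 1 / (1 + exp((V - V0) / s))
  y1 <- -y * (1 - y) / s
  y2 <- -y1 * (1 - 2 * y) / s
  y3 <- -(y2 * (1 - 2 * y) - 2 * y1^2) / s
  list(y = y, y1 = y1, y2 = y2, y3 = y3)
}

# r(V) = 1/tau(V) = cosh((V - V0)/(2 s)) / tau_bar with derivatives
derivs_invtau <- function(V, V0, s, tau_bar) {
  th <- (V - V0) / (2 * s)
  tp <- 1 / (2 * s)
  list(y = cosh(th) / tau_bar,
       y1 = sinh(th) * tp / tau_bar,
       y2 = cosh(th) * tp^2 / tau_bar,
       y3 = sinh(th) * tp^3 / tau_bar)
}

# exact second- and third-order derivative tensors of the somatic RHS
# H[i, j, k] = d2 F_i / dxi_j dxi_k ; TT[i, j, k, l] = third derivatives
somatic_tensors <- function(params, eq, Ca_fixed = params$Ca_c) {
  p <- params
  V <- eq[[1]]; n <- eq[[2]]; h <- eq[[3]]
  m <- derivs_logistic(V, p$V_m, p$s_m)
  mp <- derivs_logistic(V, p$V_p, p$s_mp)
  ninf <- derivs_logistic(V, p$V_n, p$s_n)
  hinf <- derivs_logistic(V, p$V_h, p$s_h)
  rn <- derivs_invtau(V, p$V_n, p$s_n, p$tau_n_bar)
  rh <- derivs_invtau(V, p$V_h, p$s_h, p$tau_h_bar)
  dV <- V - p$V_Na
  # a = m^3 and its V-derivatives
  a0 <- m$y^3
  a1 <- 3 * m$y^2 * m$y1
  a2 <- 6 * m$y * m$y1^2 + 3 * m$y^2 * m$y2
  a3 <- 6 * m$y1^3 + 18 * m$y * m$y1 * m$y2 + 3 * m$y^2 * m$y3
  # P = a (V - V_Na), Q = mp (V - V_Na): higher derivatives
  P2 <- a2 * dV + 2 * a1
  P3 <- a3 * dV + 3 * a2
  Q2 <- mp$y2 * dV + 2 * mp$y1
  Q3 <- mp$y3 * dV + 3 * mp$y2
  # u = x_inf * r products for the gating equations
  un2 <- ninf$y2 * rn$y + 2 * ninf$y1 * rn$y1 + ninf$y * rn$y2
  un3 <- ninf$y3 * rn$y + 3 * ninf$y2 * rn$y1 + 3 * ninf$y1 * rn$y2 +
    ninf$y * rn$y3
  uh2 <- hinf$y2 * rh$y + 2 * hinf$y1 * rh$y1 + hinf$y * rh$y2
  uh3 <- hinf$y3 * rh$y + 3 * hinf$y2 * rh$y1 + 3 * hinf$y1 * rh$y2 +
    hinf$y * rh$y3
  Cm <- p$C_m
  H <- array(0, c(3, 3, 3))
  TT <- array(0, c(3, 3, 3, 3))
  P1 <- a1 * dV + a0
  Q1 <- mp$y1 * dV + mp$y
  H[1, 1, 1] <- (-p$g_Na * P2 * (1 - n) - p$g_NaP * Q2 * h) / Cm
  H[1, 1, 2] <- H[1, 2, 1] <- p$g_Na * P1 / Cm
  H[1, 1, 3] <- H[1, 3, 1] <- -p$g_NaP * Q1 / Cm
  H[1, 2, 2] <- -12 * p$g_K * n^2 * (V - p$V_K) / Cm
  H[2, 1, 1] <- un2 - n * rn$y2
  H[2, 1, 2] <- H[2, 2, 1] <- -rn$y1
  H[3, 1, 1] <- uh2 - h * rh$y2
  H[3, 1, 3] <- H[3, 3, 1] <- -rh$y1
  TT[1, 1, 1, 1] <- (-p$g_Na * P3 * (1 - n) - p$g_NaP * Q3 * h) / Cm
  TT[1, 1, 1, 2] <- TT[1, 1, 2, 1] <- TT[1, 2, 1, 1] <- p$g_Na * P2 / Cm
  TT[1, 1, 1, 3] <- TT[1, 1, 3, 1] <- TT[1, 3, 1, 1] <- -p$g_NaP * Q2 / Cm
  TT[1, 1, 2, 2] <- TT[1, 2, 1, 2] <- TT[1, 2, 2, 1] <- -12 * p$g_K * n^2 / Cm
  TT[1, 2, 2, 2] <- -24 * p$g_K * n * (V - p$V_K) / Cm
  TT[2, 1, 1, 1] <- un3 - n * rn$y3
  TT[2, 1, 1, 2] <- TT[2, 1, 2, 1] <- TT[2, 2, 1, 1] <- -rn$y2
  TT[3, 1, 1, 1] <- uh3 - h * rh$y3
  TT[3, 1, 1, 3] <- TT[3, 1, 3, 1] <- TT[3, 3, 1, 1] <- -rh$y2
  list(H = H, T = TT)
}

# real part of the complex eigenvalue pair of the somatic Jacobian at the
# tracked equilibrium branch; NA when the spectrum is all-real
branch_re_pair <- function(params, I_exc, Ca_fixed, branch = "lower") {
  eqs <- find_equilibrium(params, I_exc, Ca_fixed)
  eq <- if (branch == "lower") eqs[1, ] else eqs[nrow(eqs), ]
  ev <- eigen(jacobian_somatic(params, eq, Ca_fixed), only.values = TRUE)$values
  cp <- ev[Im(ev) != 0]
  if (length(cp) < 2) return(list(re = NA_real_, eq = eq))
  list(re = max(Re(cp)), eq = eq)
}

#' Locate a Hopf bifurcation of the somatic subsystem
#'
#' Tracks an equilibrium branch over the stimulus current and bisects on
#' the real part of its complex eigenvalue pair until `|Re| < tol`.
#' Returns the eigen-data at the crossing: critical frequency `omega`, the
#' remaining real eigenvalue, and the critical right/left eigenvectors in
#' the normalization used by [normal_form_coeffs()] (`q` scaled to first
#' component 1; `p` solving the transposed problem at `-i omega` with
#' `<p, q> = sum(Conj(p) * q) = 1`).
#'
#' @param params a [pbc_params()] object.
#' @param I_range interval of stimulus current containing one sign change
#'   of the pair's real part on the tracked branch.
#' @param Ca_fixed calcium level (uM).
#' @param branch `"lower"` (most hyperpolarized equilibrium) or
#'   `"upper"`.
#' @param tol bisection tolerance on `Re(lambda_pair)` (1/ms).
#' @param n_scan pre-scan resolution used to bracket the crossing.
#' @return An object of class `pbc_hopf` with `I_exc_star`, `eq3`, `A`,
#'   `omega`, `lambda_real`, `q`, `p` (normal-form slots are filled by
#'   [normal_form_coeffs()]).
#' @export
locate_hopf <- function(params, I_range, Ca_fixed = params$Ca_c,
                        branch = c("lower", "upper"), tol = 1e-10,
                        n_scan = 41) {
  branch <- match.arg(branch)
  Is <- seq(I_range[1], I_range[2], length.out = n_scan)
  res <- vapply(Is, function(I) {
    tryCatch(branch_re_pair(params, I, Ca_fixed, branch)$re,
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- which(!is.na(res))
  br <- NULL
  for (i in seq_along(ok)[-1]) {
    a <- ok[i - 1]; b <- ok[i]
    if (b - a == 1 && res[a] * res[b] <= 0) {
      br <- c(Is[a], Is[b])
      break
    }
  }
  if (is.null(br))
    stop("no sign change of Re(lambda_pair) found on this branch in I_range")
  lo <- br[1]; hi <- br[2]
  f <- function(I) branch_re_pair(params, I, Ca_fixed, branch)$re
  flo <- f(lo)
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.na(fm)) stop("lost the complex pair during bisection")
    if (abs(fm) < tol || (hi - lo) < 1e-14) break
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  bp <- branch_re_pair(params, mid, Ca_fixed, branch)
  A <- jacobian_somatic(params, bp$eq, Ca_fixed)
  ev <- eigen(A)
  ip <- which(Im(ev$values) > 0)
  if (length(ip) != 1) stop("expected exactly one complex pair at the Hopf point")
  omega <- Im(ev$values[ip])
  lam_real <- Re(ev$values[Im(ev$values) == 0])
  q <- ev$vectors[, ip]
  q <- q / q[1]
  evt <- eigen(t(A))
  jm <- which.min(abs(evt$values + 1i * omega))
  p <- evt$vectors[, jm]
  p <- p / Conj(sum(Conj(p) * q))
  structure(list(I_exc_star = mid, eq3 = bp$eq, A = A, omega = omega,
                 lambda_real = lam_real, q = q, p = p,
                 Ca_fixed = Ca_fixed, branch = branch,
                 g20 = NULL, g11 = NULL, g21 = NULL, l1 = NULL,
                 direction = NULL),
            class = "pbc_hopf")
}

#' @export
print.pbc_hopf <- function(x, ...) {
  cat(sprintf("<pbc_hopf> I_exc* = %.6g, eq V = %.6g mV\n  omega = %.6g /ms, lambda_real = %.6g /ms\n",
              x$I_exc_star, x$eq3[["V"]], x$omega, x$lambda_real))
  if (!is.null(x$l1))
    cat(sprintf("  l1 = %.6g (%s)\n", x$l1, x$direction))
  invisible(x)
}

#' First Lyapunov coefficient from eigen-data and multilinear forms
#'
#' Generic Hopf normal-form engine: given the Jacobian `A` at a Hopf
#' point and callbacks for the second- and third-order multilinear forms
#' `B(x, y)` and `C(x, y, z)` of the vector field, computes
#' `g20 = <p, B(q, q)>`, `g11 = <p, B(q, qbar)>`,
#' `g21 = <p, C(q, q, qbar)>` and the first Lyapunov coefficient
#' `l1 = Re(i g20 g11 + omega g21) / (2 omega^2)`
#' with `q` scaled to unit first component and `<p, q> = 1` (inner product
#' `sum(Conj(p) * q)`).  `method = "center_manifold"` additionally applies
#' the quadratic center-manifold corrections to `g21`
#' (`+ 2 <p, B(q, h11)> + <p, B(qbar, h20)>` with
#' `h11 = -A^{-1} B(q, qbar)` and `h20 = (2 i omega I - A)^{-1} B(q, q)`),
#' which is required for the sign of `l1` to be meaningful in dimensions
#' above two.
#'
#' @param A Jacobian matrix at the Hopf point (one purely imaginary pair).
#' @param Bfun function of two vectors returning the bilinear form value.
#' @param Cfun function of three vectors returning the trilinear form
#'   value.
#' @param method `"projection"` (the plain combination above) or
#'   `"center_manifold"`.
#' @return List with `omega`, `q`, `p`, `g20`, `g11`, `g21`, `l1`,
#'   `direction` (`"supercritical"` when `l1 < 0`, else
#'   `"subcritical"`).
#' @export
hopf_normal_form <- function(A, Bfun, Cfun,
                             method = c("projection", "center_manifold")) {
  method <- match.arg(method)
  ev <- eigen(A)
  ip <- which(Im(ev$values) > 0 &
                abs(Re(ev$values)) < 1e-6 * (1 + abs(Im(ev$values))))
  if (length(ip) != 1) stop("A must have exactly one purely imaginary pair")
  omega <- Im(ev$values[ip])
  q <- ev$vectors[, ip]
  q <- q / q[1]
  evt <- eigen(t(A))
  jm <- which.min(abs(evt$values + 1i * omega))
  p <- evt$vectors[, jm]
  denom <- sum(Conj(p) * q)
  if (abs(denom) < 1e-12) stop("defective eigenpair: <p, q> ~ 0")
  p <- p / Conj(denom)
  g20 <- sum(Conj(p) * Bfun(q, q))
  g11 <- sum(Conj(p) * Bfun(q, Conj(q)))
  g21 <- sum(Conj(p) * Cfun(q, q, Conj(q)))
  if (method == "center_manifold") {
    n <- nrow(A)
    h11 <- -solve(A, Bfun(q, Conj(q)))
    h20 <- solve(2i * omega * diag(n) - A, Bfun(q, q))
    g21 <- g21 + 2 * sum(Conj(p) * Bfun(q, h11)) +
      sum(Conj(p) * Bfun(Conj(q), h20))
  }
  l1 <- Re(1i * g20 * g11 + omega * g21) / (2 * omega^2)
  list(omega = omega, q = q, p = p, g20 = g20, g11 = g11, g21 = g21,
       l1 = l1,
       direction = if (l1 < 0) "supercritical" else "subcritical")
}

#' Normal-form coefficients at a located Hopf point
#'
#' Completes a [locate_hopf()] result with the complex normal-form
#' coefficients and the first Lyapunov coefficient, using the exact
#' (analytic) second- and third-order derivative tensors of the somatic
#' right-hand side.  Both the plain projection combination
#' (`l1_projection`, the published formula for this model) and the
#' center-manifold-corrected value (`l1_center_manifold`) are stored;
#' `method` selects which one fills `l1` and decides `direction`.
#'
#' @param hopf a [locate_hopf()] result.
#' @param params the same [pbc_params()] object used to locate it.
#' @param method see [hopf_normal_form()]; default `"projection"`.
#' @return The completed `pbc_hopf` object.
#' @export
normal_form_coeffs <- function(hopf, params,
                               method = c("projection", "center_manifold")) {
  method <- match.arg(method)
  tn <- somatic_tensors(params, hopf$eq3, hopf$Ca_fixed)
  Bfun <- function(x, y)
    vapply(1:3, function(i) sum(tn$H[i, , ] * outer(x, y)), complex(1))
  Cfun <- function(x, y, z) {
    vapply(1:3, function(i) {
      acc <- 0
      for (j in 1:3) for (k in 1:3) for (l in 1:3)
        acc <- acc + tn$T[i, j, k, l] * x[j] * y[k] * z[l]
      acc
    }, complex(1))
  }
  pr <- hopf_normal_form(hopf$A, Bfun, Cfun, method = "projection")
  cm <- hopf_normal_form(hopf$A, Bfun, Cfun, method = "center_manifold")
  sel <- if (method == "projection") pr else cm
  hopf$g20 <- sel$g20
  hopf$g11 <- sel$g11
  hopf$g21 <- sel$g21
  hopf$l1_projection <- pr$l1
  hopf$l1_center_manifold <- cm$l1
  hopf$l1 <- sel$l1
  hopf$direction <- sel$direction
  hopf$method <- method
  hopf
}

#' Maximal Lyapunov exponent by the Benettin two-trajectory method
#'
#' Integrates a reference trajectory and a perturbed twin, renormalizing
#' their separation to `d0` every `renorm_interval` ms; the estimate is
#' the mean logarithmic expansion rate over the post-transient
#' renormalizations.  For delay-coupled runs the perturbed trajectory
#' carries its own history buffer, the separation norm spans the current
#' state plus the voltage history over the delay window, and
#' renormalization rescales state and history together.
#'
#' @param params a [pbc_params()] object.
#' @param I_exc single-neuron stimulus current (give either this or
#'   `net`).
#' @param net a [network_config()] for the coupled pair.
#' @param y0 initial state; defaults to [default_state()] /
#'   [default_pair_state()].
#' @param d0 perturbation and renormalization distance (mV).
#' @param renorm_interval renormalization interval (ms).
#' @param duration total run length (ms).
#' @param discard fraction of renormalizations discarded as transient.
#' @param dt_integrate integration step (ms).
#' @return An object of class `pbc_lyapunov`: `lambda_max` (1/ms),
#'   `convergence_series` (running estimate), `renorm_interval`,
#'   `tail_variation` (relative spread of the last quarter of the series).
#' @export
max_lyapunov <- function(params, I_exc = NULL, net = NULL, y0 = NULL,
                         d0 = 1e-6, renorm_interval = 50, duration = 4e5,
                         discard = 0.25, dt_integrate = 0.02) {
  stopifnot(inherits(params, "pbc_params"))
  if (is.null(I_exc) == is.null(net))
    stop("give exactly one of I_exc (single neuron) or net (coupled pair)")
  if (duration <= 2 * renorm_interval)
    stop("duration must be much larger than renorm_interval")
  res <- if (!is.null(I_exc)) {
    if (is.null(y0)) y0 <- default_state(params)
    cpp_benettin_single(unclass(params), I_exc, as.numeric(y0), d0,
                        renorm_interval, duration, discard, dt_integrate)
  } else {
    if (is.null(y0)) y0 <- default_pair_state(params)
    cpp_benettin_pair(unclass(params), unclass(net), as.numeric(y0), d0,
                      renorm_interval, duration, discard, dt_integrate)
  }
  ser <- res$convergence_series
  tail_part <- ser[seq.int(max(1, floor(0.75 * length(ser))), length(ser))]
  res$tail_variation <- if (max(abs(tail_part)) > 0)
    diff(range(tail_part)) / max(abs(tail_part)) else 0
  structure(res, class = "pbc_lyapunov")
}

#' @export
print.pbc_lyapunov <- function(x, ...) {
  cat(sprintf("<pbc_lyapunov> lambda_max = %.6g /ms (%d renormalizations, tail variation %.2g)\n",
              x$lambda_max, length(x$convergence_series), x$tail_variation))
  invisible(x)
}

#' Export a Hopf analysis as JSON
#'
#' @param hopf a completed [normal_form_coeffs()] result.
#' @param path file path.
#' @export
write_hopf_json <- function(hopf, path) {
  cplx <- function(z) if (is.null(z)) NULL else list(re = Re(z), im = Im(z))
  out <- list(
    I_exc_star = hopf$I_exc_star,
    equilibrium = as.list(hopf$eq3),
    jacobian = hopf$A,
    omega = hopf$omega,
    lambda_real = hopf$lambda_real,
    q = lapply(as.list(hopf$q), cplx),
    p = lapply(as.list(hopf$p), cplx),
    g20 = cplx(hopf$g20), g11 = cplx(hopf$g11), g21 = cplx(hopf$g21),
    l1 = hopf$l1, l1_projection = hopf$l1_projection,
    l1_center_manifold = hopf$l1_center_manifold,
    direction = hopf$direction
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
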