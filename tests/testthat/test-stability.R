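test_that("equilibria satisfy the somatic fixed-point conditions to 1e-10", {
  pc <- cal_params()
  eqs <- find_equilibrium(pc, 8.073)
  expect_equal(nrow(eqs), 3)  # cubic equilibrium branch: three coexisting roots
  for (i in seq_len(nrow(eqs))) {
    d <- rhs_single(c(eqs[i, ], pc$Ca_c, pc$l_c), 8.073, pc)[1:3]
    expect_lt(sqrt(sum(d^2)), 1e-10)
    expect_equal(unname(eqs[i, "n"]),
                 unname(gate_inf(eqs[i, "V"], pc$V_n, pc$s_n)))
    expect_equal(unname(eqs[i, "h"]),
                 unname(gate_inf(eqs[i, "V"], pc$V_h, pc$s_h)))
  }
  # lower branch V decreases monotonically with the stimulus current
  Vlow <- vapply(seq(7, 12, by = 0.5),
                 function(I) find_equilibrium(pc, I)[1, "V"], numeric(1))
  expect_true(all(diff(Vlow) < 0))
  expect_error(find_equilibrium(pc, 8, V_range = c(10, 20)), "no equilibrium")
})

test_that("analytic Jacobian has the structural zeros and matches finite differences", {
  p <- cal_params()
  st <- c(V = -50, n = 0.01, h = 0.6)  # not an equilibrium
  J <- jacobian_somatic(p, st)
  expect_identical(J[2, 3], 0)
  expect_identical(J[3, 2], 0)
  fd <- matrix(0, 3, 3)
  hstep <- 1e-5
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- hstep
    fd[, j] <- (rhs_single(c(st + e, 0.1, 0.9), 8, p)[1:3] -
                  rhs_single(c(st - e, 0.1, 0.9), 8, p)[1:3]) / (2 * hstep)
  }
  expect_equal(J, fd, tolerance = 1e-6)
})

test_that("the calibrated Jacobian at the reported Hopf state reproduces printed entries", {
  pc <- cal_params()
  V <- -51.8239
  eq <- c(V = V, n = gate_inf(V, pc$V_n, pc$s_n), h = gate_inf(V, pc$V_h, pc$s_h))
  J <- jacobian_somatic(pc, eq)
  expect_equal(J[2, 1], 0.000718508, tolerance = 1e-4)
  expect_equal(J[2, 2], -0.869859, tolerance = 1e-4)
  expect_equal(J[1, 3], 1.18619, tolerance = 1e-4)
  expect_equal(J[3, 1], -4.65547e-6, tolerance = 1e-4)
  expect_equal(J[3, 3], -0.000107, tolerance = 1e-2)
})

test_that("locate_hopf finds the lower-branch Hopf with a pure imaginary pair", {
  pc <- cal_params()
  h <- locate_hopf(pc, c(7, 9))
  ev <- eigen(h$A, only.values = TRUE)$values
  cp <- ev[Im(ev) != 0]
  expect_lt(max(abs(Re(cp))), 1e-8)
  expect_lt(h$lambda_real, 0)
  # eigenvector residuals and normalization
  expect_lt(max(Mod(h$A %*% h$q - 1i * h$omega * h$q)), 1e-10)
  expect_lt(max(Mod(t(h$A) %*% h$p + 1i * h$omega * h$p)), 1e-8)
  expect_equal(sum(Conj(h$p) * h$q), 1 + 0i, tolerance = 1e-10)
  expect_equal(h$q[1], 1 + 0i)
  # bisection tolerance convergence
  h2 <- locate_hopf(pc, c(7, 9), tol = 1e-8)
  expect_lt(abs(h2$I_exc_star - h$I_exc_star), 1e-5)
  expect_error(locate_hopf(pc, c(9, 10)), "no sign change")
})

test_that("normal-form engine recovers criticality of closed-form oracles", {
  om <- 1
  Bzero <- function(x, y) c(0, 0)
  for (s in c(-1, 1)) {
    # planar normal form: dz/dt = i om z + s z |z|^2
    A <- matrix(c(0, om, -om, 0), 2, 2)
    Cf <- function(x, y, z) {
      s * c(6 * x[1] * y[1] * z[1] +
              2 * (x[1] * y[2] * z[2] + x[2] * y[1] * z[2] + x[2] * y[2] * z[1]),
            6 * x[2] * y[2] * z[2] +
              2 * (x[2] * y[1] * z[1] + x[1] * y[2] * z[1] + x[1] * y[1] * z[2]))
    }
    nf <- hopf_normal_form(A, Bzero, Cf)
    expect_equal(sign(nf$l1), s)
    expect_equal(nf$direction,
                 if (s < 0) "supercritical" else "subcritical")
    nf2 <- hopf_normal_form(A, Bzero, Cf, method = "center_manifold")
    expect_equal(nf2$l1, nf$l1)  # no quadratic terms: corrections vanish
  }
  # 3-D system with a slaved stable mode feeding back through quadratics:
  # dx = -om y + a x w, dy = om x, dw = -w + x^2 + y^2; on the center
  # manifold w ~ x^2 + y^2, so criticality follows sign(a)
  for (a in c(-1, 1)) {
    A3 <- matrix(c(0, om, 0, -om, 0, 0, 0, 0, -1), 3, 3)
    B3 <- function(x, y) c(a * (x[1] * y[3] + x[3] * y[1]), 0,
                           2 * x[1] * y[1] + 2 * x[2] * y[2])
    C3 <- function(x, y, z) c(0, 0, 0)
    nf <- hopf_normal_form(A3, B3, C3, method = "center_manifold")
    expect_equal(sign(nf$l1), a)
  }
})

test_that("somatic normal-form tensors agree with finite differences through l1", {
  pc <- cal_params()
  h <- normal_form_coeffs(locate_hopf(pc, c(7, 9)), pc)
  expect_equal(h$direction, if (h$l1 < 0) "supercritical" else "subcritical")
  # independent route: finite-difference multilinear forms
  I_star <- h$I_exc_star
  rhs3 <- function(s) rhs_single(c(s, pc$Ca_c, pc$l_c), I_star, pc)[1:3]
  x0 <- h$eq3
  Bfd <- function(x, y) {
    dir2h <- function(u, v, hs) {
      (rhs3(x0 + hs * u + hs * v) - rhs3(x0 + hs * u - hs * v) -
         rhs3(x0 - hs * u + hs * v) + rhs3(x0 - hs * u - hs * v)) / (4 * hs^2)
    }
    # Richardson-extrapolated central differences (the quartic n^4 term
    # otherwise contaminates the plain stencil at O(h^2))
    dir2 <- function(u, v) (4 * dir2h(u, v, 5e-3) - dir2h(u, v, 1e-2)) / 3
    # complex bilinearity from real evaluations
    xr <- Re(x); xi <- Im(x); yr <- Re(y); yi <- Im(y)
    dir2(xr, yr) - dir2(xi, yi) + 1i * (dir2(xr, yi) + dir2(xi, yr))
  }
  tn <- pbcsync:::somatic_tensors(pc, h$eq3)
  Ban <- function(x, y)
    vapply(1:3, function(i) sum(tn$H[i, , ] * outer(x, y)), complex(1))
  set.seed(5)
  for (k in 1:3) {
    x <- complex(real = rnorm(3), imaginary = rnorm(3))
    y <- complex(real = rnorm(3), imaginary = rnorm(3))
    expect_equal(Bfd(x, y), Ban(x, y), tolerance = 1e-4)
  }
  # l1 is invariant under the phase rescaling q -> c q, p -> p / Conj(c)
  # with |c| = 1 (a general modulus rescales l1 by |c|^2; the sign alone
  # is modulus-invariant)
  cfac <- exp(0.7i)
  q2 <- cfac * h$q
  p2 <- h$p / Conj(cfac)
  Cfun <- function(x, y, z)
    vapply(1:3, function(i) {
      acc <- 0
      for (j in 1:3) for (k in 1:3) for (l in 1:3)
        acc <- acc + tn$T[i, j, k, l] * x[j] * y[k] * z[l]
      acc
    }, complex(1))
  g20 <- sum(Conj(p2) * Ban(q2, q2))
  g11 <- sum(Conj(p2) * Ban(q2, Conj(q2)))
  g21 <- sum(Conj(p2) * Cfun(q2, q2, Conj(q2)))
  l1b <- Re(1i * g20 * g11 + h$omega * g21) / (2 * h$omega^2)
  expect_equal(l1b, h$l1_projection, tolerance = 1e-6)
})

test_that("Benettin exponent is negative / zero / positive on stable, neutral and chaotic references", {
  p <- std_params()
  lam_q <- max_lyapunov(p, I_exc = 12, duration = 1e5)
  expect_lt(lam_q$lambda_max, 0)
  # pure calcium rotation (all conductances off): neutral
  pz <- pbc_params(g_Na = 0, g_K = 0, g_L = 0, g_NaP = 0, g_CAN = 0)
  lam_n <- max_lyapunov(pz, I_exc = 0, y0 = c(-50, 0, 0.5, 0.2, 0.9),
                        duration = 2e4)
  expect_lt(abs(lam_n$lambda_max), 1e-6)
  # delay-coupled positive coupling: chaos
  net <- network_config(g_c = 0.4, tau1 = 10, tau2 = 10)
  lam_c <- max_lyapunov(p, net = net, duration = 1.5e5)
  expect_gt(lam_c$lambda_max, 1e-4)
  expect_error(max_lyapunov(p, I_exc = 8, net = net), "exactly one")
  expect_error(max_lyapunov(p, I_exc = 8, duration = 10), "renorm_interval")
})

test_that("the chaotic exponent is robust to halving the perturbation scale", {
  p <- std_params()
  net <- network_config(g_c = 0.4, tau1 = 10, tau2 = 10)
  a <- max_lyapunov(p, net = net, duration = 2e5)
  b <- max_lyapunov(p, net = net, duration = 2e5, d0 = 5e-7,
                    renorm_interval = 25)
  expect_lt(abs(a$lambda_max - b$lambda_max) / abs(a$lambda_max), 0.2)
  expect_gt(b$lambda_max, 0)
})

test_that("Hopf JSON export round-trips the headline quantities", {
  pc <- cal_params()
  h <- normal_form_coeffs(locate_hopf(pc, c(7, 9)), pc)
  f <- tempfile(fileext = ".json")
  write_hopf_json(h, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$omega, h$omega, tolerance = 1e-12)
  expect_equal(j$direction, h$direction)
})
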