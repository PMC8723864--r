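test_that("gate_inf is the Boltzmann sigmoid with correct midpoint, limits and inversion", {
  expect_equal(gate_inf(-34, -34, -5), 0.5)
  expect_equal(gate_inf(1e4, -34, -5), 1)
  expect_equal(gate_inf(-1e4, -34, -5), 0)
  # analytic inversion: x_inf = 0.75 at V = V_half - slope*log(3) for slope < 0
  expect_equal(gate_inf(-34 + 5 * log(3), -34, -5), 0.75)
  # monotone increasing for negative slope
  V <- seq(-80, 20, by = 1)
  expect_true(all(diff(gate_inf(V, -34, -5)) > 0))
  expect_true(all(diff(gate_inf(V, -48, 5)) < 0))
  expect_error(gate_inf(0, 0, 0), "nonzero")
})

test_that("gate_tau peaks at V_half, is even, and halves at the analytic offset", {
  expect_equal(gate_tau(-29, 10, -29, -4), 10)
  x <- 7.3
  expect_equal(gate_tau(-29 + x, 10, -29, -4), gate_tau(-29 - x, 10, -29, -4))
  off <- 2 * (-4) * acosh(2)
  expect_equal(gate_tau(-29 + off, 10, -29, -4), 5)
  expect_true(all(gate_tau(seq(-100, 50, 5), 10, -29, -4) <= 10))
  expect_error(gate_tau(0, -1, -29, -4), "tau_bar")
})

test_that("ionic currents vanish at reversal potentials and with closed gates", {
  p <- std_params()
  cur <- ionic_currents(c(V = p$V_L, n = 0.2, h = 0.5), 0.1, p)
  expect_equal(cur$I_L, 0)
  cur <- ionic_currents(c(V = -20, n = 0, h = 0.5), 0.1, p)
  expect_equal(cur$I_K, 0)
  m <- gate_inf(-20, p$V_m, p$s_m)
  expect_equal(cur$I_Na, p$g_Na * m^3 * (-20 - p$V_Na))
  expect_error(ionic_currents(c(V = -50, n = 0, h = 0.5), -0.1, p),
               "invalid state")
})

test_that("the calibrated somatic current balance closes at the reported Hopf state", {
  pc <- cal_params()
  V <- -51.8239
  st <- c(V = V, n = gate_inf(V, pc$V_n, pc$s_n), h = gate_inf(V, pc$V_h, pc$s_h))
  cur <- ionic_currents(st, 0.1, pc)
  total <- sum(unlist(cur)) + 8.073
  expect_lt(abs(total), 1e-9)
})

test_that("rhs_single: calcium equilibrium at ellipse center, steady-state gates, Euler consistency", {
  p <- std_params()
  d <- rhs_single(c(-50, 0.1, 0.5, p$Ca_c, p$l_c), 8.5, p)
  expect_equal(d[4], 0)
  expect_equal(d[5], 0)
  V <- -42
  d <- rhs_single(c(V, gate_inf(V, p$V_n, p$s_n), 0.5, 0.15, 0.8), 8.5, p)
  expect_equal(d[2], 0)
  # one tiny explicit-Euler step agrees with the derivative to O(dt)
  y0 <- c(-45, 0.2, 0.6, 0.12, 0.85)
  dt <- 1e-5
  tr <- integrate_ode(function(t, y) rhs_single(y, 8.5, p), y0, dt, dt)
  fd <- (tr$states[2, ] - y0) / dt
  expect_equal(unname(fd), rhs_single(y0, 8.5, p), tolerance = 1e-4)
})

test_that("rhs_coupled degenerates correctly and obeys exchange symmetry", {
  p <- std_params()
  s <- c(-45, 0.2, 0.6)
  net0 <- network_config(g_c = -0.4, I_exc1 = 8.5, I_exc2 = 8.5)
  st8 <- c(s, s, 0.1, 0.9)
  d8 <- rhs_coupled(st8, c(s[1], s[1]), net0, p)
  d5 <- rhs_single(c(s, 0.1, 0.9), 8.5, p)
  expect_equal(d8[1:3], d5[1:3])   # coupling vanishes on the sync manifold
  expect_equal(d8[4:6], d5[1:3])
  # g_c = 0: two independent neurons
  s2 <- c(-55, 0.1, 0.7)
  netz <- network_config(g_c = 0, I_exc1 = 8.5, I_exc2 = 9.5)
  dz <- rhs_coupled(c(s, s2, 0.1, 0.9), c(s2[1], s[1]), netz, p)
  expect_equal(dz[1:3], rhs_single(c(s, 0.1, 0.9), 8.5, p)[1:3])
  expect_equal(dz[4:6], rhs_single(c(s2, 0.1, 0.9), 9.5, p)[1:3])
  # swapping neuron labels with swapped (tau, I_exc) permutes the derivative
  net <- network_config(g_c = -0.3, tau1 = 3, tau2 = 7,
                        I_exc1 = 8.5, I_exc2 = 9.0)
  netS <- network_config(g_c = -0.3, tau1 = 7, tau2 = 3,
                         I_exc1 = 9.0, I_exc2 = 8.5)
  lag <- c(-48, -52)
  d <- rhs_coupled(c(s, s2, 0.1, 0.9), lag, net, p)
  dS <- rhs_coupled(c(s2, s, 0.1, 0.9), rev(lag), netS, p)
  expect_equal(dS, d[c(4:6, 1:3, 7:8)])
})

test_that("parameter validation rejects invalid sets and YAML round-trips", {
  expect_error(pbc_params(g_Na = -1), "conductance")
  expect_error(pbc_params(l_c = 1.2), "l_c")
  expect_error(pbc_params(s_n = 0), "slope")
  expect_error(pbc_params(nonsense = 1), "unknown parameter")
  p <- pbc_params(g_NaP = 2.5, can_scale = 0.7)
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(p, f)
  expect_equal(read_params_yaml(f), p)
  shipped <- read_params_yaml(system.file("extdata", "table1.yaml",
                                          package = "pbcsync"))
  expect_s3_class(shipped, "pbc_params")
  expect_equal(shipped, pbc_params())
})

test_that("the calcium ellipse invariant has exactly zero time derivative", {
  p <- std_params()
  set.seed(42)
  for (i in 1:10) {
    Ca <- runif(1, 0.02, 0.3)
    l <- runif(1, 0.5, 1.1)
    d <- rhs_single(c(-50, 0.1, 0.5, Ca, l), 8.5, p)
    dE <- 2 * (Ca - p$Ca_c) / p$d * d[4] + 2 * p$d * (l - p$l_c) * d[5]
    expect_equal(dE, 0)
  }
})

test_that("gate variables stay inside [0, 1] along trajectories", {
  tr <- period3_run()
  expect_true(all(trace_var(tr, "n") >= 0 & trace_var(tr, "n") <= 1))
  expect_true(all(trace_var(tr, "h") >= 0 & trace_var(tr, "h") <= 1))
})
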