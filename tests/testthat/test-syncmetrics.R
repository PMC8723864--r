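test_that("correlation coefficient matches its defining sum and base-R oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  # brute-force evaluation of the defining formula
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlation_coefficient(x, y), num / den)
  expect_equal(correlation_coefficient(x, y), cor(x, y))
  set.seed(7)
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(correlation_coefficient(a, b), cor(a, b))
  expect_equal(correlation_coefficient(a, a), 1)
  expect_equal(correlation_coefficient(a, 3 - a), -1)
  # affine invariance and sign flip
  expect_equal(correlation_coefficient(2 * a + 5, b),
               correlation_coefficient(a, b))
  expect_equal(correlation_coefficient(-2 * a, b),
               -correlation_coefficient(a, b))
  expect_error(correlation_coefficient(a, rep(1, 500)), "zero variance")
  expect_error(correlation_coefficient(a, b[1:10]), "equal length")
})

test_that("max_sync_difference is the elementwise sup metric", {
  set.seed(8)
  x <- rnorm(200); y <- rnorm(200)
  brute <- 0
  for (i in seq_along(x)) brute <- max(brute, abs(x[i] - y[i]))
  expect_equal(max_sync_difference(x, y), brute)
  expect_equal(max_sync_difference(x, y), max_sync_difference(y, x))
  expect_equal(max_sync_difference(x, x), 0)
  expect_equal(max_sync_difference(x, x + 3.5), 3.5)
})

test_that("Poincare phase is piecewise linear with 2*pi steps at events", {
  set.seed(9)
  ev <- cumsum(runif(20, 0.5, 2))
  ph <- poincare_phase(ev, ev)
  expect_equal(ph, 2 * pi * (seq_along(ev) - 1))
  # midpoint of an interval sits at 2*pi*n + pi
  mid <- (ev[3] + ev[4]) / 2
  expect_equal(poincare_phase(ev, mid), 2 * pi * 2 + pi)
  # uniform events: exactly linear phase
  evu <- seq(0, 100, by = 10)
  t <- seq(0, 100, by = 0.5)
  expect_equal(poincare_phase(evu, t), 2 * pi * t / 10)
  # continuity and monotonicity on a dense grid
  tq <- seq(ev[1], ev[20], length.out = 5000)
  phq <- poincare_phase(ev, tq)
  expect_true(all(diff(phq) >= 0))
  expect_lt(max(abs(diff(phq))), 0.1)
  expect_error(poincare_phase(ev, ev[20] + 1), "outside")
})

test_that("phase synchronization criterion separates locked from drifting trains", {
  ev <- seq(0, 200, by = 10)
  r <- phase_sync_test(ev, ev)
  expect_equal(r$dphi_max, 0)
  expect_true(r$is_phase_locked)
  # 2:1 frequency ratio: unbounded phase growth, not locked
  r2 <- phase_sync_test(seq(0, 200, by = 5), ev)
  expect_false(r2$is_phase_locked)
  expect_gt(r2$dphi_max, 2 * pi)
  # constant offset below half period: locked at 2*pi*offset/period
  off <- 3
  r3 <- phase_sync_test(ev, ev + off, n_grid = 5000)
  expect_true(r3$is_phase_locked)
  expect_equal(r3$dphi_max, 2 * pi * off / 10, tolerance = 1e-6)
})

test_that("similarity function: zero on identity and pure lags, sqrt(2) for independent noise", {
  pg <- gen_pair(surrogate_spec("identical"), duration = 5e3)
  x <- trace_var(pg$trace1, "V"); y <- trace_var(pg$trace2, "V")
  expect_equal(similarity(x, y, 0), 0)
  pg <- gen_pair(surrogate_spec("lagged", lag = 35), duration = 2e4)
  x <- trace_var(pg$trace1, "V"); y <- trace_var(pg$trace2, "V")
  expect_lt(similarity(x, y, 35), 1e-10)
  expect_gt(similarity(x, y, 0), 0.5)
  # independent equal-power white noise: S^2 -> 2
  set.seed(11)
  a <- rnorm(4e4); b <- rnorm(4e4)
  expect_equal(similarity(a, b, 0)^2, 2, tolerance = 0.05)
  expect_error(similarity(rep(0, 10), rnorm(10), 0), "zero signal power")
  expect_error(similarity(a, b, 0.5), "multiple")
})

test_that("lag recovery finds generator lags, anti-phase at half period, robust to noise", {
  grid <- seq(-100, 100, by = 1)
  pg <- gen_pair(surrogate_spec("identical"), duration = 1e4)
  expect_equal(lag_recover(trace_var(pg$trace1, "V"),
                           trace_var(pg$trace2, "V"), grid), 0)
  pg <- gen_pair(surrogate_spec("lagged", lag = 35), duration = 2e4)
  expect_equal(lag_recover(trace_var(pg$trace1, "V"),
                           trace_var(pg$trace2, "V"), grid), 35)
  # anti-phase sinusoids: best lag at half the period
  t <- 0:4000
  x <- sin(2 * pi * t / 200)
  best <- lag_recover(x, -x, seq(-150, 150, by = 1))
  expect_equal(best, 100)
  # global minimum stays at the generator lag with noise up to 10% power
  carrier_sd <- sd(trace_var(gen_pair(surrogate_spec("lagged", lag = 35),
                                      duration = 5e3)$trace1, "V"))
  for (seed in 1:20) {
    spec <- surrogate_spec("lagged", lag = 35,
                           noise_sd = sqrt(0.1) * carrier_sd, seed = seed)
    pg <- gen_pair(spec, duration = 2e4)
    expect_equal(lag_recover(trace_var(pg$trace1, "V"),
                             trace_var(pg$trace2, "V"), grid), 35,
                 info = paste("seed", seed))
  }
})

test_that("classification thresholds place canonical cases in their classes", {
  expect_equal(classify_sync(R = 1, max_e = 0), "complete")
  expect_equal(classify_sync(R = 0.97, max_e = 5), "approximate")
  expect_equal(classify_sync(R = 0.5, max_e = 50, dphi_max = pi),
               "phase")
  expect_equal(classify_sync(R = 0.2, max_e = 50, dphi_max = 9,
                             S_min_nonzero = 0.01, best_lag = 35),
               "lag")
  expect_equal(classify_sync(R = 0.1, max_e = 50, dphi_max = 9,
                             S_min_nonzero = 1.4, best_lag = 17), "asynchronous")
  # anti-phase bursting: best alignment at half the burst period
  expect_equal(classify_sync(R = -0.5, max_e = 65, dphi_max = 3,
                             S_min_nonzero = 0.8, best_lag = 945,
                             burst_period = 1886, S0 = 1.7), "out_of_phase")
})

test_that("sync_report on surrogate pairs recovers the ground truth classes", {
  rep1 <- sync_report(pair_trace(gen_pair(surrogate_spec("identical"),
                                          duration = 6e3)))
  expect_equal(rep1$sync_class, "complete")
  expect_equal(rep1$R, 1)
  expect_equal(rep1$max_e, 0)
  expect_equal(rep1$S0, 0)
  rep2 <- sync_report(pair_trace(gen_pair(surrogate_spec("independent",
                                                         seed = 3),
                                          duration = 6e3)))
  expect_equal(rep2$sync_class, "asynchronous")
  expect_lt(abs(rep2$R), 0.1)
  f <- tempfile(fileext = ".json")
  write_sync_json(rep1, f)
  expect_equal(jsonlite::read_json(f)$sync_class, "complete")
})

test_that("coupled-pair runs land in their narrated synchronization classes", {
  p <- std_params()
  tr <- simulate_pair(p, network_config(g_c = -0.5), t_end = 6e4)
  r <- sync_report(tr, transient = 0.5)
  expect_equal(r$sync_class, "complete")
  expect_equal(r$R, 1, tolerance = 1e-6)
  tr <- simulate_pair(p, network_config(g_c = 0.4), t_end = 1e5)
  r <- sync_report(tr, transient = 0.5)
  expect_equal(r$sync_class, "out_of_phase")
  expect_lt(r$R, 0.5)
  expect_gt(r$max_e, 40)
})
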