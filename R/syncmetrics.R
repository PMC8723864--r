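#' Correlation coefficient of two membrane-potential series
#'
#' The centered Pearson correlation
#' `R = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`
#' computed directly from its defining sum.
#'
#' @param x,y equal-length numeric series (length >= 2), each with nonzero
#'   variance.
#' @return `R` in `[-1, 1]`.
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("undefined correlation: zero variance")
  sum(dx * dy) / sqrt(vx * vy)
}

#' Maximum synchronization difference
#'
#' `max(e) = max_k |x_k - y_k|`, the infinity norm of the sampled
#' voltage difference.
#'
#' @param x,y equal-length numeric series.
#' @return Nonnegative scalar (mV for voltage inputs).
#' @export
max_sync_difference <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  max(abs(x - y))
}

#' Poincare-section phase
#'
#' Piecewise-linear phase built from section-crossing times:
#' `phi(t) = 2 pi (t - t_n) / (t_{n+1} - t_n) + 2 pi n` for
#' `t_n <= t <= t_{n+1}`, so `phi(t_n) = 2 pi n` and the phase grows by
#' `2 pi` per crossing.
#'
#' @param events strictly increasing crossing times (ms), length >= 2.
#' @param t query times inside `[events[1], events[length(events)]]`.
#' @return `phi(t)` (rad), continuous, piecewise linear, non-decreasing.
#' @export
poincare_phase <- function(events, t) {
  if (length(events) < 2 || is.unsorted(events, strictly = TRUE))
    stop("events must be >= 2 strictly increasing times")
  if (any(t < events[1] - 1e-9) || any(t > events[length(events)] + 1e-9))
    stop("phase query outside the event span")
  n <- findInterval(t, events, rightmost.closed = TRUE)
  n <- pmin(pmax(n, 1L), length(events) - 1L)
  2 * pi * (t - events[n]) / (events[n + 1] - events[n]) + 2 * pi * (n - 1)
}

#' Phase-synchronization test
#'
#' Two event trains are phase synchronized when their Poincare phase
#' difference stays bounded: `max_t |phi1(t) - phi2(t)| < bound`, with the
#' bound `2 pi` by convention.  Phases are compared on a uniform grid over
#' the overlap of the two event spans.
#'
#' @param events1,events2 crossing times of the two oscillators, or
#'   precomputed phase vectors when `t` is supplied.
#' @param bound phase bound (rad).
#' @param n_grid grid size over the common span.
#' @param t optional common query times; when given, `events1`/`events2`
#'   are interpreted as phase series already evaluated on `t`.
#' @return List with `dphi_max` (rad) and logical `is_phase_locked`.
#' @export
phase_sync_test <- function(events1, events2, bound = 2 * pi, n_grid = 2000,
                            t = NULL) {
  if (is.null(t)) {
    lo <- max(events1[1], events2[1])
    hi <- min(events1[length(events1)], events2[length(events2)])
    if (hi <= lo) stop("event trains do not overlap")
    t <- seq(lo, hi, length.out = n_grid)
    dphi <- abs(poincare_phase(events1, t) - poincare_phase(events2, t))
  } else {
    dphi <- abs(events1 - events2)
  }
  dmax <- max(dphi)
  list(dphi_max = dmax, is_phase_locked = dmax < bound)
}

#' Similarity function between two signals
#'
#' The lag-synchronization diagnostic
#' `S^2(tau) = mean[(x(t) - y(t + tau))^2] / sqrt(mean[x^2] mean[y^2])`,
#' evaluated on the overlap window of the shifted series.  Signals are
#' mean-subtracted by default (`center = TRUE`); the returned value is
#' `S = sqrt(S^2)`, which is 0 exactly at `tau = L` when `y` is `x`
#' delayed by `L` (`y(t) = x(t - L)`), so a positive recovered lag means
#' the second signal trails the first.
#'
#' @param x,y equal-length series sampled at `dt_sample`.
#' @param lag time shift (ms); must be a multiple of `dt_sample`.
#' @param dt_sample sampling interval (ms).
#' @param center subtract each signal's mean first.
#' @return `S(tau) >= 0`.
#' @export
similarity <- function(x, y, lag = 0, dt_sample = 1, center = TRUE) {
  if (length(x) != length(y)) stop("series must have equal length")
  k <- lag / dt_sample
  if (abs(k - round(k)) > 1e-8) stop("lag must be a multiple of dt_sample")
  k <- as.integer(round(k))
  n <- length(x)
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  if (k >= 0) {
    xs <- x[1:(n - k)]
    ys <- y[(1 + k):n]
  } else {
    xs <- x[(1 - k):n]
    ys <- y[1:(n + k)]
  }
  if (length(xs) < 2) stop("overlap window shorter than 2 samples")
  px <- mean(x^2)
  py <- mean(y^2)
  if (px == 0 || py == 0) stop("zero signal power")
  sqrt(mean((xs - ys)^2) / sqrt(px * py))
}

#' Similarity over a grid of lags
#'
#' @inheritParams similarity
#' @param lag_grid lags (ms), multiples of `dt_sample`.
#' @return data.frame with `lag` and `S`.
#' @export
similarity_curve <- function(x, y, lag_grid, dt_sample = 1, center = TRUE) {
  data.frame(
    lag = lag_grid,
    S = vapply(lag_grid, function(L) similarity(x, y, L, dt_sample, center),
               numeric(1))
  )
}

#' Recover the synchronization lag
#'
#' Argmin of the similarity function over a lag grid; ties are broken
#' toward the smallest `|lag|`, and toward the positive lag when both
#' signs attain the minimum (anti-phase signals).
#'
#' @inheritParams similarity_curve
#' @return The best lag (ms); positive when the second signal trails the
#'   first.
#' @export
lag_recover <- function(x, y, lag_grid, dt_sample = 1) {
  sc <- similarity_curve(x, y, lag_grid, dt_sample)
  cand <- sc$lag[sc$S <= min(sc$S) + 1e-12]
  cand <- cand[order(abs(cand), -sign(cand))]
  cand[1]
}

#' Classify the synchronization state of a pair
#'
#' Categorical classification from the metric set, with the thresholds
#' used throughout the package: `complete` when `R > 0.999` and
#' `max_e < 1` mV; `approximate` when `R > 0.95` but not complete; `phase`
#' when the Poincare phase difference stays below `2 pi`; `lag` when the
#' similarity minimum over nonzero lags is below 0.05; `asynchronous`
#' otherwise.  `out_of_phase` replaces a phase/lag/asynchronous label when
#' the best alignment lag sits at half the burst period (anti-phase
#' bursting).
#'
#' @param R correlation coefficient.
#' @param max_e maximum synchronization difference (mV).
#' @param dphi_max maximum phase difference (rad; `NA` when phases are
#'   unavailable).
#' @param S_min_nonzero minimum similarity over nonzero lags (`NA` to
#'   skip).
#' @param best_lag lag at the similarity minimum (ms).
#' @param burst_period burst cycle length (ms; `NA` to skip the
#'   out-of-phase check).
#' @param S0 similarity at zero lag, used only to verify that the
#'   half-period alignment is genuinely better than no shift.
#' @return One of `"complete"`, `"approximate"`, `"phase"`, `"lag"`,
#'   `"out_of_phase"`, `"asynchronous"`.
#' @export
classify_sync <- function(R, max_e, dphi_max = NA, S_min_nonzero = NA,
                          best_lag = NA, burst_period = NA, S0 = NA) {
  cls <- if (R > 0.999 && max_e < 1) "complete"
  else if (R > 0.95) "approximate"
  else if (!is.na(dphi_max) && dphi_max < 2 * pi) "phase"
  else if (!is.na(S_min_nonzero) && S_min_nonzero < 0.05 &&
           !is.na(best_lag) && best_lag != 0) "lag"
  else "asynchronous"
  if (cls %in% c("phase", "lag", "asynchronous") &&
      !is.na(burst_period) && !is.na(best_lag) && best_lag != 0 &&
      (is.na(S0) || is.na(S_min_nonzero) || S_min_nonzero < 0.9 * S0)) {
    half <- burst_period / 2
    if (abs(abs(best_lag) - half) < 0.15 * half) cls <- "out_of_phase"
  }
  cls
}

#' Full synchronization report for a pair trace
#'
#' Computes every pairwise measure on the post-transient window of a
#' two-neuron trace: correlation coefficient, maximum synchronization
#' difference, similarity curve and best lag, Poincare phase difference
#' (section: burst onsets, i.e. the first spike of each burst), and the
#' categorical synchronization class.
#'
#' @param trace a [simulate_pair()] trace (columns `V1`, `V2`), already
#'   transient-free or to be cut with `transient`.
#' @param transient fraction discarded from the start (0 if the trace is
#'   already post-transient).
#' @param lag_grid lags (ms) for the similarity curve; default covers
#'   about one burst period both ways (estimated from neuron 1's bursts)
#'   in 64 steps, snapped to multiples of the sampling interval.
#' @param phase_bound bound for the phase-synchronization test (rad).
#' @param ... passed to [detect_spikes()].
#' @return An object of class `pbc_sync_report`: `R`, `max_e`, `S_tau`
#'   (data.frame), `S0`, `best_lag`, `dphi_max`, `N`, `sync_class`, and the
#'   burst summaries of both neurons.
#' @export
sync_report <- function(trace, transient = 0, lag_grid = NULL,
                        phase_bound = 2 * pi, ...) {
  if (transient > 0) trace <- discard_transient(trace, transient)
  V1 <- trace_var(trace, "V1")
  V2 <- trace_var(trace, "V2")
  dt <- trace$dt_sample
  R <- correlation_coefficient(V1, V2)
  max_e <- max_sync_difference(V1, V2)
  s1 <- detect_spikes(trace, var = "V1", ...)
  s2 <- detect_spikes(trace, var = "V2", ...)
  b1 <- if (length(s1$spike_times) >= 1) detect_bursts(s1) else NULL
  b2 <- if (length(s2$spike_times) >= 1) detect_bursts(s2) else NULL
  period <- if (!is.null(b1)) b1$period else NA_real_
  if (is.null(lag_grid)) {
    span <- if (is.finite(period)) 0.6 * period else 0.1 * diff(range(trace_times(trace)))
    step <- max(dt, round(span / 32 / dt) * dt)
    lag_grid <- step * (-32:32)   # symmetric, always contains lag 0
  }
  S_tau <- similarity_curve(V1, V2, lag_grid, dt)
  S0 <- similarity(V1, V2, 0, dt)
  nz <- S_tau$lag != 0
  S_min_nz <- if (any(nz)) min(S_tau$S[nz]) else NA_real_
  best_lag <- lag_recover(V1, V2, lag_grid, dt)
  dphi_max <- NA_real_
  if (!is.null(b1) && !is.null(b2) &&
      length(b1$burst_onsets) >= 2 && length(b2$burst_onsets) >= 2) {
    ps <- tryCatch(phase_sync_test(b1$burst_onsets, b2$burst_onsets,
                                   bound = phase_bound),
                   error = function(e) NULL)
    if (!is.null(ps)) dphi_max <- ps$dphi_max
  }
  cls <- classify_sync(R, max_e, dphi_max, S_min_nz, best_lag, period,
                       S0 = S0)
  structure(list(R = R, max_e = max_e, S_tau = S_tau, S0 = S0,
                 best_lag = best_lag, dphi_max = dphi_max,
                 N = length(V1), sync_class = cls,
                 bursts1 = b1, bursts2 = b2),
            class = "pbc_sync_report")
}

#' @export
print.pbc_sync_report <- function(x, ...) {
  cat(sprintf(
    "<pbc_sync_report> %s\n  R = %.6g, max_e = %.6g mV, S(0) = %.4g, best lag = %g ms\n  dphi_max = %s rad, N = %d\n",
    x$sync_class, x$R, x$max_e, x$S0, x$best_lag,
    if (is.na(x$dphi_max)) "NA" else sprintf("%.4g", x$dphi_max), x$N))
  invisible(x)
}

#' Serialize a synchronization report to JSON
#'
#' @param report a [sync_report()] result.
#' @param path file path.
#' @export
write_sync_json <- function(report, path) {
  out <- list(R = report$R, max_e = report$max_e, S0 = report$S0,
              best_lag = report$best_lag, dphi_max = report$dphi_max,
              N = report$N, sync_class = report$sync_class,
              S_tau = report$S_tau)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
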