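# Surrogate voltage-trace pairs with known ground-truth synchronization
# structure: a deterministic bursty carrier (raised-cosine spikes on a
# baseline) plus controlled lag, phase shift, correlation or noise, so
# every metric in the package can be validated without running the neuron
# model.

#' Specify a surrogate trace pair
#'
#' @param kind one of `"identical"`, `"lagged"`, `"phase_shifted"`,
#'   `"noisy_correlated"`, `"independent"`, `"anti_phase"`.
#' @param burst_period burst cycle length (ms).
#' @param spikes_per_burst spikes in each burst.
#' @param intra_isi interval between spikes within a burst (ms).
#' @param spike_amp spike height above baseline (mV).
#' @param baseline resting level (mV).
#' @param lag time shift of trace 2 relative to trace 1 (ms; `lagged`
#'   kind).
#' @param phase phase shift in radians (`phase_shifted` kind); converted
#'   to a lag of `phase / (2 pi) * burst_period`.
#' @param target_R expected Pearson correlation (`noisy_correlated` kind),
#'   in `[0, 1]`.
#' @param noise_sd additive white-noise standard deviation (mV).
#' @param seed RNG seed making the pair deterministic.
#' @return An object of class `pbc_surrogate_spec`.
#' @export
surrogate_spec <- function(kind = c("identical", "lagged", "phase_shifted",
                                    "noisy_correlated", "independent",
                                    "anti_phase"),
                           burst_period = 600, spikes_per_burst = 3,
                           intra_isi = 10, spike_amp = 70, baseline = -60,
                           lag = 0, phase = 0, target_R = 0.8, noise_sd = 0,
                           seed = 1) {
  kind <- match.arg(kind)
  if (burst_period <= spikes_per_burst * intra_isi)
    stop("burst_period must exceed spikes_per_burst * intra_isi")
  if (target_R < 0 || target_R > 1) stop("target_R must be in [0, 1]")
  if (spikes_per_burst < 1) stop("spikes_per_burst must be >= 1")
  structure(list(kind = kind, burst_period = burst_period,
                 spikes_per_burst = spikes_per_burst, intra_isi = intra_isi,
                 spike_amp = spike_amp, baseline = baseline, lag = lag,
                 phase = phase, target_R = target_R, noise_sd = noise_sd,
                 seed = seed),
            class = "pbc_surrogate_spec")
}

# deterministic bursty carrier evaluated at arbitrary times: raised-cosine
# spike pulses (2 ms wide) at the burst's spike times, repeated every
# burst_period, first burst onset at t = pulse width
surrogate_carrier <- function(spec, t, width = 2) {
  ph <- (t - width) %% spec$burst_period
  v <- rep(spec$baseline, length(t))
  for (k in seq_len(spec$spikes_per_burst)) {
    tc <- (k - 1) * spec$intra_isi
    d <- abs(ph - tc)
    inpulse <- d < width / 2
    v[inpulse] <- v[inpulse] +
      spec$spike_amp * 0.5 * (1 + cos(2 * pi * (ph[inpulse] - tc) / width))
  }
  v
}

#' Generate one surrogate burst trace
#'
#' Baseline plus `spikes_per_burst` stereotyped raised-cosine spike pulses
#' per burst cycle; deterministic given the spec's seed (noise, when
#' requested, is Gaussian white at the sampling resolution).
#'
#' @param spec a [surrogate_spec()].
#' @param duration trace length (ms).
#' @param dt_sample sampling interval (ms).
#' @return A [new_trace()] with one column `V`.
#' @export
gen_burst_trace <- function(spec, duration = 1e4, dt_sample = 1) {
  t <- seq(0, duration, by = dt_sample)
  v <- surrogate_carrier(spec, t)
  if (spec$noise_sd > 0) {
    v <- v + with_surrogate_seed(spec$seed,
                                 rnorm(length(t), sd = spec$noise_sd))
  }
  new_trace(matrix(v, ncol = 1, dimnames = list(NULL, "V")), dt_sample,
            meta = list(spec = spec))
}

with_surrogate_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a surrogate trace pair with known ground truth
#'
#' * `identical`: the same trace twice (`R = 1`, `max_e = 0`, `S(0) = 0`).
#' * `lagged`: trace 2 is trace 1 delayed by `lag` ms (similarity zero at
#'   that lag; phase offset `2 pi lag / burst_period`).
#' * `phase_shifted`: as `lagged` with `lag = phase/(2 pi) * burst_period`.
#' * `anti_phase`: lag of half a burst period.
#' * `noisy_correlated`: `y = rho x + sqrt(1 - rho^2) e` with `e` white
#'   noise matched to the carrier's standard deviation, so the expected
#'   Pearson correlation is `target_R`.
#' * `independent`: two independent zero-mean white-noise traces
#'   (`E[R] = 0`).
#'
#' @param spec a [surrogate_spec()].
#' @param duration trace length (ms).
#' @param dt_sample sampling interval (ms).
#' @return List with `trace1`, `trace2` and `truth` (named list of the
#'   ground-truth quantities implied by the spec).
#' @export
gen_pair <- function(spec, duration = 1e4, dt_sample = 1) {
  t <- seq(0, duration, by = dt_sample)
  x <- surrogate_carrier(spec, t)
  truth <- list(kind = spec$kind, lag = 0, R = 1,
                spikes_per_burst = spec$spikes_per_burst,
                burst_period = spec$burst_period)
  lag <- switch(spec$kind,
    identical = 0,
    lagged = spec$lag,
    phase_shifted = spec$phase / (2 * pi) * spec$burst_period,
    anti_phase = spec$burst_period / 2,
    0)
  if (spec$kind %in% c("lagged", "phase_shifted", "anti_phase")) {
    y <- surrogate_carrier(spec, t - lag)
    truth$lag <- lag
    truth$phase_offset <- 2 * pi * lag / spec$burst_period
  } else if (spec$kind == "noisy_correlated") {
    rho <- spec$target_R
    xc <- x - mean(x)
    e <- with_surrogate_seed(spec$seed, rnorm(length(t), sd = sd(xc)))
    y <- mean(x) + rho * xc + sqrt(1 - rho^2) * e
    truth$R <- spec$target_R
  } else if (spec$kind == "independent") {
    amp <- if (spec$noise_sd > 0) spec$noise_sd else spec$spike_amp / 4
    xy <- with_surrogate_seed(spec$seed,
                              list(x = rnorm(length(t), sd = amp),
                                   y = rnorm(length(t), sd = amp)))
    x <- xy$x
    y <- xy$y
    truth$R <- 0
    truth$spikes_per_burst <- NA_integer_
  } else {
    y <- x
  }
  if (spec$noise_sd > 0 && spec$kind %in% c("lagged", "phase_shifted",
                                            "anti_phase", "identical")) {
    ns <- with_surrogate_seed(spec$seed + 1,
                              list(a = rnorm(length(t), sd = spec$noise_sd),
                                   b = rnorm(length(t), sd = spec$noise_sd)))
    x <- x + ns$a
    y <- y + ns$b
  }
  mk <- function(v) new_trace(matrix(v, ncol = 1, dimnames = list(NULL, "V")),
                              dt_sample, meta = list(spec = spec))
  list(trace1 = mk(x), trace2 = mk(y), truth = truth)
}
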