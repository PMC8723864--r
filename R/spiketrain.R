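#' Detect spikes by hysteresis threshold crossing
#'
#' A spike is recorded at each upward crossing of `threshold_up`; the
#' detector then re-arms only once the voltage has fallen below
#' `threshold_rearm`, so subthreshold wiggles between the two levels are
#' ignored.  Crossing times are linearly interpolated between the
#' bracketing samples.
#'
#' @param trace a [new_trace()] object, or a numeric voltage vector.
#' @param var voltage column used when `trace` is a `pbc_trace`
#'   (default `"V"`, or `"V1"`/`"V2"` for pair runs).
#' @param threshold_up detection threshold (mV).
#' @param threshold_rearm re-arm threshold (mV), strictly below
#'   `threshold_up`.
#' @param times sample times, required when `trace` is a bare vector.
#' @return An object of class `pbc_spiketrain`: list with `spike_times`
#'   (ms, strictly increasing; possibly empty = quiescence),
#'   `threshold_up`, `source`.
#' @export
detect_spikes <- function(trace, var = "V", threshold_up = -30,
                          threshold_rearm = -40, times = NULL) {
  if (threshold_rearm >= threshold_up)
    stop("threshold_rearm must be below threshold_up")
  if (inherits(trace, "pbc_trace")) {
    v <- trace_var(trace, var)
    t <- trace_times(trace)
  } else {
    v <- as.numeric(trace)
    t <- if (is.null(times)) seq_along(v) - 1 else times
  }
  if (length(v) == 0) stop("empty trace")
  st <- numeric(0)
  armed <- v[1] < threshold_up
  for (i in seq_along(v)[-1]) {
    if (armed && v[i - 1] < threshold_up && v[i] >= threshold_up) {
      frac <- (threshold_up - v[i - 1]) / (v[i] - v[i - 1])
      st <- c(st, t[i - 1] + frac * (t[i] - t[i - 1]))
      armed <- FALSE
    } else if (!armed && v[i] < threshold_rearm) {
      armed <- TRUE
    }
  }
  structure(list(spike_times = st, threshold_up = threshold_up,
                 source = var),
            class = "pbc_spiketrain")
}

#' @export
print.pbc_spiketrain <- function(x, ...) {
  cat(sprintf("<pbc_spiketrain> %d spikes (threshold %g mV)\n",
              length(x$spike_times), x$threshold_up))
  invisible(x)
}

#' Interspike-interval sequence
#'
#' @param spiketrain a [detect_spikes()] result.
#' @return Numeric vector of successive differences (ms); empty when fewer
#'   than 2 spikes.
#' @export
isi_sequence <- function(spiketrain) {
  st <- spiketrain$spike_times
  if (length(st) < 2) return(numeric(0))
  diff(st)
}

#' Segment a spike train into bursts
#'
#' A new burst starts after any interspike interval exceeding
#' `gap_threshold`.  With `gap_threshold = "auto"` the threshold is placed
#' at the largest multiplicative gap in the sorted ISI values (the split of
#' a bimodal intra-burst / inter-burst ISI distribution); if no
#' sufficiently large gap exists the train is flagged tonic and treated as
#' a single burst.
#'
#' @param spiketrain a [detect_spikes()] result with at least 1 spike.
#' @param gap_threshold numeric (ms) or `"auto"`.
#' @param min_split_ratio smallest inter/intra ISI ratio accepted as a
#'   bimodal split in auto mode.
#' @return An object of class `pbc_bursts`: `burst_onsets`,
#'   `spikes_per_burst`, `interburst_intervals`, `period` (mean
#'   onset-to-onset, ms), `frequency` (1/ms), `tonic`, `gap_threshold`.
#' @export
detect_bursts <- function(spiketrain, gap_threshold = "auto",
                          min_split_ratio = 4) {
  st <- spiketrain$spike_times
  if (length(st) < 1) stop("burst detection needs at least one spike")
  isi <- diff(st)
  tonic <- FALSE
  if (identical(gap_threshold, "auto")) {
    if (length(isi) < 2) {
      gap_threshold <- Inf
    } else {
      s <- sort(isi)
      ratios <- s[-1] / s[-length(s)]
      k <- which.max(ratios)
      if (ratios[k] < min_split_ratio) {
        gap_threshold <- Inf
        tonic <- length(isi) >= 2
      } else {
        gap_threshold <- sqrt(s[k] * s[k + 1])  # geometric midpoint
      }
    }
  }
  grp <- cumsum(c(1, as.integer(isi > gap_threshold)))
  onsets <- st[!duplicated(grp)]
  spb <- as.integer(table(grp))
  structure(list(
    burst_onsets = onsets,
    spikes_per_burst = spb,
    interburst_intervals = if (length(onsets) > 1) diff(onsets) else numeric(0),
    period = if (length(onsets) > 1) mean(diff(onsets)) else NA_real_,
    frequency = if (length(onsets) > 1) 1 / mean(diff(onsets)) else NA_real_,
    tonic = tonic,
    gap_threshold = gap_threshold
  ), class = "pbc_bursts")
}

#' @export
print.pbc_bursts <- function(x, ...) {
  cat(sprintf("<pbc_bursts> %d bursts, spikes/burst %s, period %.5g ms%s\n",
              length(x$burst_onsets),
              paste(range(x$spikes_per_burst), collapse = "-"),
              x$period, if (x$tonic) " [tonic]" else ""))
  invisible(x)
}

#' ISI bifurcation scan over one parameter
#'
#' Runs one simulation per grid value, discards the transient, and collects
#' all post-transient interspike intervals, reproducing the dot-cloud ISI
#' bifurcation diagrams.  `param` may be the single-neuron stimulus current
#' `"I_exc"`, or `"g_c"` / `"tau"` for the coupled pair (symmetric delay;
#' ISIs taken from neuron 1 by default).
#'
#' @param param one of `"I_exc"`, `"g_c"`, `"tau"`.
#' @param grid sorted numeric grid.
#' @param params a [pbc_params()] object.
#' @param net a [network_config()] used as the base configuration for pair
#'   scans (ignored for `"I_exc"`).
#' @param t_end,transient run length (ms) and fraction discarded.
#' @param dt_integrate,dt_sample integration and sampling steps (ms).
#' @param var voltage channel for spike detection in pair scans.
#' @param ... passed to [detect_spikes()].
#' @return An object of class `pbc_isi_scan`: `isis` (long data.frame with
#'   `param_value`, `isi`), `n_spikes` and `quiescent` per grid value,
#'   `failed` error messages (if any), and the scan configuration.
#' @export
isi_scan <- function(param = c("I_exc", "g_c", "tau"), grid, params,
                     net = network_config(), t_end = 2e5, transient = 0.5,
                     dt_integrate = 0.02, dt_sample = 1, var = "V1", ...) {
  param <- match.arg(param)
  if (is.unsorted(grid)) stop("grid must be sorted")
  rows <- list()
  n_spikes <- integer(length(grid))
  failed <- rep(NA_character_, length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    res <- tryCatch({
      tr <- switch(param,
        I_exc = simulate_neuron(params, I_exc = g, t_end = t_end,
                                dt_integrate = dt_integrate,
                                dt_sample = dt_sample),
        g_c = {
          net$g_c <- g
          simulate_pair(params, net, t_end = t_end,
                        dt_integrate = dt_integrate, dt_sample = dt_sample)
        },
        tau = {
          net$tau1 <- net$tau2 <- g
          simulate_pair(params, net, t_end = t_end,
                        dt_integrate = dt_integrate, dt_sample = dt_sample)
        })
      v <- if (param == "I_exc") "V" else var
      stn <- detect_spikes(discard_transient(tr, transient), var = v, ...)
      list(n = length(stn$spike_times), isi = isi_sequence(stn))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- sprintf("%s = %g: %s", param, g, conditionMessage(res))
      next
    }
    n_spikes[i] <- res$n
    if (length(res$isi))
      rows[[length(rows) + 1]] <- data.frame(param_value = g, isi = res$isi)
  }
  structure(list(
    isis = if (length(rows)) do.call(rbind, rows)
           else data.frame(param_value = numeric(0), isi = numeric(0)),
    grid = grid, n_spikes = n_spikes,
    quiescent = n_spikes == 0,
    failed = failed[!is.na(failed)],
    param = param, t_end = t_end, transient = transient
  ), class = "pbc_isi_scan")
}

#' @export
print.pbc_isi_scan <- function(x, ...) {
  cat(sprintf("<pbc_isi_scan> %s over %d grid values, %d quiescent, %d failed\n",
              x$param, length(x$grid), sum(x$quiescent), length(x$failed)))
  invisible(x)
}

#' Write an ISI scan as tidy CSV
#'
#' Long format `(param_value, isi)`, mirroring the ISI bifurcation figures.
#' @param scan a [isi_scan()] result.
#' @param path file path.
#' @export
write_isi_csv <- function(scan, path) {
  write.csv(scan$isis, path, row.names = FALSE)
  invisible(path)
}
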