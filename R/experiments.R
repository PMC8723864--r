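# Parameter-sweep experiments over the coupled pair: 1-D and 2-D grids of
# the synchronization metrics, and the weak-delay persistence check.

pair_metrics_cell <- function(params, net, t_end, transient, dt_integrate,
                              dt_sample) {
  tr <- simulate_pair(params, net, t_end = t_end,
                      dt_integrate = dt_integrate, dt_sample = dt_sample)
  rep <- sync_report(tr, transient = transient)
  data.frame(R = rep$R, max_e = rep$max_e, S0 = rep$S0,
             dphi_max = rep$dphi_max, best_lag = rep$best_lag,
             sync_class = rep$sync_class, failed = FALSE,
             stringsAsFactors = FALSE)
}

failed_cell <- function(msg) {
  data.frame(R = NA_real_, max_e = NA_real_, S0 = NA_real_,
             dphi_max = NA_real_, best_lag = NA_real_,
             sync_class = NA_character_, failed = TRUE,
             stringsAsFactors = FALSE)
}

set_net_param <- function(net, name, value) {
  switch(name,
    g_c = { net$g_c <- value },
    tau = { net$tau1 <- value; net$tau2 <- value },
    tau1 = { net$tau1 <- value },
    tau2 = { net$tau2 <- value },
    I_exc = { net$I_exc1 <- value; net$I_exc2 <- value },
    I_exc1 = { net$I_exc1 <- value },
    I_exc2 = { net$I_exc2 <- value },
    stop("unknown sweep parameter: ", name))
  net
}

#' One-parameter synchronization sweep
#'
#' Simulates the coupled pair at each grid value of one network parameter,
#' discards the transient, and records the full synchronization report
#' per cell.  Failures are recorded per cell and the sweep continues.
#'
#' @param param one of `"g_c"`, `"tau"` (symmetric delay), `"I_exc"`
#'   (both neurons), or the asymmetric `"tau1"`, `"tau2"`, `"I_exc1"`,
#'   `"I_exc2"`.
#' @param grid numeric grid.
#' @param params a [pbc_params()] object.
#' @param net base [network_config()].
#' @param t_end,transient per-cell run length (ms) and discard fraction.
#' @param dt_integrate,dt_sample integration and sampling steps (ms).
#' @return An object of class `pbc_sweep`: a data.frame with
#'   `param_value` and the metric columns, plus provenance attributes.
#' @export
sweep_1d <- function(param, grid, params, net = network_config(g_c = -0.5),
                     t_end = 2e5, transient = 0.5, dt_integrate = 0.02,
                     dt_sample = 1) {
  cells <- lapply(grid, function(g) {
    cfg <- set_net_param(net, param, g)
    res <- tryCatch(
      pair_metrics_cell(params, cfg, t_end, transient, dt_integrate,
                        dt_sample),
      error = function(e) failed_cell(conditionMessage(e)))
    cbind(data.frame(param_value = g), res)
  })
  out <- if (length(cells)) do.call(rbind, cells)
  else cbind(data.frame(param_value = numeric(0)), failed_cell("")[0, ])
  structure(out, class = c("pbc_sweep", "data.frame"),
            param = param, t_end = t_end, transient = transient,
            net = net)
}

#' Two-parameter synchronization map
#'
#' Metric maps over the outer product of two parameter grids (e.g. the
#' `(tau1, tau2)` plane or the `(I_exc1, I_exc2)` plane).  Cells on the
#' diagonal of a `(tau1, tau2)` map with equal grids reproduce the
#' symmetric-delay 1-D sweep exactly.
#'
#' @param param1,param2 sweep parameter names (see [sweep_1d()]).
#' @param grid1,grid2 numeric grids.
#' @inheritParams sweep_1d
#' @return A `pbc_sweep` data.frame with columns `param1_value`,
#'   `param2_value` and the metrics.
#' @export
sweep_2d <- function(param1, param2, grid1, grid2, params,
                     net = network_config(g_c = -0.5), t_end = 2e5,
                     transient = 0.5, dt_integrate = 0.02, dt_sample = 1) {
  cells <- list()
  for (g2 in grid2) for (g1 in grid1) {
    cfg <- set_net_param(set_net_param(net, param1, g1), param2, g2)
    res <- tryCatch(
      pair_metrics_cell(params, cfg, t_end, transient, dt_integrate,
                        dt_sample),
      error = function(e) failed_cell(conditionMessage(e)))
    cells[[length(cells) + 1]] <-
      cbind(data.frame(param1_value = g1, param2_value = g2), res)
  }
  out <- do.call(rbind, cells)
  structure(out, class = c("pbc_sweep", "data.frame"),
            param = c(param1, param2), t_end = t_end,
            transient = transient, net = net)
}

#' Persistence of complete synchronization under weak delay
#'
#' Checks that the completely synchronized state of the negatively coupled
#' identical pair survives weak symmetric transmission delays: at each
#' delay in `tau_grid` the pair must classify as `complete`.  This is the
#' numerical embodiment of the continuous dependence of the delay system
#' on its parameters for small delays.
#'
#' @param params a [pbc_params()] object.
#' @param g_c coupling strength (default -0.5).
#' @param tau_grid symmetric delays (ms), typically inside (0, 0.02).
#' @param I_exc common stimulus current.
#' @inheritParams sweep_1d
#' @return List with `pass` (logical) and `detail` (per-delay class,
#'   `R`, `max_e`).
#' @export
weak_delay_property <- function(params, g_c = -0.5,
                                tau_grid = c(0.005, 0.01, 0.015),
                                I_exc = 8.5, t_end = 2e5, transient = 0.5,
                                dt_integrate = 0.02, dt_sample = 1) {
  net <- network_config(g_c = g_c, I_exc1 = I_exc, I_exc2 = I_exc)
  sw <- sweep_1d("tau", tau_grid, params, net, t_end = t_end,
                 transient = transient, dt_integrate = dt_integrate,
                 dt_sample = dt_sample)
  list(pass = all(!sw$failed & sw$sync_class == "complete"),
       detail = sw)
}

#' Write a sweep as CSV
#' @param sweep a [sweep_1d()] / [sweep_2d()] result.
#' @param path file path.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
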