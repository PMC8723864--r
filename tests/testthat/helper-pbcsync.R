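# Shared fixtures: canonical and calibrated parameter sets, a cache for
# expensive reference simulations reused across tests.

std_params <- function() pbc_params()
cal_params <- function() calibrate_can_scale(pbc_params())

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fn()
  .sim_cache[[key]]
}

# reference period-3 bursting run (post-transient window only)
period3_run <- function() {
  cached("period3", function() {
    discard_transient(simulate_neuron(std_params(), I_exc = 8.5, t_end = 6e4),
                      0.5)
  })
}

# assemble a two-channel trace from a surrogate pair for sync_report
pair_trace <- function(pg) {
  m <- cbind(V1 = trace_var(pg$trace1, "V"), V2 = trace_var(pg$trace2, "V"))
  new_trace(m, pg$trace1$dt_sample)
}
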