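# Simulation front end: settling, current clamp, voltage clamp, holding
# current search.  Integration is exponential-Euler on gates with a
# forward voltage update (dt = 0.025 ms by default), implemented in C++.

.settle_cache <- new.env(parent = emptyenv())

params_key <- function(params, bias, dt, settle_ms, mode = "cc", v = NA) {
  paste(format(c(unlist(params$g_soma), unlist(params$g_axon),
                 params$c_soma, params$c_axon, params$g_couple,
                 params$temperature,
                 unlist(lapply(params$channels, function(ch)
                   unlist(ch[vapply(ch, is.numeric, TRUE)]))),
                 bias, dt, settle_ms, v), digits = 17),
        collapse = ",", mode)
}

# Gate steady states at a common voltage, packed as the C++ state vector.
steady_gate_state <- function(params, v) {
  ch <- params$channels
  m <- vapply(ch, function(s)
    if (s$p > 0) boltzmann(v, s$v_half_act, s$slope_act) else 1, 1.0)
  h <- vapply(ch, function(s)
    if (s$q > 0) boltzmann(v, s$v_half_inact, s$slope_inact) else 1, 1.0)
  c(v, v, m, h, m, h)
}

run_core <- function(params, i_soma, mode, v_cmd, state0, dt, record) {
  .hh2c_core(channel_matrix(params$channels),
             as.numeric(params$g_soma), as.numeric(params$g_axon),
             params$c_soma, params$c_axon, params$g_couple,
             params$temperature, dt,
             as.numeric(i_soma), as.integer(mode), as.numeric(v_cmd),
             state0, record)
}

# Settle the model at a constant bias current (current clamp) or at a
# constant command voltage (voltage clamp) for `settle_ms`, caching the
# final state by parameter hash.
settle_state <- function(params, bias = 0, dt = 0.025, settle_ms = 2000,
                         mode = 0L, v_hold = NA) {
  key <- params_key(params, bias, dt, settle_ms,
                    if (mode == 0L) "cc" else "vc", v_hold)
  hit <- .settle_cache[[key]]
  if (!is.null(hit)) return(hit)
  v0 <- if (mode == 0L) -70 else v_hold
  nstep <- round(settle_ms / dt)
  res <- if (mode == 0L) {
    run_core(params, rep(bias, nstep), 0L, numeric(1),
             steady_gate_state(params, v0), dt, FALSE)
  } else {
    run_core(params, numeric(1), 1L, rep(v_hold, nstep + 1),
             steady_gate_state(params, v0), dt, FALSE)
  }
  if (res$bad_step > 0)
    stop(sprintf("integration failure during settling at step %d (t = %g ms)",
                 res$bad_step, res$bad_step * dt), call. = FALSE)
  st <- res$state
  .settle_cache[[key]] <- st
  st
}

new_trace <- function(df, protocol, params, extra = list()) {
  structure(df, class = c("trace", "data.frame"),
            dt = protocol$dt, mode = protocol$mode,
            protocol = protocol,
            step_onset = protocol$step_onset,
            step_duration = protocol$step_duration,
            step_amplitude = protocol$step_amplitude,
            holding_bias = protocol$holding_bias)
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s, %d samples, dt = %g ms (%g ms total)\n",
              attr(x, "mode"), nrow(x), attr(x, "dt"),
              (nrow(x) - 1) * attr(x, "dt")))
  invisible(x)
}

#' Simulate a current-clamp protocol
#'
#' Settles the two-compartment model at the protocol's holding bias
#' (2 s settling simulation by default, cached by parameter hash), then
#' integrates the full protocol and returns both compartment voltages on
#' a uniform time grid.  Deterministic given `(params, protocol, dt)`.
#'
#' @param params a [cell_parameters()] object.
#' @param protocol a current-clamp [stimulus_protocol()].
#' @param settle_ms settling duration before t = 0 (ms).
#' @return A `trace` data frame with columns `t`, `v_soma`, `v_axon` (mV).
#' @export
simulate_current_clamp <- function(params, protocol, settle_ms = 2000) {
  stopifnot(inherits(params, "cell_parameters"),
            inherits(protocol, "stimulus_protocol"),
            protocol$mode == "current_clamp")
  dt <- protocol$dt
  st <- settle_state(params, protocol$holding_bias, dt, settle_ms)
  iv <- command_vector(protocol)
  res <- run_core(params, iv, 0L, numeric(1), st, dt, TRUE)
  if (res$bad_step > 0)
    stop(sprintf("integration failure at step %d (t = %g ms)",
                 res$bad_step, res$bad_step * dt), call. = FALSE)
  df <- data.frame(t = seq(0, by = dt, length.out = length(iv) + 1),
                   v_soma = res$v_soma, v_axon = res$v_axon)
  new_trace(df, protocol, params)
}

#' Simulate a voltage-clamp protocol
#'
#' The somatic compartment follows the command; the axonal compartment
#' evolves freely.  The recorded clamp current is the balance of
#' capacitive, ionic and coupling currents at the soma (positive =
#' outward).
#'
#' @param params a [cell_parameters()] object.
#' @param protocol a voltage-clamp [stimulus_protocol()].
#' @param settle_ms settling duration at the first command level (ms).
#' @return A `trace` data frame with columns `t`, `i_clamp` (pA),
#'   `v_cmd` and `v_axon` (mV).
#' @export
simulate_voltage_clamp <- function(params, protocol, settle_ms = 2000) {
  stopifnot(inherits(params, "cell_parameters"),
            inherits(protocol, "stimulus_protocol"),
            protocol$mode == "voltage_clamp")
  dt <- protocol$dt
  v_hold <- protocol$segments$level[1]
  st <- settle_state(params, dt = dt, settle_ms = settle_ms,
                     mode = 1L, v_hold = v_hold)
  cmd <- command_vector(protocol)
  cmd <- c(cmd, cmd[length(cmd)])  # nstep + 1 command samples
  res <- run_core(params, numeric(1), 1L, cmd, st, dt, TRUE)
  if (res$bad_step > 0)
    stop(sprintf("integration failure at step %d (t = %g ms)",
                 res$bad_step, res$bad_step * dt), call. = FALSE)
  df <- data.frame(t = seq(0, by = dt, length.out = length(cmd)),
                   i_clamp = res$i_clamp, v_cmd = cmd, v_axon = res$v_axon)
  new_trace(df, protocol, params)
}

#' Settled somatic membrane potential at a bias current
#'
#' @param params a [cell_parameters()] object.
#' @param bias constant somatic current (pA).
#' @param settle_ms settling duration (ms), default 3000.
#' @param dt step size (ms).
#' @return Somatic voltage (mV) at the end of settling.
#' @export
resting_potential <- function(params, bias = 0, settle_ms = 3000,
                              dt = 0.025) {
  settle_state(params, bias, dt, settle_ms)[1]
}

#' Bias current holding the soma at a target potential
#'
#' Root-bracketing search for the continuous current whose settled
#' somatic voltage matches `target_v` (within `tol`).  A cell that
#' spikes spontaneously across the whole bracket (settled voltage not a
#' fixed point) raises a protocol error.
#'
#' @param params a [cell_parameters()] object.
#' @param target_v target somatic potential (mV), in (-100, -40).
#' @param tol voltage tolerance (mV), default 0.1.
#' @param bracket initial current bracket (pA).
#' @param settle_ms settling duration per evaluation (ms).
#' @return Holding current (pA).
#' @export
find_holding_current <- function(params, target_v, tol = 0.1,
                                 bracket = c(-150, 150), settle_ms = 3000) {
  stopifnot(target_v > -100, target_v < -40)
  settled <- function(bias) {
    st <- settle_state(params, bias, 0.025, settle_ms)
    # verify fixed point: a short continuation must stay put (no spiking)
    cont <- run_core(params, rep(bias, 4000), 0L, numeric(1), st, 0.025, TRUE)
    list(v = st[1], stationary = max(abs(cont$v_soma - st[1])) <= 2)
  }
  f <- function(bias) {
    s <- settled(bias)
    # a spiking (non-stationary) state means the bias overshot the target:
    # report a large positive residual so the root search backs off
    if (!s$stationary) return(1e3)
    s$v - target_v
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 1e3)
    stop("cell spikes spontaneously across the whole search bracket",
         call. = FALSE)
  if (flo * fhi > 0)
    stop("target potential not bracketed by the search interval",
         call. = FALSE)
  r <- stats::uniroot(f, lower = lo, upper = hi, f.lower = flo,
                      f.upper = fhi, tol = 1e-3)
  bias <- r$root
  s <- settled(bias)
  if (!s$stationary || abs(s$v - target_v) > tol)
    stop("holding-current search did not reach the target tolerance",
         call. = FALSE)
  bias
}

#' Write / read a voltage trace as delimited text
#'
#' Tab-separated columns (`t_ms`, `v_soma_mV`, `v_axon_mV` in current
#' clamp; `t_ms`, `i_clamp_pA`, `v_cmd_mV`, `v_axon_mV` in voltage
#' clamp) with a sidecar `<path>.json` metadata block holding the mode,
#' dt and stimulus description.  Round-trips at full double precision.
#'
#' @param trace a `trace` object.
#' @param path output file path (TSV).
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df) <- c(t = "t_ms", v_soma = "v_soma_mV", v_axon = "v_axon_mV",
                 i_clamp = "i_clamp_pA", v_cmd = "v_cmd_mV")[names(df)]
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  proto <- attr(trace, "protocol")
  meta <- list(mode = attr(trace, "mode"), dt = attr(trace, "dt"),
               holding_bias = attr(trace, "holding_bias"),
               step_onset = attr(trace, "step_onset"),
               step_duration = attr(trace, "step_duration"),
               step_amplitude = attr(trace, "step_amplitude"),
               segments = proto$segments)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  names(df) <- c(t_ms = "t", v_soma_mV = "v_soma", v_axon_mV = "v_axon",
                 i_clamp_pA = "i_clamp", v_cmd_mV = "v_cmd")[names(df)]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- stimulus_protocol(meta$segments, meta$mode,
                             meta$holding_bias %||% 0, meta$dt)
  proto$step_onset <- meta$step_onset
  proto$step_duration <- meta$step_duration
  proto$step_amplitude <- meta$step_amplitude
  new_trace(df, proto, NULL)
}
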