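#' Stimulus protocols
#'
#' A `stimulus_protocol` is an ordered list of piecewise-constant command
#' segments, either injected somatic current (current clamp, pA) or a
#' somatic voltage command (voltage clamp, mV), plus sampling metadata.
#' In current clamp a constant `holding_bias` (pA) is added to every
#' segment and is also the current the cell is settled at before t = 0.
#'
#' @param segments data frame with columns `duration` (ms, > 0) and
#'   `level` (pA or mV depending on `mode`).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding_bias continuous bias current (pA), current clamp only.
#' @param dt integration / sampling step (ms), default 0.025.
#' @param n_repeats number of sweeps (used by the surrogate generator).
#' @param seed integer seed associated with the protocol (noise streams).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(segments, mode = c("current_clamp",
                                                 "voltage_clamp"),
                              holding_bias = 0, dt = 0.025,
                              n_repeats = 1L, seed = 1L) {
  mode <- match.arg(mode)
  segments <- as.data.frame(segments)
  stopifnot(all(c("duration", "level") %in% names(segments)),
            nrow(segments) >= 1, all(segments$duration > 0),
            all(is.finite(segments$level)), dt > 0, n_repeats >= 1)
  structure(list(segments = segments, mode = mode,
                 holding_bias = holding_bias, dt = dt,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s, %d segment(s), dt = %g ms, total %g ms\n",
              x$mode, nrow(x$segments), x$dt, sum(x$segments$duration)))
  if (x$mode == "current_clamp")
    cat(sprintf("  holding bias %g pA\n", x$holding_bias))
  invisible(x)
}

#' Square current-step protocol
#'
#' Baseline / step / baseline current-clamp protocol, the workhorse of the
#' excitability assays (e.g. 47 pA for 800 ms).
#'
#' @param amplitude step amplitude (pA), relative to the holding bias.
#' @param duration step duration (ms), default 800 as in the excitability
#'   test pulses.
#' @param pre,post baseline durations before and after the step (ms).
#' @param holding_bias continuous bias current (pA).
#' @param dt step size (ms).
#' @param n_repeats,seed see [stimulus_protocol()].
#' @return A current-clamp [stimulus_protocol()].
#' @export
step_protocol <- function(amplitude, duration = 800, pre = 200, post = 200,
                          holding_bias = 0, dt = 0.025,
                          n_repeats = 1L, seed = 1L) {
  segs <- data.frame(duration = c(pre, duration, post),
                     level = c(0, amplitude, 0))
  segs <- segs[segs$duration > 0, ]
  p <- stimulus_protocol(segs, "current_clamp", holding_bias, dt,
                         n_repeats, seed)
  p$step_onset <- pre
  p$step_duration <- duration
  p$step_amplitude <- amplitude
  p
}

#' Voltage-clamp step protocol
#'
#' Somatic voltage command held at `v_hold`, stepped to `v_step`, and
#' returned to `v_hold` — the in-silico analogue of the subtraction
#' protocol used to isolate the D-type (Kv1) outward current
#' (commands from -80 toward -50/-45 mV).
#'
#' @param v_hold holding command (mV).
#' @param v_step step command (mV).
#' @param duration step duration (ms).
#' @param pre,post hold durations (ms).
#' @param dt step size (ms).
#' @return A voltage-clamp [stimulus_protocol()].
#' @export
vclamp_protocol <- function(v_hold = -80, v_step = -50, duration = 500,
                            pre = 100, post = 100, dt = 0.025) {
  segs <- data.frame(duration = c(pre, duration, post),
                     level = c(v_hold, v_step, v_hold))
  segs <- segs[segs$duration > 0, ]
  p <- stimulus_protocol(segs, "voltage_clamp", dt = dt)
  p$step_onset <- pre
  p$step_duration <- duration
  p
}

# Expand protocol segments into a per-step command vector of length nstep,
# where nstep = total_duration / dt (the trace has nstep + 1 samples).
command_vector <- function(protocol) {
  dt <- protocol$dt
  n_per <- round(protocol$segments$duration / dt)
  lv <- rep(protocol$segments$level, times = n_per)
  if (protocol$mode == "current_clamp") lv <- lv + protocol$holding_bias
  lv
}
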