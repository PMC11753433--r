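# In-silico experimental conditions: monocular deprivation, dendrotoxin,
# intrinsic-potentiation (LTP-IE) and T-channel block, applied as static
# conductance changes to the calibrated control cell.

#' Model condition specification
#'
#' The five conditions of the in-silico program, all expressed as static
#' conductance manipulations of the calibrated control cell:
#' * `control` — calibrated reference (gKv1 41.7 nS soma / 23 nS axon);
#' * `deprived` — monocular-deprivation analogue, gKv1 raised to
#'   101.7 / 83 nS;
#' * `dtx` — dendrotoxin analogue, gKv1 = 0 in both compartments;
#' * `ltpie` — intrinsic potentiation, gKv1 halved in both compartments;
#' * `tta_p2` — T-type channel block, gT = 0 (gKv1 untouched).
#'
#' @param name condition name.
#' @param gkv1_soma,gkv1_axon absolute gKv1 overrides (nS), used by the
#'   named conditions; custom values allowed.
#' @param gkv1_scale multiplicative gKv1 scaling (applied when absolute
#'   values are `NA`).
#' @param t_enabled logical; `FALSE` zeroes the T-type conductance.
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(name = c("control", "deprived", "dtx", "ltpie",
                                    "tta_p2"),
                           gkv1_soma = NA_real_, gkv1_axon = NA_real_,
                           gkv1_scale = NA_real_, t_enabled = TRUE) {
  name <- match.arg(name)
  defaults <- switch(name,
    control  = list(scale = 1, t = TRUE),
    deprived = list(abs = c(101.7, 83), t = TRUE),
    dtx      = list(abs = c(0, 0), t = TRUE),
    ltpie    = list(scale = 0.5, t = TRUE),
    tta_p2   = list(scale = 1, t = FALSE))
  if (is.na(gkv1_soma) && !is.null(defaults$abs)) {
    gkv1_soma <- defaults$abs[1]; gkv1_axon <- defaults$abs[2]
  }
  if (is.na(gkv1_scale) && !is.null(defaults$scale))
    gkv1_scale <- defaults$scale
  if (missing(t_enabled)) t_enabled <- defaults$t
  structure(list(name = name, gkv1_soma = gkv1_soma,
                 gkv1_axon = gkv1_axon, gkv1_scale = gkv1_scale,
                 t_enabled = t_enabled),
            class = "condition_spec")
}

#' Apply a condition to the calibrated base cell
#'
#' @param base a [cell_parameters()] object (the calibrated reference).
#' @param cond a [condition_spec()] or a condition name.
#' @return Modified [cell_parameters()].
#' @export
apply_condition <- function(base, cond) {
  if (is.character(cond)) cond <- condition_spec(cond)
  stopifnot(inherits(cond, "condition_spec"))
  p <- base
  if (!is.na(cond$gkv1_soma)) {
    p$g_soma[["Kv1"]] <- cond$gkv1_soma
    p$g_axon[["Kv1"]] <- cond$gkv1_axon
  } else if (!is.na(cond$gkv1_scale)) {
    p$g_soma[["Kv1"]] <- p$g_soma[["Kv1"]] * cond$gkv1_scale
    p$g_axon[["Kv1"]] <- p$g_axon[["Kv1"]] * cond$gkv1_scale
  }
  if (!isTRUE(cond$t_enabled)) p$g_soma[["T"]] <- 0
  cell_parameters(p$g_soma, p$g_axon, p$c_soma, p$c_axon, p$g_couple,
                  p$channels, p$temperature)
}

#' Compare two conditions over a range of step currents
#'
#' Simulates 800-ms steps at each current for both conditions from the
#' same holding regime and tabulates spike count, first-spike latency
#' and post-burst latency, with per-current deltas (an f-I comparison in
#' the style of the open-vs-deprived input-output curves).
#'
#' @param base calibrated reference [cell_parameters()].
#' @param cond_a,cond_b [condition_spec()]s or condition names.
#' @param currents step currents (pA).
#' @param holding_bias continuous bias (pA), default 0 (resting regime).
#' @param step_duration step length (ms).
#' @return List with `table` (per-current features and deltas) and
#'   `rheobase` (named, per condition at the same holding regime);
#'   simulation errors are annotated per row in the `error_a`/`error_b`
#'   columns rather than propagated.
#' @export
compare_conditions <- function(base, cond_a, cond_b,
                               currents = seq(45, 59, by = 2),
                               holding_bias = 0, step_duration = 800) {
  stopifnot(length(currents) >= 1)
  pa <- apply_condition(base, cond_a)
  pb <- apply_condition(base, cond_b)
  name_of <- function(x) if (is.character(x)) x else x$name
  one <- function(p, amp) {
    tryCatch({
      tr <- simulate_current_clamp(
        p, step_protocol(amp, step_duration, pre = 200, post = 100,
                         holding_bias = holding_bias))
      fv <- extract_features(tr)
      list(ap = fv$ap_count, lat = fv$first_spike_latency,
           lab = fv$latency_after_burst, err = NA_character_)
    }, error = function(e)
      list(ap = NA_integer_, lat = NA_real_, lab = NA_real_,
           err = conditionMessage(e)))
  }
  rows <- lapply(currents, function(amp) {
    a <- one(pa, amp); b <- one(pb, amp)
    data.frame(current_pA = amp,
               ap_a = a$ap, ap_b = b$ap, d_ap = b$ap - a$ap,
               latency_a = a$lat, latency_b = b$lat,
               latency_after_burst_a = a$lab,
               latency_after_burst_b = b$lab,
               error_a = a$err, error_b = b$err)
  })
  rheo <- function(p) {
    for (amp in seq(10, 500, by = 10)) {
      n <- tryCatch(length(detect_spikes(simulate_current_clamp(
        p, step_protocol(amp, step_duration, pre = 100, post = 100,
                         holding_bias = holding_bias)))),
        error = function(e) NA_integer_)
      if (!is.na(n) && n >= 1) return(amp)
    }
    NA_real_
  }
  list(conditions = c(name_of(cond_a), name_of(cond_b)),
       table = do.call(rbind, rows),
       rheobase = setNames(c(rheo(pa), rheo(pb)),
                           c(name_of(cond_a), name_of(cond_b))))
}

#' 40-Hz induction protocol generator
#'
#' Builds the intrinsic-plasticity induction stimulus: trains of brief
#' suprathreshold current pulses (`pulses_per_train` pulses at
#' `train_freq`) repeated every `train_interval` seconds for `duration`
#' minutes — e.g. 15 pulses at 40 Hz every 10 s for 10 min = 900 pulses.
#'
#' @param train_freq within-train pulse frequency (Hz), default 40.
#' @param pulses_per_train pulses per train, default 15.
#' @param train_interval interval between train onsets (s), default 10
#'   (i.e. trains at 0.1 Hz).
#' @param duration total induction duration (min), default 10.
#' @param pulse_width pulse width (ms), in 2-5 ms; default 2.
#' @param pulse_amp pulse amplitude (pA); suprathreshold, default 1500
#'   (1.0-2.5 nA range).
#' @param dt step size (ms).
#' @return A current-clamp [stimulus_protocol()] with attribute fields
#'   `n_pulses` and `n_trains`.
#' @export
induction_protocol <- function(train_freq = 40, pulses_per_train = 15,
                               train_interval = 10, duration = 10,
                               pulse_width = 2, pulse_amp = 1500,
                               dt = 0.025) {
  stopifnot(train_freq > 0, pulses_per_train >= 1, train_interval > 0,
            duration > 0, pulse_width > 0, pulse_width < 1000 / train_freq)
  n_trains <- round(duration * 60 / train_interval)
  period <- 1000 / train_freq                 # ms between pulse onsets
  gap_in_train <- period - pulse_width
  train_ms <- pulses_per_train * period
  tail_ms <- train_interval * 1000 - train_ms
  stopifnot(tail_ms > 0)
  seg_train <- data.frame(
    duration = rep(c(pulse_width, gap_in_train), pulses_per_train),
    level = rep(c(pulse_amp, 0), pulses_per_train))
  segs <- do.call(rbind, replicate(n_trains, rbind(
    seg_train, data.frame(duration = tail_ms, level = 0)),
    simplify = FALSE))
  p <- stimulus_protocol(segs, "current_clamp", dt = dt)
  p$n_pulses <- as.integer(pulses_per_train * n_trains)
  p$n_trains <- as.integer(n_trains)
  p
}

#' Steady dendrotoxin-sensitive (Kv1) current by in-silico subtraction
#'
#' Voltage-clamp step from `v_from` to `v_to` run with the cell's Kv1
#' conductance intact and with gKv1 = 0; the difference of the steady
#' clamp currents at `v_to` is the D-type current the subtraction
#' protocol isolates.  Sodium and T-type conductances are zeroed in both
#' runs (the in-silico analogue of the pharmacological silencing used
#' when recording isolated potassium currents); without it the poorly
#' clamped axonal compartment escapes and fires during the command
#' step.
#'
#' @param params a [cell_parameters()] object.
#' @param v_from,v_to command potentials (mV), `v_from < v_to`, both
#'   subthreshold (default -80 to -50).
#' @param duration step duration (ms); long enough for Kv1 activation to
#'   converge, default 500.
#' @return Steady DTx-sensitive current (pA, positive outward).
#' @export
dtx_sensitive_current <- function(params, v_from = -80, v_to = -50,
                                  duration = 500) {
  stopifnot(v_from < v_to)
  params <- set_conductance(params, Na_soma = 0, Na_axon = 0, T_soma = 0)
  steady_i <- function(p) {
    tr <- simulate_voltage_clamp(p, vclamp_protocol(v_from, v_to, duration))
    on_step <- tr$t >= attr(tr, "step_onset") + duration - 10 &
      tr$t < attr(tr, "step_onset") + duration
    mean(tr$i_clamp[on_step])
  }
  p0 <- set_conductance(params, Kv1_soma = 0, Kv1_axon = 0)
  steady_i(params) - steady_i(p0)
}
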