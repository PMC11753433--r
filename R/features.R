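# Electrophysiological feature definitions: spike detection and the
# excitability metrics used both on simulated and on imported traces.

#' Detect action potentials
#'
#' One event per upward crossing of `detect_v`, with successive events
#' separated by at least `refractory`.  Spike times are reported at the
#' crossing sample.
#'
#' @param trace a `trace` (current clamp) or a data frame with columns
#'   `t` and `v_soma`.
#' @param detect_v detection voltage (mV), default 0.
#' @param refractory minimal event separation (ms), default 2.
#' @return Strictly increasing spike times (ms); may be empty.
#' @export
detect_spikes <- function(trace, detect_v = 0, refractory = 2) {
  v <- trace$v_soma
  t <- trace$t
  up <- which(v[-1] > detect_v & v[-length(v)] <= detect_v) + 1L
  if (!length(up)) return(numeric(0))
  times <- t[up]
  # enforce the refractory sequentially from the first event
  out <- times[1]
  for (ti in times[-1]) if (ti - out[length(out)] >= refractory)
    out <- c(out, ti)
  out
}

#' Spike threshold from the phase plot
#'
#' Voltage at the first sample, ahead of the spike peak, where the rate
#' of rise dV/dt exceeds `dvdt_criterion` — the phase-plot definition of
#' threshold.
#'
#' @param trace a current-clamp `trace`.
#' @param spike_time a spike time from [detect_spikes()] (ms).
#' @param dvdt_criterion rate-of-rise criterion (mV/ms), default 20.
#' @param window how far before the spike to search (ms), default 20.
#' @return Threshold voltage (mV).
#' @export
spike_threshold <- function(trace, spike_time, dvdt_criterion = 20,
                            window = 20) {
  t <- trace$t; v <- trace$v_soma
  dt <- t[2] - t[1]
  i_spk <- which.min(abs(t - spike_time))
  # peak: local maximum after the detection crossing
  i_end <- min(length(v), i_spk + round(3 / dt))
  i_peak <- i_spk + which.max(v[i_spk:i_end]) - 1L
  i_start <- max(2L, i_peak - round(window / dt))
  dvdt <- (v[(i_start + 1):i_peak] - v[i_start:(i_peak - 1)]) / dt
  hit <- which(dvdt >= dvdt_criterion)
  if (!length(hit))
    stop("dV/dt criterion never crossed before the spike peak ",
         "(malformed spike)", call. = FALSE)
  v[i_start + hit[1] - 1L]
}

#' Rheobase by incremental current steps
#'
#' Smallest multiple of `increment` (default 10 pA, scanned upward from
#' one increment) that elicits at least one action potential during a
#' depolarizing step from the given holding potential.  The holding
#' potential is imposed through [find_holding_current()].
#'
#' @param params a [cell_parameters()] object.
#' @param holding_v holding potential (mV); -65 mV (approximate rest) and
#'   -56 mV (T-current inactivated, tonic transmission mode) are the two
#'   regimes of the deprivation assay.
#' @param step_duration step duration (ms), default 800.
#' @param increment current increment (pA), default 10.
#' @param cap search cap (pA), default 500.
#' @param dt step size (ms).
#' @return List with `rheobase` (pA, or `NA` if no spiking up to `cap`),
#'   `holding_current` (pA) and `n_spikes` at the returned step.
#' @export
rheobase <- function(params, holding_v = -65, step_duration = 800,
                     increment = 10, cap = 500, dt = 0.025) {
  stopifnot(increment > 0)
  bias <- find_holding_current(params, holding_v)
  for (amp in seq(increment, cap, by = increment)) {
    tr <- simulate_current_clamp(
      params, step_protocol(amp, step_duration, pre = 100, post = 100,
                            holding_bias = bias, dt = dt))
    n <- length(detect_spikes(tr))
    if (n >= 1)
      return(list(rheobase = amp, holding_current = bias, n_spikes = n))
  }
  list(rheobase = NA_real_, holding_current = bias, n_spikes = 0L)
}

#' Input resistance from a small hyperpolarizing pulse
#'
#' Steady-state voltage deflection divided by the injected current, with
#' the deflection averaged over the last 50 ms of the pulse (typical
#' probe: -20 pA for 250 ms).  Spikes during the pulse invalidate the
#' measurement.
#'
#' @param trace a current-clamp `trace` carrying step metadata (as
#'   produced by simulating a [step_protocol()]).
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(trace) {
  onset <- attr(trace, "step_onset")
  dur <- attr(trace, "step_duration")
  amp <- attr(trace, "step_amplitude")
  if (is.null(onset) || is.null(dur) || is.null(amp) || amp == 0)
    stop("trace lacks step metadata required for input resistance",
         call. = FALSE)
  if (length(detect_spikes(trace)) > 0)
    stop("spikes during the pulse invalidate the input-resistance ",
         "measurement", call. = FALSE)
  t <- trace$t; v <- trace$v_soma
  base <- mean(v[t < onset])
  stead <- mean(v[t >= onset + dur - 50 & t < onset + dur])
  # mV / pA = GOhm; report MOhm
  1000 * (stead - base) / amp
}

#' Early firing adaptation: ISI2 - ISI1
#'
#' Difference between the second and the first interspike interval;
#' negative values mean the train accelerates (the signature seen after
#' deprivation), positive values mean it slows down.
#'
#' @param spike_times spike times (ms) from [detect_spikes()].
#' @return ISI2 - ISI1 (ms), or `NA` with fewer than 3 spikes.
#' @export
isi_adaptation <- function(spike_times) {
  if (length(spike_times) < 3) return(NA_real_)
  isi <- diff(spike_times)
  isi[2] - isi[1]
}

#' First-spike latency (optionally after the initial burst)
#'
#' Latency from stimulus onset to the first spike; with
#' `skip_initial_burst = TRUE` the initial group of spikes whose
#' interspike intervals fall below `burst_isi_cut` (the low-threshold
#' T-type burst) is skipped and the latency of the first spike after it
#' is returned.
#'
#' @param trace a current-clamp `trace`, or `NULL` if `spike_times` given.
#' @param stim_onset stimulus onset time (ms); taken from the trace's
#'   step metadata when omitted.
#' @param skip_initial_burst logical, default `FALSE`.
#' @param burst_isi_cut burst/tonic ISI cut (ms), default 20.
#' @param spike_times optionally precomputed spike times.
#' @return Latency (ms), or `NA` if no qualifying spike.
#' @export
first_spike_latency <- function(trace = NULL, stim_onset = NULL,
                                skip_initial_burst = FALSE,
                                burst_isi_cut = 20, spike_times = NULL) {
  if (is.null(spike_times)) spike_times <- detect_spikes(trace)
  if (is.null(stim_onset)) stim_onset <- attr(trace, "step_onset")
  stopifnot(!is.null(stim_onset))
  st <- spike_times[spike_times >= stim_onset]
  if (!length(st)) return(NA_real_)
  if (!skip_initial_burst) return(st[1] - stim_onset)
  # walk past the initial burst: spikes chained by ISIs < burst_isi_cut
  i <- 1L
  while (i < length(st) && (st[i + 1] - st[i]) < burst_isi_cut) i <- i + 1L
  # st[i] is the last spike of the initial burst; the next spike is the
  # first post-burst spike.  A single-spike "burst" counts as tonic when
  # no burst companion exists.
  if (i == 1L && (length(st) == 1L ||
                  (length(st) > 1L && st[2] - st[1] >= burst_isi_cut)))
    return(st[1] - stim_onset)
  if (i >= length(st)) return(NA_real_)
  st[i + 1] - stim_onset
}

#' Latency jitter (standard error over repeats)
#'
#' @param latencies first-spike latencies over repeated identical
#'   stimuli (ms), length >= 2.
#' @return Standard error of the sample (ms).
#' @export
jitter_se <- function(latencies) {
  stopifnot(length(latencies) >= 2)
  stats::sd(latencies) / sqrt(length(latencies))
}

#' Excitability change between two sweep windows
#'
#' Ratio of mean spike counts, expressed in percent of the control
#' window — the measure of intrinsic-excitability potentiation (LTP-IE
#' magnitude; e.g. 200 means a doubling of the spike count).
#'
#' @param before_counts,after_counts spike counts per sweep in the
#'   control and the post-induction window.
#' @return 100 * mean(after) / mean(before) (%), `NA` if the control
#'   mean is zero.
#' @export
excitability_change <- function(before_counts, after_counts) {
  stopifnot(length(before_counts) >= 1, length(after_counts) >= 1)
  mb <- mean(before_counts)
  if (mb == 0) return(NA_real_)
  100 * mean(after_counts) / mb
}

#' Extract the standard feature vector from a step response
#'
#' Convenience wrapper computing spike count, amplitude, latencies,
#' threshold and adaptation from a single current-step trace.
#'
#' @param trace a current-clamp `trace` from a [step_protocol()].
#' @param detect_v,refractory spike-detector settings.
#' @param burst_isi_cut burst/tonic ISI cut (ms).
#' @param dvdt_criterion threshold criterion (mV/ms).
#' @return Named list: `ap_count`, `ap_amplitude` (mean peak, mV),
#'   `first_spike_latency`, `latency_after_burst`, `isi_diff`,
#'   `threshold_v`, `resting_v` (pre-step baseline).
#' @export
extract_features <- function(trace, detect_v = 0, refractory = 2,
                             burst_isi_cut = 20, dvdt_criterion = 20) {
  onset <- attr(trace, "step_onset")
  dur <- attr(trace, "step_duration")
  st <- detect_spikes(trace, detect_v, refractory)
  st_in <- st[st >= onset & st < onset + dur]
  amp <- if (length(st_in)) {
    dt <- trace$t[2] - trace$t[1]
    peaks <- vapply(st_in, function(ts) {
      i <- which.min(abs(trace$t - ts))
      max(trace$v_soma[i:min(length(trace$v_soma), i + round(3 / dt))])
    }, 1.0)
    mean(peaks)
  } else NA_real_
  thr <- if (length(st_in))
    spike_threshold(trace, st_in[1], dvdt_criterion) else NA_real_
  list(
    ap_count = length(st_in),
    ap_amplitude = amp,
    first_spike_latency = first_spike_latency(trace, onset,
                                              spike_times = st_in),
    latency_after_burst = first_spike_latency(trace, onset,
                                              skip_initial_burst = TRUE,
                                              burst_isi_cut = burst_isi_cut,
                                              spike_times = st_in),
    isi_diff = isi_adaptation(st_in),
    threshold_v = thr,
    resting_v = mean(trace$v_soma[trace$t < onset])
  )
}
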