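# Small cells built in code for unit tests.

# Passive soma (leak only), axon leak 0 and near-zero coupling, so the
# soma behaves as a single RC compartment with R = 1/g_leak.
passive_cell <- function(g_leak = 2, e_leak = -76, c_soma = 60,
                         g_couple = 1e-6) {
  ch <- default_channels(e_leak = e_leak)
  cell_parameters(
    c(Na = 0, Kdr = 0, A = 0, Kv1 = 0, T = 0, H = 0, leak = g_leak),
    c(Na = 0, Kdr = 0, Kv1 = 0, leak = 0),
    c_soma = c_soma, c_axon = 15, g_couple = g_couple, channels = ch)
}

# Minimal tonically spiking cell (Na + Kdr + leak in the soma).
spiker_cell <- function(g_na = 600, g_kdr = 150, g_leak = 2,
                        e_leak = -75) {
  ch <- default_channels(e_leak = e_leak)
  cell_parameters(
    c(Na = g_na, Kdr = g_kdr, A = 0, Kv1 = 0, T = 0, H = 0, leak = g_leak),
    c(Na = 0, Kdr = 0, Kv1 = 0, leak = 0.5),
    c_soma = 60, c_axon = 15, g_couple = 15, channels = ch)
}

# Synthetic trace with stereotyped spike waveforms at known times.
synthetic_spike_trace <- function(spike_times, total = 500, dt = 0.1,
                                  v_rest = -76) {
  t <- seq(0, total, by = dt)
  v <- rep(v_rest, length(t))
  for (ts in spike_times) {
    idx <- which(t >= ts & t < ts + 2)          # 2-ms triangular spike
    half <- length(idx) / 2
    v[idx] <- v_rest + (100 - abs(seq_along(idx) - half) * 100 / half)
  }
  structure(data.frame(t = t, v_soma = v, v_axon = v),
            class = c("trace", "data.frame"), dt = dt,
            mode = "current_clamp", step_onset = 0, step_duration = total,
            step_amplitude = 1, holding_bias = 0)
}
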