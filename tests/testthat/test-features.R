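test_that("spike detection recovers constructed spike times", {
  # construction oracle: stereotyped waveforms at known times
  times <- c(50, 120, 127, 300)
  tr <- synthetic_spike_trace(times)
  st <- detect_spikes(tr)
  expect_equal(length(st), length(times))
  expect_true(all(abs(st - times) <= 2 * attr(tr, "dt") + 1))
  # constant trace yields no events
  flat <- synthetic_spike_trace(numeric(0))
  expect_identical(detect_spikes(flat), numeric(0))
  # refractory filtering: events closer than the refractory are merged
  tr2 <- synthetic_spike_trace(c(100, 103, 106, 200))
  expect_equal(length(detect_spikes(tr2, refractory = 5)), 3)
})

test_that("phase-plot threshold finds a constructed knee and rejects ramps", {
  dt <- 0.05
  t <- seq(0, 50, by = dt)
  knee_t <- 30; knee_v <- -45
  v <- ifelse(t < knee_t, -70 + (t / knee_t) * 25,        # 0.83 mV/ms
              pmin(40, knee_v + (t - knee_t) * 60))       # 60 mV/ms
  tr <- structure(data.frame(t = t, v_soma = v, v_axon = v),
                  class = c("trace", "data.frame"), dt = dt,
                  mode = "current_clamp")
  st <- detect_spikes(tr)
  thr <- spike_threshold(tr, st[1], dvdt_criterion = 20, window = 40)
  expect_equal(thr, knee_v, tolerance = 1)
  ramp <- structure(data.frame(t = t, v_soma = -70 + 0.5 * t),
                    class = c("trace", "data.frame"), dt = dt)
  expect_error(spike_threshold(ramp, 40, dvdt_criterion = 20),
               "malformed spike")
})

test_that("threshold on the reference model is robust to sampling rate", {
  p <- set_conductance(reference_cell(), Kv1_soma = 0, Kv1_axon = 0)
  thr_at <- function(dt) {
    tr <- simulate_current_clamp(p, step_protocol(47, 400, pre = 100,
                                                  post = 50, dt = dt))
    spike_threshold(tr, detect_spikes(tr)[1])
  }
  expect_lt(abs(thr_at(0.025) - thr_at(0.0125)), 0.5)
})

test_that("ISI adaptation is the plain ISI2 - ISI1 difference", {
  expect_equal(isi_adaptation(c(0, 100, 200)), 0)
  expect_equal(isi_adaptation(c(0, 100, 150)), -50)
  expect_true(is.na(isi_adaptation(c(0, 100))))
})

test_that("first-spike latency handles bursts and degenerate cases", {
  mk <- function(times) synthetic_spike_trace(times, total = 400)
  expect_lt(abs(first_spike_latency(mk(120), stim_onset = 0) - 120), 1.5)
  # burst at 5/10/15 then tonic spike at 180: skip flag returns 180
  tr <- mk(c(5, 10, 15, 180))
  expect_lt(abs(first_spike_latency(tr, 0, skip_initial_burst = TRUE,
                                    burst_isi_cut = 20) - 180), 1.5)
  expect_lt(abs(first_spike_latency(tr, 0) - 5), 1.5)
  # burst only, no tonic spike: undefined, not an error
  expect_true(is.na(first_spike_latency(mk(c(5, 10, 15)), 0,
                                        skip_initial_burst = TRUE)))
  # no spikes at all
  expect_true(is.na(first_spike_latency(mk(numeric(0)), 0)))
  # lone first spike followed by tonic train counts as tonic
  expect_lt(abs(first_spike_latency(mk(c(100, 200, 300)), 0,
                                    skip_initial_burst = TRUE) - 100), 1.5)
})

test_that("jitter is the standard error of the latency sample", {
  expect_equal(jitter_se(c(10, 10, 10)), 0)
  expect_equal(jitter_se(c(10, 20, 30)), 10 / sqrt(3))
  expect_error(jitter_se(10))
})

test_that("excitability change is a ratio of window means in percent", {
  expect_equal(excitability_change(c(3, 3, 3), c(3, 3, 3)), 100)
  expect_equal(excitability_change(c(3), c(6)), 200)
  expect_equal(excitability_change(c(2, 4, 3), c(6, 5, 7)),
               excitability_change(c(4, 3, 2), c(7, 6, 5)))
  expect_true(is.na(excitability_change(c(0, 0), c(3))))
})

test_that("input resistance matches R = 1/g on a passive cell and is linear", {
  p <- passive_cell(g_leak = 2)
  rin_at <- function(amp) input_resistance(simulate_current_clamp(
    p, step_protocol(amp, 250, pre = 200, post = 50)))
  expect_equal(rin_at(-20), 500, tolerance = 0.01)
  expect_lt(abs(rin_at(-10) - rin_at(-20)) / rin_at(-20), 0.05)
})

test_that("input resistance refuses traces with spikes or no metadata", {
  p <- spiker_cell()
  tr <- simulate_current_clamp(p, step_protocol(100, 250, pre = 100,
                                                post = 50))
  expect_error(input_resistance(tr), "spikes")
  flat <- synthetic_spike_trace(numeric(0))
  attr(flat, "step_amplitude") <- NULL
  expect_error(input_resistance(flat), "metadata")
})

test_that("rheobase equals a brute-force 1-pA scan rounded up to the grid", {
  p <- spiker_cell()
  res <- rheobase(p, holding_v = -65, step_duration = 400, increment = 10,
                  cap = 200)
  # brute force at 1-pA resolution from the same holding current
  bias <- res$holding_current
  fine <- NA
  for (amp in seq(1, 200, by = 1)) {
    tr <- simulate_current_clamp(p, step_protocol(amp, 400, pre = 100,
                                                  post = 100,
                                                  holding_bias = bias))
    if (length(detect_spikes(tr)) >= 1) { fine <- amp; break }
  }
  expect_false(is.na(res$rheobase))
  expect_equal(res$rheobase, 10 * ceiling(fine / 10))
})

test_that("rheobase reports an explicit undefined result at the cap", {
  p <- passive_cell(g_leak = 2)
  res <- rheobase(p, holding_v = -70, step_duration = 200, increment = 50,
                  cap = 100)
  expect_true(is.na(res$rheobase))
  expect_equal(res$n_spikes, 0L)
})

test_that("feature extraction is invariant to integer-factor resampling", {
  p <- set_conductance(reference_cell(), Kv1_soma = 0, Kv1_axon = 0)
  tr <- simulate_current_clamp(p, step_protocol(47, 600, pre = 100,
                                                post = 50, dt = 0.025))
  # resample the same trace by an integer factor of 4 (dt 0.025 -> 0.1)
  down <- structure(as.data.frame(tr)[seq(1, nrow(tr), by = 4), ],
                    class = c("trace", "data.frame"), dt = 0.1,
                    mode = "current_clamp", step_onset = 100,
                    step_duration = 600, step_amplitude = 47,
                    holding_bias = 0)
  a <- extract_features(tr); b <- extract_features(down)
  expect_equal(a$ap_count, b$ap_count)
  expect_lt(abs(a$first_spike_latency - b$first_spike_latency), 2)
  expect_lt(abs(a$threshold_v - b$threshold_v), 1)
})
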