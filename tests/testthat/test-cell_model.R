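test_that("passive step response matches the RC closed form to < 1%", {
  g <- 2; C <- 60
  p <- passive_cell(g_leak = g, c_soma = C)
  tau <- C / g                       # ms
  dI <- 10
  tr <- simulate_current_clamp(p, step_protocol(dI, 10 * tau, pre = 50,
                                                post = 0))
  on <- tr$t >= 50
  t_rel <- tr$t[on] - 50
  v_exact <- -76 + (dI / g) * (1 - exp(-t_rel / tau))
  amp <- dI / g
  expect_lt(max(abs(tr$v_soma[on] - v_exact)), 0.01 * amp)
  # steady-state amplitude itself (converged after 10 tau)
  expect_equal(max(tr$v_soma) + 76, amp, tolerance = 1e-3)
})

test_that("two-compartment passive steady state matches the linear solve", {
  ch <- default_channels(e_leak = -76)
  gl_s <- 2; gl_a <- 0.5; gc <- 15; I <- 10
  p <- cell_parameters(
    c(Na = 0, Kdr = 0, A = 0, Kv1 = 0, T = 0, H = 0, leak = gl_s),
    c(Na = 0, Kdr = 0, Kv1 = 0, leak = gl_a),
    c_soma = 60, c_axon = 15, g_couple = gc, channels = ch)
  tr <- simulate_current_clamp(p, step_protocol(I, 600, pre = 50, post = 0))
  A <- matrix(c(gl_s + gc, -gc, -gc, gl_a + gc), 2, byrow = TRUE)
  dv <- solve(A, c(I, 0))
  expect_equal(max(tr$v_soma) + 76, dv[1], tolerance = 1e-3)
  expect_equal(max(tr$v_axon) + 76, dv[2], tolerance = 1e-3)
})

test_that("subthreshold integration converges under step halving", {
  p <- reference_cell()
  run <- function(dt) simulate_current_clamp(
    p, step_protocol(13, 600, pre = 100, post = 100, dt = dt))
  a <- run(0.05); b <- run(0.025)
  vb <- b$v_soma[seq(1, nrow(b), by = 2)]
  expect_lt(max(abs(a$v_soma - vb)), 0.5)
})

test_that("spiking protocols keep spike count and times stable under dt refinement", {
  p <- reference_cell()
  run <- function(dt) detect_spikes(simulate_current_clamp(
    set_conductance(p, Kv1_soma = 0, Kv1_axon = 0),
    step_protocol(47, 800, pre = 200, post = 100, dt = dt)))
  a <- run(0.025); b <- run(0.0125)
  expect_equal(length(a), length(b))
  expect_lt(max(abs(a - b)), 5)      # spike-time drift (ms)
})

test_that("simulations are deterministic given (params, protocol, dt)", {
  p <- reference_cell()
  pr <- step_protocol(47, 300, pre = 50, post = 50)
  expect_identical(simulate_current_clamp(p, pr)$v_soma,
                   simulate_current_clamp(p, pr)$v_soma)
})

test_that("settled state balances charge and traces stay finite and bounded", {
  p <- reference_cell()
  tr <- simulate_current_clamp(p, step_protocol(47, 800, pre = 200,
                                                post = 100))
  expect_true(all(is.finite(tr$v_soma)) && all(is.finite(tr$v_axon)))
  expect_true(all(tr$v_soma > -120 & tr$v_soma < 60))
  expect_equal(nrow(tr), 1100 / 0.025 + 1)
  # charge balance at rest: C dV/dt < 0.1 pA after settling
  r <- simulate_current_clamp(p, step_protocol(0, 50, pre = 50, post = 0),
                              settle_ms = 6000)
  dvdt <- abs(diff(r$v_soma[1:5])) / 0.025
  expect_lt(max(dvdt) * p$c_soma, 0.1)
})

test_that("voltage clamp reproduces passive currents and the rest definition", {
  p <- passive_cell(g_leak = 2)
  tr0 <- simulate_voltage_clamp(p, vclamp_protocol(-76, -76, 200,
                                                   pre = 50, post = 10))
  expect_lt(max(abs(tr0$i_clamp[tr0$t > 100])), 1e-6)
  tr <- simulate_voltage_clamp(p, vclamp_protocol(-76, -66, 300,
                                                  pre = 50, post = 10))
  steady <- mean(tr$i_clamp[tr$t > 300 & tr$t < 349])
  expect_equal(steady, 2 * 10, tolerance = 1e-3)
})

test_that("voltage-clamp steady current equals the per-channel summation", {
  # Na and T silenced so the unclamped axon cannot fire during the step
  p <- set_conductance(reference_cell(), Na_soma = 0, Na_axon = 0,
                       T_soma = 0)
  v_to <- -50
  tr <- simulate_voltage_clamp(p, vclamp_protocol(-80, v_to, 4000),
                               settle_ms = 4000)
  steady <- mean(tr$i_clamp[tr$t > 4050 & tr$t < 4099])
  # independent oracle: sum of channel_current at v_to with steady-state
  # gates, plus coupling to the axon's own steady state (root-solved)
  ion <- function(v, g) {
    sum(vapply(names(g), function(nm) {
      s <- p$channels[[nm]]
      m <- if (s$p > 0) steady_state(s, "activation", v) else 1
      h <- if (s$q > 0) steady_state(s, "inactivation", v) else 1
      channel_current(s, v, g[[nm]], m, h)
    }, 1.0))
  }
  ax_res <- function(va) ion(va, p$g_axon) + p$g_couple * (va - v_to)
  va <- uniroot(ax_res, c(-90, -30), tol = 1e-9)$root
  oracle <- ion(v_to, p$g_soma) + p$g_couple * (v_to - va)
  expect_equal(steady, oracle, tolerance = 0.02)
})

test_that("holding-current search matches analytic values on a passive cell", {
  g <- 2
  p <- passive_cell(g_leak = g)
  expect_equal(find_holding_current(p, -76 + 5), 5 * g, tolerance = 0.05)
  expect_lt(abs(find_holding_current(p, -76)), 0.5)
})

test_that("integration failure reports the first bad time step", {
  ch <- default_channels(e_leak = -75)
  p <- cell_parameters(
    c(Na = 5e4, Kdr = 0, A = 0, Kv1 = 0, T = 0, H = 0, leak = 2),
    c(Na = 0, Kdr = 0, Kv1 = 0, leak = 0.5),
    c_soma = 1, c_axon = 1, g_couple = 15, channels = ch)
  expect_error(
    simulate_current_clamp(p, step_protocol(200, 100, pre = 10, post = 0,
                                            dt = 1), settle_ms = 50),
    "integration failure")
})

test_that("traces round-trip through delimited text at stored precision", {
  p <- passive_cell()
  tr <- simulate_current_clamp(p, step_protocol(-20, 250, pre = 100,
                                                post = 50, dt = 0.1))
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$v_soma, tr$v_soma, tolerance = 1e-12)
  expect_equal(attr(back, "step_amplitude"), -20)
  expect_equal(attr(back, "dt"), 0.1)
})

test_that("cell parameters round-trip through YAML", {
  p <- reference_cell()
  path <- tempfile(fileext = ".yaml")
  write_cell(p, path)
  back <- read_cell(path)
  expect_equal(back$g_soma, p$g_soma)
  expect_equal(back$g_axon, p$g_axon)
  expect_equal(back$c_soma, p$c_soma)
  expect_equal(back$channels$Kv1$v_half_act, p$channels$Kv1$v_half_act)
})

test_that("localization constraints are enforced", {
  ch <- default_channels()
  expect_error(cell_parameters(
    c(Na = 100, Kdr = 50, A = 10, Kv1 = 10, T = 5, H = 1, leak = -1),
    c(Na = 100, Kdr = 50, Kv1 = 10, leak = 0.5), channels = ch))
  p <- cell_parameters(
    c(Na = 100, Kdr = 50, A = 10, Kv1 = 10, T = 5, H = 1, leak = 1),
    c(Na = 100, Kdr = 50, Kv1 = 10, A = 7, leak = 0.5), channels = ch)
  expect_equal(p$g_axon[["A"]], 0)   # A is somato-dendritic only
})
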