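test_that("steady-state gating follows the Boltzmann sigmoid", {
  ch <- default_channels()
  for (spec in ch[c("Na", "Kdr", "A", "Kv1", "T")]) {
    expect_equal(steady_state(spec, "activation", spec$v_half_act), 0.5)
    expect_equal(steady_state(spec, "activation", 1e3), 1, tolerance = 1e-6)
    expect_equal(steady_state(spec, "activation", -1e3), 0,
                 tolerance = 1e-6)
  }
  # independent arithmetic oracle one slope above the midpoint
  kv1 <- ch$Kv1
  expect_equal(steady_state(kv1, "activation",
                            kv1$v_half_act + kv1$slope_act),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(1 / (1 + exp(-1)), 0.7310586, tolerance = 1e-6)
})

test_that("requesting a gate a current lacks is a configuration error", {
  ch <- default_channels()
  expect_error(steady_state(ch$Kdr, "inactivation", -60), "no inactivation")
  expect_error(time_constant(ch$H, "activation", -60), "no activation")
  expect_error(steady_state(ch$leak, "activation", -60), "no activation")
})

test_that("activation curves are monotone and gates bounded on a 1-mV grid", {
  v <- seq(-120, 40, by = 1)
  ch <- default_channels()
  for (spec in ch[c("Na", "Kdr", "A", "Kv1", "T")]) {
    act <- steady_state(spec, "activation", v)
    expect_true(all(act >= 0 & act <= 1))
    expect_true(all(diff(act) > 0))
    if (spec$q > 0) {
      inact <- steady_state(spec, "inactivation", v)
      expect_true(all(inact >= 0 & inact <= 1))
      expect_true(all(diff(inact) < 0))
    }
  }
})

test_that("time constants are positive and follow the Q10 law", {
  ch <- default_channels()
  v <- seq(-120, 40, by = 1)
  for (spec in ch[c("Na", "Kdr", "A", "Kv1", "T", "H")]) {
    gate <- if (spec$p > 0) "activation" else "inactivation"
    tau <- time_constant(spec, gate, v)
    expect_true(all(tau > 0))
  }
  # q10 = 3, ten degrees above reference divides tau by 3
  s <- channel_spec("Kdr", p = 4L, v_half_act = -33, slope_act = 9,
                    tau_act = c(0.8, 5, -50, 20, 20), e_rev = -90,
                    q10 = 3, t_ref = 30)
  expect_equal(time_constant(s, "activation", -55, 40),
               time_constant(s, "activation", -55, 30) / 3)
  # arbitrary v equals direct evaluation of the documented tau expression
  tp <- s$tau_act; v0 <- -47.3
  expect_equal(time_constant(s, "activation", v0, 30),
               tp[1] + tp[2] / (exp((v0 - tp[3]) / tp[4]) +
                                exp(-(v0 - tp[3]) / tp[5])))
})

test_that("q10 = 1 makes simulations temperature-invariant", {
  ch <- lapply(default_channels(e_leak = -75), function(s) {
    s$q10 <- 1
    s
  })
  mk <- function(temp) cell_parameters(
    c(Na = 600, Kdr = 150, A = 0, Kv1 = 0, T = 0, H = 0, leak = 2),
    c(Na = 0, Kdr = 0, Kv1 = 0, leak = 0.5),
    channels = ch, temperature = temp)
  pr <- step_protocol(60, 200, pre = 50, post = 20)
  expect_identical(simulate_current_clamp(mk(30), pr)$v_soma,
                   simulate_current_clamp(mk(20), pr)$v_soma)
})

test_that("channel current obeys Ohm's law and flags bad gate states", {
  na <- default_channels()$Na
  expect_equal(channel_current(na, v = -20, g_max = 0, m = 1, h = 1), 0)
  expect_equal(channel_current(na, v = na$e_rev, g_max = 10, m = 1, h = 1),
               0)
  kdr <- default_channels()$Kdr
  expect_equal(channel_current(kdr, v = kdr$e_rev + 10, g_max = 10, m = 1),
               100)
  expect_error(channel_current(na, v = 0, g_max = 1, m = 1.2),
               "integration fault")
})

test_that("channel specs round-trip through YAML with units in file", {
  ch <- default_channels()
  path <- tempfile(fileext = ".yaml")
  write_channels(ch, path)
  txt <- readLines(path)
  expect_true(any(grepl("mV", txt)) && any(grepl("nS", txt)))
  back <- read_channels(path)
  expect_equal(names(back), names(ch))
  expect_equal(back$Kv1$v_half_act, ch$Kv1$v_half_act)
  expect_equal(back$T$tau_inact, ch$T$tau_inact)
  expect_equal(back$leak$p + back$leak$q, 0L)
})
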