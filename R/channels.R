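#' Define an ionic current (Hodgkin-Huxley gating scheme)
#'
#' A `channel_spec` describes one voltage-gated (or leak) current as
#' Boltzmann steady-state gating with bell-shaped voltage-dependent time
#' constants and Q10 temperature scaling.  The membrane current is
#' \deqn{I = \bar g \, m^p h^q (V - E_{rev})}
#' in pA for \eqn{\bar g} in nS and voltages in mV; positive current is
#' outward.  Steady states follow
#' \eqn{x_\infty(V) = 1/(1 + \exp(-(V - V_{1/2})/k))}: a positive slope
#' \eqn{k} gives a gate that opens with depolarization (activation), a
#' negative slope one that closes with depolarization (inactivation, and
#' the HCN gate which opens on hyperpolarization).  Time constants follow
#' \deqn{\tau(V) = \tau_{min} + \tau_{amp} / (e^{(V-V_\tau)/k_1} + e^{-(V-V_\tau)/k_2})}
#' scaled by \eqn{Q_{10}^{(T_{ref} - T)/10}}.
#'
#' @param name channel identifier, one of `"Na"`, `"Kdr"`, `"A"`, `"Kv1"`,
#'   `"T"`, `"H"`, `"leak"` (free-form names are allowed for extensions).
#' @param p,q integer activation / inactivation exponents (both 0 for leak).
#' @param v_half_act,slope_act activation Boltzmann midpoint and slope (mV);
#'   `slope_act` must be positive.
#' @param tau_act numeric vector `c(min, amp, v, k1, k2)` for the activation
#'   time constant (ms, ms, mV, mV, mV).
#' @param v_half_inact,slope_inact inactivation Boltzmann midpoint and slope
#'   (mV); `slope_inact` must be negative (gate closes with depolarization).
#' @param tau_inact as `tau_act`, for the inactivation gate.
#' @param e_rev reversal potential (mV).
#' @param q10 temperature coefficient (> 0); `q10 = 1` makes kinetics
#'   temperature-invariant.
#' @param t_ref reference temperature (degrees C) at which the stated time
#'   constants apply.
#' @return An object of class `channel_spec`.
#' @seealso [steady_state()], [time_constant()], [channel_current()],
#'   [default_channels()]
#' @export
channel_spec <- function(name, p = 0L, q = 0L,
                         v_half_act = NA_real_, slope_act = NA_real_,
                         tau_act = NULL,
                         v_half_inact = NA_real_, slope_inact = NA_real_,
                         tau_inact = NULL,
                         e_rev = 0, q10 = 3, t_ref = 30) {
  p <- as.integer(p); q <- as.integer(q)
  stopifnot(p >= 0L, q >= 0L, q10 > 0, is.finite(e_rev))
  if (p > 0L) {
    stopifnot(is.finite(v_half_act), is.finite(slope_act), slope_act != 0,
              length(tau_act) == 5L, all(is.finite(tau_act)),
              tau_act[1] > 0, tau_act[2] >= 0)
    if (slope_act < 0 && !identical(name, "H"))
      warning("activation slope < 0: gate closes with depolarization")
  }
  if (q > 0L) {
    stopifnot(is.finite(v_half_inact), is.finite(slope_inact),
              slope_inact != 0,
              length(tau_inact) == 5L, all(is.finite(tau_inact)),
              tau_inact[1] > 0, tau_inact[2] >= 0)
  }
  structure(list(name = name, p = p, q = q,
                 v_half_act = v_half_act, slope_act = slope_act,
                 tau_act = as.numeric(tau_act),
                 v_half_inact = v_half_inact, slope_inact = slope_inact,
                 tau_inact = as.numeric(tau_inact),
                 e_rev = e_rev, q10 = q10, t_ref = t_ref),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> %s  m^%d h^%d  E_rev = %g mV  Q10 = %g @ %g C\n",
              x$name, x$p, x$q, x$e_rev, x$q10, x$t_ref))
  if (x$p > 0)
    cat(sprintf("  activation:   V1/2 = %g mV, k = %g mV\n",
                x$v_half_act, x$slope_act))
  if (x$q > 0)
    cat(sprintf("  inactivation: V1/2 = %g mV, k = %g mV\n",
                x$v_half_inact, x$slope_inact))
  invisible(x)
}

boltzmann <- function(v, vh, k) 1 / (1 + exp(-(v - vh) / k))

`%||%` <- function(a, b) if (is.null(a)) b else a

check_gate <- function(spec, gate) {
  gate <- match.arg(gate, c("activation", "inactivation"))
  n <- if (gate == "activation") spec$p else spec$q
  if (n == 0L)
    stop(sprintf("channel '%s' has no %s gate", spec$name, gate),
         call. = FALSE)
  gate
}

#' Steady-state open fraction of a gate
#'
#' Boltzmann sigmoid of membrane potential; monotone increasing in `v`
#' for activation gates (positive slope), decreasing for gates with a
#' negative slope (inactivation, HCN).
#'
#' @param spec a [channel_spec()].
#' @param gate `"activation"` or `"inactivation"`.
#' @param v membrane potential (mV), vectorised.
#' @return Open fraction in \[0, 1\].
#' @export
steady_state <- function(spec, gate, v) {
  stopifnot(inherits(spec, "channel_spec"), all(is.finite(v)))
  gate <- check_gate(spec, gate)
  if (gate == "activation") boltzmann(v, spec$v_half_act, spec$slope_act)
  else boltzmann(v, spec$v_half_inact, spec$slope_inact)
}

#' Voltage-dependent gating time constant
#'
#' Bell-shaped time constant scaled to `temperature` by
#' \eqn{Q_{10}^{(T_{ref} - T)/10}}.
#'
#' @inheritParams steady_state
#' @param temperature bath temperature (degrees C); default 30, the
#'   recording-chamber temperature the model is parameterized for.
#' @return Time constant in ms (strictly positive), vectorised over `v`.
#' @export
time_constant <- function(spec, gate, v, temperature = 30) {
  stopifnot(inherits(spec, "channel_spec"), all(is.finite(v)))
  gate <- check_gate(spec, gate)
  tp <- if (gate == "activation") spec$tau_act else spec$tau_inact
  tau <- tp[1] + tp[2] / (exp((v - tp[3]) / tp[4]) + exp(-(v - tp[3]) / tp[5]))
  tau * spec$q10^((spec$t_ref - temperature) / 10)
}

#' Instantaneous ohmic channel current
#'
#' \eqn{I = \bar g m^p h^q (V - E_{rev})}; positive current is outward.
#'
#' @inheritParams steady_state
#' @param m,h gate open fractions in \[0, 1\] (ignored when the
#'   corresponding exponent is zero).
#' @param v membrane potential (mV).
#' @param g_max maximal conductance (nS), must be non-negative.
#' @return Current in pA.
#' @export
channel_current <- function(spec, v, g_max, m = 1, h = 1) {
  stopifnot(inherits(spec, "channel_spec"), g_max >= 0)
  if (any(m < 0 | m > 1) || any(h < 0 | h > 1))
    stop("gate state outside [0, 1]: integration fault", call. = FALSE)
  g_max * m^spec$p * h^spec$q * (v - spec$e_rev)
}

#' Default channel inventory of the relay-cell model
#'
#' Seven currents of a thalamocortical relay neuron: transient sodium
#' (`Na`), delayed-rectifier potassium (`Kdr`), A-type potassium (`A`),
#' low-threshold slowly inactivating D-type potassium (`Kv1`),
#' low-threshold T-type calcium (`T`), hyperpolarization-activated cation
#' (`H`) and passive leak (`leak`).  Kinetic constants are
#' literature-derived thalamocortical values expressed in the package's
#' Boltzmann / bell-tau parametric form; maximal conductances are *not*
#' part of the channel specs — they live in [cell_parameters()] and are
#' what calibration estimates.  The T current uses a fixed +120 mV
#' reversal (no intracellular calcium dynamics); the HCN gate is encoded
#' with a negative slope so it opens on hyperpolarization.
#'
#' @param e_leak leak reversal potential (mV).
#' @return Named list of [channel_spec()] objects in canonical order
#'   `Na, Kdr, A, Kv1, T, H, leak`.
#' @export
default_channels <- function(e_leak = -81) {
  list(
    Na = channel_spec("Na", p = 3L, q = 1L,
                      v_half_act = -42.8, slope_act = 5,
                      tau_act = c(0.04, 0.25, -40, 12, 12),
                      v_half_inact = -50, slope_inact = -6,
                      tau_inact = c(0.4, 6, -55, 9, 9),
                      e_rev = 50),
    Kdr = channel_spec("Kdr", p = 4L, q = 0L,
                       v_half_act = -33, slope_act = 9,
                       tau_act = c(1.5, 43, -50, 20, 20),
                       e_rev = -90),
    A = channel_spec("A", p = 4L, q = 1L,
                     v_half_act = -45, slope_act = 8,
                     tau_act = c(0.4, 1.2, -50, 15, 15),
                     v_half_inact = -78, slope_inact = -6,
                     tau_inact = c(20, 60, -78, 10, 10),
                     e_rev = -90),
    Kv1 = channel_spec("Kv1", p = 1L, q = 1L,
                       v_half_act = -44.9, slope_act = 4,
                       tau_act = c(1, 8, -48, 15, 15),
                       v_half_inact = -65, slope_inact = -5,
                       tau_inact = c(150, 240, -55, 15, 15),
                       e_rev = -90),
    T = channel_spec("T", p = 2L, q = 1L,
                     v_half_act = -57, slope_act = 6.2,
                     tau_act = c(0.6, 18, -68, 16.7, 18.2),
                     v_half_inact = -81, slope_inact = -4,
                     tau_inact = c(10, 200, -88, 10, 16),
                     e_rev = 120),
    H = channel_spec("H", p = 0L, q = 1L,
                     v_half_inact = -80, slope_inact = -6,
                     tau_inact = c(200, 1000, -80, 15, 15),
                     e_rev = -43),
    leak = channel_spec("leak", p = 0L, q = 0L, e_rev = e_leak, q10 = 1)
  )
}

# Flatten a channel list into the kinetic matrix the C++ core consumes.
# Absent gates get inert placeholders (never evaluated: exponent 0).
channel_matrix <- function(channels) {
  stopifnot(length(channels) >= 1)
  pad <- function(x, fallback) if (length(x) == 5L && !anyNA(x)) x
                               else fallback
  sc <- function(x, fallback) if (length(x) == 1L && is.finite(x)) x
                              else fallback
  rows <- lapply(channels, function(ch) {
    c(ch$p, ch$q,
      sc(ch$v_half_act, 0), sc(ch$slope_act, 1),
      pad(ch$tau_act, c(1, 0, 0, 10, 10)),
      sc(ch$v_half_inact, 0), sc(ch$slope_inact, -1),
      pad(ch$tau_inact, c(1, 0, 0, 10, 10)),
      ch$e_rev, ch$q10, ch$t_ref)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(channels, `[[`, "", "name")
  m
}

#' Write / read channel definitions as YAML
#'
#' Serializes a channel list with units stated in-file (mV, ms, nS, degC).
#'
#' @param channels named list of [channel_spec()] objects.
#' @param path file path.
#' @return `read_channels()` returns the channel list; `write_channels()`
#'   returns `path` invisibly.
#' @export
write_channels <- function(channels, path) {
  payload <- list(
    units = list(voltage = "mV", time = "ms", conductance = "nS",
                 temperature = "degC"),
    channels = lapply(channels, function(ch) ch[!vapply(ch, is.null, TRUE)])
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_channels
#' @export
read_channels <- function(path) {
  raw <- yaml::read_yaml(path)$channels
  out <- lapply(raw, function(ch) {
    do.call(channel_spec, c(
      list(name = ch$name, p = ch$p, q = ch$q, e_rev = ch$e_rev,
           q10 = ch$q10, t_ref = ch$t_ref),
      if (ch$p > 0) list(v_half_act = ch$v_half_act,
                         slope_act = ch$slope_act,
                         tau_act = unlist(ch$tau_act)),
      if (ch$q > 0) list(v_half_inact = ch$v_half_inact,
                         slope_inact = ch$slope_inact,
                         tau_inact = unlist(ch$tau_inact))))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
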