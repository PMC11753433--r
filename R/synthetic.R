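# Surrogate "recordings": deterministic model traces plus calibrated
# additive Gaussian recording noise, with a ground-truth manifest, so
# feature extraction and parameter recovery are testable without
# laboratory data.

#' Surrogate recording specification
#'
#' @param params ground-truth [cell_parameters()].
#' @param protocol current-clamp [stimulus_protocol()] to sweep.
#' @param noise_sd additive iid Gaussian voltage noise SD (mV), >= 0;
#'   default 0.2, a typical whole-cell recording noise floor.
#' @param n_sweeps number of repeated sweeps, default 1.
#' @param seed master seed; sweep `k` uses stream seed `seed + k - 1`
#'   (counter scheme), so the full sweep set is reproducible and
#'   individual sweeps are independently re-generable.
#' @return Object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(params, protocol, noise_sd = 0.2,
                           n_sweeps = 1L, seed = 1L) {
  stopifnot(inherits(params, "cell_parameters"),
            inherits(protocol, "stimulus_protocol"),
            noise_sd >= 0, n_sweeps >= 1)
  structure(list(params = params, protocol = protocol,
                 noise_sd = noise_sd, n_sweeps = as.integer(n_sweeps),
                 seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Generate surrogate sweeps with known ground truth
#'
#' Simulates the clean model response once and adds per-sweep iid
#' Gaussian noise to both compartment voltages.  With `noise_sd = 0`
#' the sweeps are bit-identical to [simulate_current_clamp()] output.
#'
#' @param spec a [surrogate_spec()].
#' @return List with `sweeps` (list of `trace` objects), `clean` (the
#'   noise-free trace) and `manifest` (one row per sweep: sweep index,
#'   stream seed, noise SD, and the ground-truth gKv1 and passive
#'   parameters).
#' @export
generate_surrogate <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  clean <- simulate_current_clamp(spec$params, spec$protocol)
  n <- nrow(clean)
  sweeps <- vector("list", spec$n_sweeps)
  for (k in seq_len(spec$n_sweeps)) {
    sk <- spec$seed + k - 1L
    tr <- clean
    if (spec$noise_sd > 0) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(sk)
      tr$v_soma <- tr$v_soma + stats::rnorm(n, 0, spec$noise_sd)
      tr$v_axon <- tr$v_axon + stats::rnorm(n, 0, spec$noise_sd)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
    sweeps[[k]] <- tr
  }
  manifest <- data.frame(
    sweep = seq_len(spec$n_sweeps),
    stream_seed = spec$seed + seq_len(spec$n_sweeps) - 1L,
    noise_sd = spec$noise_sd,
    gkv1_soma = spec$params$g_soma[["Kv1"]],
    gkv1_axon = spec$params$g_axon[["Kv1"]],
    c_soma = spec$params$c_soma,
    c_axon = spec$params$c_axon,
    g_couple = spec$params$g_couple)
  list(sweeps = sweeps, clean = clean, manifest = manifest)
}

#' Write the canonical surrogate fixture suite
#'
#' Generates and writes the standard test set for the four model
#' conditions: excitability steps over `currents` from the resting
#' regime, a -20 pA / 250 ms input-resistance pulse, and a -80 to
#' -50 mV voltage-clamp step family, plus a CSV manifest recording the
#' ground truth for every file.  Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param base calibrated reference cell; default [reference_cell()].
#' @param conditions condition names to cover.
#' @param currents step currents (pA).
#' @param noise_sd recording noise SD (mV); 0 gives clean fixtures.
#' @param seed master seed.
#' @param dt step size (ms); the default 0.1 keeps fixture files small.
#' @return Invisibly, the manifest data frame (also written as
#'   `manifest.csv`).
#' @export
fixture_suite <- function(out_dir, base = reference_cell(),
                          conditions = c("control", "deprived", "dtx",
                                         "ltpie"),
                          currents = c(45, 47, 51, 55, 59),
                          noise_sd = 0, seed = 1L, dt = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(file, kind, cond, amp, feats) {
    rows[[length(rows) + 1]] <<- data.frame(
      file = file, kind = kind, condition = cond,
      amplitude_pA = amp, noise_sd = noise_sd, seed = seed,
      ap_count = feats$ap_count %||% NA_integer_,
      first_spike_latency = feats$first_spike_latency %||% NA_real_,
      resting_v = feats$resting_v %||% NA_real_)
  }
  k <- 0L
  for (cond in conditions) {
    p <- apply_condition(base, cond)
    for (amp in currents) {
      k <- k + 1L
      proto <- step_protocol(amp, 800, pre = 200, post = 100, dt = dt)
      sur <- generate_surrogate(surrogate_spec(p, proto, noise_sd,
                                               seed = seed + k))
      tr <- sur$sweeps[[1]]
      file <- sprintf("%s_step_%dpA.tsv", cond, amp)
      write_trace(tr, file.path(out_dir, file))
      add(file, "step", cond, amp, extract_features(sur$clean))
    }
    # input-resistance pulse
    k <- k + 1L
    proto <- step_protocol(-20, 250, pre = 200, post = 100, dt = dt)
    sur <- generate_surrogate(surrogate_spec(p, proto, noise_sd,
                                             seed = seed + k))
    file <- sprintf("%s_rin_-20pA.tsv", cond)
    write_trace(sur$sweeps[[1]], file.path(out_dir, file))
    add(file, "rin", cond, -20,
        list(resting_v = mean(sur$clean$v_soma[sur$clean$t < 200])))
    # voltage-clamp step family
    for (v_to in c(-60, -55, -50)) {
      tr <- simulate_voltage_clamp(p, vclamp_protocol(-80, v_to, 500,
                                                      dt = dt))
      file <- sprintf("%s_vclamp_%dmV.tsv", cond, v_to)
      write_trace(tr, file.path(out_dir, file))
      add(file, "vclamp", cond, v_to, list())
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
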