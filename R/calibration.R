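# Feature-based model calibration: weighted quadratic feature cost and a
# rand/1/bin differential-evolution optimizer over conductances and
# half-activations.

#' Feature targets for calibration
#'
#' Each row names a measurable feature, the protocol it is measured
#' under, a target value, a weight and a tolerance (the scale of the
#' quadratic penalty).  Supported features: `resting_v` (settled somatic
#' voltage at `bias` pA), `ap_count`, `ap_amplitude`,
#' `first_spike_latency`, `latency_after_burst`, `isi_diff` (all from a
#' step of `amplitude` pA and `duration` ms on top of `bias` pA), and
#' `input_resistance` (pulse of `amplitude`/`duration` at `bias`).
#'
#' @param df data frame with columns `feature`, `target`, `weight`,
#'   `tolerance` and protocol columns `amplitude`, `duration`, `bias`
#'   (NA where not applicable).
#' @return Object of class `feature_targets`.
#' @export
feature_targets <- function(df) {
  df <- as.data.frame(df)
  need <- c("feature", "target", "weight", "tolerance")
  stopifnot(all(need %in% names(df)), all(df$weight > 0),
            all(df$tolerance > 0))
  for (col in c("amplitude", "duration", "bias"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  known <- c("resting_v", "ap_count", "ap_amplitude",
             "first_spike_latency", "latency_after_burst", "isi_diff",
             "input_resistance")
  bad <- setdiff(df$feature, known)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  structure(df, class = c("feature_targets", "data.frame"))
}

# Evaluate one named feature on a candidate cell.  Returns NA on
# simulation failure (feature_cost converts that to the penalty).
measure_feature <- function(params, feature, amplitude = NA, duration = NA,
                            bias = NA, dt = 0.025) {
  bias <- if (is.na(bias)) 0 else bias
  tryCatch({
    if (feature == "resting_v")
      return(resting_potential(params, bias))
    dur <- if (is.na(duration)) 800 else duration
    tr <- simulate_current_clamp(
      params, step_protocol(amplitude, dur, pre = 200, post = 100,
                            holding_bias = bias, dt = dt))
    if (feature == "input_resistance") return(input_resistance(tr))
    fv <- extract_features(tr)
    fv[[feature]]
  }, error = function(e) NA_real_)
}

#' Weighted quadratic feature cost
#'
#' \eqn{\sum_i w_i ((f_i - t_i)/s_i)^2} over the target rows, with
#' \eqn{s_i} the per-row tolerance.  A failed simulation or an undefined
#' feature contributes a fixed penalty of `1e6` per row, so the
#' optimizer is steered away from pathological parameter sets rather
#' than aborted.
#'
#' @param candidate a [cell_parameters()] object.
#' @param targets a [feature_targets()] table.
#' @param penalty cost charged per unmeasurable row.
#' @return Non-negative scalar.
#' @export
feature_cost <- function(candidate, targets, penalty = 1e6) {
  stopifnot(inherits(targets, "feature_targets"))
  total <- 0
  for (i in seq_len(nrow(targets))) {
    row <- targets[i, ]
    f <- measure_feature(candidate, row$feature, row$amplitude,
                         row$duration, row$bias)
    total <- total +
      if (is.na(f)) penalty
      else row$weight * ((f - row$target) / row$tolerance)^2
  }
  total
}

# Substitute a named parameter vector into a base cell.  Recognized names:
#   "<chan>_soma", "<chan>_axon"      maximal conductance (nS)
#   "c_soma", "c_axon", "g_couple"    passive parameters
#   "v_half_act_<chan>", "v_half_inact_<chan>"  Boltzmann midpoints (mV)
#   "e_leak"                          leak reversal (mV)
apply_param_vector <- function(params, values) {
  nm <- names(values)
  stopifnot(!is.null(nm), all(nzchar(nm)))
  for (i in seq_along(values)) {
    key <- nm[i]; val <- values[[i]]
    if (key %in% c("c_soma", "c_axon", "g_couple")) {
      params[[key]] <- val
    } else if (key == "e_leak") {
      params$channels$leak$e_rev <- val
    } else if (grepl("^v_half_(act|inact)_", key)) {
      ch <- sub("^v_half_(act|inact)_", "", key)
      fld <- if (grepl("^v_half_act_", key)) "v_half_act" else "v_half_inact"
      stopifnot(ch %in% names(params$channels))
      params$channels[[ch]][[fld]] <- val
    } else if (grepl("_(soma|axon)$", key)) {
      ch <- sub("_(soma|axon)$", "", key)
      side <- if (grepl("_soma$", key)) "g_soma" else "g_axon"
      stopifnot(ch %in% names(params[[side]]))
      params[[side]][[ch]] <- max(0, val)
    } else stop("unrecognized parameter name: ", key)
  }
  cell_parameters(params$g_soma, params$g_axon, params$c_soma,
                  params$c_axon, params$g_couple, params$channels,
                  params$temperature)
}

#' Differential-evolution optimizer (rand/1/bin)
#'
#' Minimizes `cost` over box bounds with the classic rand/1/bin scheme:
#' mutant \eqn{v = x_{r1} + F (x_{r2} - x_{r3})}, binomial crossover at
#' rate `CR` with one guaranteed mutant coordinate, greedy one-to-one
#' selection.  The incumbent best is never replaced by a worse vector,
#' so the reported best cost is non-increasing across generations.
#' Fully reproducible given `seed`.
#'
#' @param bounds 2-column matrix (lower, upper), one row per parameter,
#'   with row names naming the parameters.
#' @param cost function mapping a named numeric vector to a scalar cost.
#' @param seed integer RNG seed.
#' @param population population size (>= 4), default 40.
#' @param generations number of generations, default 100.
#' @param F,CR mutation factor and crossover rate, defaults 0.8 / 0.9.
#' @return Object of class `fit_result`: `par` (best vector), `cost`,
#'   `history` (best cost per generation, non-increasing), `seed`,
#'   `n_eval`.
#' @export
fit_de <- function(bounds, cost, seed = 1L, population = 40L,
                   generations = 100L, F = 0.8, CR = 0.9) {
  bounds <- as.matrix(bounds)
  stopifnot(ncol(bounds) == 2, all(bounds[, 1] <= bounds[, 2]),
            population >= 4)
  d <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  nm <- rownames(bounds)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pop <- matrix(stats::runif(population * d, lo, hi), nrow = population,
                byrow = TRUE)
  costs <- apply(pop, 1, function(x) cost(setNames(x, nm)))
  n_eval <- population
  history <- numeric(generations)
  for (g in seq_len(generations)) {
    for (i in seq_len(population)) {
      r <- sample(setdiff(seq_len(population), i), 3)
      v <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
      v <- pmin(pmax(v, lo), hi)
      jr <- sample.int(d, 1)
      cross <- stats::runif(d) < CR
      cross[jr] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      cu <- cost(setNames(u, nm))
      n_eval <- n_eval + 1
      if (cu <= costs[i]) {
        pop[i, ] <- u
        costs[i] <- cu
      }
    }
    history[g] <- min(costs)
  }
  b <- which.min(costs)
  structure(list(par = setNames(pop[b, ], nm), cost = costs[b],
                 history = history, seed = as.integer(seed),
                 n_eval = n_eval),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> cost %.6g after %d evaluations (seed %d)\n",
              x$cost, x$n_eval, x$seed))
  print(round(x$par, 4))
  invisible(x)
}

#' Calibrate a cell against feature targets
#'
#' Differential-evolution fit of a named subset of cell parameters
#' (conductances, passive parameters, half-activations — see
#' [fit_de()] for the naming scheme) to a [feature_targets()] table,
#' starting from `base` for everything not fitted.
#'
#' @param base a [cell_parameters()] object supplying all frozen values.
#' @param bounds named list of `c(lower, upper)` per fitted parameter.
#' @param targets a [feature_targets()] table.
#' @inheritParams fit_de
#' @return A `fit_result`; `$params` holds the best-fit cell.
#' @export
fit_cell <- function(base, bounds, targets, seed = 1L, population = 40L,
                     generations = 100L, F = 0.8, CR = 0.9) {
  bm <- do.call(rbind, bounds)
  rownames(bm) <- names(bounds)
  fr <- fit_de(bm, function(x) feature_cost(apply_param_vector(base, x),
                                            targets),
               seed = seed, population = population,
               generations = generations, F = F, CR = CR)
  fr$params <- apply_param_vector(base, fr$par)
  fr
}
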