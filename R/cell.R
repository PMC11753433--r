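#' Two-compartment relay-cell parameters
#'
#' Geometry-free parameterization of a dLGN relay neuron as two coupled
#' isopotential compartments: a somato-dendritic compartment carrying Na,
#' Kdr, A, Kv1, T, H and leak, and an axonal (AIS) compartment carrying
#' Na, Kdr, Kv1 and leak.  Surface areas are absorbed into capacitances
#' (pF) and absolute conductances (nS).  The A-type current is restricted
#' to the somato-dendritic compartment; T and H likewise (axonal entries
#' are forced to zero).
#'
#' @param g_soma,g_axon named numeric vectors of maximal conductances (nS),
#'   one entry per channel in `channels`.
#' @param c_soma,c_axon compartment capacitances (pF), positive.
#' @param g_couple axial coupling conductance between the compartments (nS).
#' @param channels channel inventory, default [default_channels()].
#' @param temperature bath temperature (degC), default 30.
#' @return Object of class `cell_parameters`.
#' @export
cell_parameters <- function(g_soma, g_axon,
                            c_soma = 60, c_axon = 15, g_couple = 15,
                            channels = default_channels(),
                            temperature = 30) {
  nm <- names(channels)
  stopifnot(c_soma > 0, c_axon > 0, g_couple > 0,
            all(nm %in% names(g_soma)))
  gs <- g_soma[nm]
  ga <- setNames(rep(0, length(nm)), nm)
  ga[names(g_axon)[names(g_axon) %in% nm]] <- g_axon[names(g_axon) %in% nm]
  # axonal compartment carries no A, T or H current
  ga[intersect(c("A", "T", "H"), nm)] <- 0
  if (any(gs < 0) || any(ga < 0)) stop("conductances must be >= 0")
  structure(list(g_soma = gs, g_axon = ga,
                 c_soma = c_soma, c_axon = c_axon, g_couple = g_couple,
                 channels = channels, temperature = temperature),
            class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("<cell_parameters> two-compartment relay cell\n")
  cat(sprintf("  C_soma = %g pF, C_axon = %g pF, g_couple = %g nS, T = %g C\n",
              x$c_soma, x$c_axon, x$g_couple, x$temperature))
  tab <- rbind(soma = x$g_soma, axon = x$g_axon)
  print(round(tab, 2))
  invisible(x)
}

#' Modify maximal conductances of a cell
#'
#' @param params a [cell_parameters()] object.
#' @param ... named updates; each name is `<channel>_soma`, `<channel>_axon`
#'   or `<channel>` (both compartments), value in nS.
#' @return Updated `cell_parameters`.
#' @export
set_conductance <- function(params, ...) {
  upd <- list(...)
  for (key in names(upd)) {
    val <- upd[[key]]
    stopifnot(is.numeric(val), length(val) == 1L, val >= 0)
    if (grepl("_soma$", key)) {
      params$g_soma[sub("_soma$", "", key)] <- val
    } else if (grepl("_axon$", key)) {
      params$g_axon[sub("_axon$", "", key)] <- val
    } else {
      params$g_soma[key] <- val
      if (params$g_axon[key] > 0) params$g_axon[key] <- val
    }
  }
  # re-validate localization constraints
  cell_parameters(params$g_soma, params$g_axon, params$c_soma,
                  params$c_axon, params$g_couple, params$channels,
                  params$temperature)
}

#' Write / read cell parameters as YAML
#'
#' The file is self-contained: it embeds the channel kinetics alongside
#' capacitances, coupling and per-compartment maximal conductances, with
#' units stated in-file.
#'
#' @param params a [cell_parameters()] object.
#' @param path file path.
#' @export
write_cell <- function(params, path) {
  payload <- list(
    units = list(voltage = "mV", time = "ms", conductance = "nS",
                 capacitance = "pF", current = "pA", temperature = "degC"),
    cell = list(c_soma = params$c_soma, c_axon = params$c_axon,
                g_couple = params$g_couple,
                temperature = params$temperature,
                g_soma = as.list(params$g_soma),
                g_axon = as.list(params$g_axon)),
    channels = lapply(params$channels,
                      function(ch) ch[!vapply(ch, is.null, TRUE)])
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_cell
#' @export
read_cell <- function(path) {
  raw <- yaml::read_yaml(path)
  chans <- lapply(raw$channels, function(ch) {
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
  names(chans) <- vapply(chans, `[[`, "", "name")
  cc <- raw$cell
  cell_parameters(g_soma = unlist(cc$g_soma), g_axon = unlist(cc$g_axon),
                  c_soma = cc$c_soma, c_axon = cc$c_axon,
                  g_couple = cc$g_couple, channels = chans,
                  temperature = cc$temperature)
}

#' Calibrated reference relay cell
#'
#' Loads the package's calibrated control-condition parameter fixture:
#' gKv1 = 41.7 nS (soma) / 23 nS (axon), resting near -76 mV with zero
#' injected current, about -69 mV under a +13 pA bias, and three action
#' potentials for a 47 pA / 800 ms step from rest.
#'
#' @return A [cell_parameters()] object.
#' @export
reference_cell <- function() {
  path <- system.file("extdata", "reference_cell.yaml", package = "kv1relay")
  if (!nzchar(path)) stop("reference fixture not found; reinstall package")
  read_cell(path)
}
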