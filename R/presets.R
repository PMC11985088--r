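# Preset channel configurations.
#
# Slow-gate parameterization: given the target stationary open fraction p at
# -160 mV and an effective charge difference dz = z_close - z_open (split
# evenly between the two rates), the 0 mV rate ratio follows from
#   (1 - p)/p = R0 * exp(-160 * dz / V_T),  R0 = kc0 / ko0.
# kc0 (the closing rate at 0 mV) sets the open dwell timescale and is chosen
# so that open dwells stay well above the filter rise time at every protocol
# voltage.

slow_gate_from_po <- function(po_n160, dz, kc0 = 47) {
  r0 <- (1 - po_n160) / po_n160 * exp(160 * dz / THERMAL_MV)
  list(ko0 = kc0 / r0, kc0 = kc0, z_open = -dz / 2, z_close = dz / 2)
}

# Flicker gate shared by most presets: essentially open at positive voltages
# (p_fast > 0.99 above +40 mV), closing increasingly at hyperpolarized
# voltages (p_fast ~ 0.77 at -140 mV), which reproduces the voltage-dependent
# reduction of the apparent amplitude.
default_flicker <- function() {
  list(fast_open_rate0 = 40000, fast_close_rate0 = 800,
       fast_z_open = 0.25, fast_z_close = -0.25)
}

pinned_flicker <- function() {
  list(fast_open_rate0 = 1, fast_close_rate0 = 0,
       fast_z_open = 0, fast_z_close = 0)
}

build_preset <- function(genotype, g, po_n160, dz, flicker = TRUE, kc0 = 47) {
  sg <- slow_gate_from_po(po_n160, dz, kc0)
  fg <- if (flicker) default_flicker() else pinned_flicker()
  gating_model(genotype = genotype, g_true = g,
               slow_open_rate0 = sg$ko0, slow_close_rate0 = sg$kc0,
               slow_z_open = sg$z_open, slow_z_close = sg$z_close,
               fast_open_rate0 = fg$fast_open_rate0,
               fast_close_rate0 = fg$fast_close_rate0,
               fast_z_open = fg$fast_z_open, fast_z_close = fg$fast_z_close)
}

#' Preset channel configurations
#'
#' Ready-made [gating_model()]s reproducing the functional fingerprints of the
#' wild-type channel and three characteristic mutant phenotypes:
#'
#' * `preset_wt()`: 174 pS, weakly voltage-dependent slow gate with
#'   stationary open fractions 0.034 at −160 mV and 0.005 at +160 mV.
#' * `preset_high_po()` (L94C-like): maximal open fraction 0.4 at negative
#'   voltages, conductance unchanged.
#' * `preset_low_po()` (L94M-like): voltage-independent open fraction 0.005,
#'   conductance essentially unchanged.
#' * `preset_low_g()` (L94R-like): conductance 4.3-fold below WT with the
#'   voltage dependence of the open fraction inverted.
#'
#' @param flicker include the fast flicker gate (`FALSE` pins it open, e.g.
#'   for open-probability validation where flicker is not under study).
#' @return a [gating_model()].
#' @export
preset_wt <- function(flicker = TRUE)
  build_preset("WT", 174, 0.034, 0.156278, flicker)

#' @rdname preset_wt
#' @export
preset_high_po <- function(flicker = TRUE)
  build_preset("C", 180, 0.40, 0.35, flicker, kc0 = 40)

#' @rdname preset_wt
#' @export
preset_low_po <- function(flicker = TRUE)
  build_preset("M", 170, 0.005, 0, flicker)

#' @rdname preset_wt
#' @export
preset_low_g <- function(flicker = TRUE)
  build_preset("R", 174 / 4.3, 0.005, -0.156278, flicker)

# genotype, g (pS), slow-gate open fraction at -160 mV, dz: a 20-variant
# panel spanning the observed diversity (conductances ~40-210 pS, open
# fractions ~0.004-0.4, including inverted voltage dependences for the
# cationic substitutions).
PANEL_TABLE <- data.frame(
  genotype = c("WT", "A", "C", "D", "E", "F", "G", "H", "I", "K", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y"),
  g = c(174, 150, 180, 190, 210, 160, 140, 90, 165, 60, 170, 155,
        175, 178, 174 / 4.3, 150, 172, 168, 158, 185),
  po_n160 = c(0.034, 0.010, 0.40, 0.006, 0.012, 0.030, 0.008, 0.020, 0.025,
              0.015, 0.005, 0.004, 0.35, 0.05, 0.005, 0.008, 0.030, 0.020,
              0.012, 0.06),
  dz = c(0.156278, 0.15, 0.35, 0.10, 0.12, 0.15, 0.12, 0.15, 0.16, -0.15, 0,
         0.10, 0.30, 0.15, -0.156278, 0.12, 0.15, 0.14, 0.13, 0.18))

#' Built-in 20-genotype mutant panel
#'
#' One WT reference plus 19 single-residue variants whose conductances and
#' open probabilities span the experimentally observed ranges.  Entries are
#' suitable for [make_panel()].
#'
#' @param expression_factors named or unnamed numeric vector of hidden
#'   per-genotype expression factors (default all 1).
#' @param flicker include the fast flicker gate.
#' @return list of `list(model, expression_factor, wt)` entries.
#' @export
preset_panel <- function(expression_factors = NULL, flicker = TRUE) {
  tab <- PANEL_TABLE
  ef <- expression_factors %||% rep(1, nrow(tab))
  if (!is.null(names(ef))) ef <- ef[tab$genotype]
  stopifnot(length(ef) == nrow(tab), all(ef >= 0))
  lapply(seq_len(nrow(tab)), function(i) {
    kc0 <- if (tab$po_n160[i] >= 0.2) 40 else 47
    list(model = build_preset(tab$genotype[i], tab$g[i], tab$po_n160[i],
                              tab$dz[i], flicker, kc0),
         expression_factor = unname(ef[i]),
         wt = tab$genotype[i] == "WT")
  })
}
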