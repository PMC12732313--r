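#' Published kinetic parameters for TxFKP and BfFKP
#'
#' Reference Michaelis constants and turnover numbers reported for the
#' kinase (C-terminal FUK domain) and pyrophosphorylase (N-terminal GFPP
#' domain) activities of the bifunctional enzymes TxFKP (from
#' *Thermophagus xiamenensis*) and BfFKP (from *Bacteroides fragilis*),
#' together with the published catalytic efficiencies. The BfFKP kinase
#' ATP entry is absent because substrate inhibition by ATP prevented a
#' Michaelis-Menten characterization ("N.D.").
#'
#' `eff_printed`/`eff_sd_printed` carry the published kcat/KM values in
#' M^-1 s^-1; `eff_ulp` is one unit in the last printed digit of the
#' efficiency mantissa (used to check agreement at printed precision).
#'
#' @return a data.frame with one row per enzyme/activity/substrate
#'   combination and columns `enzyme`, `activity`, `substrate`, `km_uM`,
#'   `km_sd`, `kcat`, `kcat_sd`, `eff_printed`, `eff_sd_printed`,
#'   `eff_ulp`.
#' @examples
#' fkp_kinetic_params()
#' @export
fkp_kinetic_params <- function() {
  data.frame(
    enzyme    = c("TxFKP", "TxFKP", "TxFKP", "BfFKP", "BfFKP",
                  "TxFKP", "TxFKP", "BfFKP", "BfFKP"),
    activity  = c(rep("kinase", 5L), rep("pyrophosphorylase", 4L)),
    substrate = c("L-fucose", "D-arabinose", "ATP",
                  "L-fucose", "D-arabinose",
                  "fucose-1-phosphate", "GTP",
                  "fucose-1-phosphate", "GTP"),
    km_uM   = c(77, 1320, 1000, 91, 1800, 66, 27, 120, 140),
    km_sd   = c(19, 150, 300, 15, 300, 20, 11, 60, 30),
    kcat    = c(0.90, 1.33, 0.74, 0.94, 0.74, 4.8, 8.0, 9, 13),
    kcat_sd = c(0.07, 0.07, 0.07, 0.06, 0.04, 0.6, 1.1, 3, 3),
    eff_printed    = c(1.2e4, 1.00e3, 7e2, 1.0e4, 4.1e2,
                       7e4, 3.0e5, 7e4, 9e4),
    eff_sd_printed = c(0.3e4, 0.12e3, 3e2, 0.2e4, 0.6e2,
                       3e4, 1.3e5, 5e4, 3e4),
    eff_ulp = c(1e3, 1e1, 1e2, 1e3, 1e1, 1e4, 1e4, 1e4, 1e4),
    stringsAsFactors = FALSE
  )
}

#' Published melting temperatures for FKP enzymes
#'
#' Reference melting temperatures from thermal-shift (differential
#' scanning fluorimetry) assays of wildtype and alanine-point-mutant FKP
#' enzymes, without (apo) and with 2 mM L-fucose, together with the paired
#' delta-Tm statistics. Both enzymes unfold biphasically: `tm1` is the
#' lower melting transition (attributed to the GFPP domain of TxFKP) and
#' `tm2` the higher one (attributed to the FUK domain).
#'
#' @return a data.frame with one row per protein variant and columns
#'   `protein`, `variant`, `tm1`, `tm1_sd`, `tm1_fuc`, `tm1_fuc_sd`,
#'   `dtm1`, `dtm1_sd`, `tm2`, `tm2_sd`, `tm2_fuc`, `tm2_fuc_sd`, `dtm2`,
#'   `dtm2_sd` (all in degrees Celsius).
#' @examples
#' fkp_melt_params()
#' @export
fkp_melt_params <- function() {
  data.frame(
    protein = c(rep("TxFKP", 6L), "BfFKP"),
    variant = c("WT", "G75A", "R79A", "R597A", "D606A", "D767A", "WT"),
    tm1        = c(43.8, 44.2, 44.8, 44.0, 41.4, 43.0, 39.2),
    tm1_sd     = c(0.5, 0.2, 0.2, 0.0, 0.2, 0.0, 0.2),
    tm1_fuc    = c(43.8, 44.2, 44.7, 44.0, 41.6, 42.8, 41.2),
    tm1_fuc_sd = c(0.2, 0.2, 0.2, 0.0, 0.2, 0.2, 0.2),
    dtm1       = c(-0.2, 0.0, -0.2, 0.0, 0.2, -0.2, 2.0),
    dtm1_sd    = c(0.2, 0.0, 0.2, 0.0, 0.2, 0.2, 0.0),
    tm2        = c(52.5, 52.5, 54.5, 48.4, 51.5, 51.0, 49.8),
    tm2_sd     = c(0.0, 0.0, 0.0, 0.2, 0.0, 0.0, 0.2),
    tm2_fuc    = c(54.3, 54.0, 56.0, 48.6, 51.5, 51.0, 50.8),
    tm2_fuc_sd = c(0.2, 0.0, 0.0, 0.2, 0.0, 0.0, 0.5),
    dtm2       = c(1.8, 1.5, 1.5, 0.2, 0.0, 0.0, 1.0),
    dtm2_sd    = c(0.2, 0.0, 0.0, 0.2, 0.0, 0.0, 0.4),
    stringsAsFactors = FALSE
  )
}
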