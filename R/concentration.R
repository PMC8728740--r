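#' Permeation-enhancer count from a leaflet number-percentage
#'
#' The insertion convention expresses PE loading as a percentage of the
#' lipids in the receiving leaflet, rounded to the nearest whole molecule:
#' 5\% of a 64-lipid leaflet is 3 PE molecules, 35\% is 22.
#'
#' @param percent number-percentage of the leaflet lipid count.
#' @param n_leaflet lipids per leaflet (default 64).
#' @return integer PE molecule count.
#' @examples
#' peCountFromPercent(5)   # 3
#' peCountFromPercent(35)  # 22
#' @export
peCountFromPercent <- function(percent, n_leaflet = 64L) {
    stopifnot(percent >= 0, n_leaflet > 0)
    as.integer(round(percent / 100 * n_leaflet))
}

#' Number concentration of PEs in the aqueous phase (mM)
#'
#' Converts PE and water molecule counts to a millimolar concentration
#' based on the volume of water in the system: n_pe / (n_water * v_w * N_A)
#' with v_w = 0.030 nm^3 per water molecule (bulk water near 310 K). An
#' informational utility for relating leaflet percentages to solution
#' concentrations.
#'
#' @param n_pe PE molecule count.
#' @param n_water water molecule count (> 0).
#' @param v_water volume of one water molecule in nm^3.
#' @return concentration in mM.
#' @export
peConcentration <- function(n_pe, n_water, v_water = 0.030) {
    stopifnot(n_water > 0, v_water > 0)
    avogadro <- 6.02214076e23
    ## molecules per nm^3 -> mol per litre: 1 nm^3 = 1e-24 L
    molar <- n_pe / (n_water * v_water) / (avogadro * 1e-24)
    molar * 1000
}
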