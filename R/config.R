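#' Build an analysis configuration
#'
#' Constructs an \linkS4class{AnalysisConfig} with the pipeline defaults:
#' leaflet-membership cutoff 0.9 nm, water-permeation cutoff 0.5 nm,
#' headgroup contact cutoff 0.9 nm, temperature 310.15 K. Remaining fields
#' are numerical plumbing (debouncing, fit windows, WHAM tolerances).
#'
#' @param r_expel leaflet-membership / expulsion cutoff in nm.
#' @param r_water water-permeation cutoff in nm.
#' @param contact_cutoff headgroup contact cutoff in nm.
#' @param temperature temperature in K.
#' @param debounce_frames frames a state must persist to commit.
#' @param msd_fit_window fractions of the maximum lag delimiting the MSD fit.
#' @param msd_max_lag_fraction maximum MSD lag as a fraction of series length.
#' @param pmf_bin_width PMF bin width in nm.
#' @param pmf_min_count minimum bin occupancy for a well-sampled PMF bin.
#' @param wham_tol WHAM convergence tolerance in kcal/mol.
#' @param wham_max_iter WHAM iteration cap.
#' @param water_reference_zone distance-from-center interval (nm) taken as
#'   bulk water for the PMF zero.
#' @param expel_both_leaflets test the expulsion criterion against both
#'   leaflets' phosphates (TRUE) or the initial leaflet only.
#' @param seed integer seed echoed into reports.
#' @return an \linkS4class{AnalysisConfig}
#' @examples
#' cfg <- analysisConfig()
#' cfg
#' @export
analysisConfig <- function(r_expel = 0.9, r_water = 0.5,
                           contact_cutoff = 0.9, temperature = 310.15,
                           debounce_frames = 5L,
                           msd_fit_window = c(0.1, 0.9),
                           msd_max_lag_fraction = 0.1,
                           pmf_bin_width = 0.01, pmf_min_count = 150,
                           wham_tol = 1e-6, wham_max_iter = 1e5L,
                           water_reference_zone = c(2.3, Inf),
                           expel_both_leaflets = TRUE, seed = 1L) {
    new("AnalysisConfig",
        rExpel = r_expel, rWater = r_water,
        contactCutoff = contact_cutoff, temperature = temperature,
        debounceFrames = as.integer(debounce_frames),
        msdFitWindow = msd_fit_window,
        msdMaxLagFraction = msd_max_lag_fraction,
        pmfBinWidth = pmf_bin_width, pmfMinCount = pmf_min_count,
        whamTol = wham_tol, whamMaxIter = as.integer(wham_max_iter),
        waterReferenceZone = water_reference_zone,
        expelBothLeaflets = expel_both_leaflets, seed = as.integer(seed))
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the arguments of \code{\link{analysisConfig}}
#' (snake_case); keys not present keep their defaults, unknown keys error.
#'
#' @param path path to a YAML file.
#' @return an \linkS4class{AnalysisConfig}
#' @export
readAnalysisConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    ok <- names(formals(analysisConfig))
    bad <- setdiff(names(vals), ok)
    if (length(bad))
        stop("unknown configuration keys: ", paste(bad, collapse = ", "))
    do.call(analysisConfig, vals)
}

## Thermal energy RT in kcal/mol at the configured temperature.
configRT <- function(config) .RGAS * config@temperature

#' Gas constant used throughout (kcal/mol/K)
#'
#' @return the molar gas constant, 1.9872e-3 kcal/mol/K.
#' @export
gasConstant <- function() .RGAS
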