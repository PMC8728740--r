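#' @import methods
NULL

#' Topology: atoms, role assignments and initial leaflet labels
#'
#' A \code{Topology} describes the static part of a bilayer system: one row
#' per atom (id, name, molecule id, molecule kind), a set of named atom roles
#' used by the analysis operators, and the leaflet each lipid or permeation
#' enhancer (PE) occupied at the start of the trajectory.
#'
#' Molecule kinds are \code{"POPC"}, \code{"PE"}, \code{"water"} and
#' \code{"ion"}. Roles are \code{phosphate}, \code{tail_carbon_last3},
#' \code{tail_hydrogen_last3}, \code{water_site}, \code{pe_reference} and
#' \code{pe_chain}; each maps to an integer vector of atom ids.
#'
#' @slot atoms data.frame with columns \code{id}, \code{name}, \code{molid},
#'   \code{molkind}.
#' @slot roles named list of integer atom-id vectors.
#' @slot leaflet0 named character vector (\code{"upper"}/\code{"lower"})
#'   keyed by molecule id, covering every POPC and every initially inserted PE.
#' @exportClass Topology
setClass("Topology",
    representation(atoms = "data.frame", roles = "list",
                   leaflet0 = "character"))

setValidity("Topology", function(object) {
    a <- object@atoms
    msg <- character()
    need <- c("id", "name", "molid", "molkind")
    if (!all(need %in% names(a)))
        return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(a$id))
        msg <- c(msg, "duplicated atom ids")
    if (!all(a$molkind %in% c("POPC", "PE", "water", "ion")))
        msg <- c(msg, "unknown molecule kind")
    bad <- setdiff(unlist(object@roles), a$id)
    if (length(bad))
        msg <- c(msg, "role refers to unknown atom id")
    ## every PE molecule carries exactly one reference site
    pe <- unique(a$molid[a$molkind == "PE"])
    if (length(pe)) {
        ref <- object@roles$pe_reference
        tab <- table(factor(a$molid[match(ref, a$id)], levels = pe))
        if (any(tab != 1L))
            msg <- c(msg, "every PE molecule must have exactly one pe_reference atom")
    }
    lipids <- unique(a$molid[a$molkind %in% c("POPC", "PE")])
    if (length(lipids) && !all(as.character(lipids) %in% names(object@leaflet0)))
        msg <- c(msg, "leaflet0 must cover every POPC and PE molecule")
    if (length(object@leaflet0) &&
        !all(object@leaflet0 %in% c("upper", "lower")))
        msg <- c(msg, "leaflet0 labels must be 'upper' or 'lower'")
    if (length(msg)) msg else TRUE
})

#' Trajectory: multi-frame coordinates plus topology
#'
#' Frames of atomic positions (nm) with per-frame times (ns) and periodic
#' box vectors (nm), tied to a \linkS4class{Topology}. Coordinates are stored
#' wrapped, exactly as read; consumers unwrap on demand.
#'
#' @slot times numeric, strictly increasing frame times in ns.
#' @slot coords numeric array \code{[atom, xyz, frame]} in nm.
#' @slot box numeric matrix \code{[frame, xyz]} of box vector lengths in nm.
#' @slot topology the \linkS4class{Topology}.
#' @exportClass Trajectory
setClass("Trajectory",
    representation(times = "numeric", coords = "array",
                   box = "matrix", topology = "Topology"))

setValidity("Trajectory", function(object) {
    msg <- character()
    nf <- length(object@times)
    if (nf == 0L) msg <- c(msg, "trajectory must contain at least one frame")
    if (nf > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "frame times must be strictly increasing")
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
        msg <- c(msg, "coords must be an [atom, xyz, frame] array")
    else {
        if (d[3] != nf) msg <- c(msg, "coords frame count must match times")
        if (d[1] != nrow(object@topology@atoms))
            msg <- c(msg, "coords atom count must match topology")
    }
    if (nrow(object@box) != nf || ncol(object@box) != 3L)
        msg <- c(msg, "box must be a [frame, xyz] matrix")
    else if (any(object@box <= 0))
        msg <- c(msg, "box vectors must be positive")
    if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' Holds every tunable cutoff and numerical tolerance of the pipeline.
#' Distances are nm, times ns, energies kcal/mol, temperature K.
#'
#' @slot rExpel leaflet-membership cutoff: a PE belongs to a leaflet while its
#'   reference site is within this distance of any of that leaflet's
#'   phosphates (default 0.9 nm).
#' @slot rWater water-permeation cutoff around the terminal acyl carbons
#'   (default 0.5 nm).
#' @slot contactCutoff headgroup-headgroup contact distance (default 0.9 nm).
#' @slot temperature simulation temperature, default 310.15 K (37 C).
#' @slot debounceFrames frames a new state must persist to commit (default 5).
#' @slot msdFitWindow fractions of the maximum MSD lag bounding the linear
#'   fit (default c(0.1, 0.9)).
#' @slot msdMaxLagFraction maximum MSD lag as a fraction of the series length
#'   (default 0.1).
#' @slot pmfBinWidth PMF histogram bin width (default 0.01 nm; coarse bins
#'   under stiff umbrella springs bias the reconstructed profile).
#' @slot pmfMinCount minimum per-bin sample count for a bin to be considered
#'   well sampled (default 150, keeping the per-bin statistical
#'   uncertainty RT/sqrt(n) of the free energy near 0.05 kcal/mol).
#' @slot whamTol WHAM window free-energy convergence tolerance
#'   (default 1e-6 kcal/mol).
#' @slot whamMaxIter WHAM iteration cap (default 1e5).
#' @slot waterReferenceZone distance-from-center interval defining bulk water
#'   for the PMF zero (default c(2.3, Inf) nm).
#' @slot expelBothLeaflets logical; test distance to both leaflets'
#'   phosphates (TRUE, default) or the initial leaflet only.
#' @slot seed integer seed echoed into reports.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
    representation(rExpel = "numeric", rWater = "numeric",
                   contactCutoff = "numeric", temperature = "numeric",
                   debounceFrames = "integer", msdFitWindow = "numeric",
                   msdMaxLagFraction = "numeric",
                   pmfBinWidth = "numeric", pmfMinCount = "numeric",
                   whamTol = "numeric", whamMaxIter = "integer",
                   waterReferenceZone = "numeric",
                   expelBothLeaflets = "logical", seed = "integer"))

setValidity("AnalysisConfig", function(object) {
    msg <- character()
    if (object@rExpel <= 0 || object@rWater <= 0 || object@contactCutoff <= 0)
        msg <- c(msg, "all distance cutoffs must be > 0")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    w <- object@msdFitWindow
    if (length(w) != 2L || w[1] <= 0 || w[2] >= 1 || w[1] >= w[2])
        msg <- c(msg, "msdFitWindow must satisfy 0 < lower < upper < 1")
    if (object@whamTol <= 0) msg <- c(msg, "whamTol must be > 0")
    if (object@debounceFrames < 1L) msg <- c(msg, "debounceFrames must be >= 1")
    if (object@pmfBinWidth <= 0) msg <- c(msg, "pmfBinWidth must be > 0")
    if (length(msg)) msg else TRUE
})

#' Umbrella-sampling window
#'
#' One biased simulation window: harmonic restraint centre (nm), spring
#' constant (kcal/mol/nm^2) and the sampled reaction-coordinate values.
#'
#' @slot center restraint centre xi_i in nm.
#' @slot k spring constant in kcal/mol/nm^2 (0 = unbiased).
#' @slot samples numeric vector of sampled xi values in nm.
#' @exportClass UmbrellaWindow
setClass("UmbrellaWindow",
    representation(center = "numeric", k = "numeric", samples = "numeric"))

setValidity("UmbrellaWindow", function(object) {
    msg <- character()
    if (length(object@samples) == 0L) msg <- c(msg, "window has no samples")
    if (object@k < 0) msg <- c(msg, "spring constant must be >= 0")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
        msg <- c(msg, "samples must be finite")
    if (length(msg)) msg else TRUE
})

#' Potential-of-mean-force profile
#'
#' WHAM output on a uniform half-open bin grid. \code{G} is in kcal/mol,
#' referenced so that its mean over the water reference zone is zero (when
#' that zone is populated).
#'
#' @slot xi bin centres in nm.
#' @slot G free energy per bin, kcal/mol.
#' @slot counts total sample count per bin over all windows.
#' @slot wellSampled logical per bin: counts >= pmfMinCount.
#' @slot F converged window free energies, kcal/mol.
#' @slot binWidth bin width in nm.
#' @slot converged logical convergence flag.
#' @slot iterations iterations used.
#' @exportClass PMFProfile
setClass("PMFProfile",
    representation(xi = "numeric", G = "numeric", counts = "numeric",
                   wellSampled = "logical", F = "numeric",
                   binWidth = "numeric", converged = "logical",
                   iterations = "integer"))

setValidity("PMFProfile", function(object) {
    msg <- character()
    if (length(object@xi) != length(object@G))
        msg <- c(msg, "xi and G lengths differ")
    if (any(object@counts > 0 & !is.finite(object@G)))
        msg <- c(msg, "G must be finite on populated bins")
    if (length(msg)) msg else TRUE
})

#' Partition result: free-energy difference and outside/inside ratio
#'
#' @slot deltaG free-energy difference G(membrane minimum) - G(water), kcal/mol.
#' @slot minLocation distance of the energy minimum from the membrane centre, nm.
#' @slot temperature K.
#' @slot CoOverCi outside/inside number-concentration ratio.
#' @slot convention "paper" or "boltzmann".
#' @exportClass PartitionResult
setClass("PartitionResult",
    representation(deltaG = "numeric", minLocation = "numeric",
                   temperature = "numeric", CoOverCi = "numeric",
                   convention = "character"))

setValidity("PartitionResult", function(object) {
    if (length(object@CoOverCi) && object@CoOverCi <= 0)
        "CoOverCi must be > 0" else TRUE
})
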