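## Water permeation near the acyl tails and the abundance-corrected
## fractional-interaction matrix.

#' Count water molecules near the terminal acyl tails in one frame
#'
#' Number of distinct water molecules whose water site lies within
#' \code{r_water} (minimum image; default 0.5 nm) of any atom of the
#' terminal-tail role set (the last three carbons of both chains plus
#' their hydrogens, when present).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return integer count.
#' @export
waterNearTails <- function(traj, frame = 1L, config = analysisConfig()) {
    top <- topology(traj)
    tails <- c(roleIdx(top, "tail_carbon_last3"),
               roleIdx(top, "tail_hydrogen_last3"))
    wat <- roleIdx(top, "water_site")
    if (!length(tails)) stop("tail role set is empty")
    if (!length(wat)) return(0L)
    xyz <- frameCoords(traj, frame)
    box <- boxMatrix(traj)[frame, ]
    d <- minImageCrossDist(xyz[wat, , drop = FALSE],
                           xyz[tails, , drop = FALSE], box)
    near <- apply(d, 1, min) <= config@rWater
    length(unique(top@atoms$molid[wat][near]))
}

#' Water-permeation series
#'
#' Per-frame \code{\link{waterNearTails}} counts normalised per lipid
#' (divide by \code{n_lipids}, default the 128 lipids of a 64+64 bilayer),
#' with the series mean and standard deviation.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param n_lipids normalisation divisor.
#' @param stride analyse every stride-th frame.
#' @return list with \code{series} (data.frame: frame, time, count,
#'   per_lipid), \code{mean}, \code{sd} (of per_lipid over frames).
#' @export
waterPermeationSeries <- function(traj, config = analysisConfig(),
                                  n_lipids = 128L, stride = 1L) {
    ks <- seq(1L, nFrames(traj), by = stride)
    counts <- vapply(ks, function(k) waterNearTails(traj, k, config),
                     integer(1))
    per <- counts / n_lipids
    list(series = data.frame(frame = ks, time = frameTimes(traj)[ks],
                             count = counts, per_lipid = per),
         mean = mean(per),
         sd = if (length(per) > 1L) stats::sd(per) else 0)
}

## contact counting core: unique molecule pairs closer than the cutoff
## (headgroup sites, minimum image); pts may be planar (2 cols) or 3-D
.pairContacts <- function(pts, species, box, cutoff, levels = NULL) {
    if (ncol(pts) == 2L) { pts <- cbind(pts, 0); box <- c(box[1:2], 1) }
    d <- minImageCrossDist(pts, pts, box)
    sp <- if (is.null(levels)) sort(unique(species)) else levels
    C <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
    hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
        si <- species[hit[, 1]]; sj <- species[hit[, 2]]
        for (r in seq_len(nrow(hit))) {
            C[si[r], sj[r]] <- C[si[r], sj[r]] + 1
            if (si[r] != sj[r]) C[sj[r], si[r]] <- C[sj[r], si[r]] + 1
        }
    }
    C
}

## abundance correction + row normalisation of averaged contact counts
.fractionMatrix <- function(C, N) {
    sp <- rownames(C)
    chat <- C
    for (i in sp) for (j in sp) {
        pairs <- if (i == j) N[i] * (N[i] - 1) / 2 else N[i] * N[j]
        chat[i, j] <- if (pairs > 0) C[i, j] / pairs else NA
    }
    f <- chat / rowSums(chat, na.rm = TRUE)
    list(raw = C, rate = chat, fraction = f)
}

#' Fractional interactions between molecular species
#'
#' Contacts are unique molecule pairs whose headgroup sites are closer
#' than \code{contact_cutoff} (0.9 nm, minimum image); multiple atom
#' contacts between the same pair count once. Raw pair counts C_ij are
#' averaged over frames, corrected for abundance by dividing by the
#' number of possible pairs (N_i N_j for i != j, N_i (N_i - 1)/2 within a
#' species) and row-normalised; a fraction of 0.5 everywhere indicates an
#' ideally mixed two-component system.
#'
#' For a trajectory, the analysed set is the PE-bearing leaflet: its POPC
#' phosphates plus the PEs currently assigned to that leaflet by the
#' event module's per-frame state.
#'
#' @param x either a list with \code{xy}, \code{species}, \code{box} (a
#'   single planar configuration, e.g. from
#'   \code{\link{makeLatticeMixture}}) or a \linkS4class{Trajectory}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param stride frame stride for trajectories.
#' @return list with \code{raw} (mean pair counts), \code{rate}
#'   (abundance-corrected), \code{fraction} (row-stochastic), \code{N}
#'   (species abundances).
#' @export
fractionalInteractions <- function(x, config = analysisConfig(),
                                   stride = 1L) {
    if (is(x, "Trajectory"))
        return(.fractionalInteractionsTraj(x, config, stride))
    stopifnot(is.list(x), !is.null(x$xy), !is.null(x$species))
    species <- as.character(x$species)
    N <- table(species)
    if (any(N == 0)) warning("species with zero abundance dropped")
    if (sum(N) < 2) stop("need at least 2 molecules")
    C <- .pairContacts(x$xy, species, x$box, config@contactCutoff)
    out <- .fractionMatrix(C, as.vector(N[rownames(C)]) |>
                               stats::setNames(rownames(C)))
    out$N <- N
    out
}

.fractionalInteractionsTraj <- function(traj, config, stride) {
    top <- topology(traj)
    rs <- .rawStates(traj, config)
    pes <- rs$pes
    pidx <- roleIdx(top, "phosphate")
    plab <- top@leaflet0[as.character(top@atoms$molid[pidx])]
    ref <- roleIdx(top, "pe_reference")
    insertLeaf <- if (length(pes)) top@leaflet0[as.character(pes[1])]
                  else "upper"
    pidx <- pidx[plab == insertLeaf]
    ks <- seq(1L, nFrames(traj), by = stride)
    Csum <- NULL; Nsum <- NULL
    for (k in ks) {
        inLeaf <- rs$state[, k] == "initial_leaflet"
        idx <- c(pidx, ref[inLeaf])
        species <- c(rep("POPC", length(pidx)), rep("PE", sum(inLeaf)))
        xyz <- traj@coords[idx, , k, drop = FALSE][, , 1]
        C <- .pairContacts(xyz, species, traj@box[k, ],
                           config@contactCutoff, levels = c("PE", "POPC"))
        N <- table(factor(species, levels = rownames(C)))
        if (is.null(Csum)) { Csum <- C; Nsum <- as.vector(N) }
        else { Csum <- Csum + C; Nsum <- Nsum + as.vector(N) }
    }
    Cbar <- Csum / length(ks)
    Nbar <- stats::setNames(Nsum / length(ks), rownames(Cbar))
    out <- .fractionMatrix(Cbar, Nbar)
    out$N <- Nbar
    out
}
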