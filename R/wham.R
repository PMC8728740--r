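## Weighted histogram analysis method and the outside/inside partition
## ratio. The WHAM equations are solved by direct self-consistent
## iteration on a uniform half-open bin grid:
##   P(b) = sum_i n_i(b) / sum_j N_j exp[(F_j - w_j(b)) / RT]
##   exp(-F_j / RT) = sum_b P(b) exp(-w_j(b) / RT)
## with harmonic biases w_j(b) = k_j/2 (xi_b - xi_j)^2, iterated until the
## window free energies F_j move by less than the tolerance.

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Returns the potential of mean force G(xi) = -RT ln P(xi) on a uniform
#' bin grid covering all samples, shifted so that the mean of G over the
#' water reference zone (distance-from-centre interval in the
#' configuration) is zero; when the reference zone holds no populated
#' bins the profile minimum is set to zero instead.
#'
#' @param windows list of \linkS4class{UmbrellaWindow} (>= 1; overlapping
#'   when more than one).
#' @param config an \linkS4class{AnalysisConfig}; uses
#'   \code{pmf_bin_width}, \code{pmf_min_count}, \code{wham_tol},
#'   \code{wham_max_iter}, \code{temperature}, \code{water_reference_zone}.
#' @param xi_range optional fixed reaction-coordinate range for the bin
#'   grid (samples outside are dropped); by default the grid spans the
#'   samples. Fixing it makes replicate profiles directly comparable.
#' @return a \linkS4class{PMFProfile}
#' @export
whamSolve <- function(windows, config = analysisConfig(), xi_range = NULL) {
    stopifnot(length(windows) >= 1L)
    RT <- configRT(config)
    h <- config@pmfBinWidth
    allS <- unlist(lapply(windows, function(w) w@samples))
    if (is.null(xi_range)) xi_range <- range(allS)
    lo <- floor(xi_range[1] / h) * h
    nb <- ceiling((xi_range[2] - lo) / h + 1e-9)
    edges <- lo + h * (0:nb)
    xi <- edges[-1] - h / 2
    nW <- length(windows)
    counts <- matrix(0, nW, nb)
    for (j in seq_len(nW)) {
        s <- windows[[j]]@samples
        s <- s[s >= lo & s < lo + nb * h]
        b <- floor((s - lo) / h) + 1L
        counts[j, ] <- tabulate(b, nbins = nb)
    }
    N <- rowSums(counts)
    ntot <- colSums(counts)
    if (nW > 1L) {
        ## overlap sanity: consecutive (sorted by centre) windows must
        ## share populated bins
        o <- order(vapply(windows, function(w) w@center, numeric(1)))
        for (q in seq_len(nW - 1L))
            if (!any(counts[o[q], ] > 0 & counts[o[q + 1L], ] > 0))
                stop("non-overlapping windows: empty shared bins between ",
                     "centers ", windows[[o[q]]]@center, " and ",
                     windows[[o[q + 1L]]]@center)
    }
    ## bin-averaged Boltzmann factor of the harmonic bias: evaluating the
    ## bias at the bin centre biases stiff-spring tails, so integrate
    ## exp(-k/2 (xi - c)^2 / RT) exactly over each bin (erf difference)
    erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
    expw <- matrix(0, nW, nb)
    for (j in seq_len(nW)) {
        kj <- windows[[j]]@k; cj <- windows[[j]]@center
        if (kj <= 0) { expw[j, ] <- 1; next }
        a <- sqrt(kj / (2 * RT))
        expw[j, ] <- sqrt(pi) / (2 * a * h) *
            (erf(a * (edges[-1] - cj)) - erf(a * (edges[-(nb + 1L)] - cj)))
    }
    F <- numeric(nW)
    iter <- 0L; converged <- FALSE
    while (iter < config@whamMaxIter) {
        iter <- iter + 1L
        denom <- colSums(N * exp(F / RT) * expw)   # recycles over bins
        P <- ifelse(denom > 0, ntot / denom, 0)
        P <- P / sum(P)
        Fnew <- -RT * log(as.vector(expw %*% P))
        Fnew <- Fnew - Fnew[1]
        if (max(abs(Fnew - F)) < config@whamTol) {
            F <- Fnew; converged <- TRUE; break
        }
        F <- Fnew
    }
    if (!converged)
        warning("WHAM did not converge within ", config@whamMaxIter,
                " iterations; returning partial result")
    denom <- colSums(N * exp(F / RT) * expw)
    P <- ifelse(denom > 0, ntot / denom, 0)
    P <- P / sum(P)
    G <- ifelse(P > 0, -RT * log(P), Inf)
    zone <- config@waterReferenceZone
    inZone <- xi >= zone[1] & xi <= zone[2] & is.finite(G) & ntot > 0
    G <- if (any(inZone)) G - mean(G[inZone])
         else G - min(G[is.finite(G)])
    new("PMFProfile", xi = xi, G = G, counts = ntot,
        wellSampled = ntot >= config@pmfMinCount, F = F, binWidth = h,
        converged = converged, iterations = iter)
}

#' Free-energy difference and minimum location from a PMF
#'
#' Minimum of G over the membrane zone (distance-from-centre interval),
#' restricted to well-sampled bins. Because the water reference is already
#' zeroed, delta G = G(minimum); the minimum's distance from the membrane
#' centre is reported alongside.
#'
#' @param pmf a \linkS4class{PMFProfile}.
#' @param membrane_zone xi interval (nm) searched for the energy minimum.
#' @return list with \code{deltaG} (kcal/mol) and \code{minLocation} (nm).
#' @export
extractDeltaG <- function(pmf, membrane_zone = c(0, 1.95)) {
    sel <- pmf@xi >= membrane_zone[1] & pmf@xi <= membrane_zone[2] &
        pmf@wellSampled & is.finite(pmf@G)
    if (!any(sel)) stop("membrane zone holds no well-sampled bins")
    i <- which(sel)[which.min(pmf@G[sel])]
    list(deltaG = pmf@G[i], minLocation = pmf@xi[i])
}

#' Outside/inside partition ratio from a free-energy difference
#'
#' Converts the free-energy difference between the membrane-interior
#' minimum and the water phase into the equilibrium ratio of PE number
#' concentrations outside and inside the membrane. The default
#' \code{"paper"} convention, Co/Ci = exp(deltaG / (ln 10 * R * T)),
#' reproduces the study's tabulated ratios; the textbook Boltzmann form
#' exp(deltaG / (R T)) is available as \code{"boltzmann"}. See the methods
#' vignette for the discrepancy between the two.
#'
#' @param deltaG free-energy difference G(membrane minimum) - G(water) in
#'   kcal/mol.
#' @param temperature temperature in K (default 310.15).
#' @param convention "paper" or "boltzmann".
#' @return Co/Ci, dimensionless.
#' @examples
#' partitionRatio(0.99)    # 2.01
#' partitionRatio(-4.40)   # 0.04
#' @export
partitionRatio <- function(deltaG, temperature = 310.15,
                           convention = c("paper", "boltzmann")) {
    convention <- match.arg(convention)
    stopifnot(temperature > 0)
    denom <- .RGAS * temperature
    if (convention == "paper") denom <- denom * log(10)
    exp(deltaG / denom)
}

#' Full partition analysis of a PMF
#'
#' @param pmf a \linkS4class{PMFProfile}.
#' @param membrane_zone xi interval searched for the minimum.
#' @param temperature temperature in K.
#' @param convention partition-ratio convention.
#' @return a \linkS4class{PartitionResult}
#' @export
partitionAnalysis <- function(pmf, membrane_zone = c(0, 1.95),
                              temperature = 310.15,
                              convention = c("paper", "boltzmann")) {
    convention <- match.arg(convention)
    dg <- extractDeltaG(pmf, membrane_zone)
    new("PartitionResult", deltaG = dg$deltaG,
        minLocation = dg$minLocation, temperature = temperature,
        CoOverCi = partitionRatio(dg$deltaG, temperature, convention),
        convention = convention)
}

#' Aggregate replicate PMF profiles
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) over
#' replicate profiles computed on an identical bin grid.
#'
#' @param pmfs list of >= 2 \linkS4class{PMFProfile} with matching grids.
#' @return data.frame with \code{xi}, \code{mean}, \code{sd}.
#' @export
aggregateReplicates <- function(pmfs) {
    stopifnot(length(pmfs) >= 2L)
    xi <- pmfs[[1]]@xi
    for (p in pmfs[-1])
        if (length(p@xi) != length(xi) || max(abs(p@xi - xi)) > 1e-9)
            stop("replicate PMFs are on different bin grids")
    G <- do.call(cbind, lapply(pmfs, function(p) p@G))
    data.frame(xi = xi, mean = rowMeans(G), sd = apply(G, 1, stats::sd))
}
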