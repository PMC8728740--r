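## Deuterium order parameters and lateral diffusion.

## S_CD of a set of bond vectors against +z (rows need not be unit length).
.scd <- function(v) {
    n2 <- rowSums(v * v)
    mean((3 * v[, 3]^2 / n2 - 1) / 2)
}

## Reconstruct the two C-H unit vectors at carbon C(n) from its bonded
## neighbours C(n-1), C(n+1): the hydrogens lie in the plane spanned by
## the inverse bond bisector and the bond-plane normal, at half the
## tetrahedral H-C-H angle from the bisector.
.reconstructCH <- function(cPrev, cThis, cNext) {
    a <- cPrev - cThis; b <- cNext - cThis
    na <- sqrt(rowSums(a * a)); nb <- sqrt(rowSums(b * b))
    if (any(na < 1e-12) || any(nb < 1e-12))
        stop("need at least 2 distinct bonded atoms to define C-H vectors")
    a <- a / na; b <- b / nb
    s <- a + b
    ns <- sqrt(rowSums(s * s))
    if (any(ns < 1e-8))
        stop("colinear chain carbons: C-H reconstruction undefined")
    s <- s / ns                                      # bond bisector
    p <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    p <- p / sqrt(rowSums(p * p))                    # bond-plane normal
    half <- 0.5 * 109.47 * pi / 180
    h1 <- -s * cos(half) + p * sin(half)
    h2 <- -s * cos(half) - p * sin(half)
    rbind(h1, h2)
}

#' @describeIn orderParameter S_CD of an explicit bond-vector set (an
#'   \code{n x 3} matrix); vectors need not be normalised.
#' @export
setMethod("orderParameter", "matrix", function(x, ...) {
    stopifnot(ncol(x) == 3, nrow(x) >= 1)
    .scd(x)
})

## Collect reconstructed C-H vectors for a set of chain carbons across
## frames; carbons are grouped per molecule in chain order.
.chainCHVectors <- function(traj, idxByMol, frames) {
    out <- list()
    for (k in frames) {
        xyz <- traj@coords[, , k]
        for (m in seq_along(idxByMol)) {
            ix <- idxByMol[[m]]
            if (length(ix) < 3L) next
            inner <- 2:(length(ix) - 1L)
            v <- .reconstructCH(xyz[ix[inner - 1L], , drop = FALSE],
                                xyz[ix[inner], , drop = FALSE],
                                xyz[ix[inner + 1L], , drop = FALSE])
            out[[length(out) + 1L]] <-
                list(carbon = rep(inner, 2L), v = v, mol = m)
        }
    }
    out
}

#' @describeIn orderParameter order profile of POPC acyl chains along a
#'   trajectory. C-H vectors are taken from explicit tail hydrogens when
#'   the role resolves, and reconstructed from adjacent-carbon geometry
#'   otherwise. Extra arguments: \code{chain} ("sn1", the profile chain
#'   used for reporting, or "sn2"), \code{stride}. Returns a list with
#'   \code{profile} (data.frame: carbon, scd) and \code{mean}.
#' @param chain acyl chain selection for trajectory profiles.
#' @param stride analyse every stride-th frame.
#' @export
setMethod("orderParameter", "Trajectory", function(x, chain = c("sn1", "sn2"),
                                                   stride = 1L, ...) {
    chain <- match.arg(chain)
    top <- topology(x)
    tails <- roleIdx(top, "tail_carbon_last3")
    if (!length(tails)) stop("tail carbon role is empty")
    nm <- top@atoms$name[tails]
    ## CHARMM numbering: sn-1 carbons C3xx, sn-2 carbons C2xx
    want <- if (chain == "sn1") "^C3" else "^C2"
    tails <- tails[grepl(want, nm)]
    byMol <- split(tails, top@atoms$molid[tails])
    byMol <- lapply(byMol, function(ix)
        ix[order(top@atoms$name[ix])])
    frames <- seq(1L, nFrames(x), by = stride)
    vecs <- .chainCHVectors(x, byMol, frames)
    if (!length(vecs)) stop("no chain with >= 3 carbons")
    carbon <- unlist(lapply(vecs, `[[`, "carbon"))
    v <- do.call(rbind, lapply(vecs, `[[`, "v"))
    prof <- vapply(sort(unique(carbon)), function(cc)
        .scd(v[carbon == cc, , drop = FALSE]), numeric(1))
    list(profile = data.frame(carbon = sort(unique(carbon)), scd = prof),
         mean = .scd(v))
})

#' Chain-average order parameter of the PE molecules
#'
#' Applies the S_CD estimator to the PE chain carbons (role
#' \code{pe_chain}), reconstructing C-H vectors from adjacent-carbon
#' geometry, and reports a single species average with the standard
#' deviation over molecules.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param stride analyse every stride-th frame.
#' @return list with \code{mean}, \code{sd} (over molecules), \code{n}
#'   (molecules contributing).
#' @export
peOrderParameter <- function(traj, stride = 1L) {
    top <- topology(traj)
    chain <- roleIdx(top, "pe_chain")
    if (!length(chain)) stop("pe_chain role is empty")
    byMol <- split(chain, top@atoms$molid[chain])
    byMol <- lapply(byMol, function(ix) ix[order(top@atoms$name[ix])])
    if (any(vapply(byMol, length, 1L) < 3L))
        stop("PE chains need >= 3 carbons for C-H reconstruction")
    frames <- seq(1L, nFrames(traj), by = stride)
    vecs <- .chainCHVectors(traj, byMol, frames)
    mol <- unlist(lapply(vecs, function(e) rep(e$mol, nrow(e$v))))
    v <- do.call(rbind, lapply(vecs, `[[`, "v"))
    perMol <- vapply(sort(unique(mol)), function(m)
        .scd(v[mol == m, , drop = FALSE]), numeric(1))
    list(mean = mean(perMol),
         sd = if (length(perMol) > 1L) stats::sd(perMol) else 0,
         n = length(perMol))
}

## MSD over all sliding origins by the FFT autocorrelation algorithm;
## x is a numeric series, returns msd at lags 0..maxLag.
.msdFFT1 <- function(x, maxLag) {
    n <- length(x)
    ## S2(tau) = sum_t x_t x_{t+tau} / (n - tau) via zero-padded FFT
    fx <- stats::fft(c(x, numeric(n)))
    ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / (2 * n)
    S2 <- ac[seq_len(maxLag + 1L)] / (n - 0:maxLag)
    ## S1 recursion
    D <- x * x
    Q <- 2 * sum(D)
    S1 <- numeric(maxLag + 1L)
    for (m in 0:maxLag) {
        if (m > 0L) Q <- Q - D[m] - D[n + 1L - m]
        S1[m + 1L] <- Q / (n - m)
    }
    S1 - 2 * S2
}

#' @describeIn lateralDiffusion diffusion coefficient of a
#'   \code{[walker, step, 2]} planar position array. Extra arguments:
#'   \code{dt} (step time in ns; defaults to the array's \code{dt}
#'   attribute), \code{config}, \code{remove_drift} (subtract the
#'   per-step mean position over walkers before the MSD; default TRUE).
#' @param dt frame/step spacing in ns.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param remove_drift subtract the group centre-of-mass motion.
#' @export
setMethod("lateralDiffusion", "array", function(x, dt = attr(x, "dt"),
                                                config = analysisConfig(),
                                                remove_drift = TRUE, ...) {
    stopifnot(length(dim(x)) == 3L, dim(x)[3] == 2L)
    if (is.null(dt)) stop("supply dt")
    nW <- dim(x)[1]; nT <- dim(x)[2]
    if (nT < 100L) stop("need >= 100 frames for a diffusion estimate")
    if (remove_drift)
        for (ax in 1:2)
            x[, , ax] <- x[, , ax] - rep(colMeans(x[, , ax, drop = FALSE][, , 1]),
                                         each = nW)
    maxLag <- max(10L, floor(config@msdMaxLagFraction * (nT - 1L)))
    msd <- numeric(maxLag + 1L)
    for (w in seq_len(nW))
        msd <- msd + .msdFFT1(x[w, , 1], maxLag) + .msdFFT1(x[w, , 2], maxLag)
    msd <- msd / nW
    lag <- 0:maxLag
    lo <- config@msdFitWindow[1] * maxLag
    hi <- config@msdFitWindow[2] * maxLag
    sel <- which(lag >= lo & lag <= hi)
    tau <- lag[sel] * dt
    if (stats::var(msd[sel]) == 0 && stats::var(tau) == 0)
        stop("degenerate MSD fit")
    fit <- stats::lm(msd[sel] ~ tau)
    slope <- unname(stats::coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    list(msd = data.frame(tau = lag * dt, msd = msd),
         D = slope / 4, se = se / 4, fitWindow = range(tau))
})

#' @describeIn lateralDiffusion lateral diffusion of POPC phosphates in a
#'   trajectory. Extra arguments: \code{leaflet} ("upper"/"lower"/"both";
#'   the PE-bearing leaflet is the usual choice), \code{config}. Uses
#'   unwrapped phosphate xy positions with per-leaflet centre-of-mass
#'   drift removal.
#' @param leaflet leaflet selection for trajectory input.
#' @export
setMethod("lateralDiffusion", "Trajectory",
          function(x, leaflet = "upper", config = analysisConfig(), ...) {
    top <- topology(x)
    pidx <- roleIdx(top, "phosphate")
    lab <- top@leaflet0[as.character(top@atoms$molid[pidx])]
    if (leaflet %in% c("upper", "lower")) pidx <- pidx[lab == leaflet]
    if (!length(pidx)) stop("no phosphates in the selected leaflet")
    nT <- nFrames(x)
    pos <- array(0, dim = c(length(pidx), nT, 2L))
    for (j in seq_along(pidx)) {
        pos[j, , 1] <- unwrapZ(x@coords[pidx[j], 1, ], x@box[1, 1])
        pos[j, , 2] <- unwrapZ(x@coords[pidx[j], 2, ], x@box[1, 2])
    }
    dt <- if (nT > 1L) mean(diff(frameTimes(x))) else 1
    lateralDiffusion(pos, dt = dt, config = config, remove_drift = TRUE)
})
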