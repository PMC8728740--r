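## Synthetic-data generators: every pipeline input with known ground truth.
## The bilayer emulates the study conditions -- 64 POPC per leaflet in a
## 6.60 x 6.60 x 9.35 nm periodic box, phosphate planes 1.95 nm either side
## of the box-z midpoint (the pure-POPC leaflet half-thickness), PEs
## inserted in one leaflet and scripted to stay, be expelled, flip-flop or
## cross the periodic z-boundary along piecewise-linear z-paths.

#' Build an event script for the synthetic bilayer
#'
#' @param pe integer PE indices (1-based).
#' @param kind one of \code{"stay"}, \code{"expel"}, \code{"flipflop"},
#'   \code{"pbc_cross"}, \code{"expel_reenter"} per row.
#' @param start,end frame interval over which the scripted path runs.
#' @return a validated data.frame script.
#' @export
eventScript <- function(pe, kind, start, end) {
    kinds <- c("stay", "expel", "flipflop", "pbc_cross", "expel_reenter")
    stopifnot(all(kind %in% kinds), all(start <= end), all(start >= 1))
    s <- data.frame(pe = as.integer(pe), kind = kind,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
    o <- order(s$pe, s$start)
    s <- s[o, , drop = FALSE]
    sp <- split(s, s$pe)
    for (g in sp)
        if (nrow(g) > 1L && any(g$start[-1] <= g$end[-nrow(g)]))
            stop("overlapping schedules for PE ", g$pe[1])
    s
}

## depth of the resting PE position below its leaflet's phosphate plane (nm)
.PE_STAY_DEPTH <- 0.35
## how far past the plane an expelled PE settles (nm)
.PE_EXPEL_RISE <- 1.5

## scripted z-path of one PE (wrapped into [0, boxZ))
.peZPath <- function(rows, nFrames, planeInit, planeOther, zc, boxZ, upper) {
    sgn <- if (upper) 1 else -1          # +1: initial leaflet above centre
    zStay <- planeInit - sgn * .PE_STAY_DEPTH
    zOtherStay <- planeOther + sgn * .PE_STAY_DEPTH
    zExpel <- planeInit + sgn * .PE_EXPEL_RISE
    zOtherOut <- planeOther - sgn * .PE_STAY_DEPTH  # other leaflet, water side
    z <- rep(zStay, nFrames)
    cur <- zStay
    for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        if (r$kind == "stay") next
        seg <- r$start:r$end
        after <- if (r$end < nFrames) (r$end + 1L):nFrames else integer(0)
        if (r$kind == "expel") {
            z[seg] <- seq(cur, zExpel, length.out = length(seg))
            z[after] <- zExpel; cur <- zExpel
        } else if (r$kind == "expel_reenter") {
            mid <- floor(length(seg) / 2)
            z[seg] <- c(seq(cur, zExpel, length.out = mid),
                        seq(zExpel, zStay, length.out = length(seg) - mid))
            z[after] <- zStay; cur <- zStay
        } else if (r$kind == "flipflop") {
            z[seg] <- seq(cur, zOtherStay, length.out = length(seg))
            z[after] <- zOtherStay; cur <- zOtherStay
        } else if (r$kind == "pbc_cross") {
            ## exit through the near z-face, re-enter the far face and
            ## approach the other leaflet from its water side
            target <- zOtherOut + sgn * boxZ   # unwrapped endpoint
            z[seg] <- seq(cur, target, length.out = length(seg))
            z[after] <- target; cur <- target
        }
    }
    z %% boxZ
}

#' Synthetic bilayer trajectory with scripted PE events
#'
#' Phosphates of the two leaflets sit on jittered planes at +/- half the
#' phosphate-plane separation about the box-z midpoint, acyl-tail terminal
#' carbons point inward, waters fill the slabs outside the membrane, and PE
#' molecules follow scripted piecewise-linear z-paths with small lateral
#' jitter. Ground truth (expected events, remaining-in-leaflet series,
#' scripted interior-water counts) is returned alongside.
#'
#' @param n_per_leaflet POPC molecules per leaflet (default 64).
#' @param n_pe PE molecules inserted into \code{insert_leaflet}.
#' @param script event script from \code{\link{eventScript}} (default: all
#'   stay).
#' @param box box vectors in nm (default c(6.60, 6.60, 9.35)).
#' @param n_frames number of frames.
#' @param dt frame spacing in ns (default 1).
#' @param plane_separation phosphate-plane separation (default 3.9 nm, i.e.
#'   a 1.95 nm leaflet half-thickness).
#' @param jitter_sd per-frame Gaussian jitter of phosphate positions (nm).
#' @param n_waters bulk water molecules split between the two slabs.
#' @param interior_waters optional data.frame(n, start, end): n waters held
#'   in the terminal-tail region during frames [start, end].
#' @param insert_leaflet leaflet receiving the PEs ("upper" or "lower").
#' @param seed integer seed; generation is bitwise reproducible.
#' @return list with elements \code{trajectory} (a
#'   \linkS4class{Trajectory}) and \code{truth} (list: \code{events}
#'   data.frame(pe, kind, commit), \code{remaining} per-frame count in the
#'   initial leaflet, \code{interiorWaters} per-frame scripted count,
#'   \code{zCenter}, \code{planes}, \code{insertLeaflet}).
#' @examples
#' sim <- makeBilayerTrajectory(n_pe = 4, n_frames = 20, seed = 1)
#' sim$trajectory
#' @export
makeBilayerTrajectory <- function(n_per_leaflet = 64L, n_pe = 0L,
                                  script = NULL,
                                  box = c(6.60, 6.60, 9.35),
                                  n_frames = 100L, dt = 1,
                                  plane_separation = 3.9,
                                  jitter_sd = 0.05, n_waters = 200L,
                                  interior_waters = NULL,
                                  insert_leaflet = "upper", seed = 1L) {
    stopifnot(n_pe <= n_per_leaflet, n_frames >= 1L)
    if (is.null(script) && n_pe > 0L)
        script <- eventScript(seq_len(n_pe), "stay", 1L, n_frames)
    if (!is.null(script)) {
        if (any(script$pe < 1L | script$pe > n_pe))
            stop("script refers to unknown PE id")
        if (any(script$end > n_frames))
            stop("script frame indices exceed trajectory length")
    }
    withSeed(seed, {
        zc <- box[3] / 2
        planeUp <- zc + plane_separation / 2
        planeLo <- zc - plane_separation / 2
        upperIn <- identical(insert_leaflet, "upper")
        planeInit <- if (upperIn) planeUp else planeLo
        planeOther <- if (upperIn) planeLo else planeUp

        m <- ceiling(sqrt(n_per_leaflet))
        if (m < 1 || box[1] / m < 0.3)
            stop("box too small for lattice placement")
        gx <- ((seq_len(n_per_leaflet) - 1) %% m + 0.5) * box[1] / m
        gy <- ((seq_len(n_per_leaflet) - 1) %/% m + 0.5) * box[2] / m

        atoms <- list(); nextId <- 1L; nextMol <- 1L
        addMol <- function(names, resname) {
            n <- length(names)
            df <- data.frame(id = nextId:(nextId + n - 1L), name = names,
                             molid = nextMol, resname = resname,
                             stringsAsFactors = FALSE)
            nextId <<- nextId + n; nextMol <<- nextMol + 1L
            atoms[[length(atoms) + 1L]] <<- df
            df$id
        }
        tailNames <- c("C214", "C215", "C216", "C314", "C315", "C316")
        popcIds <- list()
        for (leaf in c("upper", "lower"))
            for (i in seq_len(n_per_leaflet))
                popcIds[[paste(leaf, i)]] <-
                    addMol(c("P", tailNames), "POPC")
        peIds <- lapply(seq_len(n_pe), function(i)
            addMol(c("REF", "C1", "C2", "C3", "C4"), "PEA"))
        nwHalf <- n_waters %/% 2L
        watIds <- lapply(seq_len(2L * nwHalf), function(i)
            addMol("OW", "SOL"))
        nIw <- if (is.null(interior_waters)) 0L else sum(interior_waters$n)
        iwIds <- lapply(seq_len(nIw), function(i) addMol("OW", "SOL"))
        atoms <- do.call(rbind, atoms)
        nat <- nrow(atoms)

        coords <- array(0, dim = c(nat, 3, n_frames))
        ## POPC: phosphate on the jittered plane, terminal tail carbons
        ## stacked toward the membrane centre (two chains, +-0.05 nm in x)
        ## small x zigzag so adjacent carbons are never colinear (real
        ## acyl chains are zigzags; colinear chains have no defined C-H)
        tailZOff <- c(0.45, 0.30, 0.15, 0.45, 0.30, 0.15)
        tailXOff <- c(-0.05 + c(0.03, -0.03, 0.03),
                       0.05 + c(0.03, -0.03, 0.03))
        for (leaf in c("upper", "lower")) {
            plane <- if (leaf == "upper") planeUp else planeLo
            sgn <- if (leaf == "upper") 1 else -1
            for (i in seq_len(n_per_leaflet)) {
                ids <- popcIds[[paste(leaf, i)]]
                jit <- matrix(stats::rnorm(3L * n_frames, 0, jitter_sd),
                              3L, n_frames)
                coords[ids[1], 1, ] <- (gx[i] + jit[1, ]) %% box[1]
                coords[ids[1], 2, ] <- (gy[i] + jit[2, ]) %% box[2]
                coords[ids[1], 3, ] <- plane + jit[3, ]
                for (a in 1:6) {
                    coords[ids[1 + a], 1, ] <-
                        (gx[i] + tailXOff[a] + jit[1, ]) %% box[1]
                    coords[ids[1 + a], 2, ] <- (gy[i] + jit[2, ]) %% box[2]
                    coords[ids[1 + a], 3, ] <- zc + sgn * tailZOff[a]
                }
            }
        }
        ## PEs: lattice offset by half a spacing; scripted z-paths
        peCommit <- NULL
        remaining <- rep(n_pe, n_frames)
        sp <- if (is.null(script)) list() else split(script, script$pe)
        for (i in seq_len(n_pe)) {
            ids <- peIds[[i]]
            rows <- sp[[as.character(i)]]
            if (is.null(rows))
                rows <- data.frame(pe = i, kind = "stay", start = 1L,
                                   end = n_frames)
            zPath <- .peZPath(rows, n_frames, planeInit, planeOther, zc,
                              box[3], upperIn)
            px <- (gx[i] + box[1] / (2 * m)) %% box[1]
            py <- (gy[i] + box[2] / (2 * m)) %% box[2]
            jit <- matrix(stats::rnorm(2L * n_frames, 0, jitter_sd / 2),
                          2L, n_frames)
            chOff <- (if (upperIn) -1 else 1) * 0.13 * (seq_along(ids) - 1)
            chXOff <- c(0, 0.03, -0.03, 0.03, -0.03)[seq_along(ids)]
            for (a in seq_along(ids)) {
                coords[ids[a], 1, ] <- (px + chXOff[a] + jit[1, ]) %% box[1]
                coords[ids[a], 2, ] <- (py + jit[2, ]) %% box[2]
                coords[ids[a], 3, ] <- (zPath + chOff[a]) %% box[3]
            }
            ## ground truth: committed events and plane-distance membership
            for (ri in seq_len(nrow(rows))) {
                r <- rows[ri, ]
                if (r$kind == "stay") next
                kind <- if (r$kind == "expel_reenter") "expel" else r$kind
                ## commit = frame the scripted path completes its exit
                ## (for a re-entering PE that is the turning point)
                commit <- if (r$kind == "expel_reenter")
                    r$start + floor((r$end - r$start + 1L) / 2) - 1L
                    else r$end
                peCommit <- rbind(peCommit,
                    data.frame(pe = i, kind = kind, commit = commit,
                               reenters = r$kind == "expel_reenter"))
            }
            remaining <- remaining -
                as.integer(abs(zPath - planeInit) > 0.9)
        }
        ## bulk waters on coarse lattices in the two outer slabs
        mw <- ceiling(sqrt(max(nwHalf, 1L)))
        for (i in seq_len(2L * nwHalf)) {
            half <- if (i <= nwHalf) "top" else "bottom"
            j <- if (half == "top") i else i - nwHalf
            wx <- ((j - 1) %% mw + 0.5) * box[1] / mw
            wy <- ((j - 1) %/% mw + 0.5) * box[2] / mw
            wz <- if (half == "top") planeUp + 0.6 + 0.25 * ((j %% 3))
                  else planeLo - 0.6 - 0.25 * ((j %% 3))
            ids <- watIds[[i]]
            jit <- matrix(stats::rnorm(3L * n_frames, 0, jitter_sd / 2),
                          3L, n_frames)
            coords[ids[1], 1, ] <- (wx + jit[1, ]) %% box[1]
            coords[ids[1], 2, ] <- (wy + jit[2, ]) %% box[2]
            coords[ids[1], 3, ] <- (wz + jit[3, ]) %% box[3]
        }
        ## scripted interior waters: parked in bulk, moved to the
        ## terminal-tail region during their active window
        iwCount <- rep(0L, n_frames)
        if (nIw > 0L) {
            w <- 0L
            for (ri in seq_len(nrow(interior_waters))) {
                r <- interior_waters[ri, ]
                act <- seq(max(1L, r$start), min(n_frames, r$end))
                iwCount[act] <- iwCount[act] + r$n
                for (q in seq_len(r$n)) {
                    w <- w + 1L
                    ids <- iwIds[[w]]
                    lx <- gx[1 + (w %% n_per_leaflet)]
                    ly <- gy[1 + (w %% n_per_leaflet)]
                    zb <- rep(planeUp + 1.0, n_frames)   # parked in bulk
                    zb[act] <- zc + 0.15                 # beside a tail atom
                    coords[ids[1], 1, ] <- lx
                    coords[ids[1], 2, ] <- ly
                    coords[ids[1], 3, ] <- zb
                }
            }
        }
        times <- (seq_len(n_frames) - 1) * dt
        top <- buildTopology(atoms, xyz = coords[, , 1])
        traj <- newTrajectory(times, coords,
                              matrix(box, n_frames, 3, byrow = TRUE), top)
        truth <- list(
            events = if (is.null(peCommit))
                data.frame(pe = integer(0), kind = character(0),
                           commit = integer(0), reenters = logical(0))
                else peCommit,
            remaining = remaining, interiorWaters = iwCount,
            zCenter = zc, planes = c(lower = planeLo, upper = planeUp),
            insertLeaflet = insert_leaflet)
        list(trajectory = traj, truth = truth)
    })
}

#' Re-scan scripted PE membership independently of the event detector
#'
#' Recomputes the per-frame count of PEs still in the inserted leaflet
#' directly from the distance of each PE reference site to its initial
#' phosphate-plane mean z -- a deliberately simple scan used to verify
#' that emitted trajectories agree with their ground truth.
#'
#' @param traj a synthetic \linkS4class{Trajectory}.
#' @param truth the matching ground-truth list.
#' @return integer per-frame remaining count.
#' @export
rescanRemaining <- function(traj, truth) {
    top <- topology(traj)
    ref <- roleIdx(top, "pe_reference")
    if (!length(ref)) return(rep(0L, nFrames(traj)))
    plane <- truth$planes[[truth$insertLeaflet]]
    boxZ <- traj@box[1, 3]
    out <- integer(nFrames(traj))
    for (k in seq_len(nFrames(traj))) {
        dz <- abs(minImage(traj@coords[ref, 3, k] - plane, boxZ))
        out[k] <- sum(dz <= 0.9)
    }
    out
}

#' Planar Brownian walkers with known diffusion coefficient
#'
#' Independent 2-D Gaussian steps of variance \code{2 D dt} per axis.
#'
#' @param D diffusion coefficient in nm^2/ns (>= 0).
#' @param n_walkers number of walkers.
#' @param dt step time in ns.
#' @param n_steps number of steps (positions have n_steps + 1 entries).
#' @param seed integer seed.
#' @return array \code{[walker, step, xy]} with attribute \code{dt}.
#' @export
makeBrownianWalkers <- function(D, n_walkers, dt, n_steps, seed = 1L) {
    stopifnot(D >= 0, n_walkers >= 1, dt > 0, n_steps >= 1)
    withSeed(seed, {
        sd <- sqrt(2 * D * dt)
        out <- array(0, dim = c(n_walkers, n_steps + 1L, 2L))
        for (ax in 1:2) {
            steps <- matrix(stats::rnorm(n_walkers * n_steps, 0, sd),
                            n_walkers, n_steps)
            out[, , ax] <- cbind(0, t(apply(steps, 1, cumsum)))
        }
        attr(out, "dt") <- dt
        out
    })
}

#' Unit-vector ensembles with known orientational order
#'
#' \code{aligned}: all along +z (S_CD = 1); \code{perpendicular}: uniform in
#' the xy-plane (S_CD = -0.5); \code{isotropic}: uniform on the sphere
#' (S_CD = 0); \code{cone}: uniform azimuth at fixed polar angle
#' \code{theta0}, giving S_CD = (3 cos^2 theta0 - 1)/2 exactly.
#'
#' @param mode one of "aligned", "perpendicular", "isotropic", "cone".
#' @param n number of vectors.
#' @param theta0 polar angle in radians (cone mode).
#' @param seed integer seed.
#' @return \code{n x 3} matrix of unit vectors.
#' @export
makeOrientationEnsemble <- function(mode = c("aligned", "perpendicular",
                                             "isotropic", "cone"),
                                    n, theta0 = NULL, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(n > 0)
    withSeed(seed, {
        switch(mode,
            aligned = matrix(rep(c(0, 0, 1), each = n), n, 3),
            perpendicular = {
                phi <- stats::runif(n, 0, 2 * pi)
                cbind(cos(phi), sin(phi), 0)
            },
            isotropic = {
                z <- stats::runif(n, -1, 1)
                phi <- stats::runif(n, 0, 2 * pi)
                r <- sqrt(1 - z^2)
                cbind(r * cos(phi), r * sin(phi), z)
            },
            cone = {
                if (is.null(theta0)) stop("cone mode needs theta0")
                phi <- stats::runif(n, 0, 2 * pi)
                cbind(sin(theta0) * cos(phi), sin(theta0) * sin(phi),
                      cos(theta0))
            })
    })
}

#' Boltzmann samples of a tabulated 1-D potential under harmonic biases
#'
#' For each window centre, draws samples from the density proportional to
#' \code{exp(-(U(xi) + k/2 (xi - center)^2) / RT)} by inverse-CDF lookup on
#' a fine grid -- the exact stationary distribution an umbrella-sampling
#' simulation of that window targets.
#'
#' @param U data.frame with columns \code{xi} (nm) and \code{u} (kcal/mol),
#'   or a function of xi.
#' @param centers window centres (nm), within the tabulated support.
#' @param k spring constant (kcal/mol/nm^2).
#' @param n_samples samples per window.
#' @param temperature K.
#' @param support xi range when U is a function.
#' @param grid_n inverse-CDF grid resolution.
#' @param seed integer seed.
#' @return list of \linkS4class{UmbrellaWindow}
#' @export
makeUmbrellaSamples <- function(U, centers, k, n_samples,
                                temperature = 310.15, support = NULL,
                                grid_n = 20001L, seed = 1L) {
    stopifnot(k > 0, n_samples >= 1)
    if (is.function(U)) {
        if (is.null(support)) stop("supply support when U is a function")
        xi <- seq(support[1], support[2], length.out = grid_n)
        u <- U(xi)
    } else {
        xi <- seq(min(U$xi), max(U$xi), length.out = grid_n)
        u <- stats::approx(U$xi, U$u, xout = xi)$y
    }
    if (any(!is.finite(u))) stop("potential must be finite on its support")
    if (any(centers < min(xi) | centers > max(xi)))
        stop("window centers outside the potential's support")
    RT <- .RGAS * temperature
    withSeed(seed, {
        lapply(centers, function(cc) {
            w <- u + 0.5 * k * (xi - cc)^2
            p <- exp(-(w - min(w)) / RT)
            ## midpoint-corrected CDF: a plain cumsum places each grid
            ## cell's mass at its right edge, shifting every sample by
            ## half a cell and tilting downstream free-energy estimates
            cdf <- cumsum(p) - p / 2
            cdf <- cdf / (cdf[length(cdf)] + p[length(p)] / 2)
            ## strictly increasing knots for the inverse lookup
            keep <- c(TRUE, diff(cdf) > 0)
            s <- stats::approx(cdf[keep], xi[keep],
                               xout = stats::runif(n_samples),
                               rule = 2)$y
            umbrellaWindow(cc, k, s)
        })
    })
}

#' Single-frame planar two-species mixture
#'
#' \code{ideal}: uniformly random placement of both species in a periodic
#' square sized to membrane-like density (0.65 nm^2 per molecule);
#' \code{demixed}: each molecule is placed in its species' half of the box
#' with probability \code{strength}, uniformly otherwise.
#'
#' @param n_a,n_b molecules of species A and B (n_a + n_b >= 2).
#' @param mixing "ideal" or "demixed".
#' @param strength segregation strength in (0, 1] for demixed.
#' @param area_per_molecule nm^2 per molecule setting the box size.
#' @param seed integer seed.
#' @return list with \code{xy} (n x 2 positions, nm), \code{species}
#'   (character), \code{box} (c(Lx, Ly)).
#' @export
makeLatticeMixture <- function(n_a, n_b, mixing = c("ideal", "demixed"),
                               strength = 1, area_per_molecule = 0.65,
                               seed = 1L) {
    mixing <- match.arg(mixing)
    n <- n_a + n_b
    stopifnot(n >= 2)
    L <- sqrt(n * area_per_molecule)
    withSeed(seed, {
        species <- c(rep("A", n_a), rep("B", n_b))
        x <- stats::runif(n, 0, L)
        y <- stats::runif(n, 0, L)
        if (mixing == "demixed") {
            seg <- stats::runif(n) < strength
            x[seg & species == "A"] <- stats::runif(sum(seg & species == "A"),
                                                    0, L / 2)
            x[seg & species == "B"] <- stats::runif(sum(seg & species == "B"),
                                                    L / 2, L)
        }
        list(xy = cbind(x, y), species = species, box = c(L, L))
    })
}
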