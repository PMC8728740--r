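#' Assign lipids and PEs to leaflets in one frame
#'
#' Each molecule carrying a phosphate (POPC) is assigned by the sign of its
#' phosphate z minus the median phosphate z; PEs by their reference-site z.
#' POPC assignments are expected to be constant across frames (no lipid
#' flip-flop), which \code{\link{detectEvents}} asserts.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @return named character vector ("upper"/"lower") keyed by molecule id.
#' @export
assignLeaflets <- function(traj, frame = 1L) {
    top <- topology(traj)
    pidx <- roleIdx(top, "phosphate")
    if (!length(pidx)) stop("phosphate role is empty")
    popc <- molIds(top, "POPC")
    pmol <- top@atoms$molid[pidx]
    if (!all(popc %in% pmol))
        stop("lipid without a phosphate site: ",
             paste(setdiff(popc, pmol), collapse = ", "))
    xyz <- frameCoords(traj, frame)
    .initialLeaflets(data.frame(id = top@atoms$id, molid = top@atoms$molid),
                     top@roles, xyz)
}

#' Area per lipid
#'
#' Lateral box area divided by the lipid count of one leaflet:
#' \code{box_x * box_y / n_leaflet_lipids}. Inserted PEs never enter the
#' denominator; the divisor stays at the leaflet's POPC count.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index, or NULL for all frames.
#' @param n_leaflet_lipids lipids per leaflet (default 64).
#' @return APL in nm^2 (vector over frames when frame is NULL).
#' @examples
#' ## the mean study box gives 6.60 * 6.60 / 64 = 0.6806 nm^2
#' @export
areaPerLipid <- function(traj, frame = NULL, n_leaflet_lipids = 64L) {
    stopifnot(n_leaflet_lipids > 0)
    b <- boxMatrix(traj)
    if (!is.null(frame)) b <- b[frame, , drop = FALSE]
    unname(b[, 1] * b[, 2] / n_leaflet_lipids)
}

## per-leaflet phosphate row indices and z values for one frame
.leafletPhosphates <- function(traj, frame) {
    top <- topology(traj)
    pidx <- roleIdx(top, "phosphate")
    if (!length(pidx)) stop("phosphate role is empty")
    lab <- top@leaflet0[as.character(top@atoms$molid[pidx])]
    xyz <- frameCoords(traj, frame)
    list(idx = pidx, lab = lab, xyz = xyz)
}

#' Phosphate-plane membrane thickness
#'
#' \code{global}: difference of the two leaflet mean phosphate z values.
#' \code{local}: per-lipid distance along z to the mean z of its k nearest
#' opposite-leaflet phosphates (nearest in xy under minimum image),
#' averaged over lipids. Both return the bilayer P-P thickness; the leaflet
#' thickness is half of it.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @param mode "global" or "local".
#' @param k neighbour count for local mode (default 6).
#' @return thickness_pp in nm.
#' @export
membraneThickness <- function(traj, frame = 1L,
                              mode = c("global", "local"), k = 6L) {
    mode <- match.arg(mode)
    lp <- .leafletPhosphates(traj, frame)
    up <- lp$idx[lp$lab == "upper"]; lo <- lp$idx[lp$lab == "lower"]
    if (!length(up) || !length(lo))
        stop("a leaflet has no phosphates")
    xyz <- lp$xyz; box <- boxMatrix(traj)[frame, ]
    if (mode == "global")
        return(mean(xyz[up, 3]) - mean(xyz[lo, 3]))
    kk <- min(k, length(up), length(lo))
    perLipid <- function(from, to) {
        dxy <- minImageCrossDist(cbind(xyz[from, 1:2, drop = FALSE], 0),
                                 cbind(xyz[to, 1:2, drop = FALSE], 0), box)
        vapply(seq_along(from), function(i) {
            nb <- to[order(dxy[i, ])[seq_len(kk)]]
            abs(xyz[from[i], 3] - mean(xyz[nb, 3]))
        }, numeric(1))
    }
    mean(c(perLipid(up, lo), perLipid(lo, up)))
}

#' Membrane centre along z
#'
#' Midpoint of the two leaflet mean phosphate z values.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @return z_center in nm.
#' @export
membraneCenter <- function(traj, frame = 1L) {
    lp <- .leafletPhosphates(traj, frame)
    (mean(lp$xyz[lp$idx[lp$lab == "upper"], 3]) +
     mean(lp$xyz[lp$idx[lp$lab == "lower"], 3])) / 2
}

#' PE insertion depth
#'
#' Distance along the membrane normal between the membrane centre and the
#' centre of mass of a PE molecule's heavy atoms, with minimum-image
#' handling in z: \code{d = |z_com(PE) - z_center|}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pe PE molecule id (a \code{molid}), or its 1-based index among
#'   PE molecules when \code{as_index} is TRUE.
#' @param frame frame index.
#' @param as_index interpret \code{pe} as an index among PE molecules.
#' @return d in nm (>= 0).
#' @export
peDepth <- function(traj, pe, frame = 1L, as_index = FALSE) {
    top <- topology(traj)
    pes <- molIds(top, "PE")
    if (as_index) pe <- pes[pe]
    if (!pe %in% pes) stop("unknown PE molecule id: ", pe)
    rows <- which(top@atoms$molid == pe &
                  !grepl("^H", top@atoms$name))  # heavy atoms
    xyz <- frameCoords(traj, frame)
    boxZ <- boxMatrix(traj)[frame, 3]
    zc <- membraneCenter(traj, frame)
    ## minimum-image the atoms about the first one before averaging
    z <- xyz[rows, 3]
    z <- z[1] + minImage(z - z[1], boxZ)
    abs(minImage(mean(z) - zc, boxZ))
}

#' Per-frame membrane metrics series
#'
#' Computes APL, phosphate-plane thickness (global mode), leaflet thickness
#' and membrane centre for every analysed frame, plus the insertion depth
#' of every PE molecule.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param n_leaflet_lipids lipids per leaflet for the APL divisor.
#' @param stride analyse every stride-th frame.
#' @return list with \code{frames} (data.frame: frame, time, apl,
#'   thickness_pp, leaflet_thickness, z_center) and \code{pe_depth}
#'   (data.frame: frame, pe, d).
#' @export
membraneMetrics <- function(traj, n_leaflet_lipids = 64L, stride = 1L) {
    ks <- seq(1L, nFrames(traj), by = stride)
    top <- topology(traj)
    pes <- molIds(top, "PE")
    fr <- data.frame(frame = ks, time = frameTimes(traj)[ks],
                     apl = areaPerLipid(traj, ks, n_leaflet_lipids),
                     thickness_pp = NA_real_, z_center = NA_real_)
    for (i in seq_along(ks)) {
        fr$thickness_pp[i] <- membraneThickness(traj, ks[i], "global")
        fr$z_center[i] <- membraneCenter(traj, ks[i])
    }
    fr$leaflet_thickness <- fr$thickness_pp / 2
    pd <- NULL
    if (length(pes))
        pd <- do.call(rbind, lapply(ks, function(kf)
            data.frame(frame = kf, pe = pes,
                       d = vapply(pes, function(p)
                           peDepth(traj, p, kf), numeric(1)))))
    list(frames = fr, pe_depth = pd)
}
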