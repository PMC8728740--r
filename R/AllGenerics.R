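#' Number of frames in a trajectory
#' @param x a \linkS4class{Trajectory}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a \linkS4class{Trajectory} or \linkS4class{Topology}
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Frame times (ns)
#' @param x a \linkS4class{Trajectory}
#' @return numeric vector of times
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Per-frame box vectors (nm)
#' @param x a \linkS4class{Trajectory}
#' @return numeric matrix \code{[frame, xyz]}
#' @export
setGeneric("boxMatrix", function(x) standardGeneric("boxMatrix"))

#' Coordinates of one frame
#' @param x a \linkS4class{Trajectory}
#' @param frame frame index (1-based)
#' @return numeric matrix \code{[atom, xyz]} in nm
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' Topology accessor
#' @param x a \linkS4class{Trajectory}
#' @return the \linkS4class{Topology}
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Role accessor
#' @param x a \linkS4class{Topology} or \linkS4class{Trajectory}
#' @param role role label, e.g. \code{"phosphate"}
#' @return integer vector of atom ids
#' @export
setGeneric("roleAtoms", function(x, role) standardGeneric("roleAtoms"))

#' Deuterium order parameter
#'
#' S_CD = <(3 cos^2 theta - 1) / 2>, theta the angle between each C-H bond
#' vector and the bilayer normal (+z). 1 means perfect alignment with the
#' normal, -0.5 perfect anti-alignment (bond in the membrane plane), 0 an
#' isotropic orientation distribution.
#'
#' @param x an \code{n x 3} matrix of bond vectors, or a
#'   \linkS4class{Trajectory} (order profile along the acyl chain).
#' @param ... method-specific arguments.
#' @return for vectors, a single S_CD value; for trajectories, a data.frame
#'   profile per carbon plus a chain average (see
#'   \code{\link{orderParameter,Trajectory-method}}).
#' @export
setGeneric("orderParameter", function(x, ...) standardGeneric("orderParameter"))

#' Lateral diffusion coefficient from mean squared displacement
#'
#' Computes the in-plane MSD over all sliding time origins (after removing
#' per-group centre-of-mass drift for trajectories) and fits
#' \code{MSD = 4 D tau + b} over the configured lag window; the 2-D Einstein
#' relation gives D_L = slope / 4.
#'
#' @param x a \code{[walker, step, 2]} planar position array (nm) or a
#'   \linkS4class{Trajectory} (phosphate xy positions of one leaflet).
#' @param ... method-specific arguments, see methods.
#' @return a list with \code{msd} (data.frame tau, msd), \code{D} (nm^2/ns),
#'   \code{se} (fit standard error of D), \code{fitWindow} (lag range, ns).
#' @export
setGeneric("lateralDiffusion", function(x, ...)
    standardGeneric("lateralDiffusion"))
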