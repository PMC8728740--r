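#' @describeIn nFrames frame count of a trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@times))

#' @describeIn nAtoms atom count of a trajectory
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @describeIn nAtoms atom count of a topology
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @describeIn frameTimes times of a trajectory
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @describeIn boxMatrix per-frame box of a trajectory
#' @export
setMethod("boxMatrix", "Trajectory", function(x) x@box)

#' @describeIn frameCoords coordinate matrix of one frame
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame) {
    stopifnot(frame >= 1L, frame <= nFrames(x))
    x@coords[, , frame, drop = TRUE]
})

#' @describeIn topology topology of a trajectory
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @describeIn roleAtoms atom ids filling a role
#' @export
setMethod("roleAtoms", "Topology", function(x, role) {
    if (!role %in% names(x@roles))
        stop("unknown role: ", role)
    x@roles[[role]]
})

#' @describeIn roleAtoms atom ids filling a role, via the topology
#' @export
setMethod("roleAtoms", "Trajectory", function(x, role)
    roleAtoms(x@topology, role))

setMethod("show", "Topology", function(object) {
    a <- object@atoms
    kinds <- table(a$molkind[!duplicated(a$molid)])
    cat("Topology:", nrow(a), "atoms,",
        length(unique(a$molid)), "molecules\n")
    cat("  molecules:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
        "\n")
    cat("  roles:", paste(names(object@roles),
        vapply(object@roles, length, 1L), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", nFrames(object), "frames,", nAtoms(object), "atoms\n")
    cat(sprintf("  time %.4g .. %.4g ns; box (frame 1) %.3f x %.3f x %.3f nm\n",
        object@times[1], object@times[length(object@times)],
        object@box[1, 1], object@box[1, 2], object@box[1, 3]))
})

setMethod("show", "UmbrellaWindow", function(object) {
    cat(sprintf(
        "UmbrellaWindow: center %.3f nm, k %.3g kcal/mol/nm^2, %d samples\n",
        object@center, object@k, length(object@samples)))
})

setMethod("show", "PMFProfile", function(object) {
    cat(sprintf("PMFProfile: %d bins of %.3g nm, %sconverged (%d iterations)\n",
        length(object@xi), object@binWidth,
        if (object@converged) "" else "NOT ", object@iterations))
    pop <- object@wellSampled
    if (any(pop))
        cat(sprintf("  G range on well-sampled bins: [%.3f, %.3f] kcal/mol\n",
            min(object@G[pop]), max(object@G[pop])))
})

setMethod("show", "PartitionResult", function(object) {
    cat(sprintf(
        "PartitionResult (%s convention): dG = %.2f kcal/mol at %.2f nm, T = %.2f K\n",
        object@convention, object@deltaG, object@minLocation,
        object@temperature))
    cat(sprintf("  Co/Ci = %.2f\n", object@CoOverCi))
})

setMethod("show", "AnalysisConfig", function(object) {
    cat("AnalysisConfig:\n")
    cat(sprintf("  rExpel %.2f nm, rWater %.2f nm, contactCutoff %.2f nm\n",
        object@rExpel, object@rWater, object@contactCutoff))
    cat(sprintf("  T %.2f K, debounce %d frames, PMF bins %.3g nm\n",
        object@temperature, object@debounceFrames, object@pmfBinWidth))
})
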