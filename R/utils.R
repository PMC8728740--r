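## Internal numeric helpers shared across modules.

## Minimum-image convention for displacements along one or more axes.
## dx may be a vector or matrix; box is the matching box length(s).
minImage <- function(dx, box) {
    dx - box * round(dx / box)
}

## Minimum-image Euclidean distances from one point to a set of points.
## p: length-3 numeric; pts: n x 3 matrix; box: length-3 box vectors.
minImageDist <- function(p, pts, box) {
    d <- sweep(pts, 2, p)
    for (k in 1:3) d[, k] <- minImage(d[, k], box[k])
    sqrt(rowSums(d * d))
}

## All pairwise minimum-image distances between two point sets (m x n).
minImageCrossDist <- function(a, b, box) {
    m <- nrow(a); n <- nrow(b)
    out <- matrix(0, m, n)
    for (k in 1:3) {
        dk <- minImage(outer(a[, k], b[, k], "-"), box[k])
        out <- out + dk * dk
    }
    sqrt(out)
}

## Evaluate code under a temporary RNG seed, restoring the caller's
## RNG state afterwards so generators do not perturb user simulations.
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## Cumulative unwrapping of a wrapped 1-D coordinate series.
unwrapZ <- function(z, boxZ) {
    dz <- minImage(diff(z), boxZ)
    c(z[1], z[1] + cumsum(dz))
}

## Gas constant in kcal mol^-1 K^-1.
.RGAS <- 1.9872e-3
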