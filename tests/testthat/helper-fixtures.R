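## Shared fixtures built in code.

RT310 <- 1.9872e-3 * 310.15

## Minimal hand-built bilayer: one phosphate per leaflet at fixed lateral
## position, plus one PE reference atom at a caller-chosen position.
## Useful for exact distance/tie-break cases.
tinySystem <- function(peXYZ, nFrames = 1L, box = c(6, 6, 9),
                       zUp = 6.45, zLo = 2.55) {
    atoms <- data.frame(
        id = 1:3,
        name = c("P", "P", "REF"),
        molid = c(1L, 2L, 3L),
        resname = c("POPC", "POPC", "PEA"))
    coords <- array(0, dim = c(3, 3, nFrames))
    for (k in seq_len(nFrames)) {
        coords[1, , k] <- c(3, 3, zUp)
        coords[2, , k] <- c(3, 3, zLo)
        coords[3, , k] <- if (is.matrix(peXYZ)) peXYZ[k, ] else peXYZ
    }
    top <- buildTopology(atoms, xyz = coords[, , 1])
    newTrajectory(seq_len(nFrames) - 1, coords,
                  matrix(box, nFrames, 3, byrow = TRUE), top)
}

## Ideal all-trans zigzag chain along +z with tetrahedral C-C-C angles;
## its reconstructed C-H vectors lie exactly in the xy-plane, so the
## closed-form order parameter is -0.5 at every interior carbon.
idealChain <- function(nC = 8, bond = 0.153, origin = c(1, 1, 1)) {
    alpha <- (pi - acos(-1 / 3)) / 2     # half the bond-supplement angle
    dirs <- cbind(rep(c(1, -1), length.out = nC - 1) * sin(alpha), 0,
                  cos(alpha)) * bond
    rbind(origin, origin + apply(dirs, 2, cumsum))
}

## standard mixed-event script on 22 PEs used by several tests
mixedScript <- function() {
    eventScript(
        pe = 1:9,
        kind = c("expel", "expel", "expel", "flipflop", "flipflop",
                 "flipflop", "pbc_cross", "expel_reenter", "stay"),
        start = c(10, 15, 20, 10, 15, 20, 12, 10, 1),
        end = c(30, 35, 40, 40, 45, 50, 35, 60, 80))
}
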