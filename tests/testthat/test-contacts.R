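test_that("no water near the tails of an undisturbed bilayer", {
    sim <- makeBilayerTrajectory(n_pe = 2, n_frames = 3, n_waters = 80,
                                 seed = 15)
    expect_equal(waterNearTails(sim$trajectory, 1), 0L)
})

test_that("scripted interior waters are counted exactly", {
    iw <- data.frame(n = 3, start = 2, end = 8)
    sim <- makeBilayerTrajectory(n_pe = 1, n_frames = 10, n_waters = 40,
                                 interior_waters = iw, seed = 16)
    counts <- vapply(1:10, function(k) waterNearTails(sim$trajectory, k),
                     integer(1))
    expect_equal(counts, sim$truth$interiorWaters)
    ## brute-force check on one frame: distance of every counted water
    tr <- sim$trajectory; top <- topology(tr)
    tails <- match(top@roles$tail_carbon_last3, top@atoms$id)
    wat <- match(top@roles$water_site, top@atoms$id)
    xyz <- frameCoords(tr, 5); box <- boxMatrix(tr)[5, ]
    mind <- vapply(wat, function(i) {
        d <- sweep(xyz[tails, , drop = FALSE], 2, xyz[i, ])
        for (c in 1:3) d[, c] <- d[, c] - box[c] * round(d[, c] / box[c])
        min(sqrt(rowSums(d^2)))
    }, numeric(1))
    expect_equal(sum(mind <= 0.5), counts[5])
})

test_that("the r_water cutoff boundary is inclusive at r and exclusive past it", {
    ## hand-built: one tail atom, one water just inside / outside 0.5 nm
    atoms <- data.frame(id = 1:4, name = c("P", "C316", "OW", "OW"),
                        molid = c(1L, 1L, 2L, 3L), resname =
                            c("POPC", "POPC", "SOL", "SOL"))
    coords <- array(0, dim = c(4, 3, 1))
    coords[1, , 1] <- c(2, 2, 4)
    coords[2, , 1] <- c(2, 2, 3)
    coords[3, , 1] <- c(2, 2, 3.499)   # 0.499 nm away
    coords[4, , 1] <- c(2, 2, 3.502)   # 0.502 nm away
    top <- buildTopology(atoms, xyz = coords[, , 1])
    ## single leaflet is fine here; build trajectory directly
    tr <- newTrajectory(0, coords, matrix(c(5, 5, 8), 1, 3), top)
    cfg <- analysisConfig()
    expect_equal(waterNearTails(tr, 1, cfg), 1L)
})

test_that("water permeation series averages scripted ramps correctly", {
    iw <- data.frame(n = c(1, 1), start = c(1, 6), end = c(10, 10))
    sim <- makeBilayerTrajectory(n_pe = 1, n_frames = 10, n_waters = 20,
                                 interior_waters = iw, seed = 17)
    wp <- waterPermeationSeries(sim$trajectory)
    expect_equal(wp$series$count, sim$truth$interiorWaters)
    expect_equal(wp$series$per_lipid, sim$truth$interiorWaters / 128)
    expect_equal(wp$mean, mean(sim$truth$interiorWaters / 128))
    expect_equal(wp$sd, sd(sim$truth$interiorWaters / 128))
})

test_that("waterNearTails is invariant under wrapping and translation", {
    iw <- data.frame(n = 2, start = 1, end = 6)
    sim <- makeBilayerTrajectory(n_pe = 1, n_frames = 6, n_waters = 30,
                                 interior_waters = iw, seed = 18)
    tr <- sim$trajectory
    n0 <- waterNearTails(tr, 3)
    tr@coords[, 3, ] <- (tr@coords[, 3, ] + 2.2) %% tr@box[1, 3]
    expect_equal(waterNearTails(tr, 3), n0)
})

test_that("a single species interacts only with itself (f = 1)", {
    mx <- makeLatticeMixture(30, 0, "ideal", seed = 19)
    f <- fractionalInteractions(mx)
    expect_equal(unname(f$fraction["A", "A"]), 1)
})

test_that("fraction matrices are row-stochastic to 1e-12", {
    for (s in 1:4) {
        mx <- makeLatticeMixture(40, 60, "ideal", seed = s)
        f <- fractionalInteractions(mx)
        expect_lt(max(abs(rowSums(f$fraction) - 1)), 1e-12)
    }
})

test_that("pair counting agrees exactly with brute-force enumeration", {
    cfg <- analysisConfig()
    for (s in 1:3) {
        mx <- makeLatticeMixture(22, 26, "ideal", seed = 100 + s)
        f <- fractionalInteractions(mx, cfg)
        n <- nrow(mx$xy); L <- mx$box[1]
        C <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
            dx <- mx$xy[i, 1] - mx$xy[j, 1]; dx <- dx - L * round(dx / L)
            dy <- mx$xy[i, 2] - mx$xy[j, 2]; dy <- dy - L * round(dy / L)
            if (sqrt(dx^2 + dy^2) < cfg@contactCutoff) {
                a <- mx$species[i]; b <- mx$species[j]
                C[a, b] <- C[a, b] + 1
                if (a != b) C[b, a] <- C[b, a] + 1
            }
        }
        expect_identical(unname(f$raw), unname(C))
        chat <- C
        chat["A", "A"] <- C["A", "A"] / (22 * 21 / 2)
        chat["B", "B"] <- C["B", "B"] / (26 * 25 / 2)
        chat["A", "B"] <- chat["B", "A"] <- C["A", "B"] / (22 * 26)
        expect_equal(unname(f$fraction), unname(chat / rowSums(chat)))
    }
})

test_that("trajectory fractional interactions use the PE-bearing leaflet", {
    sim <- makeBilayerTrajectory(n_pe = 8, n_frames = 5, seed = 20)
    f <- fractionalInteractions(sim$trajectory)
    expect_equal(rownames(f$fraction), c("PE", "POPC"))
    expect_equal(unname(f$N["POPC"]), 64)   # one leaflet only
    expect_equal(unname(f$N["PE"]), 8)
    expect_lt(max(abs(rowSums(f$fraction) - 1)), 1e-12)
})
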