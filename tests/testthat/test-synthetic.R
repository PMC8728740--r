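test_that("generators are bitwise reproducible under a fixed seed", {
    a <- makeBilayerTrajectory(n_pe = 4, n_frames = 10, seed = 7)
    b <- makeBilayerTrajectory(n_pe = 4, n_frames = 10, seed = 7)
    expect_identical(a$trajectory@coords, b$trajectory@coords)
    expect_identical(a$truth, b$truth)
    expect_identical(makeBrownianWalkers(0.1, 3, 0.1, 50, seed = 2),
                     makeBrownianWalkers(0.1, 3, 0.1, 50, seed = 2))
    expect_identical(makeOrientationEnsemble("isotropic", 100, seed = 3),
                     makeOrientationEnsemble("isotropic", 100, seed = 3))
})

test_that("generators do not disturb the caller's RNG stream", {
    set.seed(42); before <- runif(1)
    set.seed(42); invisible(makeBilayerTrajectory(n_pe = 1, n_frames = 2,
                                                  seed = 9))
    expect_identical(runif(1), before)
})

test_that("an all-stay script yields zero events and a constant series", {
    sim <- makeBilayerTrajectory(n_pe = 5, n_frames = 30, seed = 1)
    expect_equal(nrow(sim$truth$events), 0L)
    expect_equal(sim$truth$remaining, rep(5L, 30))
})

test_that("expelling 5 of 22 PEs leaves 17 in the remaining series", {
    sc <- eventScript(pe = 1:5, kind = "expel",
                      start = seq(10, 18, 2), end = seq(30, 38, 2))
    sim <- makeBilayerTrajectory(n_pe = 22, script = sc, n_frames = 60,
                                 seed = 3)
    expect_equal(tail(sim$truth$remaining, 1), 17L)
    expect_equal(sim$truth$remaining[1], 22L)
})

test_that("a boundary crossing is labelled pbc_cross in the ground truth", {
    sc <- eventScript(pe = 1, kind = "pbc_cross", start = 5, end = 25)
    sim <- makeBilayerTrajectory(n_pe = 2, script = sc, n_frames = 40,
                                 seed = 4)
    expect_equal(sim$truth$events$kind, "pbc_cross")
    expect_false(any(sim$truth$events$kind == "flipflop"))
})

test_that("scripts referencing unknown PEs or frames are rejected", {
    sc <- eventScript(pe = 3, kind = "expel", start = 2, end = 8)
    expect_error(makeBilayerTrajectory(n_pe = 2, script = sc, n_frames = 10),
                 "unknown PE")
    sc2 <- eventScript(pe = 1, kind = "expel", start = 2, end = 50)
    expect_error(makeBilayerTrajectory(n_pe = 2, script = sc2, n_frames = 10),
                 "exceed")
    expect_error(eventScript(pe = c(1, 1), kind = c("expel", "flipflop"),
                             start = c(1, 5), end = c(10, 12)),
                 "overlapping")
})

test_that("ground truth is consistent with an independent re-scan", {
    sim <- makeBilayerTrajectory(n_pe = 9, script = mixedScript(),
                                 n_frames = 80, seed = 2)
    expect_equal(rescanRemaining(sim$trajectory, sim$truth),
                 sim$truth$remaining)
})

test_that("Brownian walkers have the prescribed increment statistics", {
    w0 <- makeBrownianWalkers(0, 5, 0.1, 100, seed = 1)
    expect_true(all(w0 == 0))
    D <- 0.02; dt <- 0.5
    w <- makeBrownianWalkers(D, 200, dt, 400, seed = 6)
    inc <- apply(w, c(1, 3), diff)       # [step, walker, axis]
    expect_lt(abs(mean(inc)), 3 * sd(inc) / sqrt(length(inc)))
    v <- var(as.vector(inc))
    se <- sqrt(2 / (length(inc) - 1)) * v
    expect_lt(abs(v - 2 * D * dt), 3 * se)
})

test_that("orientation ensembles hit their closed-form order parameters", {
    expect_equal(orderParameter(makeOrientationEnsemble("aligned", 50)), 1)
    expect_equal(orderParameter(
        makeOrientationEnsemble("perpendicular", 50, seed = 2)), -0.5)
    expect_lt(abs(orderParameter(
        makeOrientationEnsemble("isotropic", 1e5, seed = 3))), 0.01)
    th <- 0.7
    expect_equal(orderParameter(
        makeOrientationEnsemble("cone", 40, theta0 = th, seed = 4)),
        (3 * cos(th)^2 - 1) / 2)
})

test_that("umbrella windows under a flat potential are Gaussian", {
    k <- 100; n <- 2e4
    win <- makeUmbrellaSamples(function(x) 0 * x, centers = c(0.8, 1.2),
                               k = k, n_samples = n, support = c(0, 2),
                               seed = 5)
    expect_length(win, 2L)
    s <- win[[1]]@samples
    sigma2 <- RT310 / k
    expect_lt(abs(mean(s) - 0.8), 3 * sqrt(sigma2 / n))
    expect_lt(abs(var(s) - sigma2), 4 * sigma2 * sqrt(2 / n))
    ## stiffer springs concentrate samples at the centre
    win2 <- makeUmbrellaSamples(function(x) 0 * x, centers = 0.8,
                                k = 100 * k, n_samples = n,
                                support = c(0, 2), seed = 5)
    expect_lt(sd(win2[[1]]@samples), sd(s) / 5)
})

test_that("the study window layout gives 20 windows 0.1 nm apart", {
    centers <- seq(0, 1.9, by = 0.1)
    win <- makeUmbrellaSamples(function(x) 0 * x, centers = centers,
                               k = 239, n_samples = 10, support = c(-0.5, 2.5),
                               seed = 1)
    expect_length(win, 20L)
    expect_equal(diff(vapply(win, function(w) w@center, numeric(1))),
                 rep(0.1, 19))
})

test_that("non-finite potentials are rejected", {
    expect_error(makeUmbrellaSamples(function(x) ifelse(x > 1, Inf, 0),
                                     centers = 0.5, k = 10, n_samples = 10,
                                     support = c(0, 2)), "finite")
})

test_that("lattice mixtures cover the single-species and demixed limits", {
    one <- makeLatticeMixture(10, 0, "ideal", seed = 1)
    expect_true(all(one$species == "A"))
    dm <- makeLatticeMixture(400, 400, "demixed", strength = 1, seed = 2)
    f <- fractionalInteractions(dm)
    expect_gt(f$fraction["A", "A"], 0.85)
    expect_gt(f$fraction["B", "B"], 0.85)
})
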