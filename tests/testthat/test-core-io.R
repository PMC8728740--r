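test_that("a hand-written 2-frame GRO file parses to 2 frames of 4 atoms", {
    lines <- c(
        "tiny, t= 0.0",
        "    4",
        "    1POPC    P    1   1.000   2.000   6.450",
        "    1POPC C214    2   1.000   2.100   5.000",
        "    2SOL    OW    3   0.500   0.500   8.000",
        "    3PEA   REF    4   1.200   2.000   6.100",
        "   6.60000   6.60000   9.35000",
        "tiny, t= 1000.0",
        "    4",
        "    1POPC    P    1   1.000   2.000   6.460",
        "    1POPC C214    2   1.000   2.100   5.010",
        "    2SOL    OW    3   0.500   0.500   8.010",
        "    3PEA   REF    4   1.200   2.000   6.110",
        "   6.60000   6.60000   9.35000")
    f <- withr::local_tempfile(fileext = ".gro")
    writeLines(lines, f)
    tr <- readTrajectory(f)
    expect_equal(nFrames(tr), 2L)
    expect_equal(nAtoms(tr), 4L)
    expect_equal(frameTimes(tr), c(0, 1))     # ps in file, ns in object
    expect_equal(frameCoords(tr, 1)[1, ], c(1, 2, 6.45))
    expect_equal(boxMatrix(tr)[2, ], c(6.6, 6.6, 9.35))
    top <- topology(tr)
    expect_equal(top@atoms$molkind, c("POPC", "POPC", "water", "PE"))
    expect_equal(roleAtoms(top, "pe_reference"), 4L)
})

test_that("non-monotone frame times are rejected", {
    sim <- makeBilayerTrajectory(n_pe = 1, n_frames = 2, n_waters = 4,
                                 n_per_leaflet = 4, seed = 1)
    f <- withr::local_tempfile(fileext = ".gro")
    writeTrajectory(sim$trajectory, f)
    lines <- readLines(f)
    lines <- sub("t= 1000.0000", "t= 0.0000", lines, fixed = TRUE)
    writeLines(lines, f)
    expect_error(readTrajectory(f), "strictly increasing")
})

test_that("GRO write/read round trip is the identity within 0.001 nm", {
    sim <- makeBilayerTrajectory(n_pe = 3, n_frames = 4, seed = 2)
    tr <- sim$trajectory
    f <- withr::local_tempfile(fileext = ".gro")
    writeTrajectory(tr, f)
    tr2 <- readTrajectory(f)
    expect_equal(nFrames(tr2), nFrames(tr))
    expect_lt(max(abs(tr2@coords - tr@coords)), 0.001)
    expect_equal(frameTimes(tr2), frameTimes(tr))
    expect_equal(boxMatrix(tr2), boxMatrix(tr), ignore_attr = TRUE)
    ## 64 + 64 POPC residues preserved
    expect_equal(length(unique(topology(tr2)@atoms$molid[
        topology(tr2)@atoms$molkind == "POPC"])), 128L)
    ## role resolution is deterministic
    tr3 <- readTrajectory(f)
    expect_identical(topology(tr3)@roles, topology(tr2)@roles)
})

test_that("unparsable frames are reported with their index", {
    f <- withr::local_tempfile(fileext = ".gro")
    writeLines(c("bad, t= 0.0", "    2",
                 "    1POPC    P    1   1.000   2.000   6.450",
                 "    1POPC    X    2   oops    2.000   6.450",
                 "   6.60000   6.60000   9.35000"), f)
    expect_error(readTrajectory(f), "frame 1")
    expect_error(readTrajectory(tempfile()), "not found")
})

test_that("multi-model PDB files read with Angstrom-to-nm conversion", {
    f <- withr::local_tempfile(fileext = ".pdb")
    at <- function(i, nm, res, resno, x, y, z)
        sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
                i, nm, res, resno, x, y, z)
    writeLines(c(
        "CRYST1   66.000   66.000   93.500  90.00  90.00  90.00 P 1",
        "MODEL        1",
        at(1, "P", "POPC", 1, 10, 20, 64.5),
        at(2, "P", "POPC", 2, 10, 20, 25.5),
        "ENDMDL",
        "MODEL        2",
        at(1, "P", "POPC", 1, 10, 20, 64.6),
        at(2, "P", "POPC", 2, 10, 20, 25.6),
        "ENDMDL",
        "END"), f)
    tr <- readTrajectory(f)
    expect_equal(nFrames(tr), 2L)
    expect_equal(frameCoords(tr, 1)[1, ], c(1, 2, 6.45))
    expect_equal(boxMatrix(tr)[1, ], c(6.6, 6.6, 9.35))
})

test_that("YAML configuration round-trips and rejects unknown keys", {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("r_expel: 1.1", "temperature: 300", "debounce_frames: 3"), f)
    cfg <- readAnalysisConfig(f)
    expect_equal(cfg@rExpel, 1.1)
    expect_equal(cfg@temperature, 300)
    expect_equal(cfg@debounceFrames, 3L)
    expect_equal(cfg@rWater, 0.5)  # untouched default
    writeLines("not_a_key: 1", f)
    expect_error(readAnalysisConfig(f), "unknown configuration keys")
})

test_that("invalid configurations are rejected by the validity method", {
    expect_error(analysisConfig(r_expel = -1), "cutoffs")
    expect_error(analysisConfig(msd_fit_window = c(0.9, 0.1)), "msdFitWindow")
    expect_error(analysisConfig(wham_tol = 0), "whamTol")
})

test_that("PE counts follow the leaflet-percentage convention", {
    expect_identical(peCountFromPercent(5), 3L)
    expect_identical(peCountFromPercent(35), 22L)
    expect_identical(peCountFromPercent(0), 0L)
})

test_that("the mM conversion is linear and spans the study window", {
    expect_equal(peConcentration(0, 7000), 0)
    expect_equal(peConcentration(44, 7000), 2 * peConcentration(22, 7000))
    ## 22 PEs over a typical hydration count lands in the stated
    ## 20-160 mM window
    c35 <- peConcentration(22, 7600)
    expect_gt(c35, 20); expect_lt(c35, 200)
    c5 <- peConcentration(3, 7600)
    expect_gt(c5, 10); expect_lt(c5, 40)
})

test_that("umbrella sample files read with comment skipping", {
    d <- withr::local_tempdir()
    for (i in 1:2) {
        writeLines(c("# pull output", "@ legend",
                     sprintf("%f %f", 1:5, (1:5) / 10 + i)),
                   file.path(d, sprintf("win%d.xvg", i)))
    }
    meta <- data.frame(center = c(1.1, 2.1), k = c(100, 100),
                       file = c("win1.xvg", "win2.xvg"))
    mf <- file.path(d, "meta.csv")
    write.csv(meta, mf, row.names = FALSE)
    win <- readUmbrellaWindows(mf, dir = d)
    expect_length(win, 2L)
    expect_equal(win[[1]]@center, 1.1)
    expect_equal(win[[2]]@samples, (1:5) / 10 + 2)
})
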