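#' Construct a Trajectory from in-memory parts
#'
#' @param times frame times in ns (strictly increasing).
#' @param coords \code{[atom, xyz, frame]} array in nm.
#' @param box \code{[frame, xyz]} matrix of box vectors in nm.
#' @param topology a \linkS4class{Topology}.
#' @return a \linkS4class{Trajectory}
#' @export
newTrajectory <- function(times, coords, box, topology) {
    if (is.null(dim(box))) box <- matrix(box, nrow = length(times),
                                         ncol = 3, byrow = TRUE)
    new("Trajectory", times = as.numeric(times), coords = coords,
        box = box, topology = topology)
}

## ---- GRO (fixed-column GROMACS coordinate format) -----------------------

.parseGroFrame <- function(lines, frameIndex) {
    title <- lines[1]
    nat <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(nat) || length(lines) < nat + 3L)
        stop(sprintf("format error in frame %d: bad atom count line",
                     frameIndex))
    at <- lines[3:(nat + 2L)]
    resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
    resname <- trimws(substr(at, 6, 10))
    name <- trimws(substr(at, 11, 15))
    x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
    if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))
        stop(sprintf("format error in frame %d: unparsable atom line",
                     frameIndex))
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[nat + 3L]),
                                                "\\s+")[[1]][1:3]))
    if (anyNA(box))
        stop(sprintf("format error in frame %d: unparsable box line",
                     frameIndex))
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    list(resid = resid, resname = resname, name = name,
         xyz = cbind(x, y, z), box = box, time = time)
}

.readGroFrames <- function(path) {
    lines <- readLines(path)
    frames <- list()
    i <- 1L; fi <- 1L
    while (i + 2L <= length(lines) && nzchar(trimws(lines[i + 1L]))) {
        nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
        if (is.na(nat))
            stop(sprintf("format error in frame %d: bad atom count line", fi))
        frames[[fi]] <- .parseGroFrame(lines[i:(i + nat + 2L)], fi)
        i <- i + nat + 3L
        fi <- fi + 1L
        if (i > length(lines)) break
    }
    frames
}

#' Read a multi-frame trajectory (GRO or PDB)
#'
#' GRO files are parsed by fixed columns; concatenated frames become
#' trajectory frames with times taken from \code{t=} tags in the title
#' lines (falling back to 0, 1, 2, ... ns). PDB files (MODEL/ENDMDL) are
#' read through \pkg{bio3d} and converted from Angstrom to nm. Roles are
#' resolved from atom/residue name patterns and initial leaflets assigned
#' from the first frame.
#'
#' @param path path to a \code{.gro} or \code{.pdb} file.
#' @param roleSpec name-pattern overrides, see \code{\link{defaultRoleSpec}}.
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(path, roleSpec = defaultRoleSpec()) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.pdb$", path, ignore.case = TRUE))
        return(.readPdbTrajectory(path, roleSpec))
    frames <- .readGroFrames(path)
    if (!length(frames)) stop("no frames in ", path)
    f1 <- frames[[1]]
    nat <- nrow(f1$xyz)
    for (k in seq_along(frames))
        if (nrow(frames[[k]]$xyz) != nat)
            stop(sprintf("format error in frame %d: atom count changed", k))
    times <- vapply(frames, `[[`, numeric(1), "time")
    if (anyNA(times)) times <- seq_along(frames) - 1
    times <- times / 1000  # GRO titles carry ps; store ns
    if (length(times) > 1L && any(diff(times) <= 0))
        stop("frame times are not strictly increasing")
    coords <- array(0, dim = c(nat, 3, length(frames)))
    box <- matrix(0, length(frames), 3)
    for (k in seq_along(frames)) {
        coords[, , k] <- frames[[k]]$xyz
        box[k, ] <- frames[[k]]$box
    }
    atoms <- data.frame(id = seq_len(nat), name = f1$name,
                        molid = cumsum(c(TRUE, diff(f1$resid) != 0L)),
                        resname = f1$resname, stringsAsFactors = FALSE)
    top <- buildTopology(atoms, roleSpec, xyz = coords[, , 1])
    newTrajectory(times, coords, box, top)
}

.readPdbTrajectory <- function(path, roleSpec) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nat <- ncol(xyz) / 3L
    nfr <- nrow(xyz)
    coords <- array(0, dim = c(nat, 3, nfr))
    for (k in seq_len(nfr))
        coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
    resid <- as.integer(pdb$atom$resno)
    atoms <- data.frame(id = seq_len(nat), name = trimws(pdb$atom$elety),
                        molid = cumsum(c(TRUE, diff(resid) != 0L)),
                        resname = trimws(pdb$atom$resid),
                        stringsAsFactors = FALSE)
    box <- rep(c(10, 10, 10), each = nfr)  # fallback when no CRYST1
    cr <- readLines(path, n = 50)
    cl <- grep("^CRYST1", cr, value = TRUE)
    if (length(cl))
        box <- rep(as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                                substr(cl[1], 25, 33))) / 10, each = nfr)
    top <- buildTopology(atoms, roleSpec, xyz = coords[, , 1])
    newTrajectory(seq_len(nfr) - 1, coords, matrix(box, nfr, 3), top)
}

#' Write a trajectory as multi-frame GRO
#'
#' Fixed-column GRO output at the format's native 0.001 nm coordinate
#' precision; \code{readTrajectory(writeTrajectory(t))} reproduces
#' \code{t} within that precision.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(traj, path) {
    if (nFrames(traj) < 1L) stop("empty frame list")
    a <- traj@topology@atoms
    resname <- .resnameFor(traj@topology)
    out <- vector("list", nFrames(traj))
    for (k in seq_len(nFrames(traj))) {
        xyz <- traj@coords[, , k]
        lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         a$molid %% 100000L, resname, substr(a$name, 1, 5),
                         a$id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3])
        out[[k]] <- c(sprintf("memperturb frame %d, t= %.4f", k,
                              traj@times[k] * 1000),
                      sprintf("%5d", nrow(a)), lines,
                      sprintf("%10.5f%10.5f%10.5f", traj@box[k, 1],
                              traj@box[k, 2], traj@box[k, 3]))
    }
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot write to ", path)
    on.exit(close(con))
    writeLines(unlist(out), con)
    invisible(path)
}

## residue names for output; topologies built in memory may lack resname
.resnameFor <- function(top) {
    a <- top@atoms
    if (!is.null(a$resname)) return(a$resname)
    c(POPC = "POPC", water = "SOL", ion = "ION", PE = "PEA")[a$molkind]
}

## ---- umbrella-window sample files ---------------------------------------

#' Read umbrella-sampling windows from sample files
#'
#' Each window is a whitespace-delimited two-column text file (time,
#' reaction coordinate xi in nm) in the style of standard pull-output
#' files; lines starting with \code{#} or \code{@} are skipped. Window
#' metadata (centre, spring constant, file) comes from a table.
#'
#' @param meta data.frame with columns \code{center} (nm), \code{k}
#'   (kcal/mol/nm^2) and \code{file}, or the path of a CSV/YAML file
#'   holding such a table.
#' @param dir directory the \code{file} entries are relative to.
#' @return list of \linkS4class{UmbrellaWindow}
#' @export
readUmbrellaWindows <- function(meta, dir = ".") {
    if (is.character(meta) && length(meta) == 1L) {
        meta <- if (grepl("\\.ya?ml$", meta, ignore.case = TRUE))
            do.call(rbind.data.frame, yaml::read_yaml(meta))
        else utils::read.csv(meta)
    }
    stopifnot(all(c("center", "k", "file") %in% names(meta)))
    lapply(seq_len(nrow(meta)), function(i) {
        p <- file.path(dir, meta$file[i])
        if (!file.exists(p)) stop("sample file not found: ", p)
        lines <- grep("^\\s*[#@]", readLines(p), value = TRUE, invert = TRUE)
        vals <- utils::read.table(text = lines)
        umbrellaWindow(meta$center[i], meta$k[i], vals[[2]])
    })
}

#' Construct an umbrella window
#'
#' @param center restraint centre (nm).
#' @param k spring constant (kcal/mol/nm^2); 0 means unbiased.
#' @param samples sampled reaction-coordinate values (nm).
#' @return an \linkS4class{UmbrellaWindow}
#' @export
umbrellaWindow <- function(center, k, samples) {
    new("UmbrellaWindow", center = as.numeric(center), k = as.numeric(k),
        samples = as.numeric(samples))
}
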