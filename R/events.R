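## Event detection: classify PE trajectories into expulsion, flip-flop and
## periodic-boundary-crossing events, with debouncing, and produce the
## remaining-in-leaflet occupancy series.

#' Classify the instantaneous state of a PE molecule
#'
#' A PE belongs to a leaflet while its reference site is within
#' \code{r_expel} (default 0.9 nm, minimum image) of any of that leaflet's
#' POPC phosphate atoms; beyond that distance from both leaflets it is in
#' water. When both leaflets' cutoffs are satisfied the nearer leaflet
#' wins. Relative to the molecule's initial leaflet the state is reported
#' as \code{initial_leaflet}, \code{other_leaflet} or \code{water}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pe PE molecule id.
#' @param frame frame index.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return one of "initial_leaflet", "other_leaflet", "water".
#' @export
classifyState <- function(traj, pe, frame, config = analysisConfig()) {
    st <- .rawStates(traj, config)
    pes <- molIds(topology(traj), "PE")
    i <- match(pe, pes)
    if (is.na(i)) stop("unknown PE molecule id: ", pe)
    st$state[i, frame]
}

## Raw per-frame classification for all PEs at once.
## Returns state matrix [pe, frame] with levels initial/other/water,
## plus interior flag (within the bilayer slab but outside both cutoffs),
## unwrapped reference z, and geometry.
.rawStates <- function(traj, config) {
    top <- topology(traj)
    pes <- molIds(top, "PE")
    ref <- roleIdx(top, "pe_reference")
    pidx <- roleIdx(top, "phosphate")
    plab <- top@leaflet0[as.character(top@atoms$molid[pidx])]
    peLeaf <- top@leaflet0[as.character(pes)]
    nf <- nFrames(traj)
    state <- matrix("water", length(pes), nf)
    interior <- matrix(FALSE, length(pes), nf)
    zc <- numeric(nf); leafThick <- numeric(nf)
    zu <- matrix(0, length(pes), nf)
    for (k in seq_len(nf)) {
        xyz <- traj@coords[, , k]
        box <- traj@box[k, ]
        zUp <- mean(xyz[pidx[plab == "upper"], 3])
        zLo <- mean(xyz[pidx[plab == "lower"], 3])
        zc[k] <- (zUp + zLo) / 2
        leafThick[k] <- (zUp - zLo) / 2
        pUp <- xyz[pidx[plab == "upper"], , drop = FALSE]
        pLo <- xyz[pidx[plab == "lower"], , drop = FALSE]
        for (i in seq_along(pes)) {
            p <- xyz[ref[i], ]
            dUp <- min(minImageDist(p, pUp, box))
            dLo <- min(minImageDist(p, pLo, box))
            dInit <- if (peLeaf[i] == "upper") dUp else dLo
            dOther <- if (peLeaf[i] == "upper") dLo else dUp
            if (!config@expelBothLeaflets) dOther <- Inf
            state[i, k] <-
                if (dInit <= config@rExpel &&
                    (dOther > config@rExpel || dInit <= dOther))
                    "initial_leaflet"
                else if (dOther <= config@rExpel) "other_leaflet"
                else "water"
            if (state[i, k] == "water")
                interior[i, k] <-
                    abs(minImage(p[3] - zc[k], box[3])) < leafThick[k]
        }
    }
    for (i in seq_along(pes))
        zu[i, ] <- unwrapZ(traj@coords[ref[i], 3, ], traj@box[1, 3])
    list(state = state, interior = interior, zu = zu, zc = zc,
         leafThick = leafThick, pes = pes, peLeaf = peLeaf)
}

## Debounce a raw state sequence: a new state commits once it has
## persisted for `debounce` consecutive frames; interior frames extend the
## current committed state (a molecule crossing the bilayer interior is in
## transit, not in water).
.commitStates <- function(raw, interior, debounce) {
    nf <- length(raw)
    eff <- raw
    committed <- character(nf)
    cur <- raw[1]
    runState <- NA_character_; runLen <- 0L; runStart <- NA_integer_
    pendingStart <- NA_integer_
    departure <- rep(NA_integer_, nf)
    for (k in seq_len(nf)) {
        s <- if (interior[k]) cur else eff[k]
        if (identical(s, cur)) {
            runState <- NA_character_; runLen <- 0L
        } else if (identical(s, runState)) {
            runLen <- runLen + 1L
            if (runLen >= debounce) {
                cur <- s
                departure[k] <- runStart
                runState <- NA_character_; runLen <- 0L
            }
        } else {
            runState <- s; runLen <- 1L; runStart <- k
            if (debounce <= 1L) {
                cur <- s
                departure[k] <- runStart
                runState <- NA_character_; runLen <- 0L
            }
        }
        committed[k] <- cur
    }
    list(committed = committed, departure = departure)
}

#' Detect PE expulsion, flip-flop and boundary-crossing events
#'
#' Runs a debounced state machine per PE over the
#' \code{\link{classifyState}} series. A committed transition to water is
#' an expulsion. A committed arrival in the other leaflet is a flip-flop
#' only when the unwrapped z-path actually traversed the bilayer interior
#' and the net unwrapped displacement is below half the box height;
#' arrivals whose unwrapped z jumped by more than box_z/2 crossed the
#' periodic boundary and are recorded as
#' \code{pbc_crossing_as_expulsion} (counted with expulsions, never as
#' flip-flops). Re-entry into a leaflet after an expulsion is tracked in
#' the occupancy series but does not erase the expulsion event. Frames the
#' molecule spends inside the bilayer interior (beyond both cutoffs but
#' within a leaflet thickness of the centre) extend the previous state, so
#' slow flips are not miscounted as expulsions.
#'
#' @param traj a \linkS4class{Trajectory} with at least
#'   \code{debounce_frames} frames.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{events} (data.frame: pe, kind, departure,
#'   commit, origin, destination) and \code{occupancy} (data.frame: frame,
#'   initial_leaflet, other_leaflet, water).
#' @export
detectEvents <- function(traj, config = analysisConfig()) {
    nf <- nFrames(traj)
    if (nf < config@debounceFrames)
        stop("trajectory shorter than the debounce window")
    ## the study's bilayers show no POPC flip-flop; assert it
    if (nf > 1L) {
        l1 <- assignLeaflets(traj, 1L); l2 <- assignLeaflets(traj, nf)
        popc <- as.character(molIds(topology(traj), "POPC"))
        if (!identical(l1[popc], l2[popc]))
            warning("POPC leaflet assignment changed between frames")
    }
    rs <- .rawStates(traj, config)
    npe <- length(rs$pes)
    boxZ <- traj@box[1, 3]
    events <- NULL
    occ <- matrix(0L, nf, 3,
                  dimnames = list(NULL, c("initial_leaflet", "other_leaflet",
                                          "water")))
    for (i in seq_len(npe)) {
        cs <- .commitStates(rs$state[i, ], rs$interior[i, ],
                            config@debounceFrames)
        comm <- cs$committed
        for (k in seq_len(nf)) occ[k, comm[k]] <- occ[k, comm[k]] + 1L
        ## walk committed transitions; departure = last frame the raw
        ## state still matched the state being left (covers the interior
        ## transit frames of a slow flip)
        lastIn <- function(s, upto) {
            j <- which(rs$state[i, seq_len(upto)] == s)
            if (length(j)) j[length(j)] else upto
        }
        trans <- which(comm[-1] != comm[-nf]) + 1L
        residenceLeft <- NA_integer_   # frame it left its last leaflet
        pendingWater <- FALSE          # excursion has a tentative expulsion
        pendingOrigin <- NA_character_
        for (k in trans) {
            from <- comm[k - 1L]; to <- comm[k]
            dep <- lastIn(from, k)
            if (to == "water") {
                if (from %in% c("initial_leaflet", "other_leaflet")) {
                    residenceLeft <- dep
                    pendingWater <- TRUE
                    pendingOrigin <- from
                    events <- rbind(events, data.frame(
                        pe = rs$pes[i], kind = "expulsion",
                        departure = dep, commit = k,
                        origin = from, destination = "water"))
                }
            } else if (from == "water") {
                ## arrival from water: re-entry, or the tail of a
                ## boundary crossing
                if (pendingWater && !is.na(residenceLeft) &&
                    to != pendingOrigin) {
                    span <- residenceLeft:k
                    crossed <- any(abs(rs$zu[i, span] - rs$zc[span]) >
                                   boxZ / 2)
                    if (crossed) {
                        ## reclassify the excursion: crossed the z-boundary
                        j <- nrow(events)
                        events$kind[j] <- "pbc_crossing_as_expulsion"
                        events$commit[j] <- k
                        events$destination[j] <- "other_leaflet"
                    }
                }
                pendingWater <- FALSE
            } else {
                ## direct leaflet-to-leaflet transition
                span <- dep:k
                crossed <- any(abs(rs$zu[i, span] - rs$zc[span]) > boxZ / 2)
                reachedInterior <- any(abs(rs$zu[i, span] - rs$zc[span]) <
                                       rs$leafThick[span])
                kind <- if (crossed || !reachedInterior)
                        "pbc_crossing_as_expulsion" else "flip_flop"
                events <- rbind(events, data.frame(
                    pe = rs$pes[i], kind = kind, departure = dep,
                    commit = k, origin = from, destination = "other_leaflet"))
            }
        }
    }
    if (is.null(events))
        events <- data.frame(pe = integer(0), kind = character(0),
                             departure = integer(0), commit = integer(0),
                             origin = character(0), destination = character(0))
    rownames(events) <- NULL
    list(events = events,
         occupancy = data.frame(frame = seq_len(nf), occ,
                                check.names = FALSE))
}

#' Remaining-in-leaflet series
#'
#' Projection of the occupancy series onto the count of PEs still in their
#' initial leaflet; re-entries appear as recoveries.
#'
#' @param occupancy the occupancy data.frame from \code{\link{detectEvents}}.
#' @return integer vector, one count per frame.
#' @export
remainingSeries <- function(occupancy) {
    as.integer(occupancy$initial_leaflet)
}

#' Event summary counts
#'
#' @param events the events data.frame from \code{\link{detectEvents}}.
#' @return list with \code{expulsions}, \code{flipflops},
#'   \code{pbc_crossings}.
#' @export
eventSummary <- function(events) {
    list(expulsions = sum(events$kind == "expulsion"),
         flipflops = sum(events$kind == "flip_flop"),
         pbc_crossings = sum(events$kind == "pbc_crossing_as_expulsion"))
}
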