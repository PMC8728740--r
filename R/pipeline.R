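## Orchestration: run selected analysis stages on a trajectory and emit
## per-stage CSVs plus one consolidated JSON report.

.stageOrder <- c("events", "structure", "order", "diffusion", "water",
                 "contacts", "free_energy")

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order (leaflets and events
#' first; the free-energy stage is independent and runs only when
#' umbrella windows are supplied), writing per-stage CSV tables and a
#' consolidated JSON report. Per-frame statistics are reported as mean
#' +/- sd over the analysed frames. A stage error is recorded in the
#' report and aborts only its dependents; results go to stdout-side
#' files, log lines to stderr.
#'
#' @param trajectory a \linkS4class{Trajectory} or the path of a GRO/PDB
#'   file.
#' @param config an \linkS4class{AnalysisConfig} or the path of a YAML
#'   configuration.
#' @param stages character subset of \code{c("events", "structure",
#'   "order", "diffusion", "water", "contacts", "free_energy")}.
#' @param windows optional list of \linkS4class{UmbrellaWindow} for the
#'   free-energy stage.
#' @param output_dir directory for CSV/JSON outputs (NULL: no files).
#' @param stride frame stride for per-frame statistics.
#' @param membrane_zone xi interval for the free-energy minimum search.
#' @return the report, invisibly a list; written as \code{report.json}
#'   when \code{output_dir} is set.
#' @export
runPipeline <- function(trajectory, config = analysisConfig(),
                        stages = .stageOrder, windows = NULL,
                        output_dir = NULL, stride = 1L,
                        membrane_zone = c(0, 1.95)) {
    if (is.character(trajectory)) trajectory <- readTrajectory(trajectory)
    if (is.character(config)) config <- readAnalysisConfig(config)
    stages <- match.arg(stages, .stageOrder, several.ok = TRUE)
    if (!is.null(output_dir))
        dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    log <- function(stage, msg)
        message(sprintf("[%s] %s", stage, msg))
    report <- list(
        software = list(package = "memperturb",
                        version = as.character(utils::packageVersion("memperturb"))),
        seed = config@seed,
        config = .configAsList(config),
        stages = list())
    failed <- character()
    writeCsv <- function(df, name) {
        if (!is.null(output_dir))
            utils::write.csv(df, file.path(output_dir, name),
                             row.names = FALSE)
    }
    runStage <- function(name, deps, fn) {
        if (!name %in% stages) return()
        if (any(deps %in% failed)) {
            log(name, "skipped: upstream stage failed")
            report$stages[[name]] <<- list(status = "skipped")
            return()
        }
        log(name, "running")
        res <- tryCatch(fn(), error = function(e) e)
        if (inherits(res, "error")) {
            log(name, paste("ERROR:", conditionMessage(res)))
            failed <<- c(failed, name)
            report$stages[[name]] <<- list(status = "error",
                                           message = conditionMessage(res))
        } else {
            report$stages[[name]] <<- c(list(status = "ok"), res)
        }
    }
    eventsOut <- NULL
    runStage("events", character(), function() {
        ev <- detectEvents(trajectory, config)
        eventsOut <<- ev
        writeCsv(ev$events, "events.csv")
        writeCsv(ev$occupancy, "occupancy.csv")
        c(eventSummary(ev$events),
          list(final_remaining = utils::tail(remainingSeries(ev$occupancy), 1)))
    })
    runStage("structure", character(), function() {
        mm <- membraneMetrics(trajectory, stride = stride)
        writeCsv(mm$frames, "structure.csv")
        if (!is.null(mm$pe_depth)) writeCsv(mm$pe_depth, "pe_depth.csv")
        list(apl = list(mean = mean(mm$frames$apl),
                        sd = stats::sd(mm$frames$apl)),
             thickness_pp = list(mean = mean(mm$frames$thickness_pp),
                                 sd = stats::sd(mm$frames$thickness_pp)),
             leaflet_thickness = mean(mm$frames$leaflet_thickness),
             pe_depth = if (is.null(mm$pe_depth)) NULL
                        else list(mean = mean(mm$pe_depth$d),
                                  sd = stats::sd(mm$pe_depth$d)))
    })
    runStage("order", character(), function() {
        op <- orderParameter(trajectory, stride = stride)
        writeCsv(op$profile, "order_profile.csv")
        pe <- tryCatch(peOrderParameter(trajectory, stride = stride),
                       error = function(e) NULL)
        list(popc_mean_scd = op$mean, pe_order = pe)
    })
    runStage("diffusion", character(), function() {
        dl <- lateralDiffusion(trajectory, config = config)
        writeCsv(dl$msd, "msd.csv")
        list(D_L = dl$D, se = dl$se)
    })
    runStage("water", character(), function() {
        wp <- waterPermeationSeries(trajectory, config, stride = stride)
        writeCsv(wp$series, "water.csv")
        list(per_lipid_mean = wp$mean, per_lipid_sd = wp$sd)
    })
    runStage("contacts", "events", function() {
        fi <- fractionalInteractions(trajectory, config, stride = stride)
        long <- expand.grid(i = rownames(fi$fraction),
                            j = colnames(fi$fraction))
        long$fraction <- as.vector(fi$fraction)
        writeCsv(long, "contacts.csv")
        list(fraction = as.data.frame(fi$fraction))
    })
    runStage("free_energy", character(), function() {
        if (is.null(windows)) return(list(note = "no umbrella windows supplied"))
        pmf <- whamSolve(windows, config)
        writeCsv(data.frame(xi = pmf@xi, G = pmf@G, counts = pmf@counts),
                 "pmf.csv")
        pr <- partitionAnalysis(pmf, membrane_zone, config@temperature)
        list(deltaG = pr@deltaG, min_location = pr@minLocation,
             Co_over_Ci = pr@CoOverCi, convention = pr@convention,
             converged = pmf@converged)
    })
    report$failed <- failed
    if (!is.null(output_dir))
        jsonlite::write_json(report, file.path(output_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null")
    invisible(report)
}

.configAsList <- function(config) {
    list(r_expel = config@rExpel, r_water = config@rWater,
         contact_cutoff = config@contactCutoff,
         temperature = config@temperature,
         debounce_frames = config@debounceFrames,
         msd_fit_window = config@msdFitWindow,
         pmf_bin_width = config@pmfBinWidth,
         wham_tol = config@whamTol, wham_max_iter = config@whamMaxIter,
         water_reference_zone = config@waterReferenceZone,
         seed = config@seed)
}

#' Validate a run report against the shipped schema
#'
#' Structural validation of a pipeline report against the JSON schema in
#' \code{system.file("schema", "run-report-schema.json")}: required
#' top-level fields present with the right types and every executed stage
#' carrying a status.
#'
#' @param report a report list (from \code{\link{runPipeline}}) or the
#'   path of a report.json file.
#' @return TRUE, or a character vector of problems.
#' @export
validateRunReport <- function(report) {
    if (is.character(report)) report <- jsonlite::read_json(report)
    schema <- jsonlite::read_json(system.file("schema",
        "run-report-schema.json", package = "memperturb"))
    problems <- character()
    for (f in names(schema$properties)) {
        req <- f %in% unlist(schema$required)
        if (req && is.null(report[[f]]))
            problems <- c(problems, paste("missing required field:", f))
    }
    for (s in names(report$stages))
        if (is.null(report$stages[[s]]$status))
            problems <- c(problems, paste("stage without status:", s))
    if (length(problems)) problems else TRUE
}
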