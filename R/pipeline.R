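## One-config orchestration: simulate -> measure -> kinetics -> events ->
## anisotropy, with seed fan-out, artifact files and a run log.

#' Build a validated pipeline run configuration
#'
#' Collects every stage's parameters with the analysis defaults: 5-min
#' frame interval, k = 1 mean-plus-SD pulse threshold, 30-min clustering
#' window, 20-um streak half-width (40-um domain), 3-px intensity bands,
#' 15-degree orientation bins. The full configuration is echoed into
#' every run's output for provenance.
#'
#' @param outDir output directory.
#' @param seed global seed; per-stage child seeds are derived as
#'   \code{(seed * 48271 + stageIndex * 9973) mod (2^31 - 1)} so stages
#'   can be re-run in isolation reproducibly.
#' @param stages character vector of stages to run, in order.
#' @param nCells,meanAreaUm2,lloydIter tissue generation parameters.
#' @param calibration a \linkS4class{Calibration}.
#' @param dynamics a \code{\link{dynamicsParams}} list (its seed is
#'   overridden by the derived stage seed).
#' @param channelSpec \code{NULL}, or the \code{channels} list for
#'   \code{\link{channelModel}} to paint fluorescence channels.
#' @param thresholdK SD multiplier for the pulse threshold.
#' @param mergeGap pulse merge gap (frames).
#' @param smoothingWindow,reexpansionTolUm2,minTotalDeclineFrac period
#'   detection parameters.
#' @param windowMin event clustering window (minutes).
#' @param widthPx,binDeg,q,corMethod anisotropy parameters.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(outDir = tempfile("apicodyn_run_"), seed = 1,
                      stages = c("simulate", "measure", "kinetics",
                                 "events", "anisotropy"),
                      nCells = 60, meanAreaUm2 = 45, lloydIter = 8,
                      calibration = Calibration(),
                      dynamics = dynamicsParams(),
                      channelSpec = NULL,
                      thresholdK = 1, mergeGap = 0L,
                      smoothingWindow = 3L, reexpansionTolUm2 = 0.5,
                      minTotalDeclineFrac = 0.5,
                      windowMin = 30, widthPx = 3L, binDeg = 15,
                      q = 0.5, corMethod = "pearson") {
    cfg <- as.list(environment())
    stopifnot(all(cfg$stages %in% c("simulate", "measure", "kinetics",
                                    "events", "anisotropy")))
    class(cfg) <- "RunConfig"
    cfg
}

.childSeed <- function(seed, stageIndex)
    as.integer((as.numeric(seed) * 48271 + stageIndex * 9973) %%
               2147483647)

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [runConfig()] arguments; the
#' \code{calibration}, \code{dynamics} and \code{channelSpec} blocks map
#' onto [Calibration()], [dynamicsParams()] and the channel list.
#'
#' @param path YAML file.
#' @return list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    for (nm in setdiff(names(y), c("calibration", "dynamics", "channelSpec")))
        args[[nm]] <- y[[nm]]
    if (!is.null(y$calibration))
        args$calibration <- do.call(Calibration, y$calibration)
    if (!is.null(y$dynamics))
        args$dynamics <- do.call(dynamicsParams, y$dynamics)
    if (!is.null(y$channelSpec)) args$channelSpec <- y$channelSpec
    do.call(runConfig, args)
}

.logLine <- function(con, stage, ...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
    writeLines(msg, con)
}

#' Run the analysis pipeline from one configuration
#'
#' Executes the configured stages in order, writing every artifact
#' (series TIFFs, long-format tables, annotation/pulse/event CSVs,
#' anisotropy and polarity tables, a JSON summary, the echoed
#' configuration and a log) under \code{config$outDir}. Deterministic
#' given the global seed; re-running with the same configuration
#' reproduces the CSVs byte-identically. Stages depending on a missing
#' artifact fail fast naming it.
#'
#' @param config a \code{\link{runConfig}}.
#' @return \code{config$outDir}, invisibly.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    log <- file(file.path(out, "run.log"), "w")
    on.exit(close(log))
    cfgEcho <- config
    cfgEcho$calibration <- .calibrationToList(config$calibration)
    cfgEcho$dynamics <- unclass(config$dynamics)
    jsonlite::write_json(lapply(unclass(cfgEcho), function(x)
        if (is.function(x)) NULL else x),
        file.path(out, "config_echo.json"), auto_unbox = TRUE, digits = NA,
        force = TRUE, null = "null")
    .logLine(log, "init", "seed ", config$seed, "; stages ",
             paste(config$stages, collapse = ","))

    series <- NULL
    tracks <- NULL
    annotations <- NULL

    for (stage in config$stages) {
        si <- match(stage, c("simulate", "measure", "kinetics", "events",
                             "anisotropy"))
        sseed <- .childSeed(config$seed, si)
        if (stage == "simulate") {
            tis <- generateTissue(config$nCells, config$meanAreaUm2,
                                  config$calibration, seed = sseed,
                                  lloydIter = config$lloydIter)
            dyn <- config$dynamics
            dyn$seed <- sseed
            series <- simulateDynamics(tis, dyn)
            if (!is.null(config$channelSpec)) {
                model <- channelModel(config$channelSpec, seed = sseed)
                series <- paintChannels(series, model,
                                        widthPx = config$widthPx)
            }
            writeSeries(series, file.path(out, "series"))
            gt <- groundTruth(series)
            jsonlite::write_json(
                list(cells = gt$cells, pulses = gt$pulses,
                     phaseJunctions = gt$phaseJunctions,
                     seed = sseed),
                file.path(out, "ground_truth.json"),
                auto_unbox = TRUE, digits = NA, null = "null")
            .logLine(log, stage, nFrames(series), " frames, ",
                     length(unique(as.vector(labelImage(series)))) - 1L,
                     " cells, seed ", sseed)
        } else if (stage == "measure") {
            if (is.null(series)) {
                sdir <- file.path(out, "series")
                if (!dir.exists(sdir))
                    stop("missing artifact for stage 'measure': ", sdir)
                series <- readSeries(sdir)
            }
            tracks <- buildTracks(series, widthPx = config$widthPx)
            writeTables(tracks$cells, tracks$junctions,
                        file.path(out, "tables"), calibration(series))
            .logLine(log, stage, nrow(tracks$cells), " cell records, ",
                     nrow(tracks$junctions), " junction records")
        } else if (stage == "kinetics") {
            if (is.null(tracks)) {
                tdir <- file.path(out, "tables")
                if (!file.exists(file.path(tdir, "cells.csv")))
                    stop("missing artifact for stage 'kinetics': ",
                         file.path(tdir, "cells.csv"))
                tb <- readTables(tdir)
                tracks <- list(cells = tb$cells, junctions = tb$junctions)
            }
            dtmin <- frameIntervalMin(config$calibration)
            lastFrame <- max(tracks$cells$frame)
            ## reference pool: contraction rates of interior cells that
            ## never ingress (border-touching geometry is censored)
            ingressedIds <- setdiff(unique(tracks$cells$cell_id),
                tracks$cells$cell_id[tracks$cells$frame == lastFrame])
            borderIds <- unique(tracks$cells$cell_id[
                tracks$cells$border_touching %in% TRUE])
            refRates <- unlist(lapply(
                setdiff(unique(tracks$cells$cell_id),
                        c(ingressedIds, borderIds)),
                function(id) {
                    a <- tracks$cells$area_um2[tracks$cells$cell_id == id]
                    a <- a[!is.na(a)]
                    if (length(a) < 2L) return(NULL)
                    r <- rateSeries(a, dtmin)
                    r[r > 0]
                }))
            thr <- referenceThreshold(refRates, k = config$thresholdK)
            annotations <- list()
            pulseRows <- list()
            for (id in unique(tracks$cells$cell_id)) {
                sub <- tracks$cells[tracks$cells$cell_id == id, ]
                ann <- annotateConstriction(sub, thr, lastFrame, dtmin,
                    mergeGap = config$mergeGap,
                    smoothingWindow = config$smoothingWindow,
                    reexpansionTolUm2 = config$reexpansionTolUm2,
                    minTotalDeclineFrac = config$minTotalDeclineFrac)
                annotations[[as.character(id)]] <- ann
                if (!ann$censored && !ann$unclassifiable && ann$n_pulses > 0)
                    pulseRows[[length(pulseRows) + 1L]] <-
                        cbind(cell_id = id, ann$pulses)
            }
            annTab <- do.call(rbind, lapply(names(annotations), function(id) {
                a <- annotations[[id]]
                data.frame(cell_id = as.integer(id),
                           censored = a$censored,
                           unclassifiable = a$unclassifiable,
                           start_frame = a$start_frame %||% NA,
                           ingression_frame = a$ingression_frame %||% NA,
                           n_pulses = a$n_pulses %||% NA,
                           mean_constriction_rate =
                               a$mean_constriction_rate %||% NA,
                           frac_contracting = a$frac_contracting %||% NA,
                           frac_expanding = a$frac_expanding %||% NA,
                           frac_stable = a$frac_stable %||% NA)
            }))
            utils::write.csv(annTab, file.path(out, "annotations.csv"),
                             row.names = FALSE)
            pulses <- if (length(pulseRows)) do.call(rbind, pulseRows) else
                data.frame()
            utils::write.csv(pulses, file.path(out, "pulses.csv"),
                             row.names = FALSE)
            jsonlite::write_json(list(
                threshold = unclass(thr),
                n_reference_rates = length(refRates)),
                file.path(out, "threshold.json"), auto_unbox = TRUE,
                digits = NA)
            .logLine(log, stage, "threshold ",
                     sprintf("%.3f", thr$threshold), " um^2/min; ",
                     sum(!annTab$censored & !annTab$unclassifiable),
                     " annotated cells")
        } else if (stage == "events") {
            if (is.null(tracks))
                stop("missing artifact for stage 'events': measured tables")
            lastFrame <- max(tracks$cells$frame)
            ev <- detectIngressions(tracks$cells, lastFrame,
                                    config$calibration)
            ev <- classifyEventClusters(ev, tracks$junctions,
                                        config$windowMin)
            utils::write.csv(ev, file.path(out, "events.csv"),
                             row.names = FALSE)
            rate <- tryCatch(ingressionRatePerHour(ev, tracks$cells,
                config$calibration, domain = "all"),
                error = function(e) NULL)
            sizes <- table(factor(
                ev$cluster_size[!duplicated(ev$cluster_id)], 1:4))
            byCells <- table(factor(ev$cluster_size, 1:4))
            jsonlite::write_json(list(
                n_events = nrow(ev),
                rate_per_hour = if (!is.null(rate)) rate$mean else NA,
                rate_sem = if (!is.null(rate)) rate$sem else NA,
                clusters = as.list(sizes),
                pct_cells_by_cluster_size =
                    as.list(round(100 * byCells / max(1, nrow(ev)), 2))),
                file.path(out, "summary.json"), auto_unbox = TRUE,
                digits = NA)
            .logLine(log, stage, nrow(ev), " events")
        } else if (stage == "anisotropy") {
            if (is.null(tracks))
                stop("missing artifact for stage 'anisotropy': junctions.csv")
            jt <- tracks$junctions
            intCols <- grep("^int_", names(jt), value = TRUE)
            if (!length(intCols))
                stop("missing artifact for stage 'anisotropy': ",
                     "no intensity channels in junctions table")
            jt <- jt[jt$frame == min(jt$frame) & !jt$is_exterior, ]
            jt <- normalizeIntensities(jt, mode = "embryo_mean")
            chn <- sub("^int_", "", intCols)
            an <- do.call(rbind, lapply(chn, function(nm)
                cbind(channel = nm, cellAnisotropy(jt, nm))))
            utils::write.csv(an, file.path(out, "anisotropy.csv"),
                             row.names = FALSE)
            pol <- do.call(rbind, lapply(chn, function(nm)
                cbind(channel = nm, planarPolarity(jt, nm))))
            utils::write.csv(pol, file.path(out, "polarity.csv"),
                             row.names = FALSE)
            bins <- do.call(rbind, lapply(chn, function(nm)
                cbind(channel = nm,
                      binByOrientation(jt, nm, config$binDeg))))
            utils::write.csv(bins, file.path(out, "orientation_bins.csv"),
                             row.names = FALSE)
            cors <- list()
            if (length(chn) >= 2L) {
                prs <- utils::combn(chn, 2L, simplify = FALSE)
                for (pr in prs) {
                    nm <- paste(pr, collapse = ":")
                    cors[[nm]] <- list(
                        unfiltered = channelPairCorrelation(jt, pr[1L],
                            pr[2L], method = config$corMethod)$r,
                        filtered = channelPairCorrelation(jt, pr[1L],
                            pr[2L], filterLow = "quantile", q = config$q,
                            method = config$corMethod)$r)
                }
            }
            jsonlite::write_json(cors, file.path(out, "correlations.json"),
                                 auto_unbox = TRUE, digits = NA)
            .logLine(log, stage, nrow(an), " anisotropy records, ",
                     length(cors), " channel pairs")
        }
    }
    invisible(out)
}
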