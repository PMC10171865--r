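## Rate series, reference threshold, pulse detection, constriction-period
## annotation, phase statistics and junction-shrinkage asynchrony.

#' Signed contraction/shrinkage rate series
#'
#' The backward difference of a value series converted to physical units
#' per minute, with the contraction-positive sign convention:
#' rate(t) = (value(t-1) - value(t)) / frame interval. Applies equally to
#' apical areas (um^2/min) and junction lengths (um/min). No smoothing.
#'
#' @param values numeric series (>= 2 frames, consecutive frames).
#' @param frameIntervalMin minutes per frame.
#' @return numeric vector of length \code{length(values) - 1}; element t
#'   is the rate of the transition into frame t+1.
#' @examples
#' rateSeries(c(50, 48, 45, 45), 5)   # 0.4 0.6 0.0
#' @export
rateSeries <- function(values, frameIntervalMin) {
    if (length(values) < 2L)
        stop("insufficient data: need at least 2 frames for a rate series")
    -diff(values) / frameIntervalMin
}

#' Pulse threshold from a reference rate pool
#'
#' The pulse-defining threshold is the mean plus \code{k} sample standard
#' deviations of pooled per-frame contraction rates of reference
#' (non-ingressing) epiblast cells; with the reference pool of the
#' modelled tissue this lands near 0.7 um^2/min at k = 1.
#'
#' @param referenceRates pooled per-frame contraction rates (>= 10 values).
#' @param k SD multiplier (default 1).
#' @return list of class \code{PulseThreshold} with \code{mean}, \code{sd}
#'   (sample, n-1), \code{k}, \code{threshold}.
#' @export
referenceThreshold <- function(referenceRates, k = 1) {
    referenceRates <- referenceRates[is.finite(referenceRates)]
    if (!length(referenceRates)) stop("empty reference rate pool")
    if (length(referenceRates) < 10L)
        stop("need at least 10 reference rate samples")
    m <- mean(referenceRates)
    s <- stats::sd(referenceRates)
    structure(list(mean = m, sd = s, k = k, threshold = m + k * s),
              class = "PulseThreshold")
}

#' @export
print.PulseThreshold <- function(x, ...) {
    cat(sprintf("PulseThreshold: mean %.3f + %g x SD %.3f = %.3f um^2/min\n",
                x$mean, x$k, x$sd, x$threshold))
    invisible(x)
}

.thresholdValue <- function(threshold) {
    if (inherits(threshold, "PulseThreshold")) threshold$threshold
    else as.numeric(threshold)
}

#' Detect constriction pulses in a rate series
#'
#' A pulse is a maximal run of frames whose contraction rate exceeds the
#' threshold; runs separated by at most \code{mergeGap} sub-threshold
#' frames are merged. Pulse magnitude is the maximum rate within the
#' pulse.
#'
#' @param rates numeric rate series (contraction-positive).
#' @param threshold numeric or a \code{PulseThreshold}.
#' @param mergeGap merge runs separated by <= this many frames (default 0,
#'   no merging).
#' @return data.frame with one row per pulse: \code{start}, \code{end}
#'   (1-based indices into \code{rates}), \code{duration_frames},
#'   \code{magnitude}.
#' @examples
#' detectPulses(c(0.2, 0.9, 1.2, 0.3, 0.8, 0.1), 0.7)
#' @export
detectPulses <- function(rates, threshold, mergeGap = 0L) {
    thr <- .thresholdValue(threshold)
    above <- !is.na(rates) & rates > thr
    empty <- data.frame(start = integer(0), end = integer(0),
                        duration_frames = integer(0), magnitude = numeric(0))
    if (!any(above)) return(empty)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (mergeGap > 0L && nrow(runs) > 1L) {
        ms <- runs$start[1L]; me <- runs$end[1L]
        for (i in 2:nrow(runs)) {
            if (runs$start[i] - me[length(me)] - 1L <= mergeGap) {
                me[length(me)] <- runs$end[i]
            } else {
                ms <- c(ms, runs$start[i]); me <- c(me, runs$end[i])
            }
        }
        runs <- data.frame(start = ms, end = me)
    }
    runs$duration_frames <- runs$end - runs$start + 1L
    runs$magnitude <- vapply(seq_len(nrow(runs)), function(i)
        max(rates[runs$start[i]:runs$end[i]]), numeric(1))
    rownames(runs) <- NULL
    runs
}

#' Detect the constriction period of an ingressing cell
#'
#' The ingression frame is the last frame the label is present. The start
#' of constriction is found on the moving-average area series as the
#' onset of the final continual decline: re-expansions are rises of more
#' than \code{reexpansionTolUm2} above the running trough; after the last
#' re-expansion the start is the latest frame still within the tolerance
#' of the remaining peak (so a flat plateau ends, and an oscillation's
#' final peak starts, the period). Cells whose decline from that start is
#' less than \code{minTotalDeclineFrac} of the start area are flagged
#' unclassifiable. Tracks that end at the movie end or while touching the
#' border are censored.
#'
#' @param cellTrack data.frame for one cell with columns \code{frame} and
#'   \code{area_um2} (and optionally \code{border_touching}).
#' @param lastSeriesFrame last frame index of the movie.
#' @param smoothingWindow centered moving-average window (frames).
#' @param reexpansionTolUm2 tolerated re-expansion (um^2).
#' @param minTotalDeclineFrac required total decline as a fraction of the
#'   area at the start.
#' @return list with \code{start_frame}, \code{ingression_frame},
#'   \code{censored}, \code{unclassifiable}.
#' @export
detectConstrictionPeriod <- function(cellTrack, lastSeriesFrame,
                                     smoothingWindow = 3L,
                                     reexpansionTolUm2 = 0.5,
                                     minTotalDeclineFrac = 0.5) {
    stopifnot(all(c("frame", "area_um2") %in% names(cellTrack)))
    cellTrack <- cellTrack[order(cellTrack$frame), ]
    lastFrame <- cellTrack$frame[nrow(cellTrack)]
    endsAtBorder <- isTRUE(cellTrack$border_touching[nrow(cellTrack)])
    if (lastFrame >= lastSeriesFrame || endsAtBorder)
        return(list(start_frame = NA_integer_,
                    ingression_frame = NA_integer_,
                    censored = TRUE, unclassifiable = FALSE))
    a <- .movAvg(cellTrack$area_um2, smoothingWindow)
    n <- length(a)
    ## last re-expansion: a rise of more than the tolerance above the
    ## running trough (resets after each detected rise)
    lastRise <- 1L
    rmin <- a[1L]
    for (t in 2:n) {
        rmin <- min(rmin, a[t - 1L])
        if (a[t] > rmin + reexpansionTolUm2) {
            lastRise <- t
            rmin <- a[t]
        }
    }
    seg <- lastRise:n
    peak <- max(a[seg])
    s <- seg[max(which(a[seg] >= peak - reexpansionTolUm2))]
    if ((a[s] - a[n]) < minTotalDeclineFrac * a[s])
        return(list(start_frame = NA_integer_,
                    ingression_frame = lastFrame,
                    censored = FALSE, unclassifiable = TRUE))
    list(start_frame = cellTrack$frame[s], ingression_frame = lastFrame,
         censored = FALSE, unclassifiable = FALSE)
}

.movAvg <- function(x, w) {
    if (w <= 1L) return(x)
    h <- (w - 1L) %/% 2L
    n <- length(x)
    vapply(seq_len(n), function(i)
        mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Fractions of time spent contracting, expanding, stable
#'
#' Frames with rate above the dead-band count as contracting, below its
#' negative as expanding, within it as stable (dead-band 0 by default:
#' "stable" then means exactly zero rate, which image-derived areas attain
#' through rasterization). Mean contraction rate is the mean of the
#' positive rates; mean expansion rate the mean absolute value of the
#' negative rates.
#'
#' @param rates numeric rate series.
#' @param window optional 1-based index range \code{c(from, to)} into
#'   \code{rates}.
#' @param deadband half-width of the stable dead-band (default 0).
#' @return list with \code{frac_contracting}, \code{frac_expanding},
#'   \code{frac_stable}, \code{mean_contraction_rate},
#'   \code{mean_expansion_rate}.
#' @export
phaseTimeFractions <- function(rates, window = NULL, deadband = 0) {
    if (!is.null(window)) rates <- rates[window[1L]:window[2L]]
    rates <- rates[!is.na(rates)]
    if (!length(rates)) stop("empty window")
    n <- length(rates)
    contr <- rates > deadband
    expa <- rates < -deadband
    list(frac_contracting = sum(contr) / n,
         frac_expanding = sum(expa) / n,
         frac_stable = sum(!contr & !expa) / n,
         mean_contraction_rate = if (any(contr)) mean(rates[contr]) else NA_real_,
         mean_expansion_rate = if (any(expa)) mean(-rates[expa]) else NA_real_)
}

#' Annotate the constriction of one ingressing cell
#'
#' Combines period detection, pulse detection within the period, the
#' pulse/stable phase partition and per-cell summary statistics. The mean
#' constriction rate over the period is
#' (area(start) - area(end)) / duration.
#'
#' @param cellTrack data.frame for one cell (columns \code{frame},
#'   \code{area_um2}, optionally \code{border_touching}).
#' @param threshold numeric or \code{PulseThreshold}.
#' @param lastSeriesFrame last frame index of the movie.
#' @param frameIntervalMin minutes per frame.
#' @param mergeGap passed to [detectPulses()].
#' @param ... passed to [detectConstrictionPeriod()].
#' @return list of class \code{ConstrictionAnnotation}: period bounds,
#'   \code{pulses} (frame-indexed: \code{start_frame}/\code{end_frame} are
#'   the frames whose rates belong to the pulse), \code{phases} (frame ->
#'   phase label map over the period), fractions and rates, flags.
#' @export
annotateConstriction <- function(cellTrack, threshold, lastSeriesFrame,
                                 frameIntervalMin, mergeGap = 0L, ...) {
    per <- detectConstrictionPeriod(cellTrack, lastSeriesFrame, ...)
    if (per$censored || per$unclassifiable)
        return(structure(c(per, list(pulses = NULL, phases = NULL)),
                         class = "ConstrictionAnnotation"))
    cellTrack <- cellTrack[order(cellTrack$frame), ]
    rates <- rateSeries(cellTrack$area_um2, frameIntervalMin)
    rateFrames <- cellTrack$frame[-1L]   # frame the rate leads into
    inPeriod <- rateFrames > per$start_frame &
        rateFrames <= per$ingression_frame
    pr <- rates[inPeriod]
    pf <- rateFrames[inPeriod]
    pulses <- detectPulses(pr, threshold, mergeGap)
    pulses$start_frame <- pf[pulses$start]
    pulses$end_frame <- pf[pulses$end]
    phases <- rep(NA_character_, length(pf))
    for (i in seq_len(nrow(pulses)))
        phases[pulses$start[i]:pulses$end[i]] <- paste0("pulse_", i)
    stable <- which(is.na(phases))
    if (length(stable)) {
        ## stable_k lies after pulse_k (stable_0 before the first pulse)
        nb <- findInterval(stable, pulses$start)
        phases[stable] <- paste0("stable_", nb)
    }
    frac <- phaseTimeFractions(pr)
    area <- cellTrack$area_um2
    aStart <- area[match(per$start_frame, cellTrack$frame)]
    aEnd <- area[match(per$ingression_frame, cellTrack$frame)]
    dur <- (per$ingression_frame - per$start_frame) * frameIntervalMin
    structure(list(
        start_frame = per$start_frame,
        ingression_frame = per$ingression_frame,
        censored = FALSE, unclassifiable = FALSE,
        pulses = pulses[, c("start_frame", "end_frame", "duration_frames",
                            "magnitude")],
        phases = data.frame(frame = pf, rate = pr, phase = phases),
        n_pulses = nrow(pulses),
        pulse_occurrence_per_min = nrow(pulses) / dur,
        mean_constriction_rate = (aStart - aEnd) / dur,
        frac_contracting = frac$frac_contracting,
        frac_expanding = frac$frac_expanding,
        frac_stable = frac$frac_stable,
        mean_contraction_rate = frac$mean_contraction_rate,
        mean_expansion_rate = frac$mean_expansion_rate),
        class = "ConstrictionAnnotation")
}

#' @export
print.ConstrictionAnnotation <- function(x, ...) {
    if (x$censored) { cat("ConstrictionAnnotation: censored track\n") }
    else if (x$unclassifiable) {
        cat("ConstrictionAnnotation: unclassifiable\n")
    } else {
        cat(sprintf(
            "ConstrictionAnnotation: frames %d-%d, %d pulse(s), mean rate %.2f um^2/min\n",
            x$start_frame, x$ingression_frame, x$n_pulses,
            x$mean_constriction_rate))
    }
    invisible(x)
}

#' Per-junction mean shrinkage rate in each constriction phase
#'
#' For each junction of a cell and each phase of its constriction
#' annotation (pulse_1, stable_1, pulse_2, ...), the mean of the junction
#' length-rate over the phase's frames. Junctions absent in a phase yield
#' NA, not zero.
#'
#' @param junctionTracks data.frame of the cell's junction tracks
#'   (columns \code{junction_id}, \code{frame}, \code{length_um}).
#' @param annotation a \code{ConstrictionAnnotation} with pulses.
#' @param frameIntervalMin minutes per frame.
#' @return data.frame \code{junction_id}, \code{phase},
#'   \code{mean_shrinkage_rate_um_min}.
#' @export
junctionShrinkageByPhase <- function(junctionTracks, annotation,
                                     frameIntervalMin) {
    if (is.null(annotation$phases) || !nrow(annotation$phases))
        stop("annotation has no phases (censored or unclassifiable)")
    phases <- annotation$phases
    jids <- unique(junctionTracks$junction_id)
    out <- list()
    for (jid in jids) {
        sub <- junctionTracks[junctionTracks$junction_id == jid, ]
        sub <- sub[order(sub$frame), ]
        if (nrow(sub) < 2L) next
        jr <- rateSeries(sub$length_um, frameIntervalMin)
        jf <- sub$frame[-1L]
        contiguous <- diff(sub$frame) == min(diff(sub$frame))
        jr[!contiguous] <- NA
        for (ph in unique(phases$phase)) {
            fr <- phases$frame[phases$phase == ph]
            v <- jr[match(fr, jf)]
            out[[length(out) + 1L]] <- data.frame(
                junction_id = jid, phase = ph,
                mean_shrinkage_rate_um_min =
                    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Pairwise correlation matrix of junction length series
#'
#' Correlation of each pair of junction length time series over their
#' common frames; pairs with fewer than 3 common frames, or with a
#' zero-variance series, give NA (the latter with a warning).
#'
#' @param junctionTracks data.frame with \code{junction_id}, \code{frame},
#'   \code{length_um} for one cell's junctions.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return symmetric correlation matrix (diagonal 1) with junction ids as
#'   dimnames.
#' @export
junctionLengthCorrelation <- function(junctionTracks, method = "pearson") {
    jids <- unique(junctionTracks$junction_id)
    if (length(jids) < 2L)
        stop("need at least 2 junctions for a correlation matrix")
    series <- lapply(jids, function(jid) {
        sub <- junctionTracks[junctionTracks$junction_id == jid, ]
        stats::setNames(sub$length_um, sub$frame)
    })
    n <- length(jids)
    M <- matrix(NA_real_, n, n, dimnames = list(jids, jids))
    diag(M) <- 1
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        common <- intersect(names(series[[i]]), names(series[[j]]))
        common <- common[!is.na(series[[i]][common]) &
                         !is.na(series[[j]][common])]
        if (length(common) < 3L) next
        xi <- series[[i]][common]; xj <- series[[j]][common]
        if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
            warning("zero-variance junction length series (",
                    jids[i], " vs ", jids[j], ")")
            next
        }
        M[i, j] <- M[j, i] <- stats::cor(xi, xj, method = method)
    }
    M
}
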