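#' Parameters for the synthetic constriction dynamics
#'
#' Defines the programmed conditions of a simulated run: movie length,
#' fraction of ingressing cells, per-cell pulse schedules (2-4 constriction
#' pulses of mean magnitude 1.4 um^2/min separated by stable phases),
#' sub-threshold drift during stable phases, balanced apical-area
#' oscillation of non-ingressing cells, and the isolated/pair/triplet/
#' quadruplet ingression clustering plan realized with < 30 min gaps
#' within an event and independence between events.
#'
#' The area budget of each ingressing cell's schedule is matched to its
#' actual initial polygon area, so programmed magnitudes keep their mean
#' while small cells receive fewer pulses; scaled magnitudes are floored at
#' \code{pulseMagnitudeMinUm2Min} so every programmed pulse clears the
#' mean-plus-one-SD reference threshold (~0.7 um^2/min).
#'
#' @param nFrames number of frames (default 42, i.e. 205 min at 5
#'   min/frame, comparable to the 2-4 h recordings the analysis targets).
#' @param fracIngressing fraction of interior cells programmed to ingress.
#' @param pulseMagnitudeMeanUm2Min mean programmed pulse magnitude
#'   (um^2/min); magnitudes are drawn from a shifted gamma.
#' @param pulseMagnitudeMinUm2Min floor for (scaled) pulse magnitudes.
#' @param pulseMagnitudesUm2Min optional fixed vector of pulse magnitudes
#'   applied verbatim to every ingressing cell (no draw, no area
#'   scaling); the schedule's leftover area simply vanishes at
#'   ingression.
#' @param pulseFrames frames per pulse (>= 2; profile is a plateau with
#'   half-magnitude shoulders).
#' @param pulseShoulderFrac shoulder rate as a fraction of the magnitude.
#' @param stableFramesRange integer range of stable-phase durations
#'   (frames) between consecutive pulses.
#' @param stableRateUm2Min slow sub-threshold contraction during stable
#'   phases (um^2/min).
#' @param residualAreaUm2 apical area at which the label disappears.
#' @param oscAmpUm vertex oscillation amplitude (um) for non-ingressing
#'   tissue; balanced, so the mean signed area rate is ~0.
#' @param oscPeriodFrames mean oscillation period (frames).
#' @param clusterMix target proportions of ingressing cells in events of
#'   size 1/2/3/4 (defaults follow the observed 48/37/11/4 percent split).
#' @param clusterPlan optional explicit event counts, a named vector like
#'   \code{c(isolated = 5, pair = 3, triplet = 1, quad = 0)}; overrides
#'   \code{clusterMix}.
#' @param windowMin clustering window (min); within-event ingressions are
#'   spaced one frame apart, far below the window.
#' @param junctionsPerPulse junctions scheduled to shrink in each pulse.
#' @param seed RNG seed.
#' @return A validated list of class \code{DynamicsParams}.
#' @export
dynamicsParams <- function(nFrames = 42, fracIngressing = 0.45,
                           pulseMagnitudeMeanUm2Min = 1.4,
                           pulseMagnitudeMinUm2Min = 0.9,
                           pulseMagnitudesUm2Min = NULL,
                           pulseFrames = 3, pulseShoulderFrac = 0.5,
                           stableFramesRange = c(1, 3),
                           stableRateUm2Min = 0.2,
                           residualAreaUm2 = 2.5,
                           oscAmpUm = 0.7, oscPeriodFrames = 8,
                           clusterMix = c(single = 0.48, pair = 0.37,
                                          triplet = 0.11, quad = 0.04),
                           clusterPlan = NULL, windowMin = 30,
                           junctionsPerPulse = 2, seed = 1) {
    p <- as.list(environment())
    stopifnot(nFrames >= 5, fracIngressing >= 0, fracIngressing <= 1,
              pulseMagnitudeMeanUm2Min > 0, pulseMagnitudeMinUm2Min >= 0,
              pulseFrames >= 2, pulseShoulderFrac > 0,
              stableRateUm2Min >= 0, residualAreaUm2 > 0, oscAmpUm >= 0,
              oscPeriodFrames > 1, windowMin > 0, junctionsPerPulse >= 1)
    if (!is.null(clusterPlan))
        stopifnot(all(names(clusterPlan) %in%
                      c("isolated", "pair", "triplet", "quad")),
                  all(clusterPlan >= 0))
    class(p) <- "DynamicsParams"
    p
}

#' @export
print.DynamicsParams <- function(x, ...) {
    cat("DynamicsParams:", x$nFrames, "frames,",
        sprintf("%.0f%%", 100 * x$fracIngressing), "ingressing,",
        "pulse magnitude mean", x$pulseMagnitudeMeanUm2Min, "um^2/min\n")
    invisible(x)
}

## pulse rate profile (um^2/min) for one pulse of magnitude m
.pulseProfile <- function(m, pulseFrames, shoulder) {
    if (pulseFrames == 2L) c(m, shoulder * m)
    else c(shoulder * m, rep(m, pulseFrames - 2L), shoulder * m)
}

## event sizes from plan/mix; returns vector of event sizes (cells)
.planEventSizes <- function(nIngress, mix, plan) {
    if (!is.null(plan)) {
        sz <- c(isolated = 1L, pair = 2L, triplet = 3L, quad = 4L)
        return(rep(sz[names(plan)], plan))
    }
    counts <- c(
        quad = round(mix[["quad"]] * nIngress / 4),
        triplet = round(mix[["triplet"]] * nIngress / 3),
        pair = round(mix[["pair"]] * nIngress / 2))
    used <- 4 * counts[["quad"]] + 3 * counts[["triplet"]] +
        2 * counts[["pair"]]
    while (used > nIngress && any(counts > 0)) {
        k <- which(counts > 0)[1L]
        counts[k] <- counts[k] - 1L
        used <- used - c(quad = 4L, triplet = 3L, pair = 2L)[k]
    }
    counts <- c(counts, isolated = max(0L, nIngress - used))
    rep(c(quad = 4L, triplet = 3L, pair = 2L, isolated = 1L)[names(counts)],
        counts)
}

## pick connected cell groups for each event on the adjacency graph;
## different events may be adjacent (their timing is separated instead)
.selectEventGroups <- function(sizes, adjList, candidates) {
    navail <- max(c(unlist(adjList, use.names = FALSE), candidates, 1L))
    avail <- rep(FALSE, navail)
    avail[candidates] <- TRUE
    groups <- vector("list", length(sizes))
    ord <- order(sizes, decreasing = TRUE)
    for (ei in ord) {
        s <- sizes[ei]
        placed <- FALSE
        ## prefer starts with few already-grouped neighbors, so events
        ## spread out and the timing constraints stay satisfiable
        cand <- which(avail)
        grouped <- !avail
        nGroupedNb <- vapply(cand, function(v)
            sum(grouped[adjList[[v]]]), numeric(1))
        cand <- cand[order(nGroupedNb, stats::runif(length(cand)))]
        for (start in cand) {
            grp <- start
            while (length(grp) < s) {
                nb <- setdiff(unique(unlist(adjList[grp])), grp)
                nb <- nb[nb > 0 & avail[nb]]
                if (!length(nb)) break
                grp <- c(grp, nb[sample.int(length(nb), 1L)])
            }
            if (length(grp) == s) {
                groups[[ei]] <- grp
                avail[grp] <- FALSE
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("parameter error: clustering plan unrealizable on this ",
                 "mesh (could not place an event of ", s, " cells)")
    }
    groups
}

## assign each event a base ingression frame such that members of adjacent
## events are separated by more than the clustering window
.assignEventTimes <- function(groups, schedLenByCell, adjList, nFrames,
                              windowFrames) {
    nEv <- length(groups)
    evAdj <- matrix(FALSE, nEv, nEv)
    for (i in seq_len(nEv)) for (j in seq_len(nEv)) {
        if (i >= j) next
        nbi <- unique(unlist(adjList[groups[[i]]]))
        evAdj[i, j] <- evAdj[j, i] <- any(groups[[j]] %in% nbi)
    }
    base <- rep(NA_integer_, nEv)
    lastAdmissible <- nFrames - 2L
    ## place the most constrained events (most adjacent events) first
    deg <- rowSums(evAdj)
    ord <- order(-deg, stats::runif(nEv))
    for (ei in ord) {
        grp <- groups[[ei]]
        len <- max(schedLenByCell[as.character(grp)])
        lo <- len + 3L
        hi <- lastAdmissible - (length(grp) - 1L)
        if (lo > hi)
            stop("parameter error: nFrames too small for the pulse schedules")
        cand <- lo:hi
        for (oj in which(evAdj[ei, ] & !is.na(base))) {
            span <- length(groups[[oj]]) - 1L
            ## members at base..base+size-1 must all differ from the other
            ## event's member frames by more than the window
            bad <- (base[oj] - span - windowFrames - length(grp)):
                   (base[oj] + span + windowFrames + 1L)
            cand <- setdiff(cand, bad)
        }
        if (!length(cand))
            stop("parameter error: clustering plan unrealizable in ",
                 nFrames, " frames (adjacent events cannot be separated ",
                 "by the ", windowFrames, "-frame window)")
        base[ei] <- if (length(cand) > 1L) sample(cand, 1L) else cand
    }
    base
}

#' Simulate constriction dynamics on a synthetic tissue
#'
#' Evolves the tissue's shared-vertex polygon mesh over time. Ingressing
#' cells lose area through programmed shrinkage of per-phase scheduled
#' junctions (both endpoints of a scheduled junction move toward the cell
#' centroid by a root-solved fraction, so the junction chord contracts
#' exactly and the freed area is absorbed by neighbors); at the frame after
#' their last scheduled frame the cell's face collapses to its centroid and
#' its label disappears. Non-ingressing tissue oscillates via smooth
#' sinusoidal vertex displacements with ~zero mean area rate. Each frame is
#' re-rasterized to labels.
#'
#' @param tissue a one-frame series from \code{\link{generateTissue}}.
#' @param params a \code{\link{dynamicsParams}} object.
#' @return A \linkS4class{SegmentedFrameSeries} whose
#'   \code{metadata$groundTruth} holds the programmed schedule: \code{cells}
#'   (ingression frame = last present frame, constriction start, cluster id
#'   and size), \code{pulses} (start/end in rate-frame indexing, i.e. the
#'   frames whose backward-difference rate belongs to the pulse, and the
#'   programmed magnitude), \code{phaseJunctions} (scheduled junction per
#'   phase), \code{areas} and \code{junctionLengths} (true polygon series),
#'   and a parameter echo.
#' @export
simulateDynamics <- function(tissue, params = dynamicsParams()) {
    stopifnot(is(tissue, "SegmentedFrameSeries"))
    mesh <- tissue@metadata$mesh
    if (is.null(mesh))
        stop("tissue must come from generateTissue() (mesh metadata missing)")
    cal <- calibration(tissue)
    px <- pixelSizeUm(cal)
    dt <- frameIntervalMin(cal)
    marginPx <- tissue@metadata$marginPx %||% 2L
    dimlab <- dim(labelImage(tissue))
    set.seed(params$seed)

    nCells <- length(mesh$faces)
    adj <- .meshAdjacency(mesh)
    adjList <- vector("list", nCells)
    for (r in seq_len(nrow(adj))) {
        a <- adj$cell_a[r]; b <- adj$cell_b[r]
        adjList[[a]] <- c(adjList[[a]], b)
        adjList[[b]] <- c(adjList[[b]], a)
    }
    borderCells <- unique(mesh$edges$cell_b[mesh$edges$cell_a == 0L])
    interior <- setdiff(seq_len(nCells), borderCells)

    nIngress <- round(params$fracIngressing * length(interior))
    sizes <- if (nIngress > 0 || !is.null(params$clusterPlan))
        .planEventSizes(nIngress, params$clusterMix, params$clusterPlan)
    else integer(0)
    groups <- if (length(sizes))
        .selectEventGroups(sizes, adjList, interior) else list()
    attemptsLeft <- 30L

    ## per-cell schedules -------------------------------------------------
    V0 <- mesh$V
    area0 <- vapply(seq_len(nCells), function(i) .faceArea(mesh, i), numeric(1))
    pf <- params$pulseFrames
    meanPulseLoss <- params$pulseMagnitudeMeanUm2Min *
        sum(.pulseProfile(1, pf, params$pulseShoulderFrac)) * dt
    buildSchedules <- function(groups) {
    sched <- list()   # per ingressing cell: rates vector + phase labels
    for (gi in seq_along(groups)) {
        grp <- groups[[gi]]
        for (mi in seq_along(grp)) {
            cid <- grp[mi]
            A0 <- area0[cid]
            fixedMags <- params$pulseMagnitudesUm2Min
            nP <- if (is.null(fixedMags))
                max(2L, min(4L,
                    round((A0 - params$residualAreaUm2) / meanPulseLoss)))
            else length(fixedMags)
            repeat {
                if (is.null(fixedMags)) {
                    mags <- params$pulseMagnitudeMinUm2Min - 0.1 +
                        stats::rgamma(nP, shape = 2,
                            scale = (params$pulseMagnitudeMeanUm2Min -
                                params$pulseMagnitudeMinUm2Min + 0.1) / 2)
                } else mags <- fixedMags
                stables <- sample(seq(params$stableFramesRange[1L],
                                      params$stableFramesRange[2L]),
                                  nP - 1L, replace = TRUE)
                rates <- numeric(0); phase <- character(0)
                for (k in seq_len(nP)) {
                    rates <- c(rates, .pulseProfile(mags[k], pf,
                                                    params$pulseShoulderFrac))
                    phase <- c(phase, rep(paste0("pulse_", k), pf))
                    if (k < nP) {
                        rates <- c(rates,
                                   rep(params$stableRateUm2Min, stables[k]))
                        phase <- c(phase,
                                   rep(paste0("stable_", k), stables[k]))
                    }
                }
                if (is.null(fixedMags)) {
                    ## match the schedule's area budget to the cell's
                    ## actual initial area; if scaling would push a pulse
                    ## below the magnitude floor, use one pulse fewer
                    ## instead of truncating the schedule mid-run
                    sc <- (A0 - params$residualAreaUm2) / (sum(rates) * dt)
                    if (min(mags * sc) < params$pulseMagnitudeMinUm2Min &&
                        nP > 2L) {
                        nP <- nP - 1L
                        next
                    }
                    rates <- rates * sc
                    mags <- mags * sc
                    for (k in seq_len(nP)) {
                        if (mags[k] < params$pulseMagnitudeMinUm2Min) {
                            f <- params$pulseMagnitudeMinUm2Min / mags[k]
                            rates[phase == paste0("pulse_", k)] <-
                                rates[phase == paste0("pulse_", k)] * f
                            mags[k] <- params$pulseMagnitudeMinUm2Min
                        }
                    }
                }
                break
            }
            sched[[as.character(cid)]] <- list(rates = rates, phase = phase,
                                               mags = mags, nP = nP,
                                               group = gi, member = mi)
        }
    }
    sched
    }
    ## ingression frames: members of one event one frame (dt min) apart;
    ## adjacent events separated by more than the clustering window.
    ## group placement, schedule draws and timing are all stochastic, so
    ## retry a few draws before declaring the plan unrealizable.
    sched <- buildSchedules(groups)
    ingressFrame <- integer(0)
    if (length(groups)) {
        base <- NULL
        lastError <- NULL
        while (is.null(base) && attemptsLeft > 0L) {
            attemptsLeft <- attemptsLeft - 1L
            schedLen <- vapply(sched, function(s) length(s$rates), integer(1))
            base <- tryCatch(
                .assignEventTimes(groups, schedLen, adjList, params$nFrames,
                                  ceiling(params$windowMin / dt)),
                error = function(e) { lastError <<- e; NULL })
            if (is.null(base) && attemptsLeft > 0L) {
                groups <- .selectEventGroups(sizes, adjList, interior)
                sched <- buildSchedules(groups)
            }
        }
        if (is.null(base)) stop(lastError)
        for (gi in seq_along(groups)) {
            grp <- groups[[gi]]
            for (mi in seq_along(grp))
                ingressFrame[as.character(grp[mi])] <- base[gi] + (mi - 1L)
        }
    }

    ## junction schedule per phase ---------------------------------------
    edgeKey <- function(a, b) paste(min(a, b), max(a, b), sep = "|")
    faceEdges <- lapply(seq_len(nCells), function(i) {
        e <- mesh$edges[(mesh$edges$cell_a == i | mesh$edges$cell_b == i) &
                        mesh$edges$cell_a > 0L, ]
        e
    })
    for (cid in names(sched)) {
        s <- sched[[cid]]
        fe <- faceEdges[[as.integer(cid)]]
        phases <- unique(s$phase)
        ord <- sample.int(nrow(fe))
        take <- ifelse(grepl("^pulse", phases), params$junctionsPerPulse, 1L)
        pos <- 0L
        pj <- vector("list", length(phases))
        for (k in seq_along(phases)) {
            sel <- ((pos + seq_len(take[k]) - 1L) %% nrow(fe)) + 1L
            pos <- pos + take[k]
            rows <- fe[ord[sel], ]
            pj[[k]] <- list(phase = phases[k],
                junctions = mapply(edgeKey, rows$cell_a, rows$cell_b),
                verts = unique(c(rows$v1, rows$v2)))
        }
        sched[[cid]]$phaseJunctions <- pj
    }

    ## oscillation: the whole tissue oscillates for the whole run (cells
    ## fluctuate before they constrict); constriction moves are solved in
    ## the displaced frame each frame, so they compensate the oscillation
    ## of a constricting face and its programmed area trajectory stays
    ## exact. Field-boundary vertices are pinned so the tissue outline
    ## (and total labelled area) stays fixed.
    nV <- nrow(V0)
    startFrame0 <- vapply(names(sched), function(cid)
        ingressFrame[[cid]] - length(sched[[cid]]$rates), integer(1))
    ampV <- rep(params$oscAmpUm, nV)
    W <- tissue@metadata$fieldUm
    if (!is.null(W)) {
        onBoundary <- abs(V0[, 1L]) < 1e-6 | abs(V0[, 2L]) < 1e-6 |
            abs(V0[, 1L] - W) < 1e-6 | abs(V0[, 2L] - W) < 1e-6
        ampV[onBoundary] <- 0
    }
    oscPhase <- stats::runif(nV, 0, 2 * pi)
    oscDir <- stats::runif(nV, 0, 2 * pi)
    oscPer <- params$oscPeriodFrames * stats::runif(nV, 0.75, 1.25)

    ## simulate -----------------------------------------------------------
    Vbase <- V0
    alive <- rep(TRUE, nCells)
    labsList <- vector("list", params$nFrames)
    oscDisp <- function(t) {
        s <- ampV * sin(2 * pi * t / oscPer + oscPhase)
        cbind(s * cos(oscDir), s * sin(oscDir))
    }
    trueArea <- matrix(NA_real_, params$nFrames, nCells)
    ekeys <- with(mesh$edges, paste(pmin(cell_a, cell_b),
                                    pmax(cell_a, cell_b), sep = "|"))
    intE <- which(mesh$edges$cell_a > 0L)
    trueLen <- matrix(NA_real_, params$nFrames, length(intE),
                      dimnames = list(NULL, ekeys[intE]))
    startFrame <- startFrame0

    for (t in seq_len(params$nFrames) - 1L) {      # frame indices 0-based
        if (t > 0L) {
            ## collapse cells whose last present frame was t-1
            for (cid in names(sched)) {
                if (alive[as.integer(cid)] && t == ingressFrame[[cid]] + 1L) {
                    i <- as.integer(cid)
                    ctr <- .faceCentroid(mesh, i, Vbase)
                    Vbase[mesh$faces[[i]], 1L] <- ctr[1L]
                    Vbase[mesh$faces[[i]], 2L] <- ctr[2L]
                    alive[i] <- FALSE
                }
            }
            ## scheduled junction moves, iterated so co-ingressing
            ## neighbors converge to their own targets; solved in the
            ## displaced frame (constricting faces' vertices hold a
            ## frozen oscillation offset) so targets match measured areas
            active <- names(sched)[vapply(names(sched), function(cid)
                alive[as.integer(cid)] && t > startFrame[[cid]] &&
                    t <= ingressFrame[[cid]], logical(1))]
            D <- oscDisp(t)
            for (pass in seq_len(if (length(active) > 1L) 3L else 1L)) {
                for (cid in active) {
                    i <- as.integer(cid)
                    s <- sched[[cid]]
                    k <- t - startFrame[[cid]]
                    target <- max(params$residualAreaUm2 * 0.3,
                        .targetArea(s, k, area0[i], startFrame[[cid]],
                                    trueArea, i, dt))
                    ph <- s$phase[k]
                    pj <- s$phaseJunctions[[match(ph, vapply(s$phaseJunctions,
                        `[[`, "", "phase"))]]
                    Vd <- Vbase + D
                    Vd2 <- .solveJunctionMove(mesh, i, pj$verts, Vd, target)
                    Vbase <- Vbase + (Vd2 - Vd)
                }
            }
        }
        Vt <- Vbase + oscDisp(t)
        lab <- .rasterizeMesh(mesh, Vt, dimlab[1L], dimlab[2L], px, marginPx,
                              skip = which(!alive))
        lab <- .fillInteriorGaps(lab)
        labsList[[t + 1L]] <- lab
        for (i in seq_len(nCells))
            if (alive[i]) trueArea[t + 1L, i] <- abs(.polyArea(
                Vt[mesh$faces[[i]], , drop = FALSE]))
        le <- mesh$edges[intE, ]
        bothAlive <- alive[le$cell_a] & alive[le$cell_b]
        d <- sqrt((Vt[le$v1, 1L] - Vt[le$v2, 1L])^2 +
                  (Vt[le$v1, 2L] - Vt[le$v2, 2L])^2)
        trueLen[t + 1L, bothAlive] <- d[bothAlive]
    }

    ## ground truth -------------------------------------------------------
    gtCells <- do.call(rbind, lapply(names(sched), function(cid) {
        s <- sched[[cid]]
        data.frame(cell_id = as.integer(cid),
                   ingression_frame = ingressFrame[[cid]],
                   constriction_start_frame = startFrame[[cid]],
                   cluster_id = s$group,
                   cluster_size = length(groups[[s$group]]),
                   n_pulses = s$nP)
    }))
    gtPulses <- do.call(rbind, lapply(names(sched), function(cid) {
        s <- sched[[cid]]
        do.call(rbind, lapply(seq_len(s$nP), function(k) {
            w <- which(s$phase == paste0("pulse_", k))
            data.frame(cell_id = as.integer(cid), pulse = k,
                       start_frame = startFrame[[cid]] + min(w),
                       end_frame = startFrame[[cid]] + max(w),
                       magnitude_um2_min = s$mags[k])
        }))
    }))
    gtPhaseJ <- do.call(rbind, lapply(names(sched), function(cid) {
        s <- sched[[cid]]
        do.call(rbind, lapply(s$phaseJunctions, function(pj)
            data.frame(cell_id = as.integer(cid), phase = pj$phase,
                       junction_id = pj$junctions)))
    }))
    gt <- list(cells = gtCells, pulses = gtPulses, phaseJunctions = gtPhaseJ,
               areas = trueArea, junctionLengths = trueLen,
               params = params)
    SegmentedFrameSeries(labsList, cal,
        frameIndices = seq_len(params$nFrames) - 1L,
        metadata = list(mesh = mesh, marginPx = marginPx,
                        groundTruth = gt, seed = params$seed))
}

## target area for schedule position k (frames are absolute, rates applied
## cumulatively from the cell's area at constriction start)
.targetArea <- function(s, k, A0, start, trueArea, i, dt) {
    Astart <- if (start >= 0L && !is.na(trueArea[start + 1L, i]))
        trueArea[start + 1L, i] else A0
    Astart - sum(s$rates[seq_len(k)]) * dt
}

## move the given vertices by a fraction alpha along a direction combining
## inward motion (toward the face centroid, which frees area) with
## tangential contraction (toward the scheduled junctions' midpoint, which
## shortens the scheduled junction faster than its neighbors: the chord
## scales by 1 - 1.5*alpha while area loss is alpha-driven); alpha is
## root-solved so the face polygon area hits `target`
.solveJunctionMove <- function(mesh, i, verts, V, target) {
    ctr <- .faceCentroid(mesh, i, V)
    fidx <- mesh$faces[[i]]
    mid <- colMeans(V[verts, , drop = FALSE])
    dir <- cbind((ctr[1L] - V[verts, 1L]) + 0.5 * (mid[1L] - V[verts, 1L]),
                 (ctr[2L] - V[verts, 2L]) + 0.5 * (mid[2L] - V[verts, 2L]))
    moveArea <- function(vset, dirs) {
        function(alpha) {
            Vm <- V
            Vm[vset, ] <- V[vset, ] + alpha * dirs
            abs(.polyArea(Vm[fidx, , drop = FALSE])) - target
        }
    }
    f <- moveArea(verts, dir)
    lo <- -0.3; hi <- 0.6
    vset <- verts
    dirs <- dir
    if (f(hi) > 0) {                    # junction move cannot free enough
        vset <- fidx                    # fall back to the whole face
        dirs <- cbind(ctr[1L] - V[vset, 1L], ctr[2L] - V[vset, 2L])
        f <- moveArea(vset, dirs)
        hi <- 0.95
    }
    if (f(lo) * f(hi) > 0) return(V)    # cannot bracket; leave unchanged
    alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    V[vset, ] <- V[vset, ] + alpha * dirs
    V
}
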