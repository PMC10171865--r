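## Ingression-event detection, the 30-min isolated/clustered rule,
## streak-domain ingression rates and track displacement summaries.

#' Detect ingression events from cell tracks
#'
#' An ingression event is a track that terminates by label disappearance
#' before the final frame of the movie and whose last record does not
#' touch the border (disappearance at the border or at the movie end is
#' censored, not ingression). Event time is the last present frame times
#' the frame interval.
#'
#' @param cellTracks cell track data.frame from [buildTracks()].
#' @param lastSeriesFrame last frame index of the movie.
#' @param calibration a \linkS4class{Calibration}.
#' @return data.frame \code{cell_id}, \code{ingression_frame},
#'   \code{time_min}, \code{x_um}, \code{y_um}, \code{in_streak} (NA when
#'   no midline is set).
#' @export
detectIngressions <- function(cellTracks, lastSeriesFrame, calibration) {
    dt <- frameIntervalMin(calibration)
    if (!"track_id" %in% names(cellTracks))
        cellTracks$track_id <- as.character(cellTracks$cell_id)
    out <- list()
    for (tid in unique(cellTracks$track_id)) {
        sub <- cellTracks[cellTracks$track_id == tid, ]
        sub <- sub[order(sub$frame), ]
        last <- sub[nrow(sub), ]
        if (last$frame >= lastSeriesFrame) next
        if (isTRUE(last$border_touching)) next
        inStreak <- if (is.na(calibration@midlineXUm)) NA else
            abs(last$centroid_x_um - calibration@midlineXUm) <=
                calibration@streakHalfwidthUm
        out[[length(out) + 1L]] <- data.frame(
            cell_id = last$cell_id, ingression_frame = last$frame,
            time_min = last$frame * dt,
            x_um = last$centroid_x_um, y_um = last$centroid_y_um,
            in_streak = inStreak)
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(cell_id = integer(0), ingression_frame = integer(0),
                   time_min = numeric(0), x_um = numeric(0),
                   y_um = numeric(0), in_streak = logical(0))
    rownames(res) <- NULL
    res
}

#' Classify ingression events as isolated or clustered
#'
#' Builds a graph on events with an edge whenever the two cells were
#' adjacent neighbors and their ingression times differ by less than
#' \code{windowMin} (strictly: a 30-min or larger gap means isolated);
#' connected components are the clusters, singletons the isolated events.
#' Adjacency is evaluated at the last frame both cells exist (the earlier
#' event's ingression frame), looking back up to \code{windowMin} so a
#' shared junction that shrinks below the measurement retention threshold
#' during deep constriction still counts as adjacency.
#'
#' @param events data.frame from [detectIngressions()].
#' @param junctionTracks junction track data.frame (its
#'   \code{cell_a}/\code{cell_b}/\code{frame} columns provide the
#'   time-resolved neighbor relation).
#' @param windowMin clustering window in minutes (default 30).
#' @return \code{events} with \code{cluster_id} and \code{cluster_size}
#'   columns appended.
#' @export
classifyEventClusters <- function(events, junctionTracks, windowMin = 30) {
    n <- nrow(events)
    if (n == 0L) {
        events$cluster_id <- integer(0)
        events$cluster_size <- integer(0)
        return(events)
    }
    ## frame interval from the event table; lookback in frames
    withF <- events$ingression_frame > 0L
    dt <- if (any(withF))
        events$time_min[withF][1L] / events$ingression_frame[withF][1L]
    else 1
    lookback <- ceiling(windowMin / dt)
    edges <- matrix(integer(0), 0L, 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (abs(events$time_min[i] - events$time_min[j]) >= windowMin) next
        fEarly <- min(events$ingression_frame[i], events$ingression_frame[j])
        a <- events$cell_id[i]; b <- events$cell_id[j]
        pair <- (junctionTracks$cell_a == a & junctionTracks$cell_b == b) |
                (junctionTracks$cell_a == b & junctionTracks$cell_b == a)
        adj <- any(pair & junctionTracks$frame <= fEarly &
                   junctionTracks$frame >= fEarly - lookback)
        if (adj) edges <- rbind(edges, c(i, j))
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)
    events$cluster_id <- as.integer(comp$membership)
    events$cluster_size <- as.integer(comp$csize[comp$membership])
    events
}

#' Fraction of cells ingressing per hour
#'
#' For every sliding 60-min window: the number of ingression events in the
#' domain divided by the number of cells present in the domain at the
#' window start. The streak domain is the band within the calibrated
#' half-width of the midline.
#'
#' @param events data.frame from [detectIngressions()] (clustered or not).
#' @param cellTracks cell track data.frame.
#' @param calibration a \linkS4class{Calibration}; \code{midlineXUm} is
#'   required for \code{domain = "streak"}.
#' @param domain \code{"streak"} or \code{"all"}.
#' @param windowMinutes window length (default 60).
#' @return list with \code{per_window} (data.frame of window start/rate)
#'   and \code{mean}, \code{sem} across windows.
#' @export
ingressionRatePerHour <- function(events, cellTracks, calibration,
                                  domain = c("streak", "all"),
                                  windowMinutes = 60) {
    domain <- match.arg(domain)
    dt <- frameIntervalMin(calibration)
    if (domain == "streak" && is.na(calibration@midlineXUm))
        stop("configuration error: midlineXUm is required for the streak domain")
    frames <- sort(unique(cellTracks$frame))
    winFrames <- round(windowMinutes / dt)
    if (max(frames) < winFrames)
        stop("need at least ", windowMinutes, " min of observation")
    inDomain <- function(x) if (domain == "all") rep(TRUE, length(x)) else
        abs(x - calibration@midlineXUm) <= calibration@streakHalfwidthUm
    starts <- frames[frames + winFrames <= max(frames)]
    rows <- lapply(starts, function(s) {
        present <- cellTracks[cellTracks$frame == s, ]
        present <- present[inDomain(present$centroid_x_um), ]
        nCells <- nrow(present)
        ev <- events[events$time_min > s * dt &
                     events$time_min <= s * dt + windowMinutes, ]
        ev <- ev[ev$cell_id %in% present$cell_id & inDomain(ev$x_um), ]
        data.frame(window_start_min = s * dt, n_cells = nCells,
                   n_events = nrow(ev),
                   rate_per_hour = if (nCells > 0)
                       nrow(ev) / nCells * (60 / windowMinutes) else NA_real_)
    })
    pw <- do.call(rbind, rows)
    r <- pw$rate_per_hour[!is.na(pw$rate_per_hour)]
    list(per_window = pw, mean = mean(r),
         sem = stats::sd(r) / sqrt(length(r)))
}

#' Per-cell path length, net displacement and midline convergence
#'
#' Path length is the sum of centroid step lengths; net displacement the
#' distance between first and last centroid; convergence the reduction of
#' distance to the midline (positive = moved toward the midline; NA when
#' no midline is calibrated).
#'
#' @param cellTracks cell track data.frame.
#' @param calibration a \linkS4class{Calibration}.
#' @return data.frame \code{track_id}, \code{cell_id},
#'   \code{path_length_um}, \code{net_displacement_um},
#'   \code{convergence_um}.
#' @export
trackDisplacement <- function(cellTracks, calibration) {
    mid <- calibration@midlineXUm
    if (!"track_id" %in% names(cellTracks))
        cellTracks$track_id <- as.character(cellTracks$cell_id)
    out <- lapply(unique(cellTracks$track_id), function(tid) {
        sub <- cellTracks[cellTracks$track_id == tid, ]
        sub <- sub[order(sub$frame), ]
        sub <- sub[!is.na(sub$centroid_x_um), ]
        if (nrow(sub) < 2L) return(NULL)
        dx <- diff(sub$centroid_x_um); dy <- diff(sub$centroid_y_um)
        data.frame(track_id = tid, cell_id = sub$cell_id[1L],
                   path_length_um = sum(sqrt(dx^2 + dy^2)),
                   net_displacement_um = sqrt(
                       (sub$centroid_x_um[nrow(sub)] - sub$centroid_x_um[1L])^2 +
                       (sub$centroid_y_um[nrow(sub)] - sub$centroid_y_um[1L])^2),
                   convergence_um = if (is.na(mid)) NA_real_ else
                       abs(sub$centroid_x_um[1L] - mid) -
                       abs(sub$centroid_x_um[nrow(sub)] - mid))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
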