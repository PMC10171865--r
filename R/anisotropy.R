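## Fixed-tissue junctional quantifications: intensity normalization,
## per-cell anisotropy (sample SD and Max/Min ratio of junction means),
## planar-polarity nematics, orientation binning and pairwise channel
## correlation with the low-intensity junction filter.

#' Normalize junctional intensities
#'
#' Three normalization modes used for fixed-tissue comparisons:
#' \describe{
#'   \item{embryo_mean}{each junction mean divided by the grand mean
#'     junctional intensity of its embryo, per channel.}
#'   \item{cohort_mean}{divided by the grand mean of the pooled cohort of
#'     embryos (both genotypes), per channel.}
#'   \item{medial}{divided by the mean of the two member cells' medial
#'     (cytoplasmic) intensities (a single cell's for exterior
#'     junctions).}
#' }
#'
#' @param junctions junction table with \code{int_<channel>} columns and
#'   an \code{embryo} column (added as \code{"e1"} when absent).
#' @param channels channel names to normalize (default: all
#'   \code{int_}-prefixed columns).
#' @param mode one of \code{"embryo_mean"}, \code{"cohort_mean"},
#'   \code{"medial"}.
#' @param cells cell table with \code{medial_<channel>} columns (required
#'   for \code{mode = "medial"}; matched within embryo).
#' @return \code{junctions} with the intensity columns normalized.
#' @export
normalizeIntensities <- function(junctions, channels = NULL,
                                 mode = c("embryo_mean", "cohort_mean",
                                          "medial"),
                                 cells = NULL) {
    mode <- match.arg(mode)
    if (!"embryo" %in% names(junctions)) junctions$embryo <- "e1"
    if (is.null(channels))
        channels <- sub("^int_", "",
                        grep("^int_", names(junctions), value = TRUE))
    for (nm in channels) {
        col <- paste0("int_", nm)
        if (is.null(junctions[[col]])) stop("no channel '", nm, "' in table")
        if (mode == "embryo_mean") {
            for (e in unique(junctions$embryo)) {
                sel <- junctions$embryo == e
                g <- mean(junctions[[col]][sel], na.rm = TRUE)
                if (!is.finite(g) || g == 0)
                    stop("zero junctional normalizer for embryo ", e,
                         ", channel ", nm)
                junctions[[col]][sel] <- junctions[[col]][sel] / g
            }
        } else if (mode == "cohort_mean") {
            g <- mean(junctions[[col]], na.rm = TRUE)
            if (!is.finite(g) || g == 0)
                stop("zero cohort normalizer for channel ", nm)
            junctions[[col]] <- junctions[[col]] / g
        } else {
            if (is.null(cells))
                stop("medial mode requires the cell table")
            mcol <- paste0("medial_", nm)
            if (is.null(cells[[mcol]]))
                stop("no medial column for channel ", nm)
            if (!"embryo" %in% names(cells)) cells$embryo <- "e1"
            key <- paste(cells$embryo, cells$cell_id)
            med <- function(embryo, id) {
                v <- cells[[mcol]][match(paste(embryo, id), key)]
                v
            }
            ma <- med(junctions$embryo, junctions$cell_a)
            mb <- med(junctions$embryo, junctions$cell_b)
            denom <- rowMeans(cbind(ma, mb), na.rm = TRUE)
            bad <- !is.finite(denom) | denom == 0
            if (any(bad))
                stop("zero/missing medial normalizer for cell(s) ",
                     paste(utils::head(unique(c(junctions$cell_a[bad],
                        junctions$cell_b[bad])), 5L), collapse = ", "))
            junctions[[col]] <- junctions[[col]] / denom
        }
    }
    junctions
}

#' Per-cell junctional anisotropy (SD and Max/Min ratio)
#'
#' For each cell with at least \code{minJunctions} retained junctions: the
#' sample standard deviation of its junction mean intensities and the
#' maximal divided by the minimal junction intensity. Cells with a
#' non-positive retained intensity are excluded (ratio undefined) with a
#' message.
#'
#' @param junctions junction table with \code{int_<channel>} columns.
#' @param channel channel name.
#' @param minJunctions minimum retained junctions per cell (default 3).
#' @param excludeExterior drop junctions with the exterior (default TRUE).
#' @return data.frame \code{cell_id}, \code{n_junctions}, \code{sd},
#'   \code{max_min_ratio} (one row per retained cell; when the table has
#'   an \code{embryo} column, cells are grouped within embryo and the
#'   column is carried through).
#' @export
cellAnisotropy <- function(junctions, channel, minJunctions = 3L,
                           excludeExterior = TRUE) {
    col <- paste0("int_", channel)
    if (is.null(junctions[[col]])) stop("no channel '", channel, "'")
    if (excludeExterior && "is_exterior" %in% names(junctions))
        junctions <- junctions[!junctions$is_exterior, ]
    if (!"embryo" %in% names(junctions)) junctions$embryo <- "e1"
    long <- rbind(
        data.frame(embryo = junctions$embryo, cell = junctions$cell_a,
                   value = junctions[[col]]),
        data.frame(embryo = junctions$embryo, cell = junctions$cell_b,
                   value = junctions[[col]]))
    long <- long[long$cell > 0L & !is.na(long$value), ]
    out <- list()
    nExcluded <- 0L
    for (key in unique(paste(long$embryo, long$cell))) {
        sel <- paste(long$embryo, long$cell) == key
        v <- long$value[sel]
        if (length(v) < minJunctions) next
        if (any(v <= 0)) { nExcluded <- nExcluded + 1L; next }
        out[[length(out) + 1L]] <- data.frame(
            embryo = long$embryo[sel][1L], cell_id = long$cell[sel][1L],
            n_junctions = length(v), sd = stats::sd(v),
            max_min_ratio = max(v) / min(v))
    }
    if (nExcluded)
        message(nExcluded,
                " cell(s) excluded (non-positive junction intensity)")
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(embryo = character(0), cell_id = integer(0),
                          n_junctions = integer(0), sd = numeric(0),
                          max_min_ratio = numeric(0))
    rownames(res) <- NULL
    res
}

#' Planar-polarity nematic of junctional intensity
#'
#' The axial (180-degree periodic) summary of how a protein's junctional
#' intensity is distributed around each cell:
#' \deqn{Q = \sum_j w_j e^{2 i \theta_j} / \sum_j w_j,\quad w_j = I_j L_j}
#' with junction mean intensity \eqn{I_j}, length \eqn{L_j} and axial
#' orientation \eqn{\theta_j}. Magnitude is \eqn{|Q| \in [0, 1]}; the axis
#' is \eqn{\arg(Q)/2} folded to [0, 180). Cells with all-zero weights or
#' magnitude below 1e-6 are flagged as having an undefined axis.
#'
#' @param junctions junction table with \code{int_<channel>},
#'   \code{length_um}, \code{orientation_deg}.
#' @param channel channel name.
#' @param minJunctions minimum junctions per cell (default 3).
#' @param excludeExterior drop junctions with the exterior (default TRUE).
#' @return data.frame \code{cell_id}, \code{magnitude}, \code{axis_deg},
#'   \code{axis_defined} (plus \code{embryo} when present).
#' @export
planarPolarity <- function(junctions, channel, minJunctions = 3L,
                           excludeExterior = TRUE) {
    col <- paste0("int_", channel)
    if (is.null(junctions[[col]])) stop("no channel '", channel, "'")
    if (excludeExterior && "is_exterior" %in% names(junctions))
        junctions <- junctions[!junctions$is_exterior, ]
    if (!"embryo" %in% names(junctions)) junctions$embryo <- "e1"
    long <- rbind(
        cbind(junctions[c("embryo", "length_um", "orientation_deg", col)],
              cell = junctions$cell_a),
        cbind(junctions[c("embryo", "length_um", "orientation_deg", col)],
              cell = junctions$cell_b))
    long <- long[long$cell > 0L, ]
    out <- list()
    for (key in unique(paste(long$embryo, long$cell))) {
        sel <- paste(long$embryo, long$cell) == key
        sub <- long[sel, ]
        if (nrow(sub) < minJunctions) next
        w <- sub[[col]] * sub$length_um
        if (all(w == 0) || sum(w) == 0) {
            out[[length(out) + 1L]] <- data.frame(
                embryo = sub$embryo[1L], cell_id = sub$cell[1L],
                magnitude = 0, axis_deg = NA_real_, axis_defined = FALSE)
            next
        }
        th <- sub$orientation_deg * pi / 180
        Q <- sum(w * exp(2i * th)) / sum(w)
        mag <- Mod(Q)
        out[[length(out) + 1L]] <- data.frame(
            embryo = sub$embryo[1L], cell_id = sub$cell[1L],
            magnitude = mag,
            axis_deg = if (mag < 1e-6) NA_real_ else (Arg(Q) / 2 * 180 / pi) %% 180,
            axis_defined = mag >= 1e-6)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(embryo = character(0), cell_id = integer(0),
                          magnitude = numeric(0), axis_deg = numeric(0),
                          axis_defined = logical(0))
    rownames(res) <- NULL
    res
}

#' Mean junctional intensity by orientation bin
#'
#' Junctions are classified into half-open axial orientation bins
#' ([0, 15), ..., [165, 180) by default) and the per-bin mean intensity
#' and count reported; empty bins give NA.
#'
#' @param junctions junction table with \code{orientation_deg} and
#'   \code{int_<channel>}.
#' @param channel channel name.
#' @param binDeg bin width in degrees (default 15; must divide 180).
#' @return data.frame \code{bin_start_deg}, \code{bin_end_deg},
#'   \code{mean_intensity}, \code{n}.
#' @export
binByOrientation <- function(junctions, channel, binDeg = 15) {
    stopifnot(180 %% binDeg == 0)
    col <- paste0("int_", channel)
    if (is.null(junctions[[col]])) stop("no channel '", channel, "'")
    starts <- seq(0, 180 - binDeg, by = binDeg)
    bin <- floor((junctions$orientation_deg %% 180) / binDeg)
    data.frame(
        bin_start_deg = starts,
        bin_end_deg = starts + binDeg,
        mean_intensity = vapply(seq_along(starts) - 1L, function(b) {
            v <- junctions[[col]][bin == b]
            if (length(v)) mean(v, na.rm = TRUE) else NA_real_
        }, numeric(1)),
        n = vapply(seq_along(starts) - 1L, function(b)
            sum(bin == b), numeric(1)))
}

#' Pairwise channel correlation at junctions
#'
#' Both channels are min-max normalized to [0, 1] per embryo (by default
#' against the 1st-99th percentile range to resist hot pixels; exact
#' min/max with \code{robustRange = FALSE}). With
#' \code{filterLow = "quantile"}, only junctions whose maximum across the
#' two normalized channels exceeds the \code{q}-quantile of that maximum
#' are retained, isolating the high-intensity junctions where reciprocal
#' enrichment is expressed. Returns the pooled correlation, or the
#' distribution of per-cell coefficients with \code{groupByCell = TRUE}.
#'
#' @param junctions junction table with the two intensity columns.
#' @param channelA,channelB channel names.
#' @param filterLow \code{"none"} or \code{"quantile"}.
#' @param q quantile for the low-intensity filter (default 0.5).
#' @param groupByCell return per-cell coefficients instead of pooled.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param robustRange normalize against 1st-99th percentiles.
#' @param minJunctions minimum junctions (pooled; default 10).
#' @param minPerCell minimum junctions per cell when grouped (default 5).
#' @return For pooled: list with \code{r}, \code{n}, \code{method},
#'   \code{filtered}. For grouped: data.frame \code{cell_id}, \code{r},
#'   \code{n}.
#' @export
channelPairCorrelation <- function(junctions, channelA, channelB,
                                   filterLow = c("none", "quantile"),
                                   q = 0.5, groupByCell = FALSE,
                                   method = "pearson", robustRange = TRUE,
                                   minJunctions = 10L, minPerCell = 5L) {
    filterLow <- match.arg(filterLow)
    ca <- paste0("int_", channelA); cb <- paste0("int_", channelB)
    if (is.null(junctions[[ca]]) || is.null(junctions[[cb]]))
        stop("both channels must be present in the junction table")
    if (!"embryo" %in% names(junctions)) junctions$embryo <- "e1"
    norm01 <- function(v) {
        rng <- if (robustRange)
            stats::quantile(v, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
        else range(v, na.rm = TRUE)
        if (diff(rng) == 0) return(rep(NA_real_, length(v)))
        pmin(1, pmax(0, (v - rng[1L]) / diff(rng)))
    }
    a <- b <- rep(NA_real_, nrow(junctions))
    for (e in unique(junctions$embryo)) {
        sel <- junctions$embryo == e
        a[sel] <- norm01(junctions[[ca]][sel])
        b[sel] <- norm01(junctions[[cb]][sel])
    }
    if (all(is.na(a)) || all(is.na(b))) {
        warning("degenerate (constant) channel; correlation undefined")
        return(if (groupByCell)
            data.frame(cell_id = integer(0), r = numeric(0),
                       n = integer(0))
        else list(r = NA_real_, n = 0L, method = method,
                  filtered = filterLow))
    }
    ok <- !is.na(a) & !is.na(b)
    if (filterLow == "quantile") {
        mx <- pmax(a, b)
        thr <- stats::quantile(mx[ok], q, na.rm = TRUE, names = FALSE)
        ok <- ok & mx > thr
    }
    if (!groupByCell) {
        if (sum(ok) < minJunctions)
            stop("fewer than ", minJunctions, " junctions after filtering")
        if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
            warning("degenerate (constant) channel; correlation undefined")
            return(list(r = NA_real_, n = sum(ok), method = method,
                        filtered = filterLow))
        }
        return(list(r = stats::cor(a[ok], b[ok], method = method),
                    n = sum(ok), method = method, filtered = filterLow))
    }
    out <- list()
    cellsOf <- rbind(data.frame(i = seq_len(nrow(junctions)),
                                cell = junctions$cell_a),
                     data.frame(i = seq_len(nrow(junctions)),
                                cell = junctions$cell_b))
    cellsOf <- cellsOf[cellsOf$cell > 0L, ]
    for (cid in unique(cellsOf$cell)) {
        ii <- cellsOf$i[cellsOf$cell == cid]
        ii <- ii[ok[ii]]
        if (length(ii) < minPerCell) next
        if (stats::sd(a[ii]) == 0 || stats::sd(b[ii]) == 0) next
        out[[length(out) + 1L]] <- data.frame(
            cell_id = cid, r = stats::cor(a[ii], b[ii], method = method),
            n = length(ii))
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(cell_id = integer(0), r = numeric(0),
                          n = integer(0))
    rownames(res) <- NULL
    res
}
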