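## Per-frame geometry and intensity extraction from label images.
##
## Junction skeleton rule: a pixel belongs to the skeleton of junction
## {L, K} when its own label is L (or K) and its 8-neighborhood contains
## exactly one other label, K (or L). Pixels whose neighborhood contains
## two or more other labels are tricellular-vertex pixels and belong to no
## junction. Pixels adjacent to the image edge contribute no neighbors.

.SHIFTS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

## For every pixel: the single distinct neighboring label (NA if zero or
## several), plus vertex and border-adjacency flags.
.neighborInfo <- function(lab) {
    nr <- nrow(lab); nc <- ncol(lab)
    pad <- matrix(-1L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
    mn <- matrix(Inf, nr, nc)
    mx <- matrix(-Inf, nr, nc)
    atEdge <- matrix(FALSE, nr, nc)
    for (k in seq_len(nrow(.SHIFTS))) {
        nb <- pad[2:(nr + 1L) + .SHIFTS[k, 1L], 2:(nc + 1L) + .SHIFTS[k, 2L]]
        atEdge <- atEdge | nb == -1L
        diffnb <- nb != lab & nb != -1L
        v <- ifelse(diffnb, nb, NA_integer_)
        mn <- pmin(mn, v, na.rm = TRUE)
        mx <- pmax(mx, v, na.rm = TRUE)
    }
    hasOther <- is.finite(mn)
    list(single = ifelse(hasOther & mn == mx, mn, NA_integer_),
         vertex = hasOther & mx > mn,
         atEdge = atEdge)
}

.junctionKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

## skeleton pixel linear indices grouped by junction key
.skeletonIndex <- function(lab, info = .neighborInfo(lab)) {
    idx <- which(!is.na(info$single))
    if (!length(idx)) return(list())
    own <- lab[idx]
    oth <- info$single[idx]
    keep <- own > 0L | oth > 0L
    idx <- idx[keep]; own <- own[keep]; oth <- oth[keep]
    split(idx, .junctionKey(own, oth))
}

#' Extract per-cell geometry from one frame
#'
#' One record per positive label present in the frame: calibrated area,
#' centroid, elongation from the eigen-decomposition of the second central
#' area moments (index \eqn{(a-b)/(a+b)} with \eqn{a \ge b} the
#' equivalent-ellipse semi-axes, 0 for a disc and approaching 1 for a
#' line), major-axis orientation folded to [0, 180), neighbor count and a
#' border-touching flag (cell touches the image edge or the exterior
#' label). Coordinates are in micrometres with the origin at the center of
#' the top-left pixel and x along the column axis.
#'
#' @param series a \linkS4class{SegmentedFrameSeries}.
#' @param frame positional frame index (1-based).
#' @param minPixels junctions with fewer skeleton pixels are ignored when
#'   counting junctions per cell.
#' @return A data.frame with columns \code{cell_id}, \code{area_um2},
#'   \code{centroid_x_um}, \code{centroid_y_um}, \code{elongation_index},
#'   \code{elongation_angle_deg}, \code{n_neighbors},
#'   \code{junction_count}, \code{border_touching}.
#' @export
extractCells <- function(series, frame = 1L, minPixels = 2L) {
    lab <- labelImage(series, frame)
    px <- pixelSizeUm(series)
    ids <- sort(setdiff(unique(as.vector(lab)), 0L))
    if (!length(ids))
        return(data.frame(cell_id = integer(0), area_um2 = numeric(0),
                          centroid_x_um = numeric(0),
                          centroid_y_um = numeric(0),
                          elongation_index = numeric(0),
                          elongation_angle_deg = numeric(0),
                          n_neighbors = integer(0),
                          junction_count = integer(0),
                          border_touching = logical(0)))
    idx <- which(lab > 0L)
    own <- lab[idx]
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    x <- (cc - 1) * px
    y <- (rr - 1) * px
    f <- factor(own, levels = ids)
    npix <- as.integer(table(f))
    sx <- tapply(x, f, sum); sy <- tapply(y, f, sum)
    cxv <- sx / npix; cyv <- sy / npix
    sxx <- tapply(x^2, f, sum); syy <- tapply(y^2, f, sum)
    sxy <- tapply(x * y, f, sum)
    mu20 <- sxx / npix - cxv^2
    mu02 <- syy / npix - cyv^2
    mu11 <- sxy / npix - cxv * cyv
    tr <- mu20 + mu02
    dt2 <- sqrt(pmax(0, ((mu20 - mu02) / 2)^2 + mu11^2))
    l1 <- tr / 2 + dt2
    l2 <- tr / 2 - dt2
    a <- sqrt(pmax(l1, 0)); b <- sqrt(pmax(l2, 0))
    elong <- ifelse(a + b > 0, (a - b) / (a + b), 0)
    ang <- (atan2(2 * mu11, mu20 - mu02) / 2) * 180 / pi
    ang <- ang %% 180

    info <- .neighborInfo(lab)
    skel <- .skeletonIndex(lab, info)
    skel <- skel[vapply(skel, length, integer(1)) >= minPixels]
    jmemb <- if (length(skel))
        do.call(rbind, lapply(strsplit(names(skel), "|", fixed = TRUE),
                              as.integer)) else NULL
    nNeighbors <- junctionCount <- integer(length(ids))
    for (i in seq_along(ids)) {
        if (is.null(jmemb)) break
        isMember <- jmemb[, 1L] == ids[i] | jmemb[, 2L] == ids[i]
        junctionCount[i] <- sum(isMember)
        others <- setdiff(unique(as.vector(jmemb[isMember, , drop = FALSE])),
                          c(0L, ids[i]))
        nNeighbors[i] <- length(others)
    }
    ## a cell is border-touching if any of its pixels touches the image
    ## edge or the exterior label (0)
    nbZero <- matrix(FALSE, nrow(lab), ncol(lab))
    pad <- matrix(-1L, nrow(lab) + 2L, ncol(lab) + 2L)
    pad[2:(nrow(lab) + 1L), 2:(ncol(lab) + 1L)] <- lab
    for (k in seq_len(nrow(.SHIFTS)))
        nbZero <- nbZero | pad[2:(nrow(lab) + 1L) + .SHIFTS[k, 1L],
                               2:(ncol(lab) + 1L) + .SHIFTS[k, 2L]] == 0L
    border <- as.logical(tapply(info$atEdge[idx] | nbZero[idx], f, any))

    data.frame(cell_id = ids,
               area_um2 = npix * px^2,
               centroid_x_um = as.numeric(cxv),
               centroid_y_um = as.numeric(cyv),
               elongation_index = as.numeric(elong),
               elongation_angle_deg = as.numeric(ang),
               n_neighbors = nNeighbors,
               junction_count = junctionCount,
               border_touching = border,
               row.names = NULL)
}

#' Extract per-junction geometry from one frame
#'
#' A junction is the shared boundary of two labels. Its skeleton is the
#' set of pixels 8-adjacent to exactly one other label; tricellular-vertex
#' pixels belong to no junction. Length is the chord between the two
#' skeleton pixels extreme along the skeleton's principal axis plus one
#' pixel (exact for straight boundaries), and orientation is the axial
#' direction of that chord, measured from the +x (column) axis and folded
#' to [0, 180).
#'
#' @param series a \linkS4class{SegmentedFrameSeries}.
#' @param frame positional frame index.
#' @param minPixels drop junctions with fewer skeleton pixels (default 2).
#' @return A data.frame with columns \code{junction_id} (\code{"a|b"},
#'   \code{a < b}; \code{a = 0} marks a junction with the exterior),
#'   \code{cell_a}, \code{cell_b}, \code{length_um},
#'   \code{orientation_deg}, \code{pixel_count}, \code{is_exterior}.
#'   Skeleton pixel indices are attached as the \code{"skeleton"}
#'   attribute for intensity measurement.
#' @export
extractJunctions <- function(series, frame = 1L, minPixels = 2L) {
    lab <- labelImage(series, frame)
    px <- pixelSizeUm(series)
    skel <- .skeletonIndex(lab)
    skel <- skel[vapply(skel, length, integer(1)) >= minPixels]
    out <- lapply(names(skel), function(key) {
        idx <- skel[[key]]
        rr <- (idx - 1L) %% nrow(lab) + 1L
        cc <- (idx - 1L) %/% nrow(lab) + 1L
        x <- (cc - 1) * px; y <- (rr - 1) * px
        if (length(idx) == 1L) {
            len <- px; ang <- 0
        } else {
            cx <- x - mean(x); cy <- y - mean(y)
            cxx <- mean(cx^2); cyy <- mean(cy^2); cxy <- mean(cx * cy)
            th <- atan2(2 * cxy, cxx - cyy) / 2
            pr <- cx * cos(th) + cy * sin(th)
            ## extent and direction along the principal axis (not the
            ## endpoint chord): immune to the cross-axis width of the
            ## two-sided skeleton
            len <- max(pr) - min(pr) + px
            ang <- th * 180 / pi
        }
        memb <- as.integer(strsplit(key, "|", fixed = TRUE)[[1L]])
        data.frame(junction_id = key, cell_a = memb[1L], cell_b = memb[2L],
                   length_um = len, orientation_deg = ang %% 180,
                   pixel_count = length(idx),
                   is_exterior = memb[1L] == 0L)
    })
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(junction_id = character(0), cell_a = integer(0),
                   cell_b = integer(0), length_um = numeric(0),
                   orientation_deg = numeric(0), pixel_count = integer(0),
                   is_exterior = logical(0))
    rownames(res) <- NULL
    attr(res, "skeleton") <- skel
    res
}

## Exclusive junction bands: each junction's skeleton dilated to widthPx,
## clipped to its two member cells, excluding tricellular-vertex pixels,
## skeleton pixels of other junctions, and non-skeleton pixels contested
## by several junctions' dilations. Bands are therefore pairwise disjoint,
## so painting a band with one value and taking the band mean are exact
## inverses.
.junctionBands <- function(lab, skel, widthPx = 3L,
                           info = .neighborInfo(lab)) {
    nr <- nrow(lab); nc <- ncol(lab)
    r <- (widthPx - 1L) %/% 2L
    ownSkel <- integer(nr * nc)            # junction index owning a skeleton px
    for (i in seq_along(skel)) ownSkel[skel[[i]]] <- i
    claims <- integer(nr * nc)
    cand <- vector("list", length(skel))
    memb <- lapply(strsplit(names(skel), "|", fixed = TRUE), as.integer)
    for (i in seq_along(skel)) {
        idx <- skel[[i]]
        rr <- (idx - 1L) %% nr + 1L
        cc <- (idx - 1L) %/% nr + 1L
        band <- idx
        if (r > 0L) {
            for (dr in -r:r) for (dc in -r:r) {
                if (dr == 0L && dc == 0L) next
                r2 <- rr + dr; c2 <- cc + dc
                ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
                band <- c(band, (c2[ok] - 1L) * nr + r2[ok])
            }
            band <- unique(band)
        }
        band <- band[lab[band] %in% memb[[i]] & !info$vertex[band] &
                     (ownSkel[band] == 0L | ownSkel[band] == i)]
        cand[[i]] <- band
        nonskel <- band[ownSkel[band] == 0L]
        claims[nonskel] <- claims[nonskel] + 1L
    }
    bands <- lapply(seq_along(skel), function(i) {
        b <- cand[[i]]
        b[ownSkel[b] == i | claims[b] == 1L]
    })
    names(bands) <- names(skel)
    bands
}

#' Mean junctional intensity along dilated skeleton bands
#'
#' The skeleton of each junction is dilated to a band \code{widthPx}
#' pixels wide (default 3, ~0.5 um at 0.17 um/px), clipped to the two
#' member cells' pixels, excluding tricellular-vertex pixels and pixels
#' contested by a neighboring junction's band; the value is the mean of
#' the channel over that band.
#'
#' @param series a \linkS4class{SegmentedFrameSeries} with channels.
#' @param channel channel name.
#' @param junctions result of [extractJunctions()] for the same frame.
#' @param frame positional frame index.
#' @param widthPx band width in pixels (odd).
#' @return Numeric vector of band means, one per junction row.
#' @export
measureJunctionIntensity <- function(series, channel, junctions,
                                     frame = 1L, widthPx = 3L) {
    lab <- labelImage(series, frame)
    ch <- channelImage(series, channel, frame)
    skel <- attr(junctions, "skeleton")
    if (is.null(skel)) stop("junctions must come from extractJunctions()")
    bands <- .junctionBands(lab, skel, widthPx)
    vapply(seq_len(nrow(junctions)), function(i) {
        band <- bands[[junctions$junction_id[i]]]
        if (!length(band)) stop("measurement error: empty band for junction ",
                                junctions$junction_id[i])
        mean(ch[band])
    }, numeric(1))
}

#' Mean medial (cytoplasmic) intensity of cells
#'
#' Mean channel intensity over each cell's pixels eroded by
#' \code{erosionPx} so junction bands are excluded. If erosion empties a
#' cell, the fall-back is the cell's pixels that lie on no junction
#' skeleton or its 1-px dilation, and the record is flagged.
#'
#' @param series a \linkS4class{SegmentedFrameSeries} with channels.
#' @param channel channel name.
#' @param frame positional frame index.
#' @param erosionPx Chebyshev erosion radius in pixels (default 3).
#' @param cells optional integer vector of cell ids (default: all present).
#' @return data.frame with \code{cell_id}, \code{medial_mean},
#'   \code{fallback}.
#' @export
measureMedialIntensity <- function(series, channel, frame = 1L,
                                   erosionPx = 3L, cells = NULL) {
    lab <- labelImage(series, frame)
    ch <- channelImage(series, channel, frame)
    nr <- nrow(lab); nc <- ncol(lab)
    ## pixel is medial when every pixel within the Chebyshev radius has
    ## the same label (simultaneous erosion of all label regions)
    pad <- matrix(-1L, nr + 2L * erosionPx, nc + 2L * erosionPx)
    pad[erosionPx + 1:nr, erosionPx + 1:nc] <- lab
    medial <- matrix(TRUE, nr, nc)
    for (dr in -erosionPx:erosionPx) for (dc in -erosionPx:erosionPx) {
        if (dr == 0L && dc == 0L) next
        nb <- pad[erosionPx + 1:nr + dr, erosionPx + 1:nc + dc]
        medial <- medial & nb == lab
    }
    ids <- if (is.null(cells)) sort(setdiff(unique(as.vector(lab)), 0L))
           else cells
    skelIdx <- unlist(.skeletonIndex(lab), use.names = FALSE)
    nearSkel <- matrix(FALSE, nr, nc)
    if (length(skelIdx)) {
        rr <- (skelIdx - 1L) %% nr + 1L
        cc <- (skelIdx - 1L) %/% nr + 1L
        for (dr in -1:1) for (dc in -1:1) {
            r2 <- rr + dr; c2 <- cc + dc
            ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
            nearSkel[(c2[ok] - 1L) * nr + r2[ok]] <- TRUE
        }
    }
    out <- lapply(ids, function(id) {
        inCell <- lab == id
        if (!any(inCell)) stop("lookup error: cell ", id,
                               " absent from frame ", frame)
        use <- inCell & medial
        fb <- FALSE
        if (!any(use)) {
            use <- inCell & !nearSkel
            fb <- TRUE
            if (!any(use)) use <- inCell   # degenerate sliver: whole cell
        }
        data.frame(cell_id = id, medial_mean = mean(ch[use]), fallback = fb)
    })
    do.call(rbind, out)
}

#' Assemble cell and junction tracks from a series
#'
#' Measures every frame with [extractCells()] / [extractJunctions()] (and
#' the intensity measurers when channels are present) and assembles
#' per-entity time series. A cell track persists while its label is
#' present; single-frame dropouts are bridged with an NA record flagged
#' \code{bridged}; a gap of two or more frames splits the track (with a
#' warning), giving track ids \code{"<id>"}, \code{"<id>.2"}, ... A
#' junction track persists while its member pair shares a boundary.
#'
#' @param series a \linkS4class{SegmentedFrameSeries}.
#' @param channels channel names to measure (default: all).
#' @param minPixels junction retention threshold (skeleton pixels).
#' @param widthPx junction band width for intensity.
#' @param erosionPx medial erosion radius.
#' @return list with data.frames \code{cells} and \code{junctions}; frame
#'   columns hold the stored (0-based) frame indices.
#' @export
buildTracks <- function(series, channels = channelNames(series),
                        minPixels = 2L, widthPx = 3L, erosionPx = 3L) {
    fi <- frameIndices(series)
    cellL <- vector("list", nFrames(series))
    juncL <- vector("list", nFrames(series))
    for (k in seq_len(nFrames(series))) {
        cells <- extractCells(series, k, minPixels)
        juncs <- extractJunctions(series, k, minPixels)
        if (length(channels)) {
            for (nm in channels) {
                juncs[[paste0("int_", nm)]] <-
                    measureJunctionIntensity(series, nm, juncs, k, widthPx)
                med <- measureMedialIntensity(series, nm, k, erosionPx)
                cells[[paste0("medial_", nm)]] <-
                    med$medial_mean[match(cells$cell_id, med$cell_id)]
            }
        }
        cells$frame <- rep(fi[k], nrow(cells))
        juncs$frame <- rep(fi[k], nrow(juncs))
        attr(juncs, "skeleton") <- NULL
        cellL[[k]] <- cells
        juncL[[k]] <- juncs
    }
    cells <- do.call(rbind, cellL)
    juncs <- do.call(rbind, juncL)
    list(cells = .trackify(cells, "cell_id", fi),
         junctions = .trackify(juncs, "junction_id", fi,
                               warnSplit = FALSE))
}

## contiguity handling: bridge 1-frame gaps, split on >= 2
.trackify <- function(df, idcol, allFrames, warnSplit = TRUE) {
    if (is.null(df) || !nrow(df)) return(df)
    df <- df[order(df[[idcol]], df$frame), , drop = FALSE]
    df$bridged <- FALSE
    out <- list()
    for (id in unique(df[[idcol]])) {
        sub <- df[df[[idcol]] == id, , drop = FALSE]
        pos <- match(sub$frame, allFrames)
        gaps <- diff(pos)
        seg <- cumsum(c(1L, gaps >= 3L))
        if (max(seg) > 1L && warnSplit)
            warning("track ", id, " is non-contiguous; split into ",
                    max(seg), " tracks")
        for (s in unique(seg)) {
            ss <- sub[seg == s, , drop = FALSE]
            spos <- match(ss$frame, allFrames)
            if (any(diff(spos) == 2L)) {
                holes <- which(diff(spos) == 2L)
                for (h in holes) {
                    row <- ss[h, , drop = FALSE]
                    meas <- setdiff(names(row), c(idcol, "frame", "bridged",
                        "cell_a", "cell_b", "is_exterior", "border_touching"))
                    row[meas] <- NA
                    row$frame <- allFrames[spos[h] + 1L]
                    row$bridged <- TRUE
                    ss <- rbind(ss, row)
                }
                ss <- ss[order(ss$frame), , drop = FALSE]
            }
            ss$track_id <- if (s == 1L) as.character(id)
                           else paste0(id, ".", s)
            out[[length(out) + 1L]] <- ss
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
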