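## Polygon-mesh synthetic epithelium: Lloyd-relaxed Voronoi partition of a
## rectangular field, kept as a shared-vertex mesh so that junction moves
## deform neighboring cells consistently, and rasterized to integer labels.

.polyArea <- function(p) {
    # signed shoelace area; positive for counter-clockwise vertex order
    n <- nrow(p)
    i2 <- c(2:n, 1L)
    sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]) / 2
}

.polyCentroid <- function(p) {
    n <- nrow(p)
    i2 <- c(2:n, 1L)
    cr <- p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(colMeans(p))
    c(sum((p[, 1L] + p[i2, 1L]) * cr), sum((p[, 2L] + p[i2, 2L]) * cr)) / (6 * a)
}

## Sutherland-Hodgman clip of polygon p by half-plane {x : a.x <= b}
.clipHalfPlane <- function(p, a, b) {
    n <- nrow(p)
    if (n == 0L) return(p)
    d <- p %*% a - b
    keep <- d <= 1e-12
    out <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        if (keep[i]) { k <- k + 1L; out[[k]] <- p[i, ] }
        if (keep[i] != keep[j]) {
            t <- d[i] / (d[i] - d[j])
            k <- k + 1L
            out[[k]] <- p[i, ] + t * (p[j, ] - p[i, ])
        }
    }
    if (k == 0L) return(matrix(numeric(0), 0L, 2L))
    do.call(rbind, out[seq_len(k)])
}

.voronoiCell <- function(i, seeds, W, H) {
    poly <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
    si <- seeds[i, ]
    for (j in seq_len(nrow(seeds))) {
        if (j == i) next
        sj <- seeds[j, ]
        a <- sj - si
        b <- sum(sj^2 - si^2) / 2
        poly <- .clipHalfPlane(poly, a, b)
        if (nrow(poly) < 3L) break
    }
    poly
}

.lloyd <- function(seeds, W, H, iter) {
    for (k in seq_len(iter)) {
        seeds <- t(vapply(seq_len(nrow(seeds)), function(i)
            .polyCentroid(.voronoiCell(i, seeds, W, H)), numeric(2)))
    }
    seeds
}

## Merge near-identical vertices across independently clipped cell polygons
## into a shared vertex table; faces reference vertex indices.
.buildMesh <- function(polys, tol = 1e-6) {
    V <- matrix(numeric(0), 0L, 2L)
    faces <- vector("list", length(polys))
    for (i in seq_along(polys)) {
        p <- polys[[i]]
        if (.polyArea(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        idx <- integer(nrow(p))
        for (k in seq_len(nrow(p))) {
            if (nrow(V)) {
                d2 <- (V[, 1L] - p[k, 1L])^2 + (V[, 2L] - p[k, 2L])^2
                hit <- which(d2 < tol^2)
            } else hit <- integer(0)
            if (length(hit)) {
                idx[k] <- hit[1L]
            } else {
                V <- rbind(V, p[k, ])
                idx[k] <- nrow(V)
            }
        }
        faces[[i]] <- idx[!duplicated(idx)]
    }
    edges <- list()
    for (i in seq_along(faces)) {
        f <- faces[[i]]
        n <- length(f)
        for (k in seq_len(n)) {
            v1 <- f[k]; v2 <- f[if (k == n) 1L else k + 1L]
            key <- paste(min(v1, v2), max(v1, v2), sep = "-")
            if (is.null(edges[[key]]))
                edges[[key]] <- list(v = c(min(v1, v2), max(v1, v2)),
                                     cells = i)
            else edges[[key]]$cells <- c(edges[[key]]$cells, i)
        }
    }
    et <- data.frame(
        v1 = vapply(edges, function(e) e$v[1L], numeric(1)),
        v2 = vapply(edges, function(e) e$v[2L], numeric(1)),
        cell_a = vapply(edges, function(e)
            if (length(e$cells) == 2L) min(e$cells) else 0L, numeric(1)),
        cell_b = vapply(edges, function(e)
            if (length(e$cells) == 2L) max(e$cells) else e$cells[1L],
            numeric(1)))
    rownames(et) <- NULL
    list(V = V, faces = faces, edges = et)
}

.meshAdjacency <- function(mesh) {
    e <- mesh$edges[mesh$edges$cell_a > 0L, ]
    unique(e[, c("cell_a", "cell_b")])
}

.faceArea <- function(mesh, i, V = mesh$V)
    abs(.polyArea(V[mesh$faces[[i]], , drop = FALSE]))

.faceCentroid <- function(mesh, i, V = mesh$V)
    .polyCentroid(V[mesh$faces[[i]], , drop = FALSE])

## Scanline rasterization of the face polygons into an integer label image.
## Pixel centers sit at (c - 0.5, r - 0.5) in pixel units; half-open
## crossing conventions make shared edges partition exactly (no gaps or
## double assignment between neighboring faces).
.rasterizeMesh <- function(mesh, V, nrow, ncol, pixelSizeUm, marginPx,
                           skip = integer(0)) {
    lab <- matrix(0L, nrow, ncol)
    for (i in seq_along(mesh$faces)) {
        if (i %in% skip) next
        P <- V[mesh$faces[[i]], , drop = FALSE] / pixelSizeUm + marginPx
        if (nrow(P) < 3L) next
        n <- nrow(P)
        i2 <- c(2:n, 1L)
        rowsList <- vector("list", n)
        xsList <- vector("list", n)
        for (k in seq_len(n)) {
            y1 <- P[k, 2L]; y2 <- P[i2[k], 2L]
            if (y1 == y2) next
            ylo <- min(y1, y2); yhi <- max(y1, y2)
            rlo <- ceiling(ylo + 0.5); rhi <- ceiling(yhi + 0.5) - 1L
            if (rhi < rlo) next
            rr <- rlo:rhi
            yc <- rr - 0.5
            xc <- P[k, 1L] + (yc - y1) * (P[i2[k], 1L] - P[k, 1L]) / (y2 - y1)
            rowsList[[k]] <- rr
            xsList[[k]] <- xc
        }
        rows <- unlist(rowsList)
        xs <- unlist(xsList)
        if (!length(rows)) next
        ok <- rows >= 1L & rows <= nrow
        rows <- rows[ok]; xs <- xs[ok]
        for (r in unique(rows)) {
            x <- sort(xs[rows == r])
            m <- length(x) %/% 2L
            for (q in seq_len(m)) {
                clo <- ceiling(x[2L * q - 1L] + 0.5)
                chi <- ceiling(x[2L * q] + 0.5) - 1L
                if (chi < clo) next
                clo <- max(1L, clo); chi <- min(ncol, chi)
                if (chi >= clo) lab[r, clo:chi] <- i
            }
        }
    }
    lab
}

## Enforce a valid partition: background pixels not 4-connected to the
## image border (rasterization holes left by strongly deformed polygons)
## are filled with the modal neighboring label, iteratively for thick gaps.
.fillInteriorGaps <- function(lab) {
    if (!any(lab == 0L)) return(lab)
    comp <- EBImage::bwlabel(lab == 0L)
    edgeComps <- unique(c(comp[1L, ], comp[nrow(comp), ],
                          comp[, 1L], comp[, ncol(comp)]))
    edgeComps <- edgeComps[edgeComps > 0L]
    gaps <- which(comp > 0L & !(comp %in% edgeComps))
    nr <- nrow(lab)
    guard <- 0L
    while (length(gaps) && guard < 64L) {
        guard <- guard + 1L
        filled <- FALSE
        newlab <- lab
        for (p in gaps) {
            r <- (p - 1L) %% nr + 1L
            c <- (p - 1L) %/% nr + 1L
            nb <- lab[cbind(pmax(1L, pmin(nrow(lab), r + .SHIFTS[, 1L])),
                            pmax(1L, pmin(ncol(lab), c + .SHIFTS[, 2L])))]
            nb <- nb[nb > 0L]
            if (length(nb)) {
                t <- table(nb)
                newlab[p] <- as.integer(names(t)[which.max(t)])
                filled <- TRUE
            }
        }
        lab <- newlab
        gaps <- gaps[lab[gaps] == 0L]
        if (!filled) break
    }
    lab
}

#' Generate a synthetic segmented epithelial tissue
#'
#' Draws random seed points in a square field, Lloyd-relaxes their Voronoi
#' partition into a realistic apical cell mesh, and rasterizes it to an
#' integer label image (label 0 = exterior margin). The polygon mesh is
#' kept in the series metadata so \code{\link{simulateDynamics}} can deform
#' it with shared vertices.
#'
#' @param nCells number of cells (>= 3).
#' @param meanAreaUm2 mean apical cell area in um^2 (default 45; apical
#'   surfaces of the modelled epithelium span roughly 20-80 um^2).
#' @param calibration a \linkS4class{Calibration}; the default 0.17 um/px
#'   makes a 3-px junction band ~0.5 um wide.
#' @param seed RNG seed; identical seeds give pixel-identical labels.
#' @param lloydIter Lloyd relaxation iterations (default 8).
#' @param marginPx exterior margin in pixels around the tissue.
#' @return A one-frame \linkS4class{SegmentedFrameSeries} with the mesh in
#'   \code{metadata$mesh}.
#' @examples
#' tis <- generateTissue(12, seed = 1)
#' table(labelImage(tis) > 0)
#' @export
generateTissue <- function(nCells, meanAreaUm2 = 45,
                           calibration = Calibration(), seed = 1,
                           lloydIter = 8, marginPx = 2) {
    if (nCells < 3) stop("parameter error: nCells must be >= 3")
    px <- pixelSizeUm(calibration)
    if (meanAreaUm2 / px^2 < 30)
        stop("parameter error: field too small for nCells at this pixel size",
             " (< 30 px per cell)")
    W <- sqrt(nCells * meanAreaUm2)
    set.seed(seed)
    seeds <- cbind(runif(nCells, 0, W), runif(nCells, 0, W))
    seeds <- .lloyd(seeds, W, W, lloydIter)
    polys <- lapply(seq_len(nCells), function(i)
        .voronoiCell(i, seeds, W, W))
    if (any(vapply(polys, nrow, integer(1)) < 3L))
        stop("degenerate Voronoi cell; try another seed")
    mesh <- .buildMesh(polys)
    side <- ceiling(W / px) + 2L * marginPx
    lab <- .rasterizeMesh(mesh, mesh$V, side, side, px, marginPx)
    SegmentedFrameSeries(lab, calibration,
        metadata = list(mesh = mesh, marginPx = marginPx, fieldUm = W,
                        seed = seed))
}

#' Generate a regular honeycomb tissue
#'
#' A mesh of regular hexagons, useful as a symmetric fixture: every
#' interior cell has six equal junctions at axial orientations 0, 60 and
#' 120 degrees (flat-top hexagons), so uniform painted channels give
#' near-zero planar-polarity magnitude.
#'
#' @param rows,cols hexagon grid dimensions.
#' @param edgeUm hexagon edge length in micrometres.
#' @param calibration a \linkS4class{Calibration}.
#' @param marginPx exterior margin in pixels.
#' @return A one-frame \linkS4class{SegmentedFrameSeries} with the mesh in
#'   \code{metadata$mesh}.
#' @export
generateHoneycomb <- function(rows = 4, cols = 4, edgeUm = 4,
                              calibration = Calibration(), marginPx = 2) {
    px <- pixelSizeUm(calibration)
    e <- edgeUm
    polys <- list()
    for (i in seq_len(rows)) for (j in seq_len(cols)) {
        cx <- 1.5 * e * (j - 1) + e
        cy <- sqrt(3) * e * (i - 1) + (j %% 2) * sqrt(3) / 2 * e + e
        ang <- (0:5) * pi / 3
        polys[[length(polys) + 1L]] <-
            cbind(cx + e * cos(ang), cy + e * sin(ang))
    }
    mesh <- .buildMesh(polys, tol = 1e-9)
    W <- max(mesh$V[, 1L]); H <- max(mesh$V[, 2L])
    lab <- .rasterizeMesh(mesh, mesh$V, ceiling(H / px) + 2L * marginPx,
                          ceiling(W / px) + 2L * marginPx, px, marginPx)
    SegmentedFrameSeries(lab, calibration,
        metadata = list(mesh = mesh, marginPx = marginPx))
}
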