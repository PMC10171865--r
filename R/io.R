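#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite write_json read_json
NULL

## Labels are stored as 16-bit integer TIFF pages (bit-exact round trip,
## labels up to 65535); channels as 32-bit float pages scaled to [0,1] by a
## per-channel maximum recorded in the manifest.
.LABEL_MAX <- 65535L

.calibrationToList <- function(cal) list(
    pixelSizeUm = cal@pixelSizeUm,
    frameIntervalMin = cal@frameIntervalMin,
    midlineXUm = if (is.na(cal@midlineXUm)) NULL else cal@midlineXUm,
    streakHalfwidthUm = cal@streakHalfwidthUm)

.calibrationFromList <- function(x) {
    mid <- x$midlineXUm
    if (is.null(mid) || !length(mid) || is.list(mid)) mid <- NA_real_
    Calibration(pixelSizeUm = x$pixelSizeUm,
                frameIntervalMin = x$frameIntervalMin,
                midlineXUm = mid,
                streakHalfwidthUm = x$streakHalfwidthUm %||% 20)
}

#' Write a segmented frame series to a directory
#'
#' Writes \code{labels.tif} (multi-page 16-bit integer), one multi-page
#' 32-bit float TIFF per channel, and a \code{series.json} manifest holding
#' the frame indices, per-channel intensity scale factors and the
#' calibration. \code{readSeries} inverts it; labels round-trip bit-exactly.
#'
#' @param series a \linkS4class{SegmentedFrameSeries}.
#' @param path output directory (created if missing).
#' @return \code{path}, invisibly.
#' @seealso [readSeries()]
#' @export
writeSeries <- function(series, path) {
    stopifnot(is(series, "SegmentedFrameSeries"))
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    labs <- lapply(series@frames, `[[`, "labels")
    if (max(vapply(labs, max, numeric(1))) > .LABEL_MAX)
        stop("labels exceed the 16-bit storage range")
    writeTIFF(lapply(labs, function(m) m / .LABEL_MAX),
              file.path(path, "labels.tif"), bits.per.sample = 16L)
    chn <- channelNames(series)
    scales <- list()
    for (nm in chn) {
        imgs <- lapply(seq_len(nFrames(series)), function(i)
            channelImage(series, nm, i))
        sc <- max(1e-12, max(vapply(imgs, max, numeric(1))))
        scales[[nm]] <- sc
        writeTIFF(lapply(imgs, function(m) pmin(pmax(m / sc, 0), 1)),
                  file.path(path, paste0("channel_", nm, ".tif")),
                  bits.per.sample = 32L)
    }
    manifest <- list(frameIndices = frameIndices(series),
                     channels = scales,
                     calibration = .calibrationToList(calibration(series)))
    write_json(manifest, file.path(path, "series.json"),
               auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a segmented frame series
#'
#' Accepts either a directory written by \code{\link{writeSeries}} (with a
#' \code{series.json} manifest) or the path of a bare multi-page label TIFF
#' with optional sibling channel TIFFs. Labels are left untouched (no
#' relabelling).
#'
#' @param path directory or label-TIFF path.
#' @param calibration a \linkS4class{Calibration}; when \code{NULL} the
#'   manifest calibration is used (required for bare TIFF input).
#' @param channels for bare TIFF input, a named character vector of channel
#'   TIFF paths.
#' @return A validated \linkS4class{SegmentedFrameSeries}.
#' @export
readSeries <- function(path, calibration = NULL, channels = NULL) {
    if (dir.exists(path)) {
        manifest <- read_json(file.path(path, "series.json"),
                              simplifyVector = TRUE)
        idx <- as.integer(manifest$frameIndices)
        if (length(idx) > 1L && any(diff(idx) <= 0))
            stop("format error: non-monotone frame indices in manifest")
        if (is.null(calibration))
            calibration <- .calibrationFromList(manifest$calibration)
        labs <- .readLabelStack(file.path(path, "labels.tif"))
        chn <- names(manifest$channels)
        chans <- rep(list(list()), length(labs))
        for (nm in chn) {
            imgs <- readTIFF(file.path(path, paste0("channel_", nm, ".tif")),
                             all = TRUE)
            if (!is.list(imgs)) imgs <- list(imgs)
            sc <- manifest$channels[[nm]]
            for (i in seq_along(labs)) {
                m <- imgs[[i]] * sc
                if (!identical(dim(m), dim(labs[[i]])))
                    stop("format error: channel '", nm,
                         "' shape differs from labels in frame ", i)
                chans[[i]][[nm]] <- m
            }
        }
        return(SegmentedFrameSeries(labs, calibration, chans, idx))
    }
    if (is.null(calibration))
        stop("a Calibration is required when reading a bare label TIFF")
    labs <- .readLabelStack(path)
    chans <- rep(list(list()), length(labs))
    for (nm in names(channels)) {
        imgs <- readTIFF(channels[[nm]], all = TRUE)
        if (!is.list(imgs)) imgs <- list(imgs)
        for (i in seq_along(labs)) {
            if (!identical(dim(imgs[[i]]), dim(labs[[i]])))
                stop("format error: channel '", nm,
                     "' shape differs from labels in frame ", i)
            chans[[i]][[nm]] <- imgs[[i]]
        }
    }
    SegmentedFrameSeries(labs, calibration, chans)
}

.readLabelStack <- function(file) {
    labs <- readTIFF(file, all = TRUE, as.is = TRUE)
    if (!is.list(labs)) labs <- list(labs)
    lapply(labs, function(m) {
        if (!all(m == round(m)))
            stop("format error: non-integer label data in ", file)
        storage.mode(m) <- "integer"
        m
    })
}

## ---- long-format measurement tables -------------------------------------

## Wide track data.frames <-> the long MeasurementTable layout
## (entity, id, frame, variable, value, channel, embryo, genotype).
.CHANNEL_VARS <- c(intensity = "^int_", medial_intensity = "^medial_")

.toLong <- function(df, entity, idcol) {
    if (is.null(df) || !nrow(df)) return(NULL)
    embryo <- if ("embryo" %in% names(df)) df$embryo else "e1"
    genotype <- if ("genotype" %in% names(df)) df$genotype else NA_character_
    meta <- c(idcol, "frame", "embryo", "genotype", "track_id",
              "junction_id")
    vars <- setdiff(names(df), meta)
    out <- lapply(vars, function(v) {
        channel <- NA_character_
        variable <- v
        for (vn in names(.CHANNEL_VARS)) {
            if (grepl(.CHANNEL_VARS[[vn]], v)) {
                channel <- sub(.CHANNEL_VARS[[vn]], "", v)
                variable <- vn
            }
        }
        data.frame(entity = entity, id = .entityId(df, idcol),
                   frame = df$frame, variable = variable,
                   value = as.numeric(df[[v]]), channel = channel,
                   embryo = embryo, genotype = genotype,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

.entityId <- function(df, idcol) {
    if (length(idcol) == 1L) as.character(df[[idcol]])
    else paste(df[[idcol[1L]]], df[[idcol[2L]]], sep = "|")
}

.checkLongKeys <- function(long) {
    key <- paste(long$entity, long$id, long$frame, long$variable,
                 long$channel, sep = "\r")
    if (anyDuplicated(key))
        stop("integrity error: duplicate (entity, frame, variable, channel) keys")
    if (any(!is.finite(long$value) & !is.na(long$value)))
        stop("integrity error: non-finite values in measurement table")
    invisible(long)
}

.writeLongCSV <- function(long, file) {
    v <- formatC(long$value, digits = 17, format = "g")
    v[is.na(long$value)] <- NA
    long$value <- v
    utils::write.csv(long, file, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
}

#' Write cell and junction tracks as long-format CSV tables
#'
#' Emits \code{cells.csv} and \code{junctions.csv} in long format (one row
#' per entity/frame/variable/channel) plus a \code{calibration.json}
#' sidecar. Values are written with 17 significant digits so
#' \code{\link{readTables}} restores them exactly.
#'
#' @param cellTracks,junctionTracks wide track data.frames as returned by
#'   [buildTracks()] (either may be \code{NULL}).
#' @param path output directory.
#' @param calibration a \linkS4class{Calibration} for the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeTables <- function(cellTracks, junctionTracks, path,
                        calibration = Calibration()) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    cl <- .toLong(cellTracks, "cell", "cell_id")
    jl <- .toLong(junctionTracks, "junction", c("cell_a", "cell_b"))
    if (!is.null(cl)) .writeLongCSV(.checkLongKeys(cl),
                                    file.path(path, "cells.csv"))
    if (!is.null(jl)) .writeLongCSV(.checkLongKeys(jl),
                                    file.path(path, "junctions.csv"))
    write_json(.calibrationToList(calibration),
               file.path(path, "calibration.json"),
               auto_unbox = TRUE, digits = NA)
    invisible(path)
}

.fromLong <- function(long, idcol) {
    if (is.null(long) || !nrow(long)) return(NULL)
    long$.var <- ifelse(is.na(long$channel) | long$channel == "",
        long$variable,
        paste0(c(intensity = "int_", medial_intensity = "medial_")[long$variable],
               long$channel))
    key <- paste(long$id, long$frame, long$embryo, long$genotype,
                 sep = "\r")
    ukey <- !duplicated(key)
    wide <- data.frame(id = long$id[ukey], frame = long$frame[ukey],
                       embryo = long$embryo[ukey],
                       genotype = long$genotype[ukey],
                       stringsAsFactors = FALSE)
    rowOf <- match(key, key[ukey])
    for (v in unique(long$.var)) {
        col <- rep(NA_real_, nrow(wide))
        sel <- long$.var == v
        col[rowOf[sel]] <- long$value[sel]
        wide[[v]] <- col
    }
    if (length(idcol) == 2L) {
        parts <- strsplit(wide$id, "|", fixed = TRUE)
        wide[[idcol[1L]]] <- as.integer(vapply(parts, `[`, "", 1L))
        wide[[idcol[2L]]] <- as.integer(vapply(parts, `[`, "", 2L))
    } else {
        wide[[idcol]] <- as.integer(wide$id)
    }
    wide$id <- NULL
    for (lc in intersect(c("border_touching", "bridged", "is_exterior",
                           "fallback"), names(wide)))
        wide[[lc]] <- as.logical(wide[[lc]])
    if (length(idcol) == 2L)
        wide$junction_id <- .junctionKey(wide[[idcol[1L]]],
                                         wide[[idcol[2L]]])
    rownames(wide) <- NULL
    wide <- wide[order(wide[[idcol[1L]]], wide$frame), ]
    rownames(wide) <- NULL
    wide
}

#' Read long-format measurement tables
#'
#' Inverse of \code{\link{writeTables}}.
#'
#' @param path directory holding \code{cells.csv} / \code{junctions.csv} /
#'   \code{calibration.json}.
#' @return A list with components \code{cells}, \code{junctions} (wide
#'   data.frames, possibly \code{NULL}) and \code{calibration}.
#' @export
readTables <- function(path) {
    rd <- function(f) {
        p <- file.path(path, f)
        if (!file.exists(p)) return(NULL)
        df <- utils::read.csv(p, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
        df$value <- as.numeric(df$value)
        df
    }
    cal <- .calibrationFromList(read_json(file.path(path, "calibration.json"),
                                          simplifyVector = TRUE))
    list(cells = .fromLong(rd("cells.csv"), "cell_id"),
         junctions = .fromLong(rd("junctions.csv"), c("cell_a", "cell_b")),
         calibration = cal)
}
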