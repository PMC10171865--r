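#' Accessors for Calibration objects
#'
#' @param x a \linkS4class{Calibration} or \linkS4class{SegmentedFrameSeries}.
#' @return the requested scalar.
#' @name Calibration-accessors
#' @aliases pixelSizeUm frameIntervalMin
NULL

#' @rdname Calibration-accessors
#' @export
setMethod("pixelSizeUm", "Calibration", function(x) x@pixelSizeUm)

#' @rdname Calibration-accessors
#' @export
setMethod("frameIntervalMin", "Calibration", function(x) x@frameIntervalMin)

#' @rdname Calibration-accessors
#' @export
setMethod("pixelSizeUm", "SegmentedFrameSeries",
    function(x) x@calibration@pixelSizeUm)

#' @rdname Calibration-accessors
#' @export
setMethod("frameIntervalMin", "SegmentedFrameSeries",
    function(x) x@calibration@frameIntervalMin)

#' Accessors for SegmentedFrameSeries objects
#'
#' \code{nFrames} gives the number of frames; \code{frameIndices} the
#' stored integer frame indices; \code{labelImage} the integer label matrix
#' of frame \code{i} (positional index); \code{channelNames} the channel
#' names of the first frame; \code{channelImage} a named channel matrix;
#' \code{calibration} the \linkS4class{Calibration}; \code{groundTruth}
#' the generator ground truth (or \code{NULL} for measured data).
#'
#' @param x a \linkS4class{SegmentedFrameSeries}.
#' @param i positional frame index (1-based).
#' @param name channel name.
#' @name SegmentedFrameSeries-accessors
#' @aliases nFrames frameIndices labelImage channelNames channelImage
#'   calibration groundTruth
NULL

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("nFrames", "SegmentedFrameSeries", function(x) length(x@frames))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("frameIndices", "SegmentedFrameSeries", function(x)
    vapply(x@frames, function(f) f$frameIndex, integer(1)))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("labelImage", "SegmentedFrameSeries", function(x, i = 1L)
    x@frames[[i]]$labels)

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("channelNames", "SegmentedFrameSeries", function(x) {
    if (!length(x@frames)) return(character(0))
    names(x@frames[[1L]]$channels) %||% character(0)
})

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("channelImage", "SegmentedFrameSeries",
    function(x, name, i = 1L) {
        ch <- x@frames[[i]]$channels
        if (is.null(ch[[name]]))
            stop("no channel '", name, "' in frame ", i)
        ch[[name]]
    })

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("calibration", "SegmentedFrameSeries", function(x) x@calibration)

#' @rdname SegmentedFrameSeries-accessors
#' @export
setMethod("groundTruth", "SegmentedFrameSeries",
    function(x) x@metadata$groundTruth)

setMethod("show", "Calibration", function(object) {
    cat("Calibration: ", object@pixelSizeUm, " um/px, ",
        object@frameIntervalMin, " min/frame", sep = "")
    if (!is.na(object@midlineXUm))
        cat(", midline x = ", object@midlineXUm, " um, streak half-width ",
            object@streakHalfwidthUm, " um", sep = "")
    cat("\n")
})

setMethod("show", "SegmentedFrameSeries", function(object) {
    n <- length(object@frames)
    cat("SegmentedFrameSeries with ", n, " frame(s)\n", sep = "")
    if (n) {
        d <- dim(object@frames[[1L]]$labels)
        labs <- unique(as.vector(object@frames[[1L]]$labels))
        cat("  grid: ", d[1L], " x ", d[2L], " px; ",
            sum(labs > 0L), " cells in frame 1\n", sep = "")
        ch <- names(object@frames[[1L]]$channels)
        if (length(ch))
            cat("  channels: ", paste(ch, collapse = ", "), "\n", sep = "")
    }
    show(object@calibration)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
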