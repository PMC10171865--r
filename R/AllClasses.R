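#' @import methods
NULL

#' Spatial and temporal calibration of a segmented series
#'
#' Holds the physical scaling of a label-image series: pixel size in
#' micrometres, frame interval in minutes, and (optionally) the horizontal
#' position of the tissue midline together with the half-width of the
#' streak domain used when restricting event statistics to the region
#' around the midline (default 20 um, i.e. a 40 um wide domain).
#'
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot frameIntervalMin minutes per frame (> 0).
#' @slot midlineXUm x position (um) of the tissue midline, or \code{NA}.
#' @slot streakHalfwidthUm half-width (um) of the streak domain (> 0).
#' @aliases Calibration-class
#' @exportClass Calibration
setClass("Calibration",
    representation(
        pixelSizeUm = "numeric",
        frameIntervalMin = "numeric",
        midlineXUm = "numeric",
        streakHalfwidthUm = "numeric"
    ),
    prototype(
        pixelSizeUm = 0.17,
        frameIntervalMin = 5,
        midlineXUm = NA_real_,
        streakHalfwidthUm = 20
    )
)

setValidity("Calibration", function(object) {
    msg <- NULL
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
        msg <- c(msg, "'pixelSizeUm' must be a single positive number")
    if (length(object@frameIntervalMin) != 1L ||
        !is.finite(object@frameIntervalMin) || object@frameIntervalMin <= 0)
        msg <- c(msg, "'frameIntervalMin' must be a single positive number")
    if (length(object@streakHalfwidthUm) != 1L ||
        !is.finite(object@streakHalfwidthUm) ||
        object@streakHalfwidthUm <= 0)
        msg <- c(msg, "'streakHalfwidthUm' must be a single positive number")
    if (length(object@midlineXUm) != 1L)
        msg <- c(msg, "'midlineXUm' must be length one (may be NA)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Calibration object
#'
#' @param pixelSizeUm micrometres per pixel. The default 0.17 makes a
#'   3-pixel-wide junction band approximately 0.5 um wide.
#' @param frameIntervalMin minutes between consecutive frames.
#' @param midlineXUm optional x position (um) of the tissue midline;
#'   required only for streak-domain event statistics.
#' @param streakHalfwidthUm half-width (um) of the streak domain.
#' @return A \linkS4class{Calibration} object.
#' @examples
#' Calibration(pixelSizeUm = 0.17, frameIntervalMin = 5)
#' @export
Calibration <- function(pixelSizeUm = 0.17, frameIntervalMin = 5,
                        midlineXUm = NA_real_, streakHalfwidthUm = 20) {
    new("Calibration", pixelSizeUm = as.numeric(pixelSizeUm),
        frameIntervalMin = as.numeric(frameIntervalMin),
        midlineXUm = as.numeric(midlineXUm),
        streakHalfwidthUm = as.numeric(streakHalfwidthUm))
}

#' Tracked segmented frame series
#'
#' The canonical pipeline input: an ordered list of frames, each holding an
#' integer label image (label 0 = exterior/background; a given positive
#' label identifies the same tracked cell wherever it appears) and zero or
#' more co-registered fluorescence channel images, plus a
#' \linkS4class{Calibration}.
#'
#' @slot frames a list; each element is a list with components
#'   \code{frameIndex} (non-negative integer, strictly increasing across
#'   frames), \code{labels} (integer matrix) and \code{channels} (named
#'   list of numeric matrices of the same dimension as \code{labels}).
#' @slot calibration a \linkS4class{Calibration}.
#' @slot metadata free-form list (the synthetic generator stores its
#'   polygon mesh and ground truth here).
#' @aliases SegmentedFrameSeries-class
#' @exportClass SegmentedFrameSeries
setClass("SegmentedFrameSeries",
    representation(
        frames = "list",
        calibration = "Calibration",
        metadata = "list"
    ),
    prototype(frames = list(), metadata = list())
)

setValidity("SegmentedFrameSeries", function(object) {
    msg <- NULL
    fr <- object@frames
    if (length(fr)) {
        idx <- vapply(fr, function(f) as.numeric(f$frameIndex), numeric(1))
        if (anyNA(idx) || any(idx < 0) || any(idx != round(idx)))
            msg <- c(msg, "frame indices must be non-negative integers")
        if (length(idx) > 1L && any(diff(idx) <= 0))
            msg <- c(msg, "frame indices must be strictly increasing")
        for (i in seq_along(fr)) {
            lab <- fr[[i]]$labels
            if (!is.matrix(lab) || !(is.integer(lab) ||
                (is.numeric(lab) && all(lab == round(lab))))) {
                msg <- c(msg, sprintf("frame %d: labels must be an integer matrix", i))
                next
            }
            if (any(lab < 0))
                msg <- c(msg, sprintf("frame %d: negative labels", i))
            ch <- fr[[i]]$channels
            if (length(ch)) {
                if (is.null(names(ch)) || any(!nzchar(names(ch))))
                    msg <- c(msg, sprintf("frame %d: channels must be named", i))
                ok <- vapply(ch, function(m)
                    is.matrix(m) && identical(dim(m), dim(lab)), logical(1))
                if (!all(ok))
                    msg <- c(msg, sprintf(
                        "frame %d: channel grids must share the label grid shape", i))
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a SegmentedFrameSeries
#'
#' @param labels a list of integer label matrices (one per frame), or a
#'   single matrix for a one-frame series.
#' @param calibration a \linkS4class{Calibration}.
#' @param channels \code{NULL}, or a list (one element per frame) of named
#'   lists of numeric matrices; for a one-frame series a single named list
#'   of matrices is accepted.
#' @param frameIndices integer frame indices (default \code{0:(n-1)}).
#' @param metadata free-form list.
#' @return A validated \linkS4class{SegmentedFrameSeries}.
#' @examples
#' lab <- matrix(1L, 8, 8); lab[, 5:8] <- 2L
#' s <- SegmentedFrameSeries(lab, Calibration())
#' nFrames(s)
#' @export
SegmentedFrameSeries <- function(labels, calibration = Calibration(),
                                 channels = NULL, frameIndices = NULL,
                                 metadata = list()) {
    if (is.matrix(labels)) labels <- list(labels)
    n <- length(labels)
    if (!is.null(channels) && n == 1L && !is.null(names(channels)) &&
        all(vapply(channels, is.matrix, logical(1))))
        channels <- list(channels)
    if (is.null(channels)) channels <- rep(list(list()), n)
    if (is.null(frameIndices)) frameIndices <- seq_len(n) - 1L
    stopifnot(length(channels) == n, length(frameIndices) == n)
    frames <- lapply(seq_len(n), function(i) {
        lab <- labels[[i]]
        storage.mode(lab) <- "integer"
        list(frameIndex = as.integer(frameIndices[i]), labels = lab,
             channels = channels[[i]])
    })
    new("SegmentedFrameSeries", frames = frames, calibration = calibration,
        metadata = metadata)
}
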