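#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("labelImage", function(x, i = 1L) standardGeneric("labelImage"))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("channelImage",
    function(x, name, i = 1L) standardGeneric("channelImage"))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname Calibration-accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname Calibration-accessors
#' @export
setGeneric("frameIntervalMin",
    function(x) standardGeneric("frameIntervalMin"))

#' @rdname SegmentedFrameSeries-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
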