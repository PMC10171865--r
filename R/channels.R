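#' Channel model for painted junctional fluorescence
#'
#' Describes synthetic junctional channels with the statistical structure
#' of fixed-tissue co-stainings: a shared per-junction intensity scale, a
#' latent two-group split that loads "actomyosin-like" (group \code{"M"})
#' and "Crumbs-complex-like" (group \code{"C"}) channels reciprocally on
#' high-intensity junctions (anti-correlated between groups, positively
#' correlated within a group), an optional planar-polarity modulation, and
#' per-channel blur and noise.
#'
#' @param channels named list; each element a list with fields
#'   \code{group} (\code{"M"}, \code{"C"} or \code{"uniform"}),
#'   \code{junctional} (baseline junctional load), \code{medial}
#'   (cytoplasmic baseline), and optionally \code{polarityAxisDeg} /
#'   \code{polarityAmp} (amplitude 0 = no polarity).
#' @param highQuantile junctions above this quantile of the shared scale
#'   form the high-intensity tier where the reciprocal split acts
#'   (default top tertile).
#' @param splitSharpness logistic sharpness of the M-vs-C split.
#' @param highGain,lowGain load gain for high-tier / low-tier junctions.
#' @param scaleLnSd log-SD of the shared per-junction scale.
#' @param channelJitterSd log-SD of per-channel multiplicative jitter
#'   (keeps within-group correlation below 1).
#' @param blurSigmaPx Gaussian blur sigma in pixels (0 = none).
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param noiseGain photons per intensity unit for Poisson noise.
#' @param seed RNG seed.
#' @return list of class \code{ChannelModel}.
#' @export
channelModel <- function(channels, highQuantile = 2 / 3,
                         splitSharpness = 2, highGain = 6, lowGain = 1,
                         scaleLnSd = 0.5, channelJitterSd = 0.3,
                         blurSigmaPx = 0, noise = c("none", "poisson"),
                         noiseGain = 50, seed = 1) {
    noise <- match.arg(noise)
    if (is.null(names(channels)) || any(!nzchar(names(channels))))
        stop("parameter error: channels must be a named list")
    for (nm in names(channels)) {
        ch <- channels[[nm]]
        if (!is.list(ch) || is.null(ch$group) ||
            !ch$group %in% c("M", "C", "uniform"))
            stop("parameter error: unknown or missing group for channel '",
                 nm, "'")
        if (is.null(ch$junctional) || ch$junctional < 0)
            stop("parameter error: channel '", nm,
                 "' needs a non-negative junctional baseline")
        channels[[nm]]$medial <- ch$medial %||% 0
        channels[[nm]]$polarityAxisDeg <- ch$polarityAxisDeg %||% NA_real_
        channels[[nm]]$polarityAmp <- ch$polarityAmp %||% 0
        if (channels[[nm]]$polarityAmp > 0 &&
            is.na(channels[[nm]]$polarityAxisDeg))
            stop("parameter error: channel '", nm,
                 "' has polarity amplitude but no axis")
    }
    structure(list(channels = channels, highQuantile = highQuantile,
                   splitSharpness = splitSharpness, highGain = highGain,
                   lowGain = lowGain, scaleLnSd = scaleLnSd,
                   channelJitterSd = channelJitterSd,
                   blurSigmaPx = blurSigmaPx, noise = noise,
                   noiseGain = noiseGain, seed = seed),
              class = "ChannelModel")
}

#' Paint fluorescence channels onto a segmented series
#'
#' Junction bands (3 px wide) are painted with per-junction loads drawn
#' from the model's latent structure, medial cell interiors with the
#' medial baseline, tricellular-vertex pixels with the mean incident
#' load; the image is then blurred and noised per the model. Per-junction
#' painted means are recorded as ground truth
#' (\code{metadata$groundTruth$channelLoads}).
#'
#' @param series a \linkS4class{SegmentedFrameSeries}.
#' @param model a \code{\link{channelModel}}.
#' @param widthPx painted band width (default 3).
#' @return The series with channels added and ground truth recorded.
#' @export
paintChannels <- function(series, model, widthPx = 3L) {
    stopifnot(is(series, "SegmentedFrameSeries"),
              inherits(model, "ChannelModel"))
    set.seed(model$seed)
    ## latent structure keyed by junction id, shared across frames
    keys <- character(0)
    perFrame <- vector("list", nFrames(series))
    for (k in seq_len(nFrames(series))) {
        j <- extractJunctions(series, k, minPixels = 1L)
        perFrame[[k]] <- j
        keys <- union(keys, j$junction_id)
    }
    nj <- length(keys)
    sJ <- stats::setNames(stats::rlnorm(nj, 0, model$scaleLnSd), keys)
    zJ <- stats::setNames(stats::rnorm(nj), keys)
    split <- stats::plogis(model$splitSharpness * zJ)
    high <- sJ >= stats::quantile(sJ, model$highQuantile, names = FALSE)
    jitter <- lapply(names(model$channels), function(nm)
        stats::setNames(stats::rlnorm(nj, 0, model$channelJitterSd), keys))
    names(jitter) <- names(model$channels)

    loadOf <- function(nm, key, orientation) {
        ch <- model$channels[[nm]]
        base <- if (ch$group == "uniform") {
            rep(ch$junctional, length(key))
        } else {
            frac <- if (ch$group == "M") split[key] else 1 - split[key]
            ifelse(high[key],
                   ch$junctional * model$highGain * sJ[key] * frac,
                   ch$junctional * model$lowGain * sJ[key]) * jitter[[nm]][key]
        }
        if (ch$polarityAmp > 0) {
            f <- 1 + ch$polarityAmp *
                cos(2 * (orientation - ch$polarityAxisDeg) * pi / 180)
            base <- base * pmax(0, f)
        }
        base
    }

    gtLoads <- list()
    for (k in seq_len(nFrames(series))) {
        lab <- labelImage(series, k)
        nr <- nrow(lab); nc <- ncol(lab)
        info <- .neighborInfo(lab)
        juncs <- perFrame[[k]]
        skel <- attr(juncs, "skeleton")
        bands <- .junctionBands(lab, skel, widthPx, info)
        for (nm in names(model$channels)) {
            ch <- model$channels[[nm]]
            img <- matrix(0, nr, nc)
            img[lab > 0L] <- ch$medial
            loads <- loadOf(nm, juncs$junction_id, juncs$orientation_deg)
            for (i in seq_len(nrow(juncs)))
                img[bands[[juncs$junction_id[i]]]] <- loads[i]
            vtx <- which(info$vertex & lab > 0L)
            if (length(vtx))
                img[vtx] <- if (ch$group == "uniform") ch$junctional
                            else mean(loads)
            if (model$blurSigmaPx > 0)
                img <- as.matrix(EBImage::gblur(img,
                                                sigma = model$blurSigmaPx))
            if (model$noise == "poisson")
                img <- matrix(stats::rpois(length(img),
                    pmax(0, img) * model$noiseGain) / model$noiseGain,
                    nr, nc)
            series@frames[[k]]$channels[[nm]] <- img
            gtLoads[[length(gtLoads) + 1L]] <- data.frame(
                frame = frameIndices(series)[k], channel = nm,
                junction_id = juncs$junction_id, painted_mean = loads)
        }
    }
    gt <- series@metadata$groundTruth %||% list()
    gt$channelLoads <- do.call(rbind, gtLoads)
    gt$channelModel <- model
    series@metadata$groundTruth <- gt
    validObject(series)
    series
}
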