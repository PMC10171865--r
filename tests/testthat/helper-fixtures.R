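## Fixtures are built in code; expensive simulations are cached per test
## run so several test files can share them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
    .cache[[key]]
}

## a rasterized disc of radius r px inside an n x n frame
discSeries <- function(r = 30, n = 80, px = 0.2) {
    m <- matrix(0L, n, n)
    ctr <- (n + 1) / 2
    for (rr in seq_len(n)) for (cc in seq_len(n))
        if ((rr - ctr)^2 + (cc - ctr)^2 <= r^2) m[rr, cc] <- 1L
    SegmentedFrameSeries(m, Calibration(pixelSizeUm = px))
}

## two half-plane cells split by a vertical 50-px boundary
halfPlaneSeries <- function(px = 0.2) {
    m <- matrix(1L, 50, 60)
    m[, 31:60] <- 2L
    SegmentedFrameSeries(m, Calibration(pixelSizeUm = px))
}

## brute-force second-moment oracle: elongation index and angle from the
## raw pixel list, independent of extractCells
momentOracle <- function(lab, px) {
    idx <- which(lab > 0L)
    x <- ((idx - 1L) %/% nrow(lab)) * px
    y <- ((idx - 1L) %% nrow(lab)) * px
    mu20 <- mean(x^2) - mean(x)^2
    mu02 <- mean(y^2) - mean(y)^2
    mu11 <- mean(x * y) - mean(x) * mean(y)
    ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2))$values
    a <- sqrt(ev[1]); b <- sqrt(ev[2])
    (a - b) / (a + b)
}

## exhaustive-permutation oracle for the two-sided Mann-Whitney p value
mwEnumOracle <- function(a, b) {
    n <- length(a); m <- length(b)
    pool <- c(a, b)
    U <- function(ia) {
        ra <- rank(pool)[ia]
        sum(ra) - n * (n + 1) / 2
    }
    obs <- U(seq_len(n))
    mu <- n * m / 2
    splits <- utils::combn(n + m, n)
    us <- apply(splits, 2, U)
    mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

## small shared dynamic simulation (40 cells, default study conditions)
sharedSim <- function() cached("sharedSim", {
    tis <- generateTissue(40, seed = 3)
    simulateDynamics(tis, dynamicsParams(seed = 3))
})

sharedTracks <- function() cached("sharedTracks", {
    buildTracks(sharedSim())
})

## per-frame cell measurements only (no junction extraction) for speed
cellAreaTracks <- function(sim) {
    fi <- frameIndices(sim)
    do.call(rbind, lapply(seq_len(nFrames(sim)), function(k) {
        df <- extractCells(sim, k)
        df$frame <- fi[k]
        df
    }))
}

## batch of simulated runs totalling ~200 ingressing cells, measured and
## annotated with the full kinetics path (0.3 um/px keeps rasterization
## cheap at identical biology)
pulseRecoveryRuns <- function() cached("pulseRecoveryRuns", {
    cal <- Calibration(pixelSizeUm = 0.3, frameIntervalMin = 5)
    ## reference pool: an undisturbed oscillation-only recording stands in
    ## for epiblast away from the streak
    thr <- referenceThreshold(referencePool(), k = 1)
    lapply(101:110, function(seed) {
        tis <- generateTissue(80, calibration = cal, seed = seed)
        sim <- simulateDynamics(tis, dynamicsParams(seed = seed))
        cells <- cellAreaTracks(sim)
        gt <- groundTruth(sim)
        lastFrame <- max(cells$frame)
        ## pulse detection within the true constriction window: this
        ## isolates the pulse detector from period detection
        anns <- lapply(seq_len(nrow(gt$cells)), function(i) {
            id <- gt$cells$cell_id[i]
            sub <- cells[cells$cell_id == id, ]
            sub <- sub[order(sub$frame), ]
            r <- rateSeries(sub$area_um2, 5)
            rf <- sub$frame[-1L]
            w <- rf > gt$cells$constriction_start_frame[i] &
                 rf <= gt$cells$ingression_frame[i]
            p <- detectPulses(r[w], thr)
            list(n_pulses = nrow(p), magnitudes = p$magnitude,
                 frac_contracting = phaseTimeFractions(r[w])$frac_contracting)
        })
        names(anns) <- gt$cells$cell_id
        list(gt = gt, annotations = anns, threshold = thr, cells = cells)
    })
})

## pooled contraction rates of interior cells of the oscillation run
referencePool <- function() {
    cells <- oscillationRun()
    borderIds <- unique(cells$cell_id[cells$border_touching %in% TRUE])
    unlist(lapply(setdiff(unique(cells$cell_id), borderIds),
                  function(id) {
        r <- rateSeries(cells$area_um2[cells$cell_id == id], 5)
        r[r > 0]
    }))
}

## pure-oscillation run for the balanced-fluctuation criteria
oscillationRun <- function() cached("oscillationRun", {
    cal <- Calibration(pixelSizeUm = 0.3, frameIntervalMin = 5)
    tis <- generateTissue(100, calibration = cal, seed = 77)
    sim <- simulateDynamics(tis, dynamicsParams(fracIngressing = 0,
                                                seed = 77))
    cellAreaTracks(sim)
})

## shared painted fixed-tissue frame with the two-group channel structure
sharedPainted <- function() cached("sharedPainted", {
    tis <- generateTissue(40, seed = 7)
    mod <- channelModel(list(
        myoA = list(group = "M", junctional = 4, medial = 1),
        myoB = list(group = "M", junctional = 3, medial = 1),
        crbA = list(group = "C", junctional = 4, medial = 1),
        gfp = list(group = "uniform", junctional = 7, medial = 1)),
        seed = 7)
    p <- paintChannels(tis, mod)
    jt <- extractJunctions(p)
    for (nm in names(mod$channels))
        jt[[paste0("int_", nm)]] <- measureJunctionIntensity(p, nm, jt)
    list(series = p, junctions = jt)
})
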