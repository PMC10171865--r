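test_that("rate series implement the signed backward difference", {
    expect_equal(rateSeries(c(50, 48, 45, 45), 5), c(0.4, 0.6, 0))
    expect_equal(rateSeries(rep(30, 6), 5), rep(0, 5))
    expect_true(all(rateSeries(cumsum(runif(10, 0.1, 1)), 5) < 0))
    expect_error(rateSeries(42, 5), "insufficient")
})

test_that("telescoping identity holds exactly on synthetic tracks", {
    set.seed(31)
    for (rep in 1:20) {
        v <- cumsum(rnorm(sample(5:60, 1)))
        dt <- sample(c(1, 2, 5), 1)
        r <- rateSeries(v, dt)
        expect_equal(sum(r) * dt, v[1] - v[length(v)], tolerance = 1e-12)
    }
})

test_that("reference threshold is the mean plus k sample SDs", {
    x <- c(-0.1, 0.3, 0.7)              # mean 0.3, sample SD 0.4
    thr <- referenceThreshold(rep(x, 4), k = 1)
    expect_equal(thr$mean, 0.3)
    expect_equal(thr$threshold, thr$mean + thr$sd)
    expect_equal(referenceThreshold(rep(x, 4), k = 0)$threshold, 0.3)
    expect_error(referenceThreshold(numeric(0)), "empty")
    expect_error(referenceThreshold(rnorm(5)), "at least 10")
})

test_that("pulse detection finds maximal supra-threshold runs", {
    p <- detectPulses(c(0.2, 0.9, 1.2, 0.3, 0.8, 0.1), 0.7)
    expect_equal(nrow(p), 2L)
    expect_equal(p$start, c(2L, 5L))
    expect_equal(p$end, c(3L, 5L))
    expect_equal(p$magnitude, c(1.2, 0.8))
    expect_equal(nrow(detectPulses(c(0.1, 0.2, 0.3), 0.7)), 0L)
    ## merge_gap joins runs across short sub-threshold gaps
    r <- c(1, 1, 0.1, 1, 0.1, 0.1, 1)
    expect_equal(nrow(detectPulses(r, 0.7, mergeGap = 0L)), 3L)
    m <- detectPulses(r, 0.7, mergeGap = 1L)
    expect_equal(nrow(m), 2L)
    expect_equal(m$start[1], 1L)
    expect_equal(m$end[1], 4L)
})

test_that("raising the threshold multiplier shrinks the pulse frames", {
    ## the set of supra-threshold frames (total pulse time) is monotone
    ## in k; pulse COUNT is not (a run can split), so the invariant is on
    ## the frame set
    set.seed(32)
    for (rep in 1:15) {
        r <- abs(rnorm(40, 0.4, 0.5))
        ref <- rnorm(50, 0.3, 0.4)
        prev <- NULL
        for (k in c(0, 0.5, 1, 1.5, 2, 10)) {
            p <- detectPulses(r, referenceThreshold(ref, k))
            frames <- unlist(lapply(seq_len(nrow(p)), function(i)
                p$start[i]:p$end[i]))
            if (!is.null(prev)) expect_true(all(frames %in% prev))
            prev <- frames
        }
        expect_equal(length(prev), 0L)   # extreme threshold: no pulses
    }
})

test_that("constriction period detection finds the decline onset", {
    ## strictly decreasing to disappearance -> start at the first frame
    tr <- data.frame(frame = 0:9, area_um2 = seq(50, 5, length.out = 10))
    per <- detectConstrictionPeriod(tr, lastSeriesFrame = 20)
    expect_equal(per$start_frame, 0L)
    expect_equal(per$ingression_frame, 9L)
    expect_false(per$censored)

    ## flat then linear decline from frame 10 -> start 10 +/- half-window
    tr2 <- data.frame(frame = 0:25,
                      area_um2 = c(rep(48, 11), seq(45, 3, length.out = 15)))
    per2 <- detectConstrictionPeriod(tr2, lastSeriesFrame = 40)
    expect_lte(abs(per2$start_frame - 10L), 1L)

    ## oscillation then decline: start near the last oscillation peak
    tr3 <- data.frame(frame = 0:18,
                      area_um2 = c(45, 43, 46, 42, 47, 41, 48,
                                   seq(46, 2, length.out = 12)))
    per3 <- detectConstrictionPeriod(tr3, lastSeriesFrame = 40)
    expect_gte(per3$start_frame, 5L)
    expect_lte(per3$start_frame, 8L)

    ## ends at the movie end -> censored
    per4 <- detectConstrictionPeriod(tr, lastSeriesFrame = 9)
    expect_true(per4$censored)
    ## ends while touching the border -> censored
    tr5 <- tr; tr5$border_touching <- c(rep(FALSE, 9), TRUE)
    expect_true(detectConstrictionPeriod(tr5, 20)$censored)
})

test_that("phase time fractions split contracting/expanding/stable", {
    f <- phaseTimeFractions(c(1, -1, 1, -1))
    expect_equal(f$frac_contracting, 0.5)
    expect_equal(f$frac_expanding, 0.5)
    expect_equal(f$frac_stable, 0)
    expect_equal(f$mean_contraction_rate, 1)
    expect_equal(f$mean_expansion_rate, 1)
    f2 <- phaseTimeFractions(c(0.4, 0.6, 0))
    expect_equal(unlist(f2[1:3]), c(frac_contracting = 2 / 3,
                                    frac_expanding = 0,
                                    frac_stable = 1 / 3))
    expect_error(phaseTimeFractions(numeric(0)), "empty")
})

test_that("constriction annotation partitions the period into phases", {
    tracks <- sharedTracks()
    gt <- groundTruth(sharedSim())
    lastFrame <- max(tracks$cells$frame)
    ann <- annotateConstriction(
        tracks$cells[tracks$cells$cell_id == gt$cells$cell_id[1], ],
        0.7, lastFrame, 5)
    expect_false(ann$censored)
    ## pulse frames and stable frames partition the period
    expect_setequal(ann$phases$frame,
                    (ann$start_frame + 1):ann$ingression_frame)
    expect_false(any(is.na(ann$phases$phase)))
    pulseFrames <- unlist(lapply(seq_len(nrow(ann$pulses)), function(i)
        ann$pulses$start_frame[i]:ann$pulses$end_frame[i]))
    expect_setequal(ann$phases$frame[grepl("^pulse", ann$phases$phase)],
                    pulseFrames)
    expect_equal(ann$frac_contracting + ann$frac_expanding +
                 ann$frac_stable, 1)
})

test_that("junction shrinkage is attributed to the right phases", {
    ## one junction shrinking 0.5 um/frame only during pulse 1
    ann <- structure(list(
        start_frame = 0L, ingression_frame = 8L, censored = FALSE,
        unclassifiable = FALSE,
        pulses = data.frame(start_frame = c(1L, 5L), end_frame = c(2L, 6L),
                            duration_frames = c(2L, 2L),
                            magnitude = c(1, 1)),
        phases = data.frame(frame = 1:8, rate = 0,
                            phase = c("pulse_1", "pulse_1", "stable_1",
                                      "stable_1", "pulse_2", "pulse_2",
                                      "stable_2", "stable_2"))),
        class = "ConstrictionAnnotation")
    len <- c(10, 9.5, 9, 9, 9, 9, 9, 9, 9)
    jt <- data.frame(junction_id = "1|2", frame = 0:8, length_um = len)
    sh <- junctionShrinkageByPhase(jt, ann, 5)
    expect_equal(sh$mean_shrinkage_rate_um_min[sh$phase == "pulse_1"], 0.1)
    expect_equal(sh$mean_shrinkage_rate_um_min[sh$phase == "pulse_2"], 0)
    ## junction created mid-period: missing before creation
    jt2 <- data.frame(junction_id = "1|3", frame = 4:8,
                      length_um = c(5, 4, 4, 4, 4))
    sh2 <- junctionShrinkageByPhase(jt2, ann, 5)
    expect_true(is.na(
        sh2$mean_shrinkage_rate_um_min[sh2$phase == "pulse_1"]))
    expect_equal(sh2$mean_shrinkage_rate_um_min[sh2$phase == "pulse_2"],
                 0.1)
})

test_that("scheduled junctions shrink fastest in their phase", {
    ## low-amplitude oscillation isolates the junction shrink schedule
    ## from the area fluctuations that ride on every junction length
    tis <- generateTissue(35, seed = 19)
    sim <- simulateDynamics(tis, dynamicsParams(oscAmpUm = 0.05,
                                                seed = 19))
    gt <- groundTruth(sim)
    hits <- 0L; total <- 0L
    for (i in seq_len(nrow(gt$cells))) {
        cid <- gt$cells$cell_id[i]
        s <- gt$cells$constriction_start_frame[i]
        sched <- gt$phaseJunctions[gt$phaseJunctions$cell_id == cid, ]
        for (ph in unique(sched$phase)) {
            if (!grepl("^pulse", ph)) next
            phRow <- gt$pulses[gt$pulses$cell_id == cid &
                gt$pulses$pulse == as.integer(sub("pulse_", "", ph)), ]
            frames <- phRow$start_frame:phRow$end_frame
            lens <- gt$junctionLengths[, grepl("\\|", colnames(gt$junctionLengths)) &
                (startsWith(colnames(gt$junctionLengths), paste0(cid, "|")) |
                 endsWith(colnames(gt$junctionLengths), paste0("|", cid))),
                drop = FALSE]
            shr <- apply(lens, 2, function(L)
                mean((L[frames] - L[frames + 1]) / 5))
            shr <- shr[!is.na(shr)]
            schedJ <- intersect(sched$junction_id[sched$phase == ph],
                                names(shr))
            if (!length(schedJ) || length(shr) < 3) next
            total <- total + 1L
            ## the fastest-shrinking junction of the phase is a scheduled one
            if (names(which.max(shr)) %in% schedJ) hits <- hits + 1L
        }
    }
    expect_gt(total, 10L)
    expect_gt(hits / total, 0.8)
})

test_that("junction length correlation matches the textbook formula", {
    jt <- data.frame(
        junction_id = rep(c("a", "b"), each = 5),
        frame = rep(0:4, 2),
        length_um = c(5, 4, 3, 2, 1, 1, 2, 3, 4, 5))
    M <- junctionLengthCorrelation(jt)
    expect_equal(M["a", "b"], -1)
    jt$length_um[6:10] <- jt$length_um[1:5]
    expect_equal(junctionLengthCorrelation(jt)["a", "b"], 1)
    ## random series vs direct computation
    set.seed(33)
    jids <- letters[1:4]
    jt3 <- do.call(rbind, lapply(jids, function(j)
        data.frame(junction_id = j, frame = 0:9,
                   length_um = runif(10, 1, 6))))
    M3 <- junctionLengthCorrelation(jt3)
    for (i in 1:3) for (k in (i + 1):4) {
        xi <- jt3$length_um[jt3$junction_id == jids[i]]
        xk <- jt3$length_um[jt3$junction_id == jids[k]]
        direct <- sum((xi - mean(xi)) * (xk - mean(xk))) /
            sqrt(sum((xi - mean(xi))^2) * sum((xk - mean(xk))^2))
        expect_equal(M3[jids[i], jids[k]], direct, tolerance = 1e-12)
    }
    ## zero variance -> NA with warning
    jt4 <- data.frame(junction_id = rep(c("a", "b"), each = 4),
                      frame = rep(0:3, 2),
                      length_um = c(2, 2, 2, 2, 1, 2, 3, 4))
    expect_warning(M4 <- junctionLengthCorrelation(jt4), "zero-variance")
    expect_true(is.na(M4["a", "b"]))
})
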