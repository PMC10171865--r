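test_that("cell geometry matches analytic shapes", {
    s <- discSeries(r = 30, n = 80, px = 0.2)
    cg <- extractCells(s)
    expect_lt(cg$elongation_index, 0.02)
    expect_lt(abs(cg$area_um2 - pi * 6^2) / (pi * 6^2), 0.02)

    ## 40 x 10 px axis-aligned rectangle against the brute-force moment
    ## oracle; angle along +x
    m <- matrix(0L, 60, 60); m[25:34, 11:50] <- 1L
    s2 <- SegmentedFrameSeries(m, Calibration(pixelSizeUm = 0.2))
    cg2 <- extractCells(s2)
    expect_equal(cg2$elongation_index, momentOracle(m, 0.2),
                 tolerance = 1e-12)
    expect_lt(min(cg2$elongation_angle_deg, 180 - cg2$elongation_angle_deg),
              1)

    msq <- matrix(0L, 40, 40); msq[11:30, 11:30] <- 1L
    cg3 <- extractCells(SegmentedFrameSeries(msq, Calibration()))
    expect_lt(cg3$elongation_index, 1e-9)
})

test_that("junctions of simple partitions have exact geometry", {
    s <- halfPlaneSeries(px = 0.2)
    j <- extractJunctions(s)
    expect_equal(nrow(j), 1L)
    expect_equal(j$orientation_deg, 90)
    expect_equal(j$length_um, 50 * 0.2, tolerance = 0.01)
    expect_identical(c(j$cell_a, j$cell_b), c(1L, 2L))

    hc <- generateHoneycomb(4, 4, edgeUm = 4)
    ce <- extractCells(hc)
    inner <- ce[!ce$border_touching, ]
    expect_true(all(inner$junction_count == 6L))
})

test_that("junction counts obey the handshake identity", {
    tis <- generateTissue(35, seed = 13)
    ce <- extractCells(tis)
    jt <- extractJunctions(tis)
    nInterior <- sum(!jt$is_exterior)
    nExterior <- sum(jt$is_exterior)
    expect_equal(sum(ce$junction_count), 2L * nInterior + nExterior)
})

test_that("junction band means match a pixel-enumeration oracle", {
    px <- 0.2
    lab <- matrix(1L, 50, 60); lab[, 31:60] <- 2L
    ch <- matrix(0, 50, 60); ch[, 30:31] <- 10
    s <- SegmentedFrameSeries(lab, Calibration(pixelSizeUm = px),
                              channels = list(a = ch))
    j <- extractJunctions(s)
    got <- measureJunctionIntensity(s, "a", j, widthPx = 3L)
    ## oracle: band = skeleton (cols 30, 31, all rows) dilated by 1,
    ## clipped to the two cells -> cols 29:32; boundary pixels carry 10
    bandVals <- ch[, 29:32]
    expect_equal(got, mean(bandVals))
    ## width 1 vs width 3 identical on a constant band
    ch2 <- matrix(0, 50, 60); ch2[, 29:32] <- 6
    s2 <- SegmentedFrameSeries(lab, Calibration(pixelSizeUm = px),
                               channels = list(a = ch2))
    j2 <- extractJunctions(s2)
    expect_equal(measureJunctionIntensity(s2, "a", j2, widthPx = 1L),
                 measureJunctionIntensity(s2, "a", j2, widthPx = 3L))
})

test_that("painted junction means are recovered within 1 percent", {
    sp <- sharedPainted()
    jt <- sp$junctions
    gt <- groundTruth(sp$series)$channelLoads
    g <- gt[gt$channel == "myoA", ]
    m <- merge(jt[jt$pixel_count >= 5, ], g, by = "junction_id")
    expect_gt(nrow(m), 20)
    relerr <- abs(m$int_myoA - m$painted_mean) / pmax(m$painted_mean, 1e-9)
    expect_lt(max(relerr), 0.01)
})

test_that("medial intensity uses eroded interiors with a sliver fallback", {
    lab <- matrix(1L, 40, 40)
    lab[, 21:40] <- 2L
    ch <- matrix(5, 40, 40)
    s <- SegmentedFrameSeries(lab, Calibration(), channels = list(a = ch))
    med <- measureMedialIntensity(s, "a")
    expect_equal(med$medial_mean, c(5, 5))
    expect_false(any(med$fallback))
    ## painted fixture: junctional 10, medial 2
    tis <- generateTissue(20, seed = 14)
    mod <- channelModel(list(a = list(group = "uniform", junctional = 10,
                                      medial = 2)), seed = 14)
    p <- paintChannels(tis, mod)
    med2 <- measureMedialIntensity(p, "a")
    expect_true(all(abs(med2$medial_mean - 2) < 1e-9))
    ## 3-px-wide sliver: erosion empties it, fallback flagged
    sl <- matrix(1L, 30, 30)
    sl[, 14:16] <- 2L
    ssl <- SegmentedFrameSeries(sl, Calibration(),
                                channels = list(a = matrix(3, 30, 30)))
    medsl <- measureMedialIntensity(ssl, "a")
    expect_true(medsl$fallback[medsl$cell_id == 2L])
})

test_that("orientations rotate with the fixture", {
    tis <- generateTissue(25, seed = 15)
    j1 <- extractJunctions(tis)
    rot <- SegmentedFrameSeries(t(labelImage(tis))[ncol(labelImage(tis)):1, ],
                                calibration(tis))
    j2 <- extractJunctions(rot)
    m <- merge(j1, j2, by = "junction_id")
    m <- m[m$pixel_count.x >= 8, ]
    expect_gt(nrow(m), 10)
    d <- abs((m$orientation_deg.x + 90) %% 180 - m$orientation_deg.y)
    d <- pmin(d, 180 - d)
    expect_lt(max(d), 2)
})

test_that("area is conserved across every simulated frame", {
    sim <- sharedSim()
    for (f in c(1L, nFrames(sim) %/% 2L, nFrames(sim))) {
        lab <- labelImage(sim, f)
        ce <- extractCells(sim, f)
        expect_equal(sum(ce$area_um2) / pixelSizeUm(sim)^2 +
                     sum(lab == 0L), length(lab))
    }
})

test_that("tracks are contiguous, bridged or split as specified", {
    lab <- matrix(1L, 20, 20); lab[, 11:20] <- 2L
    s <- SegmentedFrameSeries(list(lab, lab), Calibration())
    tr <- buildTracks(s)
    expect_equal(nrow(tr$cells), 4L)
    expect_equal(unique(table(tr$cells$cell_id)), 2L)
    expect_identical(tr$cells$area_um2[1], tr$cells$area_um2[2])

    ## one-frame dropout -> bridged flag, single track
    lab2 <- lab; lab2[lab2 == 2L] <- 1L
    s2 <- SegmentedFrameSeries(list(lab, lab2, lab), Calibration())
    tr2 <- buildTracks(s2)
    c2 <- tr2$cells[tr2$cells$cell_id == 2L, ]
    expect_equal(nrow(c2), 3L)
    expect_identical(unique(c2$track_id), "2")
    expect_true(c2$bridged[c2$frame == 1L])
    expect_true(is.na(c2$area_um2[c2$frame == 1L]))

    ## two-frame gap -> split with warning
    s3 <- SegmentedFrameSeries(list(lab, lab2, lab2, lab), Calibration())
    expect_warning(tr3 <- buildTracks(s3), "non-contiguous")
    c3 <- tr3$cells[tr3$cells$cell_id == 2L, ]
    expect_setequal(unique(c3$track_id), c("2", "2.2"))
})

test_that("ingression truncates cell and junction tracks together", {
    tracks <- sharedTracks()
    gt <- groundTruth(sharedSim())
    for (i in seq_len(nrow(gt$cells))) {
        cid <- gt$cells$cell_id[i]
        endC <- max(tracks$cells$frame[tracks$cells$cell_id == cid])
        expect_equal(endC, gt$cells$ingression_frame[i])
        jsub <- tracks$junctions[tracks$junctions$cell_a == cid |
                                 tracks$junctions$cell_b == cid, ]
        expect_lte(max(jsub$frame), gt$cells$ingression_frame[i])
    }
})
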