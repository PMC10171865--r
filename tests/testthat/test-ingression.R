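## minimal hand-built tracks: two adjacent cells ingressing at set times
.twoCellFixture <- function(tA = 10, tB = 20, dt = 5, lastFrame = 20) {
    fA <- tA / dt; fB <- tB / dt
    cells <- rbind(
        data.frame(cell_id = 1L, frame = 0:fA, centroid_x_um = 5,
                   centroid_y_um = 5, border_touching = FALSE),
        data.frame(cell_id = 2L, frame = 0:fB, centroid_x_um = 8,
                   centroid_y_um = 5, border_touching = FALSE),
        data.frame(cell_id = 3L, frame = 0:lastFrame, centroid_x_um = 30,
                   centroid_y_um = 5, border_touching = FALSE))
    juncs <- data.frame(cell_a = 1L, cell_b = 2L, frame = 0:fA,
                        length_um = 3)
    list(cells = cells, junctions = juncs, lastFrame = lastFrame)
}

test_that("ingression events exclude censored tracks", {
    fx <- .twoCellFixture()
    cal <- Calibration(frameIntervalMin = 5)
    ev <- detectIngressions(fx$cells, fx$lastFrame, cal)
    expect_setequal(ev$cell_id, c(1L, 2L))   # cell 3 survives to the end
    expect_equal(ev$time_min[ev$cell_id == 1L], 10)
    ## border-touching disappearance is censored
    cells2 <- fx$cells
    cells2$border_touching[cells2$cell_id == 1L &
                           cells2$frame == 2L] <- TRUE
    ev2 <- detectIngressions(cells2, fx$lastFrame, cal)
    expect_setequal(ev2$cell_id, 2L)
})

test_that("the 30-min clustering rule is strict at the boundary", {
    cal <- Calibration(frameIntervalMin = 5)
    fx <- .twoCellFixture(tA = 10, tB = 20)
    ev <- classifyEventClusters(
        detectIngressions(fx$cells, fx$lastFrame, cal), fx$junctions)
    expect_equal(sort(ev$cluster_size), c(2L, 2L))   # 10 min apart: pair

    fx2 <- .twoCellFixture(tA = 10, tB = 50, lastFrame = 30)
    ev2 <- classifyEventClusters(
        detectIngressions(fx2$cells, fx2$lastFrame, cal), fx2$junctions)
    expect_equal(ev2$cluster_size, c(1L, 1L))        # 40 min apart: isolated

    fx3 <- .twoCellFixture(tA = 10, tB = 40, lastFrame = 30)
    ev3 <- classifyEventClusters(
        detectIngressions(fx3$cells, fx3$lastFrame, cal), fx3$junctions)
    expect_equal(ev3$cluster_size, c(1L, 1L))        # exactly 30: isolated
})

test_that("clustering is order-independent and partitions events", {
    sim <- sharedSim()
    tracks <- sharedTracks()
    cal <- calibration(sim)
    lastFrame <- max(tracks$cells$frame)
    ev <- detectIngressions(tracks$cells, lastFrame, cal)
    cl1 <- classifyEventClusters(ev, tracks$junctions)
    set.seed(1)
    cl2 <- classifyEventClusters(ev[sample(nrow(ev)), ], tracks$junctions)
    m <- merge(cl1, cl2, by = "cell_id")
    expect_identical(m$cluster_size.x, m$cluster_size.y)
    ## partition invariant
    sizes <- cl1$cluster_size[!duplicated(cl1$cluster_id)]
    expect_equal(sum(sizes), nrow(cl1))
})

test_that("a programmed clustering plan is recovered exactly", {
    tis <- generateTissue(60, seed = 21)
    sim <- simulateDynamics(tis, dynamicsParams(
        clusterPlan = c(isolated = 5, pair = 3, triplet = 1), seed = 21))
    tracks <- buildTracks(sim)
    gt <- groundTruth(sim)
    ev <- detectIngressions(tracks$cells, max(tracks$cells$frame),
                            calibration(sim))
    ev <- classifyEventClusters(ev, tracks$junctions)
    expect_setequal(ev$cell_id, gt$cells$cell_id)
    expect_identical(
        ev$cluster_size[match(gt$cells$cell_id, ev$cell_id)],
        gt$cells$cluster_size)
    counts <- table(ev$cluster_size[!duplicated(ev$cluster_id)])
    expect_equal(unname(counts[c("1", "2", "3")]),
                 as.table(c(5L, 3L, 1L)), ignore_attr = TRUE)
})

test_that("ingression rate per hour divides events by cells at window start", {
    cal <- Calibration(frameIntervalMin = 5)
    cells <- do.call(rbind, lapply(1:10, function(i) {
        last <- if (i <= 4) 6L else 12L    # 4 cells ingress within 60 min
        data.frame(cell_id = i, frame = 0:last, centroid_x_um = i,
                   centroid_y_um = 0, border_touching = FALSE)
    }))
    ev <- detectIngressions(cells, 12L, cal)
    expect_equal(nrow(ev), 4L)
    rate <- ingressionRatePerHour(ev, cells, cal, domain = "all")
    expect_equal(rate$per_window$rate_per_hour[1], 0.4)
    ## no events -> 0
    quiet <- do.call(rbind, lapply(1:5, function(i)
        data.frame(cell_id = i, frame = 0:12, centroid_x_um = i,
                   centroid_y_um = 0, border_touching = FALSE)))
    rate0 <- ingressionRatePerHour(
        detectIngressions(quiet, 12L, cal), quiet, cal, domain = "all")
    expect_equal(rate0$mean, 0)
    ## streak domain requires a midline
    expect_error(ingressionRatePerHour(ev, cells, cal, domain = "streak"),
                 "midline")
})

test_that("track displacement obeys the triangle inequality", {
    cal <- Calibration(midlineXUm = 20)
    still <- data.frame(cell_id = 1L, frame = 0:5, centroid_x_um = 3,
                        centroid_y_um = 3)
    d <- trackDisplacement(still, cal)
    expect_equal(d$path_length_um, 0)
    expect_equal(d$convergence_um, 0)
    toward <- data.frame(cell_id = 1L, frame = 0:5,
                         centroid_x_um = seq(0, 10, 2), centroid_y_um = 0)
    d2 <- trackDisplacement(toward, cal)
    expect_equal(d2$convergence_um, 10)
    expect_equal(d2$path_length_um, d2$net_displacement_um)
    set.seed(34)
    for (rep in 1:10) {
        walk <- data.frame(cell_id = 1L, frame = 0:20,
                           centroid_x_um = cumsum(rnorm(21)),
                           centroid_y_um = cumsum(rnorm(21)))
        dw <- trackDisplacement(walk, cal)
        expect_gte(dw$path_length_um, dw$net_displacement_um - 1e-12)
    }
})
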