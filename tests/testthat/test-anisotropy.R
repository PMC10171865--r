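.jtab <- function(int, cellA = 1L, cellB = 2:(length(int) + 1L),
                  len = 1, ori = 0, embryo = "e1") {
    data.frame(cell_a = pmin(cellA, cellB), cell_b = pmax(cellA, cellB),
               int_ch = int, length_um = len, orientation_deg = ori,
               embryo = embryo, is_exterior = FALSE)
}

test_that("normalization modes divide by the documented denominators", {
    jt <- .jtab(c(2, 4, 6))
    out <- normalizeIntensities(jt, "ch", mode = "embryo_mean")
    expect_equal(out$int_ch, c(0.5, 1, 1.5))

    ## medial: junction between two cells with medial 2 and 2 -> 4
    jt2 <- .jtab(8, cellA = 1L, cellB = 2L)
    cells <- data.frame(cell_id = 1:2, medial_ch = c(2, 2))
    out2 <- normalizeIntensities(jt2, "ch", mode = "medial", cells = cells)
    expect_equal(out2$int_ch, 4)
    cells3 <- data.frame(cell_id = 1:2, medial_ch = c(0, 0))
    expect_error(normalizeIntensities(jt2, "ch", mode = "medial",
                                      cells = cells3), "medial normalizer")

    ## cohort: pooled grand mean across embryos
    jtA <- .jtab(c(4, 5, 6), embryo = "e1")      # mean 5
    jtB <- .jtab(c(9, 10, 11), embryo = "e2")    # mean 10
    pooled <- rbind(jtA, jtB)
    out3 <- normalizeIntensities(pooled, "ch", mode = "cohort_mean")
    expect_equal(out3$int_ch, pooled$int_ch / mean(pooled$int_ch))
    expect_equal(mean(pooled$int_ch), 7.5)
})

test_that("per-cell anisotropy gives the sample SD and Max/Min ratio", {
    a1 <- cellAnisotropy(.jtab(c(5, 5, 5, 5)), "ch")
    expect_equal(a1$sd, 0)
    expect_equal(a1$max_min_ratio, 1)
    a2 <- cellAnisotropy(.jtab(c(2, 4, 8)), "ch")
    expect_equal(a2$sd, sd(c(2, 4, 8)))
    expect_equal(round(a2$sd, 3), 3.055)
    expect_equal(a2$max_min_ratio, 4)
    ## < 3 junctions: cell excluded
    expect_equal(nrow(cellAnisotropy(.jtab(c(2, 4)), "ch")), 0L)
    ## non-positive intensity: excluded with a message
    expect_message(a3 <- cellAnisotropy(.jtab(c(0, 4, 8)), "ch"),
                   "excluded")
    expect_equal(nrow(a3), 0L)
})

test_that("uniform painted channels give unit ratios at population level", {
    jt <- sharedPainted()$junctions
    jin <- jt[!jt$is_exterior, ]
    an <- cellAnisotropy(jin, "gfp")
    expect_gt(nrow(an), 10)
    expect_lt(mean(an$sd), 1e-9)
    expect_lt(mean(an$max_min_ratio) - 1, 1e-9)
})

test_that("planar polarity follows the weighted nematic formula", {
    ## regular hexagon, equal intensity -> magnitude 0
    hexj <- .jtab(rep(3, 6), cellA = 1L, cellB = 2:7,
                  ori = c(0, 60, 120, 0, 60, 120))
    p <- planarPolarity(hexj, "ch")
    p <- p[p$cell_id == 1L, ]
    expect_lt(p$magnitude, 1e-12)
    ## intensity only on the two junctions at 0 degrees
    j2 <- .jtab(c(5, 0, 0, 5, 0, 0), cellA = 1L, cellB = 2:7,
                ori = c(0, 60, 120, 0, 60, 120))
    p2 <- planarPolarity(j2, "ch")
    p2 <- p2[p2$cell_id == 1L, ]
    expect_equal(p2$magnitude, 1)
    expect_equal(p2$axis_deg, 0)
    ## mixed fixture against direct complex-sum evaluation
    set.seed(41)
    I <- runif(6, 0.5, 4); L <- runif(6, 1, 3); th <- runif(6, 0, 180)
    j3 <- .jtab(I, cellA = 1L, cellB = 2:7, len = L, ori = th)
    p3 <- planarPolarity(j3, "ch"); p3 <- p3[p3$cell_id == 1L, ]
    Q <- sum(I * L * exp(2i * th * pi / 180)) / sum(I * L)
    expect_equal(p3$magnitude, Mod(Q), tolerance = 1e-12)
    expect_equal(p3$axis_deg, (Arg(Q) / 2 * 180 / pi) %% 180,
                 tolerance = 1e-9)
    ## all-zero weights -> flagged undefined
    j4 <- .jtab(rep(0, 4), cellA = 1L, cellB = 2:5)
    p4 <- planarPolarity(j4, "ch"); p4 <- p4[p4$cell_id == 1L, ]
    expect_false(p4$axis_defined)
})

test_that("orientation bins are half-open 15-degree classes", {
    jt <- .jtab(c(1, 2, 3), ori = c(7, 15, 179.9))
    b <- binByOrientation(jt, "ch")
    expect_equal(nrow(b), 12L)
    expect_equal(b$mean_intensity[b$bin_start_deg == 0], 1)
    expect_equal(b$mean_intensity[b$bin_start_deg == 15], 2)
    expect_equal(b$mean_intensity[b$bin_start_deg == 165], 3)
    expect_true(is.na(b$mean_intensity[b$bin_start_deg == 45]))
    ## painted polarized control peaks in a bin at its axis (the axis
    ## sits on a bin edge, so either flanking bin may win)
    tis <- generateTissue(40, seed = 25)
    mod <- channelModel(list(pol = list(group = "uniform", junctional = 5,
        medial = 1, polarityAxisDeg = 90, polarityAmp = 0.6)), seed = 2)
    hp <- paintChannels(tis, mod)
    jh <- extractJunctions(hp)
    jh$int_pol <- measureJunctionIntensity(hp, "pol", jh)
    bb <- binByOrientation(jh[!jh$is_exterior, ], "pol")
    best <- bb$bin_start_deg[which.max(bb$mean_intensity)]
    expect_true(best %in% c(75, 90))
})

test_that("channel pair correlation handles exact and degenerate cases", {
    set.seed(42)
    base <- runif(40, 0, 10)
    jt <- .jtab(base, cellA = 1L, cellB = 2:41)
    jt$int_other <- 2 * base
    expect_equal(channelPairCorrelation(jt, "ch", "other")$r, 1)
    expect_equal(channelPairCorrelation(jt, "ch", "other",
        filterLow = "quantile")$r, 1)
    jt$int_other <- max(base) - base
    expect_equal(channelPairCorrelation(jt, "ch", "other",
        robustRange = FALSE)$r, -1)
    jt$int_other <- 5
    expect_warning(r <- channelPairCorrelation(jt, "ch", "other"),
                   "degenerate")
    expect_true(is.na(r$r))
    jt$int_other <- 2 * base
    expect_error(channelPairCorrelation(jt[1:4, ], "ch", "other"),
                 "fewer than")
})

test_that("per-cell grouping returns a coefficient distribution", {
    jt <- sharedPainted()$junctions
    jin <- jt[!jt$is_exterior, ]
    pc <- channelPairCorrelation(jin, "myoA", "myoB", groupByCell = TRUE,
                                 minPerCell = 5L)
    expect_gt(nrow(pc), 5)
    expect_gt(median(pc$r), 0.5)
})

test_that("anisotropy statistics are scale invariant", {
    jt <- sharedPainted()$junctions
    jin <- jt[!jt$is_exterior, ]
    sc <- jin
    sc$int_myoA <- sc$int_myoA * 7.3
    ## Max/Min ratio and embryo-normalized SD unchanged
    a1 <- cellAnisotropy(normalizeIntensities(jin, "myoA"), "myoA")
    a2 <- cellAnisotropy(normalizeIntensities(sc, "myoA"), "myoA")
    expect_equal(a1$sd, a2$sd, tolerance = 1e-12)
    expect_equal(a1$max_min_ratio, a2$max_min_ratio, tolerance = 1e-12)
    p1 <- planarPolarity(jin, "myoA")
    p2 <- planarPolarity(sc, "myoA")
    expect_equal(p1$magnitude, p2$magnitude, tolerance = 1e-12)
    r1 <- channelPairCorrelation(jin, "myoA", "crbA",
                                 filterLow = "quantile")
    r2 <- channelPairCorrelation(sc, "myoA", "crbA",
                                 filterLow = "quantile")
    expect_equal(r1$r, r2$r, tolerance = 1e-12)
})
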