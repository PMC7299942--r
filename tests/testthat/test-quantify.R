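test_that("cylinder histogram bins heights and sectors as documented", {
    h0 <- cylinderHistogram(matrix(numeric(0), 0, 3), H = 1)
    expect_equal(sum(h0@counts), 0)
    expect_equal(dim(h0@counts), c(5L, 4L))
    ## a bead just above the tip lands in the above-tip bin
    h1 <- cylinderHistogram(matrix(c(0, 0.05, 1.0 + 1e-9), 1), H = 1)
    expect_equal(h1@counts[5, 1], 1L)
    ## due-north bead at z = 0.1 H: cell (segment 1, sector I)
    h2 <- cylinderHistogram(matrix(c(0, 0.05, 0.1), 1), H = 1,
                            nHtBins = 5, nAzBins = 4)
    expect_equal(h2@counts[1, 1], 1L)
    expect_equal(sum(h2@counts), 1)
    ## sector winding: counterclockwise viewed from the top starting north
    west <- cylinderHistogram(matrix(c(-0.05, 0, 0.1), 1), H = 1)
    south <- cylinderHistogram(matrix(c(0, -0.05, 0.1), 1), H = 1)
    east <- cylinderHistogram(matrix(c(0.05, 0, 0.1), 1), H = 1)
    expect_equal(which(west@counts[1, ] == 1L), 2L)
    expect_equal(which(south@counts[1, ] == 1L), 3L)
    expect_equal(which(east@counts[1, ] == 1L), 4L)
    ## on-axis bead deterministically in sector 1
    ax <- cylinderHistogram(matrix(c(0, 0, 0.1), 1), H = 1)
    expect_equal(which(ax@counts[1, ] == 1L), 1L)
    ## below-base bead clamps into segment 1 and is counted
    expect_warning(hc <- cylinderHistogram(matrix(c(0, 0.05, -0.01), 1), H = 1),
                   "clamped")
    expect_equal(hc@counts[1, 1], 1L)
    expect_equal(hc@clamped, 1L)
})

test_that("rotating beads by one sector permutes sectors cyclically", {
    set.seed(20)
    n <- 200
    beads <- cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05), runif(n, 0, 1.2))
    h <- cylinderHistogram(beads, H = 1, nHtBins = 6, nAzBins = 4)
    rot <- rodriguesRotate(beads, c(0, 0, 1), 2 * pi / 4)
    hr <- cylinderHistogram(rot, H = 1, nHtBins = 6, nAzBins = 4)
    expect_equal(hr@counts, h@counts[, c(4, 1, 2, 3)])  # sector s -> s + 1
})

test_that("folding the above-tip bin conserves counts", {
    counts <- rbind(c(1, 0, 2, 0), c(0, 1, 0, 0), c(0, 0, 0, 1),
                    c(2, 2, 2, 2), c(3, 0, 1, 0))
    h <- new("CylinderHistogram", counts = counts, rowId = 2L, H = 1,
             sectorEdges = numeric(0), folded = FALSE, clamped = 0L)
    f <- foldAboveTip(h)
    expect_equal(nrow(f@counts), 4)
    expect_equal(f@counts[4, ], c(5, 2, 3, 2))
    expect_equal(sum(f@counts), sum(counts))
    ## zero above-tip row leaves the top segment unchanged
    h2 <- h; h2@counts[5, ] <- 0L
    expect_equal(foldAboveTip(h2)@counts[4, ], counts[4, ])
    expect_error(foldAboveTip(f), "already folded")
})

test_that("the ~200 nm segment rule", {
    expect_equal(segmentCount(1.0), 5L)
    expect_equal(segmentCount(0.05), 1L)
    ## a row whose average height rounds to 12 segments gets 12 (+1 above-tip)
    expect_equal(segmentCount(2.44), 12L)
    expect_equal(segmentCount(2.5), 13L)   # round half away from zero
    expect_equal(segmentCount(0.3), 2L)
})

test_that("labeling density inverts exactly and matches the closed form", {
    ## 1 bead, diameter 0.2 um, 0.2 um segments, 4 sectors, 10 cilia
    counts <- matrix(0L, 1, 4); counts[1, 2] <- 1L
    h <- new("CylinderHistogram", counts = counts, rowId = 2L, H = 0.2,
             sectorEdges = numeric(0), folded = TRUE, clamped = 0L)
    dm <- labelingDensity(h, avgRadius = 0.1, nCilia = 10)
    expect_equal(dm@density[1, 2], 1 / (pi * 0.2 * 0.2 / 4) / 10,
                 tolerance = 1e-12)
    expect_equal(dm@density[1, 2], 3.18, tolerance = 1e-2)
    ## inversion identity to 1e-12 relative, on a random histogram
    set.seed(21)
    counts <- matrix(rpois(28, 3), 7, 4)
    h2 <- new("CylinderHistogram", counts = counts, rowId = 3L, H = 1.4,
              sectorEdges = numeric(0), folded = TRUE, clamped = 0L)
    dm2 <- labelingDensity(h2, avgRadius = 0.12, nCilia = 17)
    area <- pi * dm2@diameter * dm2@segmentHeight / 4
    expect_equal(dm2@density * area * dm2@nCilia, counts + 0,
                 tolerance = 1e-12)
    ## zero counts give zero densities; unfolded input is rejected
    h3 <- h2; h3@counts[] <- 0L
    expect_true(all(labelingDensity(h3, 0.1, 2)@density == 0))
    h4 <- h2; h4@folded <- FALSE
    expect_error(labelingDensity(h4, 0.1, 2), "fold")
})

test_that("aggregation is linear and order-invariant over cells", {
    cell <- validationCell()
    parent <- file.path(tempdir(), "goldBundle-agg")
    unlink(parent, recursive = TRUE); dir.create(parent)
    cfg <- analysisConfig(resizeFactor = 0.5)
    d1 <- file.path(parent, "CellA"); d2 <- file.path(parent, "CellB")
    dir.create(d1)
    file.copy(list.files(cell$dir, full.names = TRUE), d1, recursive = TRUE)
    analyzeCell(d1, cfg)
    ## identical twin cell
    dir.create(d2)
    file.copy(list.files(d1, full.names = TRUE), d2, recursive = TRUE)
    stopifnot(dir.exists(d1), dir.exists(d2))
    one <- suppressWarnings(aggregateCells(parent, cfg, cellDirs = d1))
    two <- suppressWarnings(aggregateCells(parent, cfg, cellDirs = c(d1, d2)))
    twoRev <- suppressWarnings(aggregateCells(parent, cfg, cellDirs = c(d2, d1)))
    for (k in names(one$histograms)) {
        ## pooled counts exactly double; per-cilium densities unchanged
        expect_equal(two$histograms[[k]]@counts, 2L * one$histograms[[k]]@counts)
        expect_equal(two$densities[[k]]@density, one$densities[[k]]@density,
                     tolerance = 1e-12)
        ## order-invariance
        expect_equal(twoRev$histograms[[k]]@counts, two$histograms[[k]]@counts)
    }
    ## single cell aggregation equals the cell's own tables
    expect_equal(one$summary$nTowers,
                 goldBundle:::readNumericCsv(
                     file.path(d1, "Tables", "AvgHeightAndRadius.csv"))$nTowers)
    ## a subfolder without Tables is skipped with a warning
    dir.create(file.path(parent, "NotACell"))
    w <- capture_warnings(aggregateCells(parent, cfg))
    expect_true(any(grepl("skipped", w)))
    expect_error(aggregateCells(file.path(parent, "NotACell"), cfg),
                 "no analyzed cells")
})
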