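test_that("NN association assigns the obvious nearest tower and thresholds", {
    borders <- list("1" = cbind(0.01 * (1:20), 0, 0),
                    "2" = cbind(0.01 * (1:20), 1.5, 0))
    beads <- BeadSet(rbind(c(0.1, 0.01, 0),      # 10 nm from tower 1
                           c(0.1, 1.49, 0),      # near tower 2
                           c(150, 150, 0)))      # far from everything
    out <- associateNN(beads, borders, k = 10, minDistThr = 100)
    expect_equal(out@assignedTower[1:2], c(1L, 2L))
    expect_true(out@excluded[3])
    expect_true(is.na(out@assignedTower[3]))
    expect_equal(out@method, "NN")
    ## raising the threshold re-admits the far bead (monotonicity)
    out2 <- associateNN(beads, borders, k = 10, minDistThr = 1000)
    expect_gte(sum(!out2@excluded), sum(!out@excluded))
})

test_that("k-NN votes match a brute-force oracle, including the 9-1 split", {
    set.seed(18)
    ## construct a bead whose 10 nearest border samples split 9 A / 1 B
    a <- cbind(rnorm(9, 0, 0.005), rnorm(9, 0, 0.005), rnorm(9, 0, 0.005))
    b1 <- matrix(c(0.012, 0, 0), 1)
    bFar <- cbind(rnorm(30, 1), rnorm(30, 1), rnorm(30, 1))
    borders <- list("1" = a, "2" = rbind(b1, bFar))
    beads <- BeadSet(matrix(c(0, 0, 0), 1))
    out <- associateNN(beads, borders, k = 10, minDistThr = 100)
    expect_equal(out@assignedTower[1], 1L)
    ## brute-force oracle on random scenes
    for (rep_ in 1:5) {
        borders <- list("1" = matrix(runif(60), 20, 3),
                        "2" = matrix(runif(60), 20, 3),
                        "3" = matrix(runif(60), 20, 3))
        beads <- BeadSet(matrix(runif(15), 5, 3))
        k <- 7
        out <- associateNN(beads, borders, k = k, minDistThr = 100)
        pool <- do.call(rbind, borders)
        poolId <- rep(1:3, each = 20)
        for (i in 1:5) {
            d <- sqrt(colSums((t(pool) - beads@centroids[i, ])^2))
            nearest <- poolId[order(d)[1:k]]
            votes <- table(nearest)
            winners <- as.integer(names(votes)[votes == max(votes)])
            if (length(winners) == 1L)
                expect_equal(out@assignedTower[i], winners)
            else
                expect_true(out@assignedTower[i] %in% winners)
        }
    }
    ## oversized k is clipped with a warning
    expect_warning(
        associateNN(BeadSet(matrix(0, 1, 3)),
                    list("1" = matrix(runif(9), 3, 3)), k = 10),
        "clipped")
})

test_that("DT association equals exhaustive nearest-labelled-voxel search", {
    set.seed(19)
    a <- array(0L, c(24, 20, 12))
    a[3:8, 3:8, 2:10] <- 1L
    a[15:20, 12:17, 2:10] <- 2L
    vol <- LabelVolume(a, c(30, 30, 60))  # anisotropic
    beads <- BeadSet(rbind(
        goldBundle:::voxelCenters(matrix(c(5, 5, 5), 1), voxelSize(vol)),
        goldBundle:::voxelCenters(matrix(c(11, 10, 6), 1), voxelSize(vol)),
        matrix(runif(9, 0.05, 0.5), 3, 3)))
    out <- associateDT(beads, vol, minDistThr = 100)
    expect_equal(out@assignedTower[1], 1L)   # inside tower 1
    expect_equal(out@distance[1], 0)
    ## exhaustive oracle: loop over every labelled voxel
    lab <- which(a != 0L)
    labPts <- goldBundle:::voxelCenters(goldBundle:::linearToIjk(lab, dim(a)),
                                        voxelSize(vol))
    labIds <- a[lab]
    for (i in seq_len(nBeads(beads))) {
        d <- sqrt(colSums((t(labPts) - beads@centroids[i, ])^2))
        expect_equal(out@assignedTower[i], as.integer(labIds[which.min(d)]))
        expect_equal(out@distance[i], min(d), tolerance = 1e-12)
    }
    ## empty label volume: everything excluded
    empty <- LabelVolume(array(0L, c(8, 8, 4)), c(10, 10, 10))
    outE <- associateDT(BeadSet(matrix(0.02, 2, 3)), empty)
    expect_true(all(outE@excluded))
    ## out-of-bounds bead excluded with a diagnostic
    expect_warning(
        outB <- associateDT(BeadSet(matrix(c(-1, 0.1, 0.1), 1)), vol),
        "outside")
    expect_true(outB@excluded[1])
})

test_that("NN and DT agree on a well-separated synthetic bundle", {
    cell <- validationCell()
    vol <- resizeVolume(readLabelVolume(file.path(cell$dir, "Towers.am")), 0.5)
    gold <- readLabelVolume(file.path(cell$dir, "GoldParticles.am"))
    beads <- extractBeadCentroids(gold)
    borders <- sampleTowerBorders(vol, 0.2, seed = 1)
    nn <- associateNN(beads, borders, k = 10, minDistThr = 100)
    dt <- associateDT(beads, vol, minDistThr = 100)
    agree <- mean(nn@assignedTower == dt@assignedTower, na.rm = TRUE)
    expect_gte(agree, 0.95)
})
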