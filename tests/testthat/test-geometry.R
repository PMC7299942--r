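test_that("border sampling matches the erosion count and reproduces under seed", {
    ## solid 10x10x10 cube embedded in background
    a <- array(0L, c(14, 14, 14))
    a[3:12, 3:12, 3:12] <- 1L
    vol <- LabelVolume(a, c(10, 10, 10))
    all <- sampleTowerBorders(vol, factor = 1, seed = 1)
    expect_equal(nrow(all[["1"]]), 1000 - 8^3)  # 488: shell of the cube
    sub1 <- sampleTowerBorders(vol, factor = 1 / 10, seed = 99)
    expect_equal(nrow(sub1[["1"]]), 49)         # round(488 / 10)
    sub2 <- sampleTowerBorders(vol, factor = 1 / 10, seed = 99)
    expect_identical(sub1, sub2)
    sub3 <- sampleTowerBorders(vol, factor = 1 / 10, seed = 100)
    expect_false(identical(sub1[["1"]], sub3[["1"]]))
    ## sampled points are a subset of the full border set
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_true(all(key(sub1[["1"]]) %in% key(all[["1"]])))
})

test_that("bead centroids fall at component means with 26-connectivity", {
    a <- array(0L, c(10, 10, 6))
    a[4, 5, 3] <- 1L                      # single voxel
    a[7:8, 2:3, 5] <- 1L                  # 2x2x1 blob
    a[1, 10, 1] <- 1L; a[2, 9, 2] <- 1L   # diagonal pair: one 26-component
    vol <- LabelVolume(a, c(10, 10, 20))
    bs <- extractBeadCentroids(vol)
    expect_equal(nBeads(bs), 3)
    cents <- bs@centroids
    expect_true(any(apply(cents, 1, function(p)
        isTRUE(all.equal(p, c(3.5 * 0.01, 4.5 * 0.01, 2.5 * 0.02),
                         check.attributes = FALSE)))))
    ## 2x2x1 blob mean of the 4 voxel centres
    expect_true(any(apply(cents, 1, function(p)
        isTRUE(all.equal(p, c(7 * 0.01, 2 * 0.01, 4.5 * 0.02),
                         check.attributes = FALSE)))))
    expect_equal(nBeads(extractBeadCentroids(
        LabelVolume(array(0L, c(4, 4, 4)), c(10, 10, 10)))), 0)
})

test_that("two blobs separated by background give two centroids (flood-fill oracle)", {
    set.seed(8)
    a <- array(0L, c(20, 20, 8))
    a[2:4, 2:4, 2:3] <- 1L
    a[15:17, 15:16, 6:7] <- 1L
    bs <- extractBeadCentroids(LabelVolume(a, c(10, 10, 20)))
    ## oracle: naive BFS flood fill, 26-connectivity
    vox <- which(a != 0L)
    ijk <- goldBundle:::linearToIjk(vox, dim(a))
    seen <- rep(FALSE, length(vox)); ncomp <- 0
    for (s in seq_along(vox)) {
        if (seen[s]) next
        ncomp <- ncomp + 1
        queue <- s; seen[s] <- TRUE
        while (length(queue)) {
            cur <- queue[1]; queue <- queue[-1]
            nb <- which(!seen &
                abs(ijk[, 1] - ijk[cur, 1]) <= 1 &
                abs(ijk[, 2] - ijk[cur, 2]) <= 1 &
                abs(ijk[, 3] - ijk[cur, 3]) <= 1)
            seen[nb] <- TRUE
            queue <- c(queue, nb)
        }
    }
    expect_equal(nBeads(bs), ncomp)
})

test_that("principal directions recover constructed axes", {
    z <- cbind(0, 0, seq(0, 1, length.out = 10))
    v <- principalDirection(z)
    expect_equal(abs(v[3]), 1, tolerance = 1e-9)
    ## synthetic cylinder along (1,1,1)/sqrt(3), length 20x radius
    set.seed(9)
    axis <- c(1, 1, 1) / sqrt(3)
    t_ <- runif(500, 0, 2)
    phi <- runif(500, 0, 2 * pi)
    e1 <- c(1, -1, 0) / sqrt(2); e2 <- goldBundle:::cross3(axis, e1)
    pts <- outer(t_, axis) + 0.1 * (outer(cos(phi), e1) + outer(sin(phi), e2))
    vc <- principalDirection(pts)
    ang <- acos(min(1, abs(sum(vc * axis))))
    expect_lt(ang * 180 / pi, 1)
    ## isotropic cloud is flagged ill-conditioned
    iso <- matrix(rnorm(3000), 1000, 3)
    expect_true(attr(principalDirection(iso), "illConditioned"))
    expect_error(principalDirection(matrix(1, 5, 3)), "degenerate")
})

test_that("random sign flips are balanced, seeded and idempotent on empties", {
    expect_equal(nrow(randomSignFlip(matrix(numeric(0), 0, 3), 1)), 0)
    d <- matrix(rep(c(0, 0, 1), each = 1000), 1000, 3)
    f1 <- randomSignFlip(d, 123)
    frac <- mean(f1[, 3] < 0)
    expect_gte(frac, 0.44); expect_lte(frac, 0.56)
    expect_identical(randomSignFlip(d, 123), f1)
})

test_that("spherical mean shift finds the antipodal clusters", {
    d <- matrix(rep(c(0, 0, 1), 5), 5, 3, byrow = TRUE)
    m <- meanShiftSphere(d, 0.3)
    expect_equal(nrow(m), 1)
    expect_equal(as.vector(m), c(0, 0, 1), tolerance = 1e-6)
    ## 50 + 50 directions near +-z with 5 degree angular noise
    set.seed(10)
    noisy <- function(sign) t(replicate(50, {
        theta <- abs(rnorm(1, 0, 5 * pi / 180))
        phi <- runif(1, 0, 2 * pi)
        sign * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    }))
    m2 <- meanShiftSphere(rbind(noisy(1), noisy(-1)), 0.3)
    expect_equal(nrow(m2), 2)
    angs <- acos(pmin(1, abs(m2[, 3])))
    expect_true(all(angs < 2 * pi / 180))
    ## brute-force mode check on a 1 degree grid: the kernel-weighted score
    ## is maximal within 2 degrees of each returned centre
    dirs <- rbind(noisy(1), noisy(-1))
    score <- function(u) sum(exp(-0.5 * (acos(pmin(1, pmax(-1,
        dirs %*% u))) / 0.3)^2))
    grid <- expand.grid(theta = seq(0, pi, by = pi / 180),
                        phi = seq(0, 2 * pi, by = pi / 90))
    gu <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi), cos(grid$theta))
    gs <- apply(gu, 1, score)
    top <- gu[which.max(gs), ]
    expect_lt(min(acos(pmin(1, abs(m2 %*% top)))), 2 * pi / 180)
    ## mutual angle of the two modes: nearly opposite
    expect_gt(acos(pmin(1, pmax(-1, sum(m2[1, ] * m2[2, ])))) * 180 / pi, 170)
})

test_that("upward selection prefers the coplanar-base candidate and is equivariant", {
    set.seed(11)
    mkTower <- function(x0, h) {
        t_ <- runif(200, 0, h); phi <- runif(200, 0, 2 * pi)
        cbind(x0 + 0.1 * cos(phi), 0.1 * sin(phi), t_)
    }
    borders <- list(a = mkTower(0, 1), b = mkTower(0.5, 2), c = mkTower(1, 3))
    up <- determineUpward(borders, rbind(c(0, 0, 1), c(0, 0, -1)))
    expect_equal(as.vector(up), c(0, 0, 1), tolerance = 1e-12)
    ## equivariance: pre-rotate everything, candidates follow
    R <- randomRotation()
    bordersR <- lapply(borders, function(p) p %*% t(R))
    upR <- determineUpward(bordersR, rbind(as.vector(R %*% c(0, 0, 1)),
                                           -as.vector(R %*% c(0, 0, 1))))
    expect_equal(as.vector(upR), as.vector(R %*% c(0, 0, 1)), tolerance = 1e-6)
    ## identical towers: both stds are zero, tie-break picks the direction
    ## with the larger mean maximum projection (towers extend upward)
    same <- list(a = mkTower(0, 1), b = mkTower(0, 1))
    same$b <- same$a
    upT <- determineUpward(same, rbind(c(0, 0, 1), c(0, 0, -1)))
    expect_equal(as.vector(upT), c(0, 0, 1))
    ## upward choice is invariant to the sign-flip seed on coplanar bases
    dirs <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
    for (seed in c(1, 2, 42)) {
        flipped <- randomSignFlip(dirs, seed)
        cand <- meanShiftSphere(rbind(flipped, -flipped), 0.3)
        if (nrow(cand) == 1) cand <- rbind(cand, -cand)
        expect_equal(as.vector(determineUpward(borders, cand[1:2, ])),
                     c(0, 0, 1), tolerance = 1e-9)
    }
})

test_that("Rodrigues rotation equals the rotation-matrix product", {
    p <- matrix(c(1, 0, 0), 1)
    expect_equal(rodriguesRotate(p, c(0, 0, 1), 0), p)
    expect_equal(as.vector(rodriguesRotate(p, c(0, 0, 1), pi / 2)),
                 c(0, 1, 0), tolerance = 1e-12)
    set.seed(12)
    pts <- matrix(rnorm(300), 100, 3)
    for (i in 1:100) {
        axis <- randomUnitVectors(1)[1, ]
        angle <- runif(1, -pi, pi)
        ## oracle: explicit rotation matrix from axis-angle
        K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                      axis[2], -axis[1], 0), 3, 3)
        R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
        expect_equal(rodriguesRotate(pts, axis, angle), pts %*% t(R),
                     tolerance = 1e-9)
    }
    expect_error(rodriguesRotate(pts, c(0, 0, 0), 1), "nonzero")
})

test_that("frame normalization is an isometry that zeroes the base plane", {
    set.seed(13)
    mkTower <- function(x0, h) {
        t_ <- c(0, runif(99, 0, h)); phi <- runif(100, 0, 2 * pi)
        cbind(x0 + 0.1 * cos(phi), 0.1 * sin(phi), t_)  # base exactly z = 0
    }
    borders <- list("1" = mkTower(0, 1), "2" = mkTower(0.6, 1.8))
    towers <- new("TowerSet", ids = c(1L, 2L), row = c(2L, 3L),
        column = c(1L, 1L), used = c(TRUE, TRUE), borderPoints = borders,
        direction = matrix(NA_real_, 2, 3), north = matrix(NA_real_, 2, 3),
        height = rep(NA_real_, 2), radius = rep(NA_real_, 2))
    beads <- BeadSet(matrix(c(0.1, 0, 0.5, 0.6, 0.1, 1.0), 2, 3, byrow = TRUE))
    ## already normalized: identity within tolerance
    n0 <- normalizeFrame(towers, beads, c(0, 0, 1))
    expect_equal(n0$towers@borderPoints[["1"]], borders[["1"]],
                 tolerance = 1e-9)
    ## rotate the scene by a random R, then normalize: distances match
    R <- randomRotation()
    towersR <- towers
    towersR@borderPoints <- lapply(borders, function(p) p %*% t(R))
    beadsR <- BeadSet(beads@centroids %*% t(R))
    nR <- normalizeFrame(towersR, beadsR, as.vector(R %*% c(0, 0, 1)))
    all0 <- rbind(do.call(rbind, n0$towers@borderPoints), n0$beads@centroids)
    allR <- rbind(do.call(rbind, nR$towers@borderPoints), nR$beads@centroids)
    expect_equal(as.matrix(dist(allR)), as.matrix(dist(all0)),
                 tolerance = 1e-6)
    ## base plane exactly at z = 0
    usedZ <- do.call(rbind, nR$towers@borderPoints[nR$towers@used])[, 3]
    expect_equal(min(usedZ), 0)
    ## antiparallel upward: still an isometry
    nA <- normalizeFrame(towers, beads, c(0, 0, -1))
    expect_equal(as.matrix(dist(do.call(rbind, nA$towers@borderPoints))),
                 as.matrix(dist(do.call(rbind, borders))), tolerance = 1e-6)
})

test_that("column azimuths point north away from the mechanosensitive direction", {
    mkAt <- function(x, y) cbind(x + c(-0.05, 0.05, 0, 0), y + c(0, 0, -0.05, 0.05),
                                 c(0, 0.5, 1, 0.2))
    borders <- list("10" = mkAt(0, 3), "20" = mkAt(0, 2),
                    "30" = mkAt(0, 1), "40" = mkAt(0, 0))
    towers <- new("TowerSet", ids = c(10L, 20L, 30L, 40L), row = 1:4,
        column = rep(1L, 4), used = rep(TRUE, 4), borderPoints = borders,
        direction = matrix(NA_real_, 4, 3), north = matrix(NA_real_, 4, 3),
        height = rep(NA_real_, 4), radius = rep(NA_real_, 4))
    link <- LinkTable(matrix(c(10L, 20L, 30L, 40L), 4, 1))
    norths <- computeColumnAzimuths(towers, link)
    for (id in c("10", "20", "30", "40"))
        expect_equal(norths[[id]], c(0, -1, 0), tolerance = 1e-9)
    ## a column whose towers coincide in xy has no azimuth
    b2 <- borders
    for (nm in names(b2)) b2[[nm]][, 1:2] <- b2[["10"]][, 1:2]
    towers2 <- towers; towers2@borderPoints <- b2
    expect_null(computeColumnAzimuths(towers2, link)[["10"]])
    ## single-tower column: undefined
    link3 <- LinkTable(matrix(c(10L, 0L, 0L, 0L), 4, 1))
    expect_null(computeColumnAzimuths(towers, link3)[["10"]])
})

test_that("azimuth alignment rotates about the vertical axis only", {
    set.seed(14)
    pts <- cbind(rnorm(50, 2), rnorm(50, 3), runif(50, 0, 1))
    ## north already ahead: identity
    al0 <- azimuthAlignTower(pts, NULL, c(0, 1, 0))
    expect_equal(al0$points, pts, tolerance = 1e-12)
    ## north east: +90 degrees; a bead due east of the axis maps due north
    ctr <- colMeans(pts)
    bead <- matrix(c(ctr[1] + 0.2, ctr[2], 0.4), 1)
    al <- azimuthAlignTower(pts, bead, c(1, 0, 0))
    expect_equal(as.vector(al$beadPoints),
                 c(ctr[1], ctr[2] + 0.2, 0.4), tolerance = 1e-9)
    ## z untouched; distances preserved
    expect_equal(al$points[, 3], pts[, 3], tolerance = 1e-12)
    expect_equal(as.matrix(dist(al$points)), as.matrix(dist(pts)),
                 tolerance = 1e-6)
    expect_error(azimuthAlignTower(pts, NULL, c(0, 0, 1)), "xy plane")
})

test_that("height/radius estimates match an ideal discretized cylinder", {
    vol <- cylinderVolume(r_um = 0.15, h_um = 2.0, voxelNm = c(20, 20, 40))
    borders <- sampleTowerBorders(vol, 1, seed = 1)[["1"]]
    hr <- towerHeightRadius(borders)
    expect_lte(abs(hr[["height"]] - 2.0), 0.04 + 1e-12)   # one z voxel
    expect_lte(abs(hr[["radius"]] - 0.15), 0.02 + 1e-12)  # one xy voxel
    ## single-plane disc: height ~ 0
    disc <- cbind(cos(seq(0, 2 * pi, length.out = 20)),
                  sin(seq(0, 2 * pi, length.out = 20)), 0.3)
    expect_equal(towerHeightRadius(disc)[["height"]], 0)
    ## scale equivariance
    expect_equal(towerHeightRadius(borders * 2), hr * 2, tolerance = 1e-12)
    expect_error(towerHeightRadius(disc[1:2, ]), "3 border points")
})

test_that("template registration is the stated affine map", {
    set.seed(15)
    phi <- runif(300, 0, 2 * pi); z <- runif(300, 0, 1)
    tower <- cbind(0.3 + 0.1 * cos(phi), -0.2 + 0.1 * sin(phi), 2 + z)
    hr <- towerHeightRadius(tower)
    ## same dimensions: identity up to translation to the origin
    reg0 <- registerTowerToTemplate(tower, NULL, hr[["height"]], hr[["radius"]])
    expect_equal(as.matrix(dist(reg0$points)), as.matrix(dist(tower)),
                 tolerance = 1e-9)
    expect_equal(min(reg0$points[, 3]), 0)
    ## doubling the template height maps a mid-shaft bead linearly
    bead <- matrix(c(0.3, -0.1, 2.5), 1)
    reg <- registerTowerToTemplate(tower, bead, 2 * hr[["height"]],
                                   hr[["radius"]])
    expect_equal(unname(reg$beadPoints[1, 3]), 2 * (2.5 - min(tower[, 3])),
                 tolerance = 1e-9)
    ## two same-row towers of different sizes: registered estimates agree
    tower2 <- cbind(1.1 + 0.07 * cos(phi), 0.5 + 0.07 * sin(phi), 1.5 * z)
    avgH <- mean(c(hr[["height"]], towerHeightRadius(tower2)[["height"]]))
    avgR <- mean(c(hr[["radius"]], towerHeightRadius(tower2)[["radius"]]))
    r1 <- towerHeightRadius(registerTowerToTemplate(tower, NULL, avgH, avgR)$points)
    r2 <- towerHeightRadius(registerTowerToTemplate(tower2, NULL, avgH, avgR)$points)
    expect_lt(abs(r1[["height"]] - r2[["height"]]) / avgH, 0.02)
    expect_lt(abs(r1[["radius"]] - r2[["radius"]]) / avgR, 0.02)
})
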