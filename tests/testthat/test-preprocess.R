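mkStack <- function(nFrames, nx = 40, ny = 40, vs = c(2, 2, 15), seed = 1) {
    set.seed(seed)
    ImageStack(array(sample(0:255, nx * ny * nFrames, replace = TRUE),
                     c(nx, ny, nFrames)), vs)
}

test_that("concatenation preserves order, counts frames, and is associative", {
    a <- mkStack(224); b <- mkStack(144, seed = 2); c3 <- mkStack(5, seed = 3)
    ab <- concatenateStacks(list(a, b))
    expect_equal(dim(ab)[3], 368)  # two acquisition sessions of one cell
    expect_identical(ab@data[, , 1], a@data[, , 1])
    expect_identical(ab@data[, , 225], b@data[, , 1])
    expect_identical(concatenateStacks(list(a)), a)
    lhs <- concatenateStacks(list(concatenateStacks(list(a, b)), c3))
    rhs <- concatenateStacks(list(a, b, c3))
    expect_identical(lhs@data, rhs@data)
})

test_that("concatenation rejects mismatched geometry and metadata", {
    a <- mkStack(3, nx = 100, ny = 100)
    b <- mkStack(3, nx = 99, ny = 100)
    expect_error(concatenateStacks(list(a, b)), "dimension mismatch")
    c3 <- mkStack(3, nx = 100, ny = 100)
    c3@voxelSize <- c(3, 3, 15)
    expect_error(concatenateStacks(list(a, c3)), "voxel-size")
})

test_that("MI alignment recovers a constructed shift and bounds its search", {
    ## smooth textured frame so MI has a clean peak
    set.seed(5)
    nx <- 120; ny <- 120
    base <- outer(sin(seq(0, 6 * pi, length.out = nx)),
                  cos(seq(0, 5 * pi, length.out = ny))) +
        matrix(rnorm(nx * ny, sd = 0.2), nx, ny)
    f1 <- matrix(as.integer(round(254 * (base - min(base)) / diff(range(base)))),
                 nx, ny)
    f2 <- goldBundle:::shiftFrame(f1, 3L, -2L)
    stack <- ImageStack(array(c(f1, f2), c(nx, ny, 2)), c(2, 2, 15))
    ## brute-force oracle over the full +-6 window
    oracle <- expand.grid(dx = -6:6, dy = -6:6)
    mi <- mapply(function(dx, dy) goldBundle:::miAtOffset(f1, f2, dx, dy),
                 oracle$dx, oracle$dy)
    expect_equal(unlist(oracle[which.max(mi), ]), c(dx = -3, dy = 2))
    res <- alignStackTranslation(stack, maxTranslationFraction = 0.06)
    expect_equal(res$offsets[2, ], c(dx = -3L, dy = 2L))
    ## the bound limits the window: 0.5% of 120 px floors to the minimum 1,
    ## so a 3-px shift cannot be recovered under the small setting
    resSmall <- alignStackTranslation(stack, maxTranslationFraction = 0.01)
    expect_lte(max(abs(resSmall$offsets)), 1)
})

test_that("aligning an already-aligned stack is a fixed point", {
    set.seed(6)
    f <- matrix(as.integer(sample(0:255, 60 * 60, replace = TRUE)), 60, 60)
    stack <- ImageStack(array(rep(f, 3), c(60, 60, 3)), c(2, 2, 15))
    res <- alignStackTranslation(stack, 0.05)
    expect_true(all(res$offsets == 0L))
    expect_identical(res$stack@data, stack@data)
    ## constant frame: degenerate histogram
    bad <- ImageStack(array(7L, c(20, 20, 2)), c(2, 2, 15))
    expect_error(alignStackTranslation(bad, 0.1), "constant")
})

test_that("label resize preserves labels and physical extent", {
    vol <- cylinderVolume(r_um = 0.1, h_um = 0.5, voxelNm = c(10, 10, 20))
    expect_identical(resizeVolume(vol, 1), vol)
    half <- resizeVolume(vol, 0.5)
    expect_identical(labelIds(half), labelIds(vol))
    expect_equal(dim(half)[1:2], as.integer(round(dim(vol)[1:2] / 2)))
    ## physical extent preserved exactly by the voxel-size rescale
    expect_equal(dim(half) * voxelSize(half), dim(vol) * voxelSize(vol))
    ## labelled bounding box moves by less than one coarse voxel per axis
    bbox <- function(v) {
        idx <- which(voxelData(v) != 0L, arr.ind = FALSE)
        ijk <- goldBundle:::linearToIjk(idx, dim(v))
        pts <- goldBundle:::voxelCenters(ijk, voxelSize(v))
        rbind(apply(pts, 2, min), apply(pts, 2, max))
    }
    d <- abs(bbox(half) - bbox(vol))
    expect_true(all(t(d) <= voxelSize(half) / 1000 + 1e-12))
    expect_error(resizeVolume(vol, 0), "positive")
})

test_that("a quarter resize quadruples the xy voxel size", {
    vol <- LabelVolume(array(0L, c(64, 64, 4)), c(2.43, 2.43, 15))
    q <- resizeVolume(vol, 1 / 4)
    expect_equal(dim(q)[1], 16)
    expect_equal(voxelSize(q)[1], 4 * 2.43)
    expect_equal(voxelSize(q)[3], 15)  # z untouched by default
})

test_that("cropping keeps labels inside the box and is invertible by padding", {
    vol <- cylinderVolume(r_um = 0.08, h_um = 0.3, voxelNm = c(10, 10, 20))
    full <- list(x = c(1, dim(vol)[1]), y = c(1, dim(vol)[2]),
                 z = c(1, dim(vol)[3]))
    expect_identical(cropVolume(vol, full)@data, vol@data)
    box <- list(x = c(5, 14), y = c(5, 14), z = c(3, 12))
    sub <- cropVolume(vol, box)
    expect_equal(dim(sub), c(10L, 10L, 10L))
    expect_identical(sub@data, vol@data[5:14, 5:14, 3:12])
    expect_equal(voxelSize(sub), voxelSize(vol))
    ## pad back and compare against the masked original
    padded <- array(0L, dim(vol))
    padded[5:14, 5:14, 3:12] <- sub@data
    masked <- array(0L, dim(vol))
    masked[5:14, 5:14, 3:12] <- vol@data[5:14, 5:14, 3:12]
    expect_identical(padded, masked)
    expect_error(cropVolume(vol, list(x = c(5, 4), y = c(1, 2), z = c(1, 2))),
                 "empty")
    expect_error(cropVolume(vol, list(x = c(1, 1e4), y = c(1, 2), z = c(1, 2))),
                 "bounds")
})
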