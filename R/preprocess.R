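## Stack assembly and geometric preparation: concatenation of multi-session
## acquisitions, translation-only mutual-information slice alignment,
## label-safe resizing and cropping.

#' Concatenate image stacks acquired in separate sessions
#'
#' @param stacks list of [ImageStack-class] objects sharing xy dimensions
#'   and voxel size, in acquisition order.
#' @return one [ImageStack-class]; the frame count is the sum of the inputs
#'   and frame order is preserved.
#' @export
concatenateStacks <- function(stacks) {
    stopifnot(length(stacks) >= 1L)
    if (length(stacks) == 1L) return(stacks[[1]])
    d1 <- dim(stacks[[1]]@data)[1:2]
    vs <- stacks[[1]]@voxelSize
    for (s in stacks[-1]) {
        if (!identical(dim(s@data)[1:2], d1))
            stop(sprintf("xy dimension mismatch: %dx%d vs %dx%d",
                dim(s@data)[1], dim(s@data)[2], d1[1], d1[2]))
        if (!isTRUE(all.equal(s@voxelSize, vs)))
            stop("voxel-size mismatch between stacks")
    }
    nz <- sum(vapply(stacks, function(s) dim(s@data)[3], integer(1)))
    out <- array(0L, dim = c(d1[1], d1[2], nz))
    at <- 0L
    for (s in stacks) {
        n <- dim(s@data)[3]
        out[, , at + seq_len(n)] <- s@data
        at <- at + n
    }
    ImageStack(out, vs)
}

## Shannon mutual information (nats) of two 8-bit frames over their full
## extent, using an nbins x nbins joint histogram.
mutualInformation <- function(a, b, nbins = 64L) {
    step <- 256L %/% nbins
    ai <- as.integer(a) %/% step
    bi <- as.integer(b) %/% step
    joint <- tabulate(ai * nbins + bi + 1L, nbins * nbins)
    n <- sum(joint)
    p <- joint[joint > 0] / n
    px <- tabulate(ai + 1L, nbins); px <- px[px > 0] / n
    py <- tabulate(bi + 1L, nbins); py <- py[py > 0] / n
    hx <- -sum(px * log(px)); hy <- -sum(py * log(py))
    hxy <- -sum(p * log(p))
    hx + hy - hxy
}

## MI between ref and cur translated by (dx, dy), over the overlap region
miAtOffset <- function(ref, cur, dx, dy, nbins = 64L) {
    nx <- nrow(ref); ny <- ncol(ref)
    sx <- max(1L, 1L + dx):min(nx, nx + dx)
    sy <- max(1L, 1L + dy):min(ny, ny + dy)
    if (!length(sx) || !length(sy)) return(-Inf)
    mutualInformation(ref[sx, sy], cur[sx - dx, sy - dy], nbins)
}

shiftFrame <- function(m, dx, dy) {
    out <- matrix(0L, nrow(m), ncol(m))
    nx <- nrow(m); ny <- ncol(m)
    sx <- max(1L, 1L + dx):min(nx, nx + dx)
    sy <- max(1L, 1L + dy):min(ny, ny + dy)
    if (length(sx) && length(sy))
        out[sx, sy] <- m[sx - dx, sy - dy]
    out
}

#' Align a stack by translation-only mutual-information registration
#'
#' Each frame k >= 2 is shifted by the integer xy offset that maximizes the
#' mutual information between it and the already-aligned frame k - 1
#' (sequential chaining). The search is exhaustive over offsets bounded by
#' `maxTranslationFraction` of the frame dimension (the acquisition
#' software's "small" setting corresponds to 0.5%); pixels shifted in from
#' outside the frame are zero-filled.
#'
#' @param stack an [ImageStack-class] with >= 2 frames.
#' @param maxTranslationFraction scalar in (0, 1]; per-pair search bound as
#'   a fraction of the frame dimension.
#' @param nbins number of intensity bins per axis of the joint histogram.
#' @return list with elements `stack` (the aligned [ImageStack-class]),
#'   `offsets` (nFrames x 2 integer matrix of applied (dx, dy) shifts) and
#'   `maxTranslationFraction`.
#' @export
alignStackTranslation <- function(stack, maxTranslationFraction = 0.005,
                                  nbins = 64L) {
    stopifnot(is(stack, "ImageStack"))
    d <- dim(stack@data)
    if (d[3] < 2L) stop("alignment needs at least 2 frames")
    if (maxTranslationFraction <= 0 || maxTranslationFraction > 1)
        stop("maxTranslationFraction must be in (0, 1]")
    mx <- max(1L, floor(maxTranslationFraction * d[1]))
    my <- max(1L, floor(maxTranslationFraction * d[2]))
    offsets <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dx", "dy")))
    out <- stack@data
    for (k in 2:d[3]) {
        ref <- out[, , k - 1L]
        cur <- stack@data[, , k]
        if (length(unique(as.vector(ref))) < 2L ||
            length(unique(as.vector(cur))) < 2L)
            stop(sprintf(
                "frame %d is constant: degenerate intensity histogram", k))
        best <- c(0L, 0L); bestMi <- -Inf
        for (dy in -my:my) for (dx in -mx:mx) {
            mi <- miAtOffset(ref, cur, dx, dy, nbins)
            better <- mi > bestMi + 1e-12 ||
                (abs(mi - bestMi) <= 1e-12 &&
                 (dx^2 + dy^2 < sum(best^2)))
            if (better) { bestMi <- mi; best <- c(dx, dy) }
        }
        offsets[k, ] <- best
        out[, , k] <- shiftFrame(cur, best[1], best[2])
    }
    list(stack = ImageStack(out, stack@voxelSize), offsets = offsets,
         maxTranslationFraction = maxTranslationFraction)
}

## output index i' samples input index floor((i' - 0.5) * n / m) + 1
resampleIndex <- function(n, m) {
    pmin(n, pmax(1L, as.integer(floor((seq_len(m) - 0.5) * n / m) + 1L)))
}

#' @describeIn resizeVolume nearest-neighbour resampling for label volumes:
#'   never invents a label and preserves the physical extent (voxel size is
#'   rescaled by the inverse factor).
#' @export
setMethod("resizeVolume", "LabelVolume", function(vol, factor,
                                                  resizeZ = FALSE) {
    checkResizeFactor(vol, factor)
    d <- dim(vol@data)
    m <- resizedDims(d, factor, resizeZ)
    if (identical(m, d)) return(vol)
    data <- vol@data[resampleIndex(d[1], m[1]),
                     resampleIndex(d[2], m[2]),
                     resampleIndex(d[3], m[3]), drop = FALSE]
    LabelVolume(data, vol@voxelSize * d / m)
})

#' @describeIn resizeVolume area-averaging (mean pooling) for intensity
#'   stacks, rounded back to 8-bit.
#' @export
setMethod("resizeVolume", "ImageStack", function(vol, factor,
                                                 resizeZ = FALSE) {
    checkResizeFactor(vol, factor)
    d <- dim(vol@data)
    m <- resizedDims(d, factor, resizeZ)
    if (identical(m, d)) return(vol)
    data <- vol@data
    for (axis in 1:3) {
        if (m[axis] == dim(data)[axis]) next
        grp <- as.integer(floor((seq_len(dim(data)[axis]) - 0.5) *
                                m[axis] / dim(data)[axis]) + 1L)
        data <- poolAxisMean(data, axis, grp, m[axis])
    }
    ImageStack(array(as.integer(round(data)), dim = m), vol@voxelSize * d / m)
})

checkResizeFactor <- function(vol, factor) {
    if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
        stop("resize factor must be a positive scalar")
    if (factor > 1) stop("resize factor must be in (0, 1]")
    invisible(TRUE)
}

resizedDims <- function(d, factor, resizeZ) {
    m <- d
    m[1:2] <- pmax(1L, as.integer(round(d[1:2] * factor)))
    if (resizeZ) m[3] <- max(1L, as.integer(round(d[3] * factor)))
    m
}

## mean over groups along one axis of a 3D array
poolAxisMean <- function(a, axis, grp, nOut) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    pooled <- rowsum(m, grp, reorder = TRUE) /
        as.vector(table(factor(grp, levels = seq_len(nOut))))
    out <- array(pooled, dim = c(nOut, d[2], d[3]))
    aperm(out, order(perm))
}

cropOne <- function(data, box) {
    d <- dim(data)
    for (ax in c("x", "y", "z"))
        if (is.null(box[[ax]]) || length(box[[ax]]) != 2L)
            stop("crop box needs integer ranges $x, $y, $z")
    rx <- as.integer(box$x); ry <- as.integer(box$y); rz <- as.integer(box$z)
    if (rx[1] > rx[2] || ry[1] > ry[2] || rz[1] > rz[2])
        stop("empty crop box")
    if (rx[1] < 1L || ry[1] < 1L || rz[1] < 1L ||
        rx[2] > d[1] || ry[2] > d[2] || rz[2] > d[3])
        stop("crop box exceeds volume bounds")
    data[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE]
}

#' @describeIn cropVolume crop a label volume.
#' @export
setMethod("cropVolume", "LabelVolume", function(vol, box)
    LabelVolume(cropOne(vol@data, box), vol@voxelSize))

#' @describeIn cropVolume crop an image stack.
#' @export
setMethod("cropVolume", "ImageStack", function(vol, box)
    ImageStack(cropOne(vol@data, box), vol@voxelSize))
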