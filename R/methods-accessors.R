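#' @include AllGenerics.R
NULL

#' Construct a LabelVolume
#'
#' @param data 3D non-negative integer array, dim `c(nx, ny, nz)` (x fastest).
#' @param voxelSize numeric length-3, voxel edges (x, y, z) in nm.
#' @return a [LabelVolume-class].
#' @examples
#' v <- LabelVolume(array(0L, c(4, 4, 2)), voxelSize = c(10, 10, 20))
#' labelIds(v)
#' @export
LabelVolume <- function(data, voxelSize) {
    storage.mode(data) <- "integer"
    new("LabelVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' Construct an ImageStack
#'
#' @param data 3D array of 8-bit intensities, dim `c(nx, ny, nFrames)`.
#' @param voxelSize numeric length-3 in nm.
#' @export
ImageStack <- function(data, voxelSize) {
    storage.mode(data) <- "integer"
    new("ImageStack", data = data, voxelSize = as.numeric(voxelSize))
}

#' Construct an empty or filled BeadSet
#'
#' @param centroids n x 3 numeric matrix of bead centroids (um).
#' @export
BeadSet <- function(centroids = matrix(numeric(0), 0, 3)) {
    centroids <- as.matrix(centroids)
    if (length(centroids) == 0L) centroids <- matrix(numeric(0), 0, 3)
    n <- nrow(centroids)
    colnames(centroids) <- c("x", "y", "z")
    new("BeadSet", centroids = centroids,
        assignedTower = rep(NA_integer_, n), excluded = rep(FALSE, n),
        distance = rep(NA_real_, n), method = "")
}

#' Analysis configuration with the pipeline defaults
#'
#' See [AnalysisConfig-class] for the meaning and default of every
#' parameter. Arguments override individual defaults.
#'
#' @param ... named slots of [AnalysisConfig-class] to override.
#' @return an [AnalysisConfig-class].
#' @examples
#' cfg <- analysisConfig(gold2towerAssociationMethod = "DT", rngSeed = 7)
#' @export
analysisConfig <- function(...) {
    args <- list(...)
    for (nm in c("nNearestNeighbors", "rngSeed", "nHtBins", "nAzBins"))
        if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
    do.call(new, c(list("AnalysisConfig"), args))
}

#' Plot configuration with defaults
#' @param ... named slots of [PlotConfig-class] to override.
#' @export
plotConfig <- function(...) do.call(new, c(list("PlotConfig"), list(...)))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname voxelSize-set
#' @name voxelSize-set
#' @export
setReplaceMethod("voxelSize", "LabelVolume", function(x, value) {
    x@voxelSize <- as.numeric(value); validObject(x); x
})
#' @rdname voxelSize-set
#' @export
setReplaceMethod("voxelSize", "ImageStack", function(x, value) {
    x@voxelSize <- as.numeric(value); validObject(x); x
})

#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "ImageStack", function(x) x@data)

#' @rdname labelIds
#' @export
setMethod("labelIds", "LabelVolume", function(x) {
    u <- sort(unique(as.vector(x@data)))
    as.integer(u[u != 0L])
})

#' @rdname nBeads
#' @export
setMethod("nBeads", "BeadSet", function(x) nrow(x@centroids))

#' @rdname towerIds
#' @export
setMethod("towerIds", "TowerSet", function(x) x@ids)
#' @rdname towerIds
#' @export
setMethod("towerIds", "LinkTable", function(x) {
    v <- as.integer(x@ids[x@ids != 0])
    sort(v)
})

#' @describeIn LabelVolume voxel grid dimensions.
#' @param x a LabelVolume.
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@data))
#' @describeIn ImageStack voxel grid dimensions (nx, ny, nFrames).
#' @param x an ImageStack.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@data))

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("LabelVolume %d x %d x %d voxels, %s nm/voxel, %d label(s)\n",
        d[1], d[2], d[3],
        paste(format(object@voxelSize, trim = TRUE), collapse = " x "),
        length(labelIds(object))))
})

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("ImageStack %d x %d px, %d frame(s), %s nm/voxel\n",
        d[1], d[2], d[3],
        paste(format(object@voxelSize, trim = TRUE), collapse = " x ")))
})

setMethod("show", "LinkTable", function(object) {
    cat(sprintf("LinkTable: 4 x %d, %d linked tower(s)\n",
        ncol(object@ids), sum(object@ids != 0)))
    print(object@ids)
})

setMethod("show", "TowerUsage", function(object) {
    cat(sprintf("TowerUsage: 4 x %d, %d included\n",
        ncol(object@flags), sum(object@flags)))
})

setMethod("show", "BeadSet", function(object) {
    n <- nrow(object@centroids)
    cat(sprintf("BeadSet: %d bead(s)", n))
    if (nzchar(object@method))
        cat(sprintf(", associated by %s (%d excluded)", object@method,
            sum(object@excluded)))
    cat("\n")
})

setMethod("show", "TowerSet", function(object) {
    cat(sprintf("TowerSet: %d tower(s), %d used; rows: %s\n",
        length(object@ids), sum(object@used),
        paste(sort(unique(object@row[!is.na(object@row)])), collapse = ",")))
})

setMethod("show", "CylinderHistogram", function(object) {
    cat(sprintf(
        "CylinderHistogram row %d: %d x %d bins%s, H = %.3f um, %d bead(s)\n",
        object@rowId, nrow(object@counts), ncol(object@counts),
        if (object@folded) " (folded)" else "", object@H, sum(object@counts)))
})

setMethod("show", "DensityMap", function(object) {
    cat(sprintf(
        "DensityMap: %d segment(s) x %d sector(s), %.0f nm segments, %d cilia\n",
        nrow(object@density), ncol(object@density),
        1000 * object@segmentHeight, object@nCilia))
})

setMethod("show", "AcquisitionParams", function(object) {
    cat(sprintf("AcquisitionParams: pixel %.4g nm, z step %.4g nm\n",
        object@pixelSizeNm, object@zStepNm))
})

## -- internal coordinate helpers ------------------------------------------

## voxel indices (n x 3, 1-based) -> physical centre coordinates in um
voxelCenters <- function(idx, voxelSizeNm) {
    idx <- matrix(as.numeric(idx), ncol = 3)
    sweep(idx - 0.5, 2, voxelSizeNm / 1000, `*`)
}

## linear index of an array -> (i, j, k) index matrix
linearToIjk <- function(lin, dims) {
    lin0 <- lin - 1L
    i <- lin0 %% dims[1]
    j <- (lin0 %/% dims[1]) %% dims[2]
    k <- lin0 %/% (dims[1] * dims[2])
    cbind(i + 1L, j + 1L, k + 1L)
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
    n <- vnorm(v)
    if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
    v / n
}

cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}
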