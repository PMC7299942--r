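#' @import methods
NULL

## Central containers. Conventions used throughout:
##  * volumes are integer arrays with dim = c(nx, ny, nz); the x index is
##    fastest, matching the on-disk AmiraMesh / TIFF layout;
##  * label 0 is background and never a tower ID;
##  * voxelSize is c(x, y, z) in nanometres; physical point coordinates are in
##    micrometres, voxel (i, j, k) (1-based) has its centre at
##    ((i - 0.5) vx, (j - 0.5) vy, (k - 0.5) vz) / 1000.

#' LabelVolume: a 3D integer label field
#'
#' A segmented volume in which every voxel carries a non-negative integer
#' object index ("material"); 0 is background. Voxels may be anisotropic
#' (the milling step in z is typically 4--8x the xy pixel).
#'
#' @slot data integer array, dim `c(nx, ny, nz)`, x fastest.
#' @slot voxelSize numeric length-3, voxel edge lengths (x, y, z) in nm.
#' @export
setClass("LabelVolume",
    representation(data = "array", voxelSize = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "'data' must be a 3D array")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "'voxelSize' must be 3 strictly positive values (nm)")
        if (length(object@data) && any(object@data < 0, na.rm = TRUE))
            msg <- c(msg, "labels must be non-negative (0 = background)")
        if (is.null(msg)) TRUE else msg
    })

#' ImageStack: a 3D grid of 8-bit EM intensities
#'
#' @slot data integer array, dim `c(nx, ny, nz)`, values 0..255.
#' @slot voxelSize numeric length-3 in nm.
#' @export
setClass("ImageStack",
    representation(data = "array", voxelSize = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "'data' must be a 3D array (x, y, frame)")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "'voxelSize' must be 3 strictly positive values (nm)")
        if (length(object@data) &&
            (min(object@data) < 0 || max(object@data) > 255))
            msg <- c(msg, "intensities must be 8-bit (0..255)")
        if (is.null(msg)) TRUE else msg
    })

#' Acquisition parameters recovered from a Slice&View log
#'
#' @slot hfwUm horizontal field width in micrometres (NA if the log gave an
#'   explicit pixel size instead).
#' @slot widthPx image width in pixels (NA if unknown).
#' @slot zStepNm milling (z) step in nm.
#' @slot pixelSizeNm xy pixel size in nm; equals `1000 * hfwUm / widthPx`
#'   when derived from the field width.
#' @export
setClass("AcquisitionParams",
    representation(hfwUm = "numeric", widthPx = "numeric",
                   zStepNm = "numeric", pixelSizeNm = "numeric"))

#' LinkTable: tower IDs by row (kinocilium, tall, middle, short)
#'
#' A 4 x N integer matrix; column j lists the linked towers of column j of
#' the bundle (at most one tower per row), defining that column's
#' mechanosensitive axis. Zeros are placeholders and do not correspond to
#' any tower; every nonzero ID may appear at most once.
#'
#' @slot ids 4 x N integer matrix.
#' @export
setClass("LinkTable",
    representation(ids = "matrix"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@ids) != 4L)
            msg <- c(msg, "LinkTable must have exactly 4 rows")
        v <- as.vector(object@ids)
        if (length(v) && (any(v != round(v)) || any(v < 0)))
            msg <- c(msg, "LinkTable entries must be non-negative integers")
        nz <- v[v != 0]
        if (anyDuplicated(nz))
            msg <- c(msg, sprintf("duplicate tower ID(s) in LinkTable: %s",
                paste(unique(nz[duplicated(nz)]), collapse = ", ")))
        if (ncol(object@ids) > 0L && length(nz) == 0L)
            msg <- c(msg, "no towers linked (all-zero LinkTable)")
        if (is.null(msg)) TRUE else msg
    })

#' TowerUsage: binary inclusion table, same shape as the LinkTable
#'
#' @slot flags 4 x N binary matrix; 1 = include the tower at the same cell of
#'   the companion [LinkTable-class] in the analysis.
#' @export
setClass("TowerUsage",
    representation(flags = "matrix"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@flags) != 4L)
            msg <- c(msg, "TowerUsage must have exactly 4 rows")
        if (length(object@flags) && !all(object@flags %in% c(0, 1)))
            msg <- c(msg, "TowerUsage entries must be 0 or 1")
        if (is.null(msg)) TRUE else msg
    })

#' BeadSet: gold-bead centroids with tower assignment
#'
#' One row per connected gold-bead blob; centroids are in micrometres in
#' whatever frame the set currently lives in (raw, normalized, or
#' template-registered).
#'
#' @slot centroids n x 3 numeric matrix (x, y, z, um).
#' @slot assignedTower integer vector, NA when unassigned/excluded.
#' @slot excluded logical vector.
#' @slot distance numeric vector, distance (um) to the supporting surface
#'   evidence (nearest border sample or labelled voxel); NA before
#'   association.
#' @slot method character, "", "NN" or "DT".
#' @export
setClass("BeadSet",
    representation(centroids = "matrix", assignedTower = "integer",
                   excluded = "logical", distance = "numeric",
                   method = "character"),
    validity = function(object) {
        n <- nrow(object@centroids)
        msg <- NULL
        if (ncol(object@centroids) != 3L && n > 0L)
            msg <- c(msg, "'centroids' must have 3 columns")
        if (length(object@assignedTower) != n ||
            length(object@excluded) != n || length(object@distance) != n)
            msg <- c(msg, "per-bead slots must match the number of centroids")
        if (any(object@excluded & !is.na(object@assignedTower)))
            msg <- c(msg, "excluded beads must not carry a tower assignment")
        if (is.null(msg)) TRUE else msg
    })

#' TowerSet: per-tower geometry through the pipeline
#'
#' Border points are the sampled surface voxel centres (um) of each tower and
#' are transformed in place as the pipeline rotates / registers the bundle.
#'
#' @slot ids integer tower labels.
#' @slot row integer 1--4 (1 kinocilium, 2 tall, 3 middle, 4 short); NA when
#'   the tower is absent from the LinkTable.
#' @slot column integer column index in the LinkTable (NA if unlinked).
#' @slot used logical, inclusion flag from the TowerUsage table.
#' @slot borderPoints list of n_i x 3 matrices (um), names = ids.
#' @slot direction n x 3 matrix of unit principal directions (NA before PCA).
#' @slot north n x 3 matrix of per-tower horizontal 'north' vectors (NA when
#'   the column azimuth is undefined).
#' @slot height,radius numeric per-tower estimates (um; NA before estimation).
#' @export
setClass("TowerSet",
    representation(ids = "integer", row = "integer", column = "integer",
                   used = "logical", borderPoints = "list",
                   direction = "matrix", north = "matrix",
                   height = "numeric", radius = "numeric"),
    validity = function(object) {
        n <- length(object@ids)
        ok <- length(object@row) == n && length(object@column) == n &&
            length(object@used) == n && length(object@borderPoints) == n &&
            length(object@height) == n && length(object@radius) == n
        if (!ok) return("per-tower slots must all have one entry per tower")
        if (any(!is.na(object@height) & object@height < 0)) return("height must be >= 0")
        if (any(!is.na(object@radius) & object@radius < 0)) return("radius must be >= 0")
        TRUE
    })

#' BundleFrame: the canonical frame of a normalized bundle
#'
#' @slot upward unit 3-vector; (0, 0, 1) after normalization.
#' @slot rotationAxis,rotationAngle the Rodrigues rotation that was applied.
#' @slot translation the global translation that set the base plane to z = 0.
#' @export
setClass("BundleFrame",
    representation(upward = "numeric", rotationAxis = "numeric",
                   rotationAngle = "numeric", translation = "numeric"))

#' CylinderHistogram: bead counts over height segments x azimuth sectors
#'
#' Height bins 1..(nHtBins-1) partition [0, H] into equal segments; the last
#' bin collects beads above the tower tip (z > H). Sector 1 points 'north'
#' ((0, 1, 0)); sectors are indexed counterclockwise viewed from the top.
#'
#' @slot counts nHtBins x nAzBins integer matrix (folded: one row fewer).
#' @slot rowId integer 1--4.
#' @slot H row template height (um).
#' @slot sectorEdges azimuth sector boundaries (radians, relative to north).
#' @slot folded logical; TRUE once the above-tip bin has been folded down.
#' @slot clamped number of beads clamped from z < 0 into segment 1.
#' @export
setClass("CylinderHistogram",
    representation(counts = "matrix", rowId = "integer", H = "numeric",
                   sectorEdges = "numeric", folded = "logical",
                   clamped = "integer"),
    validity = function(object) {
        if (length(object@counts) && any(object@counts < 0))
            return("counts must be non-negative")
        if (object@H <= 0) return("template height H must be positive")
        TRUE
    })

#' DensityMap: surface-normalized labeling density per segment and sector
#'
#' Density is beads per um^2 of cilium lateral surface per cilium; it
#' inverts exactly: `density * segment area * nCilia` recovers the folded
#' counts.
#'
#' @slot density n_segments x nAzBins numeric matrix (beads um^-2 cilium^-1).
#' @slot segmentHeight segment height (um).
#' @slot diameter mean cilium diameter 2 * avg radius (um).
#' @slot nCilia number of cilia pooled.
#' @export
setClass("DensityMap",
    representation(density = "matrix", segmentHeight = "numeric",
                   diameter = "numeric", nCilia = "integer"))

#' AnalysisConfig: tunable parameters of the per-cell analysis
#'
#' Defaults follow the pipeline's published parameterization: volumes are
#' resized to 1/4 in xy before geometry, 1/10 of border voxels are sampled,
#' beads are associated by 10-nearest-neighbour voting, and beads farther
#' than 100 um from any tower surface are excluded (a bound that never
#' triggers at bundle scale, i.e. exclusion is off by default).
#'
#' @slot resizeFactor xy resize factor in (0, 1].
#' @slot borderSamplingFactor fraction of border voxels sampled, (0, 1].
#' @slot gold2towerAssociationMethod "NN" or "DT".
#' @slot nNearestNeighbors k for the NN vote.
#' @slot minDistThr bead exclusion distance (um).
#' @slot rngSeed seed for border sampling and sign flips.
#' @slot meanshiftBandwidth angular kernel bandwidth (radians).
#' @slot nHtBins,nAzBins histogram bins (last height bin = above tip).
#' @slot sectorAlignment "centered" (sector 1 centred on north) or "edge"
#'   (sector 1 starts at north).
#' @slot upwardRule "minima" (std of per-tower minimum projections) or
#'   "maxima" (the alternative reading; see the methods vignette).
#' @slot segmentTargetHeight target segment height (um) for the density
#'   analysis (~200 nm).
#' @export
setClass("AnalysisConfig",
    representation(resizeFactor = "numeric", borderSamplingFactor = "numeric",
                   gold2towerAssociationMethod = "character",
                   nNearestNeighbors = "integer", minDistThr = "numeric",
                   rngSeed = "integer", meanshiftBandwidth = "numeric",
                   nHtBins = "integer", nAzBins = "integer",
                   sectorAlignment = "character", upwardRule = "character",
                   segmentTargetHeight = "numeric"),
    prototype(resizeFactor = 0.25, borderSamplingFactor = 0.1,
              gold2towerAssociationMethod = "NN", nNearestNeighbors = 10L,
              minDistThr = 100, rngSeed = 1L, meanshiftBandwidth = 0.3,
              nHtBins = 5L, nAzBins = 4L, sectorAlignment = "centered",
              upwardRule = "minima", segmentTargetHeight = 0.2),
    validity = function(object) {
        msg <- NULL
        if (object@resizeFactor <= 0 || object@resizeFactor > 1)
            msg <- c(msg, "resizeFactor must be in (0, 1]")
        if (object@borderSamplingFactor <= 0 || object@borderSamplingFactor > 1)
            msg <- c(msg, "borderSamplingFactor must be in (0, 1]")
        if (!object@gold2towerAssociationMethod %in% c("NN", "DT"))
            msg <- c(msg, "association method must be 'NN' or 'DT'")
        if (object@nNearestNeighbors < 1L)
            msg <- c(msg, "nNearestNeighbors must be >= 1")
        if (object@minDistThr <= 0) msg <- c(msg, "minDistThr must be positive")
        if (object@meanshiftBandwidth <= 0)
            msg <- c(msg, "meanshiftBandwidth must be positive")
        if (object@nHtBins < 2L) msg <- c(msg, "nHtBins must be >= 2")
        if (object@nAzBins < 1L) msg <- c(msg, "nAzBins must be >= 1")
        if (!object@sectorAlignment %in% c("centered", "edge"))
            msg <- c(msg, "sectorAlignment must be 'centered' or 'edge'")
        if (!object@upwardRule %in% c("minima", "maxima"))
            msg <- c(msg, "upwardRule must be 'minima' or 'maxima'")
        if (object@segmentTargetHeight <= 0)
            msg <- c(msg, "segmentTargetHeight must be positive")
        if (is.null(msg)) TRUE else msg
    })

#' PlotConfig: display options for result figures
#'
#' @slot viewDirection c(azimuth, elevation) in degrees; `c(90, 0)` is a side
#'   view and `c(90, 90)` a top view.
#' @slot backgroundColor plot background.
#' @slot gpMarker,gpMarkerSize gold-bead marker and size.
#' @slot towersAsPointClouds draw hull points rather than facets.
#' @slot trMarkerSize point size when towers are drawn as point clouds.
#' @export
setClass("PlotConfig",
    representation(viewDirection = "numeric", backgroundColor = "character",
                   gpMarker = "character", gpMarkerSize = "numeric",
                   towersAsPointClouds = "logical", trMarkerSize = "numeric"),
    prototype(viewDirection = c(90, 0), backgroundColor = "black",
              gpMarker = "*", gpMarkerSize = 1, towersAsPointClouds = FALSE,
              trMarkerSize = 1))

#' BundleSpec: parameters of the synthetic bundle generator
#'
#' The generator emulates the segmented output of a FIB-SEM hair-bundle
#' dataset: near-cylindrical towers (stereocilia rows 2--4 and optionally a
#' kinocilium, row 1) standing on a common base plane, arranged as
#' rows x columns, with Table-style link/usage tables and full ground truth.
#'
#' @slot nColumns number of columns.
#' @slot rows subset of 1:4 present (1 = kinocilium).
#' @slot rowHeights,rowRadii named numeric (names "1".."4"), um.
#' @slot columnSpacing,rowSpacing centre-to-centre spacing, um.
#' @slot rotationAxis,rotationAngle global bundle rotation applied before
#'   voxelization (axis unit 3-vector, angle radians).
#' @slot basePlaneZ z of the base plane (um) before rotation.
#' @slot voxelSize c(x, y, z) nm.
#' @slot seed RNG seed for the axis tilt jitter.
#' @slot tiltJitterDeg per-tower axis tilt, degrees (0 disables).
#' @slot kinociliumColumn column carrying the kinocilium (NA = middle).
#' @export
setClass("BundleSpec",
    representation(nColumns = "integer", rows = "integer",
                   rowHeights = "numeric", rowRadii = "numeric",
                   columnSpacing = "numeric", rowSpacing = "numeric",
                   rotationAxis = "numeric", rotationAngle = "numeric",
                   basePlaneZ = "numeric", voxelSize = "numeric",
                   seed = "integer", tiltJitterDeg = "numeric",
                   kinociliumColumn = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@nColumns < 0L) msg <- c(msg, "nColumns must be >= 0")
        if (!all(object@rows %in% 1:4)) msg <- c(msg, "rows must be within 1:4")
        h <- object@rowHeights; r <- object@rowRadii
        if (!all(c("1", "2", "3", "4") %in% names(h)) ||
            !all(c("1", "2", "3", "4") %in% names(r)))
            msg <- c(msg, "rowHeights/rowRadii must be named '1'..'4'")
        else {
            if (h[["2"]] < h[["3"]] || h[["3"]] < h[["4"]])
                msg <- c(msg, "stereocilia heights must be row-monotone (row2 >= row3 >= row4)")
            if (length(object@rows)) {
                maxr <- max(r[as.character(object@rows)])
                if (object@nColumns > 1L && object@columnSpacing <= 2 * maxr)
                    msg <- c(msg, "towers overlap at the stated column spacing")
                if (length(object@rows) > 1L && object@rowSpacing <= 2 * maxr)
                    msg <- c(msg, "towers overlap at the stated row spacing")
            }
        }
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 positive values (nm)")
        if (object@tiltJitterDeg < 0) msg <- c(msg, "tiltJitterDeg must be >= 0")
        if (is.null(msg)) TRUE else msg
    })
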