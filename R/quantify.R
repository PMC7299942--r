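## Cylinder histograms over height segments x azimuth sectors, above-tip
## folding, segment-count rule (~200 nm segments), surface-area-normalized
## labeling densities, and multi-cell aggregation.

## azimuth sector of points relative to north = (0, 1, 0), counterclockwise
## viewed from the top; points exactly on the axis go to sector 1
azimuthSector <- function(x, y, nAzBins, alignment = c("centered", "edge")) {
    alignment <- match.arg(alignment)
    delta <- 2 * pi / nAzBins
    psi <- (atan2(y, x) - pi / 2) %% (2 * pi)
    s <- if (alignment == "centered") {
        floor(((psi + delta / 2) %% (2 * pi)) / delta) + 1L
    } else {
        floor(psi / delta) + 1L
    }
    s <- pmin(as.integer(s), nAzBins)
    s[x == 0 & y == 0] <- 1L
    s
}

## height bin: 1..nHtBins-1 partition [0, H]; nHtBins collects z > H;
## z < 0 clamps to 1 (counted by the caller)
heightBin <- function(z, H, nHtBins) {
    nShaft <- nHtBins - 1L
    seg <- H / nShaft
    b <- floor(z / seg) + 1
    b[z >= H] <- nShaft
    b[z > H] <- nHtBins
    b[z < 0] <- 1
    b <- pmin(pmax(as.integer(b), 1L), as.integer(nHtBins))
    b
}

#' Cylinder histogram of bead counts
#'
#' Bins template-registered bead positions of one row into height segments
#' and azimuth sectors. Height bins 1..nHtBins-1 partition [0, H] into
#' equal segments; bin nHtBins collects beads above the tower tip (z > H).
#' Sector 1 points north ((0, 1, 0)); sectors are indexed counterclockwise
#' viewed from the top, with boundaries at odd multiples of 180/nAzBins
#' degrees from north (sector 1 centred on north) under the default
#' `"centered"` alignment. Beads with z < 0 are clamped into segment 1 and
#' counted in the `clamped` slot.
#'
#' @param beadPoints m x 3 matrix of registered bead positions (um; axis
#'   vertical through the origin, base at z = 0).
#' @param H row template height (um).
#' @param nHtBins number of height bins including the above-tip bin (>= 2).
#' @param nAzBins number of azimuth sectors (>= 1).
#' @param rowId bundle row the beads belong to.
#' @param sectorAlignment `"centered"` or `"edge"`.
#' @return a [CylinderHistogram-class]; `sum(counts)` equals the number of
#'   beads.
#' @export
cylinderHistogram <- function(beadPoints, H, nHtBins = 5L, nAzBins = 4L,
                              rowId = NA_integer_,
                              sectorAlignment = c("centered", "edge")) {
    sectorAlignment <- match.arg(sectorAlignment)
    nHtBins <- as.integer(nHtBins); nAzBins <- as.integer(nAzBins)
    if (nHtBins < 2L) stop("nHtBins must be >= 2 (the last bin is above-tip)")
    if (nAzBins < 1L) stop("nAzBins must be >= 1")
    if (H <= 0) stop("template height H must be positive")
    beadPoints <- as.matrix(beadPoints)
    counts <- matrix(0L, nHtBins, nAzBins)
    clamped <- 0L
    if (nrow(beadPoints)) {
        hb <- heightBin(beadPoints[, 3], H, nHtBins)
        clamped <- sum(beadPoints[, 3] < 0)
        if (clamped > 0L)
            warning(sprintf("%d bead(s) below the base plane clamped into segment 1",
                            clamped))
        sb <- azimuthSector(beadPoints[, 1], beadPoints[, 2], nAzBins,
                            sectorAlignment)
        for (i in seq_along(hb))
            counts[hb[i], sb[i]] <- counts[hb[i], sb[i]] + 1L
    }
    delta <- 2 * pi / nAzBins
    edges <- if (sectorAlignment == "centered")
        -delta / 2 + delta * (0:nAzBins) else delta * (0:nAzBins)
    new("CylinderHistogram", counts = counts, rowId = as.integer(rowId),
        H = H, sectorEdges = edges, folded = FALSE,
        clamped = as.integer(clamped))
}

#' Fold the above-tip bin into the tip segment
#'
#' Beads above the tower tip are added, sector-wise, to the topmost
#' along-shaft segment; the total count is conserved and the result has one
#' height bin fewer.
#'
#' @param hist an unfolded [CylinderHistogram-class] with >= 2 height bins.
#' @return the folded [CylinderHistogram-class].
#' @export
foldAboveTip <- function(hist) {
    stopifnot(is(hist, "CylinderHistogram"))
    if (hist@folded) stop("histogram is already folded")
    nh <- nrow(hist@counts)
    if (nh < 2L) stop("need at least 2 height bins to fold")
    counts <- hist@counts[-nh, , drop = FALSE]
    counts[nh - 1L, ] <- counts[nh - 1L, ] + hist@counts[nh, ]
    new("CylinderHistogram", counts = counts, rowId = hist@rowId, H = hist@H,
        sectorEdges = hist@sectorEdges, folded = TRUE, clamped = hist@clamped)
}

#' Along-shaft segment count for ~200 nm segments
#'
#' The number of equal segments dividing a cilium of height H into segments
#' of about the target height (round half away from zero, at least 1). The
#' histogram for the density analysis then uses this count plus one
#' above-tip bin.
#'
#' @param H row average height (um).
#' @param targetHeight target segment height (um), default 0.2 (200 nm).
#' @return integer segment count.
#' @examples
#' segmentCount(1.0)   # 5
#' segmentCount(0.05)  # 1 (floor guard)
#' @export
segmentCount <- function(H, targetHeight = 0.2) {
    stopifnot(H > 0, targetHeight > 0)
    ## round half away from zero; the epsilon guards exact-half ratios
    ## against binary representation error (e.g. 0.3 / 0.2)
    max(1L, as.integer(floor(H / targetHeight + 0.5 + 1e-9)))
}

#' Surface-area-normalized labeling density
#'
#' Each cell of a folded histogram is divided by the lateral surface area
#' of its segment sector and the number of cilia pooled: the segment area
#' per sector is `pi * diameter * (H / nSegments) / nAzBins` with diameter
#' = 2 x average row radius. The identity
#' `density * area * nCilia == counts` holds exactly.
#'
#' @param hist a folded [CylinderHistogram-class].
#' @param avgRadius row average radius (um).
#' @param nCilia number of cilia pooled into the histogram.
#' @return a [DensityMap-class] (beads per um^2 per cilium).
#' @export
labelingDensity <- function(hist, avgRadius, nCilia) {
    stopifnot(is(hist, "CylinderHistogram"))
    if (!hist@folded) stop("fold the above-tip bin before computing densities")
    nSeg <- nrow(hist@counts); nAz <- ncol(hist@counts)
    segH <- hist@H / nSeg
    area <- pi * (2 * avgRadius) * segH / nAz
    if (area <= 0) stop("zero segment area")
    nCilia <- as.integer(nCilia)
    if (nCilia < 1L) stop("nCilia must be >= 1")
    new("DensityMap", density = hist@counts / (area * nCilia),
        segmentHeight = segH, diameter = 2 * avgRadius, nCilia = nCilia)
}

## -- multi-cell aggregation ------------------------------------------------

readCellTables <- function(cellDir) {
    tdir <- file.path(cellDir, "Tables")
    if (!dir.exists(tdir)) return(NULL)
    rows <- list()
    for (k in 1:4) {
        gp <- file.path(tdir, sprintf("AgrGPRow%d.csv", k))
        tw <- file.path(tdir, sprintf("AgrTwrRow%d.csv", k))
        hr <- file.path(tdir, sprintf("HtRadRow%d.csv", k))
        if (!file.exists(hr)) next
        rows[[as.character(k)]] <- list(
            beads = if (file.exists(gp)) as.matrix(readNumericCsv(gp))
                    else matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("x", "y", "z"))),
            hull = if (file.exists(tw)) as.matrix(readNumericCsv(tw))
                   else matrix(numeric(0), 0, 3),
            htRad = readNumericCsv(hr))
    }
    if (!length(rows)) return(NULL)
    rows
}

#' Aggregate analyzed cells under a parent folder
#'
#' Pools the per-row registered bead coordinates, hull points and tower
#' height/radius tables of every analyzed cell (a subfolder with a
#' `Tables` directory), recomputes the combined row templates, cylinder
#' histograms and labeling densities, and writes combined tables (and
#' figures) under the parent folder. Cells without tables are skipped with
#' a warning; aggregation is order-invariant (cells are pooled in sorted
#' name order).
#'
#' @param parentDir folder whose subfolders are analyzed cells.
#' @param config an [AnalysisConfig-class] (histogram binning and segment
#'   rule are taken from it).
#' @param plot a [PlotConfig-class] for the combined figures.
#' @param cellDirs optional explicit cell subfolder paths.
#' @return invisibly, a list with per-row pooled data, histograms and
#'   density maps.
#' @export
aggregateCells <- function(parentDir, config = analysisConfig(),
                           plot = plotConfig(), cellDirs = NULL) {
    if (is.null(cellDirs)) {
        cellDirs <- list.dirs(parentDir, recursive = FALSE)
        cellDirs <- cellDirs[basename(cellDirs) != "AggregateFigures"]
    }
    cellDirs <- cellDirs[order(basename(cellDirs))]
    pooled <- list()
    usable <- 0L
    for (cd in cellDirs) {
        tabs <- readCellTables(cd)
        if (is.null(tabs)) {
            warning("no Tables folder in ", cd, "; cell skipped")
            next
        }
        usable <- usable + 1L
        for (k in names(tabs)) {
            if (is.null(pooled[[k]]))
                pooled[[k]] <- list(beads = NULL, hull = NULL, htRad = NULL)
            pooled[[k]]$beads <- rbind(pooled[[k]]$beads, tabs[[k]]$beads)
            pooled[[k]]$hull <- rbind(pooled[[k]]$hull, tabs[[k]]$hull)
            pooled[[k]]$htRad <- rbind(pooled[[k]]$htRad, tabs[[k]]$htRad)
        }
    }
    if (usable == 0L) stop("no analyzed cells found under ", parentDir)
    out <- list(rows = list(), summary = NULL, histograms = list(),
                densities = list())
    summary <- NULL
    for (k in sort(names(pooled))) {
        pk <- pooled[[k]]
        avgH <- mean(pk$htRad$height); avgR <- mean(pk$htRad$radius)
        nT <- nrow(pk$htRad)
        out$rows[[k]] <- pk
        summary <- rbind(summary, data.frame(row = as.integer(k),
            avgHeight = avgH, avgRadius = avgR, nTowers = nT))
        hist <- cylinderHistogram(pk$beads, H = avgH, nHtBins = config@nHtBins,
            nAzBins = config@nAzBins, rowId = as.integer(k),
            sectorAlignment = config@sectorAlignment)
        out$histograms[[k]] <- hist
        ## density analysis: ~200 nm segments
        nSeg <- segmentCount(avgH, config@segmentTargetHeight)
        dhist <- foldAboveTip(cylinderHistogram(pk$beads, H = avgH,
            nHtBins = nSeg + 1L, nAzBins = config@nAzBins,
            rowId = as.integer(k), sectorAlignment = config@sectorAlignment))
        out$densities[[k]] <- labelingDensity(dhist, avgR, nT)
    }
    out$summary <- summary
    writeResultsTables(out, parentDir)
    for (k in names(out$histograms)) {
        writeNumericCsv(as.data.frame(out$histograms[[k]]@counts),
            file.path(parentDir, sprintf("counts_row%s.csv", k)))
        writeNumericCsv(as.data.frame(out$densities[[k]]@density),
            file.path(parentDir, sprintf("density_row%s.csv", k)))
    }
    figDir <- file.path(parentDir, "AggregateFigures")
    drawAggregateFigures(out, figDir, plot)
    invisible(out)
}
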