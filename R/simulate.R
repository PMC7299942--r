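## Synthetic cell generator: near-cylindrical towers on a common base
## plane, arranged rows x columns, with link/usage tables, optional
## validation beads in the row-specific control pattern, and full ground
## truth. The generator emulates what segmentation of a FIB-SEM hair
## bundle produces; it does not emulate EM texture, membrane coats or
## antibody chemistry.

#' Build a BundleSpec with field-realistic defaults
#'
#' Defaults model an early-postnatal outer-hair-cell bundle: three
#' stereocilia rows with row-monotone heights (tall 1.2, middle 0.8, short
#' 0.45 um; radii ~0.1 um) plus a 2 um kinocilium in the middle column,
#' 0.45 um centre-to-centre spacing, and a voxel grid of 8 x 8 x 16 nm
#' (xy pixel ~4x finer than the milling step, as acquired). A small
#' per-tower tilt jitter (3 degrees) avoids PCA degeneracy artifacts of
#' perfectly parallel synthetic cylinders.
#'
#' @param nColumns number of bundle columns (default 5).
#' @param rows rows present, subset of 1:4 (default all; 1 = kinocilium).
#' @param rowHeights,rowRadii numeric named "1".."4" (um).
#' @param columnSpacing,rowSpacing centre spacing (um).
#' @param rotationAxis,rotationAngle global rotation applied before
#'   voxelization (radians).
#' @param basePlaneZ base plane height before rotation (um).
#' @param voxelSize c(x, y, z) nm.
#' @param seed RNG seed for tilt jitter.
#' @param tiltJitterDeg per-tower axis tilt (degrees).
#' @param kinociliumColumn column carrying the kinocilium; NA = middle.
#' @return a [BundleSpec-class].
#' @export
bundleSpec <- function(nColumns = 5L, rows = 1:4,
                       rowHeights = c("1" = 2.0, "2" = 1.2, "3" = 0.8,
                                      "4" = 0.45),
                       rowRadii = c("1" = 0.11, "2" = 0.1, "3" = 0.1,
                                    "4" = 0.1),
                       columnSpacing = 0.45, rowSpacing = 0.45,
                       rotationAxis = c(0, 0, 1), rotationAngle = 0,
                       basePlaneZ = 0, voxelSize = c(8, 8, 16),
                       seed = 1L, tiltJitterDeg = 3,
                       kinociliumColumn = NA_integer_) {
    if (is.na(kinociliumColumn))
        kinociliumColumn <- as.integer(max(1L, ceiling(nColumns / 2)))
    new("BundleSpec", nColumns = as.integer(nColumns),
        rows = as.integer(sort(rows)), rowHeights = rowHeights,
        rowRadii = rowRadii, columnSpacing = columnSpacing,
        rowSpacing = rowSpacing, rotationAxis = as.numeric(rotationAxis),
        rotationAngle = rotationAngle, basePlaneZ = basePlaneZ,
        voxelSize = as.numeric(voxelSize), seed = as.integer(seed),
        tiltJitterDeg = tiltJitterDeg,
        kinociliumColumn = as.integer(kinociliumColumn))
}

## tower layout before the global rotation: columns along x, rows along y
## with row 1 (kinocilium) at the largest y, so the column line runs from
## the short row (y = 0) toward the kinocilium: the mechanosensitive
## direction is +y and north is -y.
towerLayout <- function(spec) {
    layout <- NULL
    id <- 0L
    for (r in spec@rows) {
        cols <- if (r == 1L) spec@kinociliumColumn else seq_len(spec@nColumns)
        for (cc in cols) {
            id <- id + 1L
            layout <- rbind(layout, data.frame(id = id, row = r, col = cc,
                x = (cc - 1L) * spec@columnSpacing,
                y = (4L - r) * spec@rowSpacing,
                height = spec@rowHeights[[as.character(r)]],
                radius = spec@rowRadii[[as.character(r)]]))
        }
    }
    layout
}

## unit vector within `deg` degrees of +z, uniformly jittered in azimuth
jitteredAxis <- function(deg) {
    if (deg <= 0) return(c(0, 0, 1))
    theta <- stats::runif(1, 0, deg * pi / 180)
    phi <- stats::runif(1, 0, 2 * pi)
    c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Generate a synthetic cell (towers, gold mask, tables, ground truth)
#'
#' Voxelizes capped cylinders with their bases on a common plane, applies
#' the spec's global rotation before voxelization, and emits the four
#' pipeline inputs together with per-tower ground truth. Reproducible
#' under the spec seed.
#'
#' @param spec a [BundleSpec-class].
#' @return list: `towers` ([LabelVolume-class]), `gold` (empty
#'   [LabelVolume-class]; see [placeValidationBeads()]), `link`
#'   ([LinkTable-class]), `usage` ([TowerUsage-class]), `truth` (list with
#'   `towers` data frame and `origin`, the physical coordinate of voxel
#'   corner (0,0,0) in the pre-rotation scene frame), and `spec`.
#' @export
generateBundle <- function(spec) {
    stopifnot(is(spec, "BundleSpec"))
    validObject(spec)
    if (spec@nColumns == 0L || length(spec@rows) == 0L) {
        link <- LinkTable(matrix(integer(0), 4, spec@nColumns))
        empty <- LabelVolume(array(0L, c(1, 1, 1)), spec@voxelSize)
        return(list(towers = empty, gold = empty, link = link,
            usage = new("TowerUsage",
                        flags = matrix(integer(0), 4, spec@nColumns)),
            truth = list(towers = data.frame()), spec = spec))
    }
    layout <- towerLayout(spec)
    axes <- withr::with_seed(spec@seed, t(vapply(seq_len(nrow(layout)),
        function(i) jitteredAxis(spec@tiltJitterDeg), numeric(3))))
    base <- cbind(layout$x, layout$y, spec@basePlaneZ)
    ## global rotation about the bundle centre of the base points
    if (abs(spec@rotationAngle) > 0) {
        ctr <- colMeans(base)
        base <- rodriguesRotate(sweep(base, 2, ctr), spec@rotationAxis,
                                spec@rotationAngle)
        base <- sweep(base, 2, ctr, `+`)
        axes <- rodriguesRotate(axes, spec@rotationAxis, spec@rotationAngle)
    }
    tips <- base + axes * layout$height
    margin <- max(layout$radius) + 0.08
    lo <- pmin(apply(base, 2, min), apply(tips, 2, min)) - margin
    hi <- pmax(apply(base, 2, max), apply(tips, 2, max)) + margin
    vs <- spec@voxelSize / 1000  # um
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / vs)))
    vol <- array(0L, dims)
    for (i in seq_len(nrow(layout))) {
        vol <- paintCylinder(vol, vs, lo, base[i, ], axes[i, ],
                             layout$height[i], layout$radius[i],
                             as.integer(layout$id[i]))
    }
    link <- matrix(0L, 4, spec@nColumns)
    for (i in seq_len(nrow(layout)))
        link[layout$row[i], layout$col[i]] <- layout$id[i]
    linkT <- LinkTable(link)
    usage <- TowerUsage((link != 0L) * 1L, linkT)
    mechDir <- if (abs(spec@rotationAngle) > 0)
        rodriguesRotate(matrix(c(0, 1, 0), 1), spec@rotationAxis,
                        spec@rotationAngle)[1, ] else c(0, 1, 0)
    truthTowers <- data.frame(layout,
        axisX = axes[, 1], axisY = axes[, 2], axisZ = axes[, 3],
        baseX = base[, 1] - lo[1], baseY = base[, 2] - lo[2],
        baseZ = base[, 3] - lo[3],
        upX = if (abs(spec@rotationAngle) > 0)
            rodriguesRotate(matrix(c(0, 0, 1), 1), spec@rotationAxis,
                            spec@rotationAngle)[1, 1] else 0,
        upY = if (abs(spec@rotationAngle) > 0)
            rodriguesRotate(matrix(c(0, 0, 1), 1), spec@rotationAxis,
                            spec@rotationAngle)[1, 2] else 0,
        upZ = if (abs(spec@rotationAngle) > 0)
            rodriguesRotate(matrix(c(0, 0, 1), 1), spec@rotationAxis,
                            spec@rotationAngle)[1, 3] else 1,
        northX = -mechDir[1], northY = -mechDir[2], northZ = -mechDir[3])
    list(towers = LabelVolume(vol, spec@voxelSize),
         gold = LabelVolume(array(0L, dims), spec@voxelSize),
         link = linkT, usage = usage,
         truth = list(towers = truthTowers, origin = lo), spec = spec)
}

## voxelize a capped cylinder (base point b, unit axis a, height h,
## radius r) into `vol`, volume origin at physical `lo`
paintCylinder <- function(vol, vs, lo, b, a, h, r, label) {
    dims <- dim(vol)
    bRel <- b - lo
    tipRel <- bRel + a * h
    pad <- r + max(vs)
    ilo <- pmax(1L, as.integer(floor((pmin(bRel, tipRel) - pad) / vs)) + 1L)
    ihi <- pmin(dims, as.integer(ceiling((pmax(bRel, tipRel) + pad) / vs)))
    if (any(ilo > ihi)) return(vol)
    xs <- (ilo[1]:ihi[1] - 0.5) * vs[1]
    ys <- (ilo[2]:ihi[2] - 0.5) * vs[2]
    zs <- (ilo[3]:ihi[3] - 0.5) * vs[3]
    g <- expand.grid(x = xs, y = ys, z = zs)
    rel <- cbind(g$x - bRel[1], g$y - bRel[2], g$z - bRel[3])
    t_ <- rel %*% a
    radial2 <- rowSums(rel^2) - t_^2
    inside <- t_ >= 0 & t_ <= h & radial2 <= r^2
    if (!any(inside)) return(vol)
    sub <- vol[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3], drop = FALSE]
    if (any(sub[inside] != 0L))
        stop("towers overlap during voxelization; widen the spacing")
    sub[inside] <- label
    vol[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]] <- sub
    vol
}

#' Place the row-specific validation beads
#'
#' One bead per stereocilium, none on the kinocilium, in the control
#' pattern: tall-row beads at the tip on the surface opposite the middle
#' row; middle-row beads at mid-height on the surface away from the tall
#' row; short-row beads near the base (cuticular plate) on the surface
#' opposite the middle row. Tip/base offsets (95% / 5% of height) are
#' fixture conventions. Each bead is rendered as a single voxel just
#' outside its tower surface, and its expected tower, height segment and
#' azimuth sector under the given binning are recorded as ground truth.
#'
#' @param bundle result of [generateBundle()] (rows 2--4 required).
#' @param nHtBins,nAzBins binning under which expected cells are recorded.
#' @param sectorAlignment sector indexing convention (see
#'   [cylinderHistogram()]).
#' @return the bundle with `gold` filled and `truth$beads` added (data
#'   frame: bead, towerId, row, expected segment/sector, position).
#' @export
placeValidationBeads <- function(bundle, nHtBins = 5L, nAzBins = 4L,
                                 sectorAlignment = "centered") {
    spec <- bundle$spec
    tt <- bundle$truth$towers
    if (nrow(tt) == 0L) stop("bundle has no towers")
    stereo <- tt[tt$row %in% 2:4, , drop = FALSE]
    if (!all(2:4 %in% stereo$row))
        warning("missing stereocilia row(s): partial validation pattern")
    vs <- spec@voxelSize / 1000
    dims <- dim(bundle$towers@data)
    gold <- bundle$gold@data
    ## pre-rotation offset directions; +y points from short row to
    ## kinocilium (the mechanosensitive direction), north is -y
    plus_y <- c(0, 1, 0); minus_y <- c(0, -1, 0)
    if (abs(spec@rotationAngle) > 0) {
        plus_y <- rodriguesRotate(matrix(plus_y, 1), spec@rotationAxis,
                                  spec@rotationAngle)[1, ]
        minus_y <- -plus_y
    }
    beads <- NULL
    for (i in seq_len(nrow(stereo))) {
        r <- stereo$row[i]
        ## height fractions sit mid-bin under the default 4+1 binning so
        ## that discretization never straddles a segment boundary
        frac <- switch(as.character(r), "2" = 0.95, "3" = 0.55, "4" = 0.05)
        ## rows run kinocilium (high y) -> short (low y); "opposite the
        ## middle row" is away from the middle row's y position
        dir <- switch(as.character(r),
            "2" = plus_y,    # middle row sits below (-y): opposite is +y
            "3" = minus_y,   # tall row sits above (+y): away is -y
            "4" = minus_y)   # middle row sits above (+y): opposite is -y
        axis <- c(stereo$axisX[i], stereo$axisY[i], stereo$axisZ[i])
        basePt <- c(stereo$baseX[i], stereo$baseY[i], stereo$baseZ[i])
        ## radial offset: just outside the surface
        radial <- unitize(dir - sum(dir * axis) * axis)
        pos <- basePt + axis * (frac * stereo$height[i]) +
            radial * (stereo$radius[i] + 1.5 * max(vs[1:2]))
        idx <- pmin(dims, pmax(1L, as.integer(floor(pos / vs)) + 1L))
        if (bundle$towers@data[idx[1], idx[2], idx[3]] != 0L)
            stop("validation bead voxel falls inside a tower")
        gold[idx[1], idx[2], idx[3]] <- 1L
        ## expected histogram cell from the construction: the bead sits on
        ## the mech side (+y offset -> 180 deg from north) or north side
        onMech <- sum(dir * plus_y) > 0
        psi <- if (onMech) pi else 0
        delta <- 2 * pi / nAzBins
        sector <- if (sectorAlignment == "centered")
            as.integer(floor(((psi + delta / 2) %% (2 * pi)) / delta) + 1L)
        else as.integer(floor(psi / delta) + 1L)
        segment <- as.integer(min(nHtBins - 1L,
            floor(frac * (nHtBins - 1L)) + 1L))
        beads <- rbind(beads, data.frame(towerId = stereo$id[i],
            row = r, col = stereo$col[i],
            x = (idx[1] - 0.5) * vs[1], y = (idx[2] - 0.5) * vs[2],
            z = (idx[3] - 0.5) * vs[3],
            expSegment = segment, expSector = sector))
    }
    bundle$gold <- LabelVolume(gold, spec@voxelSize)
    beads$bead <- seq_len(nrow(beads))
    bundle$truth$beads <- beads
    bundle
}

#' Write a synthetic cell folder in the pipeline's input layout
#'
#' Emits `Towers.am`, `GoldParticles.am` (byte-RLE AmiraMesh),
#' `LinkTable.csv`, `TowerUsage.csv` and `ground_truth.csv` (bead ground
#' truth; tower ground truth in `ground_truth_towers.csv`).
#'
#' @param bundle result of [generateBundle()] /
#'   [placeValidationBeads()].
#' @param dir output cell folder (created).
#' @return `dir`, invisibly.
#' @export
writeCellFolder <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLabelVolume(bundle$towers, file.path(dir, "Towers.am"), "amira_rle")
    writeLabelVolume(bundle$gold, file.path(dir, "GoldParticles.am"),
                     "amira_rle")
    writeLines(apply(bundle$link@ids, 1, paste, collapse = ","),
               file.path(dir, "LinkTable.csv"))
    writeLines(apply(bundle$usage@flags, 1, paste, collapse = ","),
               file.path(dir, "TowerUsage.csv"))
    if (!is.null(bundle$truth$beads))
        writeNumericCsv(bundle$truth$beads, file.path(dir, "ground_truth.csv"))
    writeNumericCsv(bundle$truth$towers,
                    file.path(dir, "ground_truth_towers.csv"))
    invisible(dir)
}
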