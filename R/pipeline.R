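## Per-cell orchestration, result display and multi-cell aggregation.

requireInput <- function(cellDir, name) {
    p <- file.path(cellDir, name)
    if (!file.exists(p))
        stop(sprintf("missing input file '%s' in %s (file names must match exactly)",
                     name, cellDir))
    p
}

#' Analyze one cell folder end to end
#'
#' Runs the full per-cell pipeline on a folder holding the four inputs
#' `Towers.am`, `GoldParticles.am`, `LinkTable.csv`, `TowerUsage.csv`:
#' load + resize the tower volume, sample tower borders and extract bead
#' centroids (beads at full resolution: both frames are physical, and
#' label downsampling would erase voxel-scale beads), PCA principal
#' directions + random sign flip, spherical mean shift, upward
#' determination, bead association, frame normalization, link-table
#' azimuths, per-tower azimuth transforms (usage-aware), row averages,
#' template registration and convex hulls. Writes `Tables` and `Figures`
#' subfolders plus a provenance record.
#'
#' @param cellDir folder with the four input files.
#' @param config an [AnalysisConfig-class].
#' @param plot a [PlotConfig-class] for the step figures.
#' @param voxelSize optional c(x, y, z) nm override when the `.am` headers
#'   carry no bounding box (also used for TIFF inputs).
#' @return invisibly, a list with the tower set, bead set, per-row
#'   registered data, the frame, and the paths written.
#' @export
analyzeCell <- function(cellDir, config = analysisConfig(),
                        plot = plotConfig(), voxelSize = NULL) {
    stopifnot(is(config, "AnalysisConfig"))
    towersPath <- requireInput(cellDir, "Towers.am")
    goldPath <- requireInput(cellDir, "GoldParticles.am")
    linkPath <- requireInput(cellDir, "LinkTable.csv")
    usagePath <- requireInput(cellDir, "TowerUsage.csv")

    vol <- readLabelVolume(towersPath, voxelSize)
    gold <- readLabelVolume(goldPath, voxelSize)
    link <- readLinkTable(linkPath)
    usage <- readTowerUsage(usagePath, link)
    if (sum(usage@flags) == 0L)
        stop("no towers included: TowerUsage is all zeros")
    missingIds <- setdiff(towerIds(link), labelIds(vol))
    if (length(missingIds))
        stop("LinkTable IDs absent from the tower volume: ",
             paste(missingIds, collapse = ", "))

    vol <- resizeVolume(vol, config@resizeFactor)
    borders <- sampleTowerBorders(vol, config@borderSamplingFactor,
                                  config@rngSeed)
    beads <- extractBeadCentroids(gold)

    ids <- as.integer(names(borders))
    rowOf <- colOf <- rep(NA_integer_, length(ids))
    usedOf <- rep(FALSE, length(ids))
    for (i in seq_along(ids)) {
        hit <- which(link@ids == ids[i], arr.ind = TRUE)
        if (nrow(hit)) {
            rowOf[i] <- hit[1, 1]; colOf[i] <- hit[1, 2]
            usedOf[i] <- usage@flags[hit[1, 1], hit[1, 2]] == 1L
        }
    }
    towers <- new("TowerSet", ids = ids, row = rowOf, column = colOf,
        used = usedOf, borderPoints = borders,
        direction = matrix(NA_real_, length(ids), 3),
        north = matrix(NA_real_, length(ids), 3),
        height = rep(NA_real_, length(ids)),
        radius = rep(NA_real_, length(ids)))

    dirs <- t(vapply(borders, principalDirection, numeric(3)))
    dirs <- randomSignFlip(dirs, config@rngSeed)
    towers@direction <- dirs
    modes <- meanShiftSphere(dirs, config@meanshiftBandwidth)
    candidates <- pickAntipodalCandidates(modes, dirs,
                                          config@meanshiftBandwidth)
    upward <- determineUpward(borders, candidates, config@upwardRule)

    beads <- if (config@gold2towerAssociationMethod == "NN")
        associateNN(beads, borders, config@nNearestNeighbors,
                    config@minDistThr)
    else associateDT(beads, vol, config@minDistThr)

    norm <- normalizeFrame(towers, beads, upward)
    towers <- norm$towers; beads <- norm$beads

    norths <- computeColumnAzimuths(towers, link)
    for (i in seq_along(ids)) {
        nv <- norths[[as.character(ids[i])]]
        if (!is.null(nv)) towers@north[i, ] <- nv
    }

    rowsData <- list()
    alignedBorders <- towers@borderPoints
    alignedBeads <- beads@centroids
    perTowerHt <- perTowerRad <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
        nv <- towers@north[i, ]
        if (any(is.na(nv))) next  # azimuth undefined: excluded downstream
        bIdx <- which(!beads@excluded & beads@assignedTower == ids[i])
        al <- azimuthAlignTower(towers@borderPoints[[i]],
                                beads@centroids[bIdx, , drop = FALSE], nv)
        alignedBorders[[i]] <- al$points
        if (length(bIdx)) alignedBeads[bIdx, ] <- al$beadPoints
        hr <- towerHeightRadius(al$points)
        perTowerHt[i] <- hr[["height"]]; perTowerRad[i] <- hr[["radius"]]
    }
    towers@borderPoints <- alignedBorders
    towers@height <- perTowerHt
    towers@radius <- perTowerRad
    beads@centroids <- alignedBeads

    eligible <- towers@used & !is.na(towers@row) & !is.na(perTowerHt)
    summary <- NULL
    registered <- list()
    for (r in sort(unique(towers@row[eligible]))) {
        sel <- which(eligible & towers@row == r)
        avgH <- mean(perTowerHt[sel]); avgR <- mean(perTowerRad[sel])
        summary <- rbind(summary, data.frame(row = r, avgHeight = avgH,
            avgRadius = avgR, nTowers = length(sel)))
        regB <- regP <- NULL
        for (i in sel) {
            bIdx <- which(!beads@excluded & beads@assignedTower == ids[i])
            reg <- registerTowerToTemplate(towers@borderPoints[[i]],
                beads@centroids[bIdx, , drop = FALSE], avgH, avgR)
            regP <- rbind(regP, reg$points)
            regB <- rbind(regB, reg$beadPoints)
        }
        if (is.null(regB)) regB <- matrix(numeric(0), 0, 3,
                                          dimnames = list(NULL, c("x", "y", "z")))
        hull <- convexHull3(regP)
        registered[[as.character(r)]] <- list(
            beads = regB,
            hull = regP[hull$vertices, , drop = FALSE],
            htRad = data.frame(id = ids[sel], height = perTowerHt[sel],
                               radius = perTowerRad[sel]),
            borderPoints = regP)
    }
    if (is.null(summary)) stop("no usable towers after geometry")

    tablesDir <- file.path(cellDir, "Tables")
    figDir <- file.path(cellDir, "Figures")
    dir.create(figDir, recursive = TRUE, showWarnings = FALSE)
    results <- list(rows = registered, summary = summary)
    files <- writeResultsTables(results, tablesDir)
    writeNumericCsv(assignmentTable(beads),
                    file.path(tablesDir, "BeadAssignments.csv"))
    writeProvenance(cellDir, config,
        c(Towers = towersPath, GoldParticles = goldPath,
          LinkTable = linkPath, TowerUsage = usagePath))
    drawCellFigures(figDir, towers, beads, plot)

    invisible(list(towers = towers, beads = beads, rows = registered,
                   summary = summary, frame = norm$frame, upward = upward,
                   tables = files))
}

## choose two nearly antipodal candidate directions from mean-shift modes
pickAntipodalCandidates <- function(modes, dirs, bandwidth) {
    if (nrow(modes) == 1L) return(rbind(modes[1, ], -modes[1, ]))
    if (nrow(modes) == 2L) return(modes)
    ## more than two modes: keep the two with the most supporting directions
    support <- vapply(seq_len(nrow(modes)), function(i)
        sum(acos(pmin(1, pmax(-1, dirs %*% modes[i, ]))) < bandwidth),
        numeric(1))
    modes[order(support, decreasing = TRUE)[1:2], , drop = FALSE]
}

writeProvenance <- function(cellDir, config, inputs) {
    cfg <- sapply(slotNames(config), function(s) slot(config, s),
                  simplify = FALSE)
    prov <- list(package = "goldBundle",
                 version = as.character(utils::packageVersion("goldBundle")),
                 config = cfg,
                 inputDigests = as.list(stats::setNames(
                     unname(tools::md5sum(inputs)), names(inputs))))
    jsonlite::write_json(prov, file.path(cellDir, "Tables", "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

drawCellFigures <- function(figDir, towers, beads, plot) {
    usedGray <- !towers@used
    plotBundleView(file.path(figDir, "bundle_top.png"),
        towers@borderPoints, towers@ids, beads@centroids,
        "normalized bundle (top view)", plot, view = c(90, 90),
        gray = usedGray)
    plotBundleView(file.path(figDir, "bundle_side.png"),
        towers@borderPoints, towers@ids, beads@centroids,
        "normalized bundle (side view)", plot, view = c(90, 0),
        gray = usedGray)
    invisible(figDir)
}

#' Re-create the result figures of an analyzed cell from its Tables
#'
#' Regenerates the per-row registered point-cloud figures from the Tables
#' folder alone; the `.am` inputs are not touched. Two runs over the same
#' Tables and configuration produce identical figures.
#'
#' @param cellDir an analyzed cell folder (must contain `Tables`).
#' @param plot a [PlotConfig-class].
#' @return invisibly, the figure directory.
#' @export
displayResults <- function(cellDir, plot = plotConfig()) {
    tabs <- readCellTables(cellDir)
    if (is.null(tabs))
        stop("no Tables folder in ", cellDir, "; run analyzeCell first")
    figDir <- file.path(cellDir, "Figures")
    dir.create(figDir, recursive = TRUE, showWarnings = FALSE)
    for (k in names(tabs))
        plotRowCloud(file.path(figDir, sprintf("row%s_registered.png", k)),
                     tabs[[k]]$beads, tabs[[k]]$hull, k, plot)
    invisible(figDir)
}

#' Aggregate all analyzed cells under a parent folder
#'
#' Thin wrapper over [aggregateCells()]: pools the per-row Tables of every
#' analyzed subfolder and writes the combined tables and figures under
#' `parentDir`. Re-running overwrites the outputs identically.
#'
#' @param parentDir folder containing analyzed cell subfolders.
#' @param config an [AnalysisConfig-class].
#' @param plot a [PlotConfig-class].
#' @return invisibly, the combined results list.
#' @export
aggregateResults <- function(parentDir, config = analysisConfig(),
                             plot = plotConfig()) {
    aggregateCells(parentDir, config, plot)
}

#' Read a plain-text key = value configuration file
#'
#' Every named analysis parameter can be set in a `key = value` text file
#' (hash comments allowed); unknown keys are an error. Values given on the
#' command line override the file.
#'
#' @param path file path.
#' @param base configuration to override (default: the package defaults).
#' @return an [AnalysisConfig-class].
#' @export
readConfigFile <- function(path, base = analysisConfig()) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (l in lines) {
        kv <- strsplit(l, "=", fixed = TRUE)[[1]]
        key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
        if (!key %in% slotNames(base))
            stop("unknown configuration key: ", key)
        cur <- slot(base, key)
        slot(base, key) <- if (is.numeric(cur) && !is.integer(cur))
            as.numeric(val) else if (is.integer(cur)) as.integer(val) else val
    }
    validObject(base)
    base
}
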