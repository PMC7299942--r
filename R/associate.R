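## Bead-to-tower association: k-nearest-neighbour voting over pooled border
## samples (fast, the default) or anisotropy-aware distance transform over
## the label volume. Distances are physical (um).

#' Associate beads to towers by k-nearest-neighbour voting
#'
#' For each bead, the k nearest points among the pooled border samples are
#' found; the bead is assigned the tower with the plurality of those
#' neighbours (ties broken toward the tower with the smaller mean neighbour
#' distance). A bead whose single nearest border sample is farther than
#' `minDistThr` is excluded. With k = 1 this reduces to
#' nearest-surface-sample assignment.
#'
#' @param beads a [BeadSet-class].
#' @param borders named list (tower ID -> border point matrix, um).
#' @param k number of neighbours (clipped with a warning if it exceeds the
#'   pooled point count).
#' @param minDistThr exclusion distance (um); the default of 100 um never
#'   triggers at bundle scale.
#' @return the [BeadSet-class] with assignment slots filled, method "NN".
#' @export
associateNN <- function(beads, borders, k = 10L, minDistThr = 100) {
    stopifnot(is(beads, "BeadSet"))
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    pool <- do.call(rbind, borders)
    poolId <- rep(as.integer(names(borders)),
                  vapply(borders, nrow, integer(1)))
    if (is.null(pool) || nrow(pool) == 0L)
        stop("no border points to associate against")
    if (k > nrow(pool)) {
        warning(sprintf("k = %d exceeds the %d pooled border points; clipped",
                        k, nrow(pool)))
        k <- nrow(pool)
    }
    n <- nBeads(beads)
    assigned <- rep(NA_integer_, n); dist <- rep(NA_real_, n)
    excl <- rep(FALSE, n)
    for (b in seq_len(n)) {
        d2 <- (pool[, 1] - beads@centroids[b, 1])^2 +
              (pool[, 2] - beads@centroids[b, 2])^2 +
              (pool[, 3] - beads@centroids[b, 3])^2
        ord <- order(d2)[seq_len(k)]
        nearest <- sqrt(d2[ord[1]])
        dist[b] <- nearest
        if (nearest > minDistThr) { excl[b] <- TRUE; next }
        ids <- poolId[ord]
        votes <- table(ids)
        topIds <- as.integer(names(votes)[votes == max(votes)])
        if (length(topIds) > 1L) {
            meanD <- vapply(topIds, function(id)
                mean(sqrt(d2[ord][ids == id])), numeric(1))
            topIds <- topIds[which.min(meanD)]
        }
        assigned[b] <- topIds[1]
    }
    beads@assignedTower <- assigned
    beads@excluded <- excl
    beads@distance <- dist
    beads@method <- "NN"
    validObject(beads)
    beads
}

#' Associate beads to towers by distance transform
#'
#' Computes, for each bead centroid, the anisotropy-aware Euclidean
#' distance to the nearest labelled voxel centre of the tower volume and
#' assigns the tower achieving the minimum. A bead whose centroid falls on
#' a labelled voxel gets distance 0; beads outside the volume bounds are
#' excluded with a diagnostic, as are beads farther than `minDistThr` from
#' every tower.
#'
#' @param beads a [BeadSet-class].
#' @param vol the tower [LabelVolume-class].
#' @param minDistThr exclusion distance (um).
#' @return the [BeadSet-class] with assignment slots filled, method "DT".
#' @export
associateDT <- function(beads, vol, minDistThr = 100) {
    stopifnot(is(beads, "BeadSet"), is(vol, "LabelVolume"))
    dims <- dim(vol@data)
    lin <- which(vol@data != 0L)
    n <- nBeads(beads)
    assigned <- rep(NA_integer_, n); dist <- rep(NA_real_, n)
    excl <- rep(FALSE, n)
    extent <- dims * vol@voxelSize / 1000
    inBounds <- function(p) all(p >= 0) && all(p <= extent)
    if (!length(lin)) {
        beads@assignedTower <- assigned
        beads@excluded <- rep(TRUE, n)
        beads@distance <- dist
        beads@method <- "DT"
        return(beads)
    }
    labVox <- voxelCenters(linearToIjk(lin, dims), vol@voxelSize)
    labId <- as.integer(vol@data[lin])
    chunk <- 200000L
    for (b in seq_len(n)) {
        p <- beads@centroids[b, ]
        if (!inBounds(p)) {
            excl[b] <- TRUE
            warning(sprintf("bead %d lies outside the volume bounds; excluded", b))
            next
        }
        bestD2 <- Inf; bestId <- NA_integer_
        for (start in seq(1L, length(lin), by = chunk)) {
            idx <- start:min(start + chunk - 1L, length(lin))
            d2 <- (labVox[idx, 1] - p[1])^2 + (labVox[idx, 2] - p[2])^2 +
                  (labVox[idx, 3] - p[3])^2
            w <- which.min(d2)
            if (d2[w] < bestD2) { bestD2 <- d2[w]; bestId <- labId[idx[w]] }
        }
        dist[b] <- sqrt(bestD2)
        if (dist[b] > minDistThr) { excl[b] <- TRUE; next }
        assigned[b] <- bestId
    }
    beads@assignedTower <- assigned
    beads@excluded <- excl
    beads@distance <- dist
    beads@method <- "DT"
    validObject(beads)
    beads
}

#' Per-bead assignment table
#'
#' @param beads an associated [BeadSet-class].
#' @return data frame: bead index, x, y, z (um), tower (ID or "excluded"),
#'   distance, method.
#' @export
assignmentTable <- function(beads) {
    stopifnot(is(beads, "BeadSet"))
    n <- nBeads(beads)
    tower <- ifelse(beads@excluded, "excluded",
                    as.character(beads@assignedTower))
    data.frame(bead = seq_len(n),
               x = beads@centroids[, 1], y = beads@centroids[, 2],
               z = beads@centroids[, 3],
               tower = if (n) tower else character(0),
               distance = beads@distance,
               method = if (n) rep(beads@method, n) else character(0),
               stringsAsFactors = FALSE)
}
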