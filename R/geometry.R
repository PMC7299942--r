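## The geometric core: border sampling, bead centroids, PCA orientation,
## spherical mean shift, upward determination, Rodrigues rotation, canonical
## frame normalization, link-table azimuths, per-tower height/radius,
## row-template registration.

#' Sample border voxels of every tower
#'
#' A border voxel is a nonzero voxel with at least one 6-neighbour carrying
#' a different label (background counts; voxels on the volume boundary are
#' border voxels). For each label, a uniform random subset of
#' `round(factor * count)` (at least 1) border voxel centres is returned in
#' physical micrometres, reproducibly under the given seed (towers are
#' processed in sorted label order on one RNG stream).
#'
#' @param vol a [LabelVolume-class].
#' @param factor sampling fraction in (0, 1].
#' @param seed integer RNG seed.
#' @return named list (names = label IDs) of n x 3 coordinate matrices (um).
#' @export
sampleTowerBorders <- function(vol, factor = 0.1, seed = 1L) {
    stopifnot(is(vol, "LabelVolume"))
    if (factor <= 0 || factor > 1) stop("sampling factor must be in (0, 1]")
    d <- vol@data
    dims <- dim(d)
    border <- array(FALSE, dims)
    ## x neighbours
    border[-dims[1], , ] <- border[-dims[1], , ] | (d[-dims[1], , ] != d[-1, , ])
    border[-1, , ]       <- border[-1, , ]       | (d[-1, , ] != d[-dims[1], , ])
    border[1, , ] <- TRUE; border[dims[1], , ] <- TRUE
    ## y neighbours
    border[, -dims[2], ] <- border[, -dims[2], ] | (d[, -dims[2], ] != d[, -1, ])
    border[, -1, ]       <- border[, -1, ]       | (d[, -1, ] != d[, -dims[2], ])
    border[, 1, ] <- TRUE; border[, dims[2], ] <- TRUE
    ## z neighbours
    border[, , -dims[3]] <- border[, , -dims[3]] | (d[, , -dims[3]] != d[, , -1])
    border[, , -1]       <- border[, , -1]       | (d[, , -1] != d[, , -dims[3]])
    border[, , 1] <- TRUE; border[, , dims[3]] <- TRUE
    labels <- labelIds(vol)
    out <- withr::with_seed(as.integer(seed), {
        res <- vector("list", length(labels))
        names(res) <- as.character(labels)
        for (i in seq_along(labels)) {
            lin <- which(border & (d == labels[i]))
            if (!length(lin)) {
                res[[i]] <- matrix(numeric(0), 0, 3)
                next
            }
            nTake <- max(1L, as.integer(round(factor * length(lin))))
            take <- if (nTake >= length(lin)) seq_along(lin)
                    else sort(sample.int(length(lin), nTake))
            pts <- voxelCenters(linearToIjk(lin[take], dims), vol@voxelSize)
            colnames(pts) <- c("x", "y", "z")
            res[[i]] <- pts
        }
        res
    })
    out
}

#' Extract gold-bead centroids from a bead mask
#'
#' Connected components of the nonzero voxels are found under
#' 26-connectivity (beads are compact blobs); each component contributes
#' one centroid at the unweighted mean of its member voxel centres.
#'
#' @param gold a [LabelVolume-class] holding a binary or labelled bead mask.
#' @return a [BeadSet-class]; empty for an empty mask.
#' @export
extractBeadCentroids <- function(gold) {
    stopifnot(is(gold, "LabelVolume"))
    d <- gold@data
    dims <- dim(d)
    lin <- which(d != 0L)
    if (!length(lin)) return(BeadSet())
    ijk <- linearToIjk(lin, dims)
    offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0 & offsets$dz == 0), ]
    edges <- NULL
    linSorted <- lin
    for (r in seq_len(nrow(offsets))) {
        ni <- ijk[, 1] + offsets$dx[r]
        nj <- ijk[, 2] + offsets$dy[r]
        nk <- ijk[, 3] + offsets$dz[r]
        ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
              nk >= 1L & nk <= dims[3]
        nlin <- (ni - 1L) + (nj - 1L) * dims[1] + (nk - 1L) * dims[1] * dims[2] + 1L
        hit <- match(nlin[ok], linSorted)
        src <- which(ok)[!is.na(hit)]
        dst <- hit[!is.na(hit)]
        keep <- src < dst  # each undirected edge once
        if (any(keep)) edges <- rbind(edges, cbind(src[keep], dst[keep]))
    }
    if (is.null(edges)) {
        comp <- seq_along(lin)
    } else {
        g <- igraph::graph_from_edgelist(edges, directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
        comp <- igraph::components(g)$membership
    }
    pts <- voxelCenters(ijk, gold@voxelSize)
    cen <- rowsum(pts, comp) / as.vector(table(comp))
    ## deterministic order: by first member voxel
    ord <- order(tapply(seq_along(lin), comp, min))
    BeadSet(cen[ord, , drop = FALSE])
}

#' Principal direction of a point cloud
#'
#' The unit eigenvector of the point covariance with the largest
#' eigenvalue; the sign is arbitrary (see [randomSignFlip()]). The result
#' carries attributes `eigenvalues` and `illConditioned` (TRUE when the
#' second eigenvalue is within 20% of the first, i.e. the cloud has no
#' single clear elongation axis).
#'
#' @param points n x 3 matrix (n >= 3).
#' @return unit length-3 numeric vector.
#' @export
principalDirection <- function(points) {
    points <- as.matrix(points)
    if (nrow(points) < 3L) stop("need at least 3 points")
    cv <- stats::cov(points)
    scale2 <- sum(diag(cv))
    if (!is.finite(scale2) || scale2 < 1e-18)
        stop("degenerate covariance: all points coincide")
    e <- eigen(cv, symmetric = TRUE)
    v <- unitize(e$vectors[, 1])
    attr(v, "eigenvalues") <- e$values
    attr(v, "illConditioned") <- e$values[2] > 0.8 * e$values[1]
    v
}

#' Randomly flip the signs of unit directions
#'
#' PCA leaves the sign of each principal direction arbitrary; flipping each
#' sign independently with probability 1/2 forces about half the directions
#' to point to each end, producing two nearly antipodal clusters on the
#' sphere that the mean-shift step can find robustly.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param seed integer RNG seed (reproducible).
#' @return n x 3 matrix.
#' @export
randomSignFlip <- function(directions, seed = 1L) {
    directions <- as.matrix(directions)
    n <- nrow(directions)
    if (n == 0L) return(directions)
    signs <- withr::with_seed(as.integer(seed),
        sample(c(-1, 1), n, replace = TRUE))
    directions * signs
}

#' Mode seeking on the unit sphere (mean shift)
#'
#' From every input direction, iterates weighted spherical means with a
#' Gaussian angular kernel of the given bandwidth until the displacement is
#' below 1e-6 rad; converged modes within bandwidth/2 of an earlier mode
#' are merged.
#'
#' @param directions n x 3 matrix of unit vectors (n >= 2).
#' @param bandwidth kernel bandwidth in radians.
#' @param maxIter iteration cap; exceeding it is an error.
#' @return m x 3 matrix of distinct mode centres.
#' @export
meanShiftSphere <- function(directions, bandwidth = 0.3, maxIter = 500L) {
    directions <- as.matrix(directions)
    if (nrow(directions) < 2L) stop("need at least 2 directions")
    if (bandwidth <= 0) stop("bandwidth must be positive")
    modes <- NULL
    for (s in seq_len(nrow(directions))) {
        m <- directions[s, ]
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            ang <- acos(pmin(1, pmax(-1, directions %*% m)))
            w <- exp(-0.5 * (ang / bandwidth)^2)
            mNew <- colSums(directions * as.vector(w))
            nn <- vnorm(mNew)
            if (nn < 1e-12) break  # perfectly balanced antipodes; keep m
            mNew <- mNew / nn
            step <- acos(pmin(1, pmax(-1, sum(m * mNew))))
            m <- mNew
            if (step < 1e-6) { converged <- TRUE; break }
        }
        if (!converged && it == maxIter)
            stop("spherical mean shift did not converge within ", maxIter,
                 " iterations")
        if (is.null(modes)) {
            modes <- matrix(m, 1, 3)
        } else {
            angs <- acos(pmin(1, pmax(-1, modes %*% m)))
            if (min(angs) > bandwidth / 2) modes <- rbind(modes, m)
        }
    }
    unname(modes)
}

#' Determine the bundle's upward direction
#'
#' Among the candidate directions (the two nearly antipodal mean-shift
#' modes), upward is the one under which the per-tower minimum projections
#' have the smallest standard deviation: the tower bases stand on a common
#' plane, so projecting onto true up aligns the base extremities, while the
#' tips (the opposite candidate) are staggered by row. Ties within 1e-9 are
#' broken toward the candidate with the larger mean per-tower maximum
#' projection (towers extend upward), then lexicographically.
#'
#' @param borders named list of per-tower border point matrices.
#' @param candidates 2 x 3 matrix of candidate unit vectors.
#' @param rule `"minima"` (default, the base-plane reading) or `"maxima"`
#'   (score the per-tower maximum projections instead).
#' @return unit 3-vector with attribute `std` (the two candidate scores).
#' @export
determineUpward <- function(borders, candidates, rule = c("minima", "maxima")) {
    rule <- match.arg(rule)
    borders <- borders[vapply(borders, nrow, integer(1)) > 0L]
    if (length(borders) < 2L)
        stop("need at least 2 towers to determine the upward direction")
    candidates <- as.matrix(candidates)
    stopifnot(nrow(candidates) == 2L)
    score <- numeric(2); tiescore <- numeric(2)
    for (i in 1:2) {
        u <- unitize(candidates[i, ])
        proj <- lapply(borders, function(p) p %*% u)
        ext <- vapply(proj, function(x)
            if (rule == "minima") min(x) else max(x), numeric(1))
        score[i] <- stats::sd(ext)
        tiescore[i] <- mean(vapply(proj, max, numeric(1)))
    }
    pick <- if (abs(score[1] - score[2]) > 1e-9) {
        which.min(score)
    } else if (abs(tiescore[1] - tiescore[2]) > 1e-9) {
        which.max(tiescore)
    } else {
        ## lexicographic fallback on the candidate vectors
        cmp <- sign(candidates[1, ] - candidates[2, ])
        nz <- which(cmp != 0)
        if (length(nz) && cmp[nz[1]] > 0) 1L else 2L
    }
    u <- unitize(candidates[pick, ])
    attr(u, "std") <- score
    u
}

#' Rotate points about an axis (Rodrigues formula)
#'
#' `v' = v cos(a) + (k x v) sin(a) + k (k . v) (1 - cos(a))` for unit axis
#' k and angle a, applied to every row.
#'
#' @param points n x 3 matrix.
#' @param axis unit 3-vector.
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return n x 3 matrix of rotated points.
#' @export
rodriguesRotate <- function(points, axis, angle) {
    points <- as.matrix(points)
    n <- vnorm(axis)
    if (n < 1e-12) stop("rotation axis must be nonzero")
    k <- axis / n
    if (nrow(points) == 0L) return(points)
    ca <- cos(angle); sa <- sin(angle)
    kx <- cbind(k[2] * points[, 3] - k[3] * points[, 2],
                k[3] * points[, 1] - k[1] * points[, 3],
                k[1] * points[, 2] - k[2] * points[, 1])
    kv <- as.vector(points %*% k)
    out <- points * ca + kx * sa + outer(kv, k) * (1 - ca)
    colnames(out) <- colnames(points)
    out
}

## rotation parameters taking unit vector `from` onto unit vector `to`
rotationBetween <- function(from, to) {
    from <- unitize(from); to <- unitize(to)
    ax <- cross3(from, to)
    s <- vnorm(ax); c_ <- sum(from * to)
    if (s < 1e-12) {
        if (c_ > 0) return(list(axis = c(1, 0, 0), angle = 0))
        return(list(axis = c(1, 0, 0), angle = pi))  # antiparallel: flip about x
    }
    list(axis = ax / s, angle = atan2(s, c_))
}

#' Normalize a bundle to its canonical frame
#'
#' Applies one rigid rotation (about the pooled centre of mass of all tower
#' border points; axis `upward x z`) taking `upward` onto (0, 0, 1) to all
#' tower border points and all bead centroids, then translates the scene so
#' the minimum z over the used towers' points is exactly 0 (the base
#' plane). Pairwise distances are preserved.
#'
#' @param towers a [TowerSet-class].
#' @param beads a [BeadSet-class] in the same frame.
#' @param upward unit 3-vector from [determineUpward()].
#' @return list with elements `towers`, `beads` and `frame`
#'   (a [BundleFrame-class] recording the transform).
#' @export
normalizeFrame <- function(towers, beads, upward) {
    stopifnot(is(towers, "TowerSet"), is(beads, "BeadSet"))
    allPts <- do.call(rbind, towers@borderPoints)
    if (is.null(allPts) || nrow(allPts) == 0L)
        stop("towers carry no border points")
    com <- colMeans(allPts)
    rot <- rotationBetween(upward, c(0, 0, 1))
    rotate <- function(p) {
        if (nrow(p) == 0L) return(p)
        ctr <- matrix(com, nrow(p), 3, byrow = TRUE)
        rodriguesRotate(p - ctr, rot$axis, rot$angle) + ctr
    }
    towers@borderPoints <- lapply(towers@borderPoints, rotate)
    beads@centroids <- rotate(beads@centroids)
    usedPts <- do.call(rbind, towers@borderPoints[towers@used])
    if (is.null(usedPts) || nrow(usedPts) == 0L)
        stop("no towers included: cannot place the base plane")
    tz <- -min(usedPts[, 3])
    shift <- c(0, 0, tz)
    towers@borderPoints <- lapply(towers@borderPoints, function(p)
        sweep(p, 2, shift, `+`))
    if (nrow(beads@centroids))
        beads@centroids <- sweep(beads@centroids, 2, shift, `+`)
    frame <- new("BundleFrame", upward = c(0, 0, 1), rotationAxis = rot$axis,
                 rotationAngle = rot$angle, translation = shift)
    list(towers = towers, beads = beads, frame = frame)
}

## xy centroid of a tower's border points
towerCentroid <- function(points) colMeans(points)

#' Per-column azimuth ('north') directions from the link table
#'
#' For every column of the link table with at least two linked towers, a
#' total-least-squares line is fitted through the towers' xy centroids.
#' The mechanosensitive direction is the unit xy vector pointing from the
#' row-4 (short) end of that line toward the row-1 (kinocilium) end; north
#' is its negation. Every tower of the column receives the same north
#' (zero z component).
#'
#' @param towers a [TowerSet-class] in the normalized frame.
#' @param link a [LinkTable-class].
#' @return named list (tower ID -> unit 3-vector or NULL when the column
#'   azimuth is undefined).
#' @export
computeColumnAzimuths <- function(towers, link) {
    stopifnot(is(towers, "TowerSet"), is(link, "LinkTable"))
    norths <- stats::setNames(vector("list", length(towers@ids)),
                              as.character(towers@ids))
    for (j in seq_len(ncol(link@ids))) {
        ids <- link@ids[, j]
        rows <- which(ids != 0L)
        present <- rows[ids[rows] %in% towers@ids]
        if (length(present) < 2L) next
        cen <- t(vapply(ids[present], function(id) {
            p <- towers@borderPoints[[as.character(id)]]
            towerCentroid(p)[1:2]
        }, numeric(2)))
        ctr <- colMeans(cen)
        centered <- sweep(cen, 2, ctr)
        if (max(abs(centered)) < 1e-9) next  # coincident centroids: undefined
        v <- eigen(crossprod(centered), symmetric = TRUE)$vectors[, 1]
        proj <- centered %*% v
        ## orient v toward increasing row index, then mech = -v (row4 -> row1)
        slope <- sum(proj * (present - mean(present)))
        if (slope < 0) v <- -v
        mech <- -v  # points from the row-4 end toward the row-1 end
        north <- unitize(c(-mech, 0))
        for (id in ids[present]) norths[[as.character(id)]] <- north
    }
    norths
}

#' Azimuth-align one tower and its beads
#'
#' Rotates the tower's border points and its assigned beads about the
#' vertical axis through the tower's xy centroid by the angle that maps the
#' tower's north onto (0, 1, 0) ('ahead'). z coordinates are unchanged.
#'
#' @param points tower border points (n x 3, normalized frame).
#' @param beadPoints bead centroids assigned to this tower (m x 3).
#' @param north the tower's unit north vector (z component 0).
#' @return list with rotated `points` and `beadPoints`.
#' @export
azimuthAlignTower <- function(points, beadPoints, north) {
    points <- as.matrix(points)
    if (is.null(beadPoints)) beadPoints <- matrix(numeric(0), 0, 3)
    beadPoints <- as.matrix(beadPoints)
    if (abs(north[3]) > 1e-9) stop("north must lie in the xy plane")
    ctr <- towerCentroid(points)
    delta <- pi / 2 - atan2(north[2], north[1])
    rotz <- function(p) {
        if (nrow(p) == 0L) return(p)
        x <- p[, 1] - ctr[1]; y <- p[, 2] - ctr[2]
        out <- cbind(x * cos(delta) - y * sin(delta) + ctr[1],
                     x * sin(delta) + y * cos(delta) + ctr[2],
                     p[, 3])
        colnames(out) <- colnames(p)
        out
    }
    list(points = rotz(points), beadPoints = rotz(beadPoints))
}

#' Height and radius of one tower
#'
#' Height is the z extent of the border points; radius is the mean
#' horizontal distance of the border points from the vertical axis through
#' the xy centroid (mean rather than max: robust to segmentation
#' roughness). Requires the normalized (vertical-axis) frame.
#'
#' @param points n x 3 border point matrix, n >= 3.
#' @return named numeric `c(height =, radius =)` in um.
#' @export
towerHeightRadius <- function(points) {
    points <- as.matrix(points)
    if (nrow(points) < 3L) stop("need at least 3 border points")
    h <- max(points[, 3]) - min(points[, 3])
    ctr <- colMeans(points[, 1:2, drop = FALSE])
    r <- mean(sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2))
    c(height = h, radius = r)
}

#' Register a tower (and its beads) to its row template
#'
#' Affine map per tower: translate the base axis point (xy centroid, min z)
#' to the origin, scale z by `avgHeight / height` and xy radially about the
#' axis by `avgRadius / radius`. The same map is applied to the tower's
#' beads, so bead positions are expressed in the row's template cylinder.
#'
#' @param points tower border points (normalized, azimuth-aligned frame).
#' @param beadPoints the tower's bead centroids (may be empty).
#' @param avgHeight,avgRadius the row template dimensions (um).
#' @return list with registered `points` and `beadPoints`.
#' @export
registerTowerToTemplate <- function(points, beadPoints, avgHeight, avgRadius) {
    points <- as.matrix(points)
    if (is.null(beadPoints)) beadPoints <- matrix(numeric(0), 0, 3)
    beadPoints <- as.matrix(beadPoints)
    hr <- towerHeightRadius(points)
    if (hr["height"] <= 0 || hr["radius"] <= 0)
        stop("tower has zero height or radius; excluded from registration")
    ctr <- colMeans(points[, 1:2, drop = FALSE])
    z0 <- min(points[, 3])
    sz <- avgHeight / hr[["height"]]
    sr <- avgRadius / hr[["radius"]]
    mapPts <- function(p) {
        if (nrow(p) == 0L) return(p)
        out <- cbind((p[, 1] - ctr[1]) * sr,
                     (p[, 2] - ctr[2]) * sr,
                     (p[, 3] - z0) * sz)
        colnames(out) <- c("x", "y", "z")
        out
    }
    list(points = mapPts(points), beadPoints = mapPts(beadPoints))
}
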