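## Incremental 3D convex hull with outward-oriented triangular facets.
## Written in-package: no qhull binding is available in this toolchain, and
## the hull summarises the aggregated "average" tower surface, so vertices
## must be a subset of the input points.

#' Convex hull of a 3D point set
#'
#' Incremental construction: starting from an extreme tetrahedron, each
#' remaining point outside the current hull removes its visible facets and
#' is stitched to the horizon edges. Facets are oriented outward. For
#' (near-)coplanar input, falls back to the planar hull in the best-fit
#' plane with a warning and returns a fan triangulation.
#'
#' @param points n x 3 matrix, n >= 4 for a solid hull.
#' @param tol relative tolerance classifying a point as on a facet plane.
#' @return list with `vertices` (indices into `points` of hull vertices),
#'   `facets` (m x 3 matrix of point indices, outward-oriented) and
#'   `planar` (logical).
#' @export
convexHull3 <- function(points, tol = 1e-9) {
    points <- as.matrix(points)
    n <- nrow(points)
    if (n < 4L) stop("need at least 4 points for a 3D hull")
    scale <- max(apply(points, 2, function(x) diff(range(x))), 1e-300)
    eps <- tol * scale
    init <- initialSimplex(points, eps)
    if (is.null(init)) return(planarHull(points))
    facets <- orientSimplex(init, points)
    planes <- t(apply(facets, 1, facetPlane, points = points))
    interior <- colMeans(points[init, ])
    for (p in setdiff(seq_len(n), init)) {
        dists <- planes[, 1:3, drop = FALSE] %*% points[p, ] - planes[, 4]
        visible <- which(dists > eps)
        if (!length(visible)) next
        horizon <- horizonEdges(facets, visible)
        facets <- facets[-visible, , drop = FALSE]
        planes <- planes[-visible, , drop = FALSE]
        for (e in seq_len(nrow(horizon))) {
            tri <- c(horizon[e, 1], horizon[e, 2], p)
            pl <- facetPlane(tri, points)
            ## orient outward (interior point on the negative side)
            if (sum(pl[1:3] * interior) - pl[4] > 0) {
                tri <- tri[c(2, 1, 3)]
                pl <- facetPlane(tri, points)
            }
            facets <- rbind(facets, tri)
            planes <- rbind(planes, pl)
        }
    }
    rownames(facets) <- NULL
    list(vertices = sort(unique(as.vector(facets))),
         facets = unname(facets), planar = FALSE)
}

## plane (a, b, c, d) with a x + b y + c z = d through a facet's 3 points
facetPlane <- function(tri, points) {
    p1 <- points[tri[1], ]; p2 <- points[tri[2], ]; p3 <- points[tri[3], ]
    nrm <- cross3(p2 - p1, p3 - p1)
    nn <- vnorm(nrm)
    if (nn < 1e-300) nrm <- c(0, 0, 0) else nrm <- nrm / nn
    c(nrm, sum(nrm * p1))
}

## four affinely independent points spanning a tetrahedron, NULL if coplanar
initialSimplex <- function(points, eps) {
    i1 <- which.min(points[, 1]); i2 <- which.max(points[, 1])
    if (isTRUE(all.equal(points[i1, ], points[i2, ]))) {
        ## degenerate in x: try farthest pair over all axes
        i2 <- which.max(rowSums(sweep(points, 2, points[i1, ])^2))
    }
    if (vnorm(points[i2, ] - points[i1, ]) < eps) return(NULL)
    seg <- points[i2, ] - points[i1, ]
    rel <- sweep(points, 2, points[i1, ])
    crossNorm <- sqrt(
        (rel[, 2] * seg[3] - rel[, 3] * seg[2])^2 +
        (rel[, 3] * seg[1] - rel[, 1] * seg[3])^2 +
        (rel[, 1] * seg[2] - rel[, 2] * seg[1])^2) / vnorm(seg)
    i3 <- which.max(crossNorm)
    if (crossNorm[i3] < eps) return(NULL)
    pl <- facetPlane(c(i1, i2, i3), points)
    dd <- abs(points %*% pl[1:3] - pl[4])
    i4 <- which.max(dd)
    if (dd[i4] < eps) return(NULL)
    c(i1, i2, i3, i4)
}

## the 4 outward-oriented facets of the initial tetrahedron
orientSimplex <- function(idx, points) {
    combos <- rbind(idx[c(1, 2, 3)], idx[c(1, 2, 4)],
                    idx[c(1, 3, 4)], idx[c(2, 3, 4)])
    interior <- colMeans(points[idx, ])
    t(apply(combos, 1, function(tri) {
        pl <- facetPlane(tri, points)
        if (sum(pl[1:3] * interior) - pl[4] > 0) tri[c(2, 1, 3)] else tri
    }))
}

## boundary edges of the visible facet set (each shared by exactly one
## visible facet), oriented as they appear in the visible facets
horizonEdges <- function(facets, visible) {
    edges <- NULL
    for (f in visible) {
        tri <- facets[f, ]
        edges <- rbind(edges, cbind(tri, tri[c(2, 3, 1)]))
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- names(which(table(key) == 1L))
    edges[key %in% once, , drop = FALSE]
}

planarHull <- function(points) {
    warning("input points are (near-)coplanar: returning the planar hull")
    ctr <- colMeans(points)
    centered <- sweep(points, 2, ctr)
    ev <- eigen(crossprod(centered), symmetric = TRUE)$vectors
    uv <- centered %*% ev[, 1:2]
    h <- grDevices::chull(uv[, 1], uv[, 2])
    facets <- NULL
    if (length(h) >= 3L)
        facets <- cbind(h[1], h[2:(length(h) - 1)], h[3:length(h)])
    list(vertices = sort(h), facets = facets, planar = TRUE)
}

#' Test whether points lie inside or on a convex hull
#'
#' @param hull result of [convexHull3()].
#' @param points the points the hull was built from.
#' @param query m x 3 matrix of query points.
#' @param tol boundary tolerance (absolute, um).
#' @return logical vector.
#' @export
hullContains <- function(hull, points, query, tol = 1e-9) {
    if (isTRUE(hull$planar))
        stop("containment test is not defined for a planar hull")
    query <- as.matrix(query)
    planes <- t(apply(hull$facets, 1, facetPlane, points = points))
    d <- query %*% t(planes[, 1:3, drop = FALSE]) -
        matrix(planes[, 4], nrow(query), nrow(planes), byrow = TRUE)
    apply(d <= tol, 1, all)
}
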