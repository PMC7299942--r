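## Result figures. Content mirrors the pipeline's standard plots (bundle
## top/side views, per-row registered point clouds with beads, histogram
## heat maps); styling is deliberately simple base graphics. Every PNG is
## accompanied by a JSON description naming the plot type, the data files
## it was drawn from and the parameters, so a figure can be re-created
## from Tables alone.

## orthographic projection of 3D points for a (azimuth, elevation) view
projectView <- function(points, viewDirection) {
    az <- viewDirection[1] * pi / 180
    el <- viewDirection[2] * pi / 180
    ## viewing along -(cos el cos az, cos el sin az, sin el)
    right <- c(-sin(az), cos(az), 0)
    up <- c(-sin(el) * cos(az), -sin(el) * sin(az), cos(el))
    cbind(points %*% right, points %*% up)
}

figDescription <- function(path, type, params) {
    jsonlite::write_json(c(list(figure = type), params),
        sub("\\.png$", ".json", path), auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
}

openFig <- function(path, plot) {
    grDevices::png(path, width = 900, height = 700)
    graphics::par(bg = plot@backgroundColor,
                  fg = if (plot@backgroundColor == "black") "white" else "black",
                  col.axis = if (plot@backgroundColor == "black") "white" else "black",
                  col.lab = if (plot@backgroundColor == "black") "white" else "black",
                  col.main = if (plot@backgroundColor == "black") "white" else "black")
    invisible(path)
}

plotRowCloud <- function(path, beads, hull, rowId, plot) {
    openFig(path, plot)
    on.exit(grDevices::dev.off())
    pts <- rbind(hull, beads)
    if (is.null(pts) || nrow(pts) == 0L) {
        graphics::plot.new()
        graphics::title(main = sprintf("row %s: no data", rowId))
        return(invisible(path))
    }
    pr <- projectView(pts, plot@viewDirection)
    graphics::plot(pr[, 1], pr[, 2], type = "n", asp = 1,
        xlab = "view x (um)", ylab = "view y (um)",
        main = sprintf("row %s registered towers + beads", rowId))
    if (!is.null(hull) && nrow(hull))
        graphics::points(projectView(hull, plot@viewDirection),
            pch = 16, cex = plot@trMarkerSize * 0.4, col = "gray60")
    if (!is.null(beads) && nrow(beads))
        graphics::points(projectView(beads, plot@viewDirection),
            pch = plot@gpMarker, cex = plot@gpMarkerSize * 2, col = "yellow")
    figDescription(path, "row_cloud",
        list(row = rowId, viewDirection = plot@viewDirection,
             nHull = if (is.null(hull)) 0L else nrow(hull),
             nBeads = if (is.null(beads)) 0L else nrow(beads)))
    invisible(path)
}

plotHistogramHeatmap <- function(path, counts, rowId, plot,
                                 what = "bead count") {
    openFig(path, plot)
    on.exit(grDevices::dev.off())
    graphics::image(x = seq_len(ncol(counts)), y = seq_len(nrow(counts)),
        z = t(counts), xlab = "azimuth sector (I..)",
        ylab = "height segment (1 = base)",
        main = sprintf("row %s %s per segment x sector", rowId, what),
        col = grDevices::hcl.colors(32, "inferno"), axes = FALSE)
    graphics::axis(1, at = seq_len(ncol(counts)))
    graphics::axis(2, at = seq_len(nrow(counts)))
    figDescription(path, "histogram_heatmap",
        list(row = rowId, what = what, dims = dim(counts)))
    invisible(path)
}

plotBundleView <- function(path, towerPts, towerIds, beadPts, title, plot,
                           view = c(90, 90), gray = NULL) {
    openFig(path, plot)
    on.exit(grDevices::dev.off())
    all <- do.call(rbind, towerPts)
    if (is.null(all) || nrow(all) == 0L) {
        graphics::plot.new(); graphics::title(main = title)
        return(invisible(path))
    }
    pr <- projectView(all, view)
    graphics::plot(pr[, 1], pr[, 2], type = "n", asp = 1,
        xlab = "view x (um)", ylab = "view y (um)", main = title)
    cols <- grDevices::hcl.colors(max(2L, length(towerPts)), "viridis")
    for (i in seq_along(towerPts)) {
        col <- if (!is.null(gray) && gray[i]) "gray50" else cols[i]
        pp <- projectView(towerPts[[i]], view)
        graphics::points(pp, pch = 16, cex = 0.3, col = col)
        ctr <- colMeans(pp)
        graphics::text(ctr[1], ctr[2], labels = towerIds[i], col = "red",
                       cex = 0.9)
    }
    if (!is.null(beadPts) && nrow(beadPts))
        graphics::points(projectView(beadPts, view), pch = plot@gpMarker,
            cex = plot@gpMarkerSize * 2, col = "yellow")
    figDescription(path, "bundle_view",
        list(title = title, view = view, nTowers = length(towerPts)))
    invisible(path)
}

drawAggregateFigures <- function(agg, figDir, plot) {
    dir.create(figDir, recursive = TRUE, showWarnings = FALSE)
    for (k in names(agg$rows)) {
        plotRowCloud(file.path(figDir, sprintf("row%s_cloud.png", k)),
            agg$rows[[k]]$beads, agg$rows[[k]]$hull, k, plot)
        plotHistogramHeatmap(
            file.path(figDir, sprintf("row%s_counts.png", k)),
            agg$histograms[[k]]@counts, k, plot)
        plotHistogramHeatmap(
            file.path(figDir, sprintf("row%s_density.png", k)),
            agg$densities[[k]]@density, k, plot,
            what = "density (um^-2 cilium^-1)")
    }
    invisible(figDir)
}
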