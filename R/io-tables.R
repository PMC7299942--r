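## Headerless 4-row CSV tables (link + usage), acquisition-log parsing and
## the per-cell result tables.

#' Read a tower link table
#'
#' The file is a headerless comma-separated table with exactly 4 rows
#' (kinocilium, tall, middle, short); column j lists the tower IDs forming
#' bundle column j. Zeros are placeholders. Uniqueness of nonzero IDs is
#' enforced here; existence of the IDs in the companion volume is checked by
#' the pipeline once the volume is loaded.
#'
#' @param path path to `LinkTable.csv`.
#' @return a [LinkTable-class].
#' @export
readLinkTable <- function(path) {
    rows <- readHeaderlessCsv(path)
    if (length(rows) != 4L)
        stop(sprintf("LinkTable must have exactly 4 rows, found %d",
                     length(rows)))
    LinkTable(do.call(rbind, rows))
}

#' Construct a LinkTable from a 4 x N integer matrix
#' @param ids 4 x N integer matrix.
#' @export
LinkTable <- function(ids) {
    ids <- as.matrix(ids)
    storage.mode(ids) <- "integer"
    dimnames(ids) <- NULL
    new("LinkTable", ids = ids)
}

#' Read a tower usage table
#'
#' Binary inclusion table of identical shape as the link table; a flag of 1
#' at a cell whose LinkTable ID is 0 is rejected (there is no tower to
#' include).
#'
#' @param path path to `TowerUsage.csv`.
#' @param link the companion [LinkTable-class].
#' @return a [TowerUsage-class].
#' @export
readTowerUsage <- function(path, link) {
    rows <- readHeaderlessCsv(path)
    if (length(rows) != 4L)
        stop(sprintf("TowerUsage must have exactly 4 rows, found %d",
                     length(rows)))
    flags <- do.call(rbind, rows)
    TowerUsage(flags, link)
}

#' Construct a TowerUsage table, validated against its LinkTable
#' @param flags 4 x N binary matrix.
#' @param link the companion [LinkTable-class].
#' @export
TowerUsage <- function(flags, link) {
    flags <- as.matrix(flags)
    storage.mode(flags) <- "integer"
    dimnames(flags) <- NULL
    if (!identical(dim(flags), dim(link@ids)))
        stop(sprintf("TowerUsage shape (%d x %d) differs from LinkTable (%d x %d)",
            nrow(flags), ncol(flags), nrow(link@ids), ncol(link@ids)))
    obj <- new("TowerUsage", flags = flags)
    bad <- which(flags == 1L & link@ids == 0L)
    if (length(bad))
        stop("TowerUsage flags a tower at cell(s) where the LinkTable ID is 0")
    obj
}

readHeaderlessCsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(l) {
        vals <- suppressWarnings(as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
        if (any(is.na(vals)) || any(vals != round(vals)))
            stop("non-integer cell in table row: ", l)
        as.integer(vals)
    })
}

#' Parse acquisition parameters from a Slice&View project log
#'
#' Recovers the xy pixel size and the milling (z) step from the key/value
#' text the acquisition software writes. The pixel size is computed as
#' `1000 * HFW / width` (HFW = horizontal field width, um) when the log
#' carries a field width and an image width, and taken from an explicit
#' `PixelSize` entry otherwise. `targetthickness` gives the z step.
#' Values in SI metres (e.g. `1.5E-08`) are converted.
#'
#' @param text the log contents, one string or a character vector of lines.
#' @return an [AcquisitionParams-class].
#' @examples
#' p <- parseAcquisitionLog(c("HFW = 14.9 um", "width = 6144",
#'                            "targetthickness = 1.5E-08"))
#' round(p@pixelSizeNm, 2)  # 2.43
#' @export
parseAcquisitionLog <- function(text) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
    grab <- function(key) {
        hit <- grep(paste0("(?i)\\b", key, "\\b"), lines, perl = TRUE,
                    value = TRUE)
        if (!length(hit)) return(NA_real_)
        tail <- sub(paste0("(?i).*", key), "", hit[1], perl = TRUE)
        m <- regmatches(tail, regexpr(
            "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", tail))
        if (!length(m)) return(NA_real_)
        as.numeric(m)
    }
    hfw <- grab("hfw")
    if (!is.na(hfw)) {
        hit <- grep("(?i)\\bhfw\\b", lines, perl = TRUE, value = TRUE)[1]
        if (grepl("(?i)\\bum\\b|µm|μm", hit, perl = TRUE)) {
            ## already micrometres
        } else if (hfw < 0.01) {
            hfw <- hfw * 1e6  # metres -> um
        }
    }
    widthPx <- grab("width")
    pixelSize <- grab("pixelsize")
    if (!is.na(pixelSize) && pixelSize < 1e-3)
        pixelSize <- pixelSize * 1e9  # metres -> nm
    zStep <- grab("targetthickness")
    if (is.na(zStep))
        stop("acquisition log has no 'targetthickness' entry")
    zStepNm <- if (zStep < 1e-3) zStep * 1e9 else zStep
    if (!is.na(hfw) && !is.na(widthPx)) {
        pixelSizeNm <- 1000 * hfw / widthPx
    } else if (!is.na(pixelSize)) {
        pixelSizeNm <- pixelSize
    } else {
        stop("acquisition log has neither HFW+width nor an explicit PixelSize")
    }
    new("AcquisitionParams", hfwUm = hfw, widthPx = widthPx,
        zStepNm = zStepNm, pixelSizeNm = pixelSizeNm)
}

## -- result tables ---------------------------------------------------------

## fixed-format numeric CSV writer: C locale decimal point, deterministic
## 12-significant-digit rendering, no quoting
writeNumericCsv <- function(df, path) {
    cols <- lapply(df, function(col) {
        if (is.numeric(col) && !is.integer(col))
            sub("^\\s+", "", format(col, digits = 12, trim = TRUE,
                                    scientific = FALSE))
        else as.character(col)
    })
    lines <- c(paste(names(df), collapse = ","),
               if (nrow(df)) do.call(paste, c(cols, sep = ",")))
    writeLines(lines, path)
    invisible(path)
}

readNumericCsv <- function(path) {
    utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write the per-cell result tables
#'
#' Emits, for every bundle row k present in `results`: `AgrGPRow{k}.csv`
#' (registered bead coordinates), `AgrTwrRow{k}.csv` (aggregated tower
#' convex-hull coordinates), `HtRadRow{k}.csv` (per-tower height and
#' radius), plus one `AvgHeightAndRadius.csv` summary across rows.
#'
#' @param results list with an element `rows` (named list per row id, each
#'   with matrices/data frames `beads`, `hull`, `htRad`) and a data frame
#'   `summary` with columns row, avgHeight, avgRadius, nTowers.
#' @param outDir output directory (created if needed).
#' @return character vector of the files written.
#' @export
writeResultsTables <- function(results, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    written <- character(0)
    for (k in names(results$rows)) {
        rr <- results$rows[[k]]
        p1 <- file.path(outDir, sprintf("AgrGPRow%s.csv", k))
        writeNumericCsv(as.data.frame(rr$beads), p1)
        p2 <- file.path(outDir, sprintf("AgrTwrRow%s.csv", k))
        writeNumericCsv(as.data.frame(rr$hull), p2)
        p3 <- file.path(outDir, sprintf("HtRadRow%s.csv", k))
        writeNumericCsv(as.data.frame(rr$htRad), p3)
        written <- c(written, p1, p2, p3)
    }
    summ <- results$summary
    if (is.null(summ))
        summ <- data.frame(row = integer(0), avgHeight = numeric(0),
                           avgRadius = numeric(0), nTowers = integer(0))
    p <- file.path(outDir, "AvgHeightAndRadius.csv")
    writeNumericCsv(summ, p)
    c(written, p)
}
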