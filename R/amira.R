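## AmiraMesh label-field I/O.
##
## Only the dialect the segmentation software emits for label fields is
## supported: a binary little-endian AmiraMesh file with an ASCII header, a
## uniform-coordinate `Lattice` of `byte` samples, and a data section that is
## either raw or HxByteRLE encoded. Anything else is rejected loudly.

AMIRA_MAGIC <- "# AmiraMesh BINARY-LITTLE-ENDIAN 2.1"

## -- byte run-length codec -------------------------------------------------
##
## HxByteRLE stream: a control byte c, then
##   c <= 127 : the next single byte is repeated c times;
##   c >= 128 : the next (c - 128) bytes are copied verbatim.
## A control byte of 0 never occurs in a well-formed stream.

#' Encode bytes with the Amira byte run-length scheme
#'
#' @param bytes raw vector.
#' @return raw vector of the encoded stream.
#' @keywords internal
rleEncodeBytes <- function(bytes) {
    if (length(bytes) == 0L) return(raw(0))
    r <- rle(as.integer(bytes))
    out <- raw(0)
    chunks <- list()
    litBuf <- integer(0)
    flushLit <- function() {
        while (length(litBuf) > 0L) {
            n <- min(127L, length(litBuf))
            chunks[[length(chunks) + 1L]] <<- as.raw(c(128L + n, litBuf[seq_len(n)]))
            litBuf <<- litBuf[-seq_len(n)]
        }
    }
    for (i in seq_along(r$lengths)) {
        len <- r$lengths[i]; val <- r$values[i]
        if (len == 1L) {
            litBuf <- c(litBuf, val)
        } else {
            flushLit()
            while (len > 0L) {
                n <- min(127L, len)
                chunks[[length(chunks) + 1L]] <- as.raw(c(n, val))
                len <- len - n
            }
        }
    }
    flushLit()
    do.call(c, chunks)
}

#' Decode an Amira byte run-length stream
#'
#' @param stream raw vector.
#' @param expectedLength decoded length; a mismatch signals corruption.
#' @return raw vector of `expectedLength` bytes.
#' @keywords internal
rleDecodeBytes <- function(stream, expectedLength) {
    out <- raw(expectedLength)
    pos <- 1L; opos <- 1L
    ns <- length(stream)
    while (opos <= expectedLength) {
        if (pos > ns)
            stop("corrupt HxByteRLE stream: ran out of input")
        ctrl <- as.integer(stream[pos]); pos <- pos + 1L
        if (ctrl == 0L)
            stop("corrupt HxByteRLE stream: zero control byte")
        if (ctrl <= 127L) {
            if (pos > ns) stop("corrupt HxByteRLE stream: truncated run")
            if (opos + ctrl - 1L > expectedLength)
                stop("corrupt HxByteRLE stream: decoded length mismatch")
            out[opos:(opos + ctrl - 1L)] <- stream[pos]
            pos <- pos + 1L; opos <- opos + ctrl
        } else {
            n <- ctrl - 128L
            if (pos + n - 1L > ns)
                stop("corrupt HxByteRLE stream: truncated literal block")
            if (opos + n - 1L > expectedLength)
                stop("corrupt HxByteRLE stream: decoded length mismatch")
            out[opos:(opos + n - 1L)] <- stream[pos:(pos + n - 1L)]
            pos <- pos + n; opos <- opos + n
        }
    }
    if (pos <= ns)
        stop("corrupt HxByteRLE stream: trailing bytes after decoded lattice")
    out
}

## -- header ---------------------------------------------------------------

amiraHeader <- function(dims, voxelSizeNm, dataRef) {
    ext <- dims * voxelSizeNm / 1000  # bounding box in um, voxel-edge aligned
    paste0(
        AMIRA_MAGIC, "\n\n\n",
        sprintf("define Lattice %d %d %d\n\n", dims[1], dims[2], dims[3]),
        "Parameters {\n",
        "    Content \"", sprintf("%dx%dx%d byte, uniform coordinates",
                                  dims[1], dims[2], dims[3]), "\",\n",
        sprintf("    BoundingBox 0 %.9g 0 %.9g 0 %.9g,\n",
                ext[1], ext[2], ext[3]),
        "    CoordType \"uniform\"\n",
        "}\n\n",
        "Lattice { byte Labels } ", dataRef, "\n\n",
        "# Data section follows\n@1\n")
}

parseAmiraHeader <- function(header) {
    lines <- strsplit(header, "\n", fixed = TRUE)[[1]]
    if (!grepl("^#\\s*AmiraMesh", lines[1]))
        stop("not an AmiraMesh file (missing magic line)")
    if (!grepl("BINARY-LITTLE-ENDIAN", lines[1]))
        stop("unsupported AmiraMesh flavour: ", lines[1])
    defLine <- grep("^\\s*define\\s+Lattice\\s+", lines, value = TRUE)
    if (length(defLine) != 1L)
        stop("malformed AmiraMesh header: expected one 'define Lattice' line")
    dims <- as.integer(strsplit(trimws(sub(".*define\\s+Lattice", "", defLine)),
                                "\\s+")[[1]])
    if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0L))
        stop("malformed AmiraMesh header: bad lattice dimensions")
    latLine <- grep("Lattice\\s*\\{", lines, value = TRUE)
    if (length(latLine) != 1L)
        stop("malformed AmiraMesh header: expected one lattice declaration")
    if (!grepl("\\{\\s*byte\\b", latLine))
        stop("unsupported AmiraMesh sample type (only 'byte' labels are supported)")
    encoding <- "raw"; encodedLength <- NA_integer_
    m <- regmatches(latLine, regexec("@1\\(HxByteRLE,\\s*(\\d+)\\)", latLine))[[1]]
    if (length(m) == 2L) {
        encoding <- "HxByteRLE"
        encodedLength <- as.integer(m[2])
    } else if (grepl("@1\\(", latLine)) {
        stop("unsupported AmiraMesh data encoding in: ", trimws(latLine))
    } else if (!grepl("@1", latLine)) {
        stop("malformed AmiraMesh header: lattice has no data reference")
    }
    bbox <- NULL
    bbLine <- grep("BoundingBox", lines, value = TRUE)
    if (length(bbLine) >= 1L) {
        nums <- suppressWarnings(as.numeric(strsplit(
            gsub("[,}]", " ", sub(".*BoundingBox", "", bbLine[1])), "\\s+")[[1]]))
        nums <- nums[!is.na(nums)]
        if (length(nums) == 6L) bbox <- nums
    }
    list(dims = dims, encoding = encoding, encodedLength = encodedLength,
         bbox = bbox)
}

## -- public readers / writers ---------------------------------------------

#' Read a label volume from an AmiraMesh or multipage TIFF file
#'
#' AmiraMesh files must be the label-field dialect: ASCII header, uniform
#' `Lattice` of `byte` samples, raw or `HxByteRLE` body. The voxel size is
#' recovered from the header's `BoundingBox` when present; an explicit
#' `voxelSize` argument overrides it. TIFF files are read as one z slice per
#' page and require `voxelSize`.
#'
#' @param path file path (`.am` or `.tif`/`.tiff`).
#' @param voxelSize numeric length-3 (x, y, z) in nm; optional for AmiraMesh
#'   files with a bounding box.
#' @return a [LabelVolume-class].
#' @seealso [writeLabelVolume()]
#' @export
readLabelVolume <- function(path, voxelSize = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (grepl("\\.tiff?$", path, ignore.case = TRUE))
        return(readLabelTiff(path, voxelSize))
    bytes <- readBin(path, "raw", n = file.size(path))
    marker <- charToRaw("\n@1\n")
    hdrEnd <- findRawSeq(bytes, marker)
    if (is.na(hdrEnd))
        stop("malformed AmiraMesh file: no data section marker")
    header <- rawToChar(bytes[seq_len(hdrEnd - 1L)])
    info <- parseAmiraHeader(header)
    body <- bytes[(hdrEnd + length(marker)):length(bytes)]
    ## tolerate a single trailing newline after the data block
    nvox <- prod(info$dims)
    if (info$encoding == "raw") {
        if (length(body) == nvox + 1L && body[length(body)] == charToRaw("\n"))
            body <- body[-length(body)]
        if (length(body) != nvox)
            stop(sprintf("corrupt AmiraMesh body: %d bytes for %d voxels",
                         length(body), nvox))
        decoded <- body
    } else {
        if (length(body) == info$encodedLength + 1L &&
            body[length(body)] == charToRaw("\n"))
            body <- body[-length(body)]
        if (length(body) != info$encodedLength)
            stop(sprintf(
                "corrupt AmiraMesh body: declared %d encoded bytes, found %d",
                info$encodedLength, length(body)))
        decoded <- rleDecodeBytes(body, nvox)
    }
    data <- array(as.integer(decoded), dim = info$dims)
    if (is.null(voxelSize)) {
        if (is.null(info$bbox))
            stop("AmiraMesh file has no BoundingBox; supply voxelSize")
        ext <- info$bbox[c(2, 4, 6)] - info$bbox[c(1, 3, 5)]
        voxelSize <- 1000 * ext / info$dims
    }
    LabelVolume(data, voxelSize)
}

#' Write a label volume as AmiraMesh (raw or byte-RLE) or multipage TIFF
#'
#' The written file round-trips bit-exactly through [readLabelVolume()].
#' Both formats store one byte per voxel, so labels must be <= 255.
#'
#' @param vol a [LabelVolume-class].
#' @param path output path.
#' @param format `"amira_rle"`, `"amira_raw"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path, format = c("amira_rle", "amira_raw",
                                                   "tiff")) {
    format <- match.arg(format)
    stopifnot(is(vol, "LabelVolume"))
    if (length(vol@data) && max(vol@data) > 255L)
        stop("labels exceed 255 and do not fit one byte per voxel")
    if (format == "tiff") return(writeLabelTiff(vol, path))
    dims <- dim(vol@data)
    bytes <- as.raw(as.vector(vol@data))
    if (format == "amira_rle") {
        enc <- rleEncodeBytes(bytes)
        hdr <- amiraHeader(dims, vol@voxelSize,
                           sprintf("@1(HxByteRLE,%d)", length(enc)))
        body <- enc
    } else {
        hdr <- amiraHeader(dims, vol@voxelSize, "@1")
        body <- bytes
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sub("\n@1\n$", "", hdr)), con)
    writeBin(charToRaw("\n@1\n"), con)
    writeBin(body, con)
    writeBin(charToRaw("\n"), con)
    invisible(path)
}

readLabelTiff <- function(path, voxelSize) {
    if (is.null(voxelSize))
        stop("voxelSize is required when reading TIFF label stacks")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- dim(pages[[1]])
    if (!all(vapply(pages, function(p) identical(dim(p), dims), logical(1))))
        stop("TIFF pages differ in size")
    data <- array(0L, dim = c(dims[2], dims[1], length(pages)))
    for (k in seq_along(pages)) data[, , k] <- t(pages[[k]])
    LabelVolume(data, voxelSize)
}

writeLabelTiff <- function(vol, path) {
    pages <- lapply(seq_len(dim(vol@data)[3]),
                    function(k) t(vol@data[, , k]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none",
                    reduce = FALSE)
    invisible(path)
}

## first occurrence of a raw subsequence, NA if absent
findRawSeq <- function(haystack, needle) {
    hits <- which(haystack == needle[1])
    for (h in hits) {
        if (h + length(needle) - 1L > length(haystack)) next
        if (identical(haystack[h:(h + length(needle) - 1L)], needle))
            return(h)
    }
    NA_integer_
}
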