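## Shared fixtures and independent reference implementations (oracles).

## -- independent byte-RLE reference codec (naive, loop-based) -------------
## Distinct implementation from the package: encodes runs greedily byte by
## byte; used as the round-trip oracle for the AmiraMesh body codec.
refRleEncode <- function(bytes) {
    v <- as.integer(bytes)
    out <- integer(0)
    i <- 1L
    while (i <= length(v)) {
        run <- 1L
        while (i + run <= length(v) && v[i + run] == v[i] && run < 127L)
            run <- run + 1L
        if (run >= 2L) {
            out <- c(out, run, v[i])
            i <- i + run
        } else {
            lit <- v[i]; i <- i + 1L
            while (i <= length(v) && length(lit) < 127L &&
                   (i == length(v) || v[i] != v[i + 1L])) {
                lit <- c(lit, v[i]); i <- i + 1L
            }
            out <- c(out, 128L + length(lit), lit)
        }
    }
    as.raw(out)
}

refRleDecode <- function(stream) {
    v <- as.integer(stream)
    out <- integer(0)
    i <- 1L
    while (i <= length(v)) {
        ctrl <- v[i]; i <- i + 1L
        if (ctrl <= 127L) {
            out <- c(out, rep(v[i], ctrl)); i <- i + 1L
        } else {
            n <- ctrl - 128L
            out <- c(out, v[i:(i + n - 1L)]); i <- i + n
        }
    }
    as.raw(out)
}

## -- geometry fixtures ------------------------------------------------------

## a solid axis-aligned cylinder label volume (single label)
cylinderVolume <- function(r_um = 0.1, h_um = 1.0, voxelNm = c(10, 10, 20),
                           label = 1L, pad_um = 0.08) {
    vs <- voxelNm / 1000
    ext <- c(2 * (r_um + pad_um), 2 * (r_um + pad_um), h_um + 2 * pad_um)
    dims <- as.integer(ceiling(ext / vs))
    ctr <- ext[1:2] / 2
    xs <- (seq_len(dims[1]) - 0.5) * vs[1]
    ys <- (seq_len(dims[2]) - 0.5) * vs[2]
    zs <- (seq_len(dims[3]) - 0.5) * vs[3]
    a <- array(0L, dims)
    inDisc <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`) <= r_um^2
    inZ <- zs >= pad_um & zs <= pad_um + h_um
    for (k in which(inZ)) a[, , k][inDisc] <- label
    LabelVolume(a, voxelNm)
}

## uniform random unit vectors
randomUnitVectors <- function(n) {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
}

## random rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

## lazily built shared validation bundle (written once per test run)
.fixtureEnv <- new.env(parent = emptyenv())

validationCell <- function() {
    if (is.null(.fixtureEnv$cellDir)) {
        spec <- bundleSpec(nColumns = 3, voxelSize = c(16, 16, 24), seed = 11L)
        bundle <- placeValidationBeads(generateBundle(spec))
        dir <- file.path(tempdir(), "goldBundle-fixture-cell")
        unlink(dir, recursive = TRUE)
        writeCellFolder(bundle, dir)
        .fixtureEnv$cellDir <- dir
        .fixtureEnv$bundle <- bundle
    }
    list(dir = .fixtureEnv$cellDir, bundle = .fixtureEnv$bundle)
}
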