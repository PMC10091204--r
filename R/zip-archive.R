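## Minimal store-only ZIP writer. KO packages must travel as single
## archives; entries are written uncompressed (method 0) so the payload
## bytes round-trip exactly, and archives are read back with R's
## internal unzip. Only the features a KO archive needs are implemented:
## flat file entries, no encryption, no zip64.

.crcTable <- local({
    tab <- integer(256L)
    for (n in 0:255) {
        c <- n
        for (k in 1:8) {
            c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1L))
                 else bitwShiftR(c, 1L)
        }
        tab[n + 1L] <- c
    }
    tab
})

## CRC-32 of a raw vector, returned as a nonnegative double
.crc32 <- function(bytes) {
    crc <- -1L
    b <- as.integer(bytes)
    for (i in seq_along(b)) {
        crc <- bitwXor(bitwShiftR(crc, 8L),
                       .crcTable[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
    }
    crc <- bitwXor(crc, -1L)
    if (crc < 0) crc + 2^32 else as.numeric(crc)
}

.le <- function(x, width) {
    out <- raw(width)
    for (i in seq_len(width)) {
        out[i] <- as.raw(x %% 256)
        x <- x %/% 256
    }
    out
}

## fixed DOS timestamp (2020-01-01 00:00) keeps archives byte-reproducible
.dosTime <- .le(0, 2L)
.dosDate <- .le(bitwOr(bitwShiftL(40L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L)), 2L)

#' Write files into a store-only zip archive
#'
#' @param files named list of raw vectors (entry name -> bytes).
#' @param zipfile path of the archive to create.
#' @return `zipfile`, invisibly.
#' @keywords internal
.zipWrite <- function(files, zipfile) {
    stopifnot(length(files) > 0, !is.null(names(files)))
    con <- file(zipfile, "wb")
    on.exit(close(con))
    offsets <- numeric(length(files))
    crcs <- numeric(length(files))
    pos <- 0
    for (i in seq_along(files)) {
        nameRaw <- charToRaw(names(files)[i])
        data <- files[[i]]
        crcs[i] <- .crc32(data)
        offsets[i] <- pos
        hdr <- c(charToRaw("PK\003\004"), .le(20, 2L), .le(0, 2L), .le(0, 2L),
                 .dosTime, .dosDate, .le(crcs[i], 4L),
                 .le(length(data), 4L), .le(length(data), 4L),
                 .le(length(nameRaw), 2L), .le(0, 2L), nameRaw)
        writeBin(hdr, con)
        if (length(data)) writeBin(data, con)
        pos <- pos + length(hdr) + length(data)
    }
    cdStart <- pos
    cdSize <- 0
    for (i in seq_along(files)) {
        nameRaw <- charToRaw(names(files)[i])
        data <- files[[i]]
        cd <- c(charToRaw("PK\001\002"), .le(20, 2L), .le(20, 2L),
                .le(0, 2L), .le(0, 2L), .dosTime, .dosDate,
                .le(crcs[i], 4L), .le(length(data), 4L), .le(length(data), 4L),
                .le(length(nameRaw), 2L), .le(0, 2L), .le(0, 2L),
                .le(0, 2L), .le(0, 2L), .le(0, 4L), .le(offsets[i], 4L),
                nameRaw)
        writeBin(cd, con)
        cdSize <- cdSize + length(cd)
    }
    end <- c(charToRaw("PK\005\006"), .le(0, 2L), .le(0, 2L),
             .le(length(files), 2L), .le(length(files), 2L),
             .le(cdSize, 4L), .le(cdStart, 4L), .le(0, 2L))
    writeBin(end, con)
    invisible(zipfile)
}

## Extract a zip archive into a fresh temp directory; returns the directory.
.zipExtract <- function(zipfile) {
    exdir <- tempfile("koarchive")
    dir.create(exdir)
    utils::unzip(zipfile, exdir = exdir)
    exdir
}

.isZipFile <- function(path) {
    if (dir.exists(path) || !file.exists(path)) return(FALSE)
    con <- file(path, "rb")
    on.exit(close(con))
    sig <- readBin(con, "raw", 4L)
    length(sig) == 4L && identical(sig, charToRaw("PK\003\004"))
}
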