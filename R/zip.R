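# Minimal ZIP (store method) writer.
#
# The build's output archive must be creatable without an external zip
# binary, and none of the installed packages writes zip files, so the
# container format is produced directly: per-member local headers, a
# central directory and the end record, all uncompressed.  Reading back
# goes through utils::unzip (internal method), which gives an independent
# check of the CRCs.

crc32_tab <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  ints <- as.integer(bytes)
  for (b in ints) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_tab[idx + 1L])
  }
  bitwXor(crc, -1L)
}

# fixed DOS timestamp (2020-01-01 00:00:00) for byte-identical archives
DOS_TIME <- 0L
DOS_DATE <- bitwOr(bitwShiftL(40L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L))

#' Write an uncompressed ZIP archive
#'
#' @param path Output file path.
#' @param members Named list; names are member file names, values are
#'   character (written as UTF-8 text) or raw vectors.
#' @return `path`, invisibly.
#' @keywords internal
write_stored_zip <- function(path, members) {
  stopifnot(length(members) > 0L, !is.null(names(members)))
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  offsets <- integer(length(members))
  crcs <- integer(length(members))
  sizes <- integer(length(members))
  pos <- 0L
  for (i in seq_along(members)) {
    data <- members[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
    fname <- charToRaw(names(members)[i])
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    u32(67324752L)            # local file header signature
    u16(20L); u16(0L); u16(0L)  # version, flags, method (store)
    u16(DOS_TIME); u16(DOS_DATE)
    u32(crcs[i]); u32(sizes[i]); u32(sizes[i])
    u16(length(fname)); u16(0L)
    writeBin(fname, con)
    writeBin(data, con)
    pos <- pos + 30L + length(fname) + sizes[i]
  }
  cd_start <- pos
  for (i in seq_along(members)) {
    fname <- charToRaw(names(members)[i])
    u32(33639248L)            # central directory header signature
    u16(20L); u16(20L); u16(0L); u16(0L)
    u16(DOS_TIME); u16(DOS_DATE)
    u32(crcs[i]); u32(sizes[i]); u32(sizes[i])
    u16(length(fname)); u16(0L); u16(0L)
    u16(0L); u16(0L); u32(0L)
    u32(offsets[i])
    writeBin(fname, con)
    pos <- pos + 46L + length(fname)
  }
  u32(101010256L)             # end of central directory
  u16(0L); u16(0L)
  u16(length(members)); u16(length(members))
  u32(pos - cd_start); u32(cd_start)
  u16(0L)
  invisible(path)
}
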