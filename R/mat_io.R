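# Minimal Level 4 (v4) MAT-file reader/writer, enough for the challenge
# signal container: a single real numeric matrix named "val".  The v4
# layout is a 20-byte header of five little-endian int32 (type, mrows,
# ncols, imagf, namelen), the null-terminated variable name, then the data
# column-major.  type = M*1000 + O*100 + P*10 + T with M the byte order
# (0 = little-endian), P the storage class and T = 0 for a numeric matrix.

MAT4_P <- c("double" = 0L, "single" = 1L, "int32" = 2L, "int16" = 3L,
            "uint16" = 4L, "uint8" = 5L)

read_mat_v4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  type <- hdr[1]
  if (type %/% 1000L != 0L)
    stop("unsupported MAT v4 byte order in ", path)
  p <- (type %/% 10L) %% 10L
  if (type %% 10L != 0L)
    stop("MAT v4 variable in ", path, " is not a numeric matrix")
  mrows <- hdr[2]; ncols <- hdr[3]; imagf <- hdr[4]; namelen <- hdr[5]
  name <- rawToChar(readBin(con, "raw", namelen)[seq_len(namelen - 1L)])
  n <- mrows * ncols
  vals <- switch(as.character(p),
    "0" = readBin(con, "double", n, size = 8L, endian = "little"),
    "1" = readBin(con, "double", n, size = 4L, endian = "little"),
    "2" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "3" = readBin(con, "integer", n, size = 2L, signed = TRUE,
                  endian = "little"),
    "4" = readBin(con, "integer", n, size = 2L, signed = FALSE,
                  endian = "little"),
    "5" = readBin(con, "integer", n, size = 1L, signed = FALSE,
                  endian = "little"),
    stop("unsupported MAT v4 storage class ", p, " in ", path))
  if (imagf != 0L)
    readBin(con, "raw", file.size(path))     # drain imaginary part, unused
  list(name = name, data = matrix(vals, mrows, ncols))
}

write_mat_v4 <- function(data, path, name = "val",
                         storage = c("int16", "int32", "double")) {
  storage <- match.arg(storage)
  stopifnot(is.matrix(data))
  con <- file(path, "wb")
  on.exit(close(con))
  type <- MAT4_P[[storage]] * 10L
  writeBin(as.integer(c(type, nrow(data), ncol(data), 0L,
                        nchar(name) + 1L)),
           con, size = 4L, endian = "little")
  writeBin(c(charToRaw(name), as.raw(0L)), con)
  if (storage == "double") {
    writeBin(as.numeric(data), con, size = 8L, endian = "little")
  } else {
    size <- if (storage == "int16") 2L else 4L
    lim <- if (storage == "int16") 32767 else 2147483647
    v <- round(as.numeric(data))
    if (any(abs(v) > lim))
      stop("values exceed ", storage, " range; use a wider storage class")
    writeBin(as.integer(v), con, size = size, endian = "little")
  }
  invisible(path)
}
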