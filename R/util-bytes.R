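# Low-level byte utilities: varints, integer (de)serialisation, checksums.
# All multi-byte integers in the archive are little-endian. Values may exceed
# .Machine$integer.max, so they travel as doubles and are split into bytes
# arithmetically.

CTRL_MAX <- 6L  # opcode byte space 0x01-0x05, escape 0x06

#' Encode non-negative integers as unsigned LEB128 varints
#'
#' @param x numeric vector of non-negative integers (< 2^53)
#' @return raw vector, concatenation of the varints
#' @keywords internal
uleb128_encode <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) return(raw(0))
  if (any(x < 0)) stop("uleb128: negative value")
  nb <- pmax(1L, ceiling(log2(x + 1) / 7))  # bytes per value
  total <- sum(nb)
  out <- raw(total)
  # byte slot positions: value i occupies offset[i] + 1..nb[i]
  off <- cumsum(c(0L, nb[-length(nb)]))
  rem <- x
  alive <- seq_along(x)
  k <- 1L
  while (length(alive)) {
    b <- rem[alive] %% 128
    rem[alive] <- rem[alive] %/% 128
    more <- rem[alive] > 0
    out[off[alive] + k] <- as.raw(b + 128 * more)
    alive <- alive[more]
    k <- k + 1L
  }
  out
}

#' Decode a buffer of unsigned LEB128 varints
#'
#' @param r raw vector containing only whole varints
#' @return numeric vector of decoded values
#' @keywords internal
uleb128_decode <- function(r) {
  if (length(r) == 0L) return(numeric(0))
  v <- as.integer(r)
  cont <- v >= 128L            # continuation bit set
  payload <- v %% 128L
  ends <- !cont
  if (!ends[length(ends)]) stop("uleb128: truncated varint")
  # group id per byte: 1 + number of terminators strictly before this byte
  grp <- c(0L, cumsum(ends))[seq_along(v)] + 1L
  pos <- sequence(rle(grp)$lengths)  # position within each varint, 1-based
  if (any(pos > 8L)) stop("uleb128: varint too long")
  unname(rowsum(payload * 128^(pos - 1), grp)[, 1])
}

# uint32 <-> raw (little endian), vectorised
u32_to_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0 | x >= 2^32)) stop("u32 out of range")
  m <- rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256)
  as.raw(m)
}

raw_to_u32 <- function(r) {
  if (length(r) %% 4L != 0L) stop("u32 stream not a multiple of 4 bytes")
  m <- matrix(as.numeric(r), nrow = 4L)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

# int32 two's complement, little endian
i32_to_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < -2^31 | x >= 2^31)) stop("i32 out of range")
  u32_to_raw(ifelse(x < 0, x + 2^32, x))
}

raw_to_i32 <- function(r) {
  u <- raw_to_u32(r)
  ifelse(u >= 2^31, u - 2^32, u)
}

u16_to_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, x %/% 256))
}

raw_to_u16 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 2L)
  m[1, ] + 256 * m[2, ]
}

#' Adler-32 checksum of a raw vector
#'
#' Running-sum checksum used on every archive section to tell stream
#' corruption apart from a source-digest mismatch.
#' @keywords internal
adler32 <- function(r) {
  MOD <- 65521
  a <- 1; b <- 0
  n <- length(r)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + 999999L)
    x <- as.numeric(r[i:j])
    m <- length(x)
    # b accumulates a for every byte: b' = b + m*a + sum((m - k + 1 - 1) shifted)
    b <- (b + m * a + sum(x * (m - seq_len(m) + 1))) %% MOD
    a <- (a + sum(x)) %% MOD
    i <- j + 1L
  }
  b * 65536 + a
}

md5_raw <- function(r) cli::hash_raw_md5(r)

# Serialise a character vector as [varint n][varint byte-lengths][bytes];
# the on-disk form of a text-typed local buffer.
pack_strings <- function(s) {
  if (length(s) == 0L) return(uleb128_encode(0))
  lens <- nchar(s, type = "bytes")
  c(uleb128_encode(length(s)), uleb128_encode(lens),
    charToRaw(paste(s, collapse = "")))
}

unpack_strings <- function(r) {
  if (length(r) == 0L) return(character(0))
  vals <- uleb128_decode_stream(r)
  n <- vals$values[1]
  if (n == 0) return(character(0))
  if (length(vals$values) < n + 1) stop("corrupt string pack")
  lens <- vals$values[2:(n + 1)]
  used <- vals$ends[n + 1]
  txt <- rawToChar(r[(used + 1):length(r)])
  Encoding(txt) <- "latin1"
  ends <- cumsum(lens)
  substring(txt, c(1, ends[-n] + 1), ends)
}

# Decode varints but also report the byte offset where each value ends
# (needed to find the start of a trailing payload).
uleb128_decode_stream <- function(r) {
  v <- as.integer(r)
  ends_mask <- v < 128L
  payload <- v %% 128L
  grp <- c(0L, cumsum(ends_mask))[seq_along(v)] + 1L
  # keep only complete varints
  ncomplete <- sum(ends_mask)
  keep <- grp <= ncomplete
  grp <- grp[keep]; payload <- payload[keep]
  pos <- sequence(rle(grp)$lengths)
  vals <- unname(rowsum(payload * 128^(pos - 1), grp)[, 1])
  list(values = vals, ends = which(ends_mask))
}

# gzip-transparent whole-file read -> raw vector
read_file_raw <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("cannot read file: ", path)
  r <- readBin(path, "raw", n = sz)
  if (length(r) >= 2 && r[1] == as.raw(0x1f) && r[2] == as.raw(0x8b)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      ch <- readBin(con, "raw", n = 8L * 1024L * 1024L)
      if (!length(ch)) break
      chunks[[length(chunks) + 1L]] <- ch
    }
    r <- unlist(chunks, use.names = FALSE)
    if (is.null(r)) r <- raw(0)
  }
  r
}

raw_to_text <- function(r) {
  if (length(r) == 0L) return("")
  s <- rawToChar(r)
  Encoding(s) <- "latin1"
  s
}
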