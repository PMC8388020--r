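# Codecs. Generic codecs (LZMA, BZ2, ZLIB, STORE) compress any byte stream;
# specific codecs (acgt, domqual, hapmat) transform a data type first and
# hand the result to a generic codec. The selector samples the first ~100 KB
# of a stream once per context/stream and re-uses the winner for all later
# vblocks.

GENERIC_CODECS <- c("LZMA", "BZ2", "ZLIB", "STORE")

# Fixed relative throughput ranks used for the speed side of codec selection.
# Wall-clock timing would make the chosen codec - and therefore the archive
# bytes - vary from run to run; a fixed speed table keeps selection
# deterministic while preserving the fast-vs-strong trade-off.
CODEC_SPEED <- c(LZMA = 1, BZ2 = 3, ZLIB = 8, STORE = 50)

codec_apply <- function(codec, r) {
  switch(codec,
    LZMA  = memCompress(r, "xz"),
    BZ2   = memCompress(r, "bzip2"),
    ZLIB  = memCompress(r, "gzip"),
    STORE = r,
    stop("unknown codec: ", codec))
}

codec_invert <- function(codec, r, uncompressed_len) {
  out <- switch(codec,
    LZMA  = memDecompress(r, "xz"),
    BZ2   = memDecompress(r, "bzip2"),
    ZLIB  = memDecompress(r, "gzip"),
    STORE = r,
    stop("unknown codec: ", codec))
  if (length(out) != uncompressed_len) stop("corrupt archive: codec output length mismatch")
  out
}

#' Select a generic codec for a byte stream by sampling
#'
#' Compresses the first <= 100 KB with every generic codec and keeps the best
#' compression ratio, unless a competitor is within `tol` relative ratio and
#' at least twice as fast, in which case the faster codec wins. `fast` mode
#' widens the tolerance from 5% to 15%. An empty sample selects STORE.
#' @param sample raw vector (at most the first 100 KB of the stream)
#' @param mode "best" or "fast"
#' @return list(codec, sampled_ratio, candidates data.frame)
#' @keywords internal
select_codec <- function(sample, mode = c("best", "fast")) {
  mode <- match.arg(mode)
  if (length(sample) == 0L) {
    return(list(codec = "STORE", sampled_ratio = 1,
                candidates = data.frame(codec = "STORE", ratio = 1)))
  }
  if (length(sample) > 100000L) sample <- sample[seq_len(100000L)]
  sizes <- vapply(GENERIC_CODECS, function(cd) length(codec_apply(cd, sample)), numeric(1))
  ratio <- length(sample) / sizes
  # no codec shrinks the data -> STORE
  if (max(ratio[GENERIC_CODECS != "STORE"]) <= 1) {
    return(list(codec = "STORE", sampled_ratio = 1,
                candidates = data.frame(codec = GENERIC_CODECS, ratio = ratio)))
  }
  tol <- if (mode == "fast") 0.15 else 0.05
  ord <- order(-ratio, match(GENERIC_CODECS, GENERIC_CODECS))  # ratio, then fixed order
  best <- GENERIC_CODECS[ord[1]]
  pick <- best
  for (k in ord[-1]) {
    cand <- GENERIC_CODECS[k]
    if ((ratio[best] - ratio[cand]) / ratio[best] <= tol &&
        CODEC_SPEED[[cand]] >= 2 * CODEC_SPEED[[pick]]) {
      pick <- cand
    }
  }
  list(codec = pick, sampled_ratio = ratio[[pick]],
       candidates = data.frame(codec = GENERIC_CODECS, ratio = as.numeric(ratio)))
}

# --- acgt: 2-bit nucleotide packing ----------------------------------------

ACGT_MAP <- local({
  m <- integer(256)
  m[utf8ToInt("A") + 1L] <- 0L; m[utf8ToInt("C") + 1L] <- 1L
  m[utf8ToInt("G") + 1L] <- 2L; m[utf8ToInt("T") + 1L] <- 3L
  m
})
ACGT_CHARS <- c("A", "C", "G", "T")

#' Pack a nucleotide string into 2 bits per base
#'
#' A->00 C->01 G->10 T->11, four bases per byte (first base in the high
#' bits), final partial byte zero-padded. Bytes outside ACGT pack as A and
#' are recorded in the exception stream as (varint position-delta, byte)
#' pairs so decoding is exact.
#' @param seq character scalar (any bytes)
#' @return list(packed = raw, xcgt = raw, length = n)
#' @keywords internal
codec_acgt_encode <- function(seq) {
  n <- nchar(seq, type = "bytes")
  if (n == 0L) return(list(packed = raw(0), xcgt = raw(0), length = 0L))
  b <- as.integer(charToRaw(seq))
  is_acgt <- b %in% c(65L, 67L, 71L, 84L)
  code <- ACGT_MAP[b + 1L]
  code[!is_acgt] <- 0L
  pad <- (4L - n %% 4L) %% 4L
  if (pad) code <- c(code, integer(pad))
  m <- matrix(code, nrow = 4L)
  packed <- as.raw(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
  xcgt <- raw(0)
  if (any(!is_acgt)) {
    pos <- which(!is_acgt)               # 1-based
    deltas <- diff(c(0L, pos)) - 1L      # gap before each exception
    ex <- rbind_raw(uleb128_encode_list(deltas), as.raw(b[pos]))
    xcgt <- ex
  }
  list(packed = packed, xcgt = xcgt, length = n)
}

# interleave varints with single exception bytes
uleb128_encode_list <- function(x) lapply(x, uleb128_encode)
rbind_raw <- function(varints, bytes) {
  out <- vector("list", 2L * length(bytes))
  out[seq(1, by = 2, length.out = length(bytes))] <- varints
  out[seq(2, by = 2, length.out = length(bytes))] <- as.list(bytes)
  unlist(out, use.names = FALSE)
}

#' Invert the acgt packing
#' @keywords internal
codec_acgt_decode <- function(packed, xcgt, length) {
  if (length == 0L) return("")
  v <- as.integer(packed)
  m <- rbind(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L)
  code <- as.vector(m)[seq_len(length)]
  chars <- c(65L, 67L, 71L, 84L)[code + 1L]
  if (length(xcgt)) {
    # exceptions: (varint gap, byte) pairs
    i <- 1L; pos <- 0L
    n <- length(xcgt)
    while (i <= n) {
      val <- 0; shift <- 0
      repeat {
        byte <- as.integer(xcgt[i]); i <- i + 1L
        val <- val + (byte %% 128L) * 2^shift
        shift <- shift + 7
        if (byte < 128L) break
      }
      pos <- pos + val + 1L
      chars[pos] <- as.integer(xcgt[i]); i <- i + 1L
    }
  }
  s <- rawToChar(as.raw(chars))
  Encoding(s) <- "latin1"
  s
}

# --- domqual: dominant-quality run-length coding ---------------------------

#' Choose the dominant quality score from a sample
#' @keywords internal
domqual_dominant <- function(quals) {
  txt <- paste(quals, collapse = "")
  if (nchar(txt) > 100000L) txt <- substr(txt, 1L, 100000L)
  if (!nchar(txt)) return("F")
  b <- as.integer(charToRaw(txt))
  rawToChar(as.raw(as.integer(names(which.max(table(b))))))
}

#' Encode quality strings as runs of the dominant score plus exceptions
#'
#' Per string: alternating varint run-lengths of the dominant byte and single
#' literal bytes copied to the exception stream. Decoding requires the string
#' lengths (known from the paired sequence at reconstruction time).
#' @return list(runs = raw (varints), exceptions = raw, dom = character)
#' @keywords internal
codec_domqual_encode <- function(quals, dom = NULL) {
  if (length(quals) == 0L) return(list(runs = raw(0), exceptions = raw(0), dom = "F"))
  if (is.null(dom)) dom <- domqual_dominant(quals)
  lens <- nchar(quals, type = "bytes")
  all <- paste(quals, collapse = "")
  b <- charToRaw(all)
  d <- charToRaw(dom)[1]
  isd <- b == d
  total <- length(b)
  ends <- cumsum(lens)
  # exception positions (non-dominant bytes), in order
  expos <- which(!isd)
  # for run-length computation every string is processed independently:
  # run_k = gap between consecutive "stops", where stops are exceptions and
  # string ends. Walk via data.table grouping.
  # Per string the run list is (gap before each exception, trailing run); a
  # zero-length string contributes a single zero run. Computed via grouped
  # exception positions; strings with no rows are filled in afterwards.
  str_id <- rep.int(seq_along(quals), lens)
  runs_per_string <- vector("list", length(quals))
  if (total > 0L) {
    dt <- data.table::data.table(pos = seq_len(total), sid = str_id, exc = !isd)
    walked <- dt[, {
      e <- pos[exc] - pos[1] + 1L       # 1-based within string
      L <- .N
      r <- diff(c(0L, e)) - 1L          # dominant run before each exception
      tail_run <- L - (if (length(e)) e[length(e)] else 0L)
      list(runs = list(c(r, tail_run)))
    }, by = sid]
    runs_per_string[walked$sid] <- walked$runs
  }
  empty <- lengths(runs_per_string) == 0L & lens == 0L
  runs_per_string[empty] <- list(0L)
  runs <- unlist(runs_per_string, use.names = FALSE)
  list(runs = uleb128_encode(runs), exceptions = b[expos], dom = dom)
}

#' Decode domqual given the original string lengths
#'
#' Fully vectorised: run entries cost (run + 1) consumed bytes each except
#' that a string of length L costs exactly L + 1, which partitions the run
#' stream at cumulative-cost boundaries without scanning strings one by one.
#' @keywords internal
codec_domqual_decode <- function(runs_vals, exceptions, dom, lens,
                                 rcur = 1L, ecur = 1L) {
  n <- length(lens)
  if (n == 0L) return(list(values = character(0), rcur = rcur, ecur = ecur))
  bounds <- cumsum(lens + 1)
  avail <- runs_vals[rcur:length(runs_vals)]
  cum <- cumsum(avail + 1)
  nruns <- match(bounds[n], cum)
  if (is.na(nruns)) stop("corrupt archive: quality run stream desynchronised")
  r <- avail[seq_len(nruns)]
  cum <- cum[seq_len(nruns)]
  final <- cum %in% bounds               # runs that close a string
  nexc <- nruns - n
  exc_chars <- character(nruns)
  if (nexc > 0L) {
    s <- rawToChar(exceptions[ecur:(ecur + nexc - 1L)])
    Encoding(s) <- "latin1"
    exc_chars[!final] <- substring(s, seq_len(nexc), seq_len(nexc))
  }
  pieces <- paste0(strrep(dom, r), exc_chars)
  full <- paste(pieces, collapse = "")
  ends <- cumsum(lens)
  out <- substring(full, c(1, ends[-n] + 1), ends)
  Encoding(out) <- "latin1"
  list(values = out, rcur = rcur + nruns, ecur = ecur + nexc)
}

# --- hapmat: haplotype-matrix permutation codec ----------------------------

#' Greedy nearest-neighbour ordering of haplotype rows
#'
#' Starts at row 1 and repeatedly appends the unvisited row with the smallest
#' Hamming distance to the last chosen row (ties -> lowest row index).
#' @param m integer matrix, haplotypes x variants
#' @return integer permutation of row indices
#' @keywords internal
hapmat_order <- function(m) {
  n <- nrow(m)
  if (n <= 2L) return(seq_len(n))
  perm <- integer(n)
  perm[1] <- 1L
  remaining <- setdiff(seq_len(n), 1L)
  last <- 1L
  for (k in 2:n) {
    sub <- m[remaining, , drop = FALSE]
    d <- rowSums(sub != rep(m[last, ], each = length(remaining)))
    pick <- remaining[which.min(d)]
    perm[k] <- pick
    remaining <- setdiff(remaining, pick)
    last <- pick
  }
  perm
}

#' Encode a haplotype matrix: permute rows, emit column-major bytes
#'
#' @param gt integer matrix (allele codes 0-254, 255 = missing/padding)
#' @return list(perm = integer, bytes = raw) column-major after permutation
#' @keywords internal
codec_hapmat_encode <- function(gt) {
  if (!is.matrix(gt)) stop("hapmat: matrix required")
  storage.mode(gt) <- "integer"
  if (nrow(gt) == 0L || ncol(gt) == 0L) {
    return(list(perm = seq_len(nrow(gt)), bytes = raw(0),
                n_hap = nrow(gt), n_var = ncol(gt)))
  }
  if (any(gt < 0L | gt > 255L)) stop("hapmat: allele codes out of range")
  perm <- hapmat_order(gt)
  pm <- gt[perm, , drop = FALSE]
  list(perm = perm, bytes = as.raw(as.vector(pm)),  # column-major
       n_hap = nrow(gt), n_var = ncol(gt))
}

#' Invert the hapmat transform
#' @keywords internal
codec_hapmat_decode <- function(perm, bytes, n_hap, n_var) {
  if (n_hap == 0L || n_var == 0L)
    return(matrix(integer(0), nrow = n_hap, ncol = n_var))
  pm <- matrix(as.integer(bytes), nrow = n_hap, ncol = n_var)
  inv <- integer(n_hap)
  inv[perm] <- seq_len(n_hap)
  pm[inv, , drop = FALSE]
}
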