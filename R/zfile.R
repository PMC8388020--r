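# Archive byte format. A .gcol file is:
#   magic "GCOL1", version byte,
#   sections (each: 37-byte header + codec-compressed payload),
#   trailer: [u32 footer offset][u32 footer length]"GCOLF".
# The footer is a zlib-compressed JSON table of every section, so any single
# section is reachable with two seeks. All integers little-endian; every
# section carries an Adler-32 of its compressed payload to tell archive
# corruption apart from a source-digest mismatch.

GCOL_MAGIC <- charToRaw("GCOL1")
GCOL_FMAGIC <- charToRaw("GCOLF")
GCOL_VERSION <- 1L

SEC_TYPES <- c(FILE_HEADER = 1L, TXT_HEADER = 2L, B250 = 3L, LOCAL = 4L,
               DICT = 5L, RANDOM_ACCESS = 6L, REFERENCE = 7L, FOOTER = 8L)
CODEC_IDS <- c(STORE = 0L, LZMA = 1L, BZ2 = 2L, ZLIB = 3L)
LTYPE_IDS <- c(none = 0L, text = 1L, u8 = 2L, u32 = 3L, i32 = 4L, bits = 5L,
               acgt = 6L, bytes = 7L, domqual = 8L, hapmat = 9L)

new_writer <- function(con) {
  w <- new.env(parent = emptyenv())
  w$con <- con
  w$offset <- 0
  w$entries <- list()
  w
}

writer_emit <- function(w, r) {
  writeBin(r, w$con)
  w$offset <- w$offset + length(r)
  invisible(NULL)
}

#' Write one archive section
#' @keywords internal
write_section <- function(w, type, name = "", vb = 0L, comp = 0L,
                          codec = "STORE", ltype = "none", payload = raw(0)) {
  comp_payload <- codec_apply(codec, payload)
  if (length(comp_payload) >= length(payload) && codec != "STORE") {
    codec <- "STORE"; comp_payload <- payload
  }
  nm <- charToRaw(name)
  if (length(nm) > 16L) stop("context name exceeds 16 bytes: ", name)
  nm <- c(nm, raw(16L - length(nm)))
  hdr <- c(as.raw(SEC_TYPES[[type]]), as.raw(CODEC_IDS[[codec]]),
           as.raw(LTYPE_IDS[[ltype]]), u16_to_raw(comp), u32_to_raw(vb), nm,
           u32_to_raw(length(payload)), u32_to_raw(length(comp_payload)),
           u32_to_raw(adler32(comp_payload)))
  off <- w$offset
  writer_emit(w, hdr)
  writer_emit(w, comp_payload)
  w$entries[[length(w$entries) + 1L]] <-
    list(type = type, name = name, vb = vb, comp = comp, codec = codec,
         ltype = ltype, off = off, ulen = length(payload),
         clen = length(comp_payload))
  invisible(NULL)
}

finish_archive <- function(w) {
  ft <- jsonlite::toJSON(w$entries, auto_unbox = TRUE)
  fr <- memCompress(charToRaw(ft), "gzip")
  foff <- w$offset
  writer_emit(w, fr)
  writer_emit(w, c(u32_to_raw(foff), u32_to_raw(length(fr)), GCOL_FMAGIC))
  invisible(NULL)
}

#' Open an archive and read its section table
#' @keywords internal
gcol_open <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 19) stop("not a gcol archive: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic[1:5], GCOL_MAGIC)) stop("not a gcol archive: ", path)
  seek(con, sz - 13)
  tr <- readBin(con, "raw", 13L)
  if (!identical(tr[9:13], GCOL_FMAGIC)) stop("corrupt archive: bad trailer")
  foff <- raw_to_u32(tr[1:4]); flen <- raw_to_u32(tr[5:8])
  seek(con, foff)
  fr <- readBin(con, "raw", flen)
  entries <- jsonlite::fromJSON(rawToChar(memDecompress(fr, "gzip")),
                                simplifyVector = TRUE)
  arc <- new.env(parent = emptyenv())
  class(arc) <- "gcol_archive"
  arc$path <- path
  arc$size <- sz
  arc$entries <- entries
  hdr <- read_section(arc, which(entries$type == "FILE_HEADER")[1])
  arc$meta <- jsonlite::fromJSON(rawToChar(hdr), simplifyVector = TRUE)
  th <- which(entries$type == "TXT_HEADER")
  arc$components <- lapply(th, function(i) {
    p <- read_section(arc, i)
    nul <- which(p == as.raw(0L))[1]
    meta <- jsonlite::fromJSON(rawToChar(p[seq_len(nul - 1L)]), simplifyVector = TRUE)
    meta$header_text <- if (nul < length(p)) raw_to_text(p[(nul + 1L):length(p)]) else ""
    meta
  })
  arc$ref <- NULL
  arc
}

read_section <- function(arc, i) {
  e <- arc$entries[i, ]
  con <- file(arc$path, "rb")
  on.exit(close(con))
  seek(con, e$off + 37)
  comp <- readBin(con, "raw", e$clen)
  if (adler32(comp) != read_section_adler(arc, con, e))
    stop("corrupt archive: section checksum mismatch (", e$type, " ", e$name, ")")
  codec_invert(e$codec, comp, e$ulen)
}

read_section_adler <- function(arc, con, e) {
  seek(con, e$off + 33)
  raw_to_u32(readBin(con, "raw", 4L))
}

sec_idx <- function(arc, type, name = NULL, vb = NULL, comp = NULL) {
  sel <- arc$entries$type == type
  if (!is.null(name)) sel <- sel & arc$entries$name == name
  if (!is.null(vb)) sel <- sel & arc$entries$vb == vb
  if (!is.null(comp)) sel <- sel & arc$entries$comp == comp
  which(sel)
}

# --- local buffer (de)serialisation ----------------------------------------

serialize_local <- function(ctx) {
  lt <- ctx$local_type
  if (lt == LT_TEXT) {
    s <- unlist(ctx$local, use.names = FALSE)
    if (is.null(s)) s <- character(0)
    return(list(raw = pack_strings(s), ltype = "text", xcgt = NULL))
  }
  if (lt == LT_U8) return(list(raw = as.raw(as.integer(unlist(ctx$local))), ltype = "u8"))
  if (lt == LT_U32) return(list(raw = u32_to_raw(unlist(ctx$local)), ltype = "u32"))
  if (lt == LT_I32) return(list(raw = i32_to_raw(unlist(ctx$local)), ltype = "i32"))
  if (lt == LT_BITS) {
    b <- as.logical(unlist(ctx$local))
    if (is.null(b)) b <- logical(0)
    pad <- (8L - length(b) %% 8L) %% 8L
    return(list(raw = c(u32_to_raw(length(b)), packBits(c(b, rep(FALSE, pad)))),
                ltype = "bits"))
  }
  if (lt == LT_ACGT) {
    s <- paste(unlist(ctx$local, use.names = FALSE), collapse = "")
    enc <- codec_acgt_encode(s)
    return(list(raw = c(u32_to_raw(enc$length), u32_to_raw(length(enc$packed)),
                        enc$packed), ltype = "acgt", xcgt = enc$xcgt))
  }
  if (lt == LT_BYTES) {
    r <- unlist(ctx$local, use.names = FALSE)
    if (is.null(r)) r <- raw(0)
    return(list(raw = r, ltype = "bytes"))
  }
  if (lt == LT_DOMQUAL) {
    dom <- if (is.null(ctx$dom)) "F" else ctx$dom
    r <- unlist(ctx$local, use.names = FALSE)
    if (is.null(r)) r <- raw(0)
    return(list(raw = c(charToRaw(dom), r), ltype = "domqual"))
  }
  if (lt == LT_HAPMAT) {
    if (is.null(ctx$gtmat)) return(list(raw = raw(0), ltype = "hapmat"))
    enc <- codec_hapmat_encode(ctx$gtmat)
    return(list(raw = c(u32_to_raw(enc$n_hap), u32_to_raw(enc$n_var),
                        as.raw(ctx$mp), u32_to_raw(enc$perm), enc$bytes),
                ltype = "hapmat"))
  }
  stop("unknown local type: ", lt)
}

parse_local <- function(r, ltype) {
  o <- new.env(parent = emptyenv())
  o$cur <- 1L
  if (ltype == "text") { o$entries <- unpack_strings(r); return(o) }
  if (ltype == "u8") { o$v <- as.numeric(r); return(o) }
  if (ltype == "u32") { o$v <- raw_to_u32(r); return(o) }
  if (ltype == "i32") { o$v <- raw_to_i32(r); return(o) }
  if (ltype == "bits") {
    n <- raw_to_u32(r[1:4])
    o$v <- if (n > 0) as.logical(rawToBits(r[-(1:4)]))[seq_len(n)] else logical(0)
    return(o)
  }
  if (ltype == "bytes") { o$v <- r; return(o) }
  if (ltype == "domqual") {
    o$dom <- rawToChar(r[1]); o$runs <- uleb128_decode(r[-1]); o$rcur <- 1L
    return(o)
  }
  if (ltype == "hapmat") {
    if (!length(r)) return(o)
    o$n_hap <- raw_to_u32(r[1:4]); o$n_var <- raw_to_u32(r[5:8])
    o$mp <- as.integer(r[9])
    np <- o$n_hap
    o$perm <- as.integer(raw_to_u32(r[10:(9L + 4L * np)]))
    o$bytes <- r[(10L + 4L * np):length(r)]
    o$mat <- NULL
    return(o)
  }
  if (ltype == "acgt") {
    o$ltype_raw <- r   # materialised once the exception stream is loaded
    return(o)
  }
  stop("unknown local type in archive: ", ltype)
}

materialize_acgt <- function(o, xcgt) {
  n <- raw_to_u32(o$ltype_raw[1:4])
  plen <- raw_to_u32(o$ltype_raw[5:8])
  packed <- if (plen > 0) o$ltype_raw[9:(8L + plen)] else raw(0)
  o$txt <- codec_acgt_decode(packed, xcgt, n)
  o$ltype_raw <- NULL
  o
}

# --- vblock section write/load ---------------------------------------------

# choose (and cache) the generic codec for a context stream
stream_codec <- function(zstate, name, stream, sample, mode) {
  key <- paste0(name, "/", stream)
  ch <- get0(key, envir = zstate$codec_choice, inherits = FALSE)
  if (!is.null(ch)) return(ch$codec)
  res <- select_codec(sample, mode)
  assign(key, res, envir = zstate$codec_choice)
  res$codec
}

#' Serialise one segmented+merged vblock as B250/LOCAL sections
#' @keywords internal
write_vblock_sections <- function(w, vb, zstate, comp, mode = "best") {
  # acgt exception streams must land in the paired *_X context before that
  # context is serialised; vb$order guarantees X follows its owner.
  pending_x <- list()
  for (name in vb$order) {
    ctx <- get(name, envir = vb$ctxs)
    if (!is.null(pending_x[[name]])) {
      ctx$local[[length(ctx$local) + 1L]] <- pending_x[[name]]
      ctx$uses_local <- TRUE
    }
    b250 <- ctx$b250_final
    if (length(b250)) {
      payload <- uleb128_encode(b250)
      codec <- stream_codec(zstate, name, "b250", payload, mode)
      write_section(w, "B250", name, vb$id, comp, codec, "none", payload)
    }
    has_local <- switch(ctx$local_type,
                        text = length(ctx$local) > 0L,
                        hapmat = !is.null(ctx$gtmat),
                        length(ctx$local) > 0L)
    if (!has_local) next
    loc <- serialize_local(ctx)
    if (!is.null(loc$xcgt) && length(loc$xcgt)) {
      pending_x[[paste0(name, "_X")]] <- loc$xcgt
    }
    codec <- stream_codec(zstate, name, "local", loc$raw, mode)
    write_section(w, "LOCAL", name, vb$id, comp, codec, loc$ltype, loc$raw)
  }
  invisible(NULL)
}

#' Load one vblock's decode state
#' @keywords internal
load_vblock_state <- function(arc, dicts, vb_id, comp, meta, ref = NULL) {
  b250 <- new.env(parent = emptyenv())
  locals <- new.env(parent = emptyenv())
  sel <- which((arc$entries$type == "B250" | arc$entries$type == "LOCAL") &
                 arc$entries$vb == vb_id & arc$entries$comp == comp)
  acgt_pending <- character(0)
  for (i in sel) {
    e <- arc$entries[i, ]
    payload <- read_section(arc, i)
    if (e$type == "B250") {
      assign(e$name, local({
        env <- new.env(parent = emptyenv())
        env$v <- as.integer(uleb128_decode(payload)); env$cur <- 1L
        env
      }), envir = b250)
    } else {
      o <- parse_local(payload, e$ltype)
      if (e$ltype == "acgt") acgt_pending <- c(acgt_pending, e$name)
      assign(e$name, o, envir = locals)
    }
  }
  for (nm in acgt_pending) {
    o <- get(nm, envir = locals)
    xo <- get0(paste0(nm, "_X"), envir = locals, inherits = FALSE)
    materialize_acgt(o, if (is.null(xo)) raw(0) else xo$v)
  }
  new_vbs(dicts, b250, locals, meta, ref)
}

#' Load the archive's global dictionaries
#' @keywords internal
load_dicts <- function(arc) {
  dicts <- new.env(parent = emptyenv())
  for (i in sec_idx(arc, "DICT")) {
    e <- arc$entries[i, ]
    assign(e$name, dict_deserialize(read_section(arc, i)), envir = dicts)
  }
  dicts
}

# --- reference archive ------------------------------------------------------

#' Preprocess a FASTA file into a reference archive
#'
#' Stores the contig table, the 2-bit-packed concatenated bases and the
#' sampled k-mer index. The result is loadable for both compression and
#' decompression and can be embedded into data archives.
#'
#' @param fasta path to a FASTA file (optionally gzipped)
#' @param out output path (conventionally `.ref.gcol`)
#' @return `out`, invisibly
#' @export
gcol_make_reference <- function(fasta, out) {
  ref <- gcol_load_fasta_reference(fasta)
  con <- file(out, "wb")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(out) })
  w <- new_writer(con)
  writer_emit(w, c(GCOL_MAGIC, as.raw(GCOL_VERSION)))
  meta <- list(format = "ref", vblock_size = 0, files = list())
  write_section(w, "FILE_HEADER", "", 0L, 0L, "ZLIB", "none",
                charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE)))
  write_ref_sections(w, ref)
  finish_archive(w)
  ok <- TRUE
  invisible(out)
}

write_ref_sections <- function(w, ref) {
  cm <- charToRaw(jsonlite::toJSON(ref$contigs, auto_unbox = FALSE))
  write_section(w, "REFERENCE", "RMETA", 0L, 0L, "ZLIB", "none", cm)
  enc <- codec_acgt_encode(ref$bases)
  payload <- c(u32_to_raw(enc$length), u32_to_raw(length(enc$packed)), enc$packed)
  write_section(w, "REFERENCE", "RBASES", 0L, 0L, "LZMA", "acgt", payload)
  write_section(w, "REFERENCE", "RBASES_X", 0L, 0L, "LZMA", "bytes", enc$xcgt)
  idx <- c(u32_to_raw(length(ref$idx_keys)), u32_to_raw(ref$idx_keys),
           as.raw(ref$idx_cnt), u32_to_raw(ref$idx_gpos))
  write_section(w, "REFERENCE", "RIDX", 0L, 0L, "LZMA", "bytes", idx)
  invisible(NULL)
}

#' Load a reference from a reference archive (or embedded sections)
#' @param path a `.ref.gcol` path or an open `gcol_archive`
#' @return a `gcol_reference`, or NULL when no sections are present
#' @export
gcol_load_reference <- function(path) {
  arc <- if (inherits(path, "gcol_archive")) path else gcol_open(path)
  im <- sec_idx(arc, "REFERENCE", "RMETA")
  if (!length(im)) return(NULL)
  contigs <- jsonlite::fromJSON(rawToChar(read_section(arc, im[1])),
                                simplifyVector = TRUE)
  rb <- read_section(arc, sec_idx(arc, "REFERENCE", "RBASES")[1])
  rx <- sec_idx(arc, "REFERENCE", "RBASES_X")
  xr <- if (length(rx)) read_section(arc, rx[1]) else raw(0)
  n <- raw_to_u32(rb[1:4]); plen <- raw_to_u32(rb[5:8])
  bases <- codec_acgt_decode(if (plen) rb[9:(8 + plen)] else raw(0), xr, n)
  ri <- read_section(arc, sec_idx(arc, "REFERENCE", "RIDX")[1])
  nk <- raw_to_u32(ri[1:4])
  at <- 5L
  keys <- raw_to_u32(ri[at:(at + 4L * nk - 1L)]); at <- at + 4L * nk
  cnt <- as.integer(ri[at:(at + nk - 1L)]); at <- at + nk
  gpos <- raw_to_u32(ri[at:length(ri)])
  ref <- new.env(parent = emptyenv())
  class(ref) <- "gcol_reference"
  ref$contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  ref$bases <- bases
  ref$total <- sum(ref$contigs$length)
  ref$idx_keys <- keys; ref$idx_cnt <- cnt
  ref$idx_off <- cumsum(c(0, cnt[-length(cnt)]))
  ref$idx_gpos <- gpos
  ref
}
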