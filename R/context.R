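# Contexts: one per data component. Each holds a dictionary of unique snips,
# a b250 stream of dictionary indices (one per occurrence), and a local byte
# buffer for non-dictionary data. A vblock carries its own context set, cloned
# from the global state and merged back in vblock order, which keeps archive
# bytes independent of how the work is scheduled.

# local buffer types
LT_TEXT <- "text"; LT_U8 <- "u8"; LT_U32 <- "u32"; LT_I32 <- "i32"
LT_BITS <- "bits"; LT_ACGT <- "acgt"; LT_BYTES <- "bytes"
LT_DOMQUAL <- "domqual"; LT_HAPMAT <- "hapmat"

#' Create the global (archive-level) context state
#' @keywords internal
new_zstate <- function() {
  z <- new.env(parent = emptyenv())
  z$ctxs <- new.env(parent = emptyenv())   # name -> global context record
  z$order <- character(0)                  # creation order of contexts
  z$codec_choice <- new.env(parent = emptyenv())  # "name/stream" -> CodecId
  z$aliases <- list()                      # alias name -> target name
  z$ra_entries <- list()                   # random-access index rows
  z
}

z_ctx <- function(zstate, name) {
  g <- get0(name, envir = zstate$ctxs, inherits = FALSE)
  if (is.null(g)) {
    g <- new.env(parent = emptyenv())
    g$name <- name
    g$dict <- character(0)     # global dictionary, append-only
    g$counts <- numeric(0)     # per-snip occurrence counts (whole file)
    assign(name, g, envir = zstate$ctxs)
    zstate$order <- c(zstate$order, name)
  }
  g
}

#' Create a vblock with an empty private context set
#' @keywords internal
new_vblock <- function(vblock_id, zstate) {
  vb <- new.env(parent = emptyenv())
  vb$id <- vblock_id
  vb$zstate <- zstate
  vb$ctxs <- new.env(parent = emptyenv())
  vb$order <- character(0)
  vb$line_count <- 0L
  vb$ra <- list()              # random-access entries, per chromosome
  vb
}

# Resolve aliases (e.g. MC:Z -> @CIGAR) before touching a context.
resolve_alias <- function(zstate, name) {
  tgt <- zstate$aliases[[name]]
  if (is.null(tgt)) name else tgt
}

#' Get or create a vblock-local context (cloned view of the global state)
#'
#' Cloned snips keep their global indices; new snips get provisional indices
#' starting at the global dictionary length, finalised at merge.
#' @keywords internal
vb_ctx <- function(vb, name, local_type = LT_TEXT) {
  name <- resolve_alias(vb$zstate, name)
  ctx <- get0(name, envir = vb$ctxs, inherits = FALSE)
  if (!is.null(ctx)) return(ctx)
  g <- z_ctx(vb$zstate, name)
  ctx <- new.env(parent = emptyenv())
  ctx$name <- name
  ctx$gdict <- g$dict          # snapshot: all prior vblocks merged
  ctx$gn <- length(g$dict)
  ctx$new <- character(0)      # new snips, first-occurrence order
  ctx$b250 <- list()           # chunks of 0-based indices
  ctx$nb250 <- 0
  ctx$local <- list()          # chunks, type per local_type
  ctx$local_type <- local_type
  ctx$local_codec <- NULL      # segmenter-forced codec, else auto
  ctx$allow_singleton <- (local_type == LT_TEXT)
  ctx$uses_local <- FALSE      # set when a seg op writes local directly
  assign(name, ctx, envir = vb$ctxs)
  vb$order <- c(vb$order, name)
  ctx
}

#' Place values directly in a context (vectorised seg of snips)
#'
#' Each distinct payload is stored once in the dictionary; its index is
#' appended to b250 for every occurrence. `encoded = TRUE` marks payloads that
#' already carry an opcode (delta/container/special snips built by callers).
#' @return 0-based dictionary indices, invisibly
#' @keywords internal
ctx_seg <- function(ctx, payload, encoded = FALSE) {
  if (length(payload) == 0L) return(invisible(integer(0)))
  snips <- if (encoded) payload else snip_verbatim(payload)
  known <- c(ctx$gdict, ctx$new)
  idx <- match(snips, known)
  nas <- is.na(idx)
  if (any(nas)) {
    u <- unique(snips[nas])
    base <- length(known)
    ctx$new <- c(ctx$new, u)
    idx[nas] <- base + match(snips[nas], u)
  }
  idx0 <- idx - 1L
  ctx$b250[[length(ctx$b250) + 1L]] <- idx0
  ctx$nb250 <- ctx$nb250 + length(idx0)
  invisible(idx0)
}

#' Append data to a context's local buffer
#' @keywords internal
ctx_local <- function(ctx, values) {
  ctx$uses_local <- TRUE
  ctx$allow_singleton <- FALSE
  ctx$local[[length(ctx$local) + 1L]] <- values
  invisible(NULL)
}

# --- built-in seg algorithms ------------------------------------------------

#' Seg position-like numeric fields as deltas vs the previous value
#'
#' Stores DELTA snips holding pos - anchor; anchor is the previous value in
#' the same context (0 at the start of a vblock, so every vblock reconstructs
#' standalone). Non-numeric values fall back to verbatim snips.
#' @param pos character or numeric vector of the field values, in line order
#' @keywords internal
ctx_seg_pos <- function(ctx, pos) {
  txt <- as.character(pos)
  num <- suppressWarnings(as.numeric(txt))
  # integers only; anything else (or huge) verbatim
  ok <- !is.na(num) & num == floor(num) & abs(num) < 2^53 &
    grepl("^-?[0-9]+$", txt)
  out <- character(length(txt))
  a0 <- if (is.null(ctx$last_pos)) 0 else ctx$last_pos  # carries across calls
  if (any(ok)) {
    v <- num
    v[!ok] <- NA
    anchor <- c(a0, v[-length(v)])
    # carry last numeric anchor across verbatim gaps
    if (anyNA(anchor)) {
      lastv <- a0
      for (i in seq_along(v)) {      # rare path: mixed numeric/non-numeric
        if (ok[i]) { out[i] <- snip_delta(num[i] - lastv); lastv <- num[i] }
      }
    } else {
      out[ok] <- paste0(OP_DELTA, "|",
                        format(num[ok] - anchor[ok], scientific = FALSE, trim = TRUE))
    }
    ctx$last_pos <- num[max(which(ok))]
  }
  if (any(!ok)) out[!ok] <- snip_verbatim(txt[!ok])
  ctx_seg(ctx, out, encoded = TRUE)
}

#' Seg ID fields of the form alphabetic-prefix + number (e.g. "rs23424")
#'
#' The prefix (plus digit-width when leading zeros must be preserved) becomes
#' a dictionary snip; the number goes to the local buffer as uint32. Values
#' that do not match, or whose number is >= 2^32, are stored verbatim.
#' @keywords internal
ctx_seg_id <- function(ctx, ids) {
  m <- regexpr("[0-9]+$", ids)
  haspfx <- m > 0L
  digits <- character(length(ids))
  digits[haspfx] <- regmatches(ids, m)
  num <- suppressWarnings(as.numeric(digits))
  ok <- haspfx & !is.na(num) & num < 2^32 & nchar(digits) <= 10L
  out <- character(length(ids))
  if (any(ok)) {
    pfx <- substr(ids[ok], 1L, nchar(ids[ok]) - nchar(digits[ok]))
    lead0 <- substr(digits[ok], 1L, 1L) == "0" | nchar(digits[ok]) > 10L
    width <- ifelse(lead0, nchar(digits[ok]), 0L)
    out[ok] <- snip_special("i", paste0(width, ":", pfx))
    ctx$id_local <- TRUE
    ctx_local(ctx, num[ok])   # numeric chunk; serialised as u32 at write
  }
  if (any(!ok)) out[!ok] <- snip_verbatim(ids[!ok])
  if (ctx$local_type == LT_TEXT && isTRUE(ctx$id_local)) ctx$local_type <- LT_U32
  ctx_seg(ctx, out, encoded = TRUE)
}

#' Seg numeric values as deltas vs another context on the same line
#'
#' The base context must be emitted earlier in the line's container. Values
#' that are not plain integers are stored verbatim.
#' @keywords internal
ctx_seg_delta_vs <- function(ctx, values, base_values, base_name) {
  txt <- as.character(values)
  num <- suppressWarnings(as.numeric(txt))
  bnum <- suppressWarnings(as.numeric(as.character(base_values)))
  ok <- !is.na(num) & !is.na(bnum) & grepl("^-?[0-9]+$", txt)
  out <- character(length(txt))
  if (any(ok)) {
    out[ok] <- paste0(OP_DELTA, base_name, "|",
                      format(num[ok] - bnum[ok], scientific = FALSE, trim = TRUE))
  }
  if (any(!ok)) out[!ok] <- snip_verbatim(txt[!ok])
  ctx_seg(ctx, out, encoded = TRUE)
}

# --- merge ------------------------------------------------------------------

#' Merge a segmented vblock's dictionaries into the global state
#'
#' New snips are appended to the global dictionaries in first-occurrence
#' order. A snip occurring exactly once in the vblock and absent globally (a
#' singleton) is not merged: its payload moves to the context's local buffer
#' and its b250 entry is rewritten to the LOOKUP_LOCAL escape snip. Merges
#' must be committed in vblock_id order.
#' @keywords internal
merge_contexts <- function(zstate, vb) {
  for (name in vb$order) {
    ctx <- get(name, envir = vb$ctxs)
    g <- z_ctx(zstate, name)
    # the cloned dictionary must be a prefix of the current global one
    # (append-only growth); a stale clone from a parallel worker is fine,
    # its "new" snips are re-matched against the global dictionary here.
    if (length(g$dict) < ctx$gn) stop("merge committed out of vblock order")
    b250 <- if (length(ctx$b250)) unlist(ctx$b250, use.names = FALSE) else integer(0)
    nnew <- length(ctx$new)
    if (nnew) {
      mg <- match(ctx$new, g$dict)          # present globally already?
      cnt <- tabulate(b250[b250 >= ctx$gn] - ctx$gn + 1L, nbins = nnew)
      verb <- !(substr(ctx$new, 1L, 1L) %in% CTRL_CHARS) |
        substr(ctx$new, 1L, 1L) == OP_ESCAPE
      singleton <- ctx$allow_singleton & cnt == 1L & verb & is.na(mg)
      keep <- is.na(mg) & !singleton
      kept <- ctx$new[keep]
      esc_idx <- match(OP_LOOKUP, c(g$dict, kept))
      if (any(singleton) && is.na(esc_idx)) {
        kept <- c(kept, OP_LOOKUP)
        esc_idx <- length(g$dict) + length(kept)
      }
      # remap provisional indices -> final global indices (0-based)
      map <- integer(nnew)
      map[keep] <- length(g$dict) + seq_len(sum(keep)) - 1L
      map[!is.na(mg)] <- mg[!is.na(mg)] - 1L
      if (any(singleton)) map[singleton] <- esc_idx - 1L
      isnew <- b250 >= ctx$gn
      if (any(isnew)) b250[isnew] <- map[b250[isnew] - ctx$gn + 1L]
      if (any(singleton)) {
        # payloads to local, in b250 occurrence order (each occurs once)
        prov <- which(singleton)
        occ <- which(isnew)
        sidx <- occ[(unlist(ctx$b250, use.names = FALSE)[occ] - ctx$gn + 1L) %in% prov]
        # recover original provisional ids at those positions
        orig <- unlist(ctx$b250, use.names = FALSE)[sidx] - ctx$gn + 1L
        payloads <- ctx$new[orig]
        # strip escape prefix: local stores the raw text
        escd <- substr(payloads, 1L, 1L) == OP_ESCAPE
        payloads[escd] <- substr(payloads[escd], 2L, nchar(payloads[escd]))
        ctx$local[[length(ctx$local) + 1L]] <- payloads
        ctx$uses_local <- TRUE
      }
      # counts + dictionary growth
      g$dict <- c(g$dict, kept)
      g$counts <- c(g$counts, numeric(length(kept)))
    }
    if (length(b250)) {
      tab <- tabulate(b250 + 1L, nbins = length(g$dict))
      if (length(g$counts) < length(g$dict)) g$counts <- c(g$counts, numeric(length(g$dict) - length(g$counts)))
      g$counts <- g$counts + tab
    }
    ctx$b250_final <- b250
  }
  invisible(zstate)
}
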