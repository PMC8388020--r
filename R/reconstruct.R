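# Generic reconstruction. Record layout comes solely from Container snips:
# the reconstructor walks the TOPLEVEL b250, instantiates each line's
# container and pulls one value per item from the named contexts. The only
# format-aware pieces are codec inversion and the SPECIAL-snip handlers
# registered below; adding a new segmenter requires no changes here.

# --- decode-side vblock state ----------------------------------------------

new_vbs <- function(dicts, b250, locals, meta, ref = NULL) {
  vbs <- new.env(parent = emptyenv())
  vbs$dicts <- dicts            # env: name -> character vector
  vbs$b250 <- b250              # env: name -> list(v, cur)
  vbs$locals <- locals          # env: name -> typed local object
  vbs$meta <- meta
  vbs$ref <- ref
  vbs$lastnum <- new.env(parent = emptyenv())
  vbs$cont_cache <- new.env(parent = emptyenv())
  vbs$gt_col_base <- 0
  vbs$line_base <- 0
  vbs$rec_base <- 0             # records of this component before this vblock
  vbs$pair_t1 <- NULL           # mate-1 read titles (paired decode)
  vbs$pair_gpos <- NULL         # mate-1 gpos per record
  vbs$collect_gpos <- NULL
  vbs$collect_t1 <- FALSE
  vbs
}

local_obj <- function(vbs, name) {
  o <- get0(name, envir = vbs$locals, inherits = FALSE)
  if (is.null(o)) stop("corrupt archive: missing local section for context ", name)
  o
}

local_next_text <- function(vbs, name, m) {
  o <- local_obj(vbs, name)
  if (m == 0L) return(character(0))
  v <- o$entries[o$cur:(o$cur + m - 1L)]
  o$cur <- o$cur + m
  v
}

local_next_num <- function(vbs, name, m) {
  o <- local_obj(vbs, name)
  if (m == 0L) return(numeric(0))
  v <- o$v[o$cur:(o$cur + m - 1L)]
  o$cur <- o$cur + m
  v
}

local_next_bits <- function(vbs, name, m) {
  o <- local_obj(vbs, name)
  if (m == 0L) return(logical(0))
  v <- o$v[o$cur:(o$cur + m - 1L)]
  o$cur <- o$cur + m
  v
}

local_next_chars <- function(vbs, name, total, lens) {
  # consume `total` characters from an acgt-decoded stream, split per `lens`
  if (total == 0L) return(rep("", length(lens)))
  o <- local_obj(vbs, name)
  ends <- o$cur - 1L + cumsum(lens)
  starts <- c(o$cur, ends[-length(ends)] + 1L)
  o$cur <- o$cur + total
  out <- substring(o$txt, starts, ends)
  Encoding(out) <- "latin1"
  out
}

# --- special-snip handlers --------------------------------------------------

FAM_MAP <- c(i = "id", P = "plus", q = "domqual", R = "refcopy", G = "gt",
             S = "seq", U = "seq", N = "seq", M = "mate", L = "blob")

h_id <- function(vbs, name, subs, payloads, app_pos, frame) {
  m <- length(payloads)
  nums <- local_next_num(vbs, name, m)
  out <- character(m)
  for (p in unique(payloads)) {
    sel <- payloads == p
    w <- as.integer(sub(":.*$", "", p))
    pfx <- sub("^[0-9]+:", "", p)
    dec <- if (w > 0L) formatC(nums[sel], width = w, flag = "0", format = "d")
           else format(nums[sel], scientific = FALSE, trim = TRUE)
    out[sel] <- paste0(pfx, dec)
  }
  out
}

h_plus <- function(vbs, name, subs, payloads, app_pos, frame) {
  src <- payloads[1]
  paste0("+", frame$vals[[src]][app_pos])
}

h_domqual <- function(vbs, name, subs, payloads, app_pos, frame) {
  src <- payloads[1]
  lens <- nchar(frame$vals[[src]][app_pos], type = "bytes")
  o <- local_obj(vbs, name)
  x <- local_obj(vbs, paste0(name, "_X"))
  res <- codec_domqual_decode(o$runs, x$v, o$dom, lens, o$rcur, x$cur)
  o$rcur <- res$rcur; x$cur <- res$ecur
  res$values
}

h_refcopy <- function(vbs, name, subs, payloads, app_pos, frame) {
  if (is.null(vbs$ref)) stop("archive requires a reference genome for decompression")
  len <- as.numeric(payloads)
  g <- ref_gpos(vbs$ref, frame$vals[["CHROM"]][app_pos],
                as.numeric(frame$vals[["POS"]][app_pos]))
  ref_window(vbs$ref, g, len)
}

h_mate <- function(vbs, name, subs, payloads, app_pos, frame) {
  idx <- vbs$rec_base + vbs$line_base + app_pos
  vbs$pair_t1[idx]
}

h_blob <- function(vbs, name, subs, payloads, app_pos, frame) {
  o <- local_obj(vbs, name)
  len <- as.numeric(payloads)
  if (length(len) != 1L) stop("blob pulls must be single")
  v <- if (len > 0) o$v[o$cur:(o$cur + len - 1L)] else raw(0)
  o$cur <- o$cur + len
  out <- NA_character_
  attr(out, "gcol_raw") <- v
  out
}

h_gt <- function(vbs, name, subs, payloads, app_pos, frame) {
  m <- length(subs)
  o <- local_obj(vbs, name)        # hapmat local of context GT
  if (is.null(o$mat)) {
    o$mat <- codec_hapmat_decode(o$perm, o$bytes, o$n_hap, o$n_var)
  }
  ploidy <- local_next_num(vbs, "GT_PL", m)
  phase <- local_next_text(vbs, "GT_PH", m)
  sidx <- sequence(rle(app_pos)$lengths)     # sample index within line
  col <- vbs$gt_col_base + app_pos
  mp <- o$mp
  out <- character(m)
  for (p in sort(unique(ploidy))) {
    sel <- which(ploidy == p)
    if (p == 0) { out[sel] <- "."; next }
    alle <- matrix("", nrow = length(sel), ncol = p)
    for (j in seq_len(p)) {
      rows <- (sidx[sel] - 1L) * mp + j
      codes <- o$mat[cbind(rows, col[sel])]
      alle[, j] <- ifelse(codes == 254L, ".",
                          format(codes, scientific = FALSE, trim = TRUE))
    }
    if (p == 1) out[sel] <- alle[, 1]
    else {
      acc <- alle[, 1]
      for (j in 2:p) acc <- paste0(acc, substr(phase[sel], j - 1L, j - 1L), alle[, j])
      out[sel] <- acc
    }
  }
  vbs$gt_col_base <- vbs$gt_col_base + max(app_pos)
  out
}

h_seq <- function(vbs, name, subs, payloads, app_pos, frame) {
  m <- length(subs)
  pay <- payloads
  pairdelta <- subs == "U" & grepl("\\*$", pay)
  pay <- sub("\\*$", "", pay)
  lens <- numeric(m)
  isS <- subs == "S"; isU <- subs == "U"; isN <- subs == "N"
  cig <- NULL
  if (any(isS)) {
    cig <- cig_parse(frame$vals[["@CIGAR"]][app_pos[isS]])
    lens[isS] <- vapply(cig, cig_sum, numeric(1), ops = QCONSUME)
  }
  lens[!isS] <- as.numeric(pay[!isS])
  # channel accounting (global pull order)
  nbits <- numeric(m)
  nbits[isU] <- lens[isU]
  if (any(isS)) nbits[isS] <- vapply(cig, cig_sum, numeric(1), ops = BCONSUME)
  bit_tot <- sum(nbits)
  bits <- if (bit_tot > 0) local_next_bits(vbs, name, bit_tot) else logical(0)
  bend <- cumsum(nbits); bstart <- bend - nbits + 1
  zero_cum <- c(0, cumsum(!bits))
  zeros <- zero_cum[bend + 1] - zero_cum[bstart]
  zeros[nbits == 0] <- 0
  noncons <- numeric(m)
  if (any(isS)) noncons[isS] <- vapply(cig, cig_sum, numeric(1), ops = c("I", "S"))
  nref_n <- zeros + noncons
  nref_n[isN] <- lens[isN]
  nref <- local_next_chars(vbs, "NONREF", sum(nref_n), nref_n)
  out <- character(m)
  out[isN] <- nref[isN]
  if (any(isU)) {
    iu <- which(isU)
    g <- numeric(length(iu))
    abs_u <- !pairdelta[iu]
    # GPOS consumed in pull order within each stream
    if (any(abs_u)) g[abs_u] <- local_next_num(vbs, "GPOS", sum(abs_u))
    if (any(!abs_u)) {
      d <- local_next_num(vbs, "GPOSD", sum(!abs_u))
      idx <- vbs$rec_base + vbs$line_base + app_pos[iu[!abs_u]]
      g[!abs_u] <- vbs$pair_gpos[idx] + d
    }
    fwd <- local_next_bits(vbs, "STRAND", length(iu))
    win <- ref_window(vbs$ref, g, lens[iu])
    wraw <- charToRaw(paste(win, collapse = ""))
    bsel <- unlist(lapply(iu, function(i) if (nbits[i]) bstart[i]:bend[i] else integer(0)),
                   use.names = FALSE)
    bvec <- bits[bsel]
    if (any(!bvec)) {
      mm <- charToRaw(paste(nref[iu], collapse = ""))
      wraw[which(!bvec)] <- mm
    }
    full <- rawToChar(wraw); Encoding(full) <- "latin1"
    ends <- cumsum(lens[iu]); starts <- c(1, ends[-length(ends)] + 1)
    vals <- substring(full, starts, ends)
    if (any(!fwd)) vals[!fwd] <- revcomp_fast(vals[!fwd])
    Encoding(vals) <- "latin1"
    out[isU] <- vals
    if (!is.null(vbs$collect_gpos)) {
      vbs$collect_gpos[vbs$line_base + app_pos[iu]] <- g
    }
  }
  if (any(isS)) {
    is_ <- which(isS)
    chrom <- frame$vals[["RNAME"]][app_pos[is_]]
    pos <- as.numeric(frame$vals[["POS"]][app_pos[is_]])
    g0 <- ref_gpos(vbs$ref, chrom, pos)
    for (t in seq_along(is_)) {
      i <- is_[t]
      cm <- cig[[t]]
      bl <- if (nbits[i]) bits[bstart[i]:bend[i]] else logical(0)
      nr <- nref[i]
      nops <- length(cm$op)
      qparts <- character(nops)
      bc <- 0L; rc_ <- 0; nc <- 0L
      for (oi in seq_len(nops)) {
        L <- cm$len[oi]; op <- cm$op[oi]
        if (op %in% BCONSUME) {
          bb <- bl[(bc + 1L):(bc + L)]; bc <- bc + L
          w <- ref_window(vbs$ref, g0[t] + rc_, L); rc_ <- rc_ + L
          ch <- strsplit(w, "", fixed = TRUE)[[1]]
          if (any(!bb)) {
            ch[!bb] <- strsplit(substr(nr, nc + 1L, nc + sum(!bb)), "", fixed = TRUE)[[1]]
            nc <- nc + sum(!bb)
          }
          qparts[oi] <- paste(ch, collapse = "")
        } else if (op %in% c("I", "S")) {
          qparts[oi] <- substr(nr, nc + 1L, nc + L); nc <- nc + L
        } else if (op %in% c("D", "N")) {
          rc_ <- rc_ + L
        }
      }
      out[i] <- paste(qparts, collapse = "")
    }
    Encoding(out) <- "latin1"
  }
  out
}

SPECIAL_HANDLERS <- list(id = h_id, plus = h_plus, domqual = h_domqual,
                         refcopy = h_refcopy, gt = h_gt, seq = h_seq,
                         mate = h_mate, blob = h_blob)

QCONSUME <- c("M", "=", "X", "I", "S")   # query-consuming CIGAR ops
BCONSUME <- c("M", "=", "X")             # ops that get bitmap bits (ref+query)

cig_parse <- function(cigars) {
  lapply(regmatches(cigars, gregexpr("[0-9]+[MIDNSHP=X]", cigars)), function(tok) {
    list(len = as.numeric(sub("[MIDNSHP=X]$", "", tok)),
         op = sub("^[0-9]+", "", tok))
  })
}

cig_sum <- function(cm, ops) sum(cm$len[cm$op %in% ops])

# --- value pulling ----------------------------------------------------------

pull_values <- function(vbs, name, n, frame, app_pos) {
  if (n == 0L) return(character(0))
  bt <- get0(name, envir = vbs$b250, inherits = FALSE)
  if (is.null(bt)) stop("corrupt archive: container references missing context ", name)
  if (bt$cur + n - 1L > length(bt$v)) stop("corrupt archive: b250 underrun in ", name)
  idx <- bt$v[bt$cur:(bt$cur + n - 1L)]
  bt$cur <- bt$cur + n
  dict <- get0(name, envir = vbs$dicts, inherits = FALSE)
  if (is.null(dict) || any(idx + 1L > length(dict)) || any(idx < 0L))
    stop("corrupt archive: b250 index out of dictionary range in ", name)
  snips <- dict[idx + 1L]
  first <- substr(snips, 1L, 1L)
  out <- character(n)
  raws <- NULL
  is_cont <- first == OP_CONT
  is_spec <- first == OP_SPECIAL
  plain <- !is_cont & !is_spec
  if (any(plain)) {
    p <- which(plain)
    f <- first[p]
    verb <- !(f %in% CTRL_CHARS)
    out[p[verb]] <- snips[p[verb]]
    esc <- f == OP_ESCAPE
    if (any(esc)) out[p[esc]] <- substr(snips[p[esc]], 2L, 1000000L)
    lk <- f == OP_LOOKUP
    if (any(lk)) {
      o <- local_obj(vbs, name)
      if (!is.null(o$entries)) out[p[lk]] <- local_next_text(vbs, name, sum(lk))
      else out[p[lk]] <- format(local_next_num(vbs, name, sum(lk)),
                                scientific = FALSE, trim = TRUE)
    }
    dl <- f == OP_DELTA
    if (any(dl)) {
      dp <- p[dl]
      pay <- substr(snips[dp], 2L, 1000000L)
      base <- sub("\\|.*$", "", pay)
      delta <- as.numeric(sub("^[^|]*\\|", "", pay))
      other <- base != ""
      if (any(other)) {
        for (bnm in unique(base[other])) {
          sel <- other & base == bnm
          anch <- as.numeric(frame$vals[[bnm]][app_pos[dp[sel]]])
          out[dp[sel]] <- format(anch + delta[sel], scientific = FALSE, trim = TRUE)
        }
      }
      if (any(!other)) {
        # self-delta: anchor = previous reconstructed numeric value of this
        # context within this vblock (0 at vblock start)
        selfpos <- dp[!other]
        sdelta <- delta[!other]
        lastn <- if (is.null(vbs$lastnum[[name]])) 0 else vbs$lastnum[[name]]
        # values at non-self positions are already in `out` (b250 order);
        # process blocks of consecutive self positions
        allv <- suppressWarnings(as.numeric(out))
        blk <- cumsum(c(1L, diff(selfpos) != 1L))
        for (bi in unique(blk)) {
          pos_b <- selfpos[blk == bi]
          prev <- pos_b[1] - 1L
          v0 <- if (prev >= 1L) {
            pv <- allv[prev]
            if (is.na(pv)) 0 else pv
          } else lastn
          vals <- v0 + cumsum(sdelta[blk == bi])
          out[pos_b] <- format(vals, scientific = FALSE, trim = TRUE)
          allv[pos_b] <- vals
        }
      }
    }
    nums <- suppressWarnings(as.numeric(out[p]))
    valid <- which(!is.na(nums))
    if (length(valid)) vbs$lastnum[[name]] <- nums[valid[length(valid)]]
  }
  if (any(is_spec)) {
    sp <- which(is_spec)
    subs <- substr(snips[sp], 2L, 2L)
    pays <- substr(snips[sp], 3L, 1000000L)
    fams <- FAM_MAP[subs]
    for (fm in unique(fams)) {
      sel <- fams == fm
      h <- SPECIAL_HANDLERS[[fm]]
      v <- h(vbs, name, subs[sel], pays[sel], app_pos[sp[sel]], frame)
      rw <- attr(v, "gcol_raw")
      if (!is.null(rw)) raws <- rw
      out[sp[sel]] <- v
    }
  }
  if (any(is_cont)) {
    cp <- which(is_cont)
    runs <- rle(idx[cp])
    at <- 1L
    for (ri in seq_along(runs$lengths)) {
      len <- runs$lengths[ri]
      pos_r <- cp[at:(at + len - 1L)]
      at <- at + len
      key <- paste0(name, "#", runs$values[ri])
      cont <- get0(key, envir = vbs$cont_cache, inherits = FALSE)
      if (is.null(cont)) {
        cont <- container_deserialize(dict[runs$values[ri] + 1L])
        assign(key, cont, envir = vbs$cont_cache)
      }
      sub <- recon_group(vbs, cont, len)
      out[pos_r] <- sub$text
    }
  }
  if (!is.null(raws)) attr(out, "gcol_raw") <- raws
  out
}

# Reconstruct k applications of a container; returns list(text = chr[k],
# frame) or list(raw = raw vector) for binary single-item containers.
recon_group <- function(vbs, cont, k) {
  R <- cont$repeats
  frame <- new.env(parent = emptyenv())
  frame$vals <- list()
  nit <- length(cont$items)
  item_vals <- vector("list", nit)
  raw_piece <- NULL
  for (ii in seq_len(nit)) {
    it <- cont$items[[ii]]
    if (it$name == "") {
      item_vals[[ii]] <- rep("", k * R)
    } else {
      v <- pull_values(vbs, it$name, k * R, frame,
                       app_pos = rep(seq_len(k), each = R))
      rw <- attr(v, "gcol_raw")
      if (!is.null(rw)) raw_piece <- rw
      item_vals[[ii]] <- v
      if (R == 1) frame$vals[[it$name]] <- v
    }
  }
  if (!is.null(raw_piece)) {
    if (k != 1L || R != 1 || nit != 1L)
      stop("binary blob inside a structured container")
    it <- cont$items[[1]]
    return(list(raw = c(charToRaw(it$prefix), raw_piece, charToRaw(it$sep)),
                frame = frame))
  }
  if (nit == 0L || R == 0) return(list(text = rep("", k), frame = frame))
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    pieces <- vector("list", nit)
    for (ii in seq_len(nit)) {
      it <- cont$items[[ii]]
      v <- item_vals[[ii]][seq.int(r, by = R, length.out = k)]
      pieces[[ii]] <- paste0(it$prefix, v, it$sep)
    }
    reps[[r]] <- do.call(paste0, pieces)
  }
  text <- if (R == 1) reps[[1]]
          else do.call(paste, c(reps, sep = cont$rep_sep))
  Encoding(text) <- "latin1"
  list(text = text, frame = frame)
}

#' Reconstruct one vblock from its decoded context streams
#'
#' @param vbs decode-time vblock state
#' @param n_lines number of TOPLEVEL applications (logical lines)
#' @param collect context names whose per-line values should be returned
#' @return list(lines = character vector (or list with raw pieces),
#'   collected = named list)
#' @keywords internal
reconstruct_vblock <- function(vbs, n_lines, collect = character(0)) {
  bt <- get0("TOPLEVEL", envir = vbs$b250, inherits = FALSE)
  if (is.null(bt)) stop("corrupt archive: missing TOPLEVEL context")
  dict <- get0("TOPLEVEL", envir = vbs$dicts, inherits = FALSE)
  idx <- bt$v
  if (length(idx) != n_lines) stop("corrupt archive: TOPLEVEL length mismatch")
  lines <- character(n_lines)
  raw_out <- NULL
  coll <- stats::setNames(vector("list", length(collect)), collect)
  for (nm in collect) coll[[nm]] <- rep(NA_character_, n_lines)
  runs <- rle(idx)
  at <- 1L
  for (ri in seq_along(runs$lengths)) {
    k <- runs$lengths[ri]
    pos <- at:(at + k - 1L)
    at <- at + k
    vbs$line_base <- pos[1] - 1L
    snip <- dict[runs$values[ri] + 1L]
    if (substr(snip, 1L, 1L) != OP_CONT)
      stop("corrupt archive: TOPLEVEL snip is not a container")
    key <- paste0("TOPLEVEL#", runs$values[ri])
    cont <- get0(key, envir = vbs$cont_cache, inherits = FALSE)
    if (is.null(cont)) {
      cont <- container_deserialize(snip)
      assign(key, cont, envir = vbs$cont_cache)
    }
    bt$cur <- bt$cur + k   # consume TOPLEVEL entries ourselves
    res <- recon_group(vbs, cont, k)
    if (!is.null(res$raw)) {
      raw_out <- c(raw_out, res$raw)
    } else {
      lines[pos] <- res$text
    }
    for (nm in collect) {
      v <- res$frame$vals[[nm]]
      if (!is.null(v)) coll[[nm]][pos] <- v
    }
  }
  list(lines = lines, raw = raw_out, collected = coll)
}
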