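# Sequence encoding against a reference. The aligned path (SAM records with
# RNAME/POS/CIGAR) and the aligner path (FASTQ, unaligned SAM) both decompose
# a read into SQBITMAP (one bit per reference-consuming base: 1 = matches the
# reference), NONREF (mismatching and non-consuming bases) and NONREF_X (the
# acgt exception stream); the aligner path adds GPOS and STRAND.

seq_ctxs <- function(vb) {
  sq <- vb_ctx(vb, "SQBITMAP", LT_BITS)
  nr <- vb_ctx(vb, "NONREF", LT_ACGT)
  nr$local_codec <- "ACGT"
  nx <- vb_ctx(vb, "NONREF_X", LT_BYTES)
  list(sq = sq, nr = nr, nx = nx)
}

#' Segment sequences through the aligner (FASTQ / unaligned SAM)
#'
#' With a reference, each read is placed by [gcol_align()]; placed reads
#' store gpos + strand and a match bitmap, unplaced reads (and every read
#' when no reference is given) store their bases verbatim in NONREF via the
#' acgt codec. Returns per-read gpos (NA when unplaced) for pair-state use.
#' @keywords internal
seg_seq_unaligned <- function(vb, seqs, ref = NULL, pair_gpos = NULL) {
  cs <- seq_ctxs(vb)
  n <- length(seqs)
  lens <- nchar(seqs, type = "bytes")
  if (is.null(ref)) {
    ctx_seg(cs$sq, snip_special("N", format(lens, scientific = FALSE, trim = TRUE)),
            encoded = TRUE)
    ctx_local(cs$nr, seqs)
    return(invisible(rep(NA_real_, n)))
  }
  aln <- gcol_align(seqs, ref)
  A <- which(!is.na(aln$gpos))
  pieces <- character(n)
  pieces[setdiff(seq_len(n), A)] <- seqs[setdiff(seq_len(n), A)]
  snips <- character(n)
  snips[setdiff(seq_len(n), A)] <-
    snip_special("N", format(lens[setdiff(seq_len(n), A)], scientific = FALSE, trim = TRUE))
  if (length(A)) {
    g <- aln$gpos[A]; fwd <- aln$forward[A]
    oriented <- seqs[A]
    if (any(!fwd)) oriented[!fwd] <- revcomp_fast(oriented[!fwd])
    win <- ref_window(ref, g, lens[A])
    rr <- charToRaw(paste(oriented, collapse = ""))
    rw <- charToRaw(paste(win, collapse = ""))
    eq <- rr == rw
    ctx_local(cs$sq, eq)
    mm <- which(!eq)
    if (length(mm)) {
      rid <- rep.int(seq_along(A), lens[A])[mm]
      ch <- rawToChar(rr[mm]); Encoding(ch) <- "latin1"
      chv <- substring(ch, seq_along(mm), seq_along(mm))
      mm_str <- vapply(split(chv, factor(rid, levels = seq_along(A))),
                       paste, character(1), collapse = "")
      pieces[A] <- mm_str
    } else {
      pieces[A] <- ""
    }
    # gpos: absolute, or delta vs the mate when pairing makes it cheap
    pd <- if (!is.null(pair_gpos)) !is.na(pair_gpos[A]) else rep(FALSE, length(A))
    gp <- vb_ctx(vb, "GPOS", LT_U32)
    if (any(!pd)) ctx_local(gp, g[!pd])
    if (any(pd)) {
      gd <- vb_ctx(vb, "GPOSD", LT_I32)
      ctx_local(gd, g[pd] - pair_gpos[A][pd])
    }
    st <- vb_ctx(vb, "STRAND", LT_BITS)
    ctx_local(st, fwd)
    snips[A] <- snip_special("U", paste0(format(lens[A], scientific = FALSE, trim = TRUE),
                                         ifelse(pd, "*", "")))
  }
  nonempty <- nchar(pieces) > 0
  if (any(nonempty)) ctx_local(cs$nr, pieces[nonempty])
  ctx_seg(cs$sq, snips, encoded = TRUE)
  out <- rep(NA_real_, n)
  out[A] <- aln$gpos[A]
  invisible(out)
}

#' Segment aligned SAM sequences (RNAME/POS/CIGAR present)
#' @keywords internal
seg_seq_aligned <- function(vb, seqs, cigars, rnames, poss, ref, line_offset = 0L) {
  cs <- seq_ctxs(vb)
  n <- length(seqs)
  cig <- cig_parse(cigars)
  g0 <- ref_gpos(ref, rnames, as.numeric(poss))
  bits_all <- vector("list", n)
  pieces <- character(n)
  for (i in seq_len(n)) {
    cm <- cig[[i]]
    qlen <- cig_sum(cm, QCONSUME)
    if (qlen != nchar(seqs[i]))
      stop("input format error: CIGAR/SEQ length mismatch at line ",
           line_offset + i)
    if (is.na(g0[i])) stop("input format error: unknown contig ", rnames[i])
    q <- 0L; r <- 0; bl <- logical(0); nrp <- character(0)
    for (oi in seq_along(cm$op)) {
      L <- cm$len[oi]; op <- cm$op[oi]
      if (op %in% BCONSUME) {
        sq <- substr(seqs[i], q + 1L, q + L)
        w <- ref_window(ref, g0[i] + r, L)
        if (g0[i] + r + L > ref$total)
          stop("input format error: POS beyond contig end at line ", line_offset + i)
        eq <- charToRaw(sq) == charToRaw(w)
        bl <- c(bl, eq)
        if (any(!eq)) {
          ch <- strsplit(sq, "", fixed = TRUE)[[1]]
          nrp <- c(nrp, paste(ch[!eq], collapse = ""))
        }
        q <- q + L; r <- r + L
      } else if (op %in% c("I", "S")) {
        nrp <- c(nrp, substr(seqs[i], q + 1L, q + L))
        q <- q + L
      } else if (op %in% c("D", "N")) {
        r <- r + L
      }
    }
    bits_all[[i]] <- bl
    pieces[i] <- paste(nrp, collapse = "")
  }
  ctx_local(cs$sq, unlist(bits_all, use.names = FALSE))
  nonempty <- nchar(pieces) > 0
  if (any(nonempty)) ctx_local(cs$nr, pieces[nonempty])
  ctx_seg(cs$sq, rep(snip_special("S"), n), encoded = TRUE)
  invisible(NULL)
}
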