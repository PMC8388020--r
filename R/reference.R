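# Reference genome support: preprocessing a FASTA into a reference object
# (contig table, concatenated bases, k-mer index), the compression-oriented
# aligner, and gpos arithmetic. gpos is a 0-based 32-bit global coordinate
# over all concatenated contigs; SAM/VCF POS stay 1-based at the format
# boundary.

REF_K <- 14L          # k-mer length
REF_STRIDE <- 4L      # index every 4th reference position
REF_CAP <- 8L         # max candidate gpos per k-mer
REF_QSTRIDE <- 3L     # query stride when voting
REF_MINVOTE <- 2L     # minimum votes to accept a placement

base_codes <- function(txt) {
  b <- as.integer(charToRaw(txt))
  code <- rep(NA_integer_, length(b))
  code[b == 65L] <- 0L; code[b == 67L] <- 1L
  code[b == 71L] <- 2L; code[b == 84L] <- 3L
  code
}

revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# faster reverse-complement for vectors of sequences
revcomp_fast <- function(s) {
  if (!length(s)) return(character(0))
  lens <- nchar(s, type = "bytes")
  b <- charToRaw(paste(s, collapse = ""))
  comp <- b
  sel <- function(from, to) comp[b == charToRaw(from)] <<- charToRaw(to)
  map <- c(A = "T", C = "G", G = "C", T = "A", a = "t", c = "g", g = "c", t = "a")
  for (x in names(map)) sel(x, map[[x]])
  ends <- cumsum(lens); starts <- c(1, ends[-length(ends)] + 1)
  idx <- unlist(lapply(seq_along(s), function(i) if (lens[i]) ends[i]:starts[i] else integer(0)),
                use.names = FALSE)
  out_raw <- comp[idx]
  full <- rawToChar(out_raw); Encoding(full) <- "latin1"
  out <- substring(full, starts, ends)
  Encoding(out) <- "latin1"
  out
}

# k-mer codes for 0-based start positions `starts` over a code vector; NA if
# the window contains a non-ACGT base.
kmer_codes_at <- function(code, starts0) {
  acc <- numeric(length(starts0))
  ok <- rep(TRUE, length(starts0))
  for (j in 0:(REF_K - 1L)) {
    v <- code[starts0 + j + 1L]
    ok <- ok & !is.na(v)
    v[is.na(v)] <- 0L
    acc <- acc + v * 4^(REF_K - 1L - j)
  }
  acc[!ok] <- NA
  acc
}

#' Build a reference object from a FASTA file
#'
#' Contigs are concatenated and addressed by gpos; a k-mer index samples
#' every `REF_STRIDE`-th position, skips k-mers containing non-ACGT bases and
#' caps each candidate list at `REF_CAP` positions.
#'
#' @param fasta path to a (optionally gzipped) FASTA file
#' @return an environment of class `gcol_reference`
#' @export
gcol_load_fasta_reference <- function(fasta) {
  r <- read_file_raw(fasta)
  txt <- raw_to_text(r)
  txt <- gsub("\r", "", txt, fixed = TRUE, useBytes = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("empty or invalid FASTA: ", fasta)
  grp <- cumsum(hdr)
  names_full <- sub("^>", "", lines[hdr])
  cnames <- sub("[ \t].*$", "", names_full)
  if (anyDuplicated(cnames)) stop("duplicate contig names in reference FASTA")
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (sum(lens) == 0) stop("reference FASTA contains no sequence")
  if (sum(lens) >= 2^32) stop("reference exceeds 32-bit gpos space")
  build_reference(cnames, seqs)
}

build_reference <- function(cnames, seqs) {
  lens <- nchar(seqs)
  offs <- cumsum(c(0, lens[-length(lens)]))
  ref <- new.env(parent = emptyenv())
  class(ref) <- "gcol_reference"
  ref$contigs <- data.frame(name = cnames, length = lens, offset = offs,
                            stringsAsFactors = FALSE)
  ref$bases <- paste(seqs, collapse = "")
  ref$total <- sum(lens)
  ref_build_index(ref)
  ref
}

ref_build_index <- function(ref) {
  code <- base_codes(ref$bases)
  n <- ref$total
  offs <- ref$contigs$offset; lens <- ref$contigs$length
  starts0 <- unlist(lapply(seq_len(nrow(ref$contigs)), function(i) {
    if (lens[i] < REF_K) return(integer(0))
    seq.int(offs[i], offs[i] + lens[i] - REF_K, by = REF_STRIDE)
  }), use.names = FALSE)
  kc <- kmer_codes_at(code, starts0)
  keep <- !is.na(kc)
  dt <- data.table::data.table(k = kc[keep], g = starts0[keep])
  data.table::setorder(dt, k, g)
  dt <- dt[, utils::head(.SD, REF_CAP), by = "k"]
  cnt <- dt[, .N, by = "k"]
  ref$idx_keys <- cnt$k
  ref$idx_cnt <- cnt$N
  ref$idx_off <- cumsum(c(0, cnt$N[-length(cnt$N)]))
  ref$idx_gpos <- dt$g
  ref$code <- code
  invisible(ref)
}

#' Map (contig name, 1-based pos) to gpos and back
#' @keywords internal
ref_gpos <- function(ref, rname, pos) {
  i <- match(rname, ref$contigs$name)
  ref$contigs$offset[i] + as.numeric(pos) - 1  # NA rname propagates
}

ref_locate <- function(ref, gpos) {
  # gpos (0-based) -> list(rname, pos 1-based)
  i <- findInterval(gpos, ref$contigs$offset)
  list(rname = ref$contigs$name[i], pos = gpos - ref$contigs$offset[i] + 1)
}

ref_window <- function(ref, gpos, len) {
  substring(ref$bases, gpos + 1, gpos + len)
}

#' Place reads on the reference for compression
#'
#' Votes sampled k-mers of each read and of its reverse complement against
#' the reference index; every candidate implies a start gpos. The placement
#' with most votes wins (ties: smaller gpos, forward over reverse). Gapless:
#' no indels are modelled. Returns NA gpos where fewer than `REF_MINVOTE`
#' k-mers agree or the implied window leaves the contig.
#'
#' @param seqs character vector of reads
#' @param ref a `gcol_reference`
#' @return list(gpos, forward) with NA gpos meaning no alignment
#' @export
gcol_align <- function(seqs, ref) {
  n <- length(seqs)
  out_g <- rep(NA_real_, n); out_f <- rep(TRUE, n)
  if (!n) return(list(gpos = out_g, forward = out_f))
  lens <- nchar(seqs)
  votes <- vector("list", 2L)
  for (strand in 1:2) {
    s <- if (strand == 1L) seqs else revcomp_fast(seqs)
    big <- paste(s, collapse = "")
    code <- base_codes(big)
    ends <- cumsum(lens); starts <- c(0, ends[-n])  # 0-based offsets in big
    qoff <- unlist(lapply(seq_len(n), function(i) {
      if (lens[i] < REF_K) return(integer(0))
      seq.int(0L, lens[i] - REF_K, by = REF_QSTRIDE)
    }), use.names = FALSE)
    qrid <- rep.int(seq_len(n), pmax(0L, (lens - REF_K) %/% REF_QSTRIDE + 1L) * (lens >= REF_K))
    kc <- kmer_codes_at(code, starts[qrid] + qoff)
    ok <- !is.na(kc)
    m <- match(kc[ok], ref$idx_keys)
    hit <- !is.na(m)
    if (!any(hit)) next
    rid <- qrid[ok][hit]; off <- qoff[ok][hit]; mi <- m[hit]
    cnt <- ref$idx_cnt[mi]; base <- ref$idx_off[mi]
    # expand candidate lists
    erid <- rep.int(rid, cnt); eoff <- rep.int(off, cnt)
    gidx <- rep.int(base, cnt) + sequence(cnt)
    g <- ref$idx_gpos[gidx]
    start_g <- g - eoff
    votes[[strand]] <- data.table::data.table(rid = erid, g = start_g,
                                              fwd = (strand == 1L))
  }
  dt <- data.table::rbindlist(votes[!vapply(votes, is.null, logical(1))])
  if (!nrow(dt)) return(list(gpos = out_g, forward = out_f))
  tal <- dt[, .N, by = c("rid", "fwd", "g")]
  data.table::setorder(tal, rid, -N, g, -fwd)
  best <- tal[!duplicated(tal$rid)]
  best <- best[best$N >= REF_MINVOTE & best$g >= 0]
  if (nrow(best)) {
    # window must stay inside one contig
    ci <- findInterval(best$g, ref$contigs$offset)
    cend <- ref$contigs$offset[ci] + ref$contigs$length[ci]
    inside <- best$g + lens[best$rid] <= cend
    best <- best[inside]
    out_g[best$rid] <- best$g
    out_f[best$rid] <- best$fwd
  }
  list(gpos = out_g, forward = out_f)
}
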