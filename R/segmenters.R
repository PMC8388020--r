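# Format-specific segmenters. A segmenter routes every byte of a logical
# line into contexts and registers the line's TOPLEVEL container; the
# reconstructor never needs format knowledge beyond the SPECIAL handlers.
#
# Ordering contract: each context's b250/local streams must be written in
# line order, so heterogeneous layouts are segmented in runs of consecutive
# identical layout (mirroring how the reconstructor walks TOPLEVEL runs).

.gcol_registry <- new.env(parent = emptyenv())

#' Register a segmenter
#'
#' Segmenters are looked up by `detect(filename, head_text)`; the first match
#' wins, unknown inputs fall back to the Generic segmenter. A segmenter added
#' through this registry round-trips with no changes to the reconstructor.
#'
#' @param name segmenter name (also the archive's format tag)
#' @param detect function(filename, head_text) -> logical
#' @param n_header function(lines) -> number of leading header lines
#' @param group number of physical lines per logical line (FASTQ uses 4)
#' @param seg function(vb, lines, st) performing segmentation
#' @param chrom_ctx,pos_ctx context names driving the random-access index
#'   (NULL when the format is not indexed)
#' @export
gcol_register_segmenter <- function(name, detect, seg, n_header = function(lines) 0L,
                                    group = 1L, chrom_ctx = NULL, pos_ctx = NULL) {
  assign(name, list(name = name, detect = detect, seg = seg,
                    n_header = n_header, group = group,
                    chrom_ctx = chrom_ctx, pos_ctx = pos_ctx),
         envir = .gcol_registry)
  invisible(name)
}

gcol_segmenter <- function(name) {
  s <- get0(name, envir = .gcol_registry, inherits = FALSE)
  if (is.null(s)) stop("unknown format: ", name)
  s
}

#' Detect the input format of a file
#'
#' Extension first (ignoring a .gz suffix), then structure sniffing; binary
#' or unrecognised content is handled by the Generic segmenter.
#' @export
gcol_detect_format <- function(path, head_raw = NULL) {
  base <- sub("\\.gz$", "", basename(path), ignore.case = TRUE)
  ext <- tolower(sub("^.*\\.", "", base))
  for (nm in ls(.gcol_registry)) {
    s <- get(nm, envir = .gcol_registry)
    if (!nm %in% c("fastq", "sam", "vcf", "fasta", "generic") &&
        isTRUE(s$detect(path, ""))) return(nm)
  }
  known <- c(fastq = "fastq", fq = "fastq", sam = "sam", vcf = "vcf",
             fa = "fasta", fasta = "fasta", fna = "fasta", ffn = "fasta",
             faa = "fasta")
  if (ext %in% names(known)) return(known[[ext]])
  if (is.null(head_raw)) head_raw <- tryCatch(read_file_raw(path), error = function(e) raw(0))
  head_raw <- utils::head(head_raw, 4096L)
  if (any(head_raw == as.raw(0L))) return("generic")
  txt <- raw_to_text(head_raw)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) return("generic")
  if (grepl("^##fileformat=VCF", lines[1])) return("vcf")
  if (startsWith(lines[1], ">")) return("fasta")
  if (startsWith(lines[1], "@")) {
    if (grepl("^@(HD|SQ|RG|PG|CO)\t", lines[1])) return("sam")
    if (length(lines) >= 3 && startsWith(lines[3], "+")) return("fastq")
    body <- lines[!startsWith(lines, "@")]
    if (length(body) && lengths(regmatches(body[1], gregexpr("\t", body[1]))) >= 10) return("sam")
    return("fastq")
  }
  if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) >= 10) return("sam")
  "generic"
}

# --- shared: read-name tokenizer -------------------------------------------

# Split names into alternating text/number tokens; numbers (no leading zero,
# <= 9 digits) go to a uint32 local via LOOKUP snips, text tokens to
# dictionaries. Returns one serialised container snip per distinct layout.
tok_split <- function(names) {
  strsplit(names, "(?<=[0-9])(?=[^0-9])|(?<=[^0-9])(?=[0-9])", perl = TRUE)
}

tok_numeric <- function(tok) {
  grepl("^[0-9]{1,9}$", tok) & (tok == "0" | !startsWith(tok, "0"))
}

# Segment a run of names sharing one token signature; returns the container.
seg_name_run <- function(vb, toks_mat, sig, ctx_prefix) {
  ntok <- length(sig)
  items <- vector("list", ntok)
  for (j in seq_len(ntok)) {
    vals <- toks_mat[[j]]
    if (sig[j]) {
      cname <- paste0(ctx_prefix, j, "N")
      ctx <- vb_ctx(vb, cname, LT_U32)
      ctx$allow_singleton <- FALSE
      ctx_local(ctx, as.numeric(vals))
      ctx_seg(ctx, rep(OP_LOOKUP, length(vals)), encoded = TRUE)
    } else {
      cname <- paste0(ctx_prefix, j, "T")
      ctx_seg(vb_ctx(vb, cname), vals)
    }
    items[[j]] <- list(name = paste0(ctx_prefix, j, if (sig[j]) "N" else "T"), sep = "")
  }
  items
}

# Segment a vector of names into per-run containers inside context `cctx`.
# extra_items appends items (e.g. a description) to each run's container.
seg_names <- function(vb, cctx_name, names, extra = NULL, extra_vals = NULL) {
  toks <- tok_split(names)
  nt <- lengths(toks)
  sigs <- vapply(seq_along(toks), function(i) {
    paste(as.integer(tok_numeric(toks[[i]])), collapse = "")
  }, character(1))
  key <- paste0(nt, ":", sigs, if (!is.null(extra)) paste0(":", is.na(extra_vals)) else "")
  r <- rle(key)
  pos_end <- cumsum(r$lengths)
  snips <- character(length(names))
  cctx <- vb_ctx(vb, cctx_name)
  for (ri in seq_along(r$lengths)) {
    sel <- (pos_end[ri] - r$lengths[ri] + 1L):pos_end[ri]
    tk <- toks[sel]
    sig <- tok_numeric(tk[[1]])
    mat <- lapply(seq_along(sig), function(j) vapply(tk, `[[`, character(1), j))
    items <- seg_name_run(vb, mat, sig, paste0(cctx_name, "."))
    if (!is.null(extra) && !is.na(extra_vals[sel[1]])) {
      ctx_seg(vb_ctx(vb, extra$name), extra_vals[sel])
      items <- c(items, list(list(name = extra$name, prefix = extra$prefix, sep = "")))
    }
    snips[sel] <- container_serialize(new_container(items))
  }
  ctx_seg(cctx, snips, encoded = TRUE)
  invisible(NULL)
}

# --- FASTQ ------------------------------------------------------------------

seg_fastq <- function(vb, lines, st) {
  n <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L)
    stop("input format error: FASTQ record count not a multiple of 4")
  i0 <- (seq_len(n) - 1L) * 4L
  title <- lines[i0 + 1L]; seqs <- lines[i0 + 2L]
  plus <- lines[i0 + 3L]; qual <- lines[i0 + 4L]
  bad <- which(!startsWith(title, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("input format error: malformed FASTQ record at line ",
         st$line_offset + (bad[1] - 1L) * 4L + 1L)
  tb <- substr(title, 2L, 1000000L)
  recs <- st$recs_done + seq_len(n)
  # title: mate copy when identical to mate 1, else tokenized container
  t1 <- vb_ctx(vb, "T1")
  if (!is.null(st$pair_t1)) {
    same <- !is.na(st$pair_t1[recs]) & tb == st$pair_t1[recs]
  } else same <- rep(FALSE, n)
  sp <- regexpr(" ", tb, fixed = TRUE)
  qn <- ifelse(sp > 0L, substr(tb, 1L, sp - 1L), tb)
  dsc <- ifelse(sp > 0L, substr(tb, sp + 1L, 1000000L), NA)
  if (any(!same)) {
    # runs over (same) so T1 stream stays in record order
    r <- rle(same)
    ends <- cumsum(r$lengths)
    for (ri in seq_along(r$lengths)) {
      sel <- (ends[ri] - r$lengths[ri] + 1L):ends[ri]
      if (r$values[ri]) {
        ctx_seg(t1, rep(snip_special("M"), length(sel)), encoded = TRUE)
      } else {
        seg_names(vb, "T1", qn[sel],
                  extra = list(name = "DESC", prefix = " "), extra_vals = dsc[sel])
      }
    }
  } else {
    ctx_seg(t1, rep(snip_special("M"), n), encoded = TRUE)
  }
  pg <- if (!is.null(st$pair_gpos)) st$pair_gpos[recs] else NULL
  gpos <- seg_seq_unaligned(vb, seqs, st$ref, pair_gpos = pg)
  # '+' line: bare, repeated title, or verbatim
  pl <- vb_ctx(vb, "PLUS")
  psn <- ifelse(plus == "+", "+",
                ifelse(plus == paste0("+", tb), snip_special("P", "T1"),
                       snip_verbatim(plus)))
  ctx_seg(pl, psn, encoded = TRUE)
  seg_qual(vb, st, qual, rep(TRUE, n))
  top <- new_container(list(
    list(name = "T1", prefix = "@", sep = "\n"),
    list(name = "SQBITMAP", sep = "\n"),
    list(name = "PLUS", sep = "\n"),
    list(name = "QUAL", sep = "\n")))
  ctx_seg(vb_ctx(vb, "TOPLEVEL"), rep(container_serialize(top), n), encoded = TRUE)
  vb$line_count <- n
  st$collect_t1[[length(st$collect_t1) + 1L]] <- tb
  st$collect_gpos[[length(st$collect_gpos) + 1L]] <- gpos
  invisible(NULL)
}

# quality strings: dominant-score run-length coding; `use` marks records
# coded with domqual (others must be segged verbatim by the caller).
seg_qual <- function(vb, st, quals, use) {
  qc <- vb_ctx(vb, "QUAL", LT_DOMQUAL)
  qx <- vb_ctx(vb, "QUAL_X", LT_BYTES)
  qc$allow_singleton <- FALSE
  if (is.null(st$zstate$domqual_dom)) {
    st$zstate$domqual_dom <- domqual_dominant(quals[use])
  }
  snips <- character(length(quals))
  if (any(use)) {
    enc <- codec_domqual_encode(quals[use], dom = st$zstate$domqual_dom)
    qc$dom <- enc$dom
    ctx_local(qc, enc$runs)
    ctx_local(qx, enc$exceptions)
    snips[use] <- snip_special("q", "SQBITMAP")
  }
  if (any(!use)) snips[!use] <- snip_verbatim(quals[!use])
  ctx_seg(qc, snips, encoded = TRUE)
}

# --- SAM --------------------------------------------------------------------

seg_sam <- function(vb, lines, st) {
  n <- length(lines)
  fl <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fl) < 11L)
    stop("input format error: SAM line with fewer than 11 fields at line ",
         st$line_offset + 1L)
  need <- fl[[11]]
  short <- which(is.na(need))
  if (length(short))
    stop("input format error: SAM line with fewer than 11 fields at line ",
         st$line_offset + short[1])
  st$zstate$aliases[["MC:Z"]] <- "@CIGAR"
  st$zstate$aliases[["OC:Z"]] <- "@CIGAR"
  seg_names(vb, "QNAME", fl[[1]])
  ctx_seg(vb_ctx(vb, "FLAG"), fl[[2]])
  ctx_seg(vb_ctx(vb, "RNAME"), fl[[3]])
  ctx_seg_pos(vb_ctx(vb, "POS"), fl[[4]])
  ctx_seg(vb_ctx(vb, "MAPQ"), fl[[5]])
  ctx_seg(vb_ctx(vb, "RNEXT"), fl[[7]])
  ctx_seg_delta_vs(vb_ctx(vb, "PNEXT"), fl[[8]], fl[[4]], "POS")
  ctx_seg(vb_ctx(vb, "TLEN"), fl[[9]])
  seqs <- fl[[10]]; quals <- fl[[11]]
  aligned <- fl[[3]] != "*" & fl[[6]] != "*" & fl[[4]] != "0" &
    !is.null(st$ref) & seqs != "*"
  star <- seqs == "*"
  mode <- ifelse(star, 2L, ifelse(aligned & !is.null(st$ref), 1L, 0L))
  r <- rle(mode)
  ends <- cumsum(r$lengths)
  sq <- vb_ctx(vb, "SQBITMAP", LT_BITS)
  for (ri in seq_along(r$lengths)) {
    sel <- (ends[ri] - r$lengths[ri] + 1L):ends[ri]
    if (r$values[ri] == 2L) {
      ctx_seg(sq, rep("*", length(sel)))
    } else if (r$values[ri] == 1L) {
      seg_seq_aligned(vb, seqs[sel], fl[[6]][sel], fl[[3]][sel], fl[[4]][sel],
                      st$ref, line_offset = st$line_offset + sel[1] - 1L)
    } else {
      seg_seq_unaligned(vb, seqs[sel], st$ref)
    }
  }
  seg_qual(vb, st, quals,
           use = !star & quals != "*" & nchar(quals) == nchar(seqs))
  # optional tags: per-layout containers over contexts keyed by "TAG:TYPE"
  has_opt <- length(fl) > 11L
  opt_sig <- rep("", n)
  opt_tags <- NULL
  if (has_opt) {
    opt_tags <- lapply(12:length(fl), function(j) fl[[j]])
    tagid <- lapply(opt_tags, function(v) ifelse(is.na(v), "", substr(v, 1L, 4L)))
    opt_sig <- do.call(paste, c(tagid, list(sep = "|")))
  }
  top_snips <- character(n)
  r2 <- rle(opt_sig)
  ends2 <- cumsum(r2$lengths)
  oc <- vb_ctx(vb, "OPT")
  for (ri in seq_along(r2$lengths)) {
    sel <- (ends2[ri] - r2$lengths[ri] + 1L):ends2[ri]
    sig <- r2$values[ri]
    # @CIGAR is shared with MC:Z/OC:Z aliases, so it is pulled once for the
    # CIGAR field and again inside the OPT container of the same layout run;
    # its stream must therefore be written in layout-run order.
    ctx_seg(vb_ctx(vb, "@CIGAR"), fl[[6]][sel])
    base_items <- list(
      list(name = "QNAME", sep = "\t"), list(name = "FLAG", sep = "\t"),
      list(name = "RNAME", sep = "\t"), list(name = "POS", sep = "\t"),
      list(name = "MAPQ", sep = "\t"), list(name = "@CIGAR", sep = "\t"),
      list(name = "RNEXT", sep = "\t"), list(name = "PNEXT", sep = "\t"),
      list(name = "TLEN", sep = "\t"), list(name = "SQBITMAP", sep = "\t"))
    if (sig == "" || sig == gsub("[^|]", "", sig)) {
      items <- c(base_items, list(list(name = "QUAL", sep = "\n")))
    } else {
      tags <- strsplit(sig, "|", fixed = TRUE)[[1]]
      tags <- tags[tags != ""]
      oitems <- vector("list", length(tags))
      for (tj in seq_along(tags)) {
        tag <- tags[tj]
        cname <- resolve_alias(st$zstate, substr(tag, 1L, 4L))
        vals <- substr(opt_tags[[tj]][sel], 6L, 1000000L)
        ctx_seg(vb_ctx(vb, cname), vals)
        oitems[[tj]] <- list(name = cname, prefix = paste0(tag, ":"),
                             sep = if (tj < length(tags)) "\t" else "")
      }
      ocont <- container_serialize(new_container(oitems))
      ctx_seg(oc, rep(ocont, length(sel)), encoded = TRUE)
      items <- c(base_items, list(list(name = "QUAL", sep = "\t"),
                                  list(name = "OPT", sep = "\n")))
    }
    top_snips[sel] <- container_serialize(new_container(items))
  }
  ctx_seg(vb_ctx(vb, "TOPLEVEL"), top_snips, encoded = TRUE)
  vb$line_count <- n
  vb_record_ra(vb, fl[[3]][fl[[3]] != "*"], as.numeric(fl[[4]][fl[[3]] != "*"]))
  invisible(NULL)
}

vb_record_ra <- function(vb, chrom, pos) {
  if (!length(chrom)) return(invisible(NULL))
  dt <- data.table::data.table(c = chrom, p = pos)
  agg <- dt[, list(mn = min(p), mx = max(p)), by = "c"]
  vb$ra <- lapply(seq_len(nrow(agg)), function(i) {
    list(chrom = agg$c[i], min_pos = agg$mn[i], max_pos = agg$mx[i])
  })
  invisible(NULL)
}

# --- VCF --------------------------------------------------------------------

seg_vcf <- function(vb, lines, st) {
  n <- length(lines)
  ns <- st$n_samples
  fl <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  nf_expect <- 8L + if (ns > 0L) 1L + ns else 0L
  if (length(fl) != nf_expect)
    stop("input format error: VCF has ", length(fl), " columns, expected ",
         nf_expect, " (", ns, " samples)")
  if (ns > 0L) {
    bad <- which(is.na(fl[[nf_expect]]))
    if (length(bad))
      stop("input format error: sample count mismatch at line ",
           st$line_offset + bad[1])
  }
  ctx_seg(vb_ctx(vb, "CHROM"), fl[[1]])
  ctx_seg_pos(vb_ctx(vb, "POS"), fl[[2]])
  ctx_seg_id(vb_ctx(vb, "ID"), fl[[3]])
  # REF vs the reference genome: store a lookup snip when it matches
  refv <- fl[[4]]
  rc <- vb_ctx(vb, "REF")
  if (!is.null(st$ref)) {
    g <- ref_gpos(st$ref, fl[[1]], as.numeric(fl[[2]]))
    ok <- !is.na(g) & g + nchar(refv) <= st$ref$total
    win <- rep(NA_character_, n)
    win[ok] <- ref_window(st$ref, g[ok], nchar(refv[ok]))
    hit <- ok & win == refv
    snips <- ifelse(hit,
                    snip_special("R", format(nchar(refv), scientific = FALSE, trim = TRUE)),
                    snip_verbatim(refv))
    ctx_seg(rc, snips, encoded = TRUE)
  } else ctx_seg(rc, refv)
  ctx_seg(vb_ctx(vb, "ALT"), fl[[5]])
  ctx_seg(vb_ctx(vb, "QUALF"), fl[[6]])
  ctx_seg(vb_ctx(vb, "FILTER"), fl[[7]])
  seg_vcf_info(vb, fl[[8]])
  if (ns > 0L) {
    seg_vcf_samples(vb, st, fl, ns, n)
  } else {
    top <- new_container(list(
      list(name = "CHROM", sep = "\t"), list(name = "POS", sep = "\t"),
      list(name = "ID", sep = "\t"), list(name = "REF", sep = "\t"),
      list(name = "ALT", sep = "\t"), list(name = "QUALF", sep = "\t"),
      list(name = "FILTER", sep = "\t"), list(name = "INFO", sep = "\n")))
    ctx_seg(vb_ctx(vb, "TOPLEVEL"), rep(container_serialize(top), n), encoded = TRUE)
  }
  vb$line_count <- n
  vb_record_ra(vb, fl[[1]], as.numeric(fl[[2]]))
  invisible(NULL)
}

seg_vcf_info <- function(vb, info) {
  n <- length(info)
  ic <- vb_ctx(vb, "INFO")
  pairs <- strsplit(info, ";", fixed = TRUE)
  keys <- lapply(pairs, function(p) sub("=.*$", "", p))
  # signature carries '=' presence so flag and key=value runs never mix
  sig <- vapply(pairs, function(p) {
    paste(ifelse(grepl("=", p, fixed = TRUE),
                 paste0(sub("=.*$", "", p), "="), p), collapse = ";")
  }, character(1))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  snips <- character(n)
  for (ri in seq_along(r$lengths)) {
    sel <- (ends[ri] - r$lengths[ri] + 1L):ends[ri]
    ks <- keys[[sel[1]]]
    ps <- pairs[sel]
    items <- vector("list", length(ks))
    for (j in seq_along(ks)) {
      vals_j <- vapply(ps, `[[`, character(1), j)
      hasval <- grepl("=", vals_j[1], fixed = TRUE)
      sep <- if (j < length(ks)) ";" else ""
      if (hasval) {
        cname <- paste0("I_", ks[j])
        ctx_seg(vb_ctx(vb, cname), sub("^[^=]*=", "", vals_j))
        items[[j]] <- list(name = cname, prefix = paste0(ks[j], "="), sep = sep)
      } else {
        items[[j]] <- list(name = "", prefix = ks[j], sep = sep)
      }
    }
    snips[sel] <- container_serialize(new_container(items))
  }
  ctx_seg(ic, snips, encoded = TRUE)
}

seg_vcf_samples <- function(vb, st, fl, ns, n) {
  fmt <- fl[[9]]
  fkeys <- strsplit(fmt, ":", fixed = TRUE)
  gt_first <- all(vapply(fkeys, function(k) k[1] == "GT", logical(1)))
  ctx_seg(vb_ctx(vb, "FORMAT"), fmt)
  scols <- lapply(seq_len(ns), function(s) fl[[9L + s]])
  ssplit <- lapply(scols, strsplit, split = ":", fixed = TRUE)
  sig <- vapply(fkeys, paste, character(1), collapse = ":")
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  top_snips <- character(n)
  gt_ok <- gt_first
  gts <- NULL
  if (gt_first) {
    gts <- matrix("", nrow = n, ncol = ns)
    for (s in seq_len(ns)) gts[, s] <- vapply(ssplit[[s]], `[[`, character(1), 1L)
    alle <- strsplit(as.vector(gts), "[/|]")
    acodes <- suppressWarnings(lapply(alle, function(a) ifelse(a == ".", 254, as.numeric(a))))
    if (any(vapply(acodes, function(a) anyNA(a) || any(a > 253), logical(1)))) gt_ok <- FALSE
  }
  if (gt_ok) {
    pl <- lengths(strsplit(as.vector(gts), "[/|]"))
    mp <- max(pl)
    mat <- matrix(255L, nrow = ns * mp, ncol = n)
    phase <- gsub("[^/|]", "", as.vector(gts))
    for (s in seq_len(ns)) {
      for (j in seq_len(mp)) {
        iidx <- (s - 1L) * n + seq_len(n)
        has <- pl[iidx] >= j
        if (any(has)) {
          codes <- vapply(acodes[iidx[has]], function(a) a[j], numeric(1))
          mat[(s - 1L) * mp + j, which(has)] <- as.integer(codes)
        }
      }
    }
    gtc <- vb_ctx(vb, "GT", LT_HAPMAT)
    gtc$allow_singleton <- FALSE
    gtc$gtmat <- if (is.null(gtc$gtmat)) mat else cbind(gtc$gtmat, mat)
    gtc$mp <- mp
    plc <- vb_ctx(vb, "GT_PL", LT_U8)
    phc <- vb_ctx(vb, "GT_PH")
    phc$allow_singleton <- FALSE
    # line-major, sample-minor order to match reconstruction pulls
    lm <- as.vector(t(matrix(pl, nrow = n)))
    ctx_local(plc, lm)
    ctx_local(phc, as.vector(t(matrix(phase, nrow = n))))
    ctx_seg(gtc, rep(snip_special("G"), n * ns), encoded = TRUE)
  }
  smp <- vb_ctx(vb, "SMP")
  for (ri in seq_along(r$lengths)) {
    sel <- (ends[ri] - r$lengths[ri] + 1L):ends[ri]
    ks <- fkeys[[sel[1]]]
    items <- vector("list", length(ks))
    for (j in seq_along(ks)) {
      sep <- if (j < length(ks)) ":" else ""
      if (j == 1L && gt_ok) {
        items[[j]] <- list(name = "GT", sep = sep)
        next
      }
      cname <- paste0("F_", ks[j])
      vals <- matrix("", nrow = length(sel), ncol = ns)
      for (s in seq_len(ns)) {
        vals[, s] <- vapply(ssplit[[s]][sel], function(x) {
          if (length(x) >= j) x[j] else ""
        }, character(1))
      }
      ctx_seg(vb_ctx(vb, cname), as.vector(t(vals)))
      items[[j]] <- list(name = cname, sep = sep)
    }
    scont <- container_serialize(new_container(items, repeats = ns, rep_sep = "\t"))
    ctx_seg(smp, rep(scont, length(sel)), encoded = TRUE)
    top <- new_container(list(
      list(name = "CHROM", sep = "\t"), list(name = "POS", sep = "\t"),
      list(name = "ID", sep = "\t"), list(name = "REF", sep = "\t"),
      list(name = "ALT", sep = "\t"), list(name = "QUALF", sep = "\t"),
      list(name = "FILTER", sep = "\t"), list(name = "INFO", sep = "\t"),
      list(name = "FORMAT", sep = "\t"), list(name = "SMP", sep = "\n")))
    top_snips[sel] <- container_serialize(top)
  }
  ctx_seg(vb_ctx(vb, "TOPLEVEL"), top_snips, encoded = TRUE)
}

# --- FASTA ------------------------------------------------------------------

seg_fasta <- function(vb, lines, st) {
  n <- length(lines)
  hdr <- startsWith(lines, ">")
  nr <- vb_ctx(vb, "NONREF", LT_ACGT)
  nr$local_codec <- "ACGT"
  vb_ctx(vb, "NONREF_X", LT_BYTES)
  sl <- vb_ctx(vb, "SEQLINE")
  dc <- vb_ctx(vb, "DESC")
  r <- rle(hdr)
  ends <- cumsum(r$lengths)
  for (ri in seq_along(r$lengths)) {
    sel <- (ends[ri] - r$lengths[ri] + 1L):ends[ri]
    if (r$values[ri]) {
      ctx_seg(dc, substr(lines[sel], 2L, 1000000L))
    } else {
      ctx_local(nr, lines[sel])
      ctx_seg(sl, snip_special("N", format(nchar(lines[sel]), scientific = FALSE,
                                           trim = TRUE)), encoded = TRUE)
    }
  }
  top_d <- container_serialize(new_container(list(list(name = "DESC", prefix = ">", sep = "\n"))))
  top_s <- container_serialize(new_container(list(list(name = "SEQLINE", sep = "\n"))))
  ctx_seg(vb_ctx(vb, "TOPLEVEL"), ifelse(hdr, top_d, top_s), encoded = TRUE)
  vb$line_count <- n
  invisible(NULL)
}

# --- Generic ----------------------------------------------------------------

seg_generic <- function(vb, chunk_raw, st) {
  gd <- vb_ctx(vb, "GDATA", LT_BYTES)
  gd$allow_singleton <- FALSE
  ctx_local(gd, chunk_raw)
  ctx_seg(gd, snip_special("L", format(length(chunk_raw), scientific = FALSE,
                                       trim = TRUE)), encoded = TRUE)
  top <- new_container(list(list(name = "GDATA", sep = "")))
  ctx_seg(vb_ctx(vb, "TOPLEVEL"), container_serialize(top), encoded = TRUE)
  vb$line_count <- 1L
  invisible(NULL)
}

# --- registry bootstrap -----------------------------------------------------

register_builtin_segmenters <- function() {
  gcol_register_segmenter("fastq", detect = function(f, h) FALSE, seg = seg_fastq,
                          group = 4L)
  gcol_register_segmenter("sam", detect = function(f, h) FALSE, seg = seg_sam,
                          n_header = function(lines) sum(cumprod(startsWith(lines, "@"))),
                          chrom_ctx = "RNAME", pos_ctx = "POS")
  gcol_register_segmenter("vcf", detect = function(f, h) FALSE, seg = seg_vcf,
                          n_header = function(lines) sum(cumprod(startsWith(lines, "#"))),
                          chrom_ctx = "CHROM", pos_ctx = "POS")
  gcol_register_segmenter("fasta", detect = function(f, h) FALSE, seg = seg_fasta)
  gcol_register_segmenter("generic", detect = function(f, h) FALSE, seg = seg_generic)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_segmenters()
}
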