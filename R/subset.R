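# genocat-style access: display, region/sample subsetting, downsampling and
# SAM->FASTQ translation, all driven by the random-access index and the
# containers stored in the archive.

#' Parse region strings ("chrom", "chrom:start-end", "chrom:start-")
#' @keywords internal
parse_regions <- function(regions) {
  lapply(regions, function(r) {
    if (!grepl("^[^:]+(:[0-9]+(-[0-9]*)?)?$", r))
      err_usage("malformed region: ", r)
    if (!grepl(":", r, fixed = TRUE))
      return(list(chrom = r, start = 1, end = Inf))
    chrom <- sub(":.*$", "", r)
    rng <- sub("^[^:]*:", "", r)
    start <- as.numeric(sub("-.*$", "", rng))
    end <- if (!grepl("-", rng, fixed = TRUE)) start
           else { e <- sub("^[0-9]+-", "", rng); if (e == "") Inf else as.numeric(e) }
    list(chrom = chrom, start = start, end = end)
  })
}

ra_table <- function(arc) {
  i <- sec_idx(arc, "RANDOM_ACCESS")
  if (!length(i)) return(NULL)
  ra <- jsonlite::fromJSON(rawToChar(read_section(arc, i[1])), simplifyVector = TRUE)
  if (!length(ra)) return(NULL)
  ra
}

#' Display or subset a compressed file
#'
#' @param archive archive path
#' @param regions character vector of regions (1-based inclusive); vblocks
#'   whose index ranges miss every region are skipped without decompression
#' @param samples VCF sample names to keep, in the requested order
#' @param downsample emit every n-th logical line (FASTQ: every n-th record)
#' @param fastq translate a SAM archive to FASTQ
#' @param reference external reference, if the archive needs one
#' @param out optional output file; otherwise text is returned
#' @return character scalar of the emitted text (invisibly when `out` is
#'   given), with attribute `vblocks_decompressed`
#' @export
gcol_cat <- function(archive, regions = NULL, samples = NULL, downsample = 1L,
                     fastq = FALSE, reference = NULL, out = NULL) {
  if (downsample < 1L) err_usage("downsample rate must be >= 1")
  arc <- gcol_open(archive)
  fmt <- arc$meta$format
  if (!is.null(samples) && fmt != "vcf") err_usage("--samples requires a VCF archive")
  if (fastq && fmt != "sam") err_usage("FASTQ translation requires a SAM archive")
  if (!is.null(regions) && is.null(arc$meta$chrom_ctx))
    err_usage("--regions requires an indexed format (SAM or VCF)")
  ref <- arc_reference(arc, reference)
  dicts <- load_dicts(arc)
  pieces <- character(0)
  ndec <- 0L
  warned <- character(0)
  for (ci in seq_along(arc$components)) {
    cm <- arc$components[[ci]]
    keep_vb <- NULL
    regs <- NULL
    if (!is.null(regions)) {
      regs <- parse_regions(regions)
      ra <- ra_table(arc)
      keep_vb <- integer(0)
      if (!is.null(ra)) {
        ra_c <- ra[ra$comp == ci, , drop = FALSE]
        known <- unique(ra_c$chrom)
        for (rg in regs) {
          if (!(rg$chrom %in% known)) next
          hit <- ra_c$chrom == rg$chrom & ra_c$min_pos <= rg$end &
            ra_c$max_pos >= rg$start
          keep_vb <- union(keep_vb, ra_c$vb[hit])
        }
        miss <- setdiff(vapply(regs, `[[`, character(1), "chrom"), known)
        warned <- union(warned, miss)
      }
    }
    collect <- character(0)
    if (!is.null(regs)) collect <- c(arc$meta$chrom_ctx, arc$meta$pos_ctx)
    if (fastq) collect <- union(collect, c("QNAME", "FLAG", "SQBITMAP", "QUAL"))
    res <- recon_component(arc, dicts, ci, ref, collect = collect, keep_vb = keep_vb)
    ndec <- ndec + res$decompressed_vblocks
    if (any(!vapply(res$raws, is.null, logical(1)))) {
      if (!is.null(regs) || fastq || !is.null(samples))
        err_usage("subsetting is not available for generic archives")
      pieces <- c(pieces, raw_to_text(unlist(res$raws[!vapply(res$raws, is.null, logical(1))],
                                             use.names = FALSE)))
      next
    }
    lines <- unlist(res$lines[!vapply(res$lines, is.null, logical(1))], use.names = FALSE)
    if (is.null(lines)) lines <- character(0)
    keep <- rep(TRUE, length(lines))
    if (!is.null(regs)) {
      # collected vectors cover all lines; restrict to reconstructed ones
      done <- !is.na(res$collected[[arc$meta$chrom_ctx]])
      chrom <- res$collected[[arc$meta$chrom_ctx]][done]
      pos <- suppressWarnings(as.numeric(res$collected[[arc$meta$pos_ctx]][done]))
      sel <- rep(FALSE, length(lines))
      for (rg in regs) {
        sel <- sel | (!is.na(pos) & chrom == rg$chrom &
                        pos >= rg$start & pos <= rg$end)
      }
      keep <- keep & sel
    }
    if (downsample > 1L) {
      keep <- keep & ((seq_along(lines) - 1L) %% downsample == 0L)
    }
    hdr <- cm$header_text
    if (fastq) {
      txt <- emit_sam_as_fastq(arc, res, which(keep))
      pieces <- c(pieces, txt)
      next
    }
    if (!is.null(samples)) {
      ss <- subset_samples_text(cm, lines[keep], samples)
      pieces <- c(pieces, ss$header, paste(ss$lines, collapse = ""))
      next
    }
    body <- paste(lines[keep], collapse = "")
    full <- paste0(hdr, body)
    if (!isTRUE(cm$trailing_nl) && is.null(regs) && downsample == 1L &&
        nchar(full) && substr(full, nchar(full), nchar(full)) == "\n")
      full <- substr(full, 1L, nchar(full) - 1L)
    pieces <- c(pieces, full)
  }
  if (length(warned))
    warning("unknown chromosome(s) in regions: ", paste(warned, collapse = ", "))
  txt <- paste(pieces, collapse = "")
  attr(txt, "vblocks_decompressed") <- ndec
  if (!is.null(out)) {
    writeBin(charToRaw(txt), out)
    return(invisible(txt))
  }
  txt
}

# SAM -> FASTQ emission via the stored translation container
emit_sam_as_fastq <- function(arc, res, keep_idx) {
  plan <- container_deserialize(arc$meta$top2fq)
  qn <- res$collected[["QNAME"]][keep_idx]
  fl <- as.integer(res$collected[["FLAG"]][keep_idx])
  sq <- res$collected[["SQBITMAP"]][keep_idx]
  ql <- res$collected[["QUAL"]][keep_idx]
  drop <- bitwAnd(fl, 0x900) != 0L | sq == "*"
  qn <- qn[!drop]; fl <- fl[!drop]; sq <- sq[!drop]; ql <- ql[!drop]
  rev16 <- bitwAnd(fl, 0x10) != 0L
  vals <- list(QNAME = qn, SQBITMAP = sq, QUAL = ql, FLAG = fl)
  pieces <- vector("list", length(plan$items))
  for (ii in seq_along(plan$items)) {
    it <- plan$items[[ii]]
    v <- if (it$name == "") rep("", length(qn)) else as.character(vals[[it$name]])
    if (it$translator == 1L && any(rev16)) v[rev16] <- revcomp_fast(v[rev16])
    if (it$translator == 2L && any(rev16)) {
      rv <- strsplit(v[rev16], "", fixed = TRUE)
      v[rev16] <- vapply(rv, function(x) paste(rev(x), collapse = ""), character(1))
    }
    if (it$translator == 3L) v <- rep("", length(qn))  # filter item: silent
    pieces[[ii]] <- paste0(it$prefix, v, it$sep)
  }
  paste(do.call(paste0, pieces), collapse = "")
}

# restrict VCF text lines to the named samples, in order
subset_samples_text <- function(cm, lines, samples) {
  avail <- cm$sample_names
  bad <- setdiff(samples, avail)
  if (length(bad))
    err_usage("unknown sample(s): ", paste(bad, collapse = ", "),
              "; available: ", paste(avail, collapse = ", "))
  sidx <- match(samples, avail)
  hl <- strsplit(cm$header_text, "\n", fixed = TRUE)[[1]]
  chromi <- which(startsWith(hl, "#CHROM"))
  cols <- strsplit(hl[chromi], "\t", fixed = TRUE)[[1]]
  hl[chromi] <- paste(c(cols[1:9], samples), collapse = "\t")
  header <- paste0(paste(hl, collapse = "\n"), "\n")
  if (!length(lines)) return(list(header = header, lines = character(0)))
  body <- sub("\n$", "", lines)
  fl <- strsplit(body, "\t", fixed = TRUE)
  outl <- vapply(fl, function(x) {
    paste0(paste(c(x[1:9], x[9L + sidx]), collapse = "\t"), "\n")
  }, character(1))
  list(header = header, lines = outl)
}

#' List archive metadata (genols)
#'
#' @param archives character vector of archive paths
#' @return data.frame: archive, file, format, txt_size, md5, bound files,
#'   archive compressed size and overall ratio
#' @export
gcol_ls <- function(archives) {
  rows <- list()
  for (a in archives) {
    r <- tryCatch({
      arc <- gcol_open(a)
      tot_txt <- sum(vapply(arc$components, function(cm) as.numeric(cm$size), numeric(1)))
      do.call(rbind, lapply(arc$components, function(cm) {
        data.frame(archive = a, file = cm$name, format = cm$format,
                   txt_size = as.numeric(cm$size),
                   compressed_size = as.numeric(arc$size),
                   ratio = round(tot_txt / as.numeric(arc$size), 2),
                   md5 = cm$md5, bound = length(arc$components),
                   stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      warning("not a gcol archive: ", a)
      NULL
    })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) {
    return(data.frame(archive = character(0), file = character(0),
                      format = character(0), txt_size = numeric(0),
                      compressed_size = numeric(0), ratio = numeric(0),
                      md5 = character(0), bound = integer(0)))
  }
  do.call(rbind, rows)
}

#' Per-context compression statistics (show-stats)
#'
#' One row per context/stream with the codec used, uncompressed and
#' compressed byte counts, the ratio and the share of the archive; a totals
#' row sums exactly.
#' @param archive archive path
#' @return data.frame
#' @export
gcol_stats <- function(archive) {
  arc <- gcol_open(archive)
  e <- arc$entries
  sel <- e$type %in% c("B250", "LOCAL", "DICT")
  d <- e[sel, , drop = FALSE]
  d$stream <- c(B250 = "b250", LOCAL = "local", DICT = "dict")[d$type]
  disp <- ifelse(d$type == "LOCAL" & d$ltype %in% c("acgt", "domqual", "hapmat"),
                 toupper(d$ltype), d$codec)
  d$codec_disp <- disp
  agg <- stats::aggregate(cbind(ulen, clen) ~ name + stream + codec_disp, data = d, FUN = sum)
  names(agg) <- c("context", "stream", "codec", "uncompressed", "compressed")
  agg <- agg[order(-agg$compressed), ]
  total_comp <- sum(agg$compressed)
  agg$ratio <- round(ifelse(agg$compressed > 0, agg$uncompressed / agg$compressed, 1), 2)
  agg$pct <- round(100 * agg$compressed / max(1, total_comp), 2)
  tot <- data.frame(context = "TOTAL", stream = "", codec = "",
                    uncompressed = sum(agg$uncompressed),
                    compressed = total_comp,
                    ratio = round(sum(agg$uncompressed) / max(1, total_comp), 2),
                    pct = round(sum(agg$pct), 2))
  rownames(agg) <- NULL
  rbind(agg, tot)
}
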