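# Top-level drivers: compress, decompress, cat (subsetting / translation),
# ls and stats.

err_usage <- function(...) stop(errorCondition(paste0("usage error: ", ...),
                                               class = c("gcol_usage_error", "error")))

#' Compress one or more files into a .gcol archive
#'
#' Multiple files of the same format are bound into one archive with
#' per-file boundaries and digests. `pair = TRUE` treats two FASTQ files as
#' mates: read names and placements of the second file are stored as deltas
#' against the first. Segmentation of distinct vblocks may run in parallel
#' (`workers`); merges are committed in vblock order, so the archive bytes
#' are identical for any worker count.
#'
#' @param input character vector of input paths (gzip-transparent)
#' @param output archive path (default: first input + ".gcol")
#' @param reference a reference: path to a `.ref.gcol` archive, a FASTA file,
#'   or a `gcol_reference` object
#' @param embed_reference store the reference inside the archive
#' @param vblock_size vblock size in bytes (default 1 MiB; the upstream tool
#'   scale is 16 MiB)
#' @param mode "best" (default) or "fast" codec selection
#' @param pair treat two FASTQ inputs as a read pair
#' @param workers parallel segmentation workers
#' @param format force an input format instead of auto-detection
#' @return the archive path, invisibly
#' @export
gcol_compress <- function(input, output = NULL, reference = NULL,
                          embed_reference = FALSE, vblock_size = 1048576L,
                          mode = c("best", "fast"), pair = FALSE, workers = 1L,
                          format = NULL) {
  mode <- match.arg(mode)
  if (!length(input)) err_usage("no input files")
  if (is.null(output)) output <- paste0(input[1], ".gcol")
  if (vblock_size < 1024L) err_usage("vblock size too small")
  ref <- NULL
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "gcol_reference")) reference
    else if (grepl("\\.gcol$", reference)) gcol_load_reference(reference)
    else gcol_load_fasta_reference(reference)
  }
  comps <- lapply(input, function(p) {
    r <- read_file_raw(p)
    list(path = p, raw = r, md5 = md5_raw(r))
  })
  fmt <- if (!is.null(format)) format else gcol_detect_format(input[1], comps[[1]]$raw)
  for (i in seq_along(comps)) {
    fi <- if (!is.null(format)) format else gcol_detect_format(input[i], comps[[i]]$raw)
    if (fi != fmt) err_usage("bound files must share one format (", fmt, " vs ", fi, ")")
  }
  if (pair && (length(input) != 2L || fmt != "fastq"))
    err_usage("--pair requires exactly two FASTQ files")
  zstate <- new_zstate()
  con <- file(output, "wb")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(output) })
  w <- new_writer(con)
  writer_emit(w, c(GCOL_MAGIC, as.raw(GCOL_VERSION)))
  meta <- list(format = fmt, vblock_size = vblock_size, mode = mode,
               n_components = length(input), used_ref = !is.null(ref),
               embed_ref = isTRUE(embed_reference), paired = isTRUE(pair))
  seginfo <- gcol_segmenter(fmt)
  meta$chrom_ctx <- seginfo$chrom_ctx
  meta$pos_ctx <- seginfo$pos_ctx
  if (fmt == "sam") meta$top2fq <- sam_to_fastq_plan()
  write_section(w, "FILE_HEADER", "", 0L, 0L, "ZLIB", "none",
                charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null")))
  if (isTRUE(embed_reference)) {
    if (is.null(ref)) err_usage("embed_reference requires a reference")
    write_ref_sections(w, ref)
  }
  pair_state <- NULL
  for (ci in seq_along(comps)) {
    pair_state <- compress_component(w, zstate, comps[[ci]], ci, fmt, seginfo,
                                     ref, vblock_size, mode, workers,
                                     pair_state = if (pair && ci == 2L) pair_state else NULL,
                                     collect_pair = pair && ci == 1L)
  }
  # global dictionaries, then the random-access index
  for (name in zstate$order) {
    g <- get(name, envir = zstate$ctxs)
    if (!length(g$dict)) next
    payload <- dict_serialize(g$dict)
    codec <- stream_codec(zstate, name, "dict", payload, mode)
    write_section(w, "DICT", name, 0L, 0L, codec, "none", payload)
  }
  write_section(w, "RANDOM_ACCESS", "", 0L, 0L, "ZLIB", "none",
                charToRaw(jsonlite::toJSON(zstate$ra_entries, auto_unbox = TRUE)))
  finish_archive(w)
  ok <- TRUE
  invisible(output)
}

sam_to_fastq_plan <- function() {
  # translator tags: 1 reverse-complement when FLAG 0x10, 2 reverse when
  # FLAG 0x10, 3 record filter (drop secondary/supplementary/seq-less)
  container_serialize(new_container(list(
    list(name = "QNAME", prefix = "@", sep = "\n"),
    list(name = "SQBITMAP", sep = "\n", translator = 1L),
    list(name = "", prefix = "+", sep = "\n"),
    list(name = "QUAL", sep = "\n", translator = 2L),
    list(name = "FLAG", sep = "", translator = 3L))))
}

compress_component <- function(w, zstate, comp, ci, fmt, seginfo, ref,
                               vblock_size, mode, workers,
                               pair_state = NULL, collect_pair = FALSE) {
  raw <- comp$raw
  if (fmt == "generic") {
    nvb <- max(1L, ceiling(length(raw) / vblock_size))
    cm <- list(name = basename(comp$path), size = length(raw), md5 = comp$md5,
               format = fmt, n_lines = nvb, trailing_nl = FALSE,
               lines_per_vb = rep(1L, nvb))
    write_txt_header(w, ci, cm, "")
    for (v in seq_len(nvb)) {
      lo <- (v - 1L) * vblock_size + 1L
      hi <- min(length(raw), v * vblock_size)
      vb <- new_vblock(v, zstate)
      seg_generic(vb, if (length(raw)) raw[lo:hi] else raw(0), NULL)
      merge_contexts(zstate, vb)
      write_vblock_sections(w, vb, zstate, ci, mode)
    }
    return(invisible(NULL))
  }
  txt <- raw_to_text(raw)
  trailing_nl <- length(raw) > 0 && raw[length(raw)] == as.raw(10L)
  all_lines <- if (nchar(txt)) strsplit(txt, "\n", fixed = TRUE)[[1]] else character(0)
  nh <- seginfo$n_header(all_lines)
  header_text <- if (nh > 0) paste0(paste(all_lines[seq_len(nh)], collapse = "\n"), "\n") else ""
  body <- if (nh < length(all_lines)) all_lines[(nh + 1L):length(all_lines)] else character(0)
  g <- seginfo$group
  if (g > 1L && length(body) %% g != 0L)
    stop("input format error: ", fmt, " record count not a multiple of ", g)
  nrec <- length(body) %/% g
  # vblock boundaries on logical-record byte sizes
  rec_bytes <- if (nrec > 0) {
    nb <- nchar(body, type = "bytes") + 1L
    if (g > 1L) colSums(matrix(nb, nrow = g)) else nb
  } else numeric(0)
  vb_of <- if (nrec > 0) cumsum(c(0, rec_bytes[-nrec])) %/% vblock_size + 1L
           else integer(0)
  vb_of <- match(vb_of, unique(vb_of))   # contiguous vblock ids
  nvb <- if (nrec > 0) max(vb_of) else 0L
  lines_per_vb <- if (nvb > 0) tabulate(vb_of, nvb) else integer(0)
  cm <- list(name = basename(comp$path), size = length(raw), md5 = comp$md5,
             format = fmt, n_lines = nrec, trailing_nl = trailing_nl,
             lines_per_vb = lines_per_vb,
             pair_role = if (!is.null(pair_state)) 2L else if (collect_pair) 1L else 0L)
  if (fmt == "vcf") {
    cl <- all_lines[nh]
    if (!nh || !startsWith(cl, "#CHROM"))
      stop("input format error: VCF lacks a #CHROM header line")
    cols <- strsplit(cl, "\t", fixed = TRUE)[[1]]
    cm$sample_names <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  }
  write_txt_header(w, ci, cm, header_text)
  st_proto <- list(zstate = NULL, ref = ref,
                   n_samples = if (fmt == "vcf") length(cm$sample_names) else 0L,
                   pair_t1 = pair_state$t1, pair_gpos = pair_state$gpos)
  # pre-commit the dominant quality score so codec state cannot depend on
  # which worker touches which vblock first
  if (fmt %in% c("fastq", "sam") && is.null(zstate$domqual_dom) && nrec > 0) {
    first <- body[seq_len(min(length(body), 4000L * g))]
    zstate$domqual_dom <- switch(fmt,
      fastq = domqual_dominant(first[seq.int(4L, length(first), by = 4L)]),
      sam = {
        q <- vapply(strsplit(first, "\t", fixed = TRUE), function(x)
          if (length(x) >= 11L) x[11] else "", character(1))
        domqual_dominant(q[q != "*" & q != ""])
      })
  }
  rec_starts <- cumsum(c(0L, lines_per_vb))
  seg_one <- function(v, zs) {
    vb <- new_vblock(v, zs)
    sel <- which(vb_of == v)
    lsel <- if (g > 1L) {
      as.vector(vapply(sel, function(i) ((i - 1L) * g + 1L):(i * g), integer(g)))
    } else sel
    st <- as.environment(st_proto)
    st$zstate <- zs
    st$line_offset <- (sel[1] - 1L) * g + nh
    st$recs_done <- rec_starts[v]
    st$collect_t1 <- list(); st$collect_gpos <- list()
    seginfo$seg(vb, body[lsel], st)
    list(vb = vb, t1 = unlist(st$collect_t1), gpos = unlist(st$collect_gpos))
  }
  results <- if (workers > 1L && nvb > 1L) {
    parallel::mclapply(seq_len(nvb), function(v) {
      zs <- new_zstate()
      zs$domqual_dom <- zstate$domqual_dom
      seg_one(v, zs)
    }, mc.cores = workers)
  } else NULL
  pair_t1 <- list(); pair_gpos <- list()
  for (v in seq_len(nvb)) {
    res <- if (is.null(results)) seg_one(v, zstate) else results[[v]]
    merge_contexts(zstate, res$vb)
    write_vblock_sections(w, res$vb, zstate, ci, mode)
    if (length(res$vb$ra)) {
      zstate$ra_entries <- c(zstate$ra_entries, lapply(res$vb$ra, function(e) {
        c(list(comp = ci, vb = v), e)
      }))
    }
    if (collect_pair) {
      pair_t1[[v]] <- res$t1; pair_gpos[[v]] <- res$gpos
    }
  }
  if (collect_pair) {
    return(list(t1 = unlist(pair_t1), gpos = unlist(pair_gpos)))
  }
  invisible(NULL)
}

write_txt_header <- function(w, ci, cm, header_text) {
  payload <- c(charToRaw(jsonlite::toJSON(cm, auto_unbox = TRUE)), as.raw(0L),
               charToRaw(header_text))
  write_section(w, "TXT_HEADER", "", 0L, ci, "ZLIB", "none", payload)
}

# --- decompression ----------------------------------------------------------

arc_reference <- function(arc, reference = NULL) {
  if (!is.null(arc$ref)) return(arc$ref)
  ref <- gcol_load_reference(arc)       # embedded sections, if any
  if (is.null(ref) && !is.null(reference)) {
    ref <- if (inherits(reference, "gcol_reference")) reference
    else if (grepl("\\.gcol$", reference)) gcol_load_reference(reference)
    else gcol_load_fasta_reference(reference)
  }
  if (is.null(ref) && isTRUE(arc$meta$used_ref))
    stop("archive was compressed against a reference; supply it with `reference=`")
  arc$ref <- ref
  ref
}

# Reconstruct one component to its raw bytes. `collect` returns per-line
# context values; `keep_vb` restricts to the given vblock ids (others are
# skipped entirely and counted).
recon_component <- function(arc, dicts, ci, ref = NULL, collect = character(0),
                            keep_vb = NULL, pair_t1 = NULL, pair_gpos = NULL,
                            want_gpos = FALSE) {
  cm <- arc$components[[ci]]
  nvb <- length(cm$lines_per_vb)
  rec_starts <- cumsum(c(0L, cm$lines_per_vb))
  out_lines <- vector("list", nvb)
  out_raw <- vector("list", nvb)
  coll <- stats::setNames(lapply(collect, function(x) rep(NA_character_, cm$n_lines)),
                          collect)
  gpos_all <- if (want_gpos) rep(NA_real_, cm$n_lines) else NULL
  decompressed <- 0L
  for (v in seq_len(nvb)) {
    if (!is.null(keep_vb) && !(v %in% keep_vb)) next
    decompressed <- decompressed + 1L
    vbs <- load_vblock_state(arc, dicts, v, ci, cm, ref)
    vbs$rec_base <- rec_starts[v]
    vbs$pair_t1 <- pair_t1
    vbs$pair_gpos <- pair_gpos
    n <- cm$lines_per_vb[v]
    if (want_gpos) vbs$collect_gpos <- rep(NA_real_, n)
    res <- reconstruct_vblock(vbs, n, collect = collect)
    if (!is.null(res$raw)) out_raw[[v]] <- res$raw
    else out_lines[[v]] <- res$lines
    for (nm in collect) {
      if (n > 0) coll[[nm]][(rec_starts[v] + 1L):(rec_starts[v] + n)] <- res$collected[[nm]]
    }
    if (want_gpos && n > 0)
      gpos_all[(rec_starts[v] + 1L):(rec_starts[v] + n)] <- vbs$collect_gpos
  }
  list(lines = out_lines, raws = out_raw, collected = coll,
       gpos = gpos_all, decompressed_vblocks = decompressed)
}

component_bytes <- function(arc, cm, res) {
  if (any(!vapply(res$raws, is.null, logical(1)))) {
    body <- unlist(res$raws[!vapply(res$raws, is.null, logical(1))], use.names = FALSE)
    return(c(charToRaw(cm$header_text), body))
  }
  body <- paste(unlist(res$lines, use.names = FALSE), collapse = "")
  full <- paste0(cm$header_text, body)
  b <- charToRaw(full)
  if (!isTRUE(cm$trailing_nl) && length(b) && b[length(b)] == as.raw(10L))
    b <- b[-length(b)]
  b
}

#' Decompress a .gcol archive
#'
#' Verifies the stored MD5 of every component against the reconstruction.
#' With `unbind = TRUE`, each bound file is restored under its original name
#' in `dir`. With `test = TRUE`, nothing is written.
#'
#' @param archive archive path
#' @param output output path (single-component archives)
#' @param dir output directory for `unbind`
#' @param reference external reference (if not embedded)
#' @param unbind restore bound files separately
#' @param test verify only
#' @return invisibly, a data.frame of components with md5_ok
#' @export
gcol_decompress <- function(archive, output = NULL, dir = ".",
                            reference = NULL, unbind = FALSE, test = FALSE) {
  arc <- gcol_open(archive)
  ref <- arc_reference(arc, reference)
  dicts <- load_dicts(arc)
  nc <- length(arc$components)
  if (!unbind && !test && nc > 1L && !is.null(output))
    err_usage("bound archive: use unbind=TRUE (or test=TRUE)")
  pair_t1 <- NULL; pair_gpos <- NULL
  rows <- vector("list", nc)
  for (ci in seq_len(nc)) {
    cm <- arc$components[[ci]]
    paired2 <- isTRUE(arc$meta$paired) && ci == 2L
    res <- recon_component(arc, dicts, ci, ref,
                           collect = if (isTRUE(arc$meta$paired) && ci == 1L) "T1" else character(0),
                           pair_t1 = pair_t1, pair_gpos = pair_gpos,
                           want_gpos = isTRUE(arc$meta$paired) && ci == 1L)
    if (isTRUE(arc$meta$paired) && ci == 1L) {
      pair_t1 <- res$collected[["T1"]]
      pair_gpos <- res$gpos
    }
    b <- component_bytes(arc, cm, res)
    ok <- identical(md5_raw(b), cm$md5)
    if (!ok && !test)
      stop("md5 mismatch for ", cm$name, ": stored ", cm$md5, ", got ", md5_raw(b))
    if (!test) {
      if (unbind || nc > 1L) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      dest <- if (unbind || nc > 1L) file.path(dir, cm$name)
      else if (!is.null(output)) output
      else sub("\\.gcol$", "", archive)
      writeBin(b, dest)
    }
    rows[[ci]] <- data.frame(name = cm$name, size = length(b),
                             md5 = cm$md5, md5_ok = ok, stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows))
}

#' Verify an archive without writing output
#' @export
gcol_test <- function(archive, reference = NULL) {
  r <- gcol_decompress(archive, reference = reference, test = TRUE)
  if (!all(r$md5_ok)) stop("md5 mismatch in archive ", archive)
  invisible(r)
}
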