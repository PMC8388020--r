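# Shared fixtures, built once per test run. Everything is generated by the
# package's own synthetic-data module; nothing is downloaded or stored.

fixdir <- local({
  d <- file.path(tempdir(), "gcol-fixtures")
  dir.create(d, showWarnings = FALSE)
  d
})

fx <- function(...) file.path(fixdir, ...)

# 100 kb single-contig reference + preprocessed archive (built lazily)
ref_fa <- function() {
  p <- fx("ref100k.fa")
  if (!file.exists(p)) gen_reference(p, length = 100000L, n_contigs = 1L, seed = 101L)
  p
}

ref_arc <- function() {
  p <- fx("ref100k.ref.gcol")
  if (!file.exists(p)) gcol_make_reference(ref_fa(), p)
  p
}

ref_obj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gcol_load_reference(ref_arc())
    cache
  }
})

two_contig_fa <- function() {
  p <- fx("ref2c.fa")
  if (!file.exists(p)) gen_reference(p, length = 60000L, n_contigs = 2L, seed = 102L)
  p
}

# round-trip helper: compress, decompress, byte-compare
expect_roundtrip <- function(path, ..., reference = NULL) {
  arc <- tempfile(fileext = ".gcol")
  out <- tempfile()
  on.exit(unlink(c(arc, out)))
  gcol_compress(path, arc, reference = reference, ...)
  r <- gcol_decompress(arc, output = out, reference = reference)
  expect_true(all(r$md5_ok))
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(path, "raw", file.size(path)))
  invisible(file.size(arc))
}

read_lines_raw <- function(path) {
  txt <- rawToChar(readBin(path, "raw", file.size(path)))
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

# independent SAM -> FASTQ converter used as the translation oracle
oracle_sam_to_fastq <- function(sam_path) {
  lines <- read_lines_raw(sam_path)
  body <- lines[!startsWith(lines, "@")]
  out <- character(0)
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  for (x in strsplit(body, "\t", fixed = TRUE)) {
    fl <- as.integer(x[2])
    if (bitwAnd(fl, 0x900) != 0L || x[10] == "*") next
    sq <- x[10]; ql <- x[11]
    if (bitwAnd(fl, 16L) != 0L) {
      sq <- rc(sq)
      ql <- paste(rev(strsplit(ql, "", fixed = TRUE)[[1]]), collapse = "")
    }
    out <- c(out, paste0("@", x[1]), sq, "+", ql)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
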