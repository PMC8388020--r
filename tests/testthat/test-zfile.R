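# archive format: layout, integrity, subsetting, binding, listing

test_that("empty input produces a valid archive that round-trips to empty", {
  p <- tempfile(fileext = ".txt")
  writeBin(raw(0), p)
  arc <- tempfile(fileext = ".gcol")
  out <- tempfile()
  gcol_compress(p, arc)
  r <- gcol_decompress(arc, output = out)
  expect_true(all(r$md5_ok))
  expect_equal(file.size(out), 0)
  # the empty-stream digest is the well-known constant
  expect_equal(gcol:::gcol_open(arc)$components[[1]]$md5,
               "d41d8cd98f00b204e9800998ecf8427e")
  unlink(c(p, arc, out))
})

test_that("sections are grouped by ascending vblock id", {
  rd <- gen_reads(fx("layout.fastq"), ref_fa(), n_reads = 3000L, seed = 120L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("layout.fastq"), arc, vblock_size = 200000L)
  e <- gcol:::gcol_open(arc)$entries
  vb <- e$vb[e$type %in% c("B250", "LOCAL")]
  expect_gt(max(vb), 2)                       # really multi-vblock
  expect_true(all(diff(vb) >= 0))             # non-interleaved, ascending
  # dictionaries follow all vblock sections; footer-driven access needs
  # at most the trailer seek + section seek
  expect_true(min(which(e$type == "DICT")) > max(which(e$type == "B250")))
  unlink(arc)
})

test_that("a flipped payload bit is reported as corruption, not silent output", {
  rd <- gen_reads(fx("md5.fastq"), ref_fa(), n_reads = 100L, seed = 121L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("md5.fastq"), arc)
  b <- readBin(arc, "raw", file.size(arc))
  pos <- round(length(b) * 0.6)
  b[pos] <- xor(b[pos], as.raw(1L))
  bad <- tempfile(fileext = ".gcol")
  writeBin(b, bad)
  expect_error(gcol_decompress(bad, output = tempfile()),
               "corrupt archive|md5 mismatch|length mismatch")
  unlink(c(arc, bad))
})

test_that("archives with an embedded reference decompress standalone", {
  rd <- gen_reads(fx("emb.fastq"), ref_fa(), n_reads = 300L, seed = 122L)
  arc <- tempfile(fileext = ".gcol")
  out <- tempfile()
  gcol_compress(fx("emb.fastq"), arc, reference = ref_arc(),
                embed_reference = TRUE)
  r <- gcol_decompress(arc, output = out)  # no reference argument
  expect_true(all(r$md5_ok))
  # without embedding, decompression demands the reference
  arc2 <- tempfile(fileext = ".gcol")
  gcol_compress(fx("emb.fastq"), arc2, reference = ref_arc())
  expect_error(gcol_decompress(arc2, output = tempfile()), "reference")
  unlink(c(arc, arc2, out))
})

test_that("region subsetting skips vblocks outside the requested ranges", {
  gen_vcf(fx("reg.vcf"), two_contig_fa(), n_variants = 2000L, n_samples = 2L,
          seed = 123L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("reg.vcf"), arc, vblock_size = 40000L)
  a <- gcol:::gcol_open(arc)
  nvb <- length(a$components[[1]]$lines_per_vb)
  expect_gt(nvb, 1)
  # query confined to chr1: the chr2-only vblocks stay compressed
  q <- gcol_cat(arc, regions = "chr1")
  expect_lt(attr(q, "vblocks_decompressed"), nvb)
  lines <- read_lines_raw(fx("reg.vcf"))
  body <- lines[!startsWith(lines, "#")]
  hdr <- lines[startsWith(lines, "#")]
  keep <- startsWith(body, "chr1\t")
  oracle <- paste0(paste(hdr, collapse = "\n"), "\n",
                   paste(body[keep], collapse = "\n"), "\n")
  expect_identical(as.character(q), oracle)
  # region covering everything reproduces the full body
  q2 <- gcol_cat(arc, regions = c("chr1", "chr2"))
  expect_identical(as.character(q2),
                   paste0(paste(lines, collapse = "\n"), "\n"))
  # unknown chromosome: empty body plus warning
  expect_warning(q3 <- gcol_cat(arc, regions = "chrX"), "unknown chromosome")
  expect_identical(as.character(q3), paste0(paste(hdr, collapse = "\n"), "\n"))
  # malformed region syntax is a usage error
  expect_error(gcol_cat(arc, regions = "chr1:abc"), "usage|malformed")
  unlink(arc)
})

test_that("sample subsetting restricts and reorders columns", {
  gen_vcf(fx("smp.vcf"), ref_fa(), n_variants = 300L, n_samples = 3L,
          seed = 124L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("smp.vcf"), arc)
  lines <- read_lines_raw(fx("smp.vcf"))
  # all samples in order: identical to a full decompress
  q <- gcol_cat(arc, samples = c("S1", "S2", "S3"))
  expect_identical(as.character(q), paste0(paste(lines, collapse = "\n"), "\n"))
  # one of three: 10 columns
  q1 <- gcol_cat(arc, samples = "S2")
  b1 <- strsplit(as.character(q1), "\n")[[1]]
  body1 <- b1[!startsWith(b1, "#")]
  expect_true(all(lengths(strsplit(body1, "\t")) == 10L))
  # requested order respected
  q2 <- gcol_cat(arc, samples = c("S3", "S1"))
  hl <- strsplit(as.character(q2), "\n")[[1]]
  chrom <- hl[startsWith(hl, "#CHROM")]
  expect_match(chrom, "S3\tS1$")
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t")
  oracle <- vapply(f, function(x) paste(c(x[1:9], x[12], x[10]), collapse = "\t"),
                   character(1))
  got <- hl[!startsWith(hl, "#")]
  expect_identical(got, oracle)
  # unknown sample errors and lists what is available
  expect_error(gcol_cat(arc, samples = "nope"), "S1")
  unlink(arc)
})

test_that("downsampling emits every n-th logical record from the first", {
  rd <- gen_reads(fx("ds.fastq"), ref_fa(), n_reads = 100L, seed = 125L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("ds.fastq"), arc)
  orig <- read_lines_raw(fx("ds.fastq"))
  full <- gcol_cat(arc)
  expect_identical(as.character(full), paste0(paste(orig, collapse = "\n"), "\n"))
  q <- gcol_cat(arc, downsample = 10L)
  recs <- matrix(orig, nrow = 4L)
  oracle <- paste0(paste(as.vector(recs[, seq(1, 100, by = 10)]),
                         collapse = "\n"), "\n")
  expect_identical(as.character(q), oracle)
  # n larger than the record count leaves one record
  q2 <- gcol_cat(arc, downsample = 1000L)
  expect_identical(as.character(q2), paste0(paste(recs[, 1], collapse = "\n"), "\n"))
  expect_error(gcol_cat(arc, downsample = 0L), "usage")
  unlink(arc)
})

test_that("SAM to FASTQ translation matches the oracle converter", {
  sm <- gen_sam(fx("tr.sam"), ref_fa(), n_reads = 800L, aligned_frac = 0.8,
                secondary_frac = 0.1, seed = 126L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("tr.sam"), arc, reference = ref_arc(), embed_reference = TRUE)
  q <- gcol_cat(arc, fastq = TRUE)
  expect_identical(as.character(q), oracle_sam_to_fastq(fx("tr.sam")))
  # spot-check one FLAG-16 record: emitted SEQ is the reverse complement
  lines <- read_lines_raw(fx("tr.sam"))
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body, "\t")
  i <- which(vapply(f, function(x) x[2] == "16", logical(1)))[1]
  rec <- f[[i]]
  fq <- strsplit(as.character(q), "\n")[[1]]
  at <- which(fq == paste0("@", rec[1]))
  expect_identical(fq[at + 1L], gcol:::revcomp_fast(rec[10]))
  # secondary records are absent
  sec <- vapply(f, function(x) bitwAnd(as.integer(x[2]), 0x100) != 0, logical(1))
  if (any(sec)) {
    expect_false(any(fq == paste0("@", f[[which(sec)[1]]][1])))
  }
  unlink(arc)
})

test_that("genols lists per-file metadata and digests", {
  rd <- gen_reads(fx("ls1.fastq"), ref_fa(), n_reads = 50L, seed = 127L)
  rd2 <- gen_reads(fx("ls2.fastq"), ref_fa(), n_reads = 60L, seed = 128L)
  a1 <- tempfile(fileext = ".gcol")
  gcol_compress(c(fx("ls1.fastq"), fx("ls2.fastq")), a1)
  tab <- gcol_ls(a1)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$bound, c(2L, 2L))
  expect_equal(tab$md5[1],
               gcol:::md5_raw(readBin(fx("ls1.fastq"), "raw",
                                      file.size(fx("ls1.fastq")))))
  expect_equal(nrow(gcol_ls(character(0))), 0L)
  expect_warning(gcol_ls(fx("ls1.fastq")), "not a gcol archive")
  unlink(a1)
})

test_that("bind/unbind restores each original file; pairing shrinks mates", {
  rd <- gen_reads(fx("pair1.fastq"), ref_fa(), n_reads = 600L, paired = TRUE,
                  seed = 129L)
  ab <- tempfile(fileext = ".gcol")
  gcol_compress(c(fx("pair1.fastq"), rd$mate), ab)
  dir <- tempfile(); dir.create(dir)
  r <- gcol_decompress(ab, dir = dir, unbind = TRUE)
  expect_true(all(r$md5_ok))
  for (p in c(fx("pair1.fastq"), rd$mate)) {
    expect_identical(readBin(file.path(dir, basename(p)), "raw", 1e7),
                     readBin(p, "raw", 1e7))
  }
  # paired mode stores mate-2 deltas: smaller than unpaired binding
  ap <- tempfile(fileext = ".gcol")
  gcol_compress(c(fx("pair1.fastq"), rd$mate), ap, pair = TRUE,
                reference = ref_arc())
  anp <- tempfile(fileext = ".gcol")
  gcol_compress(c(fx("pair1.fastq"), rd$mate), anp, reference = ref_arc())
  expect_lt(file.size(ap), file.size(anp))
  dir2 <- tempfile()
  r2 <- gcol_decompress(ap, dir = dir2, unbind = TRUE, reference = ref_arc())
  expect_true(all(r2$md5_ok))
  # mixed formats refuse to bind
  expect_error(gcol_compress(c(fx("pair1.fastq"), ref_fa()), tempfile()),
               "usage error")
  unlink(c(ab, ap, anp))
})
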