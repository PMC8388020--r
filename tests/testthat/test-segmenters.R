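# format segmenters: routing, byte accounting via round-trips, detection

test_that("format auto-detection routes fixtures correctly, unknown to generic", {
  fa <- ref_fa()
  rd <- gen_reads(fx("det.fastq"), fa, n_reads = 10L, seed = 107L)
  sm <- gen_sam(fx("det.sam"), fa, n_reads = 10L, seed = 108L)
  gen_vcf(fx("det.vcf"), fa, n_variants = 10L, n_samples = 1L, seed = 109L)
  gen_generic(fx("det.bin"), size = 1000L, seed = 110L)
  expect_equal(gcol_detect_format(fx("det.fastq")), "fastq")
  expect_equal(gcol_detect_format(fx("det.sam")), "sam")
  expect_equal(gcol_detect_format(fx("det.vcf")), "vcf")
  expect_equal(gcol_detect_format(fa), "fasta")
  expect_equal(gcol_detect_format(fx("det.bin")), "generic")
  # structure sniffing without a known extension
  file.copy(fx("det.vcf"), fx("mystery.dat"), overwrite = TRUE)
  expect_equal(gcol_detect_format(fx("mystery.dat")), "vcf")
})

test_that("uniform FASTQ yields a single TOPLEVEL container entry", {
  rd <- gen_reads(fx("uni.fastq"), ref_fa(), n_reads = 200L,
                  dominant_frac = 1, seed = 111L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("uni.fastq"), arc)
  a <- gcol:::gcol_open(arc)
  d <- gcol:::load_dicts(a)
  expect_length(get("TOPLEVEL", d), 1L)
  # single quality symbol: exception stream empty
  qx <- a$entries[a$entries$name == "QUAL_X" & a$entries$type == "LOCAL", ]
  expect_true(nrow(qx) == 0L || all(qx$ulen == 0))
  unlink(arc)
})

test_that("'+' line variants round-trip (bare and repeated title)", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 desc here", "ACGT", "+", "FFFF",
               "@r2", "GGGG", "+r2", "FFFF"), fq)
  expect_roundtrip(fq)
  unlink(fq)
})

test_that("ragged FASTQ records raise an input-format error naming the line", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "FFF"), fq)
  expect_error(gcol_compress(fq, tempfile(fileext = ".gcol")),
               "input format error.*line 1")
  unlink(fq)
})

test_that("SAM records choose the aligned path only with RNAME/POS/CIGAR", {
  sm <- gen_sam(fx("mix.sam"), ref_fa(), n_reads = 300L, aligned_frac = 0.5,
                seed = 112L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("mix.sam"), arc, reference = ref_arc())
  a <- gcol:::gcol_open(arc)
  # aligned records write no GPOS; aligner-placed unmapped records do
  gp <- a$entries[a$entries$name == "GPOS" & a$entries$type == "LOCAL", ]
  n_unaligned <- sum(!sm$aligned)
  expect_gt(sum(gp$ulen) / 4, 0)
  expect_lte(sum(gp$ulen) / 4, n_unaligned)
  unlink(arc)
})

test_that("SAM with fewer than 11 fields is an input-format error", {
  sm <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tchr1\t10\t60\t4M\t*\t0\tACGT"), sm)
  expect_error(gcol_compress(sm, tempfile(fileext = ".gcol")),
               "input format error")
  unlink(sm)
})

test_that("MC:Z values sharing the @CIGAR dictionary beat separate contexts", {
  sm <- gen_sam(fx("mc.sam"), ref_fa(), n_reads = 500L, aligned_frac = 1,
                mc_frac = 1, clip_rate = 0, seed = 113L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("mc.sam"), arc, reference = ref_arc())
  a <- gcol:::gcol_open(arc)
  d <- gcol:::load_dicts(a)
  # every MC:Z value repeats the CIGAR value -> one shared dictionary entry
  expect_length(get("@CIGAR", d), 1L)
  expect_false(exists("MC:Z", d))
  expect_roundtrip(fx("mc.sam"), reference = ref_arc())
  unlink(arc)
})

test_that("VCF REF stored as a reference lookup shrinks the REF stream", {
  gen_vcf(fx("refl.vcf"), ref_fa(), n_variants = 800L, n_samples = 0L, seed = 114L)
  a1 <- tempfile(fileext = ".gcol"); a2 <- tempfile(fileext = ".gcol")
  gcol_compress(fx("refl.vcf"), a1)
  gcol_compress(fx("refl.vcf"), a2, reference = ref_arc())
  d1 <- gcol:::load_dicts(gcol:::gcol_open(a1))
  d2 <- gcol:::load_dicts(gcol:::gcol_open(a2))
  expect_gt(length(get("REF", d1)), 1L)   # base dictionary
  expect_length(get("REF", d2), 1L)       # one lookup snip
  out <- tempfile()
  gcol_decompress(a2, output = out, reference = ref_arc())
  expect_identical(readBin(out, "raw", 1e7),
                   readBin(fx("refl.vcf"), "raw", 1e7))
  unlink(c(a1, a2, out))
})

test_that("phased and unphased genotypes round-trip exactly", {
  gen_vcf(fx("ph.vcf"), ref_fa(), n_variants = 400L, n_samples = 3L,
          phased_frac = 0.5, seed = 115L)
  expect_roundtrip(fx("ph.vcf"))
  # single-sample diploid: GT matrix has 2 haplotype rows
  gen_vcf(fx("one.vcf"), ref_fa(), n_variants = 100L, n_samples = 1L, seed = 116L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("one.vcf"), arc)
  a <- gcol:::gcol_open(arc)
  gt <- a$entries[a$entries$name == "GT" & a$entries$type == "LOCAL", ]
  p <- gcol:::parse_local(gcol:::read_section(a, which(a$entries$name == "GT" &
                                                         a$entries$type == "LOCAL")[1]),
                          "hapmat")
  expect_equal(p$n_hap, 2)
  expect_equal(p$n_var, 100)
  unlink(arc)
})

test_that("mixed-ploidy and missing genotypes round-trip", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
               "chr1\t10\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t1",
               "chr1\t20\t.\tG\tT\t.\tPASS\t.\tGT\t.\t0|1/1",
               "chr1\t30\t.\tT\tA\t.\tPASS\t.\tGT:DP\t0/.:7\t1/1:9"), vcf)
  expect_roundtrip(vcf)
  unlink(vcf)
})

test_that("FASTA wrapping, empty lines and protein sequences are preserved", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", strrep("ACGT", 15), "ACG", "",
               ">s2", "MKVLAAGQWPP", "QQWHY"), fa)
  expect_roundtrip(fa)
  # no trailing newline
  fa2 <- tempfile(fileext = ".fa")
  writeBin(charToRaw(">x\nACGT\nAC"), fa2)
  expect_roundtrip(fa2)
  unlink(c(fa, fa2))
})

test_that("generic segmenter round-trips arbitrary binary and stores random data", {
  gen_generic(fx("rand.bin"), size = 200000L, kind = "random", seed = 117L)
  sz <- expect_roundtrip(fx("rand.bin"))
  # STORE chosen: archive within input + bounded header overhead
  expect_lt(sz, 200000L + 4096L)
  gen_generic(fx("text.bin"), size = 100000L, kind = "text", seed = 118L)
  sz2 <- expect_roundtrip(fx("text.bin"))
  expect_lt(sz2, 0.6 * 100000L)
})

test_that("gzip-compressed inputs are read transparently", {
  rd <- gen_reads(fx("gz.fastq.gz"), ref_fa(), n_reads = 200L, gz = TRUE,
                  seed = 119L)
  arc <- tempfile(fileext = ".gcol")
  out <- tempfile()
  gcol_compress(fx("gz.fastq.gz"), arc)
  gcol_decompress(arc, output = out)
  con <- gzfile(fx("gz.fastq.gz"), "rb")
  orig <- readBin(con, "raw", 10^7); close(con)
  expect_identical(readBin(out, "raw", 10^7), orig)
  unlink(c(arc, out))
})
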