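# reference preprocessing, k-mer index, aligner, sequence encoding

test_that("make-reference records the contig table and offsets", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 250), ">chr2 description",
               strrep("GATTACA", 8)), fa)
  ref <- gcol_load_fasta_reference(fa)
  expect_equal(ref$contigs$name, c("chr1", "chr2"))
  expect_equal(ref$contigs$length, c(1000L, 56L))
  expect_equal(ref$contigs$offset, c(0, 1000))
  # duplicate contig names rejected; empty FASTA rejected
  writeLines(c(">a", "ACGT", ">a", "ACGT"), fa)
  expect_error(gcol_load_fasta_reference(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(gcol_load_fasta_reference(fa), "empty|invalid")
  unlink(fa)
})

test_that("gpos arithmetic is bijective over all contigs", {
  fa <- two_contig_fa()
  ref <- gcol_load_fasta_reference(fa)
  set.seed(21)
  g <- sort(sample(0:(ref$total - 1), 500))
  loc <- gcol:::ref_locate(ref, g)
  back <- gcol:::ref_gpos(ref, loc$rname, loc$pos)
  expect_equal(back, g)
  expect_true(all(loc$pos >= 1 & loc$pos <= ref$contigs$length[match(loc$rname, ref$contigs$name)]))
})

test_that("every sampled reference k-mer resolves to its true gpos", {
  fa <- tempfile(fileext = ".fa")
  gen_reference(fa, length = 10000L, seed = 22L)
  ref <- gcol_load_fasta_reference(fa)
  # exhaustive: each indexed k-mer's candidate list contains its source gpos
  for (j in seq_along(ref$idx_keys)) {
    cand <- ref$idx_gpos[(ref$idx_off[j] + 1):(ref$idx_off[j] + ref$idx_cnt[j])]
    w <- gcol:::ref_window(ref, cand[1], gcol:::REF_K)
    code <- gcol:::base_codes(w)
    k <- sum(code * 4^(gcol:::REF_K - seq_along(code)))
    expect_equal(k, ref$idx_keys[j])
  }
  unlink(fa)
})

test_that("aligner places exact copies, reverse complements, rejects noise", {
  ref <- ref_obj()
  set.seed(23)
  g <- sample(0:(ref$total - 151), 300)
  reads <- gcol:::ref_window(ref, g, 150)
  aln <- gcol_align(reads, ref)
  expect_true(all(!is.na(aln$gpos)))
  expect_true(all(aln$forward))
  expect_equal(aln$gpos, g)
  # reverse-complemented copies map to the same gpos, reverse strand
  aln_rc <- gcol_align(gcol:::revcomp_fast(reads), ref)
  expect_equal(aln_rc$gpos, g)
  expect_true(all(!aln_rc$forward))
  # uniform-random reads: no alignment
  rnd <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1))
  expect_true(all(is.na(gcol_align(rnd, ref)$gpos)))
})

test_that("aligner recall on exact reads is at least 99%", {
  rd <- gen_reads(fx("exact.fastq"), ref_fa(), n_reads = 3000L, read_len = 150L,
                  mutation = 0, seed = 105L)
  aln <- gcol_align(rd$seqs, ref_obj())
  hit <- !is.na(aln$gpos) & aln$gpos == rd$truth$gpos
  expect_gte(mean(hit), 0.99)
})

# helper: encode a single SAM record's SEQ and decode it back through the
# archive machinery by compressing a one-record SAM
sam_seq_roundtrip <- function(seq, cigar, pos, refpath = ref_fa()) {
  sam <- tempfile(fileext = ".sam")
  qual <- strrep("F", nchar(seq))
  writeLines(c("@HD\tVN:1.6", paste0("@SQ\tSN:chr1\tLN:100000"),
               paste("r1", "0", "chr1", pos, "60", cigar, "*", "0", "0",
                     seq, qual, sep = "\t")), sam)
  arc <- tempfile(fileext = ".gcol")
  out <- tempfile()
  on.exit(unlink(c(sam, arc, out)))
  gcol_compress(sam, arc, reference = ref_arc())
  gcol_decompress(arc, output = out, reference = ref_arc())
  x <- strsplit(read_lines_raw(out)[3], "\t", fixed = TRUE)[[1]]
  x[10]
}

test_that("aligned SEQ encoding follows CIGAR consuming semantics", {
  ref <- ref_obj()
  w <- gcol:::ref_window(ref, 1000, 10)
  # exact 10M window: bitmap all ones, NONREF empty -> archive tiny, exact
  expect_identical(sam_seq_roundtrip(w, "10M", 1001), w)
  # 4M1I4M with an inserted base
  w8 <- gcol:::ref_window(ref, 2000, 8)
  seq_ins <- paste0(substr(w8, 1, 4), "G", substr(w8, 5, 8))
  expect_identical(sam_seq_roundtrip(seq_ins, "4M1I4M", 2001), seq_ins)
  # 5S5M: clipped prefix lives in NONREF
  w5 <- gcol:::ref_window(ref, 3000, 5)
  seq_clip <- paste0("NNNNN", w5)
  expect_identical(sam_seq_roundtrip(seq_clip, "5S5M", 3001), seq_clip)
  # deletion: 4M2D4M consumes 8 reference bases but 8 query bases
  wd <- paste0(gcol:::ref_window(ref, 4000, 4), gcol:::ref_window(ref, 4006, 4))
  expect_identical(sam_seq_roundtrip(wd, "4M2D4M", 4001), wd)
})

test_that("CIGAR/SEQ length mismatch is an input-format error", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chr1\tLN:100000",
               paste("r1", "0", "chr1", "100", "60", "5M", "*", "0", "0",
                     "ACGTACGT", "FFFFFFFF", sep = "\t")), sam)
  arc <- tempfile(fileext = ".gcol")
  expect_error(gcol_compress(sam, arc, reference = ref_arc()),
               "input format error")
  unlink(c(sam, arc))
})

test_that("reads with planted SNPs store exactly those bases in NONREF", {
  ref <- ref_obj()
  g <- 5000
  w <- gcol:::ref_window(ref, g, 150)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  for (at in c(30, 90)) ch[at] <- setdiff(c("A", "C", "G", "T"), ch[at])[1]
  mut <- paste(ch, collapse = "")
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", mut, "+", strrep("F", 150)), fq)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fq, arc, reference = ref_arc())
  st <- gcol_stats(arc)
  a <- gcol:::gcol_open(arc)
  nr <- a$entries[a$entries$name == "NONREF" & a$entries$type == "LOCAL", ]
  # acgt local header is 8 bytes; 2 mismatching bases pack into 1 byte
  expect_equal(nr$ulen, 9)
  sq <- a$entries[a$entries$name == "SQBITMAP" & a$entries$type == "LOCAL", ]
  expect_gt(nrow(sq), 0)
  out <- tempfile()
  gcol_decompress(arc, output = out, reference = ref_arc())
  expect_identical(read_lines_raw(out)[2], mut)
  unlink(c(fq, arc, out))
})

test_that("reference-free mode sends whole sequences through the acgt codec", {
  rd <- gen_reads(fx("norefm.fastq"), ref_fa(), n_reads = 100L, seed = 106L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("norefm.fastq"), arc)
  st <- gcol_stats(arc)
  nr <- st[st$context == "NONREF" & st$stream == "local", ]
  expect_equal(nr$codec, "ACGT")
  expect_gte(nr$uncompressed, 100 * 150 / 4)
  unlink(arc)
})
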