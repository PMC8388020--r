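# codecs: selection, acgt, domqual, hapmat

test_that("codec selection: incompressible data stores, homopolymers compress", {
  set.seed(42)
  rnd <- as.raw(sample(0:255, 100000, replace = TRUE))
  expect_equal(gcol:::select_codec(rnd, "best")$codec, "STORE")
  hom <- charToRaw(strrep("A", 100000))
  res <- gcol:::select_codec(hom, "best")
  expect_true(res$codec != "STORE")
  expect_gt(res$sampled_ratio, 100)
  expect_equal(gcol:::select_codec(raw(0), "best")$codec, "STORE")
  # stability: same sample, same choice
  expect_equal(gcol:::select_codec(hom, "best")$codec, res$codec)
})

test_that("all generic codecs invert exactly", {
  set.seed(1)
  for (payload in list(raw(0), as.raw(1:255),
                       charToRaw(strrep("ACGT", 1000)),
                       as.raw(sample(0:255, 10000, replace = TRUE)))) {
    for (cd in gcol:::GENERIC_CODECS) {
      enc <- gcol:::codec_apply(cd, payload)
      expect_identical(gcol:::codec_invert(cd, enc, length(payload)), payload)
    }
  }
})

test_that("acgt packs 2 bits per base with the stated mapping", {
  enc <- gcol:::codec_acgt_encode("ACGT")
  expect_identical(enc$packed, as.raw(0x1B))  # 00 01 10 11
  expect_length(enc$xcgt, 0L)
  expect_identical(gcol:::codec_acgt_decode(enc$packed, enc$xcgt, 4L), "ACGT")
  # non-ACGT byte packs as A with an exception record
  enc2 <- gcol:::codec_acgt_encode("ACGN")
  expect_identical(enc2$packed, gcol:::codec_acgt_encode("ACGA")$packed)
  expect_gt(length(enc2$xcgt), 0L)
  expect_identical(gcol:::codec_acgt_decode(enc2$packed, enc2$xcgt, 4L), "ACGN")
  # empty input, exact ceil(n/4) packed size on pure ACGT
  enc3 <- gcol:::codec_acgt_encode("")
  expect_length(enc3$packed, 0L)
  for (n in c(1, 3, 4, 5, 101)) {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    e <- gcol:::codec_acgt_encode(s)
    expect_length(e$packed, ceiling(n / 4))
    expect_identical(gcol:::codec_acgt_decode(e$packed, e$xcgt, n), s)
  }
})

test_that("acgt round-trips arbitrary byte content via the exception stream", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "a", "X", "-"),
                      sample(0:200, 1), replace = TRUE), collapse = "")
    e <- gcol:::codec_acgt_encode(s)
    expect_identical(gcol:::codec_acgt_decode(e$packed, e$xcgt, nchar(s)), s)
  }
})

dq_roundtrip <- function(quals, dom = NULL) {
  enc <- gcol:::codec_domqual_encode(quals, dom = dom)
  runs <- gcol:::uleb128_decode(enc$runs)
  dec <- gcol:::codec_domqual_decode(runs, enc$exceptions, enc$dom,
                                     nchar(quals))
  dec$values
}

test_that("domqual hand-trace: 'FFAF' gives runs [2,1] and exception 'A'", {
  enc <- gcol:::codec_domqual_encode("FFAF", dom = "F")
  expect_equal(gcol:::uleb128_decode(enc$runs), c(2, 1))
  expect_identical(rawToChar(enc$exceptions), "A")
  expect_identical(dq_roundtrip("FFAF", dom = "F"), "FFAF")
})

test_that("domqual: uniform strings produce no exceptions and tiny output", {
  quals <- rep(strrep("F", 100), 1000)
  enc <- gcol:::codec_domqual_encode(quals)
  expect_length(enc$exceptions, 0L)
  stored <- length(gcol:::codec_apply("LZMA", enc$runs))
  expect_lt(stored, 0.03 * sum(nchar(quals)))
  expect_identical(dq_roundtrip(quals), quals)
})

test_that("domqual round-trips random mixtures, empty strings, no-repeat strings", {
  set.seed(9)
  quals <- vapply(1:200, function(i) {
    paste(sample(c("F", "F", "F", ",", ":", "#"), sample(0:80, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  expect_identical(dq_roundtrip(quals), quals)
  # degenerate: dominant byte absent from some strings
  expect_identical(dq_roundtrip(c("ABCD", "", "FFFF"), dom = "F"),
                   c("ABCD", "", "FFFF"))
})

test_that("hapmat greedy ordering places identical rows adjacently", {
  m <- rbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L),
             c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  perm <- gcol:::hapmat_order(m)
  # independent enumeration of the greedy walk: start 1; nearest to row 1 is
  # row 3 (distance 0); then rows 2,4 (identical) follow
  expect_equal(perm, c(1L, 3L, 2L, 4L))
  adj <- cbind(perm[-length(perm)], perm[-1])
  d <- apply(adj, 1L, function(p) sum(m[p[1], ] != m[p[2], ]))
  expect_equal(d[1], 0)   # identical pair adjacent
})

test_that("hapmat encode/decode is exact for random matrices incl. missing codes", {
  set.seed(11)
  for (i in 1:25) {
    nh <- sample(1:12, 1); nv <- sample(1:30, 1)
    m <- matrix(sample(c(0L, 1L, 2L, 254L, 255L), nh * nv, replace = TRUE,
                       prob = c(.45, .3, .05, .1, .1)), nh, nv)
    enc <- gcol:::codec_hapmat_encode(m)
    dec <- gcol:::codec_hapmat_decode(enc$perm, enc$bytes, nh, nv)
    expect_identical(dec, m)
  }
  expect_error(gcol:::codec_hapmat_encode("no"), "matrix")
})

test_that("segmenter-forced codecs are honoured in stats output", {
  fa <- ref_fa()
  rd <- gen_reads(fx("force.fastq"), fa, n_reads = 300L, seed = 103L)
  arc <- tempfile(fileext = ".gcol")
  gcol_compress(fx("force.fastq"), arc)
  st <- gcol_stats(arc)
  expect_equal(st$codec[st$context == "NONREF" & st$stream == "local"], "ACGT")
  expect_equal(st$codec[st$context == "QUAL" & st$stream == "local"], "DOMQUAL")
  vcf <- gen_vcf(fx("force.vcf"), fa, n_variants = 200L, n_samples = 4L, seed = 104L)
  arc2 <- tempfile(fileext = ".gcol")
  gcol_compress(fx("force.vcf"), arc2)
  st2 <- gcol_stats(arc2)
  expect_equal(st2$codec[st2$context == "GT" & st2$stream == "local"], "HAPMAT")
  unlink(c(arc, arc2))
})
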