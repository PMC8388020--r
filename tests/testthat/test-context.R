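# context machinery: seg ops, clone/merge lifecycle, singleton rule

new_vb1 <- function() {
  z <- gcol:::new_zstate()
  list(z = z, vb = gcol:::new_vblock(1L, z))
}

test_that("seg stores each distinct payload once and indexes every occurrence", {
  s <- new_vb1()
  ctx <- gcol:::vb_ctx(s$vb, "FILTER")
  gcol:::ctx_seg(ctx, c("PASS", "PASS"))
  expect_equal(length(ctx$new), 1L)
  expect_equal(unlist(ctx$b250), c(0L, 0L))
  s <- new_vb1()
  ctx <- gcol:::vb_ctx(s$vb, "X")
  gcol:::ctx_seg(ctx, c("A", "B", "A"))
  expect_equal(ctx$new, c("A", "B"))
  expect_equal(unlist(ctx$b250), c(0L, 1L, 0L))
})

test_that("10k distinct payloads produce a 10k dictionary with unique indices", {
  s <- new_vb1()
  ctx <- gcol:::vb_ctx(s$vb, "X")
  payloads <- paste0("v", seq_len(10000L))
  gcol:::ctx_seg(ctx, payloads)
  expect_equal(length(ctx$new), length(unique(payloads)))  # brute-force set check
  b <- unlist(ctx$b250)
  expect_equal(anyDuplicated(b), 0L)
  expect_identical(ctx$new[b + 1L], payloads)
})

test_that("seg_pos stores per-line deltas that reconstruct positions", {
  s <- new_vb1()
  ctx <- gcol:::vb_ctx(s$vb, "POS")
  gcol:::ctx_seg_pos(ctx, c("100", "105", "105"))
  snips <- ctx$new[unlist(ctx$b250) + 1L]
  deltas <- as.numeric(sub("^.\\|", "", snips))
  expect_equal(deltas, c(100, 5, 0))
  # descending positions produce a negative delta
  s <- new_vb1(); ctx <- gcol:::vb_ctx(s$vb, "POS")
  gcol:::ctx_seg_pos(ctx, c("200", "150"))
  expect_equal(as.numeric(sub("^.\\|", "", ctx$new[unlist(ctx$b250) + 1L])),
               c(200, -50))
  # large positions survive exactly (round-trip via a VCF line pair)
  s <- new_vb1(); ctx <- gcol:::vb_ctx(s$vb, "POS")
  gcol:::ctx_seg_pos(ctx, c("1000000000", "1000000001"))
  expect_equal(as.numeric(sub("^.\\|", "", ctx$new[unlist(ctx$b250) + 1L])),
               c(1e9, 1))
})

test_that("seg_id splits prefix+number, preserves leading zeros, falls back verbatim", {
  s <- new_vb1()
  ctx <- gcol:::vb_ctx(s$vb, "ID")
  gcol:::ctx_seg_id(ctx, c("rs23424", "rs007", ".", "rs99999999999"))
  snips <- ctx$new[unlist(ctx$b250) + 1L]
  expect_equal(substr(snips[1], 1L, 2L), paste0("\x04", "i"))
  expect_match(snips[1], "0:rs$")              # natural width
  expect_match(snips[2], "3:rs$")              # width 3 keeps "007"
  expect_identical(snips[3], ".")              # verbatim fallback
  expect_identical(snips[4], "rs99999999999")  # >= 2^32 falls back
  expect_equal(unlist(ctx$local), c(23424, 7))
})

test_that("delta-vs-another-field stores the difference naming the base", {
  s <- new_vb1()
  ctx <- gcol:::vb_ctx(s$vb, "PNEXT")
  gcol:::ctx_seg_delta_vs(ctx, "1150", "1000", "POS")
  sn <- ctx$new[1]
  expect_identical(sn, paste0("\x02", "POS|150"))
})

nosing <- function(vb, name) {
  ctx <- gcol:::vb_ctx(vb, name)
  ctx$allow_singleton <- FALSE   # isolate cloning semantics from the
  ctx                            # singleton rule (tested separately)
}

test_that("cloned contexts keep global indices stable across vblocks", {
  z <- gcol:::new_zstate()
  vb1 <- gcol:::new_vblock(1L, z)
  gcol:::ctx_seg(nosing(vb1, "X"), c("a", "b", "a"))
  gcol:::merge_contexts(z, vb1)
  g <- gcol:::z_ctx(z, "X")
  expect_equal(g$dict, c("a", "b"))
  # vblock 2 re-uses only vblock-1 snips: no new dictionary entries
  vb2 <- gcol:::new_vblock(2L, z)
  ctx2 <- nosing(vb2, "X")
  idx <- gcol:::ctx_seg(ctx2, c("b", "a", "b"))
  expect_equal(length(ctx2$new), 0L)
  gcol:::merge_contexts(z, vb2)
  expect_equal(g$dict, c("a", "b"))
  expect_equal(ctx2$b250_final, c(1L, 0L, 1L))
  # vblock 3: same index for a snip first seen in vblock 1
  vb3 <- gcol:::new_vblock(3L, z)
  ctx3 <- nosing(vb3, "X")
  gcol:::ctx_seg(ctx3, c("a", "a"))
  gcol:::merge_contexts(z, vb3)
  expect_equal(ctx3$b250_final, c(0L, 0L))
  # disjoint snip sets across vblocks: union in vblock order
  vb4 <- gcol:::new_vblock(4L, z)
  gcol:::ctx_seg(nosing(vb4, "X"), c("zz", "zz"))
  gcol:::merge_contexts(z, vb4)
  expect_equal(g$dict, c("a", "b", "zz"))
})

test_that("empty global state clones to an empty context", {
  z <- gcol:::new_zstate()
  vb <- gcol:::new_vblock(1L, z)
  ctx <- gcol:::vb_ctx(vb, "NEW")
  expect_equal(ctx$gn, 0L)
  expect_equal(length(ctx$gdict), 0L)
})

test_that("singletons move to local and share one LOOKUP_LOCAL dictionary entry", {
  z <- gcol:::new_zstate()
  vb <- gcol:::new_vblock(1L, z)
  ctx <- gcol:::vb_ctx(vb, "NAMES")
  uniq <- paste0("name", 1:50)
  gcol:::ctx_seg(ctx, uniq)
  gcol:::merge_contexts(z, vb)
  g <- gcol:::z_ctx(z, "NAMES")
  expect_equal(g$dict, "\x01")   # only the escape entry
  expect_equal(unique(ctx$b250_final), 0L)
  expect_equal(unlist(ctx$local), uniq)  # payloads in occurrence order
  # a snip seen twice in one vblock merges normally
  z <- gcol:::new_zstate(); vb <- gcol:::new_vblock(1L, z)
  ctx <- gcol:::vb_ctx(vb, "NAMES")
  gcol:::ctx_seg(ctx, c("dup", "dup", "once"))
  gcol:::merge_contexts(z, vb)
  g <- gcol:::z_ctx(z, "NAMES")
  expect_true("dup" %in% g$dict)
  expect_false("once" %in% g$dict)
})

test_that("alias contexts resolve reads and writes to their target", {
  z <- gcol:::new_zstate()
  z$aliases[["MC:Z"]] <- "@CIGAR"
  vb <- gcol:::new_vblock(1L, z)
  c1 <- gcol:::vb_ctx(vb, "@CIGAR")
  c2 <- gcol:::vb_ctx(vb, "MC:Z")
  expect_identical(c1, c2)
  gcol:::ctx_seg(c1, "100M")
  gcol:::ctx_seg(c2, "100M")
  expect_equal(length(c1$new), 1L)
})
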