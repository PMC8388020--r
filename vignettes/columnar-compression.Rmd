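---
title: "Columnar compression of genomic formats: model, codecs and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Columnar compression of genomic formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcol)
```

This vignette is the package's account of what it computes and why the
design is the way it is. It states no measurement that the test suite and
`scripts/acceptance.R` do not themselves recompute.

## The model: contexts, snips, containers

A genomic text file is a sequence of records whose columns have wildly
different statistics. `gcol` separates them: every data component gets a
*context* with three streams.

* **dictionary** — each distinct value (*snip*) stored once. A snip may
  carry an opcode: `LOOKUP_LOCAL` (value comes from the local buffer),
  `DELTA` (numeric difference against the previous value of the same
  context, or against another field on the same line), `CONTAINER`
  (a serialised record layout), or `SPECIAL` (owned by a segmenter/codec
  pair, e.g. the sequence and genotype handlers). Verbatim payloads that
  begin with an opcode byte are escaped, so any byte string is a legal
  value.
* **b250** — one dictionary index per occurrence, stored as unsigned
  LEB128 varints: for small dictionaries each occurrence costs about one
  byte before generic compression.
* **local** — typed bulk data (text entries, uint32/int32, bitmaps, 2-bit
  packed bases, quality run lengths, the haplotype matrix).

Record structure itself is data: a `Container` lists items (context name,
prefix, separator, optional translator tag) and a repeat count; the
`TOPLEVEL` context holds one container per line. Decompression walks
`TOPLEVEL` and pulls one value per item from the named contexts — the
reconstructor has no per-format logic beyond codec inversion and the
`SPECIAL` handlers, which is what makes third-party segmenters (registered
with `gcol_register_segmenter()`) decompress unchanged. The reconstructor
processes runs of identical layouts vectorised, so heavily uniform files
(the common case) decode in bulk; files whose layout alternates line by
line still decode correctly, just run by run.

Segmentation has a strict ordering contract: every context's streams must
be written in line order *as the reconstructor will pull them*. Contexts
pulled more than once per line (the `@CIGAR` context shared with the
`MC:Z`/`OC:Z` aliases) are therefore written per layout run rather than
per vblock.

## vblocks, dictionaries and determinism

Input is chunked into *vblocks* of whole logical lines (a FASTQ "line" is
the 4-line record). The default vblock is 1 MiB — chosen for the package's
desk-scale fixtures; the upstream tool family defaults to 16 MiB, and the
`vblock_size` argument accepts any size. The vblock is the unit of
compression, of random access, and of parallelism.

Per-vblock context sets are cloned from a global state and merged back in
vblock order. A snip occurring exactly once in its vblock and absent from
the global dictionary (a *singleton* — read names, typically) is not
merged: its payload moves to the local buffer and its index is rewritten to
the shared `LOOKUP_LOCAL` entry, keeping dictionaries small.

With `workers > 1`, vblocks are segmented in parallel against empty
dictionary snapshots and the ordered merge re-matches every new snip
against the current global dictionary. Because global dictionaries grow
append-only and merges are committed in vblock order, the resulting
dictionary contents, indices and archive bytes are identical to the serial
path — the acceptance suite asserts byte identity. Self-referential state
is confined so vblocks decode standalone: positional `DELTA` anchors reset
at each vblock boundary (the first line stores its absolute value as a
delta from zero), which is what allows region queries to skip vblocks
entirely.

## Codecs

Generic codecs are LZMA, BZ2, ZLIB and STORE. Selection compresses the
first ≤ 100 KB of a stream with each candidate and keeps the best ratio,
unless a competitor is within 5% relative ratio (15% in `--fast` mode) and
at least twice as fast, in which case the faster codec wins. The speed side
of that rule uses a fixed relative-throughput table (LZMA 1, BZ2 3, ZLIB 8,
STORE 50) rather than wall-clock timing: measured times vary run to run,
and a timing-dependent choice would change the archive bytes between
identical runs, violating the determinism contract. The choice is made once
per context/stream and reused for all later vblocks.

Specific codecs transform a data type first and hand the result to a
generic codec:

* **acgt** — A/C/G/T → 2 bits, four bases per byte, high bits first; any
  other byte packs as `A` and is recorded in a companion exception stream
  (gap varint + literal byte), carried in the paired `*_X` context. Pure
  nucleotide data costs exactly ⌈n/4⌉ bytes before the generic pass;
  protein FASTA still round-trips, every byte through the exception
  stream.
* **domqual** — quality strings are coded as alternating run lengths of
  the dominant score and literal exception bytes. The dominant byte is the
  most frequent byte in a ≤ 100 KB sample of the component's first vblock,
  committed before segmentation starts so that worker scheduling cannot
  influence it. Decoding needs the string lengths, which the reconstructor
  has from the paired sequence value on the same line.
* **hapmat** — VCF `FORMAT/GT` alleles across a vblock form a matrix of
  haplotype rows (samples × ploidy) by variant columns, allele codes 0–253,
  `.` = 254, padding for mixed ploidy = 255. Rows are reordered by a greedy
  nearest-neighbour walk on Hamming distance (start at row 1, repeatedly
  append the closest unvisited row, ties to the lowest index), the
  permutation is stored, and the matrix is emitted column-major — similar
  rows adjacent make columns near-constant, which the generic codec
  exploits. Phase separators and per-entry ploidy travel in side contexts,
  so `0|1` vs `0/1` and mixed-ploidy records round-trip exactly.

A segmenter may force a codec (`NONREF` → acgt, `QUAL` → domqual, `GT` →
hapmat), overriding selection; the stats table reports these.

## Reference-based sequence encoding

`gcol_make_reference()` concatenates the contigs of a FASTA file into a
single 0-based 32-bit coordinate space (*gpos*), packs the bases with acgt
and samples a k-mer index: k = 14, every 4th position, candidate lists
capped at 8, k-mers containing non-ACGT skipped.

Aligned SAM records (RNAME/POS/CIGAR present) store one bitmap bit per
reference-consuming base — 1 if the base equals the reference — with
mismatching bases and non-consuming bases (insertions, soft clips) in
`NONREF`. Unmapped records and FASTQ reads go through the aligner: query
k-mers (stride 3) and their reverse complements vote for implied start
positions; the placement with most votes wins (ties: smaller gpos, forward
first), requiring at least 2 votes and a window inside one contig. The
alignment is gapless and makes no claim of biological correctness — it
exists to make the bitmap dense with 1s. Placed reads store gpos (uint32)
and a strand bit (1 = forward); unplaced reads fall back to acgt. With the
default index and query strides, an indexed position coincides with a query
position every 12 bases, so a 150-mer contributes ~12 agreeing votes and
exact reads are recovered essentially always (the suite asserts ≥ 99%).
Parameter trade-offs: larger k or stride shrink the index but cost recall
on short reads; the defaults suit the 100 kb/150 bp study scale and are
deliberately not exposed as user knobs.

Paired FASTQ mates are bound into one archive; mate-2 titles identical to
mate-1 become a single mate-copy snip, and mate-2 placements are stored as
int32 deltas against the mate-1 gpos of the same read index.

The VCF segmenter checks REF against the reference at POS and replaces
matching text with a length-only lookup snip (ALT is left as a dictionary
value: it rarely matches and the REF path already exercises the mechanism).

## Archive format and random access

A `.gcol` file is a sequence of typed sections (37-byte headers:
type, codec, local type, component, vblock, context name, lengths,
checksum), followed by global dictionaries, a random-access index and a
zlib-compressed JSON footer listing every section; the trailer stores the
footer offset, so any section is reachable with two seeks. Integers are
little-endian. Every section carries an Adler-32 of its compressed payload
— a deliberately cheap, vectorisable running-sum checksum — so stream
corruption is distinguished from a source-digest (MD5) mismatch; the CLI
maps the two to different exit codes. Each bound component stores its
original name, size and MD5 (computed over the uncompressed source), which
decompression always verifies.

The random-access index records, per vblock and chromosome, the minimum and
maximum position seen. Region queries decompress only intersecting vblocks
(an instrumented counter exposes this); lines are then filtered exactly, so
output equals a plain text filter. This index is coarse by design — the
cost of a query is one vblock, not one line. Sample subsetting and
SAM→FASTQ translation fully reconstruct the intersecting vblocks (every
context stream must be consumed to keep cursors aligned) and restrict at
emission; translation is driven by a stored alternate container whose
translator tags mean "reverse-complement if FLAG 0x10", "reverse if FLAG
0x10" and "drop secondary/supplementary/sequence-less records".

## Synthetic data: what it does and does not cover

The generator module produces every input class the tests use, as pure
functions of (parameters, seed): uniform-random references; reads sampled
uniformly with strand flips, point mutations (default 0.5%) and a
binned-quality model (one dominant score, default fraction 0.8, three
alternatives — the shape of modern instrument quality binning); VCFs with
sorted unique positions, reference-consistent REF and binomial genotypes at
a given minor-allele frequency; SAMs derived from the read truth table with
soft-clip, secondary and unmapped fractions; word-model text and uniform
random bytes for the generic path.

These fixtures exercise the machinery, not sequencing reality: there are no
indels (the aligner is gapless anyway), no position-dependent error
profiles, no duplicate or contaminant reads, no linkage structure in
genotypes, and references are random sequence with none of the repeat
content of real genomes. Passing tests therefore demonstrate correctness
(losslessness, determinism, index exactness) and the *direction* of the
compression effects (reference advantage, hapmat advantage), not the
compression factors reported on real multi-gigabyte archives. Problem sizes
in the suite — 100 kb reference, 50 k × 150 bp reads, 100 samples × 2 000
variants — were chosen once as representative desk-scale conditions.

## Numerical and degenerate-input choices

* Dictionary indices are global (archive-wide) with merges in vblock
  order; varints keep small indices cheap.
* Ties everywhere are broken deterministically: codec order LZMA > BZ2 >
  ZLIB > STORE, aligner ties to smaller gpos then forward strand, hapmat
  ties to the lowest row index.
* Containers are bounded at 255 items and 2^32 repeats (fixed-width header
  fields); context names at 16 bytes.
* Empty inputs produce valid archives (the empty MD5 constant); files
  without a trailing newline round-trip via a component flag; zero-repeat
  containers reconstruct empty text; `local` reads of zero length succeed
  without a section present.
* Read-name tokens are numeric only when ≤ 9 digits with no leading zero
  (uint32-safe and width-unambiguous); everything else stays text. ID
  fields keep an explicit digit-width byte when leading zeros must
  survive.
* Non-ACGT reference bases never match a read base (bitmap 0), keeping
  bitmap semantics byte-exact around N islands.

## Known limitations

* BAM/CRAM/BCF binary dialects are out of scope (SAM/VCF text only), as
  are encryption and lossy optimisation.
* `.gz` input is consumed transparently but decompression emits plain
  text; the original gzip container is not re-created byte-identically.
* The per-vblock interpreter is vectorised per layout run; pathological
  files alternating layouts every line decode correctly but slowly.
* Sample subsetting reconstructs whole vblocks before restricting columns;
  for very large sample counts a row-restricted haplotype decode would be
  the next optimisation.
* The aligner is gapless: an indel-containing read is stored verbatim (or
  with a dense mismatch tail) rather than split — a compression, not a
  correctness, cost.
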