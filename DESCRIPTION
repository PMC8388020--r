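Package: gcol
Title: Columnar Compression for Genomic File Formats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A universal, extensible, context-based columnar compressor for
    genomic file formats (FASTQ, SAM, VCF, FASTA, and arbitrary files).
    Format-specific segmenters decompose each record into per-field contexts
    holding a dictionary, an index stream and a local byte buffer; a generic
    framework compresses every context with automatically selected or
    field-specific codecs (2-bit nucleotide packing, dominant-quality
    run-length coding, haplotype-matrix permutation). Sequence reads can be
    encoded against a reference genome located by a compression-oriented
    k-mer aligner. Decompression is format-agnostic: record layout is
    rebuilt entirely from Container metadata stored in the archive, which
    also carries a random-access index, per-file MD5 digests, region and
    sample subsetting, downsampling, file binding and SAM-to-FASTQ
    translation.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    cli,
    stats,
    utils,
    parallel
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
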