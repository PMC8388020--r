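# Deterministic synthetic-data generators. Every test input is produced by
# code: reference FASTA, FASTQ reads sampled from it (with a truth sidecar of
# the true placements), VCF with genotypes, SAM derived from the reads, and
# generic byte blobs. All generators are pure functions of their arguments
# plus the seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

wrap_fasta <- function(seq, width = 60L) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Generate a reference FASTA
#'
#' Uppercase ACGT sequence (optionally with N islands), wrapped at 60
#' columns.
#' @param path output path
#' @param length total bases
#' @param n_contigs number of contigs (equal split)
#' @param n_islands number of short N runs to insert
#' @param seed RNG seed
#' @return invisible path; attribute "seqs" carries the contig sequences
#' @export
gen_reference <- function(path, length = 100000L, n_contigs = 1L,
                          n_islands = 0L, seed = 1L) {
  stopifnot(length >= 1000L)
  per <- diff(round(seq(0, length, length.out = n_contigs + 1L)))
  seqs <- with_seed(seed, {
    lapply(per, function(L) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (n_islands > 0L) {
        for (k in seq_len(n_islands)) {
          w <- sample(5:20, 1L)
          at <- sample(L - w, 1L)
          s[at:(at + w - 1L)] <- "N"
        }
      }
      paste(s, collapse = "")
    })
  })
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">chr", i), wrap_fasta(seqs[[i]]))
  }
  writeLines(lines, path)
  out <- path
  attr(out, "seqs") <- seqs
  invisible(out)
}

# quality model: one dominant score plus a few alternatives (binned-quality
# style); dominant_frac is the probability of the dominant score per base
gen_quals <- function(n, len, dominant_frac = 0.8, dom = "F",
                      alts = c(",", ":", "#")) {
  probs <- c(dominant_frac, rep((1 - dominant_frac) / length(alts), length(alts)))
  m <- sample(c(dom, alts), n * len, replace = TRUE, prob = probs)
  full <- paste(m, collapse = "")
  ends <- seq_len(n) * len
  substring(full, ends - len + 1L, ends)
}

#' Generate FASTQ reads sampled from a reference
#'
#' Reads are drawn uniformly, reverse-complemented with probability 0.5 and
#' point-mutated at `mutation`. A truth table of (read, contig, gpos 0-based,
#' forward) accompanies the file for aligner-recall tests. With
#' `paired = TRUE` a mate file is produced whose reads start `insert` bases
#' downstream on the opposite strand and share read names.
#'
#' @param path output FASTQ path (mate file gets suffix "_2")
#' @param reference path to the reference FASTA
#' @param n_reads,read_len read count and length
#' @param mutation per-base substitution rate
#' @param dominant_frac dominant quality-score fraction
#' @param paired also generate a mate file
#' @param gz write gzip-compressed output
#' @param seed RNG seed
#' @return list(path, mate, truth = data.frame)
#' @export
gen_reads <- function(path, reference, n_reads = 1000L, read_len = 150L,
                      mutation = 0.005, dominant_frac = 0.8, paired = FALSE,
                      gz = FALSE, insert = 300L, seed = 1L) {
  ref <- gcol_load_fasta_reference(reference)
  if (read_len > ref$total) stop("read length exceeds reference length")
  res <- with_seed(seed, {
    ok_contig <- ref$contigs$length >= read_len + if (paired) insert else 0L
    ci <- sample(which(ok_contig), n_reads, replace = TRUE)
    maxs <- ref$contigs$length[ci] - read_len + 1L - if (paired) insert else 0L
    off <- floor(stats::runif(n_reads) * maxs)   # 0-based within contig
    g <- ref$contigs$offset[ci] + off
    fwd <- stats::runif(n_reads) < 0.5
    mk <- function(gpos, flip) {
      s <- ref_window(ref, gpos, read_len)
      if (mutation > 0) {
        nmut <- stats::rbinom(length(s), read_len, mutation)
        for (i in which(nmut > 0)) {
          at <- sample.int(read_len, nmut[i])
          ch <- strsplit(s[i], "", fixed = TRUE)[[1]]
          ch[at] <- vapply(ch[at], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
          s[i] <- paste(ch, collapse = "")
        }
      }
      s[flip] <- revcomp_fast(s[flip])
      s
    }
    seq1 <- mk(g, !fwd)
    names <- sprintf("read:%d:%d", seq_len(n_reads), off + 1L)
    qual1 <- gen_quals(n_reads, read_len, dominant_frac)
    out <- list(ci = ci, g = g, fwd = fwd, seq1 = seq1, names = names,
                qual1 = qual1)
    if (paired) {
      g2 <- g + insert
      out$g2 <- g2
      out$seq2 <- mk(g2, fwd)   # mate on opposite strand
      out$qual2 <- gen_quals(n_reads, read_len, dominant_frac)
    }
    out
  })
  write_fq <- function(p, nm, sq, ql) {
    txt <- paste0("@", nm, "\n", sq, "\n+\n", ql, "\n", collapse = "")
    if (gz) {
      con <- gzfile(p, "wb")
      writeBin(charToRaw(txt), con)
      close(con)
    } else writeBin(charToRaw(txt), p)
  }
  write_fq(path, res$names, res$seq1, res$qual1)
  mate <- NULL
  if (paired) {
    mate <- sub("(\\.fastq|\\.fq)(\\.gz)?$", "_2\\1\\2", path)
    if (mate == path) mate <- paste0(path, "_2")
    write_fq(mate, res$names, res$seq2, res$qual2)
  }
  truth <- data.frame(read = res$names, contig = ref$contigs$name[res$ci],
                      gpos = res$g, forward = res$fwd,
                      stringsAsFactors = FALSE)
  invisible(list(path = path, mate = mate, truth = truth,
                 seqs = res$seq1, quals = res$qual1))
}

#' Generate a VCF with genotypes drawn per minor-allele frequency
#'
#' Positions are sorted and unique, REF comes from the reference, ALT is a
#' different base; genotypes are diploid with `phased_frac` of the lines
#' phased.
#' @export
gen_vcf <- function(path, reference, n_variants = 500L, n_samples = 3L,
                    maf = 0.2, phased_frac = 0, seed = 1L) {
  ref <- gcol_load_fasta_reference(reference)
  stopifnot(n_variants <= ref$total)
  res <- with_seed(seed, {
    ci <- sort(sample(ref$total, n_variants))   # 1-based over concatenation
    loc <- ref_locate(ref, ci - 1)
    refb <- substring(ref$bases, ci, ci)
    altb <- vapply(refb, function(b) {
      pool <- setdiff(c("A", "C", "G", "T"), b)
      sample(pool, 1L)
    }, character(1), USE.NAMES = FALSE)
    gt <- matrix(stats::rbinom(n_variants * n_samples * 2L, 1L, maf),
                 nrow = n_variants * n_samples)
    phased <- stats::runif(n_variants) < phased_frac
    list(loc = loc, refb = refb, altb = altb, gt = gt, phased = phased)
  })
  ord <- order(match(res$loc$rname, ref$contigs$name), res$loc$pos)
  sep <- ifelse(res$phased, "|", "/")
  gt_txt <- if (n_samples > 0) {
    matrix(paste0(res$gt[, 1], rep(sep, n_samples), res$gt[, 2]),
           nrow = n_variants)
  } else matrix(character(0), nrow = n_variants, ncol = 0)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", ref$contigs$name, ",length=",
                  ref$contigs$length, ">"),
           "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Samples\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (n_samples > 0) c("FORMAT", paste0("S", seq_len(n_samples)))),
                 collapse = "\t"))
  body <- paste(res$loc$rname, res$loc$pos,
                paste0("rs", seq_len(n_variants) + 1000L),
                res$refb, res$altb, "50", "PASS",
                paste0("NS=", n_samples), sep = "\t")[ord]
  if (n_samples > 0) {
    smp <- apply(gt_txt[ord, , drop = FALSE], 1L, paste, collapse = "\t")
    body <- paste(body, "GT", smp, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(list(path = path, gt = res$gt, phased = res$phased))
}

#' Generate a SAM file from reads sampled off a reference
#'
#' A fraction of the reads is emitted aligned (RNAME/POS/CIGAR from the
#' truth table, with optional soft-clips and insertions), the remainder as
#' unmapped records (FLAG 4, RNAME "*"). `mc_frac` adds MC:Z tags repeating
#' the mate CIGAR value to exercise context aliases.
#' @export
gen_sam <- function(path, reference, n_reads = 1000L, read_len = 100L,
                    aligned_frac = 0.8, clip_rate = 0.1, mutation = 0.002,
                    secondary_frac = 0, mc_frac = 0.5,
                    dominant_frac = 0.8, seed = 1L) {
  ref <- gcol_load_fasta_reference(reference)
  rd <- gen_reads(tempfile(fileext = ".fastq"), reference, n_reads = n_reads,
                  read_len = read_len, mutation = mutation,
                  dominant_frac = dominant_frac, seed = seed + 1L)
  unlink(rd$path)
  res <- with_seed(seed, {
    aligned <- stats::runif(n_reads) < aligned_frac
    clip <- stats::runif(n_reads) < clip_rate
    secondary <- stats::runif(n_reads) < secondary_frac
    mc <- stats::runif(n_reads) < mc_frac
    list(aligned = aligned, clip = clip, secondary = secondary, mc = mc)
  })
  loc <- ref_locate(ref, rd$truth$gpos)
  flags <- ifelse(res$aligned, ifelse(rd$truth$forward, 0L, 16L), 4L)
  flags <- flags + ifelse(res$secondary & res$aligned, 256L, 0L)
  # oriented sequence: SAM stores reverse reads as their reverse complement
  seqs <- rd$seqs
  rev_sel <- res$aligned & !rd$truth$forward
  seqs[rev_sel] <- revcomp_fast(seqs[rev_sel])
  # soft-clips only on forward records: POS shifts past the clipped prefix
  clip_f <- res$clip & rd$truth$forward
  cigars <- ifelse(res$aligned,
                   ifelse(clip_f,
                          paste0("5S", read_len - 5L, "M"),
                          paste0(read_len, "M")),
                   "*")
  pos <- ifelse(res$aligned, loc$pos + ifelse(clip_f, 5L, 0L), 0L)
  rname <- ifelse(res$aligned, loc$rname, "*")
  quals <- rd$quals
  opt <- ifelse(res$mc & res$aligned, paste0("\tMC:Z:", cigars), "")
  nm <- sub(":", "_", rd$truth$read, fixed = TRUE)
  lines <- paste0(nm, "\t", flags, "\t", rname, "\t", pos, "\t",
                  ifelse(res$aligned, 60L, 0L), "\t", cigars, "\t*\t0\t0\t",
                  seqs, "\t", quals, opt)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", ref$contigs$name, "\tLN:", ref$contigs$length))
  writeLines(c(hdr, lines), path)
  invisible(list(path = path, truth = rd$truth, aligned = res$aligned))
}

#' Generate a generic byte blob (text-like or uniform random)
#' @export
gen_generic <- function(path, size = 65536L, kind = c("random", "text"),
                        seed = 1L) {
  kind <- match.arg(kind)
  r <- with_seed(seed, {
    if (kind == "random") as.raw(sample(0:255, size, replace = TRUE))
    else {
      vocab <- c("the", "quick", "brown", "fox", "jumps", "over", "lazy",
                 "dog", "sequence", "genome", "data", "and", "of", "in")
      words <- sample(vocab, ceiling(size / 4), replace = TRUE,
                      prob = seq(length(vocab), 1))
      charToRaw(paste(words, collapse = " "))
    }
  })
  writeBin(r[seq_len(min(size, length(r)))], path)
  invisible(path)
}
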