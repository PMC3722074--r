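#' Simulate single-end exome-capture reads from both alleles
#'
#' Each read is drawn by (1) picking a (target, allele) source with
#' probability proportional to its extended-interval length times an allelic
#' capture weight, (2) picking a start position uniformly over
#' `[start - (read_length - 1), end - 1]` on the source genome so that any
#' placement overlapping the target is equally likely, (3) a fair-coin
#' strand, and (4) copying `read_length` error-free bases from the chosen
#' genome (reverse-complemented on the minus strand) with constant Q40
#' qualities.
#'
#' The capture weight of the strain-B allele of a target with `nSNV` SNVs and
#' `nIndel` indels is `exp(-beta_snv * nSNV - beta_indel * nIndel)`; the
#' strain-A weight is always 1. With `beta_snv = beta_indel = 0` the
#' per-(target, allele) selection probability is exactly the interval length
#' divided by the cumulative length of all 2 x n_targets intervals, i.e. an
#' unbiased capture.
#'
#' Reads that would run past a chromosome end are resampled within the same
#' (target, allele) source, preserving the per-source marginal.
#'
#' @param targets Annotated target tibble with extended A and B intervals.
#' @param genome_a,genome_b The two parental genomes.
#' @param n_reads Number of reads to generate.
#' @param read_length Read length in bases (default 101).
#' @param beta_snv,beta_indel Per-SNV and per-indel log-weight penalties
#'   (>= 0) applied to the strain-B allele.
#' @param error_rate Optional uniform substitution-error rate (default 0;
#'   the capture simulator itself is error-free).
#' @param seed Integer seed.
#' @return A read tibble: id, seq, target_id, allele ("A"/"B"), chrom, start
#'   (0-based on the source genome), strand. Truth labels are embedded in
#'   `id` for FASTQ round-tripping.
#' @export
simulate_exome_reads <- function(targets, genome_a, genome_b, n_reads,
                                 read_length = 101L, beta_snv = 0,
                                 beta_indel = 0, error_rate = 0, seed = 1L) {
  stopifnot_scalar_int(n_reads, "n_reads", min = 1)
  if (nrow(targets) == 0) rlang::abort("no targets to simulate from")
  if (any(is.na(targets$startB))) {
    rlang::abort("targets must carry orthologous strain-B intervals")
  }
  if (beta_snv < 0 || beta_indel < 0) {
    rlang::abort("bias penalties must be >= 0")
  }
  withr::local_seed(seed)
  nt <- nrow(targets)
  len_a <- targets$endA - targets$startA
  len_b <- targets$endB - targets$startB
  pen <- rep(0, nt)
  if (beta_snv > 0 || beta_indel > 0) {
    if (anyNA(targets$nSNV) || anyNA(targets$nIndel)) {
      rlang::abort(
        "targets must be divergence-annotated when bias penalties are nonzero")
    }
    pen <- beta_snv * targets$nSNV + beta_indel * targets$nIndel
  }
  w <- c(len_a, len_b * exp(-pen))
  src <- sample.int(2L * nt, n_reads, replace = TRUE, prob = w / sum(w))
  allele <- ifelse(src > nt, "B", "A")
  ti <- ifelse(src > nt, src - nt, src)
  start_lo <- ifelse(allele == "A", targets$startA[ti], targets$startB[ti]) -
    (read_length - 1L)
  start_hi <- ifelse(allele == "A", targets$endA[ti], targets$endB[ti]) - 1L
  chrom <- targets$chrom[ti]
  lens_a <- genome_lengths(genome_a)
  lens_b <- genome_lengths(genome_b)
  chrom_len <- ifelse(allele == "A", lens_a[chrom], lens_b[chrom])
  n_pos <- start_hi - start_lo + 1L
  start <- start_lo + floor(runif(n_reads) * n_pos)
  # resample starts that would run off the chromosome
  bad <- which(start < 0 | start + read_length > chrom_len)
  while (length(bad) > 0) {
    start[bad] <- start_lo[bad] + floor(runif(length(bad)) * n_pos[bad])
    bad <- bad[start[bad] < 0 | start[bad] + read_length > chrom_len[bad]]
  }
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seq <- extract_read_seqs(genome_a, genome_b, allele, chrom, start,
                           read_length, strand)
  if (error_rate > 0) seq <- inject_errors(seq, error_rate)
  id <- sprintf("r%07d|%s|%s|%s|%d|%s", seq_len(n_reads), targets$id[ti],
                allele, chrom, start, strand)
  tibble::tibble(id = id, seq = seq, target_id = targets$id[ti],
                 allele = allele, chrom = chrom, start = as.integer(start),
                 strand = strand)
}

#' Simulate uniform whole-genome control reads
#'
#' The source strain is a fair coin per read, the start position is uniform
#' over all placements that fit on the chosen genome, and the strand is a
#' fair coin; qualities are constant Q40. This is the no-capture control
#' channel.
#'
#' @inheritParams simulate_exome_reads
#' @return A read tibble as in [simulate_exome_reads()] with `target_id` NA.
#' @export
simulate_wgs_reads <- function(genome_a, genome_b, n_reads,
                               read_length = 101L, seed = 1L) {
  stopifnot_scalar_int(n_reads, "n_reads", min = 1)
  withr::local_seed(seed)
  allele <- sample(c("A", "B"), n_reads, replace = TRUE)
  lens_a <- genome_lengths(genome_a)
  lens_b <- genome_lengths(genome_b)
  chrom <- character(n_reads)
  for (al in c("A", "B")) {
    lens <- if (al == "A") lens_a else lens_b
    sel <- allele == al
    slots <- pmax(0, lens - read_length + 1)
    chrom[sel] <- sample(names(lens), sum(sel), replace = TRUE,
                         prob = slots / sum(slots))
  }
  chrom_len <- ifelse(allele == "A", lens_a[chrom], lens_b[chrom])
  start <- floor(runif(n_reads) * (chrom_len - read_length + 1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seq <- extract_read_seqs(genome_a, genome_b, allele, chrom, start,
                           read_length, strand)
  id <- sprintf("w%07d|*|%s|%s|%d|%s", seq_len(n_reads), allele, chrom,
                start, strand)
  tibble::tibble(id = id, seq = seq, target_id = NA_character_,
                 allele = allele, chrom = chrom, start = as.integer(start),
                 strand = strand)
}

# vectorised sequence extraction grouped by (allele, chrom)
extract_read_seqs <- function(genome_a, genome_b, allele, chrom, start,
                              read_length, strand) {
  seq <- character(length(allele))
  for (al in c("A", "B")) {
    g <- if (al == "A") genome_a else genome_b
    for (ch in unique(chrom[allele == al])) {
      sel <- which(allele == al & chrom == ch)
      s <- as.character(g[[ch]])
      seq[sel] <- substring(s, start[sel] + 1L, start[sel] + read_length)
    }
  }
  rev <- strand == "-"
  if (any(rev)) seq[rev] <- revcomp_chr(seq[rev])
  seq
}

inject_errors <- function(seq, error_rate) {
  n <- nchar(seq[1])
  hit <- which(runif(length(seq) * n) < error_rate)
  if (length(hit) == 0) return(seq)
  ri <- (hit - 1L) %/% n + 1L
  pi <- (hit - 1L) %% n + 1L
  for (j in seq_along(hit)) {
    old <- substr(seq[ri[j]], pi[j], pi[j])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(seq[ri[j]], pi[j], pi[j]) <- new
  }
  seq
}
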