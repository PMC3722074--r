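# Readers and writers for the standard interchange formats used by the
# pipeline: FASTA (genomes), FASTQ (reads with truth labels in the id), BED
# (targets), VCF (truth variants and calls), SAM (alignments) and the
# liftover TSV. Coordinates are 0-based half-open everywhere except VCF and
# SAM POS, which are 1-based per their specifications.

#' Write a genome as FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @param strain Strain label to attach.
#' @export
read_genome_fasta <- function(path, strain = "A") {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  S4Vectors::metadata(g) <- list(strain_label = strain)
  g
}

#' Write truth variants as VCF
#'
#' Strain A is the reference; the derived strain-B allele of the F1 hybrid is
#' written as a phased heterozygous genotype `1|0`.
#' @param truth Truth tibble (chrom, pos 0-based, kind, ref, alt).
#' @param genome Reference genome (for contig headers).
#' @param path Output file.
#' @export
write_truth_vcf <- function(truth, genome, path) {
  lens <- genome_lengths(genome)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "F1", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1|0",
                  truth$chrom, truth$pos + 1L, truth$ref, truth$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a truth-variant VCF written by [write_truth_vcf()]
#' @param path VCF file.
#' @return Truth tibble with 0-based positions and a `kind` column.
#' @export
read_truth_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          kind = character(), ref = character(),
                          alt = character()))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  ref <- vapply(f, `[`, "", 4L)
  alt <- vapply(f, `[`, "", 5L)
  kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                 ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  tibble::tibble(chrom = vapply(f, `[`, "", 1L),
                 pos = as.integer(vapply(f, `[`, "", 2L)) - 1L,
                 kind = kind, ref = ref, alt = alt)
}

#' Write targets as BED
#'
#' Standard BED columns chrom/start/end/name (0-based half-open); when the
#' orthologous strain-B interval is present it is carried in columns 7-8.
#' @param targets Target tibble.
#' @param path Output file.
#' @export
write_targets_bed <- function(targets, path) {
  has_b <- nrow(targets) > 0 && !all(is.na(targets$startB))
  lines <- if (has_b) {
    sprintf("%s\t%d\t%d\t%s\t0\t+\t%d\t%d", targets$chrom, targets$startA,
            targets$endA, targets$id, targets$startB, targets$endB)
  } else {
    sprintf("%s\t%d\t%d\t%s", targets$chrom, targets$startA, targets$endA,
            targets$id)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a targets BED written by [write_targets_bed()]
#' @param path BED file.
#' @export
read_targets_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- if (length(f) > 0) length(f[[1]]) else 4L
  tg <- tibble::tibble(
    id = vapply(f, `[`, "", 4L),
    chrom = vapply(f, `[`, "", 1L),
    startA = as.integer(vapply(f, `[`, "", 2L)),
    endA = as.integer(vapply(f, `[`, "", 3L)),
    startB = if (nf >= 8) as.integer(vapply(f, `[`, "", 7L)) else NA_integer_,
    endB = if (nf >= 8) as.integer(vapply(f, `[`, "", 8L)) else NA_integer_,
    nSNV = NA_integer_, nIndel = NA_integer_, extended = FALSE)
  tg
}

#' Write a liftover map as TSV
#' @param liftover Liftover tibble (chrom, a_start, a_end, offset).
#' @param path Output file.
#' @export
write_liftover_tsv <- function(liftover, path) {
  utils::write.table(liftover, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Truth labels (target id or chromosome, source strain, 0-based start on the
#' source genome, strand) are encoded in the read id after `|` separators so
#' that a written file round-trips losslessly. Base qualities are constant
#' Q40 (`I` in Sanger encoding).
#' @param reads Read tibble from [simulate_exome_reads()] or
#'   [simulate_wgs_reads()].
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  out <- character(4L * nrow(reads))
  idx <- seq_len(nrow(reads))
  out[4L * idx - 3L] <- paste0("@", reads$id)
  out[4L * idx - 2L] <- reads$seq
  out[4L * idx - 1L] <- "+"
  out[4L * idx] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ written by [write_fastq()], decoding truth labels
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  ids <- sub("^@", "", ln[seq(1, length(ln), by = 4)])
  seqs <- ln[seq(2, length(ln), by = 4)]
  parts <- strsplit(ids, "|", fixed = TRUE)
  tibble::tibble(
    id = ids, seq = seqs,
    target_id = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""),
    allele = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, ""),
    chrom = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""),
    start = vapply(parts, function(p) if (length(p) >= 5) as.integer(p[5]) else NA_integer_, 1L),
    strand = vapply(parts, function(p) if (length(p) >= 6) p[6] else NA_character_, ""))
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM: FLAG carries the strand bit (and 4 for unmapped),
#' MAPQ is 60 for unique placements and 0 otherwise, and the NM tag holds the
#' edit distance.
#' @param alignments Alignment tibble from [map_reads()].
#' @param index The [build_index()] object the alignments refer to (for
#'   header contig lines).
#' @param path Output file.
#' @param reads Optional read tibble supplying sequences for the SEQ column.
#' @export
write_sam <- function(alignments, index, path, reads = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$chrom_names, index$chrom_lens))
  seqs <- rep("*", nrow(alignments))
  if (!is.null(reads)) {
    m <- match(alignments$read_id, reads$id)
    seqs <- reads$seq[m]
    rev <- alignments$strand == "-"
    seqs[rev] <- revcomp_chr(seqs[rev])
  }
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  mapq <- ifelse(alignments$is_unique, 60L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  alignments$read_id, flag, alignments$chrom,
                  alignments$pos + 1L, mapq, alignments$cigar, seqs,
                  alignments$edit)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM written by [write_sam()]
#' @param path SAM file.
#' @param genome_label Label to attach to the records.
#' @export
read_sam <- function(path, genome_label = "A") {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x, value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  }, 1L)
  tibble::tibble(
    read_id = vapply(f, `[`, "", 1L),
    genome = genome_label,
    chrom = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(as.integer(vapply(f, `[`, "", 2L)), 16L) > 0,
                    "-", "+"),
    edit = nm,
    cigar = vapply(f, `[`, "", 6L),
    ref_len = cigar_ref_len(vapply(f, `[`, "", 6L)),
    is_unique = as.integer(vapply(f, `[`, "", 5L)) >= 60L)
}

# reference span consumed by a CIGAR (M and D consume reference)
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[MID]", cg))[[1]]
    sum(n[op %in% c("M", "D")])
  }, 1L, USE.NAMES = FALSE)
}

#' Write heterozygous SNV calls as VCF
#' @param calls Call tibble from [call_het_snvs()].
#' @param genome Reference (strain A) genome.
#' @param path Output file.
#' @export
write_vcf <- function(calls, genome, path) {
  lens <- genome_lengths(genome)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sample", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t0/1:%d:%d,%d",
                  calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
                  calls$depth, calls$depth - calls$alt_count,
                  calls$alt_count)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a calls VCF written by [write_vcf()]
#' @param path VCF file.
#' @export
read_calls_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          depth = integer(), alt_count = integer()))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  fmt <- strsplit(vapply(f, `[`, "", 10L), ":", fixed = TRUE)
  ad <- strsplit(vapply(fmt, `[`, "", 3L), ",", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(f, `[`, "", 1L),
    pos = as.integer(vapply(f, `[`, "", 2L)) - 1L,
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L),
    depth = as.integer(vapply(fmt, `[`, "", 2L)),
    alt_count = as.integer(vapply(ad, `[`, "", 2L)))
}
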