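#' Build an exact k-mer index over a genome
#'
#' Every position whose k-mer contains only A/C/G/T is indexed; k-mers
#' containing N are skipped. The index backs the seed-and-extend mapper.
#'
#' @param genome Genome to index.
#' @param k Seed length, 8..32 (default 20).
#' @param label Genome label carried into alignment records (defaults to the
#'   genome's strain label).
#' @return An object of class `genome_index`.
#' @export
build_index <- function(genome, k = 20L, label = NULL) {
  if (k < 8 || k > 32) rlang::abort("seed length k must be in [8, 32]")
  seqs <- genome_as_character(genome)
  ptr <- cpp_build_index(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 label = label %||% strain_label(genome),
                 chrom_names = names(seqs),
                 chrom_lens = unname(vapply(seqs, nchar, integer(1)))),
            class = "genome_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index '%s': %d chromosomes, %s bp, k = %d>\n",
              x$label, length(x$chrom_names),
              format(sum(x$chrom_lens), big.mark = ","), x$k))
  invisible(x)
}

#' Look up the exact positions of a k-mer in an index
#' @param index A [build_index()] object.
#' @param kmer A k-length DNA string.
#' @return Tibble of chrom, pos (0-based) exact occurrences.
#' @export
index_lookup <- function(index, kmer) {
  hit <- cpp_index_lookup(index$ptr, kmer)
  pos <- attr(hit, "pos")
  if (length(hit) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer()))
  }
  tibble::tibble(chrom = index$chrom_names[as.integer(hit)],
                 pos = as.integer(pos))
}

#' Map reads to a genome by seed-and-extend banded alignment
#'
#' Both strands are seeded with evenly spaced non-overlapping exact k-mer
#' seeds; every candidate locus is scored with a semi-global edit-distance
#' alignment (substitutions, insertions and deletions each cost 1), and all
#' loci attaining the minimal edit distance <= `max_edit` are reported. A
#' read is unique iff exactly one minimal-distance locus exists. Reads whose
#' best alignment exceeds `max_edit` are unmapped and absent from the result,
#' which reproduces the mappability cliff where reads carrying more than
#' `max_edit` variants against a genome cannot be placed on it.
#'
#' @param reads Read tibble (columns `id`, `seq`) or character vector of
#'   sequences.
#' @param index A [build_index()] object.
#' @param max_edit Maximum edit distance (default 5).
#' @param n_seeds Seeds per strand (default 4).
#' @return Alignment tibble: read_id, genome, chrom, pos (0-based leftmost),
#'   strand, edit, cigar, ref_len, n_best, is_unique.
#' @export
map_reads <- function(reads, index, max_edit = 5L, n_seeds = 4L) {
  if (is.character(reads)) {
    reads <- tibble::tibble(id = paste0("q", seq_along(reads)), seq = reads)
  }
  res <- cpp_map_reads(index$ptr, reads$seq, as.integer(max_edit),
                       as.integer(n_seeds))
  tibble::tibble(
    read_id = reads$id[res$read],
    genome = index$label,
    chrom = index$chrom_names[res$chrom],
    pos = res$pos,
    strand = ifelse(res$rev, "-", "+"),
    edit = res$edit,
    cigar = res$cigar,
    ref_len = res$ref_len,
    n_best = res$n_best,
    is_unique = res$n_best == 1L)
}

#' Map reads to both parental genomes
#'
#' Runs [map_reads()] against each genome and combines the per-genome best
#' placements into one row per read. Reads that map to multiple
#' equally-good positions in one or both genomes are flagged
#' `status = "multi"` and are discarded by all downstream analyses.
#'
#' @param reads Read tibble.
#' @param index_a,index_b Indexes over the two genomes.
#' @inheritParams map_reads
#' @return A dual-mapping tibble with one row per read that mapped to at
#'   least one genome: read_id, status ("both", "only_A", "only_B", "multi"),
#'   and chrom/pos/strand/edit/ref_len for each side (NA when absent).
#' @export
map_reads_dual <- function(reads, index_a, index_b, max_edit = 5L,
                           n_seeds = 4L) {
  aln_a <- map_reads(reads, index_a, max_edit, n_seeds)
  aln_b <- map_reads(reads, index_b, max_edit, n_seeds)
  combine_dual(aln_a, aln_b)
}

#' Combine per-genome alignments into a dual-mapping table
#'
#' @param aln_a,aln_b Alignment tibbles for the two genomes (all reported
#'   loci, as returned by [map_reads()]). Deduplicated tibbles (one record
#'   per read) are also accepted.
#' @return See [map_reads_dual()].
#' @export
combine_dual <- function(aln_a, aln_b) {
  side <- function(aln, suffix) {
    multi <- unique(aln$read_id[!aln$is_unique])
    uni <- aln[aln$is_unique, c("read_id", "chrom", "pos", "strand", "edit",
                                "ref_len")]
    names(uni)[-1] <- paste0(c("chrom_", "pos_", "strand_", "edit_",
                               "ref_len_"), suffix)
    list(multi = multi, uni = uni)
  }
  a <- side(aln_a, "a")
  b <- side(aln_b, "b")
  dm <- dplyr::full_join(a$uni, b$uni, by = "read_id")
  dm$status <- dplyr::case_when(
    !is.na(dm$edit_a) & !is.na(dm$edit_b) ~ "both",
    !is.na(dm$edit_a) ~ "only_A",
    TRUE ~ "only_B")
  multi <- union(a$multi, b$multi)
  extra <- setdiff(multi, dm$read_id)
  if (length(extra) > 0) {
    dm <- dplyr::bind_rows(dm, tibble::tibble(read_id = extra))
  }
  dm$status[dm$read_id %in% multi] <- "multi"
  dm
}

#' Remove PCR duplicates from an alignment table
#'
#' Among records sharing (genome, chrom, pos, strand) exactly one is
#' retained — the lexicographically smallest read id, for determinism.
#'
#' @param records Alignment tibble.
#' @return The deduplicated tibble.
#' @export
remove_duplicates <- function(records) {
  records %>%
    dplyr::arrange(.data$genome, .data$chrom, .data$pos, .data$strand,
                   .data$read_id) %>%
    dplyr::distinct(.data$genome, .data$chrom, .data$pos, .data$strand,
                    .keep_all = TRUE)
}
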