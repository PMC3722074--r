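# Two-strategy comparison identifying targets confounded by mapping bias:
# reads are mapped either to both parental genomes (dual strategy) or to
# strain A alone; a target where the two strategies recover different
# numbers of reads loses reads purely through alignment and is excluded
# from variant-detection analyses.

# (read_id, target_id) overlap pairs of alignment records vs target intervals
overlap_pairs <- function(records, targets, start_col, end_col) {
  out <- list()
  for (ch in unique(targets$chrom)) {
    tsel <- which(targets$chrom == ch)
    rsel <- which(records$chrom == ch)
    if (length(rsel) == 0) next
    ir_t <- IRanges::IRanges(targets[[start_col]][tsel] + 1L,
                             targets[[end_col]][tsel])
    ir_r <- IRanges::IRanges(records$pos[rsel] + 1L,
                             records$pos[rsel] + records$ref_len[rsel])
    hits <- IRanges::findOverlaps(ir_r, ir_t)
    if (length(hits) == 0) next
    out[[ch]] <- tibble::tibble(
      read_id = records$read_id[rsel[S4Vectors::queryHits(hits)]],
      target_id = targets$id[tsel[S4Vectors::subjectHits(hits)]])
  }
  dplyr::bind_rows(out)
}

#' Count reads recovered per target under the two mapping strategies
#'
#' `n_dual` counts deduplicated reads that map uniquely to at least one
#' genome (and to multiple positions in neither) and overlap the target on
#' whichever genome they are placed on. `n_single` counts deduplicated reads
#' that map uniquely to strain A and overlap the target's strain-A interval
#' — the single-reference strategy, which silently loses divergent-allele
#' reads. Deduplication uses the strain-A placement when one exists, so the
#' two strategies collapse duplicates identically on undiverged targets.
#'
#' @param reads Read tibble (an unbiased simulated replicate).
#' @param index_a,index_b Genome indexes.
#' @param targets Target tibble with extended A and B intervals.
#' @param max_edit,n_seeds Aligner parameters.
#' @return Tibble: target_id, n_dual, n_single.
#' @export
count_mapped_two_strategies <- function(reads, index_a, index_b, targets,
                                        max_edit = 5L, n_seeds = 4L) {
  aln_a <- map_reads(reads, index_a, max_edit, n_seeds)
  aln_b <- map_reads(reads, index_b, max_edit, n_seeds)
  strategy_counts(aln_a, aln_b, targets)
}

#' Strategy counts from precomputed alignments
#' @param aln_a,aln_b Alignment tibbles from [map_reads()] for the two
#'   genomes.
#' @param targets Target tibble with extended A and B intervals.
#' @return Tibble: target_id, n_dual, n_single.
#' @export
strategy_counts <- function(aln_a, aln_b, targets) {
  multi <- union(aln_a$read_id[!aln_a$is_unique],
                 aln_b$read_id[!aln_b$is_unique])
  uni_a <- aln_a[aln_a$is_unique & !(aln_a$read_id %in% multi), ]
  uni_b <- aln_b[aln_b$is_unique & !(aln_b$read_id %in% multi), ]
  # dedup key: strain-A placement when present, else strain-B placement
  key_tbl <- dplyr::bind_rows(
    tibble::tibble(read_id = uni_a$read_id,
                   key = paste("A", uni_a$chrom, uni_a$pos, uni_a$strand)),
    tibble::tibble(read_id = setdiff(uni_b$read_id, uni_a$read_id)))
  kb <- uni_b[match(key_tbl$read_id[is.na(key_tbl$key)], uni_b$read_id), ]
  key_tbl$key[is.na(key_tbl$key)] <- paste("B", kb$chrom, kb$pos, kb$strand)
  keep_ids <- key_tbl %>%
    dplyr::arrange(.data$key, .data$read_id) %>%
    dplyr::distinct(.data$key, .keep_all = TRUE) %>%
    dplyr::pull("read_id")
  dual_a <- uni_a[uni_a$read_id %in% keep_ids, ]
  dual_b <- uni_b[uni_b$read_id %in% keep_ids, ]
  pairs_dual <- dplyr::distinct(dplyr::bind_rows(
    overlap_pairs(dual_a, targets, "startA", "endA"),
    overlap_pairs(dual_b, targets, "startB", "endB")))
  # single strategy: unique on A regardless of B, deduped on A placement
  sing <- aln_a[aln_a$is_unique, ] %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand, .data$read_id) %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$strand, .keep_all = TRUE)
  pairs_single <- overlap_pairs(sing, targets, "startA", "endA")
  nd <- dplyr::count(pairs_dual, .data$target_id, name = "n_dual")
  ns <- dplyr::count(pairs_single, .data$target_id, name = "n_single")
  tibble::tibble(target_id = targets$id) %>%
    dplyr::left_join(nd, by = "target_id") %>%
    dplyr::left_join(ns, by = "target_id") %>%
    dplyr::mutate(n_dual = dplyr::coalesce(.data$n_dual, 0L),
                  n_single = dplyr::coalesce(.data$n_single, 0L))
}

#' Retain targets free of mapping bias across replicates
#'
#' A target is retained only when the dual-genome and single-genome
#' strategies recover exactly the same number of reads in every replicate.
#'
#' @param strategy_list List of [count_mapped_two_strategies()] tibbles, one
#'   per simulated replicate, over the same target universe.
#' @return Tibble: target_id, n_equal (replicates with equal counts),
#'   retained.
#' @export
retain_unbiased_targets <- function(strategy_list) {
  ids <- strategy_list[[1]]$target_id
  for (sc in strategy_list[-1]) {
    if (!identical(sort(sc$target_id), sort(ids))) {
      rlang::abort("replicate strategy counts cover different target sets")
    }
  }
  eq <- vapply(strategy_list, function(sc) {
    sc <- sc[match(ids, sc$target_id), ]
    sc$n_dual == sc$n_single
  }, logical(length(ids)))
  n_equal <- rowSums(eq)
  tibble::tibble(target_id = ids, n_equal = as.integer(n_equal),
                 retained = n_equal == length(strategy_list))
}
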