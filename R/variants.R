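#' Per-position base counts over target intervals
#'
#' Walks each alignment's CIGAR (M consumes read and reference, I read only,
#' D reference only) and accumulates A/C/G/T counts at every reference
#' position of every target's strain-A interval. Insertions contribute
#' nothing; deleted positions receive no contribution from the read.
#'
#' @param alignments Strain-A alignment tibble (deduplicated, one record per
#'   read).
#' @param reads Read tibble supplying sequences (matched by id).
#' @param targets Target tibble whose (extended) strain-A intervals are
#'   piled up.
#' @param genome Strain-A genome (for chromosome sizes).
#' @return Tibble: target_id, chrom, pos (0-based), A, C, G, T, depth.
#' @export
pileup <- function(alignments, reads, targets, genome) {
  lens <- genome_lengths(genome)
  chrom_names <- names(lens)
  seqs <- reads$seq[match(alignments$read_id, reads$id)]
  if (anyNA(seqs)) rlang::abort("alignments reference reads not in `reads`")
  rev <- alignments$strand == "-"
  seqs[rev] <- revcomp_chr(seqs[rev])
  m <- cpp_pileup(match(alignments$chrom, chrom_names), alignments$pos,
                  alignments$cigar, seqs,
                  match(targets$chrom, chrom_names), targets$startA,
                  targets$endA, unname(lens))
  pos <- unlist(lapply(seq_len(nrow(targets)), function(i) {
    seq.int(targets$startA[i], targets$endA[i] - 1L)
  }))
  tibble::tibble(
    target_id = rep(targets$id, targets$endA - targets$startA),
    chrom = rep(targets$chrom, targets$endA - targets$startA),
    pos = as.integer(pos),
    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
    depth = as.integer(rowSums(m)))
}

#' Call heterozygous SNVs from a pileup
#'
#' A position yields a heterozygous call when a single non-reference base
#' reaches the depth, count and fraction thresholds and the position is
#' compatible with heterozygosity (the reference base is still observed, or
#' the alternate fraction does not exceed 0.8). When two distinct alternate
#' bases pass, the higher-count one is emitted and flagged multi-allelic.
#'
#' @param pile Pileup tibble from [pileup()].
#' @param genome Strain-A genome (reference bases).
#' @param min_depth Minimum total depth (default 5).
#' @param min_alt_count Minimum alternate-base count (default 3).
#' @param min_alt_fraction Minimum alternate fraction of depth (default 0.2).
#' @return Call tibble: chrom, pos (0-based), ref, alt, depth, alt_count,
#'   multi_allelic.
#' @export
call_het_snvs <- function(pile, genome, min_depth = 5L, min_alt_count = 3L,
                          min_alt_fraction = 0.2) {
  if (nrow(pile) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          depth = integer(), alt_count = integer(),
                          multi_allelic = logical()))
  }
  ga <- genome_as_character(genome)
  ref <- character(nrow(pile))
  for (ch in unique(pile$chrom)) {
    sel <- pile$chrom == ch
    ref[sel] <- substring(ga[[ch]], pile$pos[sel] + 1L, pile$pos[sel] + 1L)
  }
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pile[, bases])
  ref_idx <- match(ref, bases)
  keep <- !is.na(ref_idx)
  cnt_alt <- cnt
  cnt_alt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  alt_idx <- max.col(cnt_alt, ties.method = "first")
  alt_count <- cnt[cbind(seq_len(nrow(cnt)), alt_idx)]
  # second-best alternate, for the multi-allelic flag
  cnt_alt2 <- cnt_alt
  cnt_alt2[cbind(seq_len(nrow(cnt)), alt_idx)] <- -1L
  alt2_count <- pmax(cnt_alt2[, 1], cnt_alt2[, 2], cnt_alt2[, 3],
                     cnt_alt2[, 4])
  depth <- pile$depth
  frac <- ifelse(depth > 0, alt_count / depth, 0)
  ref_count <- cnt[cbind(seq_len(nrow(cnt)), ifelse(keep, ref_idx, 1L))]
  pass <- keep & depth >= min_depth & alt_count >= min_alt_count &
    frac >= min_alt_fraction & (ref_count > 0 | frac <= 0.8)
  multi <- alt2_count >= min_alt_count &
    ifelse(depth > 0, alt2_count / depth, 0) >= min_alt_fraction
  out <- tibble::tibble(chrom = pile$chrom, pos = pile$pos, ref = ref,
                        alt = bases[alt_idx], depth = depth,
                        alt_count = as.integer(alt_count),
                        multi_allelic = multi)[pass, ]
  dplyr::distinct(out, .data$chrom, .data$pos, .keep_all = TRUE)
}

#' Subsample alignments to a requested mean target depth
#'
#' Reads are kept independently with probability `requested / current`,
#' where the current depth is the overall mean over the targets' strain-A
#' intervals ([mean_target_depth()]). Global Bernoulli thinning preserves
#' any allelic capture-bias structure in the retained reads.
#'
#' @param alignments Alignment tibble.
#' @param targets Target tibble.
#' @param target_mean_depth Requested mean depth (must not exceed the
#'   current one).
#' @param seed Integer seed.
#' @return The thinned alignment tibble.
#' @export
subsample_to_depth <- function(alignments, targets, target_mean_depth,
                               seed = 1L) {
  cur <- mean_target_depth(alignments, targets)
  if (target_mean_depth > cur * (1 + 1e-9)) {
    rlang::abort(sprintf(
      "requested depth %.1f exceeds current mean depth %.1f",
      target_mean_depth, cur))
  }
  p <- min(1, target_mean_depth / cur)
  withr::local_seed(seed)
  alignments[runif(nrow(alignments)) < p, ]
}

#' Score a callset against the truth, by divergence group
#'
#' @param calls Call tibble from [call_het_snvs()].
#' @param truth Truth variant tibble.
#' @param targets Retained (annotated, extended) target tibble.
#' @return Tibble: nSNV_group, n_truth, n_detected, sensitivity.
#' @export
score_sensitivity <- function(calls, truth, targets) {
  ts <- truth_snvs_in_targets(truth, targets)
  if (nrow(ts) == 0) {
    return(tibble::tibble(nSNV_group = integer(), n_truth = integer(),
                          n_detected = integer(), sensitivity = numeric()))
  }
  key_calls <- paste(calls$chrom, calls$pos, calls$alt)
  ts$detected <- paste(ts$chrom, ts$pos, ts$alt) %in% key_calls
  ts %>%
    dplyr::group_by(nSNV_group = .data$nSNV) %>%
    dplyr::summarise(n_truth = dplyr::n(),
                     n_detected = sum(.data$detected),
                     sensitivity = mean(.data$detected), .groups = "drop")
}

# truth SNVs falling inside retained targets, labelled with the target nSNV
truth_snvs_in_targets <- function(truth, targets) {
  snv <- truth[truth$kind == "SNV", ]
  out <- list()
  for (ch in unique(targets$chrom)) {
    tsel <- which(targets$chrom == ch)
    vsel <- which(snv$chrom == ch)
    if (length(vsel) == 0) next
    ir_t <- IRanges::IRanges(targets$startA[tsel] + 1L, targets$endA[tsel])
    ir_v <- IRanges::IRanges(snv$pos[vsel] + 1L, snv$pos[vsel] + 1L)
    hits <- IRanges::findOverlaps(ir_v, ir_t)
    if (length(hits) == 0) next
    rows <- snv[vsel[S4Vectors::queryHits(hits)], ]
    rows$target_id <- targets$id[tsel[S4Vectors::subjectHits(hits)]]
    rows$nSNV <- targets$nSNV[tsel[S4Vectors::subjectHits(hits)]]
    out[[ch]] <- rows
  }
  dplyr::bind_rows(out)
}

#' Variant-detection sensitivity across a depth grid
#'
#' For every requested mean depth and every subsampling seed: thin the
#' strain-A alignments to that depth, pile up, call heterozygous SNVs and
#' score sensitivity per target SNV-count group.
#'
#' @param alignments Deduplicated strain-A alignment tibble at full depth.
#' @param reads Read tibble (sequences).
#' @param truth Truth variant tibble.
#' @param targets Retained target tibble.
#' @param genome Strain-A genome.
#' @param depth_grid Mean depths to evaluate (default 10..80 by 10).
#' @param seeds Subsampling seeds (default 1).
#' @param min_depth,min_alt_count,min_alt_fraction Caller thresholds.
#' @return Tibble: seed, mean_depth_level, nSNV_group, n_truth, n_detected,
#'   sensitivity.
#' @export
sensitivity_by_depth <- function(alignments, reads, truth, targets, genome,
                                 depth_grid = seq(10, 80, by = 10),
                                 seeds = 1L, min_depth = 5L,
                                 min_alt_count = 3L,
                                 min_alt_fraction = 0.2) {
  out <- list()
  for (sd in seeds) {
    for (dp in depth_grid) {
      sub <- subsample_to_depth(alignments, targets, dp, seed = sd)
      pile <- pileup(sub, reads, targets, genome)
      calls <- call_het_snvs(pile, genome, min_depth, min_alt_count,
                             min_alt_fraction)
      sc <- score_sensitivity(calls, truth, targets)
      sc$seed <- sd
      sc$mean_depth_level <- dp
      out[[length(out) + 1L]] <- sc
    }
  }
  dplyr::bind_rows(out)[, c("seed", "mean_depth_level", "nSNV_group",
                            "n_truth", "n_detected", "sensitivity")]
}

#' Concordance of callsets across replicates
#'
#' @param callsets List of call tibbles (same reference).
#' @param truth Truth variant tibble.
#' @return One-row tibble: calls found in exactly 1/2/3 replicates, truth
#'   SNVs recovered in at least 1, at least 2 and all 3 replicates, and
#'   false calls (absent from the truth) by replicate support.
#' @export
compare_callsets <- function(callsets, truth) {
  keys <- lapply(callsets, function(cs) paste(cs$chrom, cs$pos, cs$alt))
  all_keys <- unlist(keys)
  support <- table(table(all_keys))
  n_in <- function(k) as.integer(if (as.character(k) %in% names(support))
    support[[as.character(k)]] else 0L)
  snv <- truth[truth$kind == "SNV", ]
  tkey <- paste(snv$chrom, snv$pos, snv$alt)
  tsupp <- vapply(tkey, function(k) {
    sum(vapply(keys, function(ks) k %in% ks, logical(1)))
  }, integer(1))
  fkey <- setdiff(unique(all_keys), tkey)
  fsupp <- table(all_keys)[fkey]
  tibble::tibble(
    n_calls_1 = n_in(1), n_calls_2 = n_in(2), n_calls_3 = n_in(3),
    n_truth = length(tkey),
    truth_ge1 = sum(tsupp >= 1), truth_ge2 = sum(tsupp >= 2),
    truth_eq3 = sum(tsupp >= 3),
    false_1 = sum(fsupp == 1), false_2 = sum(fsupp == 2),
    false_3 = sum(fsupp >= 3))
}
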