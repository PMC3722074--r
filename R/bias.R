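#' Assign each read an allelic origin from its dual mapping
#'
#' Reads that map to multiple positions in one or both genomes are
#' discarded. Of the rest, a read mapped to only one genome takes that
#' genome as its allelic origin; a read mapped to both takes the genome with
#' the smaller edit distance; equal edit distances leave the origin
#' undetermined and the read is excluded from bias analyses as `ambiguous`.
#'
#' @param dual Dual-mapping tibble from [map_reads_dual()] or
#'   [combine_dual()] (deduplication per genome is expected to have been
#'   applied already, see [remove_duplicates()]).
#' @return The tibble with an added `origin` column in
#'   `c("A", "B", "ambiguous", "discarded")`.
#' @export
assign_allelic_origin <- function(dual) {
  dual$origin <- dplyr::case_when(
    dual$status == "multi" ~ "discarded",
    dual$status == "only_A" ~ "A",
    dual$status == "only_B" ~ "B",
    dual$edit_a < dual$edit_b ~ "A",
    dual$edit_a > dual$edit_b ~ "B",
    TRUE ~ "ambiguous")
  dual
}

#' Count allele-specific reads per target
#'
#' A read contributes to a target's strain-A count when its origin is A and
#' its alignment interval overlaps the target's (extended) strain-A interval
#' by at least one base; strain-B counts are symmetric on the strain-B
#' intervals. Ambiguous and discarded reads contribute to neither. The log2
#' bias ratio is `log2((count_A + c) / (count_B + c))` with pseudocount `c`;
#' positive values mean bias toward strain A.
#'
#' @param assigned Output of [assign_allelic_origin()].
#' @param targets Target tibble with extended A and B intervals.
#' @param pseudocount Pseudocount `c` (default 0.5).
#' @return Tibble: target_id, count_A, count_B, sum, log2_ratio.
#' @export
count_reads_per_target <- function(assigned, targets, pseudocount = 0.5) {
  count_side <- function(origin, side) {
    rd <- assigned[assigned$origin == origin, ]
    pos_col <- paste0("pos_", tolower(side))
    len_col <- paste0("ref_len_", tolower(side))
    chrom_col <- paste0("chrom_", tolower(side))
    start_col <- if (side == "a") "startA" else "startB"
    end_col <- if (side == "a") "endA" else "endB"
    n <- integer(nrow(targets))
    for (ch in unique(targets$chrom)) {
      tsel <- which(targets$chrom == ch)
      rsel <- which(rd[[chrom_col]] == ch)
      if (length(rsel) == 0) next
      ir_t <- IRanges::IRanges(targets[[start_col]][tsel] + 1L,
                               targets[[end_col]][tsel])
      ir_r <- IRanges::IRanges(rd[[pos_col]][rsel] + 1L,
                               rd[[pos_col]][rsel] + rd[[len_col]][rsel])
      n[tsel] <- IRanges::countOverlaps(ir_t, ir_r)
    }
    n
  }
  count_a <- count_side("A", "a")
  count_b <- count_side("B", "b")
  tibble::tibble(
    target_id = targets$id,
    count_A = count_a,
    count_B = count_b,
    sum = count_a + count_b,
    log2_ratio = log2((count_a + pseudocount) / (count_b + pseudocount)))
}

#' Flag per-replicate quantile outliers across simulated replicates
#'
#' Per replicate, targets whose log2 ratio falls outside the empirical
#' `[q_low, q_high]` quantiles (computed over targets with at least one
#' assigned read) are flagged; targets flagged in at least `min_flagged`
#' replicates are discarded.
#'
#' @param count_list List of per-target count tibbles (one per replicate)
#'   over the same target set.
#' @param q_low,q_high Quantile bounds (defaults 0.005 and 0.995).
#' @param min_flagged Replicates a target must be flagged in to be discarded
#'   (default 2).
#' @return Tibble: target_id, n_flagged, retained.
#' @export
filter_outlier_targets_simulation <- function(count_list, q_low = 0.005,
                                              q_high = 0.995,
                                              min_flagged = 2L) {
  ids <- count_list[[1]]$target_id
  for (cc in count_list[-1]) {
    if (!identical(sort(cc$target_id), sort(ids))) {
      rlang::abort("replicate count tables cover different target sets")
    }
  }
  flags <- vapply(count_list, function(cc) {
    cc <- cc[match(ids, cc$target_id), ]
    usable <- cc$sum > 0
    qs <- quantile(cc$log2_ratio[usable], c(q_low, q_high), names = FALSE)
    usable & (cc$log2_ratio < qs[1] | cc$log2_ratio > qs[2])
  }, logical(length(ids)))
  n_flagged <- rowSums(flags)
  tibble::tibble(target_id = ids, n_flagged = as.integer(n_flagged),
                 retained = n_flagged < min_flagged)
}

#' Flag outlier targets from the whole-genome control
#'
#' Targets whose log2 ratio falls outside the `[q_low, q_high]` quantiles,
#' or whose total assigned read count exceeds `sum_cap`, are discarded. The
#' default `sum_cap = "auto"` uses the `q_high` quantile of the sums, which
#' keeps the rule scale-invariant across sequencing depths; an absolute cap
#' may be supplied instead.
#'
#' @param counts Per-target count tibble from the WGS control channel.
#' @param q_low,q_high Quantile bounds.
#' @param sum_cap `"auto"` or an absolute total-count cap.
#' @return Tibble: target_id, outlier_ratio, outlier_sum, retained.
#' @export
filter_outlier_targets_wgs <- function(counts, q_low = 0.005,
                                       q_high = 0.995, sum_cap = "auto") {
  usable <- counts$sum > 0
  qs <- quantile(counts$log2_ratio[usable], c(q_low, q_high), names = FALSE)
  cap <- if (identical(sum_cap, "auto")) {
    quantile(counts$sum, q_high, names = FALSE)
  } else {
    as.numeric(sum_cap)
  }
  out_ratio <- usable & (counts$log2_ratio < qs[1] | counts$log2_ratio > qs[2])
  out_sum <- counts$sum > cap
  tibble::tibble(target_id = counts$target_id,
                 outlier_ratio = out_ratio, outlier_sum = out_sum,
                 retained = !(out_ratio | out_sum))
}

#' Summarise capture bias by divergence group
#'
#' Targets (with at least one assigned read) are grouped by SNV count, capped
#' at `max_snv_group`, separately for indel-free and indel-bearing targets.
#' Each group is compared to the reference group (0 SNVs, no indels) with a
#' two-sided Mann-Whitney U test.
#'
#' @param counts Per-target count tibble.
#' @param targets Annotated target tibble (source of nSNV/nIndel).
#' @param max_snv_group Largest SNV count given its own group; higher counts
#'   are lumped into it (default 6).
#' @return Tibble: nSNV_group, has_indel, n_targets, median, q1, q3,
#'   p_value (NA for the reference group and groups below 2 targets).
#' @export
group_bias_by_divergence <- function(counts, targets, max_snv_group = 6L) {
  dat <- counts %>%
    dplyr::inner_join(
      targets[, c("id", "nSNV", "nIndel")],
      by = c(target_id = "id")) %>%
    dplyr::filter(.data$sum > 0) %>%
    dplyr::mutate(nSNV_group = pmin(.data$nSNV, max_snv_group),
                  has_indel = .data$nIndel > 0)
  ref <- dat$log2_ratio[dat$nSNV_group == 0 & !dat$has_indel]
  groups <- dat %>%
    dplyr::group_by(.data$nSNV_group, .data$has_indel) %>%
    dplyr::summarise(n_targets = dplyr::n(),
                     median = median(.data$log2_ratio),
                     q1 = quantile(.data$log2_ratio, 0.25, names = FALSE),
                     q3 = quantile(.data$log2_ratio, 0.75, names = FALSE),
                     ratios = list(.data$log2_ratio), .groups = "drop") %>%
    dplyr::arrange(.data$has_indel, .data$nSNV_group)
  groups$p_value <- vapply(seq_len(nrow(groups)), function(i) {
    if (groups$nSNV_group[i] == 0 && !groups$has_indel[i]) return(NA_real_)
    x <- groups$ratios[[i]]
    if (length(x) < 2 || length(ref) < 2) return(NA_real_)
    test_group_difference(x, ref)
  }, numeric(1))
  dplyr::select(groups, -"ratios")
}

#' Two-sided Mann-Whitney U test between two groups of bias ratios
#'
#' @param x,y Numeric vectors of log2 ratios (each length >= 2).
#' @return The two-sided p-value. Degenerate all-tied input returns 1 with a
#'   warning.
#' @export
test_group_difference <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("both groups must contain at least 2 targets")
  }
  if (length(unique(c(x, y))) == 1) {
    rlang::warn("all values tied; returning p = 1")
    return(1)
  }
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Capture-bias dependence on the spacing of SNV pairs
#'
#' Restricted to targets carrying exactly two SNVs and no indels, targets
#' are binned by the distance between the two SNVs; each bin is summarised
#' and compared (Mann-Whitney) against the largest-spacing populated bin.
#'
#' @param counts Per-target count tibble.
#' @param targets Annotated target tibble (extended).
#' @param truth Truth variant tibble (source of SNV positions).
#' @param breaks Upper bin edges; defaults give bins 1, 2-10, 11-30, 31-60,
#'   >60 bases.
#' @return Tibble: spacing_bin, n_targets, median, p_value (NA for the
#'   reference bin).
#' @export
snv_spacing_analysis <- function(counts, targets, truth,
                                 breaks = c(1, 10, 30, 60)) {
  two <- targets[!is.na(targets$nSNV) & targets$nSNV == 2 &
                   targets$nIndel == 0, ]
  if (nrow(two) == 0) {
    return(tibble::tibble(spacing_bin = character(), n_targets = integer(),
                          median = numeric(), p_value = numeric()))
  }
  snv <- truth[truth$kind == "SNV", ]
  spacing <- vapply(seq_len(nrow(two)), function(i) {
    p <- snv$pos[snv$chrom == two$chrom[i] & snv$pos >= two$startA[i] &
                   snv$pos < two$endA[i]]
    as.integer(diff(sort(p)))
  }, integer(1))
  edges <- c(0, breaks, Inf)
  labs <- c(sprintf("%d", breaks[1]),
            sprintf("%d-%d", utils::head(breaks, -1) + 1,
                    utils::tail(breaks, -1)),
            sprintf(">%d", breaks[length(breaks)]))
  bin <- cut(spacing, edges, labels = labs)
  dat <- tibble::tibble(target_id = two$id, spacing_bin = as.character(bin)) %>%
    dplyr::inner_join(counts, by = "target_id") %>%
    dplyr::filter(.data$sum > 0)
  lev <- labs[labs %in% dat$spacing_bin]
  ref_bin <- lev[length(lev)]
  ref <- dat$log2_ratio[dat$spacing_bin == ref_bin]
  out <- dat %>%
    dplyr::group_by(spacing_bin = factor(.data$spacing_bin, levels = lev)) %>%
    dplyr::summarise(n_targets = dplyr::n(),
                     median = median(.data$log2_ratio),
                     ratios = list(.data$log2_ratio), .groups = "drop") %>%
    dplyr::arrange(.data$spacing_bin)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    if (as.character(out$spacing_bin[i]) == ref_bin) return(NA_real_)
    if (out$n_targets[i] < 2 || length(ref) < 2) return(NA_real_)
    test_group_difference(out$ratios[[i]], ref)
  }, numeric(1))
  out$spacing_bin <- as.character(out$spacing_bin)
  dplyr::select(out, -"ratios")
}

#' Per-position sequencing depth of a target
#'
#' The depth of a position is the number of (deduplicated) reads whose
#' alignment overlaps it; a target's depth is the mean over all positions of
#' its strain-A interval.
#'
#' @param alignments Alignment tibble (one record per read, deduplicated).
#' @param target One-row target tibble.
#' @return List with `depth` (integer vector over the interval) and
#'   `mean_depth`.
#' @export
compute_depth <- function(alignments, target) {
  stopifnot(nrow(target) == 1)
  rd <- alignments[alignments$chrom == target$chrom, ]
  if (nrow(rd) == 0) {
    len <- target$endA - target$startA
    return(list(depth = integer(len), mean_depth = 0))
  }
  cov <- IRanges::coverage(IRanges::IRanges(rd$pos + 1L,
                                            rd$pos + rd$ref_len),
                           width = max(target$endA, max(rd$pos + rd$ref_len)))
  depth <- as.integer(cov[(target$startA + 1L):target$endA])
  list(depth = depth, mean_depth = mean(depth))
}

#' Mean depth over a set of targets
#'
#' Total aligned bases overlapping the targets' strain-A intervals divided
#' by the total interval length — the quantity the depth-subsampling grid is
#' defined on.
#'
#' @param alignments Alignment tibble.
#' @param targets Target tibble (strain-A intervals).
#' @return A single number.
#' @export
mean_target_depth <- function(alignments, targets) {
  total <- 0
  for (ch in unique(targets$chrom)) {
    tsel <- targets[targets$chrom == ch, ]
    rd <- alignments[alignments$chrom == ch, ]
    if (nrow(rd) == 0) next
    ir_t <- IRanges::IRanges(tsel$startA + 1L, tsel$endA)
    ir_r <- IRanges::IRanges(rd$pos + 1L, rd$pos + rd$ref_len)
    hits <- IRanges::findOverlaps(ir_r, ir_t)
    ov <- IRanges::pintersect(ir_r[S4Vectors::queryHits(hits)],
                              ir_t[S4Vectors::subjectHits(hits)])
    total <- total + sum(IRanges::width(ov))
  }
  total / sum(targets$endA - targets$startA)
}
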