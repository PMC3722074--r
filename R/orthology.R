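#' Align capture targets to the alternate genome
#'
#' The strain-A sequence of every (unextended) target is aligned to strain B
#' with the built-in seed-and-extend aligner, reporting all placements whose
#' edit distance is at most `max_edit_fraction` times the target length.
#'
#' @param targets Target tibble (strain-A intervals).
#' @param genome_a Strain-A genome (source of target sequences).
#' @param index_b A [build_index()] over strain B (or a genome, which will
#'   be indexed with `k`).
#' @param max_edit_fraction Maximum edit distance as a fraction of target
#'   length (default 0.25).
#' @param k,n_seeds Seeding parameters passed to the aligner.
#' @return Placement tibble: target_id plus chrom, pos, strand, edit,
#'   ref_len, n_best for every reported locus. Unplaced targets are absent.
#' @export
map_targets_to_alt_genome <- function(targets, genome_a, index_b,
                                      max_edit_fraction = 0.25, k = 20L,
                                      n_seeds = 4L) {
  if (!inherits(index_b, "genome_index")) index_b <- build_index(index_b, k)
  if (nrow(targets) == 0) {
    return(tibble::tibble(target_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          edit = integer(), ref_len = integer(),
                          n_best = integer()))
  }
  if (length(unique(targets$endA - targets$startA)) != 1) {
    rlang::abort("targets must share a single length for orthology mapping")
  }
  seqs <- extract_read_seqs(genome_a, NULL, rep("A", nrow(targets)),
                            targets$chrom, targets$startA,
                            targets$endA[1] - targets$startA[1],
                            rep("+", nrow(targets)))
  max_edit <- floor(max_edit_fraction * (targets$endA[1] - targets$startA[1]))
  aln <- map_reads(tibble::tibble(id = targets$id, seq = seqs), index_b,
                   max_edit = max_edit, n_seeds = n_seeds)
  dplyr::rename(aln, target_id = "read_id")[, c("target_id", "chrom", "pos",
                                                "strand", "edit", "ref_len",
                                                "n_best")]
}

#' Keep targets placed uniquely on the expected chromosome
#'
#' A target survives iff it has exactly one best placement genome-wide and
#' that placement lies on the same chromosome as on strain A. Unplaced and
#' multi-placed targets are dropped with reason `multi_or_unmapped`; unique
#' placements on another chromosome with reason `wrong_chrom`.
#'
#' @param targets Target tibble.
#' @param placements Output of [map_targets_to_alt_genome()].
#' @return List with `survivors` (targets with provisional startB/endB and a
#'   `strandB` column) and `dropped` (tibble id, reason).
#' @export
filter_unique_same_chrom <- function(targets, placements) {
  n_loci <- table(placements$target_id)
  uniq <- placements[placements$n_best == 1L &
                       placements$target_id %in%
                         names(n_loci)[n_loci == 1L], ]
  dropped <- tibble::tibble(id = character(), reason = character())
  not_uniq <- setdiff(targets$id, uniq$target_id)
  if (length(not_uniq) > 0) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      id = not_uniq, reason = "multi_or_unmapped"))
  }
  m <- match(uniq$target_id, targets$id)
  wrong <- uniq$chrom != targets$chrom[m]
  if (any(wrong)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      id = uniq$target_id[wrong], reason = "wrong_chrom"))
  }
  keep <- uniq[!wrong, ]
  surv <- targets[match(keep$target_id, targets$id), ]
  surv$startB <- keep$pos
  surv$endB <- keep$pos + keep$ref_len
  surv$strandB <- keep$strand
  list(survivors = dplyr::arrange(surv, .data$chrom, .data$startA),
       dropped = dropped)
}

#' Keep targets collinear with their neighbours on strain B
#'
#' Within each chromosome, targets are taken in strain-A order and the
#' longest strictly-increasing subsequence of strain-B start positions is
#' retained; targets outside it do not lie in the same 5'-to-3' order as
#' their neighbours and are dropped (reason `non_syntenic`). Placements on
#' the reverse strand are orientation-flipped relative to strain A and are
#' likewise dropped as non-syntenic.
#'
#' @param survivors Output `survivors` of [filter_unique_same_chrom()].
#' @return List with `survivors` and `dropped`.
#' @export
filter_syntenic_order <- function(survivors) {
  dropped <- tibble::tibble(id = character(), reason = character())
  flipped <- survivors$strandB == "-"
  if (any(flipped)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      id = survivors$id[flipped], reason = "non_syntenic"))
    survivors <- survivors[!flipped, ]
  }
  keep_rows <- logical(nrow(survivors))
  for (ch in unique(survivors$chrom)) {
    sel <- which(survivors$chrom == ch)
    keep_rows[sel[lis_indices(survivors$startB[sel])]] <- TRUE
  }
  if (any(!keep_rows)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      id = survivors$id[!keep_rows], reason = "non_syntenic"))
  }
  list(survivors = survivors[keep_rows, ], dropped = dropped)
}

# indices of a longest strictly increasing subsequence (first optimal one)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  out <- integer(len[best])
  k <- len[best]
  while (best != 0L) {
    out[k] <- best
    k <- k - 1L
    best <- prev[best]
  }
  out
}

#' Extend targets by 100 nt per side and apply the N filter
#'
#' Both the strain-A and strain-B intervals are extended 100 nt from the 5'
#' and 3' ends. Targets whose extension crosses a chromosome boundary, or
#' whose extended interval contains an N (missing reference sequence) in
#' either genome, are dropped with reason `n_extension`.
#'
#' @param survivors Survivor targets with both intervals.
#' @param genome_a,genome_b The two genomes.
#' @param extension Extension per side in bases (default 100).
#' @return List with `survivors` (extended, `extended = TRUE`) and `dropped`.
#' @export
extend_and_filter_n <- function(survivors, genome_a, genome_b,
                                extension = 100L) {
  lens_a <- genome_lengths(genome_a)
  lens_b <- genome_lengths(genome_b)
  sA <- survivors$startA - extension
  eA <- survivors$endA + extension
  sB <- survivors$startB - extension
  eB <- survivors$endB + extension
  ok <- sA >= 0 & sB >= 0 & eA <= lens_a[survivors$chrom] &
    eB <= lens_b[survivors$chrom]
  has_n <- logical(nrow(survivors))
  ga <- genome_as_character(genome_a)
  gb <- genome_as_character(genome_b)
  for (i in which(ok)) {
    ch <- survivors$chrom[i]
    wa <- substr(ga[[ch]], sA[i] + 1L, eA[i])
    wb <- substr(gb[[ch]], sB[i] + 1L, eB[i])
    has_n[i] <- grepl("N", wa, fixed = TRUE) || grepl("N", wb, fixed = TRUE)
  }
  drop <- !ok | has_n
  dropped <- tibble::tibble(id = survivors$id[drop],
                            reason = rep("n_extension", sum(drop)))
  out <- survivors[!drop, ]
  out$startA <- sA[!drop]
  out$endA <- eA[!drop]
  out$startB <- sB[!drop]
  out$endB <- eB[!drop]
  out$extended <- TRUE
  list(survivors = out, dropped = dropped)
}

#' Establish one-to-one orthologous target intervals on strain B
#'
#' Runs the full orthology chain: align each target to strain B, keep unique
#' same-chromosome placements, keep targets collinear with their neighbours,
#' extend by 100 nt per side and drop targets extending into missing (N)
#' sequence. Every dropped target carries exactly one reason.
#'
#' @inheritParams map_targets_to_alt_genome
#' @param genome_b Strain-B genome.
#' @param extension Extension per side in bases (default 100).
#' @return An `orthology_result`: list with `retained` (extended targets
#'   with both intervals) and `dropped` (tibble id, reason with reasons in
#'   multi_or_unmapped, wrong_chrom, non_syntenic, n_extension).
#' @export
establish_orthology <- function(targets, genome_a, genome_b,
                                max_edit_fraction = 0.25, k = 20L,
                                n_seeds = 4L, extension = 100L) {
  index_b <- build_index(genome_b, k)
  pl <- map_targets_to_alt_genome(targets, genome_a, index_b,
                                  max_edit_fraction, k, n_seeds)
  s1 <- filter_unique_same_chrom(targets, pl)
  s2 <- filter_syntenic_order(s1$survivors)
  s3 <- extend_and_filter_n(s2$survivors, genome_a, genome_b, extension)
  retained <- dplyr::select(s3$survivors, -"strandB")
  structure(list(retained = retained,
                 dropped = dplyr::bind_rows(s1$dropped, s2$dropped,
                                            s3$dropped)),
            class = "orthology_result")
}

#' @export
print.orthology_result <- function(x, ...) {
  cat(sprintf("<orthology_result: %d retained, %d dropped>\n",
              nrow(x$retained), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) print(dplyr::count(x$dropped, .data$reason))
  invisible(x)
}
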