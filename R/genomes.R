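#' Generate a random base ("strain A") genome
#'
#' Chromosome sequences are i.i.d. draws over A/C/G/T with a fixed GC
#' fraction, emulating a reference strain at desk scale. No N bases are ever
#' generated; use [insert_n_block()] to construct assembly-gap fixtures.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length of every chromosome in bases (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @param strain Strain label stored in the genome metadata.
#' @return A named [Biostrings::DNAStringSet] with chromosomes `chr1`,
#'   `chr2`, ...
#' @export
generate_base_genome <- function(n_chrom, chrom_length, gc = 0.5, seed = 1L,
                                 strain = "A") {
  stopifnot_scalar_int(n_chrom, "n_chrom", min = 1)
  stopifnot_scalar_int(chrom_length, "chrom_length", min = 1000)
  if (!is.numeric(gc) || length(gc) != 1 || is.na(gc) || gc <= 0 || gc >= 1) {
    rlang::abort("`gc` must be a single number strictly between 0 and 1")
  }
  withr::local_seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(probs), chrom_length, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(n_chrom))
  S4Vectors::metadata(g) <- list(strain_label = strain)
  g
}

#' Overwrite a genome region with N bases
#'
#' Used to build controlled assembly-gap fixtures for the N-extension filter.
#'
#' @param genome A genome ([Biostrings::DNAStringSet]).
#' @param chrom Chromosome name.
#' @param start 0-based start of the N block.
#' @param length Block length in bases.
#' @export
insert_n_block <- function(genome, chrom, start, length) {
  if (!chrom %in% names(genome)) rlang::abort("unknown chromosome")
  L <- length(genome[[chrom]])
  if (start < 0 || start + length > L) rlang::abort("N block out of bounds")
  s <- as.character(genome[[chrom]])
  substr(s, start + 1, start + length) <- strrep("N", length)
  md <- S4Vectors::metadata(genome)
  genome[[chrom]] <- Biostrings::DNAString(s)
  S4Vectors::metadata(genome) <- md
  genome
}

#' Divergence configuration for deriving a "strain B" genome
#'
#' The default preset emulates a wild-derived strain diverged from the
#' reference at roughly 1 SNV per 70 bp and 1 indel per 550 bp genome-wide,
#' with geometric indel lengths of mean 2. A fraction of the genome is laid
#' out as conserved blocks carrying no variants at all, so that a realistic
#' share of capture targets is identical between the strains.
#'
#' @param snv_rate Expected SNVs per base outside conserved blocks (in
#'   \[0, 0.2\]).
#' @param indel_rate Expected indels per base outside conserved blocks (in
#'   \[0, 0.2\]).
#' @param indel_mean_length Mean indel length (geometric, lengths >= 1).
#' @param conserved_fraction Fraction of genome blocks that carry no variants.
#' @param conserved_block Length of the conserved-block mosaic in bases.
#' @param seed Integer seed.
#' @return A list of class `divergence_config`.
#' @export
divergence_config <- function(snv_rate = 1 / 70, indel_rate = 1 / 550,
                              indel_mean_length = 2,
                              conserved_fraction = 0.45,
                              conserved_block = 400L, seed = 1L) {
  if (snv_rate < 0 || snv_rate > 0.2) {
    rlang::abort("`snv_rate` must be in [0, 0.2]")
  }
  if (indel_rate < 0 || indel_rate > 0.2) {
    rlang::abort("`indel_rate` must be in [0, 0.2]")
  }
  if (indel_mean_length < 1) rlang::abort("`indel_mean_length` must be >= 1")
  if (conserved_fraction < 0 || conserved_fraction >= 1) {
    rlang::abort("`conserved_fraction` must be in [0, 1)")
  }
  structure(list(snv_rate = snv_rate, indel_rate = indel_rate,
                 indel_mean_length = indel_mean_length,
                 conserved_fraction = conserved_fraction,
                 conserved_block = as.integer(conserved_block),
                 seed = as.integer(seed)),
            class = "divergence_config")
}

#' Derive a divergent "strain B" genome with a truth variant table
#'
#' Applies random SNVs and indels to the base genome. Variants never overlap
#' one another on strain A coordinates: indel placements that would collide
#' with an existing variant are resampled. Returns the derived genome, the
#' sorted truth table, and a liftover map giving the strain-A to strain-B
#' coordinate offset for every colinear block.
#'
#' Truth variants use anchored VCF-style alleles: an SNV has single distinct
#' `ref`/`alt` bases at `pos`; an insertion has `ref` = the anchor base and
#' `alt` = anchor plus inserted sequence; a deletion has `ref` = anchor plus
#' deleted bases and `alt` = the anchor base. All positions are 0-based.
#'
#' @param base Base genome ([Biostrings::DNAStringSet]).
#' @param cfg A [divergence_config()].
#' @param strain Strain label for the derived genome.
#' @return A list with elements `genome` (DNAStringSet), `truth` (tibble:
#'   chrom, pos, kind, ref, alt) and `liftover` (tibble: chrom, a_start,
#'   a_end, offset; 0-based half-open blocks where B = A + offset).
#' @export
derive_divergent_genome <- function(base, cfg = divergence_config(),
                                    strain = "B") {
  stopifnot(inherits(cfg, "divergence_config"))
  withr::local_seed(cfg$seed)
  edge <- 60L  # keep variants away from chromosome ends
  truth <- list()
  seqs_b <- character(length(base))
  lift <- list()
  chroms <- names(base)
  p_geom <- 1 / cfg$indel_mean_length

  for (ci in seq_along(chroms)) {
    a_seq <- as.character(base[[ci]])
    L <- nchar(a_seq)
    # conserved-block mosaic
    n_blocks <- ceiling(L / cfg$conserved_block)
    conserved_blk <- runif(n_blocks) < cfg$conserved_fraction
    pos_all <- seq.int(edge, L - edge - 1L)
    blk_of <- pos_all %/% cfg$conserved_block + 1L
    avail <- pos_all[!conserved_blk[blk_of]]
    a_bases <- strsplit(a_seq, "")[[1]]
    avail <- avail[a_bases[avail + 1L] != "N"]

    occupied <- logical(L)
    # --- SNVs ---
    n_snv <- rbinom(1, length(avail), cfg$snv_rate)
    snv_pos <- sort(sample(avail, n_snv))
    occupied[snv_pos + 1L] <- TRUE
    alts <- vapply(snv_pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), a_bases[p + 1L]), 1)
    }, character(1))
    chrom_truth <- list()
    if (n_snv > 0) {
      chrom_truth[[1]] <- tibble::tibble(
        chrom = chroms[ci], pos = snv_pos, kind = "SNV",
        ref = a_bases[snv_pos + 1L], alt = alts)
    }
    # --- indels (resample on collision) ---
    n_indel <- rbinom(1, length(avail), cfg$indel_rate)
    if (n_indel > 0) {
      kind <- sample(c("insertion", "deletion"), n_indel, replace = TRUE)
      len <- 1L + rgeom(n_indel, p_geom)
      ipos <- integer(n_indel)
      keep <- logical(n_indel)
      for (i in seq_len(n_indel)) {
        span <- if (kind[i] == "deletion") len[i] + 1L else 2L
        for (try in 1:100) {
          p <- sample(avail, 1)
          if (p + span <= L - edge && !any(occupied[(p + 1L):(p + span)])) {
            occupied[(p + 1L):(p + span)] <- TRUE
            ipos[i] <- p
            keep[i] <- TRUE
            break
          }
        }
      }
      kind <- kind[keep]; len <- len[keep]; ipos <- ipos[keep]
      if (length(ipos) > 0) {
        ref <- character(length(ipos)); alt <- character(length(ipos))
        for (i in seq_along(ipos)) {
          anchor <- a_bases[ipos[i] + 1L]
          if (kind[i] == "insertion") {
            ins <- paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
                         collapse = "")
            ref[i] <- anchor
            alt[i] <- paste0(anchor, ins)
          } else {
            ref[i] <- paste0(anchor, substr(a_seq, ipos[i] + 2L,
                                            ipos[i] + 1L + len[i]))
            alt[i] <- anchor
          }
        }
        chrom_truth[[length(chrom_truth) + 1L]] <- tibble::tibble(
          chrom = chroms[ci], pos = ipos, kind = kind, ref = ref, alt = alt)
      }
    }
    tv <- if (length(chrom_truth) > 0) {
      dplyr::arrange(dplyr::bind_rows(chrom_truth), .data$pos)
    } else {
      tibble::tibble(chrom = character(), pos = integer(), kind = character(),
                     ref = character(), alt = character())
    }
    built <- apply_variants_to_chrom(a_seq, tv)
    seqs_b[ci] <- built$seq
    lift[[ci]] <- dplyr::mutate(built$lift, chrom = chroms[ci],
                                .before = 1L)
    truth[[ci]] <- tv
  }
  gB <- Biostrings::DNAStringSet(seqs_b)
  names(gB) <- chroms
  S4Vectors::metadata(gB) <- list(strain_label = strain)
  list(genome = gB,
       truth = dplyr::bind_rows(truth),
       liftover = dplyr::bind_rows(lift))
}

# Apply a sorted per-chromosome truth table to a sequence; returns the derived
# sequence and the colinear liftover blocks.
apply_variants_to_chrom <- function(a_seq, tv) {
  L <- nchar(a_seq)
  pieces <- character(0)
  cur <- 0L          # 0-based cursor on A
  d <- 0L            # current offset B - A
  bs <- 0L           # current block start on A
  blocks <- list()
  if (nrow(tv) > 0) {
    for (i in seq_len(nrow(tv))) {
      p <- tv$pos[i]
      if (tv$kind[i] == "SNV") {
        pieces <- c(pieces, substr(a_seq, cur + 1L, p), tv$alt[i])
        cur <- p + 1L
      } else if (tv$kind[i] == "insertion") {
        ins_len <- nchar(tv$alt[i]) - 1L
        pieces <- c(pieces, substr(a_seq, cur + 1L, p + 1L),
                    substr(tv$alt[i], 2L, nchar(tv$alt[i])))
        cur <- p + 1L
        blocks[[length(blocks) + 1L]] <- c(bs, p + 1L, d)
        d <- d + ins_len
        bs <- p + 1L
      } else {  # deletion
        del_len <- nchar(tv$ref[i]) - 1L
        pieces <- c(pieces, substr(a_seq, cur + 1L, p + 1L))
        cur <- p + 1L + del_len
        blocks[[length(blocks) + 1L]] <- c(bs, p + 1L, d)
        d <- d - del_len
        bs <- p + 1L + del_len
      }
    }
  }
  pieces <- c(pieces, substr(a_seq, cur + 1L, L))
  blocks[[length(blocks) + 1L]] <- c(bs, L, d)
  bl <- do.call(rbind, blocks)
  list(seq = paste(pieces, collapse = ""),
       lift = tibble::tibble(a_start = as.integer(bl[, 1]),
                             a_end = as.integer(bl[, 2]),
                             offset = as.integer(bl[, 3])))
}

#' Map strain-A positions to strain-B through a liftover map
#'
#' @param liftover Liftover tibble from [derive_divergent_genome()].
#' @param chrom Chromosome name (recycled).
#' @param pos 0-based positions on strain A.
#' @return 0-based strain-B positions; `NA` for positions deleted in B.
#' @export
lift_positions <- function(liftover, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    lo <- liftover[liftover$chrom == ch, ]
    if (nrow(lo) == 0) next
    idx <- findInterval(pos[sel], lo$a_start)
    ok <- idx >= 1 & pos[sel] < lo$a_end[pmax(idx, 1L)]
    out[sel][ok] <- pos[sel][ok] + lo$offset[idx[ok]]
  }
  out
}

#' Map a strain-A interval to strain B through a liftover map
#'
#' Endpoints falling in deleted regions are moved inward to the nearest
#' mapped position.
#'
#' @inheritParams lift_positions
#' @param start,end 0-based half-open interval on strain A.
#' @return A list with `start` and `end` (0-based half-open on B).
#' @export
lift_interval <- function(liftover, chrom, start, end) {
  lo <- liftover[liftover$chrom == chrom, ]
  inside <- lo[lo$a_end > start & lo$a_start < end, ]
  if (nrow(inside) == 0) return(list(start = NA_integer_, end = NA_integer_))
  s <- max(start, inside$a_start[1]) + inside$offset[1]
  k <- nrow(inside)
  e <- min(end, inside$a_end[k]) + inside$offset[k]
  list(start = as.integer(s), end = as.integer(e))
}

#' Define non-overlapping capture targets on a genome
#'
#' Places `n_targets` intervals of `target_length` bases (default 120,
#' matching capture-probe length) uniformly at random subject to a minimum
#' inter-target gap and a margin from chromosome ends. Targets are allocated
#' to chromosomes proportionally to length, sorted by (chrom, start), and get
#' stable ids.
#'
#' @param genome Genome the targets live on (strain A).
#' @param n_targets Number of targets (>= 0).
#' @param target_length Target length in bases (default 120).
#' @param min_gap Minimum gap between neighbouring targets (default 250, so
#'   that 100-nt extensions never overlap).
#' @param seed Integer seed.
#' @param margin Distance kept free at each chromosome end.
#' @return A tibble with columns id, chrom, startA, endA (0-based half-open),
#'   startB, endB (NA until orthology is established), nSNV, nIndel (NA until
#'   annotated), extended.
#' @export
define_targets <- function(genome, n_targets, target_length = 120L,
                           min_gap = 250L, seed = 1L, margin = 500L) {
  stopifnot_scalar_int(n_targets, "n_targets", min = 0)
  empty <- tibble::tibble(id = character(), chrom = character(),
                          startA = integer(), endA = integer(),
                          startB = integer(), endB = integer(),
                          nSNV = integer(), nIndel = integer(),
                          extended = logical())
  if (n_targets == 0) return(empty)
  withr::local_seed(seed)
  lens <- genome_lengths(genome)
  usable <- pmax(0, lens - 2 * margin)
  n_per <- floor(n_targets * usable / sum(usable))
  rem <- n_targets - sum(n_per)
  if (rem > 0) {
    ord <- order(usable, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
  }
  out <- list()
  for (ci in seq_along(lens)) {
    n <- n_per[ci]
    if (n == 0) next
    need <- n * target_length + (n - 1) * min_gap
    slack <- usable[ci] - need
    if (slack < 0) {
      rlang::abort(sprintf(
        "cannot pack %d targets of %d bp with gap %d on %s",
        n, target_length, min_gap, names(lens)[ci]))
    }
    u <- sort(sample.int(slack + 1, n, replace = TRUE) - 1L)
    starts <- margin + u + (seq_len(n) - 1L) * (target_length + min_gap)
    out[[ci]] <- tibble::tibble(chrom = names(lens)[ci],
                                startA = as.integer(starts),
                                endA = as.integer(starts + target_length))
  }
  tg <- dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$startA)
  tg$id <- sprintf("t%05d", seq_len(nrow(tg)))
  tg$startB <- NA_integer_
  tg$endB <- NA_integer_
  tg$nSNV <- NA_integer_
  tg$nIndel <- NA_integer_
  tg$extended <- FALSE
  tg[, c("id", "chrom", "startA", "endA", "startB", "endB",
         "nSNV", "nIndel", "extended")]
}

#' Annotate targets with truth divergence counts
#'
#' Sets `nSNV` and `nIndel` to the number of truth variants whose strain-A
#' position lies inside the target's (extended) half-open interval. Targets
#' must already be extended, since divergence grouping is defined on the
#' extended interval.
#'
#' @param targets Target tibble with `extended = TRUE`.
#' @param truth Truth variant tibble.
#' @return The target tibble with `nSNV`/`nIndel` filled in.
#' @export
annotate_target_divergence <- function(targets, truth) {
  if (nrow(targets) > 0 && !all(targets$extended)) {
    rlang::abort("targets must be extended before divergence annotation")
  }
  snv <- truth[truth$kind == "SNV", ]
  ind <- truth[truth$kind != "SNV", ]
  targets$nSNV <- count_positions_in_intervals(targets, snv)
  targets$nIndel <- count_positions_in_intervals(targets, ind)
  targets
}

# count truth positions (0-based) falling in [startA, endA) per target
count_positions_in_intervals <- function(targets, variants) {
  n <- integer(nrow(targets))
  if (nrow(targets) == 0 || nrow(variants) == 0) return(n)
  for (ch in unique(targets$chrom)) {
    sel <- which(targets$chrom == ch)
    vp <- variants$pos[variants$chrom == ch]
    if (length(vp) == 0) next
    ir_t <- IRanges::IRanges(targets$startA[sel] + 1L, targets$endA[sel])
    ir_v <- IRanges::IRanges(vp + 1L, vp + 1L)
    n[sel] <- IRanges::countOverlaps(ir_t, ir_v)
  }
  n
}
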