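test_that("allelic origin follows the smaller-edit-distance rule", {
  dual <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    chrom_a = c("chr1", "chr1", NA, "chr1", "chr1", NA),
    pos_a = c(10L, 10L, NA, 10L, 10L, NA),
    strand_a = "+", edit_a = c(0L, 1L, NA, 2L, 3L, NA),
    ref_len_a = 101L,
    chrom_b = c("chr1", "chr1", "chr1", NA, "chr1", NA),
    pos_b = c(10L, 10L, 10L, NA, 10L, NA),
    strand_b = "+", edit_b = c(2L, 1L, 0L, NA, 1L, NA),
    ref_len_b = 101L,
    status = c("both", "both", "only_B", "only_A", "both", "multi"))
  out <- assign_allelic_origin(dual)
  expect_equal(out$origin,
               c("A", "ambiguous", "B", "A", "B", "discarded"))
})

test_that("per-target counts respect one-base overlap and the log2 ratio formula", {
  targets <- tibble::tibble(
    id = "t1", chrom = "chr1", startA = 1000L, endA = 1320L,
    startB = 1000L, endB = 1320L, nSNV = 1L, nIndel = 0L, extended = TRUE)
  mk <- function(n, origin, pos) {
    tibble::tibble(
      read_id = sprintf("%s_%d_%d", origin, pos, seq_len(n)),
      chrom_a = "chr1", pos_a = pos, strand_a = "+", edit_a = 0L,
      ref_len_a = 101L, chrom_b = "chr1", pos_b = pos, strand_b = "+",
      edit_b = 1L, ref_len_b = 101L, status = "both", origin = origin)
  }
  assigned <- dplyr::bind_rows(
    mk(5, "A", 1100L), mk(3, "B", 1150L),
    # abutting reads: end exactly at start, or start exactly at end
    mk(2, "A", 899L), mk(2, "B", 1320L),
    # one-base overlap on each side counts
    mk(1, "A", 900L), mk(1, "B", 1319L))
  cnt <- count_reads_per_target(assigned, targets, pseudocount = 0)
  expect_equal(cnt$count_A, 6L)
  expect_equal(cnt$count_B, 4L)
  expect_equal(cnt$sum, 10L)
  cnt2 <- count_reads_per_target(
    dplyr::bind_rows(mk(5, "A", 1100L), mk(3, "B", 1150L)),
    targets, pseudocount = 0)
  expect_equal(cnt2$log2_ratio, log2(5 / 3), tolerance = 1e-6)
  expect_equal(round(cnt2$log2_ratio, 3), 0.737)
})

test_that("assigned reads are conserved between targets and off-target space", {
  w <- small_world()
  reads <- simulate_exome_reads(w$ret, w$ga, w$gb, 20000, seed = 40)
  mc <- map_and_count(reads, w$ia, w$ib, w$ret, capbias_config())
  asg <- mc$assigned
  n_assigned <- sum(asg$origin %in% c("A", "B"))
  on_target <- sum(mc$counts$count_A) + sum(mc$counts$count_B)
  # brute-force (read, target) overlap pairs per origin genome; a read
  # overlapping two neighbouring extended targets counts once in each
  pair_count <- function(reads, pos_col, len_col, chrom_col, s_col, e_col) {
    sum(vapply(seq_len(nrow(reads)), function(i) {
      sel <- w$ret$chrom == reads[[chrom_col]][i]
      sum(reads[[pos_col]][i] + reads[[len_col]][i] > w$ret[[s_col]][sel] &
            reads[[pos_col]][i] < w$ret[[e_col]][sel])
    }, numeric(1)))
  }
  a_reads <- asg[asg$origin == "A", ]
  b_reads <- asg[asg$origin == "B", ]
  pairs_a <- pair_count(a_reads, "pos_a", "ref_len_a", "chrom_a",
                        "startA", "endA")
  pairs_b <- pair_count(b_reads, "pos_b", "ref_len_b", "chrom_b",
                        "startB", "endB")
  expect_equal(on_target, pairs_a + pairs_b)
  # distinct-read accounting: assigned = on-target reads + off-target reads
  off_a <- nrow(a_reads) - sum(vapply(seq_len(nrow(a_reads)), function(i) {
    sel <- w$ret$chrom == a_reads$chrom_a[i]
    any(a_reads$pos_a[i] + a_reads$ref_len_a[i] > w$ret$startA[sel] &
          a_reads$pos_a[i] < w$ret$endA[sel])
  }, logical(1)))
  off_b <- nrow(b_reads) - sum(vapply(seq_len(nrow(b_reads)), function(i) {
    sel <- w$ret$chrom == b_reads$chrom_b[i]
    any(b_reads$pos_b[i] + b_reads$ref_len_b[i] > w$ret$startB[sel] &
          b_reads$pos_b[i] < w$ret$endB[sel])
  }, logical(1)))
  on_reads_a <- nrow(a_reads) - off_a
  on_reads_b <- nrow(b_reads) - off_b
  expect_equal(n_assigned, on_reads_a + on_reads_b + off_a + off_b)
  expect_gte(on_target, on_reads_a + on_reads_b)
})

test_that("simulation outlier filter flags quantile outliers in >= 2 replicates", {
  withr::local_seed(41)
  n <- 1000
  base <- tibble::tibble(
    target_id = sprintf("t%04d", 1:n),
    count_A = rpois(n, 50), count_B = rpois(n, 50))
  mk <- function(tb) {
    tb$sum <- tb$count_A + tb$count_B
    tb$log2_ratio <- log2((tb$count_A + 0.5) / (tb$count_B + 0.5))
    tb
  }
  r1 <- mk(base)
  r2 <- mk(dplyr::mutate(base, count_A = rpois(n, 50)))
  r3 <- mk(dplyr::mutate(base, count_B = rpois(n, 50)))
  # one target extreme in all replicates, one extreme in exactly one
  extreme <- function(tb, i, a, b) {
    tb$count_A[i] <- a; tb$count_B[i] <- b
    mk(tb[, c("target_id", "count_A", "count_B")])
  }
  r1 <- extreme(r1, 1, 100L, 1L); r2 <- extreme(r2, 1, 100L, 1L)
  r3 <- extreme(r3, 1, 100L, 1L)
  r2 <- extreme(r2, 2, 1L, 100L)
  out <- filter_outlier_targets_simulation(list(r1, r2, r3))
  expect_false(out$retained[out$target_id == "t0001"])
  expect_true(out$retained[out$target_id == "t0002"])
  # conservation and brute-force agreement per replicate
  expect_equal(nrow(out), n)
  qs <- quantile(r1$log2_ratio, c(0.005, 0.995), names = FALSE)
  brute1 <- r1$log2_ratio < qs[1] | r1$log2_ratio > qs[2]
  flagged_ge1 <- out$n_flagged >= 1
  expect_true(all(which(brute1) %in% which(flagged_ge1)))
})

test_that("WGS outlier filter applies both the quantile and the sum cap", {
  withr::local_seed(42)
  n <- 1000
  tb <- tibble::tibble(
    target_id = sprintf("t%04d", 1:n),
    count_A = rpois(n, 30), count_B = rpois(n, 30))
  tb$sum <- tb$count_A + tb$count_B
  tb$log2_ratio <- log2((tb$count_A + 0.5) / (tb$count_B + 0.5))
  tb$sum[5] <- 111L  # mid-ratio but huge sum
  tb$log2_ratio[5] <- 0
  out <- filter_outlier_targets_wgs(tb, sum_cap = 110)
  expect_false(out$retained[5])
  expect_true(out$outlier_sum[5] && !out$outlier_ratio[5])
  # median-everything target is retained
  mid <- which.min(abs(tb$log2_ratio - median(tb$log2_ratio)))[1]
  expect_true(out$retained[mid])
  # brute-force recomputation of the retained set
  qs <- quantile(tb$log2_ratio[tb$sum > 0], c(0.005, 0.995), names = FALSE)
  brute <- !(tb$sum > 0 & (tb$log2_ratio < qs[1] | tb$log2_ratio > qs[2])) &
    tb$sum <= 110
  expect_equal(out$retained, brute)
})

test_that("group comparison matches an exact permutation oracle at small n", {
  withr::local_seed(43)
  x <- c(0.1, 0.4, -0.2, 0.8, 0.3, -0.1, 0.55, 0.25)
  y <- c(0.9, 1.4, 1.1, 0.6, 1.3, 0.7, 1.8, 1.05)
  p_impl <- test_group_difference(x, y)
  # exact permutation distribution of the rank-sum statistic
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_along(x)])
  combs <- utils::combn(16, 8)
  rk <- rank(pooled)
  stats <- apply(combs, 2, function(i) sum(rk[i]))
  p_perm <- mean(abs(stats - sum(rk) / 2) >= abs(r_obs - sum(rk) / 2) - 1e-9)
  expect_lt(abs(p_impl - p_perm) / p_perm, 0.10)
  # identical groups: p ~ 1; all-tied input warns and returns 1
  expect_gt(test_group_difference(x, x), 0.9)
  expect_warning(p1 <- test_group_difference(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(p1, 1)
  # 3-pooled-SD shift at n = 200 is overwhelmingly significant
  a <- rnorm(200)
  expect_lt(test_group_difference(a, a + 3), 0.01)
})

test_that("divergence groups partition targets and respect injected bias", {
  w <- small_world()
  reads <- simulate_exome_reads(w$ret, w$ga, w$gb, 150000,
                                beta_snv = 0.2, seed = 44)
  mc <- map_and_count(reads, w$ia, w$ib, w$ret, capbias_config())
  fit <- capture_bias_fit(mc$counts, w$ret)
  td <- tidy(fit)
  usable <- sum(mc$counts$sum > 0 &
                  mc$counts$target_id %in% w$ret$id)
  expect_equal(sum(td$n_targets), usable)
  m <- td[!td$has_indel, ]
  m <- m[order(m$nSNV_group), ]
  # medians increase with the SNV count under a per-SNV selection penalty
  expect_true(all(diff(m$median[m$nSNV_group >= 1]) > 0))
  expect_gt(m$median[m$nSNV_group == 4], m$median[m$nSNV_group == 1])
  gl <- glance(fit)
  expect_equal(gl$n_groups, nrow(td))
})

test_that("SNV spacing is computed from the truth table and binned correctly", {
  targets <- tibble::tibble(
    id = c("t1", "t2", "t3"), chrom = "chr1",
    startA = c(0L, 1000L, 2000L), endA = c(320L, 1320L, 2320L),
    startB = c(0L, 1000L, 2000L), endB = c(320L, 1320L, 2320L),
    nSNV = 2L, nIndel = 0L, extended = TRUE)
  truth <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 101L, 1100L, 1105L, 2100L, 2200L),
    kind = "SNV", ref = "A", alt = "C")
  counts <- tibble::tibble(
    target_id = c("t1", "t2", "t3"),
    count_A = c(30L, 20L, 10L), count_B = c(10L, 15L, 10L))
  counts$sum <- counts$count_A + counts$count_B
  counts$log2_ratio <- log2(counts$count_A / counts$count_B)
  out <- snv_spacing_analysis(counts, targets, truth)
  expect_equal(out$spacing_bin, c("1", "2-10", ">60"))
  expect_equal(out$n_targets, c(1L, 1L, 1L))
  expect_equal(out$median,
               c(log2(3), log2(20 / 15), 0), tolerance = 1e-9)
  # no 2-SNV targets: empty result
  none <- snv_spacing_analysis(counts, dplyr::mutate(targets, nSNV = 3L),
                               truth)
  expect_equal(nrow(none), 0)
})

test_that("per-target depth equals brute-force per-position counting", {
  target <- tibble::tibble(id = "t1", chrom = "chr1", startA = 500L,
                           endA = 620L)
  one_read <- tibble::tibble(read_id = "r1", genome = "A", chrom = "chr1",
                             pos = 480L, strand = "+", edit = 0L,
                             cigar = "150M", ref_len = 150L, n_best = 1L,
                             is_unique = TRUE)
  d <- compute_depth(one_read, target)
  expect_equal(d$mean_depth, 1.0)
  half <- dplyr::mutate(one_read, pos = 560L, ref_len = 60L)
  expect_equal(compute_depth(half, target)$mean_depth, 0.5)
  # random fixture against a brute-force interval-stabbing count
  withr::local_seed(45)
  rd <- tibble::tibble(
    read_id = sprintf("r%d", 1:200), genome = "A", chrom = "chr1",
    pos = sample(300:700, 200, replace = TRUE), strand = "+", edit = 0L,
    cigar = "101M", ref_len = 101L, n_best = 1L, is_unique = TRUE)
  d2 <- compute_depth(rd, target)
  brute <- vapply(500:619, function(p) {
    sum(rd$pos <= p & rd$pos + rd$ref_len > p)
  }, integer(1))
  expect_equal(d2$depth, brute)
  expect_equal(d2$mean_depth, mean(brute))
  expect_equal(mean_target_depth(rd, target), mean(brute))
})
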