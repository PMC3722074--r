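toy_pileup_world <- function() {
  memo_fixture("toy_pileup_world", function() {
    withr::local_seed(60)
    ga <- Biostrings::DNAStringSet(c(chr1 = rand_seq(5000)))
    S4Vectors::metadata(ga) <- list(strain_label = "A")
    target <- tibble::tibble(
      id = "t1", chrom = "chr1", startA = 1000L, endA = 1320L,
      startB = 1000L, endB = 1320L, nSNV = 0L, nIndel = 0L,
      extended = TRUE)
    list(ga = ga, target = target)
  })
}

test_that("pileup counts bases per position and honours CIGAR semantics", {
  tw <- toy_pileup_world()
  g <- as.character(tw$ga[[1]])
  reads <- tibble::tibble(id = sprintf("r%d", 1:10),
                          seq = substring(g, 1051, 1151))
  aln <- tibble::tibble(read_id = reads$id, genome = "A", chrom = "chr1",
                        pos = 1050L, strand = "+", edit = 0L,
                        cigar = "101M", ref_len = 101L, n_best = 1L,
                        is_unique = TRUE)
  pile <- pileup(aln, reads, tw$target, tw$ga)
  expect_equal(nrow(pile), 320)
  covered <- pile$pos >= 1050 & pile$pos < 1151
  expect_true(all(pile$depth[covered] == 10))
  expect_true(all(pile$depth[!covered] == 0))
  # counted base equals the reference base of each read copy
  i <- which(pile$pos == 1100)
  base <- substr(g, 1101, 1101)
  expect_equal(pile[[base]][i], 10L)
  # a read with a 2-base deletion contributes nothing at deleted positions
  del_read <- tibble::tibble(
    id = "d1", seq = paste0(substring(g, 1051, 1100),
                            substring(g, 1103, 1153)))
  del_aln <- tibble::tibble(read_id = "d1", genome = "A", chrom = "chr1",
                            pos = 1050L, strand = "+", edit = 2L,
                            cigar = "50M2D51M", ref_len = 103L,
                            n_best = 1L, is_unique = TRUE)
  p2 <- pileup(del_aln, del_read, tw$target, tw$ga)
  expect_equal(p2$depth[p2$pos %in% c(1100, 1101)], c(0L, 0L))
  expect_equal(p2$depth[p2$pos == 1099], 1L)
  expect_equal(p2$depth[p2$pos == 1102], 1L)
})

test_that("pileup totals agree with compute_depth on shared fixtures", {
  tw <- toy_pileup_world()
  g <- as.character(tw$ga[[1]])
  withr::local_seed(61)
  pos <- sample(800:1400, 100, replace = TRUE)
  reads <- tibble::tibble(id = sprintf("r%d", 1:100),
                          seq = substring(g, pos + 1, pos + 101))
  aln <- tibble::tibble(read_id = reads$id, genome = "A", chrom = "chr1",
                        pos = pos, strand = "+", edit = 0L, cigar = "101M",
                        ref_len = 101L, n_best = 1L, is_unique = TRUE)
  pile <- pileup(aln, reads, tw$target, tw$ga)
  d <- compute_depth(aln, tw$target)
  expect_equal(pile$depth, d$depth)
})

test_that("the het caller applies its depth, count and fraction thresholds", {
  tw <- toy_pileup_world()
  g <- as.character(tw$ga[[1]])
  ref <- substr(g, 1101, 1101)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk_pile <- function(depth, alt_n) {
    p <- tibble::tibble(target_id = "t1", chrom = "chr1", pos = 1100L,
                        A = 0L, C = 0L, G = 0L, T = 0L,
                        depth = as.integer(depth))
    p[[ref]] <- as.integer(depth - alt_n)
    p[[alt]] <- as.integer(alt_n)
    p
  }
  call1 <- call_het_snvs(mk_pile(20, 10), tw$ga)
  expect_equal(nrow(call1), 1)
  expect_equal(call1$ref, ref)
  expect_equal(call1$alt, alt)
  expect_equal(call1$depth, 20L)
  expect_equal(call1$alt_count, 10L)
  # below min_alt_count
  expect_equal(nrow(call_het_snvs(mk_pile(20, 2), tw$ga)), 0)
  # below min_depth
  expect_equal(nrow(call_het_snvs(mk_pile(4, 3), tw$ga)), 0)
  # below min_alt_fraction: 3/20 = 0.15 < 0.2
  expect_equal(nrow(call_het_snvs(mk_pile(20, 3), tw$ga)), 0)
  # pure alternate column fails the heterozygosity guard
  expect_equal(nrow(call_het_snvs(mk_pile(20, 20), tw$ga)), 0)
  # het call at fraction 0.5 passes it
  expect_equal(nrow(call_het_snvs(mk_pile(10, 5), tw$ga)), 1)
})

test_that("a noise-free full-depth callset equals the truth inside targets", {
  w <- small_world()
  reads <- simulate_exome_reads(w$ret, w$ga, w$gb, 60000, seed = 62)
  aln_a <- map_reads(reads, w$ia)
  aln_b <- map_reads(reads, w$ib)
  sc0 <- strategy_counts(aln_a, aln_b, w$ret)
  vd <- w$ret[w$ret$id %in%
                sc0$target_id[sc0$n_dual == sc0$n_single], ]
  aln <- remove_duplicates(aln_a[aln_a$is_unique, ])
  pile <- pileup(aln, reads, vd, w$ga)
  calls <- call_het_snvs(pile, w$ga)
  sc <- score_sensitivity(calls, w$truth, vd)
  expect_gte(sum(sc$n_detected) / sum(sc$n_truth), 0.999)
  # no false calls on error-free reads
  truth_key <- paste(w$truth$chrom, w$truth$pos, w$truth$alt)
  expect_equal(sum(!(paste(calls$chrom, calls$pos, calls$alt) %in%
                       truth_key)), 0)
})

test_that("depth subsampling thins reads at the requested Bernoulli rate", {
  tw <- toy_pileup_world()
  withr::local_seed(63)
  pos <- sample(900:1300, 4000, replace = TRUE)
  aln <- tibble::tibble(read_id = sprintf("r%d", 1:4000), genome = "A",
                        chrom = "chr1", pos = pos, strand = "+", edit = 0L,
                        cigar = "101M", ref_len = 101L, n_best = 1L,
                        is_unique = TRUE)
  cur <- mean_target_depth(aln, tw$target)
  same <- subsample_to_depth(aln, tw$target, cur, seed = 1)
  expect_identical(same, aln)
  half <- subsample_to_depth(aln, tw$target, cur / 2, seed = 2)
  expect_lt(abs(nrow(half) / 4000 - 0.5), 3 * sqrt(0.25 / 4000))
  achieved <- mean_target_depth(half, tw$target)
  expect_lt(abs(achieved - cur / 2) / (cur / 2), 0.05)
  expect_error(subsample_to_depth(aln, tw$target, cur * 2), "exceeds")
})

test_that("callset concordance counts match brute-force set algebra", {
  mk_calls <- function(pos) {
    tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "C",
                   depth = 20L, alt_count = 10L, multi_allelic = FALSE)
  }
  truth <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L, 4L),
                          kind = "SNV", ref = "A", alt = "C")
  cs <- list(mk_calls(c(1L, 2L, 3L, 10L)), mk_calls(c(1L, 2L, 10L)),
             mk_calls(c(1L, 5L)))
  out <- compare_callsets(cs, truth)
  expect_equal(out$n_calls_3, 1)   # pos 1
  expect_equal(out$n_calls_2, 2)   # pos 2, 10
  expect_equal(out$n_calls_1, 2)   # pos 3, 5
  expect_equal(out$truth_ge1, 3)
  expect_equal(out$truth_ge2, 2)
  expect_equal(out$truth_eq3, 1)
  expect_equal(out$false_2, 1)     # pos 10
  expect_equal(out$false_1, 1)     # pos 5
  ident <- compare_callsets(list(mk_calls(1:5), mk_calls(1:5),
                                 mk_calls(1:5)), truth)
  expect_equal(ident$n_calls_3, 5)
  expect_equal(ident$n_calls_1 + ident$n_calls_2, 0)
  disj <- compare_callsets(list(mk_calls(1L), mk_calls(2L), mk_calls(3L)),
                           truth)
  expect_equal(disj$n_calls_1, 3)
})

test_that("calls round-trip through VCF with 1-based positions", {
  tw <- toy_pileup_world()
  calls <- tibble::tibble(chrom = "chr1", pos = c(99L, 149L),
                          ref = c("A", "G"), alt = c("T", "C"),
                          depth = c(20L, 15L), alt_count = c(9L, 7L),
                          multi_allelic = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, tw$ga, path)
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  expect_length(body, 2)
  expect_equal(as.integer(sapply(strsplit(body, "\t"), `[`, 2)),
               c(100L, 150L))
  back <- read_calls_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$alt_count, calls$alt_count)
  # the reference VCF parser reads it too
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  expect_equal(unname(BiocGenerics::start(
    SummarizedExperiment::rowRanges(vcf))), c(100L, 150L))
})

test_that("truth variants round-trip through VCF as phased het records", {
  w <- small_world()
  path <- tempfile(fileext = ".vcf")
  write_truth_vcf(w$truth, w$ga, path)
  back <- read_truth_vcf(path)
  expect_equal(back$pos, w$truth$pos)
  expect_equal(back$kind, w$truth$kind)
  expect_equal(back$ref, w$truth$ref)
  expect_equal(back$alt, w$truth$alt)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  expect_equal(dim(vcf)[1], nrow(w$truth))
  gt <- VariantAnnotation::geno(vcf)$GT
  expect_true(all(gt == "1|0"))
})
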