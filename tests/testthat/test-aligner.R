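test_that("the k-mer index returns exactly the brute-force positions", {
  withr::local_seed(21)
  s <- rand_seq(10000)
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  idx <- build_index(g, k = 12)
  for (i in sample(1:(10000 - 12), 25)) {
    kmer <- substr(s, i, i + 11)
    hits <- index_lookup(idx, kmer)
    brute <- as.integer(
      gregexpr(kmer, s, fixed = TRUE)[[1]]) - 1L
    # gregexpr misses overlapping occurrences; verify by direct scan
    brute <- which(vapply(0:(10000 - 12), function(p) {
      substr(s, p + 1, p + 12) == kmer
    }, logical(1))) - 1L
    expect_setequal(hits$pos, brute)
  }
})

test_that("a repeated k-mer indexes all its copies and N-kmers none", {
  unit <- "ACGTTGCAGGAT"  # 12-mer planted twice
  s <- paste0(rand_seq(500), unit, rand_seq(500), unit, rand_seq(500))
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  g <- insert_n_block(g, "chr1", 100L, 30L)
  idx <- build_index(g, k = 12)
  expect_equal(sort(index_lookup(idx, unit)$pos), c(500L, 1012L))
  # any window overlapping the N block is unindexed
  nk <- substr(as.character(g[[1]]), 96, 107)
  expect_equal(nrow(index_lookup(idx, nk)), 0)
  expect_error(build_index(g, k = 4), "k")
})

test_that("exact reads map uniquely to their locus with edit 0", {
  w <- small_world()
  withr::local_seed(22)
  g <- as.character(w$ga[[1]])
  starts <- sample(1:(100000 - 101), 50)
  reads <- tibble::tibble(id = paste0("r", seq_along(starts)),
                          seq = substring(g, starts, starts + 100))
  aln <- map_reads(reads, w$ia)
  expect_equal(nrow(aln), 50)
  expect_true(all(aln$edit == 0))
  expect_true(all(aln$is_unique))
  expect_equal(aln$pos[order(aln$read_id)],
               (starts - 1L)[order(reads$id)])
  expect_true(all(aln$strand == "+"))
  # reverse-complemented copies map to the same loci on the minus strand
  aln_rc <- map_reads(tibble::tibble(id = reads$id, seq = rc(reads$seq)),
                      w$ia)
  expect_true(all(aln_rc$strand == "-"))
  expect_equal(sort(aln_rc$pos), sort(aln$pos))
})

test_that("reported edit distances match the independent DP oracle", {
  w <- small_world()
  withr::local_seed(23)
  g <- as.character(w$ga[[1]])
  n <- 1000
  starts <- sample(200:(100000 - 301), n)
  n_mut <- sample(0:5, n, replace = TRUE)
  reads <- tibble::tibble(
    id = paste0("m", seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      mutate_subs(substr(g, starts[i], starts[i] + 100), n_mut[i])
    }, character(1)))
  aln <- map_reads(reads, w$ia, max_edit = 5)
  expect_gt(nrow(aln), 0.97 * n)
  ok <- vapply(seq_len(nrow(aln)), function(i) {
    win <- substr(g, aln$pos[i] - 5, aln$pos[i] + aln$ref_len[i] + 5)
    q <- reads$seq[match(aln$read_id[i], reads$id)]
    if (aln$strand[i] == "-") q <- rc(q)
    oracle_edit(q, win) == aln$edit[i]
  }, logical(1))
  expect_true(all(ok))
  # mapper never beats the oracle at the true locus
  m <- match(aln$read_id, reads$id)
  expect_true(all(aln$edit[aln$strand == "+"] <= n_mut[m][aln$strand == "+"]))
})

test_that("reads beyond the maximum edit distance are never mapped", {
  w <- small_world()
  withr::local_seed(24)
  g <- as.character(w$ga[[1]])
  for (i in 1:30) {
    s <- sample(200:(100000 - 301), 1)
    src <- substr(g, s, s + 100)
    mut <- mutate_subs(src, 8)
    # confirm with the oracle that >5 edits remain after mutation
    d <- oracle_edit(mut, substr(g, s - 10, s + 110))
    if (d <= 5) next
    aln <- map_reads(mut, w$ia, max_edit = 5)
    expect_equal(nrow(aln), 0)
  }
  # 6 substitutions against max_edit = 5 is the documented cliff; the
  # mutations sit in the first 60 bases so an intact seed remains and the
  # locus is still found once max_edit allows it
  s <- 40000
  mut6 <- substr(g, s, s + 100)
  for (p in c(5L, 15L, 25L, 35L, 45L, 55L)) {
    old <- substr(mut6, p, p)
    substr(mut6, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  if (oracle_edit(mut6, substr(g, s - 10, s + 110)) > 5) {
    expect_equal(nrow(map_reads(mut6, w$ia, max_edit = 5)), 0)
  }
  expect_gt(nrow(map_reads(mut6, w$ia, max_edit = 8)), 0)
})

test_that("indel-bearing reads map with CIGARs that walk the reference", {
  w <- small_world()
  withr::local_seed(25)
  g <- as.character(w$ga[[1]])
  s <- 30001
  # read with a 3-base deletion relative to the reference
  del_read <- paste0(substr(g, s, s + 49), substr(g, s + 53, s + 103))
  aln <- map_reads(del_read, w$ia, max_edit = 5)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$edit, 3L)
  expect_equal(aln$pos, s - 1L)
  expect_equal(aln$ref_len, 104L)
  expect_match(aln$cigar, "50M3D51M")
  # read with a 2-base insertion
  ins_read <- paste0(substr(g, s, s + 49), "GG", substr(g, s + 50, s + 98))
  aln2 <- map_reads(ins_read, w$ia, max_edit = 5)
  expect_equal(aln2$edit, 2L)
  expect_equal(aln2$ref_len, 99L)
})

test_that("multi-mapping reads are flagged and discarded downstream", {
  withr::local_seed(26)
  copy <- rand_seq(300)
  s <- paste0(rand_seq(2000), copy, rand_seq(2000), copy, rand_seq(2000))
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  S4Vectors::metadata(g) <- list(strain_label = "A")
  idx <- build_index(g, k = 20)
  read <- substr(copy, 50, 150)
  aln <- map_reads(read, idx)
  expect_equal(nrow(aln), 2)
  expect_true(all(!aln$is_unique))
  expect_true(all(aln$n_best == 2))
  # dual mapping flags the whole read as discarded
  w <- small_world()
  dm <- map_reads_dual(tibble::tibble(id = "q1", seq = read), idx, w$ib)
  expect_equal(dm$status, "multi")
  expect_equal(assign_allelic_origin(dm)$origin, "discarded")
})

test_that("dual mapping separates alleles by edit distance symmetrically", {
  # hand-built genome pair with exactly two planted SNVs
  withr::local_seed(27)
  a_seq <- rand_seq(5000)
  b_seq <- a_seq
  for (p in c(2040L, 2080L)) {
    old <- substr(b_seq, p, p)
    substr(b_seq, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  ga <- Biostrings::DNAStringSet(c(chr1 = a_seq))
  S4Vectors::metadata(ga) <- list(strain_label = "A")
  gb <- Biostrings::DNAStringSet(c(chr1 = b_seq))
  S4Vectors::metadata(gb) <- list(strain_label = "B")
  ia <- build_index(ga)
  ib <- build_index(gb)
  # identical-segment read hits both genomes with edit 0
  read_0 <- substr(a_seq, 501, 601)
  dm0 <- map_reads_dual(tibble::tibble(id = "q0", seq = read_0), ia, ib)
  expect_equal(dm0$status, "both")
  expect_equal(dm0$edit_a, 0L)
  expect_equal(dm0$edit_b, 0L)
  expect_equal(assign_allelic_origin(dm0)$origin, "ambiguous")
  # B-allele read across both SNVs: edit 0 on B, 2 on A
  read_b <- substr(b_seq, 2001, 2101)
  dm <- map_reads_dual(tibble::tibble(id = "b1", seq = read_b), ia, ib)
  expect_equal(dm$status, "both")
  expect_equal(dm$edit_b, 0L)
  expect_equal(dm$edit_a, 2L)
  expect_equal(assign_allelic_origin(dm)$origin, "B")
  # swapping the genome labels swaps the sides exactly
  dm_sw <- map_reads_dual(tibble::tibble(id = "b1", seq = read_b), ib, ia)
  expect_equal(dm_sw$edit_a, dm$edit_b)
  expect_equal(dm_sw$edit_b, dm$edit_a)
  expect_equal(dm_sw$pos_a, dm$pos_b)
  # with the genomes swapped the assigned side swaps too
  expect_equal(assign_allelic_origin(dm_sw)$origin, "A")
})

test_that("duplicate removal keeps one read per (genome, chrom, pos, strand)", {
  recs <- tibble::tibble(
    read_id = c("r2", "r1", "r3", "r4", "r5"),
    genome = "A", chrom = "chr1",
    pos = c(100L, 100L, 100L, 200L, 100L),
    strand = c("+", "+", "-", "+", "+"),
    edit = 0L, cigar = "101M", ref_len = 101L, n_best = 1L,
    is_unique = TRUE)
  dd <- remove_duplicates(recs)
  expect_equal(nrow(dd), 3)
  # lowest read id retained at the duplicated locus
  expect_true("r1" %in% dd$read_id)
  expect_false(any(c("r2", "r5") %in% dd$read_id))
  # opposite strands both survive
  expect_true("r3" %in% dd$read_id)
  # spiking exact duplicates never changes the deduplicated set
  spiked <- dplyr::bind_rows(recs, dplyr::mutate(recs, read_id = paste0("z", read_id)))
  expect_equal(dplyr::select(remove_duplicates(spiked), -"read_id"),
               dplyr::select(dd, -"read_id"))
})

test_that("simulated reads map back to their true source locus", {
  w <- small_world()
  reads <- simulate_exome_reads(w$ret, w$ga, w$gb, 5000, seed = 30)
  ra <- reads[reads$allele == "A", ]
  aln <- map_reads(ra, w$ia)
  aln <- aln[aln$is_unique & aln$edit == 0, ]
  m <- match(aln$read_id, ra$id)
  agree <- aln$pos == ra$start[m] & aln$chrom == ra$chrom[m] &
    aln$strand == ra$strand[m]
  expect_gte(mean(agree), 0.999)
})
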