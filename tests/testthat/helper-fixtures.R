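# Shared fixtures (built once per run) and independent oracles.

fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# independent semi-global edit-distance oracle (query global, window local),
# via Biostrings dynamic-programming alignment with unit costs
oracle_edit <- function(query, window) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  -Biostrings::score(Biostrings::pairwiseAlignment(
    query, window, type = "global-local", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 1))
}

# substitutions at n distinct positions (each to a different base)
mutate_subs <- function(seq, n_sub) {
  pos <- sample(nchar(seq), n_sub)
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seq
}

# small synthetic world shared by the unit tests
small_world <- function() {
  memo_fixture("small_world", function() {
    ga <- generate_base_genome(2, 100000, 0.5, seed = 42)
    div <- derive_divergent_genome(ga, divergence_config(seed = 43))
    tg <- define_targets(ga, 120, seed = 44)
    orth <- establish_orthology(tg, ga, div$genome)
    ret <- annotate_target_divergence(orth$retained, div$truth)
    list(ga = ga, gb = div$genome, truth = div$truth,
         lift = div$liftover, targets = tg, orth = orth, ret = ret,
         ia = build_index(ga), ib = build_index(div$genome))
  })
}

# full study conditions (default configuration) with the three unbiased
# control replicates simulated and dual-mapped; shared by the acceptance
# tests so the expensive mapping runs once
study_world <- function() {
  memo_fixture("study_world", function() {
    cfg <- capbias_config()
    prep <- prepare_experiment(cfg)
    ia <- build_index(prep$genome_a, cfg$aligner$k)
    ib <- build_index(prep$genome_b, cfg$aligner$k)
    control <- lapply(seq_len(3), function(r) {
      reads <- simulate_exome_reads(
        prep$retained, prep$genome_a, prep$genome_b,
        cfg$simulation$n_reads, cfg$simulation$read_length, 0, 0, 0,
        seed = cfg$simulation$control_seeds[r])
      mc <- map_and_count(reads, ia, ib, prep$retained, cfg)
      mc$reads <- reads
      mc
    })
    list(cfg = cfg, prep = prep, ia = ia, ib = ib, control = control)
  })
}
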