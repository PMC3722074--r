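# End-to-end orchestration: genomes -> orthology -> simulation -> dual
# mapping -> outlier filters -> bias analyses -> mapping-bias filter ->
# strain-A-only calling and the sensitivity grid. Each stage logs its
# conservation counts (reads in/out, targets retained/dropped), which are
# the test surface for the conservation properties.

write_tsv0 <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prepare the genome pair and orthologous targets of an experiment
#'
#' Runs the generation stages of [run_full_experiment()] only: base genome,
#' divergent genome with truth table and liftover, target definition,
#' orthology filtering and divergence annotation.
#'
#' @param config A [capbias_config()].
#' @return List: genome_a, genome_b, truth, liftover, targets (as defined),
#'   orthology (an `orthology_result`), retained (extended, annotated
#'   targets).
#' @export
prepare_experiment <- function(config = capbias_config()) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    rlang::abort(c("invalid configuration", viol))
  }
  g <- config$genome
  genome_a <- generate_base_genome(g$n_chrom, g$chrom_length, g$gc, g$seed,
                                   strain = "A")
  d <- config$divergence
  div <- derive_divergent_genome(
    genome_a,
    divergence_config(d$snv_rate, d$indel_rate, d$indel_mean_length,
                      d$conserved_fraction, d$conserved_block, d$seed),
    strain = "B")
  tg <- config$targets
  targets <- define_targets(genome_a, tg$n_targets, tg$target_length,
                            tg$min_gap, tg$seed, tg$margin)
  orth <- establish_orthology(targets, genome_a, div$genome,
                              config$orthology$max_edit_fraction,
                              config$aligner$k, config$aligner$n_seeds,
                              config$orthology$extension)
  retained <- annotate_target_divergence(orth$retained, div$truth)
  list(genome_a = genome_a, genome_b = div$genome, truth = div$truth,
       liftover = div$liftover, targets = targets, orthology = orth,
       retained = retained)
}

#' Map one read set to both genomes and count allele-specific reads
#'
#' Maps, removes PCR duplicates per genome, combines the dual mapping,
#' assigns allelic origins and counts reads per target.
#'
#' @param reads Read tibble.
#' @param index_a,index_b Genome indexes.
#' @param targets Extended target tibble.
#' @param config A [capbias_config()] (aligner and bias blocks are used).
#' @return List: aln_a, aln_b (all reported loci), assigned (dual table with
#'   origins), counts (per-target allele counts).
#' @export
map_and_count <- function(reads, index_a, index_b, targets,
                          config = capbias_config()) {
  al <- config$aligner
  aln_a <- map_reads(reads, index_a, al$max_edit, al$n_seeds)
  aln_b <- map_reads(reads, index_b, al$max_edit, al$n_seeds)
  dd_a <- remove_duplicates(aln_a[aln_a$is_unique, ])
  dd_b <- remove_duplicates(aln_b[aln_b$is_unique, ])
  multi_a <- aln_a[!aln_a$is_unique, ]
  multi_b <- aln_b[!aln_b$is_unique, ]
  dual <- combine_dual(dplyr::bind_rows(dd_a, multi_a),
                       dplyr::bind_rows(dd_b, multi_b))
  assigned <- assign_allelic_origin(dual)
  counts <- count_reads_per_target(assigned, targets,
                                   config$bias$pseudocount)
  list(aln_a = aln_a, aln_b = aln_b, assigned = assigned, counts = counts)
}

#' Run the full capture-bias experiment
#'
#' Stages: genome/target generation and orthology; simulation of biased
#' exome replicates, unbiased control replicates and a WGS control; dual
#' mapping with duplicate removal; quantile outlier filters on the control
#' channels; divergence-group and SNV-spacing bias analyses; the
#' two-strategy mapping-bias filter; strain-A-only calling with the
#' depth-sensitivity grid and replicate concordance. All tables are written
#' as TSV under `out_dir` together with a run manifest.
#'
#' @param config A [capbias_config()].
#' @param out_dir Output directory (created if missing).
#' @return (Invisibly) a list with every intermediate table.
#' @export
run_full_experiment <- function(config = capbias_config(),
                                out_dir = tempfile("capbias_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) inform(paste0("[capbias] ", sprintf(...)))

  stage("generating genomes and targets")
  prep <- prepare_experiment(config)
  write_genome_fasta(prep$genome_a, file.path(out_dir, "genome_A.fasta"))
  write_genome_fasta(prep$genome_b, file.path(out_dir, "genome_B.fasta"))
  write_truth_vcf(prep$truth, prep$genome_a, file.path(out_dir, "truth.vcf"))
  write_liftover_tsv(prep$liftover, file.path(out_dir, "liftover.tsv"))
  write_targets_bed(prep$targets, file.path(out_dir, "targets.bed"))
  write_targets_bed(prep$retained,
                    file.path(out_dir, "targets_orthologous.bed"))
  write_tsv0(prep$orthology$dropped,
             file.path(out_dir, "orthology_drops.tsv"))
  stage("orthology: %d retained, %d dropped", nrow(prep$retained),
        nrow(prep$orthology$dropped))

  al <- config$aligner
  index_a <- build_index(prep$genome_a, al$k)
  index_b <- build_index(prep$genome_b, al$k)
  sim <- config$simulation
  nrep <- sim$replicates

  stage("simulating and mapping %d exome replicates", nrep)
  exome <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    reads <- simulate_exome_reads(prep$retained, prep$genome_a,
                                  prep$genome_b, sim$n_reads,
                                  sim$read_length, sim$beta_snv,
                                  sim$beta_indel, sim$error_rate,
                                  seed = sim$seeds[r])
    exome[[r]] <- map_and_count(reads, index_a, index_b, prep$retained,
                                config)
    exome[[r]]$reads <- reads
    write_tsv0(exome[[r]]$counts,
               file.path(out_dir, sprintf("exome_counts_rep%d.tsv", r)))
  }

  stage("simulating and mapping %d unbiased control replicates", nrep)
  control <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    reads <- simulate_exome_reads(prep$retained, prep$genome_a,
                                  prep$genome_b, sim$n_reads,
                                  sim$read_length, 0, 0, 0,
                                  seed = sim$control_seeds[r])
    control[[r]] <- map_and_count(reads, index_a, index_b, prep$retained,
                                  config)
    control[[r]]$reads <- reads
    write_tsv0(control[[r]]$counts,
               file.path(out_dir, sprintf("control_counts_rep%d.tsv", r)))
  }

  stage("simulating and mapping the WGS control")
  wgs_reads <- simulate_wgs_reads(prep$genome_a, prep$genome_b,
                                  config$wgs$n_reads, sim$read_length,
                                  seed = config$wgs$seed)
  wgs <- map_and_count(wgs_reads, index_a, index_b, prep$retained, config)
  write_tsv0(wgs$counts, file.path(out_dir, "wgs_counts.tsv"))

  stage("outlier filters")
  fl <- config$filters
  sim_filter <- filter_outlier_targets_simulation(
    lapply(control, `[[`, "counts"), fl$q_low, fl$q_high, fl$min_flagged)
  wgs_filter <- filter_outlier_targets_wgs(wgs$counts, fl$q_low, fl$q_high,
                                           fl$sum_cap)
  write_tsv0(sim_filter, file.path(out_dir, "filter_simulation.tsv"))
  write_tsv0(wgs_filter, file.path(out_dir, "filter_wgs.tsv"))
  keep_ids <- intersect(sim_filter$target_id[sim_filter$retained],
                        wgs_filter$target_id[wgs_filter$retained])
  analysis_targets <- prep$retained[prep$retained$id %in% keep_ids, ]
  stage("analysis targets after outlier filters: %d of %d",
        nrow(analysis_targets), nrow(prep$retained))

  stage("bias analyses")
  counts1 <- exome[[1]]$counts[exome[[1]]$counts$target_id %in% keep_ids, ]
  groups <- group_bias_by_divergence(counts1, analysis_targets,
                                     config$bias$max_snv_group)
  spacing <- snv_spacing_analysis(counts1, analysis_targets, prep$truth)
  ma <- dplyr::left_join(
    counts1,
    tibble::tibble(target_id = sim_filter$target_id,
                   sim_outlier = !sim_filter$retained),
    by = "target_id")
  write_tsv0(groups, file.path(out_dir, "bias_groups.tsv"))
  write_tsv0(spacing, file.path(out_dir, "bias_snv_spacing.tsv"))
  write_tsv0(ma, file.path(out_dir, "ma_exome_rep1.tsv"))

  stage("mapping-bias filter")
  strat <- lapply(control, function(ct) {
    strategy_counts(ct$aln_a, ct$aln_b, prep$retained)
  })
  for (r in seq_len(nrep)) {
    write_tsv0(strat[[r]],
               file.path(out_dir, sprintf("strategy_counts_rep%d.tsv", r)))
  }
  mapfilter <- retain_unbiased_targets(strat)
  write_tsv0(mapfilter, file.path(out_dir, "mapfilter_retained.tsv"))
  vd_targets <- analysis_targets[
    analysis_targets$id %in% mapfilter$target_id[mapfilter$retained], ]
  stage("targets retained for variant detection: %d", nrow(vd_targets))

  stage("variant calling and sensitivity grid")
  ca <- config$caller
  callsets <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    aln <- remove_duplicates(
      exome[[r]]$aln_a[exome[[r]]$aln_a$is_unique, ])
    pile <- pileup(aln, exome[[r]]$reads, vd_targets, prep$genome_a)
    callsets[[r]] <- call_het_snvs(pile, prep$genome_a, ca$min_depth,
                                   ca$min_alt_count, ca$min_alt_fraction)
    write_vcf(callsets[[r]], prep$genome_a,
              file.path(out_dir, sprintf("calls_rep%d.vcf", r)))
  }
  concordance <- compare_callsets(callsets, truth_snvs_in_targets(
    prep$truth, vd_targets))
  write_tsv0(concordance, file.path(out_dir, "concordance.tsv"))
  aln1 <- remove_duplicates(exome[[1]]$aln_a[exome[[1]]$aln_a$is_unique, ])
  cur_depth <- mean_target_depth(aln1, vd_targets)
  grid <- config$depth$grid[config$depth$grid <= cur_depth]
  if (length(grid) < length(config$depth$grid)) {
    stage("full-data mean depth %.1f; clipping depth grid to %s", cur_depth,
          paste(grid, collapse = ","))
  }
  sens <- sensitivity_by_depth(aln1, exome[[1]]$reads, prep$truth,
                               vd_targets, prep$genome_a,
                               grid, config$depth$seeds,
                               ca$min_depth, ca$min_alt_count,
                               ca$min_alt_fraction)
  write_tsv0(sens, file.path(out_dir, "sensitivity.tsv"))

  write_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("capbias")),
    r_version = R.version.string,
    n_targets_defined = nrow(prep$targets),
    n_targets_orthologous = nrow(prep$retained),
    n_targets_analysis = nrow(analysis_targets),
    n_targets_variant_detection = nrow(vd_targets))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(config = config, out_dir = out_dir, prep = prep,
                 exome = exome, control = control, wgs = wgs,
                 sim_filter = sim_filter, wgs_filter = wgs_filter,
                 analysis_targets = analysis_targets, groups = groups,
                 spacing = spacing, strategy = strat,
                 mapfilter = mapfilter, vd_targets = vd_targets,
                 callsets = callsets, concordance = concordance,
                 sensitivity = sens))
}
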