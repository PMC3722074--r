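#' Experiment configuration
#'
#' Builds the full nested configuration for [run_full_experiment()], with
#' desk-scale defaults: two 400 kb chromosomes, 600 targets of 120 bp,
#' three 300k-read replicates of 101-nt single-end capture reads per
#' channel, seed-and-extend mapping with k = 20 and a maximum edit distance
#' of 5, 0.5%/99.5% outlier quantiles, and a depth grid of 10 to 80 in
#' steps of 10. Every random stage carries an explicit seed.
#'
#' @param ... Named blocks overriding defaults, e.g.
#'   `simulation = list(n_reads = 1e5)`. Unknown block or field names are
#'   rejected by [validate_config()].
#' @return A nested list of class `capbias_config`.
#' @export
capbias_config <- function(...) {
  cfg <- list(
    genome = list(n_chrom = 2L, chrom_length = 400000L, gc = 0.5,
                  seed = 101L),
    divergence = list(snv_rate = 1 / 70, indel_rate = 1 / 550,
                      indel_mean_length = 2, conserved_fraction = 0.45,
                      conserved_block = 400L, seed = 202L),
    targets = list(n_targets = 600L, target_length = 120L, min_gap = 250L,
                   seed = 303L, margin = 500L),
    orthology = list(max_edit_fraction = 0.25, extension = 100L),
    simulation = list(n_reads = 300000L, read_length = 101L,
                      replicates = 3L, seeds = c(11L, 12L, 13L),
                      control_seeds = c(111L, 112L, 113L),
                      beta_snv = 0, beta_indel = 0, error_rate = 0),
    wgs = list(n_reads = 150000L, seed = 21L),
    aligner = list(k = 20L, n_seeds = 4L, max_edit = 5L),
    filters = list(q_low = 0.005, q_high = 0.995, sum_cap = "auto",
                   min_flagged = 2L),
    bias = list(pseudocount = 0.5, max_snv_group = 6L),
    caller = list(min_depth = 5L, min_alt_count = 3L,
                  min_alt_fraction = 0.2),
    depth = list(grid = seq(10L, 80L, by = 10L), seeds = c(1L, 2L, 3L)))
  over <- list(...)
  for (blk in names(over)) {
    if (!blk %in% names(cfg)) {
      rlang::abort(sprintf("unknown config block '%s'", blk))
    }
    for (fld in names(over[[blk]])) {
      if (!fld %in% names(cfg[[blk]])) {
        rlang::abort(sprintf("unknown field '%s' in block '%s'", fld, blk))
      }
      cfg[[blk]][[fld]] <- over[[blk]][[fld]]
    }
  }
  structure(cfg, class = "capbias_config")
}

#' Validate an experiment configuration
#'
#' @param config A [capbias_config()].
#' @return A character vector of violations, empty when the configuration
#'   is valid. Each violation names the offending field and rule.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$genome$n_chrom >= 1, "genome.n_chrom: must be >= 1")
  chk(config$genome$chrom_length >= 1000,
      "genome.chrom_length: must be >= 1000")
  chk(config$genome$gc > 0 && config$genome$gc < 1,
      "genome.gc: must be in (0, 1)")
  chk(config$divergence$snv_rate >= 0 && config$divergence$snv_rate <= 0.2,
      "divergence.snv_rate: must be in [0, 0.2]")
  chk(config$divergence$indel_rate >= 0 &&
        config$divergence$indel_rate <= 0.2,
      "divergence.indel_rate: must be in [0, 0.2]")
  chk(config$targets$n_targets >= 0, "targets.n_targets: must be >= 0")
  chk(config$targets$target_length >= 1,
      "targets.target_length: must be >= 1")
  chk(config$simulation$n_reads >= 1, "simulation.n_reads: must be >= 1")
  chk(config$simulation$read_length >= config$aligner$k,
      "simulation.read_length: must be >= aligner.k")
  chk(length(config$simulation$seeds) >= config$simulation$replicates,
      "simulation.seeds: one seed per replicate required")
  chk(length(config$simulation$control_seeds) >=
        config$simulation$replicates,
      "simulation.control_seeds: one seed per replicate required")
  chk(config$simulation$beta_snv >= 0, "simulation.beta_snv: must be >= 0")
  chk(config$simulation$beta_indel >= 0,
      "simulation.beta_indel: must be >= 0")
  chk(config$aligner$k >= 8 && config$aligner$k <= 32,
      "aligner.k: must be in [8, 32]")
  chk(config$aligner$max_edit >= 0, "aligner.max_edit: must be >= 0")
  chk(config$filters$q_low < config$filters$q_high,
      "filters.q_low: must be below filters.q_high")
  chk(config$filters$q_low >= 0 && config$filters$q_high <= 1,
      "filters quantiles: must lie in [0, 1]")
  chk(config$bias$pseudocount >= 0, "bias.pseudocount: must be >= 0")
  chk(config$caller$min_depth >= 1, "caller.min_depth: must be >= 1")
  chk(config$caller$min_alt_fraction >= 0 &&
        config$caller$min_alt_fraction <= 1,
      "caller.min_alt_fraction: must be in [0, 1]")
  chk(all(config$depth$grid > 0), "depth.grid: depths must be positive")
  v
}

#' Write a configuration as YAML
#' @param config A [capbias_config()].
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Read a YAML configuration
#' @param path YAML file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(capbias_config, raw)
}
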