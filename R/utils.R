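# Internal helpers shared across modules.

# Reverse-complement a character vector of DNA strings.
revcomp_chr <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a genome to a named character vector of chromosome sequences.
genome_as_character <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    rlang::abort("genome must be a named DNAStringSet or named character vector")
  }
}

genome_lengths <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(genome, nchar, integer(1))
  }
}

strain_label <- function(genome, default = "?") {
  md <- tryCatch(S4Vectors::metadata(genome), error = function(e) NULL)
  if (!is.null(md$strain_label)) md$strain_label else default
}

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x)) {
    rlang::abort(sprintf("`%s` must be a single integer", name))
  }
  if (!is.null(min) && x < min) {
    rlang::abort(sprintf("`%s` must be >= %s", name, min))
  }
  invisible(as.integer(x))
}

# 0-based half-open interval overlap length
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
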