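#' Fit the capture-bias analysis as one object
#'
#' Bundles the per-target allele counts, divergence annotations and the
#' divergence-group summaries into a single fitted object with broom-style
#' [tidy()]/[glance()] methods and an [ggplot2::autoplot()] method.
#'
#' @param counts Per-target count tibble from [count_reads_per_target()].
#' @param targets Annotated target tibble.
#' @param max_snv_group Largest SNV count given its own group (default 6).
#' @return An object of class `capture_bias`.
#' @export
capture_bias_fit <- function(counts, targets, max_snv_group = 6L) {
  groups <- group_bias_by_divergence(counts, targets, max_snv_group)
  dat <- dplyr::inner_join(counts, targets[, c("id", "nSNV", "nIndel")],
                           by = c(target_id = "id"))
  structure(list(counts = dat, groups = groups,
                 max_snv_group = max_snv_group),
            class = "capture_bias")
}

#' @export
print.capture_bias <- function(x, ...) {
  cat(sprintf("<capture_bias: %d targets, %d divergence groups>\n",
              nrow(x$counts), nrow(x$groups)))
  print(x$groups)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-group summaries of a capture-bias fit
#' @param x A `capture_bias` object.
#' @param ... Unused.
#' @export
tidy.capture_bias <- function(x, ...) {
  x$groups
}

#' One-row summary of a capture-bias fit
#' @param x A `capture_bias` object.
#' @param ... Unused.
#' @export
glance.capture_bias <- function(x, ...) {
  usable <- x$counts[x$counts$sum > 0, ]
  tibble::tibble(
    n_targets = nrow(x$counts),
    n_usable = nrow(usable),
    grand_median = median(usable$log2_ratio),
    n_groups = nrow(x$groups),
    n_significant = sum(x$groups$p_value < 0.01, na.rm = TRUE))
}

#' @export
autoplot.capture_bias <- function(object, ...) {
  dat <- object$counts[object$counts$sum > 0, ]
  dat$nSNV_group <- factor(pmin(dat$nSNV, object$max_snv_group))
  dat$indels <- ifelse(dat$nIndel > 0, "with indels", "no indels")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nSNV_group,
                                    y = .data$log2_ratio,
                                    fill = .data$indels)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "SNVs per target", y = "log2(count A / count B)",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' MA plot of per-target allele counts
#'
#' Total assigned reads (x, log10) against the log2 allele ratio (y);
#' targets flagged by an outlier filter can be highlighted.
#'
#' @param counts Per-target count tibble.
#' @param flagged Optional character vector of outlier target ids.
#' @export
plot_ma <- function(counts, flagged = NULL) {
  dat <- counts[counts$sum > 0, ]
  dat$outlier <- dat$target_id %in% (flagged %||% character(0))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sum, y = .data$log2_ratio,
                                    colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey55") +
    ggplot2::labs(x = "assigned reads per target (A + B)",
                  y = "log2(count A / count B)") +
    ggplot2::theme_bw()
}

#' Sensitivity-versus-depth curves by divergence group
#'
#' @param sens Sensitivity tibble from [sensitivity_by_depth()].
#' @export
plot_sensitivity <- function(sens) {
  dat <- sens %>%
    dplyr::group_by(.data$mean_depth_level, .data$nSNV_group) %>%
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_depth_level,
                                    y = .data$sensitivity,
                                    colour = factor(.data$nSNV_group))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean sequencing depth", y = "sensitivity",
                  colour = "SNVs/target") +
    ggplot2::theme_bw()
}
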