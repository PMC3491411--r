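#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a smoothed profile into long format
#'
#' @param x A [smooth_profile()] result.
#' @param ... Unused.
#' @return Tibble with `chrom`, `pos`, `h`, `sample`, `f`, `valid`.
#' @method tidy meth_smooth
#' @export
tidy.meth_smooth <- function(x, ...) {
  s <- attr(x, "samples")
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("f_", s)),
                        names_to = "sample", names_prefix = "f_",
                        values_to = "f") |>
    dplyr::mutate(valid = !is.na(.data$f))
}

#' @rdname tidy.meth_smooth
#' @method glance meth_smooth
#' @export
glance.meth_smooth <- function(x, ...) {
  f <- smooth_values(x)
  p <- attr(x, "params")
  tibble::tibble(n_loci = nrow(x), n_samples = ncol(f),
                 n_invalid = sum(is.na(f)),
                 min_cpgs = p$min_cpgs, min_width_bp = p$min_width_bp,
                 median_h = stats::median(x$h))
}

#' Tidy / summarise a t-statistic track
#'
#' @param x A [tstat()] track.
#' @param ... Unused.
#' @method tidy tstat_track
#' @export
tidy.tstat_track <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.tstat_track
#' @method glance tstat_track
#' @export
glance.tstat_track <- function(x, ...) {
  des <- attr(x, "design")
  tibble::tibble(n_loci = nrow(x), n_masked = sum(is.na(x$t)),
                 n1 = des$n1, n2 = des$n2,
                 sd_floor = min(x$sd, na.rm = TRUE),
                 t_sd = stats::sd(x$t, na.rm = TRUE))
}

#' Tidy / summarise region calls
#'
#' @param x A `region_calls` tibble ([call_dmrs()], [call_blocks()],
#'   [call_fisher_dmrs()]).
#' @param ... Unused.
#' @method tidy region_calls
#' @export
tidy.region_calls <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.region_calls
#' @method glance region_calls
#' @export
glance.region_calls <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x),
                 n_hyper = sum(x$direction == "hyper"),
                 n_hypo = sum(x$direction == "hypo"),
                 total_width = sum(x$end - x$start + 1),
                 median_cpgs = stats::median(x$n_cpgs))
}

#' Plot an M-bias table
#'
#' Methylation proportion by read position, one curve per read length; a
#' flat line is the expected behaviour, deviations are M-bias.
#'
#' @param object An [compute_mbias()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mbias_table
#' @export
autoplot.mbias_table <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$proportion), ],
                  ggplot2::aes(x = .data$read_pos, y = .data$proportion,
                               colour = factor(.data$read_length))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "read position (cycle)",
                  y = "methylation proportion", colour = "read length") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mbias_table
#' @export
plot_mbias <- function(object, ...) autoplot.mbias_table(object, ...)

#' Plot smoothed methylation profiles
#'
#' @param object A [smooth_profile()] result.
#' @param chrom Chromosome to plot (default: first).
#' @param xlim Optional position range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meth_smooth
#' @export
autoplot.meth_smooth <- function(object, chrom = NULL, xlim = NULL, ...) {
  long <- tidy(object)
  if (is.null(chrom)) chrom <- long$chrom[1]
  long <- long[long$chrom == chrom, ]
  if (!is.null(xlim)) long <- long[long$pos >= xlim[1] & long$pos <= xlim[2], ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$f,
                                     colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0("position on ", chrom),
                  y = "smoothed methylation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a t-statistic track with called regions
#'
#' @param object A [tstat()] track.
#' @param calls Optional `region_calls` to shade.
#' @param chrom Chromosome to plot (default: first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tstat_track
#' @export
autoplot.tstat_track <- function(object, calls = NULL, chrom = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (is.null(chrom)) chrom <- d$chrom[1]
  d <- d[d$chrom == chrom & !is.na(d$t), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$t)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = paste0("position on ", chrom), y = "t statistic") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    cc <- calls[calls$chrom == chrom, ]
    if (nrow(cc)) {
      p <- p + ggplot2::geom_rect(
        data = tibble::as_tibble(cc),
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf, fill = .data$direction),
        alpha = 0.2, inherit.aes = FALSE)
    }
  }
  p
}

#' Plot ROC points
#'
#' @param roc A [roc_points()] result (or several, row-bound with a
#'   `method` column).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  aes <- if ("method" %in% names(roc)) {
    ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$method)
  } else {
    ggplot2::aes(x = .data$fpr, y = .data$tpr)
  }
  ggplot2::ggplot(roc, aes) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
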