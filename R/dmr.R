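#' Per-locus group means and difference
#'
#' From smoothed per-sample profiles, estimates the baseline profile
#' `alpha` (mean of the smoothed values over all samples) and the group
#' difference `beta` (mean over group 1 minus mean over group 0). A locus
#' invalid in any sample is masked (`NA`) in both.
#'
#' @param sm A [smooth_profile()] result.
#' @param design A [group_design()].
#' @return Tibble with `chrom`, `pos`, `alpha`, `beta`.
#' @export
group_stats <- function(sm, design) {
  f <- smooth_values(sm)
  stopifnot(ncol(f) == length(design$labels))
  g1 <- design$labels == 1L
  alpha <- rowMeans(f)
  beta <- rowMeans(f[, g1, drop = FALSE]) - rowMeans(f[, !g1, drop = FALSE])
  bad <- rowSums(is.na(f)) > 0
  alpha[bad] <- NA_real_; beta[bad] <- NA_real_
  tibble::tibble(chrom = sm$chrom, pos = sm$pos, alpha = alpha, beta = beta)
}

#' Local standard deviation with flooring and running-mean smoothing
#'
#' Per-locus biological-variability estimate: the pooled within-group
#' standard deviation of the smoothed values (denominator `n1 + n2 - 2`),
#' or the single-group SD of the reference group when `normal_only = TRUE`
#' (recommended for cancer/normal comparisons, where the cancer group is
#' more variable). The raw SDs are floored at their `floor_quantile`
#' quantile (computed over all unmasked loci in the run) and then smoothed
#' with a centered running mean of `run_mean_window` loci per chromosome,
#' the window shrinking at chromosome ends.
#'
#' @param sm A [smooth_profile()] result.
#' @param design A [group_design()].
#' @param floor_quantile Flooring quantile (default 0.75).
#' @param run_mean_window Running-mean window in CpGs (odd; default 101).
#' @param normal_only If `TRUE`, estimate the SD from the group-0 samples
#'   only.
#' @return Tibble with `chrom`, `pos`, `sd_raw`, `sd` (`NA` at masked
#'   loci).
#' @export
local_sd <- function(sm, design, floor_quantile = 0.75,
                     run_mean_window = 101L, normal_only = FALSE) {
  f <- smooth_values(sm)
  g1 <- design$labels == 1L
  if (normal_only) {
    if (design$n1 < 2L) stop("normal-only SD needs >= 2 group-0 samples")
    x0 <- f[, !g1, drop = FALSE]
    sd_raw <- apply(x0, 1, stats::sd)
  } else {
    if (design$n1 < 2L || design$n2 < 2L) {
      stop("pooled SD needs >= 2 samples per group")
    }
    x0 <- f[, !g1, drop = FALSE]; x1 <- f[, g1, drop = FALSE]
    ss0 <- rowSums((x0 - rowMeans(x0))^2)
    ss1 <- rowSums((x1 - rowMeans(x1))^2)
    sd_raw <- sqrt((ss0 + ss1) / (design$n1 + design$n2 - 2L))
  }
  bad <- rowSums(is.na(f)) > 0
  sd_raw[bad] <- NA_real_
  fl <- stats::quantile(sd_raw, floor_quantile, na.rm = TRUE, names = FALSE)
  floored <- pmax(sd_raw, fl)
  sd_sm <- rep(NA_real_, length(sd_raw))
  for (ch in unique(sm$chrom)) {
    idx <- which(sm$chrom == ch & !bad)
    if (length(idx)) sd_sm[idx] <- running_mean(floored[idx], run_mean_window)
  }
  # the mean of floored values cannot drop below the floor; re-applying it
  # removes ~1e-15 cumsum round-off so the floor invariant holds exactly
  sd_sm <- pmax(sd_sm, fl)
  tibble::tibble(chrom = sm$chrom, pos = sm$pos,
                 sd_raw = sd_raw, sd = sd_sm)
}

#' Signal-to-noise t-statistic track
#'
#' Combines [group_stats()] and [local_sd()] into the per-CpG statistic
#' `t = beta / (sd * sqrt(1/n1 + 1/n2))`. Loci masked in either input, or
#' with `sd = 0`, carry `NA`.
#'
#' @inheritParams local_sd
#' @param ... Passed to [local_sd()] (`floor_quantile`, `run_mean_window`,
#'   `normal_only`).
#' @return A tibble of class `tstat_track` with columns `chrom`, `pos`,
#'   `alpha`, `beta`, `sd_raw`, `sd`, `t`, and the design stored as an
#'   attribute.
#' @export
tstat <- function(sm, design, ...) {
  gs <- group_stats(sm, design)
  sd_tab <- local_sd(sm, design, ...)
  scale <- sqrt(1 / design$n1 + 1 / design$n2)
  t <- gs$beta / (sd_tab$sd * scale)
  t[!is.finite(t)] <- NA_real_
  out <- dplyr::bind_cols(gs, sd_tab[, c("sd_raw", "sd")])
  out$t <- t
  attr(out, "design") <- design
  class(out) <- c("tstat_track", class(tibble::tibble()))
  out
}

#' DMR calling parameters
#'
#' @param cutoff Fixed positive cutoff `c` on `t`; if `NULL` it is derived
#'   from `cutoff_quantile`.
#' @param cutoff_quantile Tail mass `q`: the lower/upper cutoffs are the
#'   `q` and `1 - q` quantiles of the empirical `t` distribution.
#' @param maxgap Maximum gap in bp between consecutive member CpGs
#'   (default 300).
#' @param min_cpgs Minimum member CpGs per region (default 3).
#' @param min_mean_beta Minimum |mean beta| per region (default 0.1).
#' @param min_width Minimum region width in bp (default 0; used by the
#'   block caller).
#' @return List of class `dmr_params`.
#' @export
dmr_params <- function(cutoff = NULL, cutoff_quantile = 0.025,
                       maxgap = 300L, min_cpgs = 3L, min_mean_beta = 0.1,
                       min_width = 0L) {
  stopifnot(is.null(cutoff) || cutoff > 0, maxgap > 0)
  structure(list(cutoff = cutoff, cutoff_quantile = cutoff_quantile,
                 maxgap = as.integer(maxgap), min_cpgs = as.integer(min_cpgs),
                 min_mean_beta = min_mean_beta, min_width = as.integer(min_width)),
            class = "dmr_params")
}

#' Call differentially methylated regions from a t-statistic track
#'
#' DMRs are maximal runs of consecutive CpGs whose statistics all exceed
#' the upper cutoff (`hyper`) or all fall below the lower cutoff (`hypo`;
#' strict inequalities), split wherever consecutive member CpGs are more
#' than `maxgap` bp apart — which also enforces "at least one CpG every
#' `maxgap` bp" inside every region. Runs are then filtered by member
#' count, |mean beta| and width, and sorted by decreasing area
#' (sum of |t| over members).
#'
#' @param track A [tstat()] track (masked loci are excluded; if a
#'   `t_corrected` column is present, e.g. from [correct_tstat()], it is
#'   used instead of `t`).
#' @param params A [dmr_params] object.
#' @return A tibble of class `region_calls` with columns `chrom`, `start`,
#'   `end`, `n_cpgs`, `mean_beta`, `area`, `direction`, `mean_meth_g0`,
#'   `mean_meth_g1`.
#' @export
call_dmrs <- function(track, params = dmr_params()) {
  tcol <- if ("t_corrected" %in% names(track)) "t_corrected" else "t"
  des <- attr(track, "design")
  # overall mean alpha splits into group means via the group sizes
  w0 <- if (is.null(des)) 0.5 else des$n2 / (des$n1 + des$n2)
  w1 <- 1 - w0
  d <- track[!is.na(track[[tcol]]), c("chrom", "pos", "alpha", "beta")]
  d$t <- track[[tcol]][!is.na(track[[tcol]])]
  if (is.null(params$cutoff)) {
    cuts <- stats::quantile(d$t, c(params$cutoff_quantile,
                                   1 - params$cutoff_quantile), names = FALSE)
  } else {
    cuts <- c(-params$cutoff, params$cutoff)
  }
  state <- ifelse(d$t > cuts[2], 1L, ifelse(d$t < cuts[1], -1L, 0L))
  new_chrom <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)])
  big_gap <- c(TRUE, diff(d$pos) > params$maxgap) | new_chrom
  run_id <- cumsum(big_gap | c(TRUE, diff(state) != 0))
  d$run <- run_id; d$state <- state
  if (!any(state != 0L)) {
    regs <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer(), n_cpgs = integer(),
                           mean_beta = numeric(), area = numeric(),
                           direction = character(),
                           mean_meth_g0 = numeric(),
                           mean_meth_g1 = numeric())
    attr(regs, "cutoffs") <- cuts
    class(regs) <- c("region_calls", class(tibble::tibble()))
    return(regs)
  }
  regs <- d |>
    dplyr::filter(.data$state != 0L) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = .data$chrom[1], start = min(.data$pos), end = max(.data$pos),
      n_cpgs = dplyr::n(), mean_beta = mean(.data$beta),
      area = sum(abs(.data$t)),
      direction = if (.data$state[1] > 0) "hyper" else "hypo",
      mean_meth_g0 = mean(.data$alpha - .data$beta * w0),
      mean_meth_g1 = mean(.data$alpha + .data$beta * w1),
      .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= params$min_cpgs,
                  abs(.data$mean_beta) >= params$min_mean_beta,
                  .data$end - .data$start + 1L >= params$min_width) |>
    dplyr::arrange(dplyr::desc(.data$area)) |>
    dplyr::select(-"run")
  attr(regs, "cutoffs") <- cuts
  class(regs) <- c("region_calls", class(tibble::tibble()))
  regs
}

#' Remove the slowly varying component of a t-statistic track
#'
#' For cancer/normal comparisons the group difference decomposes into a
#' slowly varying block component and sharp small-DMR components, and so
#' does the statistic: `t = t1 + t2`. The slow component `t2` is estimated
#' by linearly interpolating `t` onto a `grid_bp` grid, smoothing the grid
#' values with a robust local regression (tricube weights, degree 2,
#' biweight robustness iterations) over `window_bp` windows, and evaluating
#' the smooth back at the CpG positions. Small DMRs are then called on the
#' corrected statistic `t - t2`.
#'
#' @param track A [tstat()] track.
#' @param grid_bp Grid spacing in bp (default 2000).
#' @param window_bp Smoothing window in bp (default 50000).
#' @return The track with added columns `t_slow` (the estimate of `t2`)
#'   and `t_corrected = t - t_slow`.
#' @export
correct_tstat <- function(track, grid_bp = 2000L, window_bp = 50000L) {
  t_slow <- rep(NA_real_, nrow(track))
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch & !is.na(track$t))
    if (length(idx) == 0L) next
    pos <- track$pos[idx]; t <- track$t[idx]
    span_bp <- diff(range(pos))
    if (length(idx) < 2L || span_bp < grid_bp) {
      t_slow[idx] <- mean(t)
      message("chromosome ", ch, " shorter than one grid step; ",
              "using mean t as slow component")
      next
    }
    grid <- seq(min(pos), max(pos), by = grid_bp)
    tg <- stats::approx(pos, t, xout = grid, ties = mean)$y
    npts <- window_bp / grid_bp
    if (length(grid) <= npts) {
      # window covers the whole chromosome: a single robust quadratic fit
      fit <- stats::lm(tg ~ grid + I(grid^2))
      sm_grid <- stats::fitted(fit)
    } else {
      span <- min(1, npts / length(grid))
      # near-singular local fits at the grid ends fall back to a
      # pseudoinverse inside loess; harmless for a smooth trend estimate
      fit <- withCallingHandlers(
        stats::loess(tg ~ grid, span = span, degree = 2,
                     family = "symmetric",
                     control = stats::loess.control(surface = "direct")),
        warning = function(w) {
          # loess emits a cascade of near-singularity notes on flat or
          # constant stretches; the pseudoinverse trend fit is still what
          # we want there
          invokeRestart("muffleWarning")
        })
      sm_grid <- stats::fitted(fit)
    }
    t_slow[idx] <- stats::approx(grid, sm_grid, xout = pos, rule = 2)$y
  }
  track$t_slow <- t_slow
  track$t_corrected <- track$t - t_slow
  track
}

#' Call large hypomethylated blocks
#'
#' The small-DMR pipeline run with wide-window smoothing (500 CpGs /
#' 40 kb), a relaxed grouping gap suited to CpG-sparse regions, and —
#' when `normal_only = TRUE` — a variance estimate from the group-0
#' (normal) samples only.
#'
#' @param ds A [meth_data] object.
#' @param design A [group_design()].
#' @param smooth_p Block-mode smoothing parameters.
#' @param params Block-mode DMR parameters (default: `maxgap` 10 kb,
#'   minimum width 10 kb).
#' @param normal_only Estimate the SD from group-0 samples only.
#' @param ... Passed to [local_sd()] via [tstat()].
#' @return A `region_calls` tibble (see [call_dmrs()]).
#' @export
call_blocks <- function(ds, design, smooth_p = block_smooth_params(),
                        params = dmr_params(maxgap = 10000L,
                                            min_width = 10000L),
                        normal_only = FALSE, ...) {
  sm <- smooth_profile(ds, smooth_p)
  tr <- tstat(sm, design, normal_only = normal_only, ...)
  call_dmrs(tr, params)
}
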