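#' Per-region, per-sample mean methylation over high-coverage CpGs
#'
#' Averages the raw proportion M/N over the member CpGs of each region that
#' reach `min_cov` coverage in a sample — the summary used to turn a
#' high-coverage capture panel into gold-standard regional measurements.
#'
#' @param ds A [meth_data] object.
#' @param regions Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   non-overlapping within the set.
#' @param min_cov High-coverage threshold (default 30).
#' @return Long tibble: `region_id`, `chrom`, `start`, `end`, `sample`,
#'   `n_high_cov` (CpGs used), `mean_meth` (`NA` if none).
#' @export
region_mean_methylation <- function(ds, regions, min_cov = 30L) {
  s <- meth_samples(ds)
  cnt <- meth_counts(ds)
  prop <- cnt$M / cnt$N  # NaN at zero coverage; masked below
  purrr::map_dfr(seq_len(nrow(regions)), function(r) {
    inreg <- ds$chrom == regions$chrom[r] & ds$pos >= regions$start[r] &
      ds$pos <= regions$end[r]
    purrr::map_dfr(seq_along(s), function(k) {
      use <- inreg & cnt$N[, k] >= min_cov
      tibble::tibble(region_id = r, chrom = regions$chrom[r],
                     start = regions$start[r], end = regions$end[r],
                     sample = s[k], n_high_cov = sum(use),
                     mean_meth = if (any(use)) mean(prop[use, k]) else NA_real_)
    })
  })
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' two-sided. With both groups constant and equal means the statistic is
#' undefined; by convention `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors (>= 2 values each; a warning is issued below
#'   3 per group, where the test is fragile).
#' @return A list with `statistic`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (length(x) < 3L || length(y) < 3L) {
    warning("fewer than 3 samples in a group; Welch test is fragile")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(statistic = sign(mean(y) - mean(x)) * Inf, df = NA_real_,
                p = 0, degenerate = TRUE))
  }
  # orientation: group 1 minus group 0, consistent with beta
  tt <- stats::t.test(y, x, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Build a gold standard from high-coverage regional measurements
#'
#' Labels regions as positive / negative using one of two definitions.
#' `mean_diff`: regions with at least `min_cpgs_per_sample` high-coverage
#' CpGs in at least `min_samples_per_group` samples of each group are
#' eligible; the group difference of (per-sample then across-sample)
#' averages labels positives (`|delta| > pos_threshold`, direction
#' recorded) and negatives (`|delta| < neg_threshold`). `welch`: regions
#' with at least `welch_min_cpgs` high-coverage CpGs in *all* samples are
#' eligible; a Welch t-test on the per-sample means labels positives
#' (`p < welch_pos_p`) and negatives (`p > welch_neg_p`). Mid-zone regions
#' stay unlabeled (`NA`).
#'
#' @param ds A [meth_data] object (e.g. a capture experiment).
#' @param regions Candidate regions (`chrom`, `start`, `end`).
#' @param design A [group_design()].
#' @param mode `"mean_diff"` or `"welch"`.
#' @param min_cov High-coverage CpG threshold (default 30).
#' @param pos_threshold,neg_threshold Mean-difference thresholds
#'   (defaults 0.25 / 0.03).
#' @param min_cpgs_per_sample,min_samples_per_group Eligibility for
#'   `mean_diff` (defaults 5 / 2).
#' @param welch_min_cpgs Eligibility for `welch` (default 4, in every
#'   sample).
#' @param welch_pos_p,welch_neg_p Welch p-value thresholds
#'   (defaults 0.01 / 0.25).
#' @return Tibble of class `gold_standard`: `chrom`, `start`, `end`,
#'   `eligible`, `delta`, `p` (welch mode), `label`
#'   (`"positive"`/`"negative"`/`NA`), `direction`.
#' @export
build_gold_standard <- function(ds, regions, design,
                                mode = c("mean_diff", "welch"),
                                min_cov = 30L,
                                pos_threshold = 0.25, neg_threshold = 0.03,
                                min_cpgs_per_sample = 5L,
                                min_samples_per_group = 2L,
                                welch_min_cpgs = 4L,
                                welch_pos_p = 0.01, welch_neg_p = 0.25) {
  mode <- match.arg(mode)
  rm_tab <- region_mean_methylation(ds, regions, min_cov = min_cov)
  g1 <- design$labels == 1L
  s <- meth_samples(ds)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
    sub <- rm_tab[rm_tab$region_id == r, ]
    sub <- sub[match(s, sub$sample), ]
    res <- tibble::tibble(chrom = regions$chrom[r], start = regions$start[r],
                          end = regions$end[r], eligible = FALSE,
                          delta = NA_real_, p = NA_real_,
                          label = NA_character_, direction = NA_character_)
    if (mode == "mean_diff") {
      ok0 <- sub$n_high_cov[!g1] >= min_cpgs_per_sample
      ok1 <- sub$n_high_cov[g1] >= min_cpgs_per_sample
      if (sum(ok0) < min_samples_per_group ||
          sum(ok1) < min_samples_per_group) return(res)
      res$eligible <- TRUE
      m0 <- mean(sub$mean_meth[!g1][ok0]); m1 <- mean(sub$mean_meth[g1][ok1])
      res$delta <- m1 - m0
      if (abs(res$delta) > pos_threshold) {
        res$label <- "positive"
        res$direction <- if (res$delta > 0) "hyper" else "hypo"
      } else if (abs(res$delta) < neg_threshold) {
        res$label <- "negative"
      }
    } else {
      if (any(sub$n_high_cov < welch_min_cpgs)) return(res)
      res$eligible <- TRUE
      x <- sub$mean_meth[!g1]; y <- sub$mean_meth[g1]
      wt <- welch_t(x, y)
      res$delta <- mean(y) - mean(x)
      res$p <- wt$p
      if (wt$p < welch_pos_p) {
        res$label <- "positive"
        res$direction <- if (res$delta > 0) "hyper" else "hypo"
      } else if (wt$p > welch_neg_p) {
        res$label <- "negative"
      }
    }
    res
  })
  class(out) <- c("gold_standard", class(tibble::tibble()))
  out
}

# fraction of each gold region covered by any one call, plus direction match;
# returns, per gold region, the best (lowest) rank of a hitting call
gold_hit_ranks <- function(calls, gold, min_overlap_frac, match_direction) {
  vapply(seq_len(nrow(gold)), function(g) {
    cand <- which(calls$chrom == gold$chrom[g])
    if (!length(cand)) return(NA_real_)
    ov <- interval_overlap(calls$start[cand], calls$end[cand],
                           gold$start[g], gold$end[g])
    frac <- ov / (gold$end[g] - gold$start[g] + 1)
    hit <- frac > min_overlap_frac
    if (match_direction && !is.na(gold$direction[g])) {
      hit <- hit & calls$direction[cand] == gold$direction[g]
    }
    if (!any(hit)) return(NA_real_)
    min(cand[hit])
  }, numeric(1))
}

#' ROC points for ranked region calls against a gold standard
#'
#' Walks down the ranked call list (equivalently, relaxes the statistic
#' cutoff); at each list size `k` the true positive rate is the fraction
#' of gold positives overlapped by more than `min_overlap_frac` of *their
#' own* length by a call of matching direction, and the false positive
#' rate is the fraction of gold negatives so overlapped (no direction
#' requirement — negatives have none).
#'
#' @param calls A `region_calls` tibble ranked by decreasing area (as
#'   produced by the callers), or any region tibble sorted best-first.
#' @param gold A [build_gold_standard()] result.
#' @param min_overlap_frac Overlap fraction threshold (default 0.5).
#' @return Tibble with `k`, `tp`, `fp`, `tpr`, `fpr`, one row per list
#'   size 0..n; `tpr` and `fpr` are non-decreasing in `k`.
#' @export
roc_points <- function(calls, gold, min_overlap_frac = 0.5) {
  pos <- gold[!is.na(gold$label) & gold$label == "positive", ]
  neg <- gold[!is.na(gold$label) & gold$label == "negative", ]
  n_call <- nrow(calls)
  pos_rank <- gold_hit_ranks(calls, pos, min_overlap_frac, TRUE)
  neg_rank <- gold_hit_ranks(calls, neg, min_overlap_frac, FALSE)
  k <- 0:n_call
  tp <- vapply(k, function(kk) sum(!is.na(pos_rank) & pos_rank <= kk),
               numeric(1))
  fp <- vapply(k, function(kk) sum(!is.na(neg_rank) & neg_rank <= kk),
               numeric(1))
  tibble::tibble(k = k, tp = tp, fp = fp,
                 tpr = if (nrow(pos)) tp / nrow(pos) else NA_real_,
                 fpr = if (nrow(neg)) fp / nrow(neg) else NA_real_)
}

#' @rdname roc_points
#' @param roc A [roc_points()] result.
#' @param fpr Target false positive rate.
#' @return `tpr_at_fpr()`: the highest TPR attained at FPR <= `fpr`.
#' @export
tpr_at_fpr <- function(roc, fpr = 0.05) {
  ok <- roc$fpr <= fpr
  if (!any(ok)) return(0)
  max(roc$tpr[ok])
}

#' TSS-proximity log2 odds ratio of region calls
#'
#' For each list size `k`, cross-tabulates labeled transcription start
#' sites (differentially expressed vs not) against having a top-`k` call
#' within `window` bp, and returns the log2 odds ratio (Haldane 0.5
#' correction when any cell is zero). Distance is the minimal bp distance
#' from the region interval to the TSS point; within `window` is
#' inclusive.
#'
#' @param calls A ranked `region_calls` tibble.
#' @param tss Tibble with `chrom`, `pos`, `de` (logical: differentially
#'   expressed; `NA` = unlabeled, excluded).
#' @param window Proximity window in bp (default 5000).
#' @param k_grid List sizes to evaluate (default: 10 steps up to the
#'   number of calls).
#' @return Tibble with `k`, `de_hit`, `de_miss`, `nonde_hit`,
#'   `nonde_miss`, `log2_or`.
#' @export
tss_log2_odds <- function(calls, tss, window = 5000L, k_grid = NULL) {
  tss <- tss[!is.na(tss$de), ]
  if (all(tss$de) || !any(tss$de)) {
    stop("TSS set must contain both DE and non-DE genes")
  }
  if (is.null(k_grid)) {
    k_grid <- unique(pmax(1L, round(seq_len(10) / 10 * nrow(calls))))
  }
  # best (lowest) call rank within `window` of each TSS
  best_rank <- vapply(seq_len(nrow(tss)), function(i) {
    cand <- which(calls$chrom == tss$chrom[i])
    if (!length(cand)) return(NA_real_)
    d <- pmax(0, pmax(calls$start[cand] - tss$pos[i],
                      tss$pos[i] - calls$end[cand]))
    near <- d <= window
    if (!any(near)) return(NA_real_)
    min(cand[near])
  }, numeric(1))
  purrr::map_dfr(k_grid, function(kk) {
    hit <- !is.na(best_rank) & best_rank <= kk
    a <- sum(hit & tss$de); b <- sum(!hit & tss$de)
    c_ <- sum(hit & !tss$de); d <- sum(!hit & !tss$de)
    if (any(c(a, b, c_, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    tibble::tibble(k = kk, de_hit = sum(hit & tss$de),
                   de_miss = sum(!hit & tss$de),
                   nonde_hit = sum(hit & !tss$de),
                   nonde_miss = sum(!hit & !tss$de),
                   log2_or = log2((a * d) / (b * c_)))
  })
}
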