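#' Pool counts within groups
#'
#' Sums methylated and unmethylated counts over the samples of each group,
#' giving the per-locus 2x2 table that the Fisher baseline tests. Pooling
#' discards biological replication: the exact test then accounts for read
#' sampling variability only.
#'
#' @param ds A [meth_data] object.
#' @param design A [group_design()].
#' @return Tibble with `chrom`, `pos`, `M1`, `U1` (group 0), `M2`, `U2`
#'   (group 1), and `testable` (both row sums positive).
#' @export
pool_counts <- function(ds, design) {
  cnt <- meth_counts(ds)
  g1 <- design$labels == 1L
  out <- tibble::tibble(
    chrom = ds$chrom, pos = ds$pos,
    M1 = as.integer(rowSums(cnt$M[, !g1, drop = FALSE])),
    U1 = as.integer(rowSums(cnt$U[, !g1, drop = FALSE])),
    M2 = as.integer(rowSums(cnt$M[, g1, drop = FALSE])),
    U2 = as.integer(rowSums(cnt$U[, g1, drop = FALSE])))
  out$testable <- (out$M1 + out$U1) > 0L & (out$M2 + out$U2) > 0L
  out
}

#' Two-sided Fisher's exact test for 2x2 count tables
#'
#' Exact two-sided p-value by hypergeometric enumeration: conditioning on
#' the table margins, the p-value is the sum of the probabilities of all
#' outcomes no more probable than the observed one (with the conventional
#' relative tolerance `1 + 1e-7` for ties). Vectorised over loci.
#'
#' @param M1,U1,M2,U2 Integer vectors: methylated/unmethylated counts of
#'   group 0 and group 1.
#' @return Numeric vector of p-values; `NA` where a group has zero total
#'   (untestable).
#' @export
fisher_exact <- function(M1, U1, M2, U2) {
  n <- length(M1)
  stopifnot(length(U1) == n, length(M2) == n, length(U2) == n)
  p <- rep(NA_real_, n)
  r1 <- M1 + U1; r2 <- M2 + U2
  mw <- M1 + M2; nb <- U1 + U2
  ok <- r1 > 0L & r2 > 0L
  for (i in which(ok)) {
    lo <- max(0L, mw[i] - r2[i]); hi <- min(mw[i], r1[i])
    supp <- lo:hi
    d <- stats::dhyper(supp, mw[i], nb[i], r1[i])
    dobs <- stats::dhyper(M1[i], mw[i], nb[i], r1[i])
    p[i] <- min(1, sum(d[d <= dobs * (1 + 1e-7)]))
  }
  p
}

#' Fisher-baseline region parameters
#'
#' The single-CpG test feeds a region finder whose output constraints are:
#' regions at least `min_region_len` bp long, containing at least
#' `min_dm_cpgs` differentially methylated (DM) CpGs, with every
#' `subregion_len` bp window fully inside the region containing at least
#' `min_dm_per_subregion` DM CpGs.
#'
#' @param p_adjust Multiple-testing adjustment for the per-CpG rule
#'   (`"BH"` or `"none"`).
#' @param p_threshold Significance threshold on the (adjusted) p-value.
#' @param min_region_len Minimum region length in bp.
#' @param min_dm_cpgs Minimum DM CpGs per region.
#' @param subregion_len Subregion window length in bp.
#' @param min_dm_per_subregion Minimum DM CpGs per subregion window.
#' @return List of class `fisher_params`.
#' @export
fisher_params <- function(p_adjust = c("BH", "none"), p_threshold = 0.05,
                          min_region_len = 2000L, min_dm_cpgs = 10L,
                          subregion_len = 1000L, min_dm_per_subregion = 4L) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(min_region_len > 0, min_dm_cpgs > 0, subregion_len > 0,
            min_dm_per_subregion > 0, subregion_len <= min_region_len)
  structure(list(p_adjust = p_adjust, p_threshold = p_threshold,
                 min_region_len = as.integer(min_region_len),
                 min_dm_cpgs = as.integer(min_dm_cpgs),
                 subregion_len = as.integer(subregion_len),
                 min_dm_per_subregion = as.integer(min_dm_per_subregion)),
            class = "fisher_params")
}

# TRUE iff every window of length L fully inside [s, e] holds >= k of the
# sorted positions dm (themselves inside [s, e]).
subregion_ok <- function(dm, s, e, L, k) {
  if (e - s + 1 < L) return(TRUE)  # no window fits; nothing to violate
  xs <- sort(unique(c(s, e - L, dm + 1, dm - L)))
  xs <- xs[xs >= s & xs <= e - L]
  for (x in xs) {
    cnt <- sum(dm >= x & dm <= x + L)
    if (cnt < k) return(FALSE)
  }
  TRUE
}

fisher_region_valid <- function(dm, i, j, fp) {
  (dm[j] - dm[i] + 1L >= fp$min_region_len) &&
    (j - i + 1L >= fp$min_dm_cpgs) &&
    subregion_ok(dm[i:j], dm[i], dm[j], fp$subregion_len,
                 fp$min_dm_per_subregion)
}

#' Call DMRs with the Fisher's-exact-test baseline
#'
#' Pools counts within groups, tests each covered CpG with
#' [fisher_exact()], flags DM CpGs by the (adjusted) p-value rule, and
#' reports every *maximal* region whose endpoints are DM CpGs and which
#' satisfies all three constraints in [fisher_params()]; maximal means the
#' region cannot be extended by one DM CpG on either side and still pass.
#' Deterministic; regions are ranked by decreasing area
#' (sum of -log10 p over member DM CpGs).
#'
#' @param ds A [meth_data] object.
#' @param design A [group_design()].
#' @param fp A [fisher_params] object.
#' @return A `region_calls` tibble with added columns `n_dm_cpgs` and
#'   `min_subregion_dm`.
#' @export
call_fisher_dmrs <- function(ds, design, fp = fisher_params()) {
  pooled <- pool_counts(ds, design)
  pooled$p <- fisher_exact(pooled$M1, pooled$U1, pooled$M2, pooled$U2)
  padj <- pooled$p
  if (fp$p_adjust == "BH") {
    padj[pooled$testable] <- stats::p.adjust(pooled$p[pooled$testable], "BH")
  }
  pooled$dm <- !is.na(padj) & padj < fp$p_threshold
  pooled$delta <- with(pooled, M2 / (M2 + U2) - M1 / (M1 + U1))

  regions <- list()
  for (ch in unique(pooled$chrom)) {
    sub <- pooled[pooled$chrom == ch & pooled$dm, ]
    if (nrow(sub) < fp$min_dm_cpgs) next
    dmp <- sub$pos
    # a valid region cannot span a DM gap wider than the subregion window
    # (that window would hold at most one DM CpG), so split into
    # components first; only safe when >= 2 DM CpGs per window are required
    if (fp$min_dm_per_subregion >= 2L) {
      comp <- cumsum(c(TRUE, diff(dmp) > fp$subregion_len))
    } else {
      comp <- rep(1L, length(dmp))
    }
    for (cid in unique(comp)) {
      ii <- which(comp == cid)
      m <- length(ii)
      if (m < fp$min_dm_cpgs) next
      p_local <- dmp[ii]
      valid <- function(i, j) fisher_region_valid(p_local, i, j, fp)
      for (i in seq_len(m - fp$min_dm_cpgs + 1L)) {
        for (j in seq(i + fp$min_dm_cpgs - 1L, m)) {
          if (!valid(i, j)) next
          if ((i == 1L || !valid(i - 1L, j)) &&
              (j == m || !valid(i, j + 1L))) {
            regions[[length(regions) + 1L]] <-
              list(chrom = ch, start = p_local[i], end = p_local[j])
          }
        }
      }
    }
  }
  if (length(regions) == 0L) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_cpgs = integer(),
                          mean_beta = numeric(), area = numeric(),
                          direction = character(), n_dm_cpgs = integer(),
                          min_subregion_dm = integer())
    class(out) <- c("region_calls", class(tibble::tibble()))
    return(out)
  }
  out <- purrr::map_dfr(regions, function(r) {
    inreg <- pooled$chrom == r$chrom & pooled$pos >= r$start &
      pooled$pos <= r$end
    memb <- pooled[inreg, ]
    dmm <- memb[memb$dm, ]
    delta <- mean(memb$delta[memb$testable], na.rm = TRUE)
    tibble::tibble(
      chrom = r$chrom, start = r$start, end = r$end,
      n_cpgs = nrow(memb), mean_beta = delta,
      area = sum(-log10(pmax(dmm$p, 1e-300))),
      direction = if (delta >= 0) "hyper" else "hypo",
      n_dm_cpgs = nrow(dmm),
      min_subregion_dm = min_window_dm(dmm$pos, r$start, r$end,
                                       fp$subregion_len))
  })
  out <- dplyr::distinct(out) |> dplyr::arrange(dplyr::desc(.data$area))
  class(out) <- c("region_calls", class(tibble::tibble()))
  out
}

# minimum DM-CpG count over subregion windows fully inside [s, e]
min_window_dm <- function(dm, s, e, L) {
  if (e - s + 1 < L) return(length(dm))
  xs <- sort(unique(c(s, e - L, dm + 1, dm - L)))
  xs <- xs[xs >= s & xs <= e - L]
  min(vapply(xs, function(x) sum(dm >= x & dm <= x + L), integer(1)))
}
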