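# Independent brute-force oracles used to pin the semantics of the fast
# implementations. These deliberately share no code with the package
# internals beyond public accessors.

# small meth_data built from plain vectors/matrices
make_ds <- function(pos, M, U, chrom = "chr1", ids = NULL) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(M)))
  meth_data(rep(chrom, length(pos)), pos, M, U, ids)
}

# brute-force coverage filter: row-by-row loop over loci
bf_filter_coverage <- function(N, min_cov, min_samples) {
  keep <- logical(nrow(N))
  for (i in seq_len(nrow(N))) {
    keep[i] <- sum(N[i, ] >= min_cov) >= min_samples
  }
  keep
}

# brute-force window selection: scan candidate half-widths upward
bf_select_window <- function(pos, j, min_cpgs, min_width) {
  cand <- sort(unique(c(min_width / 2, abs(pos - pos[j]))))
  cand <- cand[cand >= min_width / 2]
  for (h in cand) {
    if (sum(pos >= pos[j] - h & pos <= pos[j] + h) >= min(min_cpgs, length(pos))) {
      return(h)
    }
  }
  max(cand)
}

# brute-force local likelihood maximizer: direct optimization of the
# tricube-weighted binomial log-likelihood over polynomial coefficients
bf_local_fit <- function(pos, M, U, center, h, degree = 2) {
  N <- M + U
  w <- (1 - pmin(1, abs((pos - center) / h))^3)^3
  keep <- w > 0 & N > 0
  pos <- pos[keep]; M <- M[keep]; N <- N[keep]; w <- w[keep]
  z <- (pos - center) / 1000
  Xr <- cbind(1, z, z^2)[, seq_len(degree + 1), drop = FALSE]
  # optimize in an orthonormal basis (well-conditioned even for tiny,
  # unbalanced windows); the fitted value at the center is basis-free
  qrX <- qr(Xr)
  X <- qr.Q(qrX)
  center_row <- drop(c(1, rep(0, degree)) %*% solve(qr.R(qrX)))
  negll <- function(b) {
    eta <- pmin(30, pmax(-30, drop(X %*% b)))
    mu <- plogis(eta)
    -sum(w * (M * log(mu) + (N - M) * log1p(-mu)))
  }
  grad <- function(b) {
    eta <- pmin(30, pmax(-30, drop(X %*% b)))
    mu <- plogis(eta)
    -drop(crossprod(X, w * (M - N * mu)))
  }
  eta0 <- qlogis(min(1 - 1e-6, max(1e-6, sum(w * M) / sum(w * N))))
  b0 <- drop(crossprod(X, rep(eta0, length(z)))) / colSums(X^2)
  o1 <- optim(b0, negll, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-15))
  o2 <- nlminb(o1$par, negll, gradient = grad,
               control = list(rel.tol = 1e-15, abs.tol = 0, iter.max = 1e4))
  eta_c <- sum(center_row * o2$par)
  plogis(min(8, max(-8, eta_c)))
}

# brute-force floor + centered running mean (window shrinks at the ends)
bf_floor_runmean <- function(sd_raw, floor_q, k) {
  fl <- quantile(sd_raw, floor_q, names = FALSE)
  x <- pmax(sd_raw, fl)
  n <- length(x)
  out <- numeric(n)
  hw <- (k - 1) / 2
  for (i in seq_len(n)) {
    idx <- max(1, i - hw):min(n, i + hw)
    out[i] <- mean(x[idx])
  }
  out
}

# exhaustive enumeration of maximal same-sign super-threshold runs with the
# gap-split rule, then the count/mean-beta filters
bf_call_dmrs <- function(pos, t, beta, cut_lo, cut_hi, maxgap, min_cpgs,
                         min_mean_beta) {
  n <- length(pos)
  state <- ifelse(t > cut_hi, 1L, ifelse(t < cut_lo, -1L, 0L))
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (state[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == state[i] &&
           pos[j + 1L] - pos[j] <= maxgap) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  out <- NULL
  for (r in runs) {
    idx <- r[1]:r[2]
    if (length(idx) < min_cpgs) next
    mb <- mean(beta[idx])
    if (abs(mb) < min_mean_beta) next
    out <- rbind(out, data.frame(start = pos[r[1]], end = pos[r[2]],
                                 n_cpgs = length(idx), mean_beta = mb,
                                 area = sum(abs(t[idx])),
                                 direction = if (state[r[1]] > 0) "hyper" else "hypo"))
  }
  out
}

# exhaustive two-sided Fisher p by direct outcome enumeration
bf_fisher_p <- function(M1, U1, M2, U2) {
  r1 <- M1 + U1; r2 <- M2 + U2; cm <- M1 + M2; cu <- U1 + U2
  if (r1 == 0 || r2 == 0) return(NA_real_)
  supp <- max(0, cm - r2):min(cm, r1)
  probs <- vapply(supp, function(x) {
    choose(cm, x) * choose(cu, r1 - x) / choose(cm + cu, r1)
  }, numeric(1))
  pobs <- probs[match(M1, supp)]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# slow validity check of a Fisher-baseline candidate region: every 1 kb
# (subregion_len) window fully inside, slid at 1 bp resolution
bf_fisher_valid <- function(dm, s, e, min_len, min_dm, sub_len, sub_min) {
  inside <- dm[dm >= s & dm <= e]
  if (e - s + 1 < min_len) return(FALSE)
  if (length(inside) < min_dm) return(FALSE)
  if (e - s + 1 >= sub_len) {
    for (x in s:(e - sub_len)) {
      if (sum(inside >= x & inside <= x + sub_len) < sub_min) return(FALSE)
    }
  }
  TRUE
}

# exhaustive Fisher-baseline region finder over all DM CpG index pairs
bf_fisher_regions <- function(dm_pos, min_len = 2000, min_dm = 10,
                              sub_len = 1000, sub_min = 4) {
  m <- length(dm_pos)
  valid <- function(i, j) {
    i >= 1 && j <= m &&
      bf_fisher_valid(dm_pos, dm_pos[i], dm_pos[j], min_len, min_dm,
                      sub_len, sub_min)
  }
  out <- NULL
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j < i) next
      if (!valid(i, j)) next
      if (!valid(i - 1, j) && !valid(i, j + 1)) {
        out <- rbind(out, data.frame(start = dm_pos[i], end = dm_pos[j]))
      }
    }
  }
  unique(out)
}

# Welch statistic from the textbook formulas
bf_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force overlap counting for ROC points
bf_roc_hit <- function(calls, gold_region, frac, need_dir) {
  if (nrow(calls) == 0) return(FALSE)
  for (i in seq_len(nrow(calls))) {
    if (calls$chrom[i] != gold_region$chrom) next
    ov <- min(calls$end[i], gold_region$end) -
      max(calls$start[i], gold_region$start) + 1
    if (ov / (gold_region$end - gold_region$start + 1) > frac) {
      if (!need_dir || calls$direction[i] == gold_region$direction) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# gold standard built directly from simulation truth: planted regions are
# positives; negatives are sampled unaffected intervals
truth_gold <- function(truth, n_neg = 100, width = 2000, seed = 99) {
  pos_reg <- truth$regions[truth$regions$type == "dmr", ]
  gold_pos <- tibble::tibble(chrom = pos_reg$chrom, start = pos_reg$start,
                             end = pos_reg$end, label = "positive",
                             direction = pos_reg$direction)
  loci <- truth$loci
  withr::with_seed(seed, {
    neg <- NULL
    tries <- 0
    while ((is.null(neg) || nrow(neg) < n_neg) && tries < n_neg * 50) {
      tries <- tries + 1
      s <- sample(loci$pos, 1)
      e <- s + width - 1
      memb <- loci$pos >= s & loci$pos <= e
      if (sum(memb) >= 3 && all(loci$beta[memb] == 0) &&
          !any(pmin(e, truth$regions$end) - pmax(s, truth$regions$start) > -5000)) {
        neg <- rbind(neg, data.frame(chrom = loci$chrom[1], start = s, end = e))
      }
    }
  })
  gold_neg <- tibble::tibble(chrom = neg$chrom, start = as.integer(neg$start),
                             end = as.integer(neg$end), label = "negative",
                             direction = NA_character_)
  dplyr::bind_rows(gold_pos, gold_neg)
}

# synthetic TSS layout coupled to planted DMRs: DE genes sit next to a
# planted DMR, non-DE genes sit in unaffected territory
truth_tss <- function(truth, n_nonde = 200, seed = 17) {
  dmr <- truth$regions[truth$regions$type == "dmr", ]
  de <- tibble::tibble(chrom = dmr$chrom,
                       pos = as.integer(dmr$start - 500), de = TRUE)
  loci <- truth$loci
  withr::with_seed(seed, {
    cand <- sample(loci$pos[loci$beta == 0], n_nonde * 3)
    far <- vapply(cand, function(p) {
      all(abs(p - (dmr$start + dmr$end) / 2) > 20000)
    }, logical(1))
    nonde <- tibble::tibble(chrom = loci$chrom[1],
                            pos = as.integer(head(cand[far], n_nonde)),
                            de = FALSE)
  })
  dplyr::bind_rows(de, nonde)
}

# fraction of a single truth region covered by each call
interval_overlap_frac <- function(calls, region) {
  if (nrow(calls) == 0) return(0)
  ov <- pmax(0, pmin(calls$end, region$end[1]) -
               pmax(calls$start, region$start[1]) + 1)
  ov / (region$end[1] - region$start[1] + 1)
}

# build a dataset whose DM calls are fully controlled: DM loci get extreme
# pooled counts, non-DM loci identical counts
dm_fixture <- function(pos, dm, depth = 30L) {
  n <- length(pos)
  M <- matrix(0L, n, 4); U <- matrix(0L, n, 4)
  M[, 1:2] <- depth; U[, 1:2] <- 0L          # group 0 fully methylated
  M[!dm, 3:4] <- depth; U[!dm, 3:4] <- 0L    # non-DM: same in group 1
  M[dm, 3:4] <- 0L; U[dm, 3:4] <- depth      # DM: opposite in group 1
  make_ds(pos, M, U, ids = c("a", "b", "c", "d"))
}
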