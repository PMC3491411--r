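# fabricate a meth_smooth object directly from an f matrix
make_sm <- function(pos, f, chrom = "chr1", ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(f)))
  out <- tibble::tibble(chrom = rep(chrom, length(pos)), pos = pos,
                        h = 1000)
  for (k in seq_along(ids)) out[[paste0("f_", ids[k])]] <- f[, k]
  attr(out, "samples") <- ids
  attr(out, "params") <- smooth_params()
  class(out) <- c("meth_smooth", class(tibble::tibble()))
  out
}

design22 <- group_design(c(0, 0, 1, 1))
design33 <- group_design(c(0, 0, 0, 1, 1, 1))

test_that("group means and differences follow hand arithmetic", {
  f <- rbind(c(0.2, 0.4, 0.7, 0.9))
  gs <- group_stats(make_sm(100L, f), design22)
  expect_equal(gs$alpha, 0.55)
  expect_equal(gs$beta, 0.5)

  # two identical groups: beta = 0
  f2 <- rbind(c(0.3, 0.6, 0.3, 0.6))
  expect_equal(group_stats(make_sm(100L, f2), design22)$beta, 0)

  # label swap negates beta, alpha unchanged
  gs_swap <- group_stats(make_sm(100L, f), group_design(c(1, 1, 0, 0)))
  expect_equal(gs_swap$beta, -0.5)
  expect_equal(gs_swap$alpha, 0.55)

  # invalid locus masked
  f3 <- rbind(c(0.2, NA, 0.7, 0.9), c(0.1, 0.2, 0.3, 0.4))
  gs3 <- group_stats(make_sm(c(100L, 200L), f3), design22)
  expect_true(is.na(gs3$alpha[1]) && is.na(gs3$beta[1]))
  expect_false(is.na(gs3$beta[2]))
})

test_that("pooled within-group SD matches the df = n1+n2-2 formula", {
  f <- rbind(c(0.2, 0.4, 0.6, 0.8))
  sd_tab <- local_sd(make_sm(100L, f), design22)
  expect_equal(sd_tab$sd_raw, sqrt((0.02 + 0.02) / 2))
})

test_that("flooring and running-mean match a brute-force oracle exactly", {
  withr::with_seed(61, {
    n <- 1000L
    f <- matrix(plogis(rnorm(4 * n, 1, 0.8)), n, 4)
  })
  sm <- make_sm(seq(100L, by = 100L, length.out = n), f)
  sd_tab <- local_sd(sm, design22)
  want <- bf_floor_runmean(sd_tab$sd_raw, 0.75, 101)
  expect_equal(sd_tab$sd, want)
  # floor property: smoothed SD never drops below the raw 75th percentile
  expect_gte(min(sd_tab$sd), quantile(sd_tab$sd_raw, 0.75, names = FALSE))
})

test_that("normal-only SD uses the reference group alone", {
  f <- rbind(c(0.2, 0.4, 0.9, 0.1))
  sd_tab <- local_sd(make_sm(100L, f), design22, normal_only = TRUE)
  expect_equal(sd_tab$sd_raw, sd(c(0.2, 0.4)))
  expect_error(local_sd(make_sm(100L, f), group_design(c(0, 1, 1, 1)),
                        normal_only = TRUE), "2 group-0")
})

test_that("t statistic follows its formula and masks degenerate loci", {
  # identical profiles: sd = 0, t masked
  f0 <- matrix(0.5, 3, 4)
  tr0 <- tstat(make_sm(c(100L, 200L, 300L), f0), design22)
  expect_true(all(is.na(tr0$t)))

  # hand arithmetic: beta 0.2, sd 0.1, n1 = n2 = 3
  withr::with_seed(62, f <- matrix(plogis(rnorm(30, 1, 1)), 5, 6))
  tr <- tstat(make_sm(seq(100L, 500L, by = 100L), f), design33)
  expect_equal(tr$t, tr$beta / (tr$sd * sqrt(1 / 3 + 1 / 3)))
  expect_equal(sign(tr$t), sign(tr$beta))
  expect_equal(0.2 / (0.1 * sqrt(2 / 3)), 2.449489742783178)

  # label swap negates the track
  tr_swap <- tstat(make_sm(seq(100L, 500L, by = 100L), f),
                   group_design(c(1, 1, 1, 0, 0, 0)))
  expect_equal(tr_swap$t, -tr$t)
})

make_track <- function(pos, t, beta = NULL, chrom = "chr1",
                       design = design33) {
  if (is.null(beta)) beta <- sign(t) * 0.3
  out <- tibble::tibble(chrom = rep(chrom, length(pos)), pos = pos,
                        alpha = 0.5, beta = beta, sd_raw = 0.1, sd = 0.1,
                        t = t)
  attr(out, "design") <- design
  class(out) <- c("tstat_track", class(tibble::tibble()))
  out
}

test_that("DMR grouping applies the cutoff, gap and filter rules", {
  # single run of 3 within the gap limit
  r1 <- call_dmrs(make_track(c(100L, 200L, 450L), c(3, 3, 3)),
                  dmr_params(cutoff = 2))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_cpgs, 3L)
  expect_equal(r1$start, 100L)
  expect_equal(r1$end, 450L)

  # 400 bp gap splits the run; both pieces fail min_cpgs
  r2 <- call_dmrs(make_track(c(100L, 200L, 600L), c(3, 3, 3)),
                  dmr_params(cutoff = 2))
  expect_equal(nrow(r2), 0L)

  # sign change breaks the run; the surviving run of 3 becomes one DMR
  r3 <- call_dmrs(make_track(seq(100L, 500L, by = 100L),
                             c(3, -3, 3, 3, 3)),
                  dmr_params(cutoff = 2))
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$start, 300L)
  expect_equal(r3$n_cpgs, 3L)
  expect_equal(r3$direction, "hyper")

  # ties at |t| = c are excluded (strict inequality)
  r4 <- call_dmrs(make_track(c(100L, 200L, 300L), c(2, 3, 3)),
                  dmr_params(cutoff = 2))
  expect_equal(nrow(r4), 0L)
})

test_that("DMR grouping equals exhaustive run enumeration on random tracks", {
  withr::with_seed(63, {
    for (rep in 1:15) {
      n <- sample(50:1000, 1)
      pos <- sort(sample.int(n * 150L, n))
      t <- rnorm(n, 0, 2) + rep(rnorm(ceiling(n / 20), 0, 2),
                                each = 20)[seq_len(n)]
      beta <- t * 0.08 + rnorm(n, 0, 0.02)
      tr <- make_track(pos, t, beta)
      p <- dmr_params(cutoff = 2.5, maxgap = 300, min_cpgs = 3,
                      min_mean_beta = 0.1)
      got <- call_dmrs(tr, p)
      want <- bf_call_dmrs(pos, t, beta, -2.5, 2.5, 300, 3, 0.1)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        got <- dplyr::arrange(tibble::as_tibble(got), start)
        want <- dplyr::arrange(tibble::as_tibble(want), start)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$n_cpgs, want$n_cpgs)
        expect_equal(got$mean_beta, want$mean_beta)
        expect_equal(got$area, want$area)
        expect_equal(got$direction, want$direction)
      }
    }
  })
})

test_that("antisymmetry: label swap maps hyper to hypo with identical bounds", {
  withr::with_seed(64, {
    n <- 600L
    pos <- sort(sample.int(80000L, n))
    f <- matrix(plogis(rnorm(6 * n, 1, 0.6)), n, 6)
  })
  sm <- make_sm(pos, f)
  p <- dmr_params(cutoff = 1.5, min_mean_beta = 0.05)
  a <- call_dmrs(tstat(sm, design33), p)
  b <- call_dmrs(tstat(sm, group_design(c(1, 1, 1, 0, 0, 0))), p)
  a <- dplyr::arrange(tibble::as_tibble(a), start)
  b <- dplyr::arrange(tibble::as_tibble(b), start)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$mean_beta, -b$mean_beta)
  expect_equal(a$direction, dplyr::recode(b$direction,
                                          hyper = "hypo", hypo = "hyper"))
})

test_that("slow-component correction preserves constants and sharp bumps", {
  pos <- seq(1000L, by = 400L, length.out = 1500L)

  # constant track corrects to (numerically) zero
  trc <- make_track(pos, rep(5, 1500L))
  cc <- correct_tstat(trc)
  expect_equal(max(abs(cc$t_corrected)), 0, tolerance = 1e-8)

  # slow sinusoid (200 kb period) + sharp 2 kb bump
  slow <- 3 * sin(2 * pi * pos / 200000)
  bump_idx <- pos >= 300000 & pos <= 302000
  t <- slow + ifelse(bump_idx, 4, 0)
  cc2 <- correct_tstat(make_track(pos, t))
  # sinusoid amplitude reduced by >= 80% away from the bump
  away <- !(pos >= 295000 & pos <= 307000)
  expect_lt(max(abs(cc2$t_corrected[away])), 0.2 * 3)
  # bump amplitude retained within 10%
  bump_height <- max(cc2$t_corrected[bump_idx]) -
    stats::median(cc2$t_corrected[away])
  expect_gt(bump_height, 0.9 * 4)
  expect_lt(bump_height, 1.1 * 4)

  # isolated outliers barely move the robust slow fit
  t3 <- slow
  out_idx <- c(300L, 700L, 1100L)
  t3[out_idx] <- t3[out_idx] + 25
  c_with <- correct_tstat(make_track(pos, t3))
  c_without <- correct_tstat(make_track(pos, slow))
  expect_lt(max(abs(c_with$t_slow[-out_idx] - c_without$t_slow[-out_idx])),
            0.1)
})

test_that("block caller finds a planted wide hypomethylated block", {
  cfg <- sim_config(n_cpgs = 6000L, n_dmrs = 0L, n_blocks = 1L,
                    block_width = c(180000L, 220000L), block_effect = -0.15,
                    background_spacing_mean = 120, seed = 31L)
  sim <- simulate_dataset(cfg)
  blocks <- call_blocks(sim$data, sim$design, normal_only = TRUE,
                        params = dmr_params(cutoff = 2, maxgap = 10000L,
                                            min_width = 10000L))
  tru <- sim$truth$regions[sim$truth$regions$type == "block", ]
  expect_gte(nrow(blocks), 1L)
  # a very long run may split on a brief sub-threshold dip, so recovery is
  # judged by the combined coverage of the truth by hypo block calls
  hypo <- blocks[blocks$direction == "hypo", ]
  ov <- sum(interval_overlap(hypo$start, hypo$end, tru$start[1], tru$end[1]))
  expect_gt(ov / (tru$end[1] - tru$start[1] + 1), 0.8)

  # small-DMR caller on the corrected track does not report the block
  sm <- smooth_profile(sim$data)
  tr <- correct_tstat(tstat(sm, sim$design, normal_only = TRUE))
  dmrs <- call_dmrs(tr, dmr_params(cutoff = 4))
  if (nrow(dmrs)) {
    covered <- sum(interval_overlap(dmrs$start, dmrs$end,
                                    tru$start[1], tru$end[1]))
    expect_lt(covered / (tru$end[1] - tru$start[1] + 1), 0.5)
  } else {
    succeed()
  }
})

test_that("a DMR planted inside a block is recovered on the corrected track", {
  cfg <- sim_config(n_cpgs = 6000L, n_dmrs = 0L, n_blocks = 1L,
                    block_width = c(180000L, 220000L), block_effect = -0.2,
                    background_spacing_mean = 120, seed = 33L)
  sim <- simulate_dataset(cfg)
  # plant a 1 kb DMR inside the block by editing the counts of group 1
  tru_b <- sim$truth$regions[1, ]
  s <- tru_b$start + floor((tru_b$end - tru_b$start) / 2)
  e <- s + 2000L
  memb <- which(sim$data$pos >= s & sim$data$pos <= e)
  skip_if(length(memb) < 4, "planted interval too sparse under this seed")
  ds <- sim$data
  for (id in c("g1_1", "g1_2", "g1_3")) {
    n_cov <- ds[[paste0("M_", id)]][memb] + ds[[paste0("U_", id)]][memb]
    ds[[paste0("M_", id)]][memb] <- n_cov  # drive the interior fully methylated
    ds[[paste0("U_", id)]][memb] <- 0L
  }
  sm <- smooth_profile(ds)
  tr <- correct_tstat(tstat(sm, sim$design, normal_only = TRUE))
  dmrs <- call_dmrs(tr, dmr_params(cutoff = 3, min_mean_beta = 0.05))
  hit <- any(dmrs$chrom == tru_b$chrom & dmrs$direction == "hyper" &
               interval_overlap(dmrs$start, dmrs$end, s, e) > 500)
  expect_true(hit)
})

test_that("biological variability does not shrink with coverage", {
  sd_at <- function(cov) {
    cfg <- sim_config(n_cpgs = 2500L, n_dmrs = 0L, coverage = cov,
                      sigma_eps = 0.3, seed = 35L)
    sim <- simulate_dataset(cfg)
    tr <- tstat(smooth_profile(sim$data), sim$design)
    mean(tr$sd_raw, na.rm = TRUE)
  }
  s4 <- sd_at(4); s30 <- sd_at(30)
  expect_lt(abs(s30 - s4) / s4, 0.25)
})
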