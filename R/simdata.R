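#' Synthetic WGBS simulation configuration
#'
#' Defines the generative model the DMR machinery assumes: clustered CpG
#' positions (island/background two-state spacing), a smooth baseline
#' methylation profile `alpha(l)` on the logit scale (cubic spline through
#' knots every `alpha_knot_bp`), a planted group-difference component
#' (narrow DMRs and/or wide blocks, effect sizes on the probability
#' scale), per-sample biological noise `eps` smoothed along the genome so
#' its variance is locally smooth, and binomial read sampling at
#' Poisson-distributed coverage. Defaults are the package's standard study
#' conditions: 3 vs 3 samples at 4x coverage with 50 planted DMRs of
#' 1-3 kb and probability-scale effects 0.2-0.4, biological SD 0.3 on the
#' logit scale.
#'
#' @param n_cpgs Number of CpG loci.
#' @param n_per_group Samples per group (group 0, group 1).
#' @param coverage Mean of the per-locus, per-sample Poisson coverage.
#' @param island_rate Probability of starting a CpG island at each
#'   background step.
#' @param island_size_mean,island_spacing_mean Island CpG count and
#'   within-island spacing (bp) means.
#' @param background_spacing_mean Mean background inter-CpG spacing (bp).
#' @param alpha_knot_bp Baseline-profile knot spacing (bp).
#' @param alpha_knot_mean,alpha_knot_sd Knot value distribution (logit
#'   scale); the defaults give mostly methylated background with
#'   occasional low regions, as in mammalian genomes.
#' @param island_alpha_dip Depth (logit scale) of the smooth
#'   hypomethylation dip applied at each CpG island; planted DMRs are
#'   centered on islands, mirroring where real DMRs occur.
#' @param n_dmrs,dmr_width,dmr_effect Planted DMR count, width range (bp)
#'   and probability-scale effect range.
#' @param n_blocks,block_width,block_effect Planted block count, width
#'   range (bp) and signed probability-scale effect (blocks are typically
#'   wide, modest hypomethylation).
#' @param sigma_eps Marginal SD of the biological noise (logit scale).
#' @param noise_smooth_cpgs Running-mean window (CpGs) applied to the
#'   noise so its variance varies smoothly along the genome.
#' @param seed Integer seed; fully determines the dataset.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cpgs = 30000L, n_per_group = c(3L, 3L),
                       coverage = 4, island_rate = 0.02,
                       island_size_mean = 15, island_spacing_mean = 20,
                       background_spacing_mean = 150,
                       island_alpha_dip = 2.5,
                       alpha_knot_bp = 10000L,
                       alpha_knot_mean = 1.5, alpha_knot_sd = 1.2,
                       n_dmrs = 50L, dmr_width = c(1000L, 3000L),
                       dmr_effect = c(0.2, 0.4),
                       n_blocks = 0L, block_width = c(100000L, 300000L),
                       block_effect = -0.15,
                       sigma_eps = 0.3, noise_smooth_cpgs = 51L,
                       seed = 1L) {
  stopifnot(n_cpgs > 0, all(n_per_group >= 1), coverage > 0,
            sigma_eps >= 0, noise_smooth_cpgs %% 2 == 1,
            diff(dmr_width) >= 0, diff(dmr_effect) >= 0,
            all(dmr_effect > 0), all(dmr_effect < 1))
  structure(as.list(environment()), class = "sim_config")
}

# non-overlapping planted intervals over [1, span]; returns start/end
place_regions <- function(n, width_range, span, occupied, margin = 2000L) {
  starts <- integer(0); ends <- integer(0)
  tries <- 0L
  while (length(starts) < n && tries < n * 200L) {
    tries <- tries + 1L
    w <- round(stats::runif(1, width_range[1], width_range[2]))
    s <- round(stats::runif(1, 1, max(1, span - w)))
    e <- s + w - 1L
    clash <- any(interval_overlap(s - margin, e + margin,
                                  c(occupied$start, starts),
                                  c(occupied$end, ends)) > 0)
    if (!clash) {
      starts <- c(starts, s); ends <- c(ends, e)
    }
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Simulate a WGBS methylation dataset with known truth
#'
#' Draws CpG positions, a smooth baseline profile, planted DMR/block
#' effects and smoothed biological noise per the configuration, then
#' samples counts: `pi_ij = plogis(alpha_j + beta_j X_i + eps_ij)` clamped
#' to \[0.001, 0.999\], `N_ij ~ Poisson(coverage)`,
#' `M_ij ~ Binomial(N_ij, pi_ij)`. Fully reproducible from `cfg$seed`.
#'
#' Planted effects are constant within a region on the probability scale:
#' the logit effect at each member locus is chosen so the group-1
#' probability is the baseline probability shifted by the region's signed
#' `delta` (clamped away from 0/1). Direction is drawn at random but
#' forced feasible where the baseline is already near 0 or 1.
#'
#' @param cfg A [sim_config()].
#' @return A list with `data` (a [meth_data] with samples `g0_1..`,
#'   `g1_1..`), `design` (the matching [group_design()]), and `truth`
#'   (list: `loci` tibble with per-locus true `alpha`, `beta` (logit
#'   scale), `pi` matrix column per sample; `regions` tibble of planted
#'   regions with `chrom`, `start`, `end`, `delta`, `type`, `direction`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed, {
    n <- cfg$n_cpgs
    # two-state positions: background spacing vs dense island runs; islands
    # are recorded so planted DMRs can sit at CpG-dense loci, as real DMRs
    # (islands, shores) do
    pos <- integer(n)
    island_start <- integer(0); island_end <- integer(0)
    cur <- 1L; i <- 1L
    while (i <= n) {
      if (stats::runif(1) < cfg$island_rate) {
        isz <- min(n - i + 1L, stats::rpois(1, cfg$island_size_mean) + 3L)
        gaps <- 2L + stats::rpois(isz, cfg$island_spacing_mean - 2)
        island_start <- c(island_start, cur)
        for (g in gaps[seq_len(isz)]) {
          pos[i] <- cur; cur <- cur + g; i <- i + 1L
          if (i > n) break
        }
        island_end <- c(island_end, pos[min(i - 1L, n)])
      } else {
        pos[i] <- cur
        cur <- cur + 2L + round(stats::rexp(1, 1 / cfg$background_spacing_mean))
        i <- i + 1L
      }
    }
    span <- pos[n]

    # baseline profile: spline through logit-scale knots, plus a smooth
    # hypomethylation dip at each island (raised cosine over the island +/- 1 kb) — islands are unmethylated in mammalian genomes
    knots <- seq(1L, span + cfg$alpha_knot_bp, by = cfg$alpha_knot_bp)
    kv <- stats::rnorm(length(knots), cfg$alpha_knot_mean, cfg$alpha_knot_sd)
    alpha <- stats::spline(knots, kv, xout = pos)$y
    if (cfg$island_alpha_dip > 0 && length(island_start)) {
      for (k in seq_along(island_start)) {
        ck <- (island_start[k] + island_end[k]) / 2
        wk <- (island_end[k] - island_start[k]) + 2000
        memb <- which(abs(pos - ck) <= wk / 2)
        alpha[memb] <- alpha[memb] -
          cfg$island_alpha_dip * cos(pi * (pos[memb] - ck) / wk)^2
      }
    }

    # planted regions: blocks first (they are wide), then DMRs avoiding them
    occupied <- tibble::tibble(start = integer(0), end = integer(0))
    blocks <- place_regions(cfg$n_blocks, cfg$block_width, span, occupied)
    if (nrow(blocks)) {
      blocks$delta <- rep_len(cfg$block_effect, nrow(blocks))
      blocks$type <- "block"
    }
    occupied <- blocks[, c("start", "end")]
    # DMRs centered on CpG islands (sampled without replacement), falling
    # back to random placement when islands run out
    dmrs <- tibble::tibble(start = integer(0), end = integer(0))
    if (length(island_start) && cfg$n_dmrs > 0) {
      ctr <- (island_start + island_end) %/% 2L
      ctr <- ctr[sample.int(length(ctr))]
      for (cc in ctr) {
        if (nrow(dmrs) >= cfg$n_dmrs) break
        w <- round(stats::runif(1, cfg$dmr_width[1], cfg$dmr_width[2]))
        s <- as.integer(cc - w %/% 2L); e <- as.integer(s + w - 1L)
        if (s < 1L || e > span) next
        occ <- dplyr::bind_rows(occupied, dmrs)
        if (any(interval_overlap(s - 2000L, e + 2000L, occ$start, occ$end) > 0)) next
        if (sum(pos >= s & pos <= e) < 4L) next
        dmrs <- dplyr::bind_rows(dmrs, tibble::tibble(start = s, end = e))
      }
    }
    tries <- 0L
    while (nrow(dmrs) < cfg$n_dmrs && tries < 50L) {
      tries <- tries + 1L
      cand <- place_regions(cfg$n_dmrs - nrow(dmrs), cfg$dmr_width, span,
                            dplyr::bind_rows(occupied, dmrs))
      # keep only candidates holding enough CpGs to be callable
      keep <- vapply(seq_len(nrow(cand)), function(r) {
        sum(pos >= cand$start[r] & pos <= cand$end[r]) >= 4L
      }, logical(1))
      dmrs <- dplyr::bind_rows(dmrs, cand[keep, ])
    }
    if (nrow(dmrs)) {
      # balanced direction mix assigned by baseline headroom: hyper
      # effects at low-methylation regions (island gain of methylation),
      # hypo effects where the baseline is high
      mean_p0 <- vapply(seq_len(nrow(dmrs)), function(r) {
        memb <- pos >= dmrs$start[r] & pos <= dmrs$end[r]
        mean(stats::plogis(alpha[memb]))
      }, numeric(1))
      dir <- rep(-1, nrow(dmrs))
      dir[rank(mean_p0, ties.method = "first") <= nrow(dmrs) / 2] <- 1
      dmrs$delta <- stats::runif(nrow(dmrs), cfg$dmr_effect[1],
                                 cfg$dmr_effect[2]) * dir
      dmrs$type <- "dmr"
    }
    regions <- dplyr::bind_rows(blocks, dmrs)
    beta <- numeric(n)
    if (nrow(regions)) {
      for (r in seq_len(nrow(regions))) {
        memb <- which(pos >= regions$start[r] & pos <= regions$end[r])
        if (!length(memb)) next
        p0 <- stats::plogis(alpha[memb])
        # force a feasible direction where the baseline leaves no headroom
        d <- regions$delta[r]
        if (mean(p0) + abs(d) > 0.98 && d > 0) d <- -d
        if (mean(p0) - abs(d) < 0.02 && d < 0) d <- -d
        regions$delta[r] <- d
        p1 <- clamp(p0 + d, 0.005, 0.995)
        beta[memb] <- stats::qlogis(p1) - alpha[memb]
      }
      regions$direction <- ifelse(regions$delta > 0, "hyper", "hypo")
      regions <- dplyr::arrange(regions, .data$start)
      regions <- tibble::tibble(chrom = "chrS", regions)
    } else {
      regions <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), delta = numeric(),
                                type = character(), direction = character())
    }

    n0 <- cfg$n_per_group[1]; n1 <- cfg$n_per_group[2]
    ns <- n0 + n1
    labels <- c(rep(0L, n0), rep(1L, n1))
    ids <- c(paste0("g0_", seq_len(n0)), paste0("g1_", seq_len(n1)))

    # biological noise, smoothed along the genome so var is locally smooth
    eps <- matrix(0, n, ns)
    if (cfg$sigma_eps > 0) {
      for (k in seq_len(ns)) {
        z <- running_mean(stats::rnorm(n), cfg$noise_smooth_cpgs)
        eps[, k] <- z * (cfg$sigma_eps / stats::sd(z))
      }
    }

    eta <- alpha + outer(beta, labels) + eps
    pi <- clamp(stats::plogis(eta), 0.001, 0.999)
    N <- matrix(stats::rpois(n * ns, cfg$coverage), n, ns)
    M <- matrix(stats::rbinom(n * ns, N, pi), n, ns)
    U <- N - M

    ds <- meth_data(rep("chrS", n), pos, M, U, ids)
    truth_loci <- tibble::tibble(chrom = "chrS", pos = pos,
                                 alpha = alpha, beta = beta)
    list(data = ds,
         design = group_design(labels, ids),
         truth = list(loci = truth_loci, pi = pi, regions = regions))
  })
}

#' Simulate read-level measurements with planted M-bias
#'
#' Generates single-end reads over a synthetic chromosome with regularly
#' spaced CpGs; each read yields one measurement per covered CpG, whose
#' methylation call probability is `pi + bias(read_pos)` — a
#' position-in-read (cycle) artifact like those produced by degrading
#' base-call quality.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length (bases).
#' @param pi True methylation probability (constant).
#' @param bias Numeric vector of length `read_length`: additive error on
#'   the call probability per cycle (default all zero).
#' @param cpg_spacing Spacing of synthetic CpGs in bp.
#' @param genome_length Length of the synthetic chromosome.
#' @param seed Integer seed.
#' @return Tibble of read-level measurements: `read_id`, `chrom`,
#'   `ref_pos`, `strand`, `read_length`, `read_pos`, `methylated`.
#' @export
simulate_biased_reads <- function(n_reads, read_length = 50L, pi = 0.5,
                                  bias = numeric(read_length),
                                  cpg_spacing = 20L, genome_length = 10000L,
                                  seed = 1L) {
  stopifnot(length(bias) == read_length)
  prob <- pi + bias
  if (any(prob < 0 | prob > 1)) {
    stop("pi + bias outside [0, 1] at some cycle")
  }
  withr::with_seed(seed, {
    cpg <- seq(1L, genome_length - read_length, by = cpg_spacing)
    start <- sample.int(genome_length - read_length, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    # a plus-strand read measures the forward C; a minus-strand read
    # measures the reverse-strand C at forward position + 1
    obs_pos <- ifelse(strand == "-", 1L, 0L)
    lo <- findInterval(start - obs_pos - 1L, cpg) + 1L
    hi <- findInterval(start + read_length - 1L - obs_pos, cpg)
    n_per <- pmax(0L, hi - lo + 1L)
    keep <- n_per > 0L
    ridx <- rep.int(which(keep), n_per[keep])
    cidx <- sequence(n_per[keep], from = lo[keep])
    obs <- cpg[cidx] + obs_pos[ridx]
    offset <- obs - start[ridx] + 1L
    cycle <- ifelse(strand[ridx] == "+", offset,
                    read_length - offset + 1L)
    out <- tibble::tibble(read_id = paste0("read", ridx), chrom = "chrS",
                          ref_pos = as.integer(obs), strand = strand[ridx],
                          read_length = as.integer(read_length),
                          read_pos = as.integer(cycle))
    out$methylated <- stats::rbinom(nrow(out), 1L, prob[out$read_pos]) == 1L
    out
  })
}
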