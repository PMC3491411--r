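#' Smoothing parameters
#'
#' The local-likelihood smoother fits, at each CpG, a quadratic-in-position
#' logistic model to the binomial counts inside an adaptive genomic window.
#' The window half-width grows symmetrically in bp until it contains
#' `min_cpgs` loci, and is never narrower than `min_width_bp`. Defaults are
#' the standard small-DMR settings (70 CpGs / 2 kb); for hypomethylated
#' block detection use `block_smooth_params()` (500 CpGs / 40 kb).
#'
#' @param min_cpgs Minimum CpGs per window.
#' @param min_width_bp Minimum window width in bp.
#' @param logit_clamp Bound on the fitted logit; estimates are clamped to
#'   `plogis(c(-1, 1) * logit_clamp)`, which keeps separated fits (all
#'   methylated / all unmethylated windows) finite.
#' @param maxit Maximum IRLS iterations per window fit.
#' @return A list of class `smooth_params`.
#' @export
smooth_params <- function(min_cpgs = 70L, min_width_bp = 2000L,
                          logit_clamp = 8, maxit = 50L) {
  stopifnot(min_cpgs >= 1L, min_width_bp >= 1L, logit_clamp > 0)
  structure(list(min_cpgs = as.integer(min_cpgs),
                 min_width_bp = as.integer(min_width_bp),
                 logit_clamp = logit_clamp, maxit = as.integer(maxit)),
            class = "smooth_params")
}

#' @rdname smooth_params
#' @export
block_smooth_params <- function(min_cpgs = 500L, min_width_bp = 40000L, ...) {
  smooth_params(min_cpgs = min_cpgs, min_width_bp = min_width_bp, ...)
}

#' Tricube kernel
#'
#' `w(u) = (1 - |u|^3)^3` for `|u| <= 1`, else 0.
#'
#' @param u Scaled distance(s).
#' @return Weight(s) in \[0, 1\].
#' @export
tricube <- function(u) {
  w <- (1 - abs(u)^3)^3
  w[abs(u) > 1] <- 0
  w
}

#' Select the smoothing window around one locus
#'
#' The smallest symmetric interval `[pos_j - h, pos_j + h]` with
#' `h >= min_width_bp / 2` containing at least `min_cpgs` loci (or every
#' locus on the chromosome if fewer exist). Near chromosome ends the
#' interval is symmetric in bp but effectively one-sided in loci.
#'
#' @param pos Sorted (strictly increasing) positions on one chromosome.
#' @param j Index of the center locus.
#' @param params A [smooth_params] object.
#' @return A list with `lo`, `hi` (index range of contained loci) and `h`
#'   (the realized half-width in bp).
#' @export
select_window <- function(pos, j, params = smooth_params()) {
  n <- length(pos)
  k <- min(params$min_cpgs, n)
  d <- sort(abs(pos - pos[j]), partial = k)[k]
  h <- max(params$min_width_bp / 2, d)
  lo <- findInterval(pos[j] - h, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos[j] + h, pos)
  list(lo = lo, hi = hi, h = h)
}

#' Local weighted binomial logit-quadratic fit
#'
#' Maximizes the tricube-weighted binomial log-likelihood of a model in
#' which the logit of the methylation probability is a second-degree
#' polynomial of genomic position, and returns the inverse-logit of the
#' fitted polynomial at `center`. Kernel weights act as prior likelihood
#' weights, so each locus effectively contributes `w_k * N_k` trials: the
#' binomial variance `pi(1-pi)/N` is internalized by the likelihood rather
#' than plugged in, which keeps loci at observed proportions 0 or 1
#' well-defined. On IRLS non-convergence the fit falls back to degree 1,
#' then degree 0 (kernel-weighted mean proportion).
#'
#' @param pos,M,U Window loci: positions and methylated / unmethylated
#'   counts (equal-length vectors).
#' @param center Position at which to evaluate the fit.
#' @param h Kernel half-width in bp; loci with `|pos - center| >= h` get
#'   (near) zero weight.
#' @param params A [smooth_params] object (for `logit_clamp` and `maxit`).
#' @param degree Polynomial degree to start from (2, falling back on
#'   failure).
#' @return A list with `fitted` (estimate in \[0,1\], `NA` if the window
#'   has no covered locus), `degree` used, and `converged`.
#' @export
local_fit <- function(pos, M, U, center, h, params = smooth_params(),
                      degree = 2L) {
  N <- M + U
  w <- tricube((pos - center) / h)
  keep <- which(w > 0 & N > 0)
  if (length(keep) == 0L) {
    return(list(fitted = NA_real_, degree = NA_integer_, converged = FALSE))
  }
  pos <- pos[keep]; M <- M[keep]; N <- N[keep]; w <- w[keep]
  z <- (pos - center) / 1000  # kb units for conditioning
  y <- M / N
  pw <- w * N                 # effective binomial trials
  for (deg in seq(degree, 0L)) {
    X <- cbind(1, z, z * z)[, seq_len(deg + 1L), drop = FALSE]
    fit <- fit_wbinom(X, y, pw, maxit = params$maxit)
    if (fit$converged && all(is.finite(fit$coef))) {
      eta <- fit$coef[1]  # z = 0 at center
      eta <- clamp(eta, -params$logit_clamp, params$logit_clamp)
      return(list(fitted = unname(stats::plogis(eta)), degree = deg,
                  converged = TRUE))
    }
  }
  # last resort: clamped logit of the kernel-weighted proportion
  eta <- stats::qlogis(clamp(sum(w * M) / sum(w * N), 1e-8, 1 - 1e-8))
  eta <- clamp(eta, -params$logit_clamp, params$logit_clamp)
  list(fitted = unname(stats::plogis(eta)), degree = 0L, converged = FALSE)
}

# Newton IRLS for a weighted binomial logit model: maximizes
# sum_k pw_k * [y_k log mu_k + (1 - y_k) log(1 - mu_k)], mu = plogis(X b).
# Step-halving on deviance increase; "converged" when the deviance is
# stationary (covers separated fits, whose coefficients the caller clamps).
fit_wbinom <- function(X, y, pw, maxit = 50L, tol = 1e-14) {
  p <- ncol(X)
  mu0 <- sum(pw * y) / sum(pw)
  beta <- c(stats::qlogis(clamp(mu0, 1e-8, 1 - 1e-8)), rep(0, p - 1L))
  dev_of <- function(eta) {
    mu <- stats::plogis(clamp(eta, -30, 30))
    -2 * sum(pw * (y * log(mu) + (1 - y) * log1p(-mu)))
  }
  eta <- drop(X %*% beta)
  dev <- dev_of(eta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(clamp(eta, -30, 30))
    wd <- pw * mu * (1 - mu)
    grad <- crossprod(X, pw * (y - mu))
    hess <- crossprod(X, X * wd)
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    if (max(abs(grad)) < 1e-10 * (sum(pw) + 1)) { converged <- TRUE; break }
    # step-halve until the deviance does not increase
    ok <- FALSE
    for (half in 0:10) {
      beta_new <- beta + drop(step) / 2^half
      eta_new <- drop(X %*% beta_new)
      dev_new <- dev_of(eta_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-10) { ok <- TRUE; break }
    }
    if (!ok) {  # no descent possible: stationary unless the gradient says otherwise
      converged <- max(abs(grad)) < 1e-6 * (sum(pw) + 1)
      break
    }
    moved <- abs(dev - dev_new)
    step_size <- max(abs(beta_new - beta))
    beta <- beta_new; eta <- eta_new; dev <- dev_new
    if (moved < tol * (abs(dev) + 0.1) || step_size < 1e-10) {
      converged <- TRUE; break
    }
  }
  list(coef = beta, converged = converged, deviance = dev)
}

#' Smooth per-sample methylation profiles
#'
#' Applies [select_window()] + [local_fit()] at every locus, independently
#' per sample and per chromosome. Loci with zero coverage in a sample still
#' receive an estimate from the surrounding window (the smoother
#' interpolates over them); a locus is invalid (`NA`) only when its whole
#' window holds no covered CpG for that sample.
#'
#' @param ds A [meth_data] object.
#' @param params A [smooth_params] object.
#' @return A tibble of class `meth_smooth` with columns `chrom`, `pos`,
#'   `h` (realized half-width) and one `f_<sample>` column per sample
#'   (smoothed methylation estimate in \[0,1\], `NA` where invalid).
#' @export
smooth_profile <- function(ds, params = smooth_params()) {
  s <- meth_samples(ds)
  cnt <- meth_counts(ds)
  out <- tibble::tibble(chrom = ds$chrom, pos = ds$pos,
                        h = NA_real_)
  fmat <- matrix(NA_real_, nrow(ds), length(s))
  for (ch in unique(ds$chrom)) {
    idx <- which(ds$chrom == ch)
    pos <- ds$pos[idx]
    win <- lapply(seq_along(pos), function(j) select_window(pos, j, params))
    out$h[idx] <- vapply(win, `[[`, numeric(1), "h")
    for (k in seq_along(s)) {
      M <- cnt$M[idx, k]; U <- cnt$U[idx, k]
      fmat[idx, k] <- vapply(seq_along(pos), function(j) {
        w <- win[[j]]
        rng <- w$lo:w$hi
        local_fit(pos[rng], M[rng], U[rng], center = pos[j], h = w$h,
                  params = params)$fitted
      }, numeric(1))
    }
  }
  for (k in seq_along(s)) out[[paste0("f_", s[k])]] <- fmat[, k]
  attr(out, "samples") <- s
  attr(out, "params") <- params
  class(out) <- c("meth_smooth", class(tibble::tibble()))
  out
}

#' @rdname smooth_profile
#' @param sm A `meth_smooth` object.
#' @return `smooth_values()`: the loci x samples matrix of estimates.
#' @export
smooth_values <- function(sm) {
  s <- attr(sm, "samples")
  f <- as.matrix(sm[, paste0("f_", s), drop = FALSE])
  colnames(f) <- s
  f
}
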