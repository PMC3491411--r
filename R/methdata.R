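#' Per-CpG methylation count tables
#'
#' A `meth_data` object is a tibble with one row per CpG locus and, for each
#' sample `<s>`, a pair of integer columns `M_<s>` (methylated read count)
#' and `U_<s>` (unmethylated read count). Coverage is `N = M + U`. Positions
#' are 1-based forward-strand coordinates of the CpG cytosine, strictly
#' increasing within each chromosome, with no duplicate loci. A sample with
#' no reads at a locus carries `M = U = 0`; "no data" and "zero coverage"
#' are the same state, distinguished from analysis only by
#' [filter_by_coverage()].
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based CpG positions.
#' @param M,U Integer matrices (loci x samples) of methylated / unmethylated
#'   read counts.
#' @param sample_ids Character vector of sample labels (one per column).
#' @return A tibble of class `meth_data`.
#' @export
meth_data <- function(chrom, pos, M, U, sample_ids) {
  M <- as.matrix(M); U <- as.matrix(U)
  stopifnot(
    length(chrom) == length(pos),
    nrow(M) == length(pos), identical(dim(M), dim(U)),
    ncol(M) == length(sample_ids)
  )
  out <- tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos))
  for (k in seq_along(sample_ids)) {
    out[[paste0("M_", sample_ids[k])]] <- as.integer(M[, k])
    out[[paste0("U_", sample_ids[k])]] <- as.integer(U[, k])
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "samples") <- as.character(sample_ids)
  class(out) <- c("meth_data", class(tibble::tibble()))
  validate_meth_data(out)
}

validate_meth_data <- function(ds) {
  key <- paste(ds$chrom, ds$pos)
  if (anyDuplicated(key)) {
    stop("duplicate locus: ", key[duplicated(key)][1])
  }
  unsorted <- unlist(lapply(split(ds$pos, ds$chrom), function(p) any(diff(p) <= 0)))
  if (any(unsorted)) stop("positions not strictly increasing within chromosome")
  cnt <- as.matrix(ds[, -(1:2)])
  if (any(cnt < 0) || anyNA(cnt)) stop("counts must be non-negative and non-missing")
  ds
}

#' @rdname meth_data
#' @param ds A `meth_data` object.
#' @export
meth_samples <- function(ds) attr(ds, "samples")

#' Extract count matrices from a `meth_data` tibble
#'
#' @param ds A `meth_data` object.
#' @return A list with integer matrices `M`, `U` and `N` (loci x samples).
#' @export
meth_counts <- function(ds) {
  s <- meth_samples(ds)
  M <- as.matrix(ds[, paste0("M_", s), drop = FALSE])
  U <- as.matrix(ds[, paste0("U_", s), drop = FALSE])
  colnames(M) <- colnames(U) <- s
  list(M = M, U = U, N = M + U)
}

#' Two-group sample design
#'
#' @param labels Integer/logical vector of group indicators (0/1), one per
#'   sample, in the column order of the dataset.
#' @param sample_ids Optional sample labels; defaults to names of `labels`.
#' @return A list of class `group_design` with elements `labels`, `n1`
#'   (group-0 size), `n2` (group-1 size), `sample_ids`.
#' @export
group_design <- function(labels, sample_ids = names(labels)) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 0L); n2 <- sum(labels == 1L)
  if (n1 < 1L || n2 < 1L) stop("each group needs at least one sample")
  structure(list(labels = labels, n1 = n1, n2 = n2,
                 sample_ids = sample_ids),
            class = "group_design")
}

#' Read CpG methylation counts from TSV
#'
#' Two dialects are supported. `"bedgraph"`: one file per sample with four
#' columns `chrom, pos, M, U` (1-based positions; lines starting with `#`
#' are skipped); several files are merged on the union of loci, a locus
#' absent from a sample getting `M = U = 0`. `"matrix"`: a single combined
#' file with `chrom, pos` followed by `M_<sample>, U_<sample>` column pairs.
#'
#' @param path Character vector of file paths (length > 1 only for the
#'   per-sample dialect).
#' @param dialect `"bedgraph"` or `"matrix"`.
#' @param sample_ids Sample labels for the per-sample dialect; defaults to
#'   file base names.
#' @return A [meth_data] tibble sorted by (chrom, pos).
#' @export
read_counts <- function(path, dialect = c("bedgraph", "matrix"),
                        sample_ids = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    stopifnot(length(path) == 1L)
    tab <- read_counts_table(path, n_min_cols = 4L)
    nm <- names(tab)
    if (!identical(nm[1:2], c("chrom", "pos"))) names(tab)[1:2] <- c("chrom", "pos")
    mcols <- grep("^M_", names(tab), value = TRUE)
    ids <- sub("^M_", "", mcols)
    stopifnot(all(paste0("U_", ids) %in% names(tab)))
    return(meth_data(tab$chrom, tab$pos,
                     as.matrix(tab[, paste0("M_", ids)]),
                     as.matrix(tab[, paste0("U_", ids)]), ids))
  }
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(path))
  }
  stopifnot(length(sample_ids) == length(path))
  per <- lapply(path, function(p) {
    tab <- read_counts_table(p, n_min_cols = 4L)
    names(tab)[1:4] <- c("chrom", "pos", "M", "U")
    key <- paste(tab$chrom, tab$pos)
    if (anyDuplicated(key)) stop("duplicate locus in ", p, ": ",
                                 key[duplicated(key)][1])
    tab
  })
  loci <- dplyr::distinct(
    dplyr::bind_rows(lapply(per, function(x) x[, c("chrom", "pos")]))
  )
  loci <- dplyr::arrange(loci, .data$chrom, .data$pos)
  n <- nrow(loci)
  M <- matrix(0L, n, length(path)); U <- matrix(0L, n, length(path))
  key <- paste(loci$chrom, loci$pos)
  for (k in seq_along(per)) {
    idx <- match(paste(per[[k]]$chrom, per[[k]]$pos), key)
    M[idx, k] <- as.integer(per[[k]]$M)
    U[idx, k] <- as.integer(per[[k]]$U)
  }
  meth_data(loci$chrom, loci$pos, M, U, sample_ids)
}

# readr-based TSV reader that reports the first malformed line; the header
# line is optional (files may carry only a '#' comment header)
read_counts_table <- function(path, n_min_cols) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- ""
  n_comment <- 0L
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    first <- readLines(con, n = 1L)
    if (length(first) == 0L || !startsWith(first, "#")) break
    n_comment <- n_comment + 1L
  }
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 2L &&
    is.na(suppressWarnings(as.numeric(fields[2])))
  if (has_header) {
    nms <- fields
  } else {
    nms <- c("chrom", "pos", "M", "U",
             paste0("V", seq_len(max(0, length(fields) - 4L))))[
               seq_along(fields)]
  }
  types <- do.call(readr::cols, c(
    stats::setNames(list(readr::col_character()), nms[1]),
    list(.default = readr::col_integer())))
  skip <- n_comment + as.integer(has_header)
  tab <- suppressWarnings(
    readr::read_tsv(path, comment = "#", col_names = nms,
                    col_types = types, skip = skip, progress = FALSE))
  pr <- readr::problems(tab)
  if (nrow(pr) > 0) {
    stop("parse error in ", path, " at line ", pr$row[1] + skip,
         ": expected ", pr$expected[1], ", got '", pr$actual[1], "'")
  }
  if (ncol(tab) < n_min_cols) stop("too few columns in ", path)
  tab
}

#' Write a `meth_data` object as a combined matrix TSV
#'
#' @param ds A [meth_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ds, path) {
  readr::write_tsv(as.data.frame(ds), path, progress = FALSE)
  invisible(path)
}

#' Collapse stranded CpG calls onto forward-strand positions
#'
#' CpG methylation is symmetric across strands: evidence for the reverse
#' strand cytosine of a CpG sits at forward position + 1. Counts from both
#' strands are summed and reported at the position of the forward-strand C.
#'
#' @param records Tibble with columns `chrom`, `pos`, `strand` (`"+"` or
#'   `"-"`), `M`, `U`. Reverse-strand `pos` is the (forward) coordinate of
#'   the G, i.e. forward C position + 1.
#' @return Tibble with columns `chrom`, `pos`, `M`, `U`, one row per CpG at
#'   forward-strand positions.
#' @export
collapse_strands <- function(records) {
  stopifnot(all(c("chrom", "pos", "strand", "M", "U") %in% names(records)))
  stopifnot(all(records$strand %in% c("+", "-")))
  fwd_pos <- ifelse(records$strand == "-", records$pos - 1L, records$pos)
  if (any(fwd_pos <= 0L)) {
    stop("reverse-strand record at pos ", records$pos[fwd_pos <= 0L][1],
         " has no valid forward partner position")
  }
  records |>
    dplyr::mutate(pos = as.integer(fwd_pos)) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(M = sum(.data$M), U = sum(.data$U), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Filter loci by read coverage across samples
#'
#' Retains loci where at least `min_samples` samples have coverage
#' `N >= min_cov`. The default keeps loci covered in every sample,
#' the strictest version of the "some coverage in most or all samples"
#' inclusion rule; relax via `min_samples`.
#'
#' @param ds A [meth_data] object.
#' @param min_cov Minimum coverage per sample (>= 1).
#' @param min_samples Minimum number of samples meeting `min_cov`; default
#'   all samples.
#' @return A [meth_data] object with the retained loci, order preserved.
#' @export
filter_by_coverage <- function(ds, min_cov = 1L,
                               min_samples = length(meth_samples(ds))) {
  stopifnot(min_cov >= 1L, min_samples >= 1L,
            min_samples <= length(meth_samples(ds)))
  cnt <- meth_counts(ds)
  keep <- rowSums(cnt$N >= min_cov) >= min_samples
  out <- ds[keep, , drop = FALSE]
  attr(out, "samples") <- meth_samples(ds)
  class(out) <- class(ds)
  out
}

#' Export loci or regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` becomes `start - 1` and `end` is kept (a 1 bp locus at pos p
#' becomes `p-1, p`).
#'
#' @param x A tibble with `chrom` plus either `pos` (loci) or
#'   `start`/`end` (regions); extra columns after the first three become
#'   BED name/score fields if present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if ("pos" %in% names(x) && !"start" %in% names(x)) {
    bed <- tibble::tibble(chrom = x$chrom, start = x$pos - 1L, end = x$pos)
  } else {
    bed <- tibble::tibble(chrom = x$chrom, start = x$start - 1L, end = x$end)
    if ("direction" %in% names(x)) bed$name <- x$direction
    if ("area" %in% names(x)) bed$score <- x$area
  }
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
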