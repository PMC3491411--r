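#' Extract read-level methylation measurements from a SAM/BAM file
#'
#' For each uniquely aligned read (mapping quality >= `min_mapq`), records
#' one measurement per aligned base that overlaps a reference CpG cytosine
#' and reads C (methylated) or T (unmethylated); other bases at CpG sites
#' are discarded. Plus-strand alignments inform the forward-strand C;
#' minus-strand alignments inform the reverse-strand C (at forward
#' position + 1), whose evidence appears as G/A in the reference-oriented
#' SAM sequence. The read position is the sequencing cycle, counted from
#' the 5' end of the read *as sequenced* — so it runs backwards along the
#' reference for minus-strand alignments, since M-bias is a
#' chemistry/cycle artifact.
#'
#' Requires the `Rsamtools` and `GenomicAlignments` packages. Records
#' without a sequence, on chromosomes absent from `ref_cpgs`, or below the
#' mapping-quality threshold are skipped; skip counts are reported via a
#' message.
#'
#' @param path SAM or BAM file path (SAM is converted on the fly).
#' @param ref_cpgs Tibble with `chrom`, `pos`: forward-strand coordinates
#'   of reference CpG cytosines.
#' @param min_mapq Minimum mapping quality defining "uniquely aligned"
#'   (default 20).
#' @return Tibble of measurements: `read_id`, `chrom`, `ref_pos` (the
#'   observed C: forward pos for `+` evidence, forward pos + 1 for `-`),
#'   `strand`, `read_length`, `read_pos` (cycle), `methylated`.
#' @export
extract_read_measurements <- function(path, ref_cpgs, min_mapq = 20L) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for SAM/BAM input")
    }
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "mapq", "flag"))
  ga <- GenomicAlignments::readGAlignments(path, param = param, use.names = FALSE)
  md <- S4Vectors::mcols(ga)
  seqs <- as.character(md$seq)
  n_noseq <- sum(seqs == "" | is.na(seqs))
  low_q <- !is.na(md$mapq) & md$mapq < min_mapq
  keep <- !low_q & !(seqs == "" | is.na(seqs))
  known <- as.character(GenomeInfoDb::seqnames(ga)) %in%
    unique(ref_cpgs$chrom)
  n_unknown <- sum(keep & !known)
  keep <- keep & known
  if (n_noseq || sum(low_q) || n_unknown) {
    message("skipped: ", n_noseq, " without sequence, ", sum(low_q),
            " below mapq ", min_mapq, ", ", n_unknown,
            " on unknown chromosomes")
  }
  ga <- ga[keep]; seqs <- seqs[keep]
  qnames <- md$qname[keep]
  minus <- as.character(BiocGenerics::strand(ga)) == "-"
  cig <- GenomicAlignments::cigar(ga)
  starts <- BiocGenerics::start(ga)
  chroms <- as.character(GenomeInfoDb::seqnames(ga))
  # per-chromosome sorted CpG positions: forward C and its reverse partner
  fwd <- split(ref_cpgs$pos, ref_cpgs$chrom)
  fwd <- lapply(fwd, sort)

  ref_ranges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = starts)
  qry_ranges <- GenomicAlignments::cigarRangesAlongQuerySpace(cig)
  ops <- GenomicAlignments::explodeCigarOps(cig)

  out <- vector("list", length(ga))
  for (a in seq_along(ga)) {
    cpg_f <- fwd[[chroms[a]]]
    if (is.null(cpg_f)) next
    L <- nchar(seqs[a])
    rows <- NULL
    op <- ops[[a]]
    rr <- ref_ranges[[a]]; qr <- qry_ranges[[a]]
    for (o in seq_along(op)) {
      if (!op[o] %in% c("M", "=", "X")) next
      r0 <- BiocGenerics::start(rr)[o]; r1 <- BiocGenerics::end(rr)[o]
      q0 <- BiocGenerics::start(qr)[o]
      # forward-strand CpG Cs in this aligned stretch
      f_in <- cpg_f[cpg_f >= r0 & cpg_f <= r1]
      # reverse-strand CpG Cs (forward pos + 1) in this stretch
      g_in <- cpg_f[cpg_f + 1L >= r0 & cpg_f + 1L <= r1] + 1L
      tgt <- if (minus[a]) g_in else f_in
      if (!length(tgt)) next
      qpos <- tgt - r0 + q0
      base <- substring(seqs[a], qpos, qpos)
      if (minus[a]) {
        call <- ifelse(base == "G", TRUE, ifelse(base == "A", FALSE, NA))
      } else {
        call <- ifelse(base == "C", TRUE, ifelse(base == "T", FALSE, NA))
      }
      ok <- !is.na(call)
      if (!any(ok)) next
      cycle <- if (minus[a]) L - qpos + 1L else qpos
      rows <- rbind(rows, data.frame(
        read_id = qnames[a], chrom = chroms[a], ref_pos = tgt[ok],
        strand = if (minus[a]) "-" else "+", read_length = L,
        read_pos = cycle[ok], methylated = call[ok]))
    }
    out[[a]] <- rows
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Stratify read-level measurements by read position
#'
#' Tabulates methylated / unmethylated calls per (read length, read
#' position) stratum. Since the methylation state cannot depend on the
#' sequencing cycle, the per-position proportions should form a flat line;
#' deviations expose position-in-read bias (M-bias). Datasets with mixed
#' read lengths get one table per length.
#'
#' @param ms Measurements from [extract_read_measurements()] or
#'   [simulate_biased_reads()].
#' @return A tibble of class `mbias_table`: `read_length`, `read_pos`,
#'   `n_meth`, `n_unmeth`, `proportion` (`NA` where a stratum is empty).
#' @export
compute_mbias <- function(ms) {
  out <- ms |>
    dplyr::group_by(.data$read_length, .data$read_pos) |>
    dplyr::summarise(n_meth = sum(.data$methylated),
                     n_unmeth = sum(!.data$methylated), .groups = "drop")
  out <- out |>
    dplyr::group_split(.data$read_length) |>
    purrr::map(function(d) {
      tidyr::complete(d, read_length = d$read_length[1],
                      read_pos = seq_len(d$read_length[1]),
                      fill = list(n_meth = 0L, n_unmeth = 0L))
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(total = .data$n_meth + .data$n_unmeth,
                  proportion = ifelse(.data$total > 0,
                                      .data$n_meth / .data$total, NA_real_)) |>
    dplyr::select(-"total") |>
    dplyr::arrange(.data$read_length, .data$read_pos)
  class(out) <- c("mbias_table", class(tibble::tibble()))
  out
}

#' M-bias filtering of read-level measurements
#'
#' Retains measurements whose read position lies in the configured
#' inclusive range for their read length; the rest are excluded from
#' downstream methylation summaries (the full read was still used for
#' alignment upstream). Lengths with no configured range are kept
#' unchanged with a warning (`unconfigured = "keep"`) or dropped
#' (`unconfigured = "drop"`).
#'
#' @param ms Measurements tibble.
#' @param keep Either a length-2 vector `c(first, last)` applied to every
#'   read length, or a tibble with columns `read_length`, `first`, `last`.
#' @param unconfigured Policy for lengths with no configured range.
#' @return The filtered measurements; the number removed per stratum is
#'   attached as attribute `"removed"`.
#' @export
apply_mbias_filter <- function(ms, keep, unconfigured = c("keep", "drop")) {
  unconfigured <- match.arg(unconfigured)
  if (!is.data.frame(keep)) {
    stopifnot(length(keep) == 2L, keep[1] >= 1L, keep[1] <= keep[2])
    keep <- tibble::tibble(read_length = unique(ms$read_length),
                           first = keep[1], last = keep[2])
  }
  stopifnot(all(keep$first >= 1L), all(keep$first <= keep$last))
  m <- match(ms$read_length, keep$read_length)
  unconf <- is.na(m)
  if (any(unconf)) {
    warning(sum(unconf), " measurements with unconfigured read length (",
            paste(unique(ms$read_length[unconf]), collapse = ", "),
            "): policy '", unconfigured, "'")
  }
  in_range <- !unconf & ms$read_pos >= keep$first[m] &
    ms$read_pos <= keep$last[m]
  retain <- in_range | (unconf & unconfigured == "keep")
  removed <- ms[!retain, ] |>
    dplyr::count(.data$read_length, .data$read_pos, name = "n_removed")
  out <- ms[retain, ]
  attr(out, "removed") <- removed
  out
}

#' Aggregate read-level measurements to per-CpG counts
#'
#' Counts methylated and unmethylated measurements per observed cytosine,
#' then collapses strands onto forward CpG positions (reverse-strand
#' evidence sits at forward position + 1), yielding a single-sample
#' [meth_data].
#'
#' @param ms Measurements tibble (needs `chrom`, `ref_pos`, `strand`,
#'   `methylated`).
#' @param sample_id Sample label for the resulting dataset.
#' @return A single-sample [meth_data] object.
#' @export
aggregate_to_counts <- function(ms, sample_id = "sample1") {
  rec <- ms |>
    dplyr::group_by(.data$chrom, pos = .data$ref_pos, .data$strand) |>
    dplyr::summarise(M = sum(.data$methylated),
                     U = sum(!.data$methylated), .groups = "drop")
  coll <- collapse_strands(rec)
  meth_data(coll$chrom, coll$pos, matrix(coll$M), matrix(coll$U), sample_id)
}
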