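# hand-built SAM fixture for the read-measurement extractor; reference CpG
# (forward C) positions on chrT: 110, 120, 130, 150
write_sam_fixture <- function(path) {
  seq_plus <- paste0(strrep("A", 6), "C", strrep("A", 9), "T",
                     strrep("A", 9), "G", strrep("A", 23))  # C@7, T@17, G@27
  stopifnot(nchar(seq_plus) == 50)
  # minus-strand read at pos 108: reverse CpG Cs (fwd + 1) at 111, 121,
  # 131, 151 -> query pos 4, 14, 24, 44 (reference orientation)
  seq_minus <- paste0(strrep("A", 3), "G", strrep("A", 9), "A",
                      strrep("A", 9), "C", strrep("A", 19), "G",
                      strrep("A", 6))  # G@4, A@14, C@24, G@44
  stopifnot(nchar(seq_minus) == 50)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrT\tLN:1000",
    "@SQ\tSN:chrUn\tLN:1000",
    paste("r1", 0, "chrT", 104, 60, "50M", "*", 0, 0, seq_plus,
          strrep("I", 50), sep = "\t"),
    paste("r2", 16, "chrT", 108, 60, "50M", "*", 0, 0, seq_minus,
          strrep("I", 50), sep = "\t"),
    paste("r3", 0, "chrT", 104, 5, "50M", "*", 0, 0, seq_plus,
          strrep("I", 50), sep = "\t"),
    paste("r4", 0, "chrUn", 104, 60, "50M", "*", 0, 0, seq_plus,
          strrep("I", 50), sep = "\t"))
  writeLines(lines, path)
  path
}

ref_cpgs_fixture <- tibble::tibble(chrom = "chrT",
                                   pos = c(110L, 120L, 130L, 150L))
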