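#' Nucleotide and dinucleotide content of sequences
#'
#' Counts the four unambiguous nucleotides and the sixteen dinucleotides
#' with an overlapping scan (width 2, step 1). Any window containing an
#' ambiguous base (N or any other IUPAC code) is skipped entirely, and
#' ambiguous bases are excluded from the nucleotide counts.
#'
#' @param seqs A [Biostrings::DNAStringSet], `DNAString`, character vector
#'   or FASTA path.
#' @return A data frame with one row per sequence: `seq_id`, the 4
#'   nucleotide counts (`A`,`C`,`G`,`T`) and the 16 dinucleotide counts
#'   (`AA` .. `TT`).
#' @examples
#' count_dinucleotides(c(x = "CGCG"))
#' @export
count_dinucleotides <- function(seqs) {
  seqs <- as_dna(seqs)
  nt <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  dn <- Biostrings::dinucleotideFrequency(seqs, step = 1)
  out <- data.frame(seq_id = names(seqs) %||% sprintf("seq%d", seq_along(seqs)),
                    nt, dn, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Normalised CpG content (CpG o/e)
#'
#' Computes, per sequence, the observed/expected CpG ratio
#' \deqn{CpG_{o/e} = \frac{N \cdot CpG}{C \cdot G}}
#' where `N` is the number of unambiguous (A/C/G/T) bases, `CpG` the number
#' of CpG dinucleotides found by an overlapping scan in which both members
#' must be unambiguous, and `C` and `G` the cytosine and guanine counts.
#' Under independence of adjacent bases the expected CpG frequency is
#' `(C/N)(G/N)` per position, so values near 1 mean no depletion and
#' values well below 1 mean historical CpG loss — the footprint of
#' germ-line DNA methylation.
#'
#' The ratio is undefined when `C = 0` or `G = 0`; such sequences get
#' `NA` with the reason in the `undefined_reason` column (no error is
#' raised — batch filtering happens in [cpg_oe_table()]).
#'
#' @inheritParams count_dinucleotides
#' @return A data frame with columns `seq_id`, `N`, `C`, `G`, `CpG`,
#'   `cpg_oe`, `undefined_reason`.
#' @examples
#' cpg_oe(c(tiny = "ACGT"))   # 4 * 1 / (1 * 1) = 4
#' @export
cpg_oe <- function(seqs) {
  seqs <- as_dna(seqs)
  nt <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  cpg <- if (length(seqs) > 0L) {
    Biostrings::dinucleotideFrequency(seqs, step = 1)[, "CG", drop = TRUE]
  } else {
    integer(0)
  }
  N <- as.numeric(rowSums(nt))
  C <- as.numeric(nt[, "C"])
  G <- as.numeric(nt[, "G"])
  CpG <- as.numeric(cpg)
  defined <- C > 0 & G > 0
  oe <- ifelse(defined, N * CpG / (C * G), NA_real_)
  reason <- ifelse(defined, NA_character_, "zero_C_or_G")
  data.frame(seq_id = names(seqs) %||% sprintf("seq%d", seq_along(seqs)),
             N = N, C = C, G = G, CpG = CpG, cpg_oe = oe,
             undefined_reason = reason,
             stringsAsFactors = FALSE)
}

#' Batch CpG o/e with exclusion accounting
#'
#' Computes [cpg_oe()] for a collection and drops sequences that cannot
#' support a stable estimate: those with fewer than `min_length`
#' unambiguous bases (the sampling variance of the ratio is extreme at
#' small N — a 4-mer can score 4.0) and those where the ratio is undefined
#' (no C or no G). The exclusion tally is attached as
#' `attr(x, "exclusions")`.
#'
#' @inheritParams count_dinucleotides
#' @param min_length Minimum number of unambiguous bases (default 200).
#' @param keep_undefined Keep undefined rows (as `NA`) instead of dropping
#'   them.
#' @return A data frame as in [cpg_oe()] (without `undefined_reason`
#'   unless `keep_undefined`), input order preserved, with attribute
#'   `exclusions = list(n_input, too_short, undefined, n_kept)`.
#' @export
cpg_oe_table <- function(seqs, min_length = 200L, keep_undefined = FALSE) {
  seqs <- as_dna(seqs)
  if (length(seqs) == 0L) stop_data("no usable sequences: empty input")
  tab <- cpg_oe(seqs)
  too_short <- tab$N < min_length
  undefined <- !too_short & is.na(tab$cpg_oe)
  keep <- !too_short & (keep_undefined | !is.na(tab$cpg_oe))
  out <- tab[keep, , drop = FALSE]
  if (!keep_undefined) out$undefined_reason <- NULL
  rownames(out) <- NULL
  if (nrow(out) == 0L || all(is.na(out$cpg_oe))) {
    stop_data("no usable sequences: %d too short (< %d bp), %d with undefined CpG o/e",
              sum(too_short), min_length, sum(undefined))
  }
  attr(out, "exclusions") <- list(n_input = nrow(tab),
                                  too_short = sum(too_short),
                                  undefined = sum(undefined),
                                  n_kept = nrow(out))
  out
}

#' Write a CpG o/e table as TSV
#'
#' Six tab-separated columns with a header line: `seq_id`, `N`, `C`, `G`,
#' `CpG`, `cpg_oe`; undefined values are written as `NA`.
#'
#' @param tab A data frame from [cpg_oe()] or [cpg_oe_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(tab, path) {
  cols <- c("seq_id", "N", "C", "G", "CpG", "cpg_oe")
  write.table(tab[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
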