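# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: character-level loops instead of Biostrings
# counting, power iteration instead of eigen decomposition.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force CpG o/e: explicit sliding scan over a character string.
oracle_cpg_stats <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  good <- ch %in% c("A", "C", "G", "T")
  N <- sum(good)
  C <- sum(ch == "C")
  G <- sum(ch == "G")
  CpG <- 0L
  if (length(ch) >= 2) {
    for (i in seq_len(length(ch) - 1L)) {
      if (ch[i] == "C" && ch[i + 1L] == "G") CpG <- CpG + 1L
    }
  }
  oe <- if (C > 0 && G > 0) N * CpG / (C * G) else NA_real_
  list(N = N, C = C, G = G, CpG = CpG, cpg_oe = oe)
}

# Random sequence with optional ambiguity fraction.
random_dna <- function(n, p_ambiguous = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (p_ambiguous > 0) {
    amb <- runif(n) < p_ambiguous
    s[amb] <- "N"
  }
  paste(s, collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Stationary distribution by power iteration (independent of eigen()).
stationary_power <- function(P, iters = 10000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.numeric(v %*% P)
  v / sum(v)
}

# Small deterministic two-exon test genome used by several io tests.
toy_genome <- function() {
  Biostrings::DNAStringSet(c(scf1 = "AACCGGTTAACC", scf2 = "ACGTACGTACGT"))
}

toy_models <- function() {
  gene_models(data.frame(
    gene_id = c("g1", "g1", "g2"),
    seqid = c("scf1", "scf1", "scf2"),
    strand = c("+", "+", "-"),
    start = c(0L, 8L, 0L),
    end = c(4L, 12L, 4L)
  ))
}

# A fake two-component fit for classify() symmetry checks.
fake_fit_2 <- function(means = c(0.3, 0.9), sds = c(0.1, 0.1),
                       weights = c(0.5, 0.5)) {
  structure(list(K = 2L, weights = weights, means = means,
                 variances = sds^2, variance_family = "unequal",
                 loglik = NA_real_, n_params = 5L, bic = NA_real_,
                 n_obs = NA_integer_, converged = TRUE, n_iter = 0L,
                 ll_trace = numeric(0)),
            class = "mixture_fit")
}
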