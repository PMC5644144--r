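#' Specification of a simulated gene class
#'
#' A class of genes sharing base composition, a CpG depletion factor and a
#' length distribution. The depletion factor `d` multiplies the C->G
#' transition probability of a first-order Markov chain whose baseline
#' rows equal the base composition; `d = 1` means no depletion (expected
#' CpG o/e exactly 1), `d < 1` mimics the end state of germ-line
#' methylation followed by CpG->TpG decay. Because the C row is
#' renormalised, the realised CpG o/e is not `d` itself; use
#' [expected_cpg_oe()] for the analytic mapping and
#' [depletion_for_cpg_oe()] for its inverse.
#'
#' @param label Class label (e.g. `"methylated"`).
#' @param proportion Fraction of genes in this class.
#' @param cpg_depletion Depletion factor `d` in (0, 1.5].
#' @param gc_fraction GC fraction of the baseline composition, in
#'   (0.05, 0.95). Default 0.35, a typical AT-rich arthropod gene space.
#' @param length_mean,length_sd,length_min Transcript length distribution
#'   in bp: normal with this mean/sd, floored at `length_min`.
#' @return A `class_spec` object.
#' @export
class_spec <- function(label, proportion = 1, cpg_depletion,
                       gc_fraction = 0.35, length_mean = 1500,
                       length_sd = 700, length_min = 200) {
  if (!is.numeric(cpg_depletion) || cpg_depletion <= 0 || cpg_depletion > 1.5) {
    stop_usage("class_spec: cpg_depletion must be in (0, 1.5], got %s",
               format(cpg_depletion))
  }
  if (gc_fraction <= 0.05 || gc_fraction >= 0.95) {
    stop_usage("class_spec: gc_fraction must be in (0.05, 0.95)")
  }
  if (length_min < 2) stop_usage("class_spec: length_min must be >= 2")
  if (proportion <= 0 || proportion > 1) {
    stop_usage("class_spec: proportion must be in (0, 1]")
  }
  structure(list(label = as.character(label), proportion = proportion,
                 cpg_depletion = cpg_depletion, gc_fraction = gc_fraction,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_min),
            class = "class_spec")
}

#' Markov transition matrix with CpG depletion
#'
#' Builds the 4x4 first-order transition matrix (rows and columns in
#' A, C, G, T order) whose baseline rows all equal the base composition
#' implied by `gc_fraction` (`p_A = p_T = (1-gc)/2`,
#' `p_C = p_G = gc/2`). The C-row entry for G is multiplied by
#' `cpg_depletion` and the C row renormalised. The stationary
#' distribution of the resulting chain and the analytic expected CpG o/e,
#' `p(G|C) / pi_G`, are computed from it.
#'
#' @inheritParams class_spec
#' @return A list: `P` (row-stochastic matrix), `stationary` (length-4
#'   distribution), `expected_cpg_oe`.
#' @examples
#' build_transition_matrix(0.5, 1.0)$expected_cpg_oe  # exactly 1
#' @export
build_transition_matrix <- function(gc_fraction, cpg_depletion) {
  if (!is.numeric(cpg_depletion) || cpg_depletion <= 0 || cpg_depletion > 1.5) {
    stop_usage("cpg_depletion must be in (0, 1.5], got %s", format(cpg_depletion))
  }
  if (gc_fraction <= 0.05 || gc_fraction >= 0.95) {
    stop_usage("gc_fraction must be in (0.05, 0.95)")
  }
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  P <- matrix(rep(p, each = 4), 4, 4,
              dimnames = list(from = names(p), to = names(p)))
  P["C", "G"] <- P["C", "G"] * cpg_depletion
  rs <- sum(P["C", ])
  if (rs <= 0) stop_usage("cpg_depletion degenerates the C row")
  P["C", ] <- P["C", ] / rs
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  st <- Re(ev$vectors[, i])
  st <- st / sum(st)
  names(st) <- names(p)
  list(P = P, stationary = st,
       expected_cpg_oe = as.numeric(P["C", "G"] / st[["G"]]))
}

#' Analytic expected CpG o/e of the depletion chain
#'
#' In the stationary chain the observed per-position CpG frequency is
#' `pi_C * p(G|C)` and the expected frequency is `pi_C * pi_G`, so the
#' asymptotic CpG o/e of a long simulated sequence is `p(G|C) / pi_G`.
#'
#' @inheritParams class_spec
#' @return The expected CpG o/e (a positive number; 1 when
#'   `cpg_depletion = 1`).
#' @export
expected_cpg_oe <- function(gc_fraction, cpg_depletion) {
  build_transition_matrix(gc_fraction, cpg_depletion)$expected_cpg_oe
}

#' Depletion factor required for a target CpG o/e
#'
#' Numerically inverts [expected_cpg_oe()] in `d` at fixed GC fraction, so
#' simulated classes can be specified by the CpG o/e they should realise
#' (e.g. 0.35 for a historically methylated class, 0.85 for an
#' unmethylated one).
#'
#' @param target_oe Desired asymptotic CpG o/e.
#' @inheritParams class_spec
#' @return The depletion factor `d` in (0, 1.5].
#' @export
depletion_for_cpg_oe <- function(target_oe, gc_fraction = 0.35) {
  lo <- 1e-8
  hi <- 1.5
  rng <- c(expected_cpg_oe(gc_fraction, lo), expected_cpg_oe(gc_fraction, hi))
  if (target_oe <= rng[[1L]] || target_oe >= rng[[2L]]) {
    stop_usage("target_oe %.3f outside achievable range (%.4f, %.4f) at gc = %.2f",
               target_oe, rng[[1L]], rng[[2L]], gc_fraction)
  }
  uniroot(function(d) expected_cpg_oe(gc_fraction, d) - target_oe,
          interval = c(lo, hi), tol = 1e-10)$root
}

#' Simulate one sequence from a class specification
#'
#' First base drawn from the stationary distribution, subsequent bases
#' from the depletion chain. Deterministic given `seed`.
#'
#' @param length Sequence length in bp (>= 2).
#' @param spec A [class_spec].
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @param id Sequence id for the output.
#' @return A length-1 named [Biostrings::DNAStringSet].
#' @export
generate_sequence <- function(length, spec, seed = NULL, id = "sim_seq") {
  stopifnot(inherits(spec, "class_spec"))
  if (length < 2) stop_usage("generate_sequence: length must be >= 2")
  tm <- build_transition_matrix(spec$gc_fraction, spec$cpg_depletion)
  s <- with_seed(seed, sim_markov_chain(as.integer(length), tm$P, tm$stationary))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- id
  out
}

#' Specification of a simulated annotated genome
#'
#' Bundles the gene classes with the gene count, the intergenic/intronic
#' composition and the scaffold layout. Class proportions must sum to 1.
#' Intergenic and intronic sequence is simulated with its own GC fraction
#' and depletion factor so that spliced gene bodies are statistically
#' distinguishable from genomic spans. Defaults emulate an AT-rich
#' arthropod genome without germ-line methylation: single gene class at
#' CpG o/e 0.7 and genome-wide background near 0.79.
#'
#' @param classes List of [class_spec] objects (proportions summing to 1).
#' @param n_genes Number of genes to simulate.
#' @param intergenic_gc GC fraction of intergenic/intronic sequence.
#' @param intergenic_depletion Depletion factor of intergenic/intronic
#'   sequence (default: the factor realising CpG o/e 0.79 at
#'   `intergenic_gc`).
#' @param scaffold_count Number of scaffolds genes are spread over.
#' @param seed Integer seed making every derived simulation reproducible.
#' @param intergenic_length_mean,intergenic_length_sd,intergenic_length_min
#'   Length distribution (bp) of intergenic spacers.
#' @param intron_length_mean,intron_length_sd,intron_length_min Length
#'   distribution (bp) of introns.
#' @param max_exons Maximum exons per gene (drawn uniformly from
#'   `1:max_exons`).
#' @return A `genome_sim_spec` object.
#' @export
genome_sim_spec <- function(classes, n_genes, intergenic_gc = 0.33,
                            intergenic_depletion = NULL, scaffold_count = 3L,
                            seed = 1L,
                            intergenic_length_mean = 1500,
                            intergenic_length_sd = 500,
                            intergenic_length_min = 200,
                            intron_length_mean = 300,
                            intron_length_sd = 150,
                            intron_length_min = 60,
                            max_exons = 3L) {
  if (inherits(classes, "class_spec")) classes <- list(classes)
  stopifnot(all(vapply(classes, inherits, logical(1), "class_spec")))
  props <- vapply(classes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9) {
    stop_usage("genome_sim_spec: class proportions must sum to 1 (got %.6f)",
               sum(props))
  }
  if (n_genes < 1) stop_usage("genome_sim_spec: n_genes must be >= 1")
  if (scaffold_count < 1) stop_usage("genome_sim_spec: scaffold_count must be >= 1")
  if (is.null(intergenic_depletion)) {
    intergenic_depletion <- depletion_for_cpg_oe(0.79, intergenic_gc)
  }
  structure(list(classes = classes, n_genes = as.integer(n_genes),
                 intergenic_gc = intergenic_gc,
                 intergenic_depletion = intergenic_depletion,
                 scaffold_count = as.integer(scaffold_count),
                 seed = as.integer(seed),
                 intergenic_length_mean = intergenic_length_mean,
                 intergenic_length_sd = intergenic_length_sd,
                 intergenic_length_min = intergenic_length_min,
                 intron_length_mean = intron_length_mean,
                 intron_length_sd = intron_length_sd,
                 intron_length_min = intron_length_min,
                 max_exons = as.integer(max_exons)),
            class = "genome_sim_spec")
}

#' Preset gene-class sets for the two canonical CpG o/e patterns
#'
#' `"unimodal"`: one class realising CpG o/e 0.7 — the pattern of a
#' species without historical germ-line methylation (e.g. a collembolan
#' or \emph{Drosophila}). `"bimodal"`: two equal classes realising 0.35
#' (historically methylated) and 0.85 (unmethylated) — the honeybee-like
#' pattern. Depletion factors are obtained analytically via
#' [depletion_for_cpg_oe()] at GC 0.35.
#'
#' @param modality `"unimodal"` or `"bimodal"`.
#' @param gc_fraction Baseline GC fraction of the classes.
#' @return A list of [class_spec] objects.
#' @export
default_gene_classes <- function(modality = c("unimodal", "bimodal"),
                                 gc_fraction = 0.35) {
  modality <- match.arg(modality)
  if (modality == "unimodal") {
    list(class_spec("no_methylation", 1,
                    depletion_for_cpg_oe(0.7, gc_fraction),
                    gc_fraction = gc_fraction))
  } else {
    list(class_spec("methylated", 0.5,
                    depletion_for_cpg_oe(0.35, gc_fraction),
                    gc_fraction = gc_fraction),
         class_spec("unmethylated", 0.5,
                    depletion_for_cpg_oe(0.85, gc_fraction),
                    gc_fraction = gc_fraction))
  }
}

draw_lengths <- function(n, mean, sd, minimum) {
  pmax(round(rnorm(n, mean, sd)), minimum)
}

#' Simulate a transcript (gene-body) set with known class truth
#'
#' Draws each gene's class from the class proportions, its length from the
#' class length distribution (normal, floored at `length_min`), and its
#' sequence from the class depletion chain. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [genome_sim_spec].
#' @return A list: `sequences` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame `gene_id`, `class`, `length`, `cpg_depletion`,
#'   `gc_fraction`, `expected_oe`).
#' @export
generate_gene_set <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    props <- vapply(spec$classes, `[[`, numeric(1), "proportion")
    cls_idx <- sample.int(length(spec$classes), n, replace = TRUE, prob = props)
    tms <- lapply(spec$classes, function(cl) {
      build_transition_matrix(cl$gc_fraction, cl$cpg_depletion)
    })
    gene_id <- sprintf("gene%05d", seq_len(n))
    seqs <- character(n)
    lens <- integer(n)
    for (i in seq_len(n)) {
      cl <- spec$classes[[cls_idx[[i]]]]
      lens[[i]] <- draw_lengths(1L, cl$length_mean, cl$length_sd, cl$length_min)
      seqs[[i]] <- sim_markov_chain(lens[[i]], tms[[cls_idx[[i]]]]$P,
                                    tms[[cls_idx[[i]]]]$stationary)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- gene_id
    truth <- data.frame(
      gene_id = gene_id,
      class = vapply(spec$classes, `[[`, character(1), "label")[cls_idx],
      length = lens,
      cpg_depletion = vapply(spec$classes, `[[`, numeric(1), "cpg_depletion")[cls_idx],
      gc_fraction = vapply(spec$classes, `[[`, numeric(1), "gc_fraction")[cls_idx],
      expected_oe = vapply(tms, `[[`, numeric(1), "expected_cpg_oe")[cls_idx],
      stringsAsFactors = FALSE
    )
    list(sequences = out, truth = truth)
  })
}

#' Simulate an annotated toy genome (FASTA + gene models + truth)
#'
#' Generates a transcript set as in [generate_gene_set()], splits each
#' transcript into 1..`max_exons` exons, inserts introns and intergenic
#' spacers drawn from the intergenic composition, assigns genes round-robin
#' to scaffolds and a random strand, and records exon coordinates as a
#' [gene_models] object. By construction
#' `extract_gene_bodies(genome, genes, mode = "spliced")` reproduces the
#' generated transcript of every gene exactly (minus-strand genes are laid
#' down as the reverse complement of the transcript construct).
#'
#' @param spec A [genome_sim_spec].
#' @return A list: `genome` (named [Biostrings::DNAStringSet]), `genes`
#'   ([gene_models]), `transcripts` (the generated exonic sequences),
#'   `truth` (data frame, one row per gene with class, strand, scaffold).
#' @export
generate_annotated_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  gs <- generate_gene_set(spec)
  with_seed(spec$seed + 1L, {
    n <- spec$n_genes
    ig_tm <- build_transition_matrix(spec$intergenic_gc, spec$intergenic_depletion)
    sim_ig <- function(len) sim_markov_chain(as.integer(len), ig_tm$P, ig_tm$stationary)

    scaffold_of <- rep(seq_len(spec$scaffold_count), length.out = n)
    strand_of <- sample(c("+", "-"), n, replace = TRUE)
    scaf_parts <- rep(list(character(0)), spec$scaffold_count)
    scaf_pos <- integer(spec$scaffold_count)  # current 0-based length
    exon_rows <- vector("list", n)

    for (i in seq_len(n)) {
      tx <- as.character(gs$sequences[[i]])
      L <- nchar(tx)
      max_ex <- min(spec$max_exons, max(1L, L %/% 100L))
      n_ex <- sample.int(max_ex, 1L)
      # split transcript into n_ex chunks of >= 50 bp where possible
      if (n_ex > 1L) {
        cuts <- sort(sample.int(L - 1L, n_ex - 1L))
        # enforce a minimal exon size by nudging degenerate cuts
        ok <- all(diff(c(0L, cuts, L)) >= 50L)
        if (!ok) {
          cuts <- round(seq_len(n_ex - 1L) * L / n_ex)
        }
      } else {
        cuts <- integer(0)
      }
      bounds <- c(0L, cuts, L)
      exon_seqs <- substring(tx, bounds[-length(bounds)] + 1L, bounds[-1L])
      introns <- if (n_ex > 1L) {
        vapply(draw_lengths(n_ex - 1L, spec$intron_length_mean,
                            spec$intron_length_sd, spec$intron_length_min),
               sim_ig, character(1))
      } else {
        character(0)
      }
      # interleave exons and introns into the gene's plus-strand construct
      parts <- character(2L * n_ex - 1L)
      parts[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
      if (n_ex > 1L) parts[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
      block <- paste(parts, collapse = "")
      B <- nchar(block)
      widths <- nchar(parts)
      ends <- cumsum(widths)
      starts <- ends - widths          # 0-based half-open within block
      ex_sel <- seq(1L, by = 2L, length.out = n_ex)
      ex_start <- starts[ex_sel]
      ex_end <- ends[ex_sel]
      if (strand_of[[i]] == "-") {
        block <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(block)))
        new_start <- B - ex_end
        new_end <- B - ex_start
        ord <- order(new_start)
        ex_start <- new_start[ord]
        ex_end <- new_end[ord]
      }
      sc <- scaffold_of[[i]]
      spacer <- sim_ig(draw_lengths(1L, spec$intergenic_length_mean,
                                    spec$intergenic_length_sd,
                                    spec$intergenic_length_min))
      offset <- scaf_pos[[sc]] + nchar(spacer)
      scaf_parts[[sc]] <- c(scaf_parts[[sc]], spacer, block)
      scaf_pos[[sc]] <- offset + B
      exon_rows[[i]] <- data.frame(
        gene_id = gs$truth$gene_id[[i]],
        seqid = sprintf("scaffold%d", sc),
        strand = strand_of[[i]],
        start = offset + ex_start,
        end = offset + ex_end,
        stringsAsFactors = FALSE
      )
    }
    # terminal spacer per scaffold
    for (sc in seq_len(spec$scaffold_count)) {
      spacer <- sim_ig(draw_lengths(1L, spec$intergenic_length_mean,
                                    spec$intergenic_length_sd,
                                    spec$intergenic_length_min))
      scaf_parts[[sc]] <- c(scaf_parts[[sc]], spacer)
    }
    genome <- Biostrings::DNAStringSet(
      vapply(scaf_parts, paste, character(1), collapse = ""))
    names(genome) <- sprintf("scaffold%d", seq_len(spec$scaffold_count))

    genes <- gene_models(do.call(rbind, exon_rows))
    truth <- gs$truth
    truth$scaffold <- sprintf("scaffold%d", scaffold_of)
    truth$strand <- strand_of
    list(genome = genome, genes = genes, transcripts = gs$sequences,
         truth = truth, spec = spec)
  })
}

#' Write a simulated genome to disk
#'
#' Emits `<prefix>.genome.fa`, `<prefix>.genes.gff3`,
#' `<prefix>.transcripts.fa` and `<prefix>.truth.tsv`. The seed is echoed
#' in a `##` comment of the truth table so every output is traceable to
#' its simulation.
#'
#' @param sim Result of [generate_annotated_genome()].
#' @param prefix Output path prefix.
#' @return The vector of paths written, invisibly.
#' @export
write_genome_sim <- function(sim, prefix) {
  paths <- c(genome = paste0(prefix, ".genome.fa"),
             gff = paste0(prefix, ".genes.gff3"),
             transcripts = paste0(prefix, ".transcripts.fa"),
             truth = paste0(prefix, ".truth.tsv"))
  write_fasta(sim$genome, paths[["genome"]])
  write_gff_genes(sim$genes, paths[["gff"]])
  write_fasta(sim$transcripts, paths[["transcripts"]])
  con <- file(paths[["truth"]], open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("## cpgoe simulation seed=%d", sim$spec$seed), con)
  write.table(sim$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
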