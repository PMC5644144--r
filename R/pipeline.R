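#' Frequency histogram of CpG o/e values
#'
#' Fixed-width bins (default 0.05) over `[0, 2)` plus an open-ended final
#' bin `[2, Inf)`, so counts always sum to the number of values.
#'
#' @param values Numeric vector of CpG o/e values (non-negative).
#' @param bin_width Bin width.
#' @param upper Start of the open-ended final bin.
#' @return A data frame: `bin_start`, `bin_end` (last is `Inf`), `count`.
#' @export
histogram_cpg_oe <- function(values, bin_width = 0.05, upper = 2) {
  if (bin_width <= 0) stop_usage("bin_width must be positive")
  edges <- seq(0, upper, by = bin_width)
  idx <- findInterval(values, c(edges, Inf), rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges))
  data.frame(bin_start = edges,
             bin_end = c(edges[-1L], Inf),
             count = counts)
}

new_report <- function(analysis, inputs, params, stats, histogram, call,
                       ranking, values, seed) {
  structure(list(
    analysis = analysis,
    inputs = inputs,
    params = params,
    stats = stats,
    histogram = histogram,
    call = call,
    ranking = ranking,
    overall_mean = mean(values),
    overall_sd = sd(values),
    n_values = length(values),
    seed = seed,
    version = as.character(packageVersion("cpgoe"))
  ), class = "cpgoe_report")
}

#' @export
print.cpgoe_report <- function(x, ...) {
  cat(sprintf("cpgoe analysis report: %s\n", x$analysis))
  cat(sprintf("  sequences analysed: %d (mean CpG o/e %.4f, sd %.4f)\n",
              x$n_values, x$overall_mean, x$overall_sd))
  ex <- x$inputs$exclusions
  if (!is.null(ex)) {
    cat(sprintf("  exclusions: %d too short, %d undefined (of %d input)\n",
                ex$too_short, ex$undefined, ex$n_input))
  }
  if (!is.null(x$call)) print(x$call)
  invisible(x)
}

#' Gene-body CpG o/e analysis with a methylation-signature call
#'
#' The full transcript-level survey: obtain gene bodies (directly from a
#' transcript FASTA, or extracted from a genome + GFF3), compute CpG o/e
#' per gene with [cpg_oe_table()], histogram the distribution, fit
#' Gaussian mixtures over the model grid and call the presence or absence
#' of the historical methylation signature with
#' [call_methylation_signature()].
#'
#' Exactly one input form must be supplied: `transcripts`, or `genome`
#' together with `genes`.
#'
#' @param transcripts Transcript sequences: FASTA path or
#'   [Biostrings::DNAStringSet].
#' @param genome Genome sequences (FASTA path or DNAStringSet), used with
#'   `genes`.
#' @param genes Gene models: GFF3 path or [gene_models] object.
#' @param mode,truncate_to Passed to [extract_gene_bodies()] when
#'   extracting from a genome.
#' @param min_length Minimum unambiguous length for [cpg_oe_table()].
#' @param bin_width Histogram bin width.
#' @param k_max,delta_bic_min,separation_min,n_starts Passed to
#'   [call_methylation_signature()].
#' @param seed Integer seed for the mixture fitting.
#' @param out_prefix If non-`NULL`, write `<prefix>.stats.tsv`,
#'   `<prefix>.report.json`, `<prefix>.hist.tsv` and
#'   `<prefix>.posteriors.tsv` via [write_report()].
#' @return A `cpgoe_report` (invisibly when `out_prefix` is given).
#' @export
run_gene_body_analysis <- function(transcripts = NULL, genome = NULL,
                                   genes = NULL, mode = "spliced",
                                   truncate_to = NULL, min_length = 200L,
                                   bin_width = 0.05, k_max = 4L,
                                   delta_bic_min = 6, separation_min = 2,
                                   n_starts = 10L, seed = NULL,
                                   out_prefix = NULL) {
  have_tx <- !is.null(transcripts)
  have_gen <- !is.null(genome) || !is.null(genes)
  if (have_tx == have_gen) {
    stop_usage("supply either `transcripts` or both `genome` and `genes`, not both/neither")
  }
  if (have_gen && (is.null(genome) || is.null(genes))) {
    stop_usage("genome-based input needs both `genome` and `genes`")
  }
  input_desc <- list()
  if (have_tx) {
    if (is.character(transcripts)) input_desc$transcripts_file <- transcripts
    bodies <- as_dna(transcripts, "transcripts")
    if (!is.null(truncate_to)) {
      w <- Biostrings::width(bodies)
      bodies <- Biostrings::subseq(bodies, 1L, pmin(w, as.integer(truncate_to)))
    }
  } else {
    if (is.character(genome)) input_desc$genome_file <- genome
    if (is.character(genes)) input_desc$gff_file <- genes
    gen <- as_dna(genome, "genome")
    gm <- if (is.character(genes)) read_gff_genes(genes) else genes
    bodies <- extract_gene_bodies(gen, gm, mode = mode, truncate_to = truncate_to)
  }
  input_desc$n_sequences <- length(bodies)

  stats <- cpg_oe_table(bodies, min_length = min_length)
  input_desc$exclusions <- attr(stats, "exclusions")
  values <- stats$cpg_oe
  hist <- histogram_cpg_oe(values, bin_width = bin_width)
  mc <- call_methylation_signature(values, delta_bic_min = delta_bic_min,
                                   separation_min = separation_min,
                                   k_max = k_max, n_starts = n_starts,
                                   seed = seed)
  params <- list(mode = mode, truncate_to = truncate_to,
                 min_length = min_length, bin_width = bin_width,
                 k_max = k_max, delta_bic_min = delta_bic_min,
                 separation_min = separation_min, n_starts = n_starts)
  rep <- new_report("gene_body", input_desc, params, stats, hist, mc,
                    mc$ranking, values, seed)
  if (!is.null(out_prefix)) {
    write_report(rep, out_prefix)
    return(invisible(rep))
  }
  rep
}

#' Genome-window CpG o/e analysis
#'
#' Tiles the genome into fixed windows with [tile_genome()], computes CpG
#' o/e per window and summarises the genome-wide distribution (mean, sd,
#' histogram). The modality call is optional here (`call_modality`): for
#' whole-genome fragments the headline number is the genome-wide mean.
#'
#' @param genome Genome FASTA path or [Biostrings::DNAStringSet].
#' @param window Window width in bp.
#' @param max_ambiguous_frac Maximum ambiguous-base fraction per window.
#' @param call_modality Also run [call_methylation_signature()] on the
#'   window values.
#' @inheritParams run_gene_body_analysis
#' @return A `cpgoe_report`.
#' @export
run_genome_window_analysis <- function(genome, window = 1000L,
                                       max_ambiguous_frac = 0.2,
                                       bin_width = 0.05,
                                       call_modality = FALSE, k_max = 4L,
                                       delta_bic_min = 6, separation_min = 2,
                                       n_starts = 10L, seed = NULL,
                                       out_prefix = NULL) {
  input_desc <- list()
  if (is.character(genome)) input_desc$genome_file <- genome
  gen <- as_dna(genome, "genome")
  wins <- tile_genome(gen, window = window,
                      max_ambiguous_frac = max_ambiguous_frac)
  meta <- S4Vectors::metadata(wins)
  if (length(wins) == 0L) {
    stop_data("no windows survive tiling (window = %d bp; %d discarded as ambiguous)",
              as.integer(window), meta$n_discarded_ambiguous)
  }
  input_desc$n_scaffolds <- length(gen)
  input_desc$windows <- meta

  # windows are all exactly `window` bp; retain those with a defined ratio
  stats <- cpg_oe_table(wins, min_length = 2L)
  input_desc$exclusions <- attr(stats, "exclusions")
  values <- stats$cpg_oe
  hist <- histogram_cpg_oe(values, bin_width = bin_width)
  mc <- NULL
  if (isTRUE(call_modality)) {
    mc <- call_methylation_signature(values, delta_bic_min = delta_bic_min,
                                     separation_min = separation_min,
                                     k_max = k_max, n_starts = n_starts,
                                     seed = seed)
  }
  params <- list(window = as.integer(window),
                 max_ambiguous_frac = max_ambiguous_frac,
                 bin_width = bin_width, call_modality = call_modality,
                 k_max = k_max, delta_bic_min = delta_bic_min,
                 separation_min = separation_min, n_starts = n_starts)
  rep <- new_report("genome_windows", input_desc, params, stats, hist, mc,
                    if (is.null(mc)) NULL else mc$ranking, values, seed)
  if (!is.null(out_prefix)) {
    write_report(rep, out_prefix)
    return(invisible(rep))
  }
  rep
}

#' Mixture fitting on a precomputed table of CpG o/e values
#'
#' Refits the mixture model and makes the modality call on values supplied
#' directly — a numeric vector, a data frame with a `cpg_oe` (or single
#' numeric) column, or a one-column TSV file.
#'
#' @param values Numeric vector, data frame or path to a tabular file.
#' @param header Does the file have a header line? (Only used for file
#'   input.)
#' @inheritParams run_gene_body_analysis
#' @return A `cpgoe_report`.
#' @export
run_fit_only <- function(values, header = TRUE, bin_width = 0.05,
                         k_max = 4L, delta_bic_min = 6, separation_min = 2,
                         n_starts = 10L, seed = NULL, out_prefix = NULL) {
  input_desc <- list()
  if (is.character(values) && length(values) == 1L) {
    input_desc$values_file <- values
    values <- read_values_table(values, header = header)
  } else if (is.data.frame(values)) {
    col <- if ("cpg_oe" %in% names(values)) "cpg_oe" else names(values)[[1L]]
    values <- values[[col]]
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop_data("non-finite values at rows: %s",
              paste(head(which(!is.finite(values)), 10L), collapse = ", "))
  }
  input_desc$n_values <- length(values)
  hist <- histogram_cpg_oe(values, bin_width = bin_width)
  mc <- call_methylation_signature(values, delta_bic_min = delta_bic_min,
                                   separation_min = separation_min,
                                   k_max = k_max, n_starts = n_starts,
                                   seed = seed)
  stats <- data.frame(seq_id = sprintf("value%d", seq_along(values)),
                      N = NA_real_, C = NA_real_, G = NA_real_,
                      CpG = NA_real_, cpg_oe = values)
  params <- list(bin_width = bin_width, k_max = k_max,
                 delta_bic_min = delta_bic_min,
                 separation_min = separation_min, n_starts = n_starts)
  rep <- new_report("fit_only", input_desc, params, stats, hist, mc,
                    mc$ranking, values, seed)
  if (!is.null(out_prefix)) {
    write_report(rep, out_prefix)
    return(invisible(rep))
  }
  rep
}

read_values_table <- function(path, header = TRUE) {
  if (!file.exists(path)) stop_data("values table not found: %s", path)
  tab <- read.delim(path, header = header, sep = "",
                    colClasses = "character", comment.char = "#")
  col <- if (header && "cpg_oe" %in% names(tab)) "cpg_oe" else names(tab)[[1L]]
  raw <- tab[[col]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !(raw %in% c("NA", "")))
  if (length(bad) > 0L) {
    stop_data("non-numeric entries in '%s' at data row(s): %s", path,
              paste(head(bad, 10L), collapse = ", "))
  }
  vals[!is.na(vals)]
}

serialize_fit <- function(f) {
  list(K = f$K, weights = f$weights, means = f$means,
       variances = f$variances, variance_family = f$variance_family,
       loglik = f$loglik, n_params = f$n_params, bic = f$bic,
       n_obs = f$n_obs, converged = f$converged, n_iter = f$n_iter)
}

#' Write an analysis report to disk
#'
#' Emits `<prefix>.stats.tsv` (per-sequence CpG o/e table),
#' `<prefix>.report.json` (inputs, parameter echo, ranked fits, call,
#' summary), `<prefix>.hist.tsv` (histogram) and, when a modality call was
#' made, `<prefix>.posteriors.tsv` (per-value posterior membership under
#' the selected fit). JSON output is deterministic for fixed inputs and
#' seed; set `timestamp = TRUE` to embed the wall-clock time.
#'
#' @param report A `cpgoe_report`.
#' @param out_prefix Output path prefix.
#' @param timestamp Embed the current time in the JSON report.
#' @return Named vector of paths written, invisibly.
#' @export
write_report <- function(report, out_prefix, timestamp = FALSE) {
  stopifnot(inherits(report, "cpgoe_report"))
  paths <- c(stats = paste0(out_prefix, ".stats.tsv"),
             report = paste0(out_prefix, ".report.json"),
             hist = paste0(out_prefix, ".hist.tsv"))
  write_cpg_table(report$stats, paths[["stats"]])
  write.table(report$histogram, paths[["hist"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  body <- list(
    analysis = report$analysis,
    version = report$version,
    seed = report$seed,
    inputs = report$inputs,
    params = report$params,
    overall_mean = report$overall_mean,
    overall_sd = report$overall_sd,
    n_values = report$n_values,
    histogram = report$histogram,
    ranking = if (!is.null(report$ranking)) lapply(report$ranking, serialize_fit),
    call = if (!is.null(report$call)) list(
      verdict = report$call$verdict,
      delta_bic = report$call$delta_bic,
      separation = report$call$separation,
      delta_bic_min = report$call$delta_bic_min,
      separation_min = report$call$separation_min,
      best_K = report$call$best_fit$K,
      best_family = report$call$best_fit$variance_family
    )
  )
  if (isTRUE(timestamp)) body$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(body, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (!is.null(report$call)) {
    paths <- c(paths, posteriors = paste0(out_prefix, ".posteriors.tsv"))
    cls <- classify(report$stats$cpg_oe, report$call$best_fit)
    post <- data.frame(seq_id = report$stats$seq_id,
                       cpg_oe = report$stats$cpg_oe,
                       cls$posterior,
                       label = cls$label)
    write.table(post, paths[["posteriors"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
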