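#' Read a FASTA file of nucleotide sequences
#'
#' Wraps [Biostrings::readDNAStringSet()] with the conventions used
#' throughout this package: the sequence id is the header token up to the
#' first whitespace, residues are upper-cased, duplicate ids are an error,
#' and an empty file yields an empty set with a warning. Plain and
#' gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", ">b", "NNGC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_data("FASTA file not found: %s", path)
  check_fasta_header_first(path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (length(x) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(x)
  }
  if (any(!nzchar(names(x)))) {
    stop_data("FASTA file '%s' contains an entry with an empty id", path)
  }
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup) > 0L) {
    stop_data("duplicate sequence ids in '%s': %s", path,
              paste(dup, collapse = ", "))
  }
  x
}

# FASTA must open with a header line; report the offending line number
# otherwise (Biostrings' own error does not).
check_fasta_header_first <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) return(invisible(TRUE))  # empty file
    lineno <- lineno + 1L
    if (nzchar(trimws(ln))) break
  }
  if (!startsWith(trimws(ln), ">")) {
    stop_data("malformed FASTA '%s': line %d contains sequence before the first '>' header",
              path, lineno)
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] (or coercible object).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_dna(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Gene models: exon structures on genome scaffolds
#'
#' A `gene_models` object is a data frame with one row per exon and columns
#' `gene_id`, `seqid`, `strand` (`+`/`-`) and `start`/`end` in 0-based
#' half-open coordinates (converted from GFF3's 1-based inclusive
#' convention on read). Exons of a gene must be non-overlapping and are
#' stored sorted by start.
#'
#' @param exons A data frame with columns `gene_id`, `seqid`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @return A `gene_models` object (a validated, sorted data frame).
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "seqid", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss) > 0L) {
    stop_usage("gene_models: missing columns: %s", paste(miss, collapse = ", "))
  }
  exons <- as.data.frame(exons)[, need]
  exons$gene_id <- as.character(exons$gene_id)
  exons$seqid <- as.character(exons$seqid)
  exons$strand <- as.character(exons$strand)
  if (nrow(exons) == 0L) stop_data("gene_models: no exons")
  if (!all(exons$strand %in% c("+", "-"))) {
    stop_data("gene_models: strand must be '+' or '-'")
  }
  if (any(exons$end <= exons$start)) {
    stop_data("gene_models: exon with end <= start")
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    if (length(unique(e$seqid)) != 1L) {
      stop_data("gene '%s' has exons on multiple scaffolds", g)
    }
    if (length(unique(e$strand)) != 1L) {
      stop_data("gene '%s' has exons on both strands", g)
    }
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop_data("gene '%s' has overlapping exons", g)
    }
  }
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d scaffold(s)\n",
              length(unique(x$gene_id)), nrow(x),
              length(unique(x$seqid))))
  NextMethod()
}

#' Read gene models from a GFF3 file
#'
#' Parses exon features and resolves each to a gene id by climbing the
#' `Parent` chain (exon -> mRNA/transcript -> gene, or exon -> gene
#' directly). If an exon's parent id is not defined elsewhere in the file
#' it is taken to be the gene id itself. Exons that cannot be resolved are
#' skipped with a warning; the number skipped is recorded in
#' `attr(x, "n_skipped")`. GFF3 1-based inclusive coordinates are
#' converted to the package's internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop_data("GFF3 file not found: %s", path)
  check_gff_coordinates(path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  id <- if (!is.null(g$ID)) as.character(g$ID) else rep(NA_character_, length(g))
  parent <- if (!is.null(g$Parent)) {
    vapply(g$Parent, function(p) if (length(p) > 0L) p[[1L]] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(g))
  }
  id2type <- setNames(type[!is.na(id)], id[!is.na(id)])
  id2parent <- setNames(parent[!is.na(id)], id[!is.na(id)])

  resolve_gene <- function(p) {
    for (depth in 1:10) {
      if (is.na(p)) return(NA_character_)
      ty <- id2type[p]
      if (is.na(ty)) return(p)            # undefined parent: take it as the gene id
      if (ty == "gene") return(p)
      p <- id2parent[p]
    }
    NA_character_
  }

  is_exon <- type == "exon"
  if (!any(is_exon)) stop_data("GFF3 '%s' contains no exon features", path)
  ex <- g[is_exon]
  gene_id <- vapply(parent[is_exon], resolve_gene, character(1))
  skipped <- is.na(gene_id)
  if (any(skipped)) {
    warning(sum(skipped), " exon(s) without a resolvable gene parent were skipped")
  }
  ex <- ex[!skipped]
  gene_id <- gene_id[!skipped]
  if (length(ex) == 0L) stop_data("GFF3 '%s': no exon resolved to a gene", path)

  models <- gene_models(data.frame(
    gene_id = gene_id,
    seqid = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  ))
  attr(models, "n_skipped") <- sum(skipped)
  models
}

# Pre-scan GFF3 text so coordinate errors carry a line number.
check_gff_coordinates <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  lineno <- 0L
  repeat {
    lns <- readLines(con, n = 5000L)
    if (length(lns) == 0L) break
    for (i in seq_along(lns)) {
      lineno <- lineno + 1L
      ln <- lns[[i]]
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 9L) next
      s <- suppressWarnings(as.numeric(f[[4L]]))
      e <- suppressWarnings(as.numeric(f[[5L]]))
      if (is.na(s) || is.na(e) || e < s) {
        stop_data("malformed GFF3 '%s': line %d has end < start (or non-numeric coordinates)",
                  path, lineno)
      }
    }
  }
  invisible(TRUE)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per gene plus its `exon` children, converting
#' the internal 0-based half-open coordinates back to GFF3's 1-based
#' inclusive convention. `read_gff_genes(write_gff_genes(x))` is the
#' identity on well-formed models.
#'
#' @param models A [gene_models] object.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(models, path, source = "cpgoe") {
  stopifnot(inherits(models, "gene_models"))
  lines <- c("##gff-version 3")
  for (g in unique(models$gene_id)) {
    e <- models[models$gene_id == g, , drop = FALSE]
    gs <- min(e$start) + 1L
    ge <- max(e$end)
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              e$seqid[[1L]], source, gs, ge, e$strand[[1L]], g))
    for (i in seq_len(nrow(e))) {
      lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                                e$seqid[[i]], source, e$start[[i]] + 1L, e$end[[i]],
                                e$strand[[i]], g, i, g))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract gene-body sequences from a genome
#'
#' Builds one sequence per gene, either by splicing (concatenating exon
#' sequences in genomic order; the default, matching a transcript-level
#' analysis) or by taking the genomic span from the first exon start to
#' the last exon end (introns included). Minus-strand genes are
#' reverse-complemented after extraction so every output reads 5'->3' in
#' the gene's own sense. This choice cannot affect CpG o/e, which is
#' strand-symmetric, but keeps the sequences biologically interpretable.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or FASTA path).
#' @param genes A [gene_models] object.
#' @param mode `"spliced"` (exons only) or `"span"` (first to last exon,
#'   introns included).
#' @param truncate_to Optional length in bp. Sequences longer than this are
#'   cut to their first `truncate_to` bases (5'-anchored); shorter
#'   sequences are kept full-length. Use `1000` to reproduce a uniform
#'   1-kb truncation.
#' @return A [Biostrings::DNAStringSet] named by `gene_id`.
#' @export
extract_gene_bodies <- function(genome, genes, mode = c("spliced", "span"),
                                truncate_to = NULL) {
  mode <- match.arg(mode)
  genome <- as_dna(genome, "genome")
  stopifnot(inherits(genes, "gene_models"))
  if (!is.null(truncate_to) && (!is.numeric(truncate_to) || truncate_to < 1)) {
    stop_usage("truncate_to must be a positive length in bp")
  }

  missing_scaf <- setdiff(unique(genes$seqid), names(genome))
  if (length(missing_scaf) > 0L) {
    bad <- unique(genes$gene_id[genes$seqid %in% missing_scaf])
    stop_data("scaffold(s) %s not present in genome (genes: %s)",
              paste(missing_scaf, collapse = ", "),
              paste(head(bad, 5L), collapse = ", "))
  }
  scaf_len <- setNames(Biostrings::width(genome), names(genome))
  over <- genes$end > scaf_len[genes$seqid]
  if (any(over)) {
    stop_data("gene(s) %s extend beyond scaffold bounds",
              paste(unique(genes$gene_id[over]), collapse = ", "))
  }

  gene_ids <- unique(genes$gene_id)
  if (mode == "spliced") {
    # extract all exons per scaffold in one call, then concatenate per gene
    exon_chr <- character(nrow(genes))
    for (sc in unique(genes$seqid)) {
      idx <- which(genes$seqid == sc)
      rng <- IRanges::IRanges(start = genes$start[idx] + 1L, end = genes$end[idx])
      exon_chr[idx] <- as.character(Biostrings::extractAt(genome[[sc]], rng))
    }
    body_chr <- vapply(split(exon_chr, genes$gene_id)[gene_ids],
                       paste, character(1), collapse = "")
  } else {
    first <- genes[!duplicated(genes$gene_id), , drop = FALSE]
    span_start <- tapply(genes$start, genes$gene_id, min)[gene_ids]
    span_end <- tapply(genes$end, genes$gene_id, max)[gene_ids]
    sc <- setNames(first$seqid, first$gene_id)[gene_ids]
    body_chr <- vapply(seq_along(gene_ids), function(i) {
      as.character(Biostrings::subseq(genome[[sc[[i]]]],
                                      start = span_start[[i]] + 1L,
                                      end = span_end[[i]]))
    }, character(1))
  }
  out <- Biostrings::DNAStringSet(body_chr)
  names(out) <- gene_ids

  strand <- setNames(genes$strand[!duplicated(genes$gene_id)],
                     genes$gene_id[!duplicated(genes$gene_id)])[gene_ids]
  neg <- strand == "-"
  if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])

  if (!is.null(truncate_to)) {
    w <- Biostrings::width(out)
    out <- Biostrings::subseq(out, start = 1L, end = pmin(w, as.integer(truncate_to)))
  }
  out
}

#' Tile a genome into fixed-width windows
#'
#' Cuts each scaffold into non-overlapping windows starting at position 0;
#' the trailing partial window is discarded. Windows whose fraction of
#' ambiguous bases (anything outside A/C/G/T) exceeds
#' `max_ambiguous_frac` are discarded and counted. Window ids are
#' `"<scaffold>:<0-based start>"`.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or FASTA path).
#' @param window Window width in bp (default 1000, the 1-kb fragments of a
#'   whole-genome CpG survey).
#' @param max_ambiguous_frac Maximum tolerated fraction of ambiguous bases
#'   per window.
#' @return A [Biostrings::DNAStringSet] of windows, all exactly `window`
#'   bp. `S4Vectors::metadata()` carries `n_windows_total`,
#'   `n_discarded_ambiguous` and `n_kept`.
#' @export
tile_genome <- function(genome, window = 1000L, max_ambiguous_frac = 0.2) {
  if (!is.numeric(window) || window < 2) {
    stop_usage("window must be >= 2 bp (got %s)", format(window))
  }
  window <- as.integer(window)
  genome <- as_dna(genome, "genome")

  pieces <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[[i]]
    k <- L %/% window
    if (k == 0L) {
      pieces[[i]] <- Biostrings::DNAStringSet()
      next
    }
    starts0 <- (seq_len(k) - 1L) * window
    w <- Biostrings::extractAt(genome[[i]],
                               IRanges::IRanges(start = starts0 + 1L, width = window))
    w <- Biostrings::DNAStringSet(w)
    names(w) <- sprintf("%s:%d", names(genome)[[i]], starts0)
    pieces[[i]] <- w
  }
  out <- do.call(c, pieces)
  n_total <- length(out)
  if (n_total > 0L) {
    good <- rowSums(Biostrings::letterFrequency(out, c("A", "C", "G", "T")))
    amb_frac <- 1 - good / window
    keep <- amb_frac <= max_ambiguous_frac
    out <- out[keep]
  }
  S4Vectors::metadata(out) <- list(
    window = window,
    n_windows_total = n_total,
    n_discarded_ambiguous = n_total - length(out),
    n_kept = length(out)
  )
  out
}
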