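# Internal helpers: classed conditions (so the CLI can map them to exit
# codes) and seed scoping.

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cpgoe_usage_error", "cpgoe_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cpgoe_data_error", "cpgoe_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cpgoe_numerical_error", "cpgoe_error")))
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a path or XStringSet-like object to a named DNAStringSet.
as_dna <- function(x, what = "sequences") {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_fasta(x))
  }
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  if (methods::is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- "seq1"
    return(out)
  }
  stop_usage("cannot interpret %s: expected a FASTA path, DNAStringSet or character vector",
             what)
}
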