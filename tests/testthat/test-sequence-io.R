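test_that("read_fasta normalises case, trims ids at whitespace, round-trips", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a extra description", "acgt", ">b", "NNGC"), fa)
  x <- read_fasta(fa)
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x), c(a = "ACGT", b = "NNGC"))

  # round trip: write + re-read reproduces ids and residues exactly
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, out)
  y <- read_fasta(out)
  expect_identical(as.character(y), as.character(x))

  # gzip round trip
  gz <- withr::local_tempfile(fileext = ".fa.gz")
  write_fasta(x, gz)
  expect_identical(as.character(read_fasta(gz)), as.character(x))
})

test_that("read_fasta rejects malformed input and flags degenerate files", {
  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_fasta(dup), "duplicate.*a", class = "cpgoe_data_error")

  noheader <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">a", "ACGT"), noheader)
  expect_error(read_fasta(noheader), "line 1", class = "cpgoe_data_error")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_warning(x <- read_fasta(empty), "no sequences")
  expect_length(x, 0)
})

test_that("read_gff_genes converts 1-based inclusive to 0-based half-open", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scf1\tsim\tgene\t101\t400\t.\t+\t.\tID=g1",
    "scf1\tsim\tmRNA\t101\t400\t.\t+\t.\tID=m1;Parent=g1",
    "scf1\tsim\texon\t101\t200\t.\t+\t.\tID=e1;Parent=m1",
    "scf1\tsim\texon\t301\t400\t.\t+\t.\tID=e2;Parent=m1",
    "scf1\tsim\tgene\t500\t600\t.\t-\t.\tID=g2",
    "scf1\tsim\texon\t500\t600\t.\t-\t.\tParent=g2"
  ), gff)
  m <- read_gff_genes(gff)
  g1 <- m[m$gene_id == "g1", ]
  expect_equal(g1$start, c(100, 300))
  expect_equal(g1$end, c(200, 400))
  expect_equal(unique(m$strand[m$gene_id == "g2"]), "-")
  expect_equal(sort(unique(m$gene_id)), c("g1", "g2"))
})

test_that("read_gff_genes reports coordinate errors with a line number and skips orphans", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scf1\tsim\tgene\t100\t200\t.\t+\t.\tID=g1",
    "scf1\tsim\texon\t250\t210\t.\t+\t.\tParent=g1"
  ), bad)
  expect_error(read_gff_genes(bad), "line 3", class = "cpgoe_data_error")

  orphan <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scf1\tsim\tgene\t1\t100\t.\t+\t.\tID=g1",
    "scf1\tsim\texon\t1\t100\t.\t+\t.\tParent=g1",
    "scf1\tsim\texon\t200\t300\t.\t+\t.\tID=lost"
  ), orphan)
  expect_warning(m <- read_gff_genes(orphan), "skipped")
  expect_equal(unique(m$gene_id), "g1")
  expect_equal(attr(m, "n_skipped"), 1L)
})

test_that("gene models survive a GFF3 write/read round trip", {
  m <- toy_models()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(m, gff)
  m2 <- read_gff_genes(gff)
  for (col in c("gene_id", "seqid", "strand", "start", "end")) {
    expect_equal(m2[[col]], m[[col]])
  }
})

test_that("extract_gene_bodies splices, spans and reverse-complements", {
  gen <- toy_genome()
  m <- toy_models()
  spliced <- extract_gene_bodies(gen, m, mode = "spliced")
  # g1: exons [0,4) and [8,12) of AACCGGTTAACC -> AACC + AACC
  expect_equal(as.character(spliced[["g1"]]), "AACCAACC")
  # g2: minus-strand [0,4) of ACGT... -> revcomp("ACGT") = "ACGT" (palindrome)
  expect_equal(as.character(spliced[["g2"]]), "ACGT")

  span <- extract_gene_bodies(gen, m, mode = "span")
  expect_equal(as.character(span[["g1"]]), "AACCGGTTAACC")

  # spliced output length equals the sum of exon lengths
  expect_equal(Biostrings::width(spliced)[[1]], sum(4, 4))

  # non-palindromic minus-strand check
  m3 <- gene_models(data.frame(gene_id = "g3", seqid = "scf1", strand = "-",
                               start = 2L, end = 6L))
  expect_equal(as.character(extract_gene_bodies(gen, m3)[["g3"]]),
               revcomp_chr("CCGG"))
})

test_that("extract_gene_bodies truncation is 5prime-anchored and keeps short genes", {
  gen <- toy_genome()
  m <- toy_models()
  tr <- extract_gene_bodies(gen, m, mode = "spliced", truncate_to = 5)
  expect_equal(as.character(tr[["g1"]]), "AACCA")  # first 5 of AACCAACC
  expect_equal(as.character(tr[["g2"]]), "ACGT")   # shorter than 5: untouched
})

test_that("extract_gene_bodies validates scaffolds and bounds", {
  gen <- toy_genome()
  m <- gene_models(data.frame(gene_id = "gx", seqid = "nope", strand = "+",
                              start = 0L, end = 4L))
  expect_error(extract_gene_bodies(gen, m), "gx", class = "cpgoe_data_error")
  m2 <- gene_models(data.frame(gene_id = "gy", seqid = "scf1", strand = "+",
                               start = 0L, end = 50L))
  expect_error(extract_gene_bodies(gen, m2), "bounds", class = "cpgoe_data_error")
})

test_that("tile_genome windows are exact, partials dropped, ambiguity filtered", {
  set.seed(42)
  gen <- Biostrings::DNAStringSet(c(s1 = random_dna(2500), s2 = random_dna(999)))
  w <- tile_genome(gen, window = 1000)
  expect_equal(length(w), 2L)
  expect_true(all(Biostrings::width(w) == 1000))
  expect_equal(names(w), c("s1:0", "s1:1000"))
  md <- S4Vectors::metadata(w)
  expect_equal(md$n_windows_total, 2L)  # floor(2500/1000) + floor(999/1000)
  expect_equal(md$n_discarded_ambiguous, 0L)

  # a window with 30% N is discarded and counted
  seq_n <- paste0(random_dna(700), strrep("N", 300), random_dna(1000))
  wn <- tile_genome(Biostrings::DNAStringSet(c(a = seq_n)), window = 1000,
                    max_ambiguous_frac = 0.2)
  expect_equal(S4Vectors::metadata(wn)$n_discarded_ambiguous, 1L)
  expect_equal(length(wn), 1L)

  expect_error(tile_genome(gen, window = 1), class = "cpgoe_usage_error")
})

test_that("tile_genome total window count matches the floor arithmetic", {
  set.seed(7)
  lens <- c(3100, 1000, 1999, 500)
  gen <- Biostrings::DNAStringSet(setNames(
    vapply(lens, random_dna, character(1)),
    paste0("c", seq_along(lens))))
  w <- tile_genome(gen, window = 1000)
  expect_equal(S4Vectors::metadata(w)$n_windows_total, sum(lens %/% 1000))
  expect_equal(length(w), sum(lens %/% 1000))
})
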