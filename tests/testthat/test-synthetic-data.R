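test_that("transition matrix: baseline case is the i.i.d. chain", {
  tm <- build_transition_matrix(0.5, 1.0)
  expect_equal(unname(tm$P), matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(unname(tm$stationary), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(tm$expected_cpg_oe, 1, tolerance = 1e-12)
})

test_that("transition matrix rows are stochastic and parameters are guarded", {
  for (gc in c(0.2, 0.35, 0.6)) {
    for (d in c(0.1, 0.5, 1.0, 1.4)) {
      tm <- build_transition_matrix(gc, d)
      expect_equal(unname(rowSums(tm$P)), rep(1, 4), tolerance = 1e-12)
      expect_equal(sum(tm$stationary), 1, tolerance = 1e-12)
      # stationarity: pi P = pi
      expect_equal(as.numeric(tm$stationary %*% tm$P),
                   unname(tm$stationary), tolerance = 1e-10)
    }
  }
  expect_error(build_transition_matrix(0.5, 0), class = "cpgoe_usage_error")
  expect_error(build_transition_matrix(0.5, -0.2), class = "cpgoe_usage_error")
  expect_error(build_transition_matrix(0.5, 1.6), class = "cpgoe_usage_error")
  expect_error(build_transition_matrix(0.01, 0.5), class = "cpgoe_usage_error")
})

test_that("stationary distribution matches an independent power-iteration oracle", {
  for (d in c(0.3, 0.7, 1.2)) {
    tm <- build_transition_matrix(0.4, d)
    expect_equal(unname(tm$stationary), stationary_power(tm$P),
                 tolerance = 1e-9)
  }
})

test_that("depletion_for_cpg_oe inverts the analytic map", {
  for (target in c(0.35, 0.7, 0.85, 1.0)) {
    d <- depletion_for_cpg_oe(target, 0.35)
    expect_equal(expected_cpg_oe(0.35, d), target, tolerance = 1e-6)
  }
  expect_error(depletion_for_cpg_oe(2.5, 0.35), class = "cpgoe_usage_error")
})

test_that("simulated sequences realise the analytic CpG o/e", {
  cl <- function(d) class_spec("x", 1, d, gc_fraction = 0.4)
  for (d in c(0.3, 1.0)) {
    s <- generate_sequence(100000, cl(d), seed = 17)
    emp <- cpg_oe(s)$cpg_oe
    expect_equal(emp, expected_cpg_oe(0.4, d), tolerance = 0.05)
  }
})

test_that("sequence generation is deterministic given the seed", {
  cl <- class_spec("x", 1, 0.5)
  a <- generate_sequence(2000, cl, seed = 99)
  b <- generate_sequence(2000, cl, seed = 99)
  expect_identical(as.character(a), as.character(b))
  c2 <- generate_sequence(2, cl, seed = 1)
  expect_identical(as.character(c2), as.character(generate_sequence(2, cl, seed = 1)))
  d2 <- generate_sequence(2000, cl, seed = 100)
  expect_false(identical(as.character(a), as.character(d2)))
})

test_that("dinucleotide frequencies of simulated sequence match the chain", {
  # chi-square goodness of fit of observed dinucleotide counts against
  # pi_i * P_ij; expect no rejection at alpha = 0.01 in >= 18 of 20 seeds
  tm <- build_transition_matrix(0.35, 0.5)
  expected_p <- as.numeric(t(tm$P * as.numeric(tm$stationary)))
  labs <- as.vector(t(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  pass <- 0L
  for (seed in 1:20) {
    s <- generate_sequence(20000, class_spec("x", 1, 0.5), seed = 1000 + seed)
    counts <- as.numeric(count_dinucleotides(s)[1, labs])
    p <- suppressWarnings(chisq.test(counts, p = expected_p)$p.value)
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 18L)
})

test_that("realised mean CpG o/e increases strictly with the depletion factor", {
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  means <- vapply(seq_along(grid), function(i) {
    s <- generate_sequence(50000, class_spec("x", 1, grid[[i]]), seed = 500 + i)
    cpg_oe(s)$cpg_oe
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("gene sets follow the class proportions and are reproducible", {
  classes <- default_gene_classes("bimodal")
  spec <- genome_sim_spec(classes, n_genes = 2000, seed = 123)
  gs <- generate_gene_set(spec)
  expect_equal(length(gs$sequences), 2000)
  expect_equal(nrow(gs$truth), 2000)
  n_meth <- sum(gs$truth$class == "methylated")
  # binomial(2000, 0.5) 99% bounds
  expect_true(abs(n_meth - 1000) <= qnorm(0.995) * sqrt(2000 * 0.25))
  expect_true(all(gs$truth$length >= 200))

  # byte-identical FASTA and truth table on re-run
  gs2 <- generate_gene_set(spec)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(gs$sequences, f1); write_fasta(gs2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(gs$truth, gs2$truth)

  one <- genome_sim_spec(default_gene_classes("unimodal"), n_genes = 100,
                         seed = 5)
  gs1 <- generate_gene_set(one)
  expect_equal(unique(gs1$truth$class), "no_methylation")
})

test_that("class proportions must sum to one", {
  bad <- list(class_spec("a", 0.6, 0.5), class_spec("b", 0.6, 0.9))
  expect_error(genome_sim_spec(bad, n_genes = 10), "sum to 1",
               class = "cpgoe_usage_error")
})

test_that("annotated genomes are consistent and round-trip exactly", {
  spec <- genome_sim_spec(default_gene_classes("bimodal"), n_genes = 120,
                          scaffold_count = 3, seed = 321)
  sim <- generate_annotated_genome(spec)
  expect_equal(length(sim$genome), 3)
  expect_equal(length(unique(sim$genes$gene_id)), 120)

  # all exons within scaffold bounds
  scaf_len <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  expect_true(all(sim$genes$end <= scaf_len[sim$genes$seqid]))
  expect_true(all(sim$genes$start >= 0))

  # genes do not overlap on a scaffold
  for (sc in names(sim$genome)) {
    e <- sim$genes[sim$genes$seqid == sc, ]
    spans <- do.call(rbind, lapply(split(e, e$gene_id), function(x) {
      data.frame(s = min(x$start), e = max(x$end))
    }))
    spans <- spans[order(spans$s), ]
    if (nrow(spans) > 1) {
      expect_true(all(spans$s[-1] >= spans$e[-nrow(spans)]))
    }
  }

  # spliced extraction reproduces every generated transcript byte-exactly
  ext <- extract_gene_bodies(sim$genome, sim$genes, mode = "spliced")
  expect_identical(as.character(ext[names(sim$transcripts)]),
                   as.character(sim$transcripts))

  # file round trip: written FASTA + GFF3 reproduce the extraction
  p <- write_genome_sim(sim, file.path(withr::local_tempdir(), "sim"))
  ext2 <- extract_gene_bodies(read_fasta(p[["genome"]]),
                              read_gff_genes(p[["gff"]]), mode = "spliced")
  expect_identical(as.character(ext2[names(sim$transcripts)]),
                   as.character(sim$transcripts))
})

test_that("intergenic composition differs from gene-body composition in span mode", {
  # spliced bodies should realise the class target; spans (introns included)
  # drift toward the intergenic composition for multi-exon genes
  spec <- genome_sim_spec(
    list(class_spec("hot", 1, depletion_for_cpg_oe(1.0, 0.35))),
    n_genes = 60, intergenic_depletion = depletion_for_cpg_oe(0.3, 0.33),
    seed = 55)
  sim <- generate_annotated_genome(spec)
  spliced <- mean(cpg_oe_table(extract_gene_bodies(sim$genome, sim$genes,
                                                   "spliced"))$cpg_oe)
  span <- mean(cpg_oe_table(extract_gene_bodies(sim$genome, sim$genes,
                                                "span"))$cpg_oe)
  expect_gt(spliced, span)
})
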