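test_that("generated genomes hit their GC target and are reproducible", {
  g <- generate_genome(0.5, 100000, 2, seed = 1)
  gc <- gc_content(g$sequence)
  expect_gte(gc, 0.47)
  expect_lte(gc, 0.53)
  g2 <- generate_genome(0.5, 100000, 2, seed = 1)
  expect_identical(g$sequence, g2$sequence)
  expect_false(identical(g$sequence,
                         generate_genome(0.5, 100000, 2, seed = 2)$sequence))
  expect_error(generate_genome(1.2, 5000), "gc_target")
  expect_error(generate_genome(0.5, 100), "length")
})

test_that("genomes at distinct GC targets produce separated contigs", {
  g_lo <- generate_genome(0.35, 60000, 2, seed = 5)
  g_hi <- generate_genome(0.65, 60000, 2, seed = 6)
  c_lo <- fragment_contigs(g_lo, 30, 5000, 1000, 1000, seed = 7)
  c_hi <- fragment_contigs(g_hi, 30, 5000, 1000, 1000, seed = 8)
  expect_gt(mean(c_hi$gc) - mean(c_lo$gc), 0.2)
})

test_that("fragmentation respects the floor, labels and determinism", {
  g <- generate_genome(0.5, 50000, 1, seed = 9)
  empty <- fragment_contigs(g, 0, 5000, 1000, 1000, seed = 1)
  expect_equal(nrow(empty), 0L)

  ctg <- fragment_contigs(g, 200, 2000, 800, 300, seed = 2)
  expect_true(all(ctg$length >= 300))
  expect_true(all(ctg$truth_label == g$genome_id))
  expect_identical(ctg, fragment_contigs(g, 200, 2000, 800, 300, seed = 2))
  small <- generate_genome(0.5, 1000, 0, seed = 1)
  expect_error(fragment_contigs(small, 5, 5000, 0, 2000, seed = 1),
               "shorter")
})

test_that("evolved pairs keep frame, avoid stops and honour omega limits", {
  p0 <- evolve_ortholog_pair(120, 0, 80, 0, seed = 13)
  prot <- function(x) strainpop:::translate_cds(x)
  expect_identical(prot(p0$cds_a), prot(p0$cds_b))

  pf <- evolve_ortholog_pair(120, 0.5, 0, 0, seed = 14)
  expect_identical(pf$cds_a, pf$cds_b)

  set.seed(1)
  for (i in 1:5) {
    p <- evolve_ortholog_pair(100, runif(1, 0, 1.5), 50, runif(1, 0, 3),
                              seed = 20 + i)
    for (cds in c(p$cds_a, p$cds_b)) {
      expect_equal(nchar(cds) %% 3, 0)
      codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      expect_false(any(.ORACLE_CODE[codons] == "*"))
    }
  }
  expect_error(evolve_ortholog_pair(50, 0.5), "n_codons")
  expect_error(evolve_ortholog_pair(120, 2.0), "omega_true")
})

test_that("snp profiles reproduce the no-differentiation limit", {
  snps <- generate_snp_profiles(100, n_pops = 2, divergence = 0,
                                depth = 1000000L, seed = 3)
  expect_lt(abs(pairwise_fst(snps, "pop_01", "pop_02")), 0.01)
  mid <- generate_snp_profiles(200, n_pops = 3, divergence = 0.3, depth = 80,
                               seed = 4)
  f <- pairwise_fst(mid, "pop_01", "pop_03")
  expect_gt(f, 0)
  expect_lt(f, 1)
  expect_error(generate_snp_profiles(0, 2, 0.1, 50), "n_snps")
  expect_error(generate_snp_profiles(10, 2, 0.1, 5), "depth")
})

test_that("community generation honours the configured truth tables", {
  cfg <- community_config(genome_gc = c(0.35, 0.65), genome_length = 20000L,
                          contigs_per_genome = 10L, contig_len_mean = 3000,
                          contig_len_sd = 500, contig_min_len = 1000,
                          n_core = 12L, n_free = 5L, n_endo = 3L,
                          n_unassigned = 2L, gene_codons = 80L,
                          n_pairs = 3L, pair_codons = 120L,
                          n_snps = 20L, n_taxa = 10L)
  cm <- generate_community(cfg, seed = 42)
  counts <- table(cm$gene_truth$category)
  expect_equal(unname(counts[c("core", "free_living", "endosymbiont")]),
               c(12L, 5L, 3L), ignore_attr = TRUE)
  expect_equal(nrow(cm$contigs), 20L)
  expect_true(all(cm$contigs$truth_label %in%
                    vapply(c(0.35, 0.65), function(g) {
                      sprintf("genome_gc%02.0f", 100 * g)
                    }, character(1))))
  expect_equal(length(cm$pairs), 3L)
  expect_error(community_config(genome_gc = 0.5), "distinct")
})

test_that("community writing is byte-identical under a fixed seed", {
  cfg <- community_config(genome_gc = c(0.4, 0.6), genome_length = 15000L,
                          contigs_per_genome = 5L, contig_len_mean = 2000,
                          contig_len_sd = 300, contig_min_len = 1000,
                          n_core = 4L, n_free = 2L, n_endo = 2L,
                          n_unassigned = 1L, gene_codons = 60L,
                          n_pairs = 2L, pair_codons = 110L,
                          n_snps = 10L, n_taxa = 6L)
  d1 <- file.path(tempdir(), "cmA")
  d2 <- file.path(tempdir(), "cmB")
  write_community(generate_community(cfg, seed = 7), d1)
  write_community(generate_community(cfg, seed = 7), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
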