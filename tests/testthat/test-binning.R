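test_that("gc_content counts G+C over unambiguous bases only", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGT"), 1 / 3)
  expect_equal(gc_content("atgc"), 0.5)
  expect_error(gc_content("NNN"), "unambiguous")
  expect_error(gc_content(""), "non-empty")
})

test_that("tnf profiles are normalised and strand-symmetric", {
  p <- tnf_profile(strrep("A", 100))
  expect_equal(unname(p["AAAA"]), 0.5)
  expect_equal(unname(p["TTTT"]), 0.5)
  expect_equal(sum(p), 1)
  expect_equal(sum(p > 0), 2L)

  set.seed(42)
  for (i in 1:20) {
    s <- random_dna(sample(50:500, 1))
    ps <- tnf_profile(s)
    expect_equal(sum(ps), 1, tolerance = 1e-9)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(ps, tnf_profile(rc))
  }
  expect_error(tnf_profile("ACG"), "shorter")
})

test_that("length filter keeps the 300 bp boundary inclusive", {
  ctg <- data.frame(contig_id = c("a", "b", "c"),
                    length = c(299L, 300L, 301L))
  expect_equal(nrow(filter_contigs(ctg, 300L)), 2L)
  expect_identical(filter_contigs(ctg, 0L), ctg)
  expect_equal(nrow(filter_contigs(ctg[0, ], 300L)), 0L)
})

test_that("clustering honours the interprofile R^2 cutoff", {
  # identical sequences -> identical profiles -> one bin
  ctg <- data.frame(contig_id = sprintf("c%d", 1:4),
                    sequence = rep(random_dna(2000, seed = 7), 4),
                    length = 2000L, gc = 0.5, stringsAsFactors = FALSE)
  res <- cluster_contigs(ctg, binning_config())
  expect_equal(length(unique(res$bin_id)), 1L)

  # two compositional groups far apart -> exactly two bins
  g1 <- generate_genome(0.30, 50000, 2, seed = 11)
  g2 <- generate_genome(0.70, 50000, 2, seed = 12)
  ctg2 <- rbind(fragment_contigs(g1, 10, 5000, 500, 1000, seed = 1),
                fragment_contigs(g2, 10, 5000, 500, 1000, seed = 2))
  res2 <- cluster_contigs(ctg2, binning_config())
  expect_equal(length(unique(res2$bin_id)), 2L)
  split_labels <- split(ctg2$truth_label, res2$bin_id)
  expect_true(all(vapply(split_labels, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("clustering is invariant to input order and monotone in the cutoff", {
  g <- lapply(c(0.35, 0.5, 0.65), function(gc) {
    generate_genome(gc, 40000, 2, seed = round(100 * gc))
  })
  ctg <- do.call(rbind, lapply(seq_along(g), function(i) {
    fragment_contigs(g[[i]], 15, 5000, 500, 1000, seed = i)
  }))
  res <- cluster_contigs(ctg, binning_config())
  set.seed(99)
  perm <- sample(nrow(ctg))
  res_shuf <- cluster_contigs(ctg[perm, ], binning_config())
  part1 <- split(res$contig_id, res$bin_id)
  part2 <- split(res_shuf$contig_id, res_shuf$bin_id)
  norm <- function(p) unname(sort(vapply(p, function(x) {
    paste(sort(x), collapse = ",")
  }, character(1))))
  expect_identical(norm(part1), norm(part2))

  n_bins <- vapply(c(0.99, 0.9, 0.5, 0.1), function(r2) {
    length(unique(cluster_contigs(ctg, binning_config(r2_cutoff = r2))$bin_id))
  }, integer(1))
  expect_true(all(diff(n_bins) <= 0))
})

test_that("chimera removal follows the single-pass 1-SD GC rule", {
  # hand oracle: GC% {40,41,42,60} -> mean 45.75, sample SD ~9.53;
  # only the 60% contig lies beyond 1 SD
  b <- data.frame(contig_id = c("w", "x", "y", "z"),
                  gc = c(0.40, 0.41, 0.42, 0.60))
  res <- remove_chimeric(b, multiplier = 1)
  expect_identical(res$removed, "z")
  expect_equal(nrow(res$kept), 3L)

  same <- data.frame(contig_id = c("a", "b", "c"), gc = rep(0.5, 3))
  expect_length(remove_chimeric(same, 1)$removed, 0L)
  expect_length(remove_chimeric(b, Inf)$removed, 0L)

  tiny <- data.frame(contig_id = c("a", "b"), gc = c(0.2, 0.8))
  expect_length(remove_chimeric(tiny, 1)$removed, 0L)
})

test_that("n50 is the half-assembly length threshold", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(10), 10)
  expect_equal(n50(c(1, 1, 1, 1)), 1)
  expect_error(n50(numeric(0)), "empty")
  expect_error(n50(c(3, 0)), "positive")
})

test_that("adjusted Rand index scores bin recovery", {
  truth <- rep(c("g1", "g2", "g3"), each = 10)
  expect_equal(bin_recovery_score(truth, truth), 1.0)
  expect_lt(abs(bin_recovery_score(rep("one", 30), truth)), 1e-9)
  set.seed(123)
  rand <- sample(c("a", "b"), 1000, replace = TRUE)
  truth2 <- rep(c("x", "y"), each = 500)
  expect_lt(abs(bin_recovery_score(rand, truth2)), 0.05)
  expect_error(bin_recovery_score(c("a", NA), c("x", "y")), "missing")
})

test_that("a small three-genome community is recovered into clean bins", {
  gs <- lapply(seq_along(c(0.35, 0.5, 0.65)), function(i) {
    generate_genome(c(0.35, 0.5, 0.65)[i], 60000, 2, seed = 300 + i)
  })
  ctg <- do.call(rbind, lapply(seq_along(gs), function(i) {
    fragment_contigs(gs[[i]], 40, 8000, 1500, 1000, seed = 400 + i)
  }))
  b <- bin_contigs(ctg)
  ari <- bin_recovery_score(
    b$membership$bin_id,
    ctg$truth_label[match(b$membership$contig_id, ctg$contig_id)])
  expect_gte(ari, 0.9)
  expect_true(all(c("n_contigs", "total_bp", "n50", "mean_gc", "sd_gc",
                    "removed_chimeras") %in% names(b$qc)))
  expect_false(any(duplicated(b$membership$contig_id)))
})
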