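test_that("global identity counts gap columns as mismatch", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAA", "AAA"), 0.75)
  expect_error(pairwise_identity("", "AAA"), "empty")
})

test_that("greedy identity clustering respects the 97% threshold", {
  same <- setNames(rep(random_dna(300, seed = 2), 4), paste0("g", 1:4))
  expect_length(cluster_identity(same, 0.97), 1L)

  base <- random_dna(300, seed = 3)
  mut <- strsplit(base, "")[[1]]
  set.seed(4)
  idx <- sample(300, 30)
  mut[idx] <- vapply(mut[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  pair <- c(a = base, b = paste(mut, collapse = ""))
  expect_length(cluster_identity(pair, 0.97), 2L)
  expect_length(cluster_identity(pair, 0.85), 1L)
})

test_that("mutually divergent marker variants found one cluster each", {
  # 12 variants all pairwise < 97% identical -> 12 clusters
  set.seed(6)
  variants <- setNames(vapply(1:12, function(i) random_dna(250),
                              character(1)),
                       sprintf("var%02d", 1:12))
  expect_length(cluster_identity(variants, 0.97), 12L)
})

test_that("species counts are the median over marker families", {
  one <- data.frame(gene_id = "m1", family = "rpoB",
                    sequence = random_dna(200, seed = 8))
  expect_equal(estimate_species_count(one)$n_species, 1L)

  set.seed(9)
  mk <- function(fam, k) {
    data.frame(gene_id = sprintf("%s_%d", fam, 1:k), family = fam,
               sequence = vapply(1:k, function(i) random_dna(200),
                                 character(1)))
  }
  markers <- rbind(mk("famA", 3), mk("famB", 3), mk("famC", 5))
  res <- estimate_species_count(markers)
  expect_equal(res$n_species, 3L)
  expect_equal(sort(res$per_family$n_clusters), c(3L, 3L, 5L))
  expect_error(estimate_species_count(one[0, ]), "no marker")
})

test_that("best hit enforces thresholds and deterministic tie-breaking", {
  q <- random_protein(100, seed = 11)
  targets <- c(t_exact = q,
               t_far = random_protein(100, seed = 12),
               t_short = substr(q, 1, 30))
  hit <- best_hit(q, targets)
  expect_equal(hit$target, "t_exact")

  expect_null(best_hit(q, c(only = random_protein(100, seed = 13)),
                       min_identity = 0.9))
  # two identical targets tie on score and identity -> lexically smaller id
  tie <- c(zzz = q, aaa = q)
  expect_equal(best_hit(q, tie)$target, "aaa")
})

test_that("reciprocal best hits recover planted orthologs and reject decoys", {
  set.seed(15)
  n <- 8
  planted <- setNames(vapply(1:n, function(i) random_protein(120),
                             character(1)), sprintf("a%02d", 1:n))
  # orthologs at ~80% identity
  orth <- vapply(planted, function(p) {
    ch <- strsplit(p, "")[[1]]
    idx <- sample(120, 24)
    ch[idx] <- vapply(ch[idx], function(x) {
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1))
  names(orth) <- sprintf("b%02d", 1:n)
  decoys <- setNames(vapply(1:4, function(i) random_protein(120),
                            character(1)), sprintf("d%02d", 1:4))
  rbh <- reciprocal_best_hits(planted, c(orth, decoys))
  expect_equal(nrow(rbh), n)
  expect_equal(sort(rbh$gene_b), sort(names(orth)))
  expect_true(all(rbh$identity > 0.7))

  # symmetry: swapping the sets flips orientation but keeps the pair set
  rbh_rev <- reciprocal_best_hits(c(orth, decoys), planted)
  expect_setequal(paste(rbh$gene_a, rbh$gene_b),
                  paste(rbh_rev$gene_b, rbh_rev$gene_a))

  # a's best is b but b's best is elsewhere -> no pair
  a_set <- c(a1 = planted[[1]])
  b_set <- c(b1 = orth[[1]], b2 = planted[[1]])
  rbh2 <- reciprocal_best_hits(a_set, b_set)
  expect_true(nrow(rbh2) == 0L || all(rbh2$gene_b == "b2"))
})

test_that("lifestyle partition applies the two-reference rule and recovers planted counts", {
  cfg <- community_config(genome_gc = c(0.4, 0.6), genome_length = 15000L,
                          contigs_per_genome = 2L, contig_len_mean = 2000,
                          contig_len_sd = 300, contig_min_len = 1000,
                          n_core = 10L, n_free = 4L, n_endo = 3L,
                          n_unassigned = 3L, gene_codons = 90L,
                          n_pairs = 2L, pair_codons = 110L,
                          n_snps = 10L, n_taxa = 5L)
  cm <- generate_community(cfg, seed = 19)
  part <- partition_gene_sets(
    setNames(cm$pop_genes$protein, cm$pop_genes$gene_id),
    setNames(cm$refs$endo_ref$protein, cm$refs$endo_ref$gene_id),
    lapply(cm$refs$free_refs, function(r) setNames(r$protein, r$gene_id)))
  expect_equal(as.integer(part$counts[c("core", "free_living",
                                        "endosymbiont", "unassigned")]),
               c(10L, 4L, 3L, 3L))
  merged <- merge(part$assignments, cm$gene_truth, by = "gene_id")
  expect_true(all(merged$category.x == merged$category.y))
  # categories are exhaustive and mutually exclusive
  expect_equal(nrow(part$assignments), 20L)
  expect_false(any(duplicated(part$assignments$gene_id)))
})
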