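# Seeded synthetic-community generator. Emulates the statistical structure
# the downstream analysis assumes: source genomes with distinct GC and
# tetranucleotide signatures fragmented into contigs, orthologous gene pairs
# evolved at a specified dN/dS and codon-usage-bias strength, lifestyle gene
# presence/absence against reference proteomes, biallelic SNP allele counts
# across populations, and site coordinates with abundance vectors.

#' Generate a genome with a target GC and a distinct tetranucleotide signature
#'
#' Draws a sequence from an order-`markov_order` Markov chain. Every context
#' emits G+C with probability exactly `gc_target`; the G:C and A:T splits
#' within each context are perturbed per genome (log-odds noise seeded by
#' `seed`), so different genomes carry distinct 4-mer spectra at identical
#' GC. Realised GC is therefore binomially tight around the target.
#'
#' @param gc_target Target GC fraction in (0, 1).
#' @param length Genome length in bases (>= 1000).
#' @param markov_order Chain order (small integer >= 0).
#' @param seed RNG seed.
#' @param genome_id Optional label.
#' @param signature_sd Standard deviation of the per-context log-odds
#'   perturbation; controls how strong (and how genome-specific) the
#'   tetranucleotide signature is. The default 2 gives within-genome
#'   profile correlations comparable to real bacterial genomes (contig
#'   pairs of ~10 kb correlate at R^2 > 0.9).
#' @return List of class `genome_truth` with `genome_id`, `sequence`,
#'   `gc_target`, `markov_order`, `seed`.
#' @export
generate_genome <- function(gc_target, length, markov_order = 2L, seed = 1L,
                            genome_id = NULL, signature_sd = 2) {
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0,1)")
  if (length < 1000) stop("length must be at least 1000")
  if (markov_order < 0) stop("markov_order must be >= 0")
  k <- as.integer(markov_order)
  ncontext <- 4L^k
  seq_int <- with_seed(seed, {
    # per-context splits of the fixed GC mass (keeps stationary GC exact)
    g_frac <- stats::plogis(stats::rnorm(ncontext, 0, signature_sd))
    a_frac <- stats::plogis(stats::rnorm(ncontext, 0, signature_sd))
    p <- cbind(A = (1 - gc_target) * a_frac,
               C = gc_target * (1 - g_frac),
               G = gc_target * g_frac,
               T = (1 - gc_target) * (1 - a_frac))
    cum <- t(apply(p, 1, cumsum))
    u <- stats::runif(length)
    out <- integer(length)
    ctx <- 1L
    modk <- if (k > 0) 4L^(k - 1L) else 1L
    for (i in seq_len(length)) {
      r <- u[i]
      b <- if (r <= cum[ctx, 1]) 1L else if (r <= cum[ctx, 2]) 2L
           else if (r <= cum[ctx, 3]) 3L else 4L
      out[i] <- b
      if (k > 0) ctx <- ((ctx - 1L) %% modk) * 4L + b
    }
    out
  })
  structure(list(genome_id = genome_id %||% sprintf("genome_gc%02.0f",
                                                    100 * gc_target),
                 sequence = paste(BASES[seq_int], collapse = ""),
                 gc_target = gc_target,
                 markov_order = k,
                 seed = seed),
            class = "genome_truth")
}

#' Fragment a genome into contigs with truth labels
#'
#' Contig start positions are uniform over the genome; lengths are
#' truncated-normal with floor `min_len` (and capped at the genome length).
#'
#' @param genome A `genome_truth` from [generate_genome()].
#' @param n Number of contigs.
#' @param length_mean,length_sd Contig length distribution in bp.
#' @param min_len Minimum contig length (>= 300).
#' @param seed RNG seed.
#' @return Contig data.frame (`contig_id`, `sequence`, `length`, `gc`,
#'   `truth_label`).
#' @export
fragment_contigs <- function(genome, n, length_mean = 10000, length_sd = 2000,
                             min_len = 1000, seed = 1L) {
  if (min_len < 300) stop("min_len must be at least 300")
  if (length_mean <= min_len) stop("length_mean must exceed min_len")
  glen <- nchar(genome$sequence)
  if (glen < min_len) stop("genome shorter than requested contig")
  if (n == 0L) {
    return(data.frame(contig_id = character(0), sequence = character(0),
                      length = integer(0), gc = numeric(0),
                      truth_label = character(0), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    lens <- pmin(pmax(round(stats::rnorm(n, length_mean, length_sd)),
                      min_len), glen)
    starts <- vapply(lens, function(l) sample.int(glen - l + 1L, 1L),
                     integer(1))
    seqs <- substring(genome$sequence, starts, starts + lens - 1L)
    data.frame(contig_id = sprintf("%s_ctg%04d", genome$genome_id,
                                   seq_len(n)),
               sequence = seqs,
               length = as.integer(lens),
               gc = vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE),
               truth_label = genome$genome_id,
               stringsAsFactors = FALSE)
  })
}

preferred_codon_table <- function(seed) {
  gc <- genetic_code()
  sc <- sense_codons()
  aas <- unique(gc[sc])
  with_seed(seed, {
    prefs <- vapply(aas, function(a) {
      fam <- sc[gc[sc] == a]
      fam[sample.int(length(fam), 1L)]
    }, character(1))
    stats::setNames(prefs, aas)
  })
}

random_cds <- function(n_codons, cub_strength = 0, seed = 1L,
                       pref = NULL) {
  gc <- genetic_code()
  sc <- sense_codons()
  if (is.null(pref)) pref <- preferred_codon_table(derive_seed(seed, 17L))
  with_seed(seed, {
    aas <- sample(names(pref), n_codons, replace = TRUE)
    codons <- vapply(aas, function(a) {
      fam <- sc[gc[sc] == a]
      w <- ifelse(fam == pref[[a]], exp(cub_strength), 1)
      fam[sample.int(length(fam), 1L, prob = w)]
    }, character(1))
    paste(codons, collapse = "")
  })
}

#' Evolve an orthologous gene pair at a specified dN/dS
#'
#' Builds an ancestor of `n_codons` sense codons whose synonymous-codon
#' choice follows a Boltzmann weighting of strength `cub_strength`
#' (`cub_strength = 0` gives uniform synonymous usage; each amino acid has
#' one run-seeded preferred codon weighted `exp(cub_strength)`). Each of
#' the two descendants then evolves independently: `mutation_attempts`
#' random single-nucleotide changes are proposed; proposals creating a stop
#' codon are rejected and redrawn (not counted), synonymous proposals are
#' accepted, and nonsynonymous proposals are accepted with probability
#' `min(omega_true, 1)`.
#'
#' @param n_codons Gene length in codons (>= 100; the NG86 estimator is
#'   unstable below that).
#' @param omega_true True dN/dS in [0, 1.5].
#' @param mutation_attempts Counted mutation proposals per descendant.
#' @param cub_strength Non-negative codon-usage-bias strength.
#' @param seed RNG seed.
#' @return List of class `evolved_pair` with `cds_a`, `cds_b`,
#'   `omega_true`, `cub_strength`, `n_attempted_mutations`, `seed`.
#' @export
evolve_ortholog_pair <- function(n_codons, omega_true, mutation_attempts = 150L,
                                 cub_strength = 0, seed = 1L) {
  if (n_codons < 100) stop("n_codons must be at least 100")
  if (omega_true < 0 || omega_true > 1.5) stop("omega_true must be in [0, 1.5]")
  if (mutation_attempts < 0 || cub_strength < 0) stop("negative parameter")
  ancestor <- random_cds(n_codons, cub_strength, seed = derive_seed(seed, 1L))
  acc <- min(omega_true, 1)
  gc <- genetic_code()
  evolve_one <- function(cds, sub_seed) {
    with_seed(sub_seed, {
      chars <- strsplit(cds, "", fixed = TRUE)[[1]]
      len <- length(chars)
      attempts <- 0L
      while (attempts < mutation_attempts) {
        pos <- sample.int(len, 1L)
        newb <- sample(setdiff(BASES, chars[pos]), 1L)
        ci <- (pos - 1L) %/% 3L
        old_codon <- paste(chars[ci * 3L + 1:3], collapse = "")
        mut <- chars[ci * 3L + 1:3]
        mut[(pos - 1L) %% 3L + 1L] <- newb
        new_codon <- paste(mut, collapse = "")
        if (gc[new_codon] == "*") next  # redrawn, not counted
        attempts <- attempts + 1L
        synonymous <- gc[new_codon] == gc[old_codon]
        if (synonymous || stats::runif(1) < acc) chars[pos] <- newb
      }
      paste(chars, collapse = "")
    })
  }
  structure(list(cds_a = evolve_one(ancestor, derive_seed(seed, 2L)),
                 cds_b = evolve_one(ancestor, derive_seed(seed, 3L)),
                 omega_true = omega_true,
                 cub_strength = cub_strength,
                 n_attempted_mutations = as.integer(mutation_attempts),
                 seed = as.integer(seed)),
            class = "evolved_pair")
}

#' Generate biallelic SNP allele-count profiles across populations
#'
#' Per SNP, an ancestral allele frequency is drawn uniformly in (0.1, 0.9);
#' per-population frequencies are drawn around it from a Balding-Nichols
#' Beta mixture whose spread is controlled by `divergence` (the expected
#' Fst): `divergence = 0` leaves frequencies identical up to binomial
#' sampling, `divergence = 1` fixes one allele per population. Counts are
#' binomial at the given read depth.
#'
#' @param n_snps Number of loci (>= 1).
#' @param n_pops Number of populations (>= 2).
#' @param divergence Differentiation parameter in [0, 1].
#' @param depth Allele-count depth per population per locus (>= 10).
#' @param seed RNG seed.
#' @param pop_ids Optional population labels.
#' @return List of class `snp_matrix` with `counts` (data.frame `locus_id`,
#'   `pop`, `allele1`, `allele2`), `divergence`, `depth`.
#' @export
generate_snp_profiles <- function(n_snps, n_pops = 2L, divergence = 0.1,
                                  depth = 50L, seed = 1L, pop_ids = NULL) {
  if (n_snps < 1) stop("n_snps must be at least 1")
  if (depth < 10) stop("depth must be at least 10")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  pops <- pop_ids %||% sprintf("pop_%02d", seq_len(n_pops))
  n_pops <- length(pops)
  counts <- with_seed(seed, {
    anc <- stats::runif(n_snps, 0.1, 0.9)
    rows <- vector("list", n_snps * n_pops)
    idx <- 1L
    for (s in seq_len(n_snps)) {
      for (p in seq_len(n_pops)) {
        pf <- if (divergence == 0) {
          anc[s]
        } else if (divergence == 1) {
          as.numeric(stats::runif(1) < anc[s])
        } else {
          shape <- (1 - divergence) / divergence
          stats::rbeta(1, anc[s] * shape, (1 - anc[s]) * shape)
        }
        a1 <- stats::rbinom(1, depth, pf)
        rows[[idx]] <- data.frame(locus_id = sprintf("snp_%05d", s),
                                  pop = pops[p],
                                  allele1 = a1, allele2 = depth - a1,
                                  stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    do.call(rbind, rows)
  })
  structure(list(counts = counts, divergence = divergence,
                 depth = as.integer(depth)),
            class = "snp_matrix")
}

#' Configuration for a synthetic community
#'
#' Defaults define the standard three-genome demonstration community: GC
#' targets 0.35/0.50/0.65, 200 contigs of ~10 kb per genome, lifestyle gene
#' counts core = 50, free-living = 20, endosymbiont = 10 (plus 10
#' unassigned), orthologous pairs in the strongly purifying regime, and the
#' seven packaged waterway sites for geography.
#'
#' @param genome_gc GC targets, one per genome (>= 2 distinct values).
#' @param genome_length Genome length in bp.
#' @param markov_order Markov order of the genome generator.
#' @param contigs_per_genome,contig_len_mean,contig_len_sd,contig_min_len
#'   Fragmentation parameters.
#' @param n_core,n_free,n_endo,n_unassigned Lifestyle gene counts.
#' @param gene_codons Gene length in codons.
#' @param n_pairs Number of evolved ortholog pairs.
#' @param pair_codons Codons per evolved pair.
#' @param mutation_attempts Mutation proposals per descendant.
#' @param omega_range Range the true dN/dS is drawn from.
#' @param cub_max Maximum codon-bias strength.
#' @param coupling `"none"` (bias independent of omega) or `"negative"`
#'   (stronger bias on more constrained, low-omega pairs).
#' @param n_snps,divergence,depth SNP profile parameters.
#' @param n_taxa Taxa in the per-site abundance vectors.
#' @param sites Site table; defaults to [caws_sites()].
#' @return A `community_config` list.
#' @export
community_config <- function(genome_gc = c(0.35, 0.50, 0.65),
                             genome_length = 120000L,
                             markov_order = 2L,
                             contigs_per_genome = 200L,
                             contig_len_mean = 10000,
                             contig_len_sd = 2000,
                             contig_min_len = 1000,
                             n_core = 50L, n_free = 20L, n_endo = 10L,
                             n_unassigned = 10L,
                             gene_codons = 150L,
                             n_pairs = 60L,
                             pair_codons = 300L,
                             mutation_attempts = 100L,
                             omega_range = c(0.02, 0.30),
                             cub_max = 3,
                             coupling = c("negative", "none"),
                             n_snps = 150L, divergence = 0.15, depth = 50L,
                             n_taxa = 40L,
                             sites = NULL) {
  coupling <- match.arg(coupling)
  if (length(genome_gc) < 2L || length(unique(genome_gc)) < 2L) {
    stop("config must name at least 2 genomes with distinct gc_target")
  }
  if (any(c(n_core, n_free, n_endo, n_unassigned) < 0)) {
    stop("gene category counts must be non-negative")
  }
  structure(as.list(environment()), class = "community_config")
}

mutate_protein <- function(protein, rate, seed) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    ch <- strsplit(protein, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(aas, a), 1L),
                      character(1))
    paste(ch, collapse = "")
  })
}

#' Generate a fully labelled synthetic community
#'
#' Orchestrates [generate_genome()], [fragment_contigs()],
#' [evolve_ortholog_pair()] and [generate_snp_profiles()], plants lifestyle
#' gene categories against synthetic endosymbiont and free-living reference
#' proteomes, and attaches site geography and per-site abundances.
#'
#' @param config A [community_config()].
#' @param seed RNG seed; all internal seeds derive from it.
#' @return List of class `synthetic_community` with elements `contigs`,
#'   `gene_truth`, `pop_genes`, `refs`, `pairs`, `ortholog_truth`,
#'   `snp_matrix`, `sites`, `abundance`, `config`, `seed`.
#' @export
generate_community <- function(config = community_config(), seed = 1L) {
  sites <- config$sites %||% caws_sites()

  genomes <- lapply(seq_along(config$genome_gc), function(i) {
    generate_genome(config$genome_gc[i], config$genome_length,
                    config$markov_order, seed = derive_seed(seed, 100L + i))
  })
  contigs <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    fragment_contigs(genomes[[i]], config$contigs_per_genome,
                     config$contig_len_mean, config$contig_len_sd,
                     config$contig_min_len,
                     seed = derive_seed(seed, 200L + i))
  }))

  # lifestyle genes: category decides which reference proteomes carry an
  # ortholog of the population gene
  cats <- c(rep("core", config$n_core), rep("free_living", config$n_free),
            rep("endosymbiont", config$n_endo),
            rep("unassigned", config$n_unassigned))
  n_genes <- length(cats)
  pop_genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                          category = cats, stringsAsFactors = FALSE)
  pop_genes$cds <- vapply(seq_len(n_genes), function(i) {
    random_cds(config$gene_codons, cub_strength = 0,
               seed = derive_seed(seed, 300L + i))
  }, character(1))
  pop_genes$protein <- vapply(pop_genes$cds, translate_cds, character(1),
                              USE.NAMES = FALSE)

  make_ref <- function(keep_cats, tag, off) {
    idx <- which(pop_genes$category %in% keep_cats)
    data.frame(gene_id = sprintf("%s_%04d", tag, seq_along(idx)),
               protein = vapply(seq_along(idx), function(j) {
                 mutate_protein(pop_genes$protein[idx[j]], 0.05,
                                derive_seed(seed, off + j))
               }, character(1)),
               stringsAsFactors = FALSE)
  }
  refs <- list(
    endo_ref = make_ref(c("core", "endosymbiont"), "endo", 1000L),
    free_refs = list(make_ref(c("core", "free_living"), "freeA", 2000L),
                     make_ref(c("core", "free_living"), "freeB", 3000L)))

  # evolved ortholog pairs for selection/CUB coupling
  pair_cats <- rep_len(c("core", "free_living", "endosymbiont"),
                       config$n_pairs)
  pair_par <- with_seed(derive_seed(seed, 400L), {
    omega <- stats::runif(config$n_pairs, config$omega_range[1],
                          config$omega_range[2])
    cub <- if (config$coupling == "negative") {
      span <- diff(config$omega_range)
      config$cub_max * (config$omega_range[2] - omega) / span +
        stats::rnorm(config$n_pairs, 0, 0.15)
    } else {
      stats::runif(config$n_pairs, 0, config$cub_max)
    }
    list(omega = omega, cub = pmax(cub, 0))
  })
  pairs <- lapply(seq_len(config$n_pairs), function(i) {
    evolve_ortholog_pair(config$pair_codons, pair_par$omega[i],
                         config$mutation_attempts, pair_par$cub[i],
                         seed = derive_seed(seed, 500L + i))
  })
  ortholog_truth <- data.frame(pair_id = sprintf("pair_%04d",
                                                 seq_len(config$n_pairs)),
                               category = pair_cats,
                               omega_true = pair_par$omega,
                               cub_strength = pair_par$cub,
                               stringsAsFactors = FALSE)

  snps <- generate_snp_profiles(config$n_snps, n_pops = nrow(sites),
                                divergence = config$divergence,
                                depth = config$depth,
                                seed = derive_seed(seed, 600L),
                                pop_ids = sites$site_id)
  abundance <- with_seed(derive_seed(seed, 700L), {
    m <- matrix(stats::rgamma(nrow(sites) * config$n_taxa, shape = 0.8),
                nrow = nrow(sites),
                dimnames = list(sites$site_id,
                                sprintf("taxon_%03d", seq_len(config$n_taxa))))
    m / rowSums(m)
  })

  structure(list(contigs = contigs,
                 gene_truth = pop_genes[, c("gene_id", "category")],
                 pop_genes = pop_genes,
                 refs = refs,
                 pairs = pairs,
                 ortholog_truth = ortholog_truth,
                 snp_matrix = snps,
                 sites = sites,
                 abundance = abundance,
                 config = config,
                 seed = as.integer(seed)),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("Synthetic community\n")
  cat(sprintf("  genomes: %d (GC %s)\n", length(x$config$genome_gc),
              paste(x$config$genome_gc, collapse = "/")))
  cat(sprintf("  contigs: %d; genes: %d; ortholog pairs: %d\n",
              nrow(x$contigs), nrow(x$gene_truth), length(x$pairs)))
  cat(sprintf("  SNPs: %d across %d populations; sites: %d\n",
              length(unique(x$snp_matrix$counts$locus_id)),
              length(unique(x$snp_matrix$counts$pop)), nrow(x$sites)))
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Contigs and pair CDSs as FASTA, truth tables as TSV, configuration as a
#' YAML file (seed included).
#'
#' @param community A `synthetic_community`.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_community <- function(community, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(stats::setNames(community$contigs$sequence,
                              community$contigs$contig_id),
              file.path(outdir, "contigs.fasta"))
  cds <- unlist(lapply(seq_along(community$pairs), function(i) {
    p <- community$pairs[[i]]
    stats::setNames(c(p$cds_a, p$cds_b),
                    paste0(community$ortholog_truth$pair_id[i], c("_a", "_b")))
  }))
  write_fasta(cds, file.path(outdir, "ortholog_cds.fasta"))
  write_stage_tsv(community$contigs[, c("contig_id", "length", "gc",
                                        "truth_label")],
                  file.path(outdir, "contig_truth.tsv"), "simulate")
  write_stage_tsv(community$gene_truth,
                  file.path(outdir, "gene_truth.tsv"), "simulate")
  write_stage_tsv(community$ortholog_truth,
                  file.path(outdir, "ortholog_truth.tsv"), "simulate")
  write_stage_tsv(community$snp_matrix$counts,
                  file.path(outdir, "snp_counts.tsv"), "simulate")
  cfg <- community$config
  cfg$sites <- NULL
  yaml::write_yaml(c(cfg, list(seed = community$seed)),
                   file.path(outdir, "config.yaml"))
  invisible(outdir)
}
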