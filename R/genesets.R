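# Species-count estimation from single-copy markers and partitioning of
# population gene content into core / free-living-specific /
# endosymbiont-specific sets via reciprocal best hits against reference
# proteomes.

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment; identity = matches / alignment
#' columns, gap columns counting as mismatch (so "AAAA" vs "AAA" is 0.75).
#'
#' @param seq_a,seq_b Sequences (nucleotide or protein).
#' @param type `"DNA"` or `"AA"` (controls the scoring scheme).
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  aln <- if (type == "DNA") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(seq_a)),
                                  Biostrings::DNAString(toupper(seq_b)),
                                  substitutionMatrix = mat,
                                  gapOpening = 2, gapExtension = 1,
                                  type = "global")
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(sanitize_protein(seq_a)),
      Biostrings::AAString(sanitize_protein(seq_b)),
      substitutionMatrix = blosum62_x0(),
      gapOpening = 11, gapExtension = 1, type = "global")
  }
  aln_identity(aln, nchar(seq_a), nchar(seq_b))
}

# identity = matches / alignment columns, with
# columns = len_a + len_b - aligned residue pairs (so every gap column,
# terminal or internal, counts against identity)
aln_identity <- function(aln, len_p, len_s) {
  aligned <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  Biostrings::nmatch(aln) / (len_p + len_s - aligned)
}

#' Greedy identity clustering of genes
#'
#' Genes are sorted by length (descending; ties by id for determinism);
#' each gene joins the first existing cluster whose representative it
#' matches at `identity >= threshold`, else founds a new cluster.
#'
#' @param genes Named character vector of sequences (names = gene ids).
#' @param threshold Identity threshold (default 0.97).
#' @param type `"DNA"` or `"AA"`.
#' @return List of clusters, each with `representative` and `members`.
#' @export
cluster_identity <- function(genes, threshold = 0.97, type = "DNA") {
  if (length(genes) == 0L) stop("need at least one gene")
  ord <- order(-nchar(genes), names(genes))
  genes <- genes[ord]
  clusters <- list()
  for (i in seq_along(genes)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_seq <- genes[[clusters[[k]]$representative]]
      if (pairwise_identity(genes[[i]], rep_seq, type) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, names(genes)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(representative = names(genes)[i], members = names(genes)[i],
             threshold = threshold)
    }
  }
  clusters
}

#' Estimate the number of species from single-copy marker families
#'
#' Each single-copy marker family is clustered at 97% identity; the
#' per-family cluster count estimates the number of species carrying that
#' marker, and the median across families is the summary estimate
#' (round-half-even on fractional medians).
#'
#' @param markers Data.frame with columns `gene_id`, `family`, `sequence`.
#' @param threshold Identity threshold (default 0.97).
#' @param type Sequence type passed to [cluster_identity()].
#' @return List with `n_species` (integer) and `per_family` (data.frame).
#' @export
estimate_species_count <- function(markers, threshold = 0.97, type = "DNA") {
  if (nrow(markers) == 0L) stop("no marker genes supplied")
  fams <- split(markers, markers$family)
  per_family <- data.frame(
    family = names(fams),
    n_clusters = vapply(fams, function(f) {
      length(cluster_identity(stats::setNames(f$sequence, f$gene_id),
                              threshold, type))
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_family) <- NULL
  list(n_species = as.integer(round(stats::median(per_family$n_clusters))),
       per_family = per_family)
}

# Vectorised global protein alignment of one query against many targets.
align_scores <- function(query, targets) {
  q <- Biostrings::AAString(sanitize_protein(query))
  t <- Biostrings::AAStringSet(vapply(targets, sanitize_protein, character(1)))
  aln <- Biostrings::pairwiseAlignment(t, q,
                                       substitutionMatrix = blosum62_x0(),
                                       gapOpening = 11, gapExtension = 1,
                                       type = "global")
  data.frame(target = names(targets),
             score = Biostrings::score(aln),
             identity = aln_identity(aln, nchar(targets), nchar(query)),
             stringsAsFactors = FALSE)
}

# Full score/identity matrices between two protein sets, one vectorised
# alignment call per set_b sequence (score(a,b) is symmetric, so one matrix
# serves both RBH directions).
align_matrix <- function(set_a, set_b) {
  a <- Biostrings::AAStringSet(vapply(set_a, sanitize_protein, character(1)))
  score_m <- matrix(0, length(set_a), length(set_b),
                    dimnames = list(names(set_a), names(set_b)))
  ident_m <- score_m
  for (j in seq_along(set_b)) {
    aln <- Biostrings::pairwiseAlignment(
      a, Biostrings::AAString(sanitize_protein(set_b[[j]])),
      substitutionMatrix = blosum62_x0(),
      gapOpening = 11, gapExtension = 1, type = "global")
    score_m[, j] <- Biostrings::score(aln)
    ident_m[, j] <- aln_identity(aln, nchar(set_a), nchar(set_b[[j]]))
  }
  list(score = score_m, identity = ident_m)
}

#' Best hit of a query protein in a target set
#'
#' Highest global-alignment score above the minimum identity and mutual
#' coverage thresholds (coverage under global alignment is the length ratio
#' min/max of the two sequences). Score ties break by identity, then by
#' lexically smaller gene id.
#'
#' @param query Protein string.
#' @param targets Named character vector of target proteins.
#' @param min_identity Minimum alignment identity (default 0.4).
#' @param min_coverage Minimum mutual coverage (default 0.5).
#' @return List with `target` and `score`, or `NULL` if nothing passes.
#' @export
best_hit <- function(query, targets, min_identity = 0.4, min_coverage = 0.5) {
  if (length(targets) == 0L) return(NULL)
  res <- align_scores(query, targets)
  qlen <- nchar(query)
  tlen <- nchar(targets)
  res$coverage <- pmin(qlen, tlen) / pmax(qlen, tlen)
  res <- res[res$identity >= min_identity & res$coverage >= min_coverage, ,
             drop = FALSE]
  if (nrow(res) == 0L) return(NULL)
  res <- res[order(-res$score, -res$identity, res$target), , drop = FALSE]
  list(target = res$target[1], score = res$score[1],
       identity = res$identity[1])
}

#' Reciprocal best hits between two protein sets
#'
#' (a, b) is a pair iff b is a's best hit in set B and a is b's best hit in
#' set A, under the configured identity and coverage thresholds.
#'
#' @param set_a,set_b Named character vectors of proteins.
#' @param min_identity,min_coverage Passed to [best_hit()].
#' @return Data.frame (`gene_a`, `gene_b`, `score`, `identity`).
#' @export
reciprocal_best_hits <- function(set_a, set_b, min_identity = 0.4,
                                 min_coverage = 0.5) {
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty gene set")
  mats <- align_matrix(set_a, set_b)
  cov <- outer(nchar(set_a), nchar(set_b),
               function(x, y) pmin(x, y) / pmax(x, y))
  pass <- mats$identity >= min_identity & cov >= min_coverage
  pick <- function(score, ident, ok, ids) {
    # best passing column: score desc, identity desc, lexical id asc
    cand <- which(ok)
    if (length(cand) == 0L) return(NA_integer_)
    ord <- order(-score[cand], -ident[cand], ids[cand])
    cand[ord[1]]
  }
  fwd <- vapply(seq_along(set_a), function(i) {
    pick(mats$score[i, ], mats$identity[i, ], pass[i, ], names(set_b))
  }, integer(1))
  rev <- vapply(seq_along(set_b), function(j) {
    pick(mats$score[, j], mats$identity[, j], pass[, j], names(set_a))
  }, integer(1))
  keep <- which(!is.na(fwd) & rev[fwd] == seq_along(set_a))
  data.frame(gene_a = names(set_a)[keep],
             gene_b = names(set_b)[fwd[keep]],
             score = mats$score[cbind(keep, fwd[keep])],
             identity = mats$identity[cbind(keep, fwd[keep])],
             stringsAsFactors = FALSE)
}

#' Partition population genes into lifestyle-specific sets
#'
#' A population gene with a reciprocal best hit in the endosymbiont
#' reference AND in at least one free-living reference is core; an RBH only
#' in the endosymbiont reference is endosymbiont-specific; only in
#' free-living reference(s) is free-living-specific; no RBH anywhere is
#' unassigned.
#'
#' @param pop_genes Named character vector of population proteins.
#' @param endo_ref Named character vector: endosymbiont reference proteome.
#' @param free_refs List of named character vectors: free-living reference
#'   proteomes (>= 1).
#' @param min_identity,min_coverage RBH thresholds.
#' @return List of class `gene_set_partition` with `assignments`
#'   (data.frame `gene_id`, `category`) and `counts`.
#' @export
partition_gene_sets <- function(pop_genes, endo_ref, free_refs,
                                min_identity = 0.4, min_coverage = 0.5) {
  if (length(pop_genes) == 0L) stop("empty population gene list")
  if (length(endo_ref) == 0L || length(free_refs) == 0L) {
    stop("need at least one reference proteome per lifestyle")
  }
  in_endo <- reciprocal_best_hits(pop_genes, endo_ref, min_identity,
                                  min_coverage)$gene_a
  in_free <- unique(unlist(lapply(free_refs, function(ref) {
    reciprocal_best_hits(pop_genes, ref, min_identity, min_coverage)$gene_a
  })))
  cat_of <- function(g) {
    e <- g %in% in_endo
    f <- g %in% in_free
    if (e && f) "core" else if (e) "endosymbiont"
    else if (f) "free_living" else "unassigned"
  }
  assignments <- data.frame(
    gene_id = names(pop_genes),
    category = vapply(names(pop_genes), cat_of, character(1)),
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  counts <- table(factor(assignments$category,
                         levels = c("core", "free_living", "endosymbiont",
                                    "unassigned")))
  structure(list(assignments = assignments, counts = counts),
            class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("Population gene-set partition\n")
  n <- sum(x$counts)
  nass <- n - x$counts[["unassigned"]]
  for (k in names(x$counts)) {
    frac <- if (k != "unassigned" && nass > 0) {
      sprintf(" (%.0f%% of assigned)", 100 * x$counts[[k]] / nass)
    } else ""
    cat(sprintf("  %-13s %d%s\n", k, x$counts[[k]], frac))
  }
  invisible(x)
}
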