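# Composition-based genotype binning: tetranucleotide-frequency profiles,
# hierarchical clustering at an interprofile correlation cutoff, and
# GC-based chimeric-contig removal.

#' G+C content of a nucleotide sequence
#'
#' `N` bases are excluded from both numerator and denominator; a sequence
#' with no unambiguous base is an error.
#'
#' @param sequence Nucleotide string (A/C/G/T, N allowed).
#' @return Fraction of G+C among unambiguous bases.
#' @export
gc_content <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  sequence <- toupper(sequence)
  counts <- table(strsplit(sequence, "", fixed = TRUE)[[1]])
  gcn <- sum(counts[names(counts) %in% c("G", "C")])
  acgt <- sum(counts[names(counts) %in% BASES])
  if (acgt == 0L) stop("sequence contains no unambiguous (A/C/G/T) base")
  gcn / acgt
}

all_tetramers <- function() {
  if (is.null(.sp_env$tetramers)) {
    g <- expand.grid(BASES, BASES, BASES, BASES, stringsAsFactors = FALSE)
    .sp_env$tetramers <- sort(apply(g, 1, paste, collapse = ""))
  }
  .sp_env$tetramers
}

#' Tetranucleotide-frequency profile of a contig
#'
#' Counts every overlapping 4-mer (step 1) on the sequence and on its reverse
#' complement, then normalises to sum 1, so the profile is strand-symmetric.
#' Windows containing `N` are skipped.
#'
#' @param sequence Nucleotide string of length >= 4.
#' @return Named numeric vector over the 256 tetranucleotides, summing to 1.
#' @export
tnf_profile <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 4L) stop("sequence shorter than 4 bases")
  fwd <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = 4L)
  rev <- Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence)), width = 4L)
  counts <- fwd + rev
  total <- sum(counts)
  if (total == 0) stop("no valid (N-free) 4-mer window in sequence")
  counts[all_tetramers()] / total
}

# TNF matrix (contigs x 256) for a contig table.
tnf_matrix <- function(contigs) {
  m <- t(vapply(contigs$sequence, tnf_profile, numeric(256L)))
  rownames(m) <- contigs$contig_id
  m
}

#' Drop contigs below a minimum length
#'
#' The boundary is inclusive-keep: a contig exactly `min_len` long is kept.
#'
#' @param contigs Contig data.frame with a `length` column.
#' @param min_len Minimum retained length in bp (default 300).
#' @return Filtered contig data.frame.
#' @export
filter_contigs <- function(contigs, min_len = 300L) {
  if (min_len < 0) stop("min_len must be non-negative")
  contigs[contigs$length >= min_len, , drop = FALSE]
}

#' Binning configuration
#'
#' @param r2_cutoff Interprofile squared-correlation cutoff; the dendrogram
#'   is cut at distance `1 - r2_cutoff`.
#' @param min_contig_len Minimum contig length in bp.
#' @param gc_sd_multiplier Chimera rule: remove members more than this many
#'   GC standard deviations from the bin mean.
#' @param cluster_on_gc If TRUE, append GC as a 257th clustering feature
#'   (default FALSE: GC is used only by the chimera filter).
#' @return A `binning_config` list.
#' @export
binning_config <- function(r2_cutoff = 0.9, min_contig_len = 300L,
                           gc_sd_multiplier = 1.0, cluster_on_gc = FALSE) {
  stopifnot(r2_cutoff > 0, r2_cutoff <= 1)
  structure(list(r2_cutoff = r2_cutoff, min_contig_len = min_contig_len,
                 linkage = "average", gc_sd_multiplier = gc_sd_multiplier,
                 cluster_on_gc = cluster_on_gc),
            class = "binning_config")
}

#' Cluster contigs into genotype bins by tetranucleotide profile
#'
#' Average-linkage agglomerative clustering on the distance
#' \eqn{d = 1 - R^2}, where \eqn{R^2} is the squared Pearson correlation of
#' two 256-component tetranucleotide-frequency vectors; the tree is cut at
#' \eqn{d = 1 - r2\_cutoff}. A zero-variance (constant) profile cannot be
#' correlated and is assigned to its own flagged singleton bin.
#'
#' @param contigs Contig data.frame (`contig_id`, `sequence`, `length`, `gc`).
#' @param config A [binning_config()].
#' @return Data.frame (`contig_id`, `bin_id`, `gc`, `length`, `flagged`).
#' @export
cluster_contigs <- function(contigs, config = binning_config()) {
  if (nrow(contigs) < 1L) stop("need at least one contig")
  m <- tnf_matrix(contigs)
  if (isTRUE(config$cluster_on_gc)) m <- cbind(m, gc = contigs$gc)
  vars <- apply(m, 1, stats::var)
  flagged <- vars <= 0 | !is.finite(vars)
  assign_id <- integer(nrow(m))
  ok <- which(!flagged)
  if (length(ok) == 1L) {
    assign_id[ok] <- 1L
  } else if (length(ok) > 1L) {
    r2 <- stats::cor(t(m[ok, , drop = FALSE]))^2
    d <- stats::as.dist(1 - r2)
    hc <- stats::hclust(d, method = config$linkage)
    assign_id[ok] <- stats::cutree(hc, h = 1 - config$r2_cutoff)
  }
  nb <- max(assign_id, 0L)
  assign_id[flagged] <- nb + seq_len(sum(flagged))
  data.frame(contig_id = contigs$contig_id,
             bin_id = sprintf("bin_%03d", assign_id),
             gc = contigs$gc,
             length = contigs$length,
             flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Remove chimeric contigs from a bin by the 1-SD GC rule
#'
#' Single pass: the mean and sample standard deviation of member GC are
#' computed once, and members with \eqn{|gc - mean| > multiplier \cdot SD}
#' are removed; statistics are not recomputed after removal. Bins with fewer
#' than 3 members are returned unchanged (the SD is unstable).
#'
#' @param members Data.frame with `contig_id` and `gc` columns for one bin.
#' @param multiplier GC standard-deviation multiplier (default 1).
#' @return List with `kept` (data.frame) and `removed` (contig ids).
#' @export
remove_chimeric <- function(members, multiplier = 1.0) {
  if (nrow(members) == 0L) stop("bin is empty")
  if (nrow(members) < 3L) {
    return(list(kept = members, removed = character(0)))
  }
  mu <- mean(members$gc)
  sdev <- stats::sd(members$gc)
  out <- abs(members$gc - mu) > multiplier * sdev
  out[is.na(out)] <- FALSE
  list(kept = members[!out, , drop = FALSE],
       removed = members$contig_id[out])
}

#' Assembly N50
#'
#' Smallest length L such that contigs of length >= L together contain at
#' least half of the total assembly length.
#'
#' @param lengths Positive contig lengths.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length vector")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Adjusted Rand Index between bin assignment and truth labels
#'
#' @param bin_ids Bin assignment per contig.
#' @param truth_labels True genome label per contig (same order).
#' @return ARI in [-1, 1]; 1 for identical partitions, ~0 at chance.
#' @export
bin_recovery_score <- function(bin_ids, truth_labels) {
  if (length(bin_ids) != length(truth_labels)) {
    stop("bin_ids and truth_labels must have equal length")
  }
  if (anyNA(bin_ids) || anyNA(truth_labels)) stop("missing labels")
  mclust::adjustedRandIndex(bin_ids, truth_labels)
}

#' Bin the contigs of a community and refine bins
#'
#' Full binning stage: length filter, TNF clustering, per-bin chimera
#' removal, and QC summaries.
#'
#' @param contigs Contig data.frame.
#' @param config A [binning_config()].
#' @return List with `membership` (post-refinement contig table), `qc`
#'   (per-bin data.frame with n_contigs, total_bp, n50, mean_gc, sd_gc,
#'   removed_chimeras) and `removed` (chimeric contig ids).
#' @export
bin_contigs <- function(contigs, config = binning_config()) {
  kept <- filter_contigs(contigs, config$min_contig_len)
  if (nrow(kept) == 0L) stop("no contig passes the length filter")
  membership <- cluster_contigs(kept, config)
  removed_all <- character(0)
  keep_rows <- logical(nrow(membership))
  for (b in unique(membership$bin_id)) {
    idx <- which(membership$bin_id == b)
    res <- remove_chimeric(membership[idx, , drop = FALSE],
                           config$gc_sd_multiplier)
    removed_all <- c(removed_all, res$removed)
    keep_rows[idx] <- !(membership$contig_id[idx] %in% res$removed)
  }
  refined <- membership[keep_rows, , drop = FALSE]
  qc <- do.call(rbind, lapply(split(refined, refined$bin_id), function(g) {
    data.frame(bin_id = g$bin_id[1],
               n_contigs = nrow(g),
               total_bp = sum(g$length),
               n50 = n50(g$length),
               mean_gc = mean(g$gc),
               sd_gc = if (nrow(g) > 1L) stats::sd(g$gc) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL
  qc$removed_chimeras <- vapply(qc$bin_id, function(b) {
    sum(membership$bin_id == b) - qc$n_contigs[qc$bin_id == b]
  }, numeric(1))
  list(membership = refined, qc = qc, removed = removed_all)
}
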