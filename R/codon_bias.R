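# Codon deviation coefficient (CDC): codon usage bias measured as the cosine
# distance between observed codon usage and a null expectation built from
# positional GC and purine content under an independence factorisation.

#' Positional nucleotide composition of a CDS
#'
#' GC and purine (A+G) fractions at each of the three codon positions.
#'
#' @param cds In-frame CDS string (no internal stops).
#' @return List with numeric 3-vectors `gc` and `purine`.
#' @export
positional_composition <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  pos <- rep_len(1:3, length(chars))
  gc <- vapply(1:3, function(p) mean(chars[pos == p] %in% c("G", "C")),
               numeric(1))
  pur <- vapply(1:3, function(p) mean(chars[pos == p] %in% c("A", "G")),
                numeric(1))
  list(gc = gc, purine = pur)
}

#' Expected codon usage from positional composition
#'
#' Independence factorisation: at position p,
#' P(G) = gc_p * pur_p, P(A) = (1 - gc_p) * pur_p,
#' P(C) = gc_p * (1 - pur_p), P(T) = (1 - gc_p)(1 - pur_p); a codon's
#' expected probability is the product over its three positions. Stop codons
#' are removed and the 61-vector renormalised to sum 1.
#'
#' @param comp Output of [positional_composition()].
#' @return Named numeric 61-vector over sense codons, summing to 1.
#' @export
expected_codon_usage <- function(comp) {
  probs <- lapply(1:3, function(p) {
    g <- comp$gc[p]; r <- comp$purine[p]
    c(A = (1 - g) * r, C = g * (1 - r), G = g * r, T = (1 - g) * (1 - r))
  })
  sc <- sense_codons()
  e <- vapply(sc, function(cod) {
    ch <- strsplit(cod, "", fixed = TRUE)[[1]]
    probs[[1]][ch[1]] * probs[[2]][ch[2]] * probs[[3]][ch[3]]
  }, numeric(1))
  tot <- sum(e)
  if (tot <= 0) stop("degenerate composition: zero mass on all sense codons")
  e / tot
}

#' Observed codon usage of a CDS
#'
#' @param cds In-frame CDS string.
#' @return Named numeric 61-vector of sense-codon frequencies, summing to 1.
#' @export
observed_codon_usage <- function(cds) {
  codons <- codon_split(toupper(cds))
  sc <- sense_codons()
  codons <- codons[codons %in% sc]
  if (length(codons) == 0L) stop("no sense codon in CDS")
  counts <- table(factor(codons, levels = sc))
  as.numeric(counts / sum(counts)) |> stats::setNames(sc)
}

#' Codon deviation coefficient of a gene
#'
#' CDC = 1 - cosine similarity between the observed sense-codon usage and
#' the expectation from positional GC/purine composition. 0 means usage
#' exactly matches the compositional expectation; larger values mean
#' stronger codon usage bias. Genes shorter than 30 codons are computed but
#' flagged low-confidence.
#'
#' @param cds In-frame CDS string.
#' @return List of class `cdc_result` with `cdc`, `n_codons`, `low_confidence`.
#' @export
cdc <- function(cds) {
  obs <- observed_codon_usage(cds)
  exp_u <- expected_codon_usage(positional_composition(cds))
  cosine <- sum(obs * exp_u) / (sqrt(sum(obs^2)) * sqrt(sum(exp_u^2)))
  n <- sum(codon_split(toupper(cds)) %in% sense_codons())
  structure(list(cdc = 1 - cosine, n_codons = n,
                 low_confidence = n < 30L),
            class = "cdc_result")
}

#' Bootstrap significance of a CDC value
#'
#' Null genes of the same codon length are resampled codon-by-codon from the
#' gene's expected usage; the add-one p-value is
#' (1 + #\{bootstrap CDC >= observed\}) / (1 + n_boot).
#'
#' @param cds In-frame CDS string.
#' @param n_boot Number of bootstrap genes (>= 99).
#' @param seed RNG seed.
#' @return p-value in (0, 1].
#' @export
cdc_significance <- function(cds, n_boot = 999L, seed = 1L) {
  if (n_boot < 99L) stop("n_boot must be at least 99")
  obs_cdc <- cdc(cds)$cdc
  exp_u <- expected_codon_usage(positional_composition(cds))
  n <- sum(codon_split(toupper(cds)) %in% sense_codons())
  sc <- sense_codons()
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    g <- paste(sample(sc, n, replace = TRUE, prob = exp_u), collapse = "")
    cdc(g)$cdc
  }, numeric(1)))
  (1 + sum(boot >= obs_cdc)) / (1 + n_boot)
}

#' Pair-mean CDC of two orthologous genes
#'
#' Arithmetic mean of the two genes' codon deviation coefficients; this is
#' the per-pair codon-bias value used against pairwise dN/dS in the
#' coupling analysis.
#'
#' @param cds_a,cds_b In-frame CDS strings.
#' @return Mean CDC (numeric).
#' @export
pair_mean_cdc <- function(cds_a, cds_b) {
  (cdc(cds_a)$cdc + cdc(cds_b)$cdc) / 2
}
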