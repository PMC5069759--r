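# Independent oracles: written from the method definitions, sharing no code
# path with the package internals they check.

.ORACLE_CODE <- Biostrings::GENETIC_CODE

# NG86 site counts by direct enumeration of the 9 single-base mutants.
oracle_ng86_sites <- function(codon) {
  code <- .ORACLE_CODE
  aa <- code[[codon]]
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    muts <- setdiff(c("A", "C", "G", "T"), ch[pos])
    mut_codons <- vapply(muts, function(b) {
      x <- ch; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    mut_aa <- code[mut_codons]
    keep <- mut_aa != "*"
    if (any(keep)) s <- s + sum(mut_aa[keep] == aa) / sum(keep)
  }
  c(s = s, n = 3 - s)
}

# NG86 difference counts by recursive depth-first enumeration of all
# single-step pathway orderings, skipping pathways through stop codons.
oracle_ng86_diff <- function(codon_a, codon_b) {
  code <- .ORACLE_CODE
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  k <- sum(ca != cb)
  paths <- list()
  walk <- function(cur, s, n) {
    remaining <- which(cur != cb)
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(s, n)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") next
      if (aa_cur == aa_nxt) walk(nxt, s + 1, n) else walk(nxt, s, n + 1)
    }
  }
  walk(ca, 0, 0)
  if (length(paths) == 0L) return(c(sd = 0, nd = k))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Great-circle distance, closed-form haversine, radius 6371 km.
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# Random helpers ------------------------------------------------------------

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_sense_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(.ORACLE_CODE)[.ORACLE_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# symmetric random "distance" matrix with zero diagonal
random_dist_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}
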