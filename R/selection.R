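# Pairwise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
# correction: exact global protein alignment, codon back-threading, per-codon
# synonymous/nonsynonymous site counting with stop-codon exclusion, and
# pathway-averaged difference counting.

GAP3 <- "---"

blosum62_x0 <- function() {
  if (is.null(.sp_env$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    # non-standard residues map to X, scored 0 against anything
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .sp_env$blosum <- m
  }
  .sp_env$blosum
}

sanitize_protein <- function(p) {
  gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", toupper(p))
}

#' Global protein alignment (Needleman-Wunsch, BLOSUM62)
#'
#' Exact global alignment with BLOSUM62 substitution scores, gap open -11 and
#' gap extend -1. Non-standard residues are mapped to `X` and scored 0
#' against anything. Deterministic for fixed inputs.
#'
#' @param a,b Amino-acid strings.
#' @return List with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length) and `score`.
#' @export
align_proteins_global <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty protein sequence")
  a2 <- sanitize_protein(a)
  b2 <- sanitize_protein(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a2), Biostrings::AAString(b2),
    substitutionMatrix = blosum62_x0(),
    gapOpening = 11, gapExtension = 1, type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Thread codons back through a protein alignment
#'
#' Maps each amino-acid column of a protein alignment to the source codon of
#' each CDS; protein gaps become gap triplets. A trailing stop codon on
#' either CDS is dropped. Columns where either side is a gap are excluded
#' from downstream NG86 counting.
#'
#' @param aln A protein alignment from [align_proteins_global()].
#' @param cds_a,cds_b In-frame CDS strings whose translations equal the
#'   ungapped aligned proteins (trailing stop allowed).
#' @return List with `codons_a`, `codons_b`: equal-length character vectors
#'   of codons or `"---"`.
#' @export
backthread_codons <- function(aln, cds_a, cds_b) {
  thread_one <- function(aligned, cds) {
    codons <- codon_split(toupper(cds))
    if (length(codons) && is_stop(codons[length(codons)])) {
      codons <- codons[-length(codons)]
    }
    prot <- translate_cds(paste(codons, collapse = ""))
    cols <- strsplit(aligned, "", fixed = TRUE)[[1]]
    if (paste(cols[cols != "-"], collapse = "") != prot) {
      stop("aligned protein does not match CDS translation")
    }
    out <- rep(GAP3, length(cols))
    out[cols != "-"] <- codons
    out
  }
  ca <- thread_one(aln$aligned_a, cds_a)
  cb <- thread_one(aln$aligned_b, cds_b)
  list(codons_a = ca, codons_b = cb)
}

# --- NG86 counting ---------------------------------------------------------

# Synonymous/nonsynonymous site counts for one sense codon. At each of the
# three positions the synonymous fraction is (#synonymous single-base
# changes) / (#single-base changes not creating a stop); mutations to stop
# codons are excluded from both numerator and denominator.
ng86_site_one <- function(codon) {
  gc <- genetic_code()
  aa <- gc[codon]
  if (is.na(aa) || aa == "*") stop("stop or invalid codon: ", codon)
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars; mut[pos] <- b
      maa <- gc[paste(mut, collapse = "")]
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

ng86_site_table <- function() {
  if (is.null(.sp_env$sites)) {
    sc <- sense_codons()
    tab <- t(vapply(sc, ng86_site_one, c(s = 0, n = 0)))
    .sp_env$sites <- tab
  }
  .sp_env$sites
}

#' NG86 synonymous/nonsynonymous site counts for a codon
#'
#' @param codon A sense codon (standard genetic code).
#' @return Numeric `c(s, n)` with `s + n = 3`.
#' @export
count_sites_ng86 <- function(codon) {
  tab <- ng86_site_table()
  codon <- toupper(codon)
  if (!codon %in% rownames(tab)) stop("not a sense codon: ", codon)
  tab[codon, ]
}

# Integer codon machinery: codon index = 16*(b1-1) + 4*(b2-1) + b3, bases
# encoded A=1, C=2, G=3, T=4 to match the alphabetical codon ordering of
# the genetic-code table.
codon_int_tables <- function() {
  if (is.null(.sp_env$cint)) {
    idx_codon <- character(64)
    bases_m <- matrix(0L, 64, 3)
    for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
      i <- 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3
      idx_codon[i] <- paste0(BASES[b1], BASES[b2], BASES[b3])
      bases_m[i, ] <- c(b1, b2, b3)
    }
    aa <- genetic_code()[idx_codon]
    .sp_env$cint <- list(codon = idx_codon, bases = bases_m,
                         aa = unname(aa),
                         index = stats::setNames(seq_len(64), idx_codon))
  }
  .sp_env$cint
}

# All mutational pathways between two sense codons: permutations of the
# differing positions. Pathways passing through a stop codon are excluded
# and the average renormalised over the remainder; if every pathway crosses
# a stop, the differing positions are counted as nonsynonymous. Vectorised
# over all sense-codon pairs at once: every pair is walked under all six
# position orderings (steps at non-differing positions are no-ops, so
# orderings collapse to the k! distinct pathways with uniform multiplicity
# and the average is unchanged).
ng86_diff_tables <- function() {
  if (is.null(.sp_env$diff_sd)) {
    ct <- codon_int_tables()
    sense <- which(ct$aa != "*")
    sc <- ct$codon[sense]
    n <- length(sc)
    pow <- c(16L, 4L, 1L)
    grid <- expand.grid(i = seq_len(n), j = seq_len(n))
    bi <- ct$bases[sense[grid$i], , drop = FALSE]
    bj <- ct$bases[sense[grid$j], , drop = FALSE]
    k <- rowSums(bi != bj)
    aa <- ct$aa
    perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L),
                  c(3L,1L,2L), c(3L,2L,1L))
    s_sum <- numeric(nrow(grid)); n_sum <- s_sum; v_sum <- s_sum
    for (ord in perms) {
      cur <- bi
      cur_idx <- (cur[, 1] - 1L) * 16L + (cur[, 2] - 1L) * 4L + cur[, 3]
      s <- numeric(nrow(grid)); nn <- s; valid <- rep(TRUE, nrow(grid))
      for (pos in ord) {
        nxt_idx <- cur_idx + (bj[, pos] - cur[, pos]) * pow[pos]
        changed <- nxt_idx != cur_idx
        hit_stop <- changed & aa[nxt_idx] == "*"
        syn <- changed & !hit_stop & aa[nxt_idx] == aa[cur_idx]
        non <- changed & !hit_stop & aa[nxt_idx] != aa[cur_idx]
        valid <- valid & !hit_stop
        s <- s + as.numeric(syn)
        nn <- nn + as.numeric(non)
        cur[, pos] <- bj[, pos]
        cur_idx <- nxt_idx
      }
      s_sum <- s_sum + ifelse(valid, s, 0)
      n_sum <- n_sum + ifelse(valid, nn, 0)
      v_sum <- v_sum + as.numeric(valid)
    }
    sd_v <- ifelse(v_sum > 0, s_sum / v_sum, 0)
    nd_v <- ifelse(v_sum > 0, n_sum / v_sum, k)
    .sp_env$diff_sd <- matrix(sd_v, n, n, dimnames = list(sc, sc))
    .sp_env$diff_nd <- matrix(nd_v, n, n, dimnames = list(sc, sc))
  }
  list(sd = .sp_env$diff_sd, nd = .sp_env$diff_nd)
}

#' NG86 pathway-averaged difference counts between two codons
#'
#' Averages synonymous/nonsynonymous step counts over all orderings of the
#' differing positions, excluding pathways through stop codons (renormalised
#' over the remainder). `sd + nd` equals the number of differing positions
#' whenever at least one valid pathway exists.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Numeric `c(sd, nd)`.
#' @export
count_differences_ng86 <- function(codon_a, codon_b) {
  tabs <- ng86_diff_tables()
  a <- toupper(codon_a); b <- toupper(codon_b)
  if (!a %in% rownames(tabs$sd) || !b %in% rownames(tabs$sd)) {
    stop("not a sense codon pair: ", a, "/", b)
  }
  c(sd = tabs$sd[a, b], nd = tabs$nd[a, b])
}

#' Pairwise dN/dS from a codon alignment (NG86 + Jukes-Cantor)
#'
#' Sites and differences are summed over comparable columns (both sides
#' sense codons; per-column site counts are the mean of the two codons'
#' counts so the statistic is symmetric in its arguments). Proportions are
#' corrected with the Jukes-Cantor distance \eqn{d = -3/4 \log(1 - 4p/3)}.
#' `omega` is `dN/dS`, reported `NA` (undefined) when `dS = 0`; the result
#' is flagged saturated when either proportion reaches 3/4.
#'
#' @param caln Codon alignment from [backthread_codons()] (or a list with
#'   `codons_a`, `codons_b`).
#' @return An object of class `ng86_result` with fields `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons`, `saturated`.
#' @export
dnds <- function(caln) {
  ca <- toupper(caln$codons_a)
  cb <- toupper(caln$codons_b)
  stopifnot(length(ca) == length(cb))
  sc <- sense_codons()
  comp <- ca %in% sc & cb %in% sc
  if (!any(comp)) stop("no comparable codon column")
  ca <- ca[comp]; cb <- cb[comp]
  sites <- ng86_site_table()
  S <- sum((sites[ca, "s"] + sites[cb, "s"]) / 2)
  N <- sum((sites[ca, "n"] + sites[cb, "n"]) / 2)
  tabs <- ng86_diff_tables()
  idx <- cbind(match(ca, rownames(tabs$sd)), match(cb, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  saturated <- pS >= 3 / 4 || pN >= 3 / 4
  omega <- if (saturated || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = sum(comp), saturated = saturated),
            class = "ng86_result")
}

#' @export
print.ng86_result <- function(x, ...) {
  cat("NG86 pairwise selection estimate\n")
  cat(sprintf("  codons compared: %d\n", x$n_codons))
  cat(sprintf("  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %s, dN = %s, omega = %s%s\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              if (is.na(x$omega)) "undefined" else format(x$omega, digits = 4),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Full pairwise dN/dS for two CDSs
#'
#' Convenience wrapper: translate, align globally, back-thread codons and
#' run NG86 counting.
#'
#' @param cds_a,cds_b In-frame CDS strings.
#' @return An `ng86_result` (see [dnds()]).
#' @export
dnds_pair <- function(cds_a, cds_b) {
  pa <- translate_cds(sub("(TAA|TAG|TGA)$", "", toupper(cds_a)))
  pb <- translate_cds(sub("(TAA|TAG|TGA)$", "", toupper(cds_b)))
  aln <- align_proteins_global(pa, pb)
  dnds(backthread_codons(aln, cds_a, cds_b))
}

#' Classify selection regime from an NG86 result
#'
#' @param result An `ng86_result`.
#' @return `"purifying"` (omega < 1), `"positive"` (omega > 1), or
#'   `"neutral_or_undetermined"` (omega undefined or exactly 1).
#' @export
classify_selection <- function(result) {
  omega <- if (is.list(result)) result$omega else result
  if (is.na(omega) || omega == 1) return("neutral_or_undetermined")
  if (omega < 1) "purifying" else "positive"
}
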