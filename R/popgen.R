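# Pool-based pairwise Fst across core-gene SNPs, geographic and community
# distances, diversity indices, and Mantel distance-decay tests.

#' Per-SNP Fst between two pooled populations
#'
#' Heterozygosity form: Hw is the mean within-population expected
#' heterozygosity 1 - sum(p^2), Ht the total heterozygosity at the
#' unweighted mean allele frequency; Fst = (Ht - Hw) / Ht. Returns `NA`
#' when Ht = 0 (the locus is monomorphic overall).
#'
#' @param counts_a,counts_b Length-2 allele-count vectors for the two
#'   populations at one biallelic locus.
#' @return Fst in [0, 1], or `NA` when undefined.
#' @export
fst_per_snp <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L)
  na <- sum(counts_a); nb <- sum(counts_b)
  if (na < 1 || nb < 1) stop("zero-depth population")
  pa <- counts_a[1] / na
  pb <- counts_b[1] / nb
  hw <- mean(c(1 - pa^2 - (1 - pa)^2, 1 - pb^2 - (1 - pb)^2))
  pbar <- (pa + pb) / 2
  ht <- 1 - pbar^2 - (1 - pbar)^2
  if (ht == 0) return(NA_real_)
  unname((ht - hw) / ht)
}

#' Mean pairwise Fst between two populations across a SNP matrix
#'
#' Unweighted mean of per-SNP Fst over loci where it is defined.
#'
#' @param snps SNP matrix: data.frame with columns `locus_id`, `pop`,
#'   `allele1`, `allele2` (counts), or a list as produced by
#'   [generate_snp_profiles()].
#' @param pop_a,pop_b Population labels.
#' @return Mean Fst.
#' @export
pairwise_fst <- function(snps, pop_a, pop_b) {
  df <- as_snp_df(snps)
  a <- df[df$pop == pop_a, ]
  b <- df[df$pop == pop_b, ]
  a <- a[order(a$locus_id), ]; b <- b[order(b$locus_id), ]
  if (!identical(a$locus_id, b$locus_id)) {
    stop("populations do not share the same loci")
  }
  vals <- vapply(seq_len(nrow(a)), function(i) {
    fst_per_snp(c(a$allele1[i], a$allele2[i]), c(b$allele1[i], b$allele2[i]))
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no SNP with defined Fst")
  mean(vals)
}

as_snp_df <- function(snps) {
  if (is.data.frame(snps)) return(snps)
  if (is.list(snps) && !is.null(snps$counts)) return(snps$counts)
  stop("unrecognised SNP matrix representation")
}

#' Fst matrix over all population pairs
#'
#' @param snps SNP matrix (see [pairwise_fst()]).
#' @return Symmetric matrix of mean pairwise Fst, zero diagonal.
#' @export
fst_matrix <- function(snps) {
  df <- as_snp_df(snps)
  pops <- sort(unique(df$pop))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j > i) m[i, j] <- m[j, i] <- pairwise_fst(df, pops[i], pops[j])
  }
  m
}

#' Great-circle distance between two sites, in kilometers
#'
#' Haversine formula on a sphere of radius 6371.0 km.
#'
#' @param lat_a,lon_a,lat_b,lon_b Decimal-degree coordinates.
#' @return Distance in km.
#' @export
haversine_km <- function(lat_a, lon_a, lat_b, lon_b) {
  if (abs(lat_a) > 90 || abs(lat_b) > 90 || abs(lon_a) > 180 ||
      abs(lon_b) > 180) {
    stop("invalid coordinates")
  }
  geosphere::distHaversine(c(lon_a, lat_a), c(lon_b, lat_b),
                           r = 6371000) / 1000
}

#' Geographic distance matrix for a site table
#'
#' @param sites Data.frame with `site_id`, `latitude`, `longitude`.
#' @return Symmetric km distance matrix labelled by site id.
#' @export
geo_distance_matrix <- function(sites) {
  n <- nrow(sites)
  m <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      m[i, j] <- m[j, i] <- haversine_km(sites$latitude[i], sites$longitude[i],
                                         sites$latitude[j], sites$longitude[j])
    }
  }
  m
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' @param x,y Non-negative abundance vectors of equal length.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix for a site-by-taxon abundance table
#'
#' @param abund Matrix with sites as rows.
#' @return Symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(abund) {
  as.matrix(vegan::vegdist(abund, method = "bray"))
}

#' Shannon diversity and Pielou evenness
#'
#' Shannon H in natural log over positive entries; Pielou J = H / ln(S)
#' with S the number of positive entries. J is undefined (`NA`) for S = 1.
#'
#' @param abund Non-negative abundance vector.
#' @return List with `H` and `J`.
#' @export
diversity_indices <- function(abund) {
  if (all(abund <= 0)) stop("all-zero abundance vector")
  h <- vegan::diversity(abund, index = "shannon")
  s <- sum(abund > 0)
  j <- if (s > 1) h / log(s) else NA_real_
  list(H = unname(h), J = unname(j))
}

upper_tri <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles; two-sided permutation test
#' permuting rows and columns of the second matrix jointly, with the
#' add-one p-value (1 + #\{|r*| >= |r|\}) / (1 + n_perm).
#'
#' @param d1,d2 Square symmetric matrices with identical labels/order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List of class `mantel_result` with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 999L, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(identical(dim(d1), dim(d2)))
  if (nrow(d1) < 3L) stop("need at least 3 sites")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  r_obs <- stats::cor(upper_tri(d1), upper_tri(d2))
  n <- nrow(d1)
  exceed <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      r_perm <- stats::cor(upper_tri(d1), upper_tri(d2[idx, idx]))
      if (!is.na(r_perm) && abs(r_perm) >= abs(r_obs)) count <- count + 1L
    }
    count
  })
  structure(list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Distance-decay regression plus Mantel test
#'
#' Ordinary least squares of community dissimilarity on geographic distance
#' over the upper-triangle site pairs, with a Mantel test of the same two
#' matrices. Slope units: dissimilarity per km.
#'
#' @param geo Geographic distance matrix (km).
#' @param comm Community dissimilarity matrix, same sites/order.
#' @param n_perm,seed Passed to [mantel()].
#' @return List with `slope`, `intercept`, `r2`, `mantel`.
#' @export
distance_decay <- function(geo, comm, n_perm = 999L, seed = 1L) {
  g <- upper_tri(as.matrix(geo))
  c2 <- upper_tri(as.matrix(comm))
  if (stats::var(g) == 0) stop("degenerate (constant) geographic distances")
  fit <- stats::lm(c2 ~ g)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared,
       mantel = mantel(geo, comm, n_perm = n_perm, seed = seed))
}
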