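---
title: "Methods: strain-level population genomics from metagenome contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level population genomics from metagenome contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`strainpop` implements a contig-level population-genomics workflow for a
single abundant taxon sampled across many sites: reconstruct population
genotype bins from assembled contigs, partition the population gene content
by lifestyle, estimate the strength of natural selection per orthologous
gene pair, measure codon usage bias, and test whether the two covary — the
signature that local functional constraints, rather than dispersal
limitation, structure the populations. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made where
the methods literature leaves the details open.

## Genotype binning

Each contig of length ≥ 300 bp is summarised by its tetranucleotide
frequency (TNF) profile: every overlapping 4-mer is counted on the sequence
*and* its reverse complement and the 256-component vector normalised to sum
one. Counting both strands makes the profile strand-symmetric without
collapsing to the 136 canonical words; windows containing `N` are skipped,
and `N` bases are likewise excluded from both numerator and denominator of
the G+C fraction.

Contigs are clustered by average-linkage agglomerative clustering on the
distance $d = 1 - R^2$, where $R^2$ is the squared Pearson correlation
between two TNF vectors, and the dendrogram is cut at $d = 0.1$
(equivalently, an interprofile correlation cutoff of $R^2 = 0.9$). Average
linkage matches the "interprofile" semantics: merging decisions compare
group-average similarities. GC content is deliberately *not* part of the
clustering feature vector (TNF already encodes it); a `cluster_on_gc`
switch exists for users who want it appended. A zero-variance profile
(e.g. a homopolymer) has no defined correlation and becomes a flagged
singleton bin.

Bins are then refined by the chimera rule: in a single pass, members whose
GC deviates from the bin mean by more than `gc_sd_multiplier` (default 1)
sample standard deviations are removed; the statistics are not recomputed
after removal, the inequality is strict, and bins with fewer than three
members are left untouched because the sample SD is unstable. With
normally distributed within-bin GC this rule removes roughly a third of
members — that is inherent to a 1-SD cutoff and is reported per bin in the
QC table rather than hidden.

The recovery metric is the adjusted Rand index (ARI) between the bin
assignment and the generator's truth labels (via `mclust`). Lowering the
$R^2$ cutoff can only coarsen the partition, so the number of bins is
monotone in the cutoff.

## Gene-set partitioning

Orthology is decided by reciprocal best hits (RBH) under exact global
Needleman–Wunsch protein alignment with BLOSUM62, gap open −11, gap extend
−1 (via `Biostrings::pairwiseAlignment`; the traceback is deterministic).
Non-standard residues map to `X`, rescored 0 against everything. Alignment
identity is matches divided by *all* alignment columns — terminal and
internal gap columns count against identity — which makes thresholds like
97% reproducible without an appendix; coverage under global alignment is
the min/max length ratio of the two sequences, since a global alignment
spans both sequences by construction. Defaults: identity ≥ 0.4, coverage
≥ 0.5, ties broken by score, then identity, then the lexically smaller
gene id.

A population gene with an RBH in the endosymbiont reference *and* in at
least one free-living reference is **core**; only in the endosymbiont
reference, **endosymbiont-specific**; only in free-living reference(s),
**free-living-specific**; otherwise **unassigned**. Requiring presence in
both lifestyles (rather than in every reference) matches a design with one
endosymbiont genome and several free-living genomes. Reports give raw
counts and fractions of assigned genes, since lifestyle fractions depend
on which denominator one prefers.

Species counts per site come from single-copy marker families: each family
is clustered greedily at 97% identity (genes sorted by length descending,
ties by id, each joining the first cluster whose representative it matches)
and the median cluster count across families is the estimate; fractional
medians are rounded half-to-even. The median was chosen because a
copy-number-variation analysis without a stated aggregation rule needs a
robust summary.

## Pairwise dN/dS (NG86 with Jukes–Cantor correction)

Selection strength is the ratio ω = dN/dS estimated by Nei–Gojobori (1986)
counting on a codon alignment obtained by threading each CDS through the
global protein alignment of its translation (protein gaps become codon gap
triplets; terminal stop codons are dropped; columns with a gap on either
side are excluded).

*Sites.* For a sense codon, the synonymous fraction at each position is
the number of synonymous single-base changes divided by the number of
single-base changes that do not create a stop codon; mutations to stops
are excluded from numerator and denominator alike. Summing over positions
gives $s$ per codon, with $n = 3 - s$, so $S + N = 3 \times$ (codon
columns) exactly. Per column the site counts of the two codons are
averaged, making the statistic symmetric in its arguments.

*Differences.* For a codon pair differing at $k$ positions, the
synonymous/nonsynonymous step counts are averaged over all $k!$ orderings
of the single-step pathways; pathways passing through a stop codon are
excluded and the average renormalised over the remainder (if every pathway
crosses a stop, the positions count as nonsynonymous — the standard
convention). The implementation walks all pairs under all six position
orderings simultaneously (no-op steps collapse duplicate orderings with
uniform multiplicity), and the test suite checks it against an independent
recursive enumeration over the full 61 × 61 sense-codon table to 1e-9.

*Correction and classification.* Proportions $p_S = S_d/S$ and
$p_N = N_d/N$ are corrected by the Jukes–Cantor distance
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; $p \ge 3/4$ flags saturation.
ω is undefined when $d_S = 0$ and such pairs are excluded from medians and
correlations rather than reported as infinite. ω < 1 is purifying, ω > 1
positive, anything else neutral-or-undetermined. NG86 is unweighted
(no transition/transversion bias) and the workflow is strictly pairwise —
no maximum-likelihood codon models, by design: in the strongly purifying,
low-divergence regime the counting estimator is accurate, fully
specified, and deterministic.

## Codon deviation coefficient

Codon usage bias is measured per gene. The expected usage derives from the
gene's own positional composition under an independence factorisation: at
codon position $p$ with GC fraction $g_p$ and purine fraction $r_p$,

$$P(G) = g_p r_p,\quad P(A) = (1-g_p) r_p,\quad
  P(C) = g_p(1-r_p),\quad P(T) = (1-g_p)(1-r_p),$$

a codon's expected probability is the product over its three positions,
stop codons are removed and the 61-vector renormalised. The CDC is one
minus the cosine similarity between observed and expected usage, so it is
0 exactly when usage matches the compositional expectation, bounded by 1,
and invariant to codon order. Significance comes from a parametric
bootstrap: null genes of the same codon length resampled from the expected
usage, with the add-one p-value $(1 + \#\{\mathrm{CDC}^* \ge
\mathrm{CDC}\})/(1 + B)$. Genes under 30 codons are computed but flagged
low-confidence. For an orthologous pair the *pair-mean CDC* (arithmetic
mean of the two genes) is the bias value carried into the coupling
analysis. A single-codon gene has CDC 0 under this model — its expectation
degenerates to the gene itself — so "bias" here always means deviation
beyond composition, not amino-acid repetitiveness.

## Coupling between selection and codon bias

The central statistic is, per gene category (core / free-living /
endosymbiont), the Spearman rank correlation between pairwise ω and
pair-mean CDC, two-sided, with a Bonferroni-adjusted p across the three
categories reported alongside the raw p. Spearman is the default because ω
distributions are heavy-tailed; Pearson is available by argument. Pairs
with undefined ω are excluded; categories with fewer than three usable
pairs, or with zero variance in either variable, are reported with an
undefined correlation rather than an error.

## Population genetics and distance decay

Per-SNP Fst uses the heterozygosity form
$F_{st} = (H_t - H_w)/H_t$ with $H_w$ the mean within-population expected
heterozygosity and $H_t$ computed at the unweighted mean allele frequency;
a locus monomorphic overall ($H_t = 0$) is undefined and skipped, and the
population-pair value is the unweighted mean over defined loci. Geographic
distances are haversine great-circle distances on a 6371.0 km sphere;
community dissimilarity is Bray–Curtis (via `vegan`); diversity is Shannon
H in natural log with Pielou $J = H/\ln S$ over taxa with positive
abundance ($J$ undefined for $S = 1$). The Mantel test correlates upper
triangles by Pearson and permutes rows and columns of the second matrix
jointly, two-sided with the add-one p-value — implemented in-package
because established implementations default to a one-sided test without
the add-one convention; the test suite cross-checks the statistic against
`vegan::mantel`. Distance decay adds an ordinary least-squares fit of
dissimilarity on distance (slope in dissimilarity per km).

## The synthetic-community generator

The generator produces data with exactly the statistical structure the
pipeline assumes, so recovery tests are meaningful end to end.

*Genomes.* An order-$k$ Markov chain (default $k = 2$) in which every
context emits G+C with probability exactly the target GC — so realised GC
is binomially tight around the target — while the G:C and A:T splits
within each context are perturbed per genome by log-odds noise with
standard deviation `signature_sd` (default 2). This yields genomes whose
4-mer spectra are mutually distinct and internally coherent: ~10 kb
contigs from one genome correlate at $R^2 > 0.9$, which is what makes an
$R^2 = 0.9$ cutoff a meaningful recovery threshold, and is comparable to
the compositional coherence of real bacterial genomes. The default
demonstration community uses three genomes at GC 0.35/0.50/0.65, 200
contigs of ~10 kb each (truncated-normal lengths, uniform positions).

*Ortholog pairs.* An ancestor of $n$ sense codons is drawn with
per-amino-acid Boltzmann weighting: each amino acid has one run-seeded
preferred codon weighted $e^{c}$ (bias strength $c$; $c = 0$ gives uniform
synonymous usage). Two descendants then evolve independently: a fixed
number of single-nucleotide proposals, each rejected and redrawn if it
creates a stop (not counted against the budget), accepted if synonymous,
and accepted with probability $\min(\omega, 1)$ if nonsynonymous. This is
a generative caricature, not a population-genetic model — but its NG86
estimate converges near the nominal ω at low divergence because the
acceptance ratio directly scales the nonsynonymous substitution rate, and
the parameter-recovery tests (median estimate over 200 pairs of 500
codons within ±0.1·max(1, 1/ω) windows at ω ∈ {0.1, 0.5, 1.0}) confirm
it. Mean CDC rises monotonically with the bias strength over
$c \in \{0, 1, 3\}$.

*SNP profiles.* Per locus an ancestral frequency is uniform on
(0.1, 0.9); population frequencies follow a Balding–Nichols Beta mixture
whose divergence parameter equals the expected Fst (0 degenerates to the
ancestral frequency, 1 draws fixed alleles), and counts are binomial at
the configured depth. The field divergence of in-situ strains is not
asserted anywhere; it is a free parameter (default 0.15 in the demo,
chosen as a moderate, clearly sub-fixation level of differentiation).

*Lifestyle genes.* Population genes are random sense-codon CDSs; the
synthetic reference proteomes carry 5%-mutated copies of exactly the genes
whose category implies presence (core genes in all references, lifestyle
genes in their own reference only, unassigned genes nowhere), so the RBH
partition can be checked against planted counts. These references are
synthetic stand-ins constructed for testability; they are not the
published reference genomes.

*What passing does and does not show.* The generator emulates
compositional signatures, divergence, codon bias, and differentiation — it
does not simulate read-level error, strain mixtures within a bin, uneven
coverage, horizontal transfer, or recombination. Recovery on synthetic
communities therefore validates the estimators and their plumbing, not the
biological robustness of binning on real assemblies.

## Numerical choices and degenerate inputs

* Contig length filter boundary: "< 300 bp excluded" means exactly 300 bp
  is kept.
* Chimera rule: sample (n−1) SD, strict inequality, single pass.
* dS = 0 → ω reported missing; saturation ($p \ge 3/4$) flagged, not
  fatal; zero comparable codon columns is an error.
* All-stop or empty sequences, all-zero abundance vectors, zero-depth
  populations, and degenerate (constant) geographic distances raise
  informative errors.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; derived seeds stay below 2³¹.
* Default problem sizes (600 contigs, 90 genes, 60 pairs of 300 codons,
  150 SNPs across 7 sites) run the full demonstration pipeline in well
  under a minute on a laptop; the recovery simulations use 120–200 pairs
  per condition, enough for stable medians.

## Known limitations

NG86 with Jukes–Cantor correction underestimates divergence at high
substitution loads and ignores transition/transversion bias; the CDC
expectation assumes positional independence of nucleotide composition;
the RBH partition has no synteny awareness; the pipeline starts from
contigs (no assembly, no read simulation) and takes marker-family
membership and SNP allele counts as inputs rather than calling them.
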