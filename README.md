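# strainpop

Population genomics of strain-level endemism from metagenome contigs.

`strainpop` asks a question that recurs in freshwater microbial ecology:
when the same bacterial taxon (here, the ubiquitous bacterioplankton genus
*Polynucleobacter*) is found at every site along a waterway, are the local
populations interchangeable migrants, or locally adapted endemic strains?
The package implements the full contig-level analysis needed to answer it,
together with a seeded synthetic-community generator so that every stage is
testable without any external download:

1. **Genotype binning** — tetranucleotide-frequency (TNF) profiles computed
   on both strands, average-linkage hierarchical clustering with an
   interprofile correlation cutoff of R² = 0.9, exclusion of contigs
   < 300 bp, and removal of chimeric contigs whose G+C content deviates
   from the bin mean by more than 1 standard deviation.
2. **Gene-set partitioning** — reciprocal best hits (exact global protein
   alignment, BLOSUM62) against endosymbiont and free-living reference
   proteomes split population genes into *core*, *free-living-specific*,
   *endosymbiont-specific* and *unassigned* sets; single-copy markers
   clustered at 97% identity estimate species counts.
3. **Selection** — pairwise dN/dS (ω) by Nei–Gojobori (1986) counting:
   synonymous/nonsynonymous sites per codon with stop-codon exclusion,
   difference counts averaged over all mutational pathway orderings, and
   Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3).
4. **Codon usage bias** — the codon deviation coefficient (CDC): one minus
   the cosine similarity between observed sense-codon usage and an
   expectation built from positional GC and purine content.
5. **Coupling** — the central statistic: the per-category Spearman
   correlation between pairwise ω and pair-mean CDC. Strong local
   functional constraints predict a negative correlation (highly biased,
   highly expressed genes evolve under stronger purifying selection).
6. **Population genetics** — pool-based per-SNP Fst
   ((Ht − Hw)/Ht), Bray–Curtis dissimilarities, Shannon/Pielou diversity,
   haversine geographic distances, and Mantel distance-decay tests.

A seven-station site table for the Chicago Area Waterway System (latitude,
longitude, water chemistry) ships with the package as the default geography
for distance-decay analyses.

## Worked example

```r
library(strainpop)

manifest <- run_demo(outdir = "demo_out", seed = 1)
manifest
#> strainpop pipeline run (seed 1 )
#>   stages: simulate -> bin -> genesets -> select_cub -> couple -> popgen
#>   binning ARI vs truth: 1.000
#>   gene partition: core=50, free_living=20, endosymbiont=10, unassigned=10
#>   coupling (rho per category):
#>      category n_pairs    rho        p    p_adj   method
#>          core      20 -0.880 3.21e-07 9.64e-07 spearman
#>   free_living      20 -0.639 2.42e-03 7.25e-03 spearman
#>  endosymbiont      20 -0.851 1.96e-06 5.88e-06 spearman
```

Reading the output: the three simulated genomes (GC 0.35/0.50/0.65, 200
contigs of ~10 kb each) are rebinned with an adjusted Rand index of 1.0
against the truth labels; the planted lifestyle gene counts (50 core, 20
free-living, 10 endosymbiont) are recovered exactly by the
reciprocal-best-hit partition; and because the demonstration community
couples stronger codon bias to lower true ω, every gene category shows a
significant negative Spearman correlation between pair-mean CDC and the
NG86 ω estimate — the signature of selection tracking local functional
constraints.

Individual stages are plain functions: `tnf_profile()`, `bin_contigs()`,
`partition_gene_sets()`, `dnds_pair()`, `cdc()`, `pairwise_fst()`,
`mantel()`, each documented with its exact conventions.

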