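# paleoquartet

Quantifying the phylogenetic information of small ancient-protein panels.

Tooth enamel and collagen proteins survive in fossils for over a million
years — far beyond ancient DNA — but a dozen heavily conserved amino-acid
sequences carry only a sliver of the genome's signal. This package is for
molecular evolutionists and palaeoproteomics researchers who want to know,
before trusting a protein-based tree: *how much phylogenetic information do
P proteins actually contain for four closely related taxa, and when does
translation from DNA to protein destroy the answer?*

The package provides, end to end and fully simulation-backed:

* **A multispecies-coalescent simulator** on a four-taxon population tree
  `(((A,B),C),O)` (coalescent units, per-branch population sizes,
  admixture pulses). A locus genealogy is discordant with the population
  tree with probability `(2/3)·exp(-T)` for an internal branch of `T`
  coalescent units — the incomplete-lineage-sorting rate the simulator is
  tested against. A simplified codon process (synonymous rate 1,
  nonsynonymous rate `omega`, stops rejected) evolves DNA along each
  genealogy; proteins are exact translations, so every panel has known
  ground truth.
* **Conservation scoring**: per-site Shannon entropy (bits) and fixed-tree
  maximum-likelihood site rates, with totals, per-length scores, the
  divide-by-3 codon correction for DNA/protein comparability, locus
  rankings, and the one-individual-per-taxon resampling protocol.
* **Exhaustive quartet maximum likelihood**: Felsenstein pruning under
  JC69 (DNA) or a Poisson amino-acid model, all three topologies fitted by
  cyclic Brent search, likelihood ties and short/unsupported internal
  branches collapsed to polytomies, bootstrap support, and classification
  against a reference population tree into labels `#1` (concordant), `#2`,
  `#3` (alternative arrangements), `#4` (polytomy).
* **The iterative concatenation analysis**: for each N, repeatedly sample
  N proteins and one individual per taxon, concatenate, infer, classify,
  and count ingroup variant columns — tracking how resolution grows as
  proteins accumulate.
* **Introgression overlap**: archaic haplotype segments (BED-like,
  half-open) intersected with gene intervals; carrier frequencies per
  population panel and globally, at chromosome or individual level.

## Worked example

```r
library(paleoquartet)

panel <- build_panel(hominid_tree(), deep_time_loci(), 2, seed = 1)
panel
#> <protein_panel> 12 loci x 4 taxa (Homo, Pan, Gorilla, Pongo)
#>   individuals/taxon: 2; discordant gene trees: 2; introgressed loci: 0

ana <- run_analysis(panel, n_range = c(1, 4, 8, 12), reps = 100, seed = 2)
ana
#> <iterative_analysis> protein, N in {1...12}, 100 reps each
#>   #1 frequency: 26.0% at N=1 -> 100.0% at N=12

fit <- fit_quartet(panel_quartet(panel, "ENAM"))
fit
#> <quartet_fit> Gorilla,Pongo|Homo,Pan
#>   model PoissonAA, 1142 sites, lnL -3768.7596
quartet_newick(fit)
#> ((Homo:0.00527,Pan:0.00527):0.00174861,Gorilla:0.00703638,Pongo:0.0159009);
```

The panel realised 2 of 12 discordant gene trees (the expected ILS rate at
the preset internal branch is ~16%). A single protein resolves the
population tree in only 26% of iterations — most single-protein quartets
contain no topology-informative site and return the `#4` polytomy — while
the full 12-protein concatenation recovers it every time, with the mean
ingroup variant count growing from ~10 (N = 1) to ~118 (N = 12).
Per-length conservation ranking puts AMELY and ODAM at the top and the
collagens at the bottom:

```r
profs <- lapply(panel_loci(panel), function(l)
  profile_entropy(panel_quartet(panel, l), "protein", l))
head(rank_loci(profs, normalize = TRUE), 3)
#>   rank locus data_type  score  tied
#> 1    1 AMELY   protein 0.0670 FALSE
#> 2    2  ODAM   protein 0.0523 FALSE
#> 3    3  AMBN   protein 0.0390 FALSE
```

`autoplot(ana)` draws the stacked topology-frequency barplot;
`plot_variant_counts(ana)` the variant box plots; `run_pipeline()` ties
simulate → score → iterate → introgress into one reproducible run with a
JSON manifest.

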