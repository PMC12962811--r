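---
title: "Models and methods behind paleoquartet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoquartet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paleoquartet)
```

## The question the package addresses

A handful of enamel and collagen proteins survive in fossils for over a
million years, long after DNA has degraded. Their amino-acid sequences are
the only molecular window into deep-time hominid evolution, but they are
few, short, and heavily conserved. paleoquartet quantifies how much
phylogenetic information such a panel actually carries: how often a
four-taxon gene tree inferred from proteins differs from the population
tree, how conservation varies across loci and data types (intron+exon DNA,
exon-only DNA, protein), how quickly resolution accumulates as proteins are
concatenated, and how archaic introgression in modern genomes perturbs the
picture.

Everything runs on synthetic panels with known ground truth, so each stage
is testable without any external download.

## The coalescent simulator

Genealogies are drawn under the multispecies coalescent on a rooted
four-taxon population tree `(((A,B),C),O)`. All times are in coalescent
units (one unit = 2N generations of a reference population); per-branch
`pop_sizes` rescale the pair-coalescence rate within each population. The
key parameter is `internal_t`, the duration of the branch between the two
ingroup splits: the A and B lineages fail to coalesce there with
probability `exp(-internal_t / N_AB)`, and two thirds of such deep
coalescences yield a topology discordant with the population tree — the
classical `(2/3)·exp(-T)` incomplete-lineage-sorting (ILS) rate, which the
test suite verifies against simulation to three binomial standard errors.

Admixture is a pulse: at a stated time, each sampled lineage of the target
taxon jumps to the source population with probability `m`. This mimics an
archaic pulse into one ingroup taxon; carrier haplotypes are recorded per
individual and per locus in the panel's ground-truth tables.

Multi-individual sampling is not bolted on afterwards: all sampled
lineages enter the same structured coalescent, so within-taxon
polymorphism and shared ancestral variation arise naturally. Ground-truth
topology labels for a locus are defined on the genealogy restricted to the
first individual of each taxon (with several individuals per taxon a locus
has no single "its" topology; the restriction gives a stable reference and
matches how single representatives are used downstream).

## The sequence model

Each locus evolves under a deliberately simple GY94-flavoured codon
process: single-nucleotide changes are proposed at rate `mu` per codon per
coalescent unit (modulated by an optional per-codon rate profile),
proposals creating stop codons are rejected, synonymous proposals are
accepted at relative rate 1 and nonsynonymous ones at relative rate
`omega`. Uniform codon frequencies are used. The package needs
conservation *heterogeneity* — proteins whose DNA varies while the protein
does not — rather than a calibrated mutation model, and this process
delivers exactly that with two interpretable knobs. With `omega = 1` the
nucleotide-level process collapses to Jukes–Cantor at rate `mu/3` per
site, which gives the divergence check used in the tests. Protein tips are
always exact standard-code translations of the DNA tips. Optional neutral
"intron" sites evolve alongside at the synonymous-equivalent rate,
enabling the intron+exon versus exon versus protein information
comparison.

### Preset study conditions

The shipped presets were fixed once, before any downstream analysis, to
reproduce the observed scale of real deep-time protein panels:

* `hominid_tree()`: t_ab = 5, internal_t = 1.4, t_out = 12, tip
  populations 0.1. The implied true-gene-tree discordance,
  (2/3)e^{-1.4} ≈ 16%, matches the observed rate of DNA gene trees
  disagreeing with the great-ape population tree (2 of 12).
* `hominin_tree()`: t_ab = 0.6, internal_t = 0.05, ancestral ingroup
  population 0.3, t_out = 12. The very short internal branch makes most
  true gene trees discordant, emulating three populations that split
  within a few hundred thousand years.
* `deep_time_loci()`: twelve loci with the real proteins' lengths (AMELX
  205 codons … COL17A1 1497) and heterogeneous `omega` (collagens 0.05,
  ODAM 0.7), with `mu = 0.004` chosen so that a single-protein hominid
  quartet shows ~9 ingroup amino-acid variants on average and the hominin
  panel roughly ten times fewer — the variant scales reported for the
  real data.
* `conserved_loci()`: collagen-like loci (omega 0.02, 400 codons,
  mu 0.012) whose DNA usually resolves the quartet while the protein does
  not; this is the regime in which translation demonstrably destroys
  phylogenetic signal.

These presets are the package's own modelling choices on the
coalescent-unit scale; split times and population sizes for the real taxa
are not asserted.

## Conservation scoring

Per-column Shannon entropy is computed in bits over observed residue
frequencies. Defaults: gaps excluded from the frequencies (the gap
fraction is reported alongside; `as_state` is available), `X` always
excluded, `N` excluded only for nucleotide data (it is a real amino acid).
Totals, per-length scores, and the codon correction give three views of a
locus; rankings by total and by per-length score legitimately disagree for
long conserved versus short variable proteins, which is why both are
reported.

The divide-by-3 codon correction can be applied on either side: the
default divides nucleotide per-site scores by 3 and keeps the protein
intact; the converse (protein divided by 3) is exposed as
`correction_side = "protein"`. The two conventions order loci identically
and differ by a constant factor; both appear in descriptions of this
correction, so the choice is declared rather than silent.

Site rates replace empirical-Bayes machinery with a transparent
approximation: with the gene tree fixed, each site's relative rate is the
maximum-likelihood scaling of all branch lengths under a Poisson (or JC69)
model, normalised to mean 1. Invariant sites get rate 0 before
normalisation; a fully invariant alignment returns a flat profile. This
estimator is validated in the tests at the level the package uses it for —
rankings and relative rates — not as a reproduction of any particular
rate-inference tool.

The 1,000-repetition individual-resampling protocol
(`resampled_scores()`) draws one individual per taxon per repetition and
reports means with Monte-Carlo standard errors; a two-individual panel is
checked against the exhaustive 16-combination average.

## Quartet inference

All trees in this problem have four leaves, so heuristic tree search is
replaced by exhaustive maximum likelihood: for each of the three resolved
unrooted topologies, the five branch lengths are optimised by bounded
one-dimensional (Brent) search per branch, cycled until the relative
log-likelihood gain falls below 1e-8 (lengths capped at 10
substitutions/site), and the best topology is kept.

Substitution models are JC69 for DNA and a Poisson model (equal
exchangeabilities and frequencies) for amino acids. At hominid-scale
divergence only a handful of substitutions separate the taxa and the
topology decision is driven by shared derived states, so an empirical
exchangeability matrix would change essentially nothing while costing
transparency. Under these exchangeable models the site likelihood depends
only on the *pattern* of equalities among the four tips, so alignments are
compressed to at most 15 canonical patterns and the four-state sum is
evaluated in closed form over a lumped state space (observed states plus
one "other" class) — exact, and fast enough that the iterative analysis
fits thousands of quartets in minutes. The implementation is checked
against brute-force enumeration over internal states and, for DNA, against
an independent phylogenetics library.

Ties are polytomies: if the two best topologies differ by less than
`tie_tol` (1e-6 lnL) the quartet is declared unresolved rather than broken
arbitrarily. Bootstrap support for the ingroup pair resamples site-pattern
counts multinomially (equivalent in distribution to resampling columns)
and reports the recovery percentage. `collapse_branches()` then applies
the conservative trimming used before classification: internal branch
below `min_length` (default 1e-6 subst/site) or support below
`min_support` (default 50%) becomes a polytomy. These thresholds are
declared package defaults — reasonable, conventional values — not values
asserted from any external source.

Classification roots the quartet on the outgroup and maps the ingroup
cherry to labels #1 (concordant with the reference population tree), #2,
#3 (the alternative resolved arrangements) or #4 (polytomy). An outgroup
landing inside the inferred cherry is a legitimate outcome, not an error;
rooting still leaves a unique ingroup pair.

## The iterative analysis

`run_analysis()` repeats, for each panel size N: draw N loci without
replacement; draw one individual per taxon (independently per locus by
default — the literal reading of sampling one representative per protein —
with `individual_draw = "per-rep"` as the alternative); concatenate; fit;
optionally bootstrap; collapse; classify; count ingroup variant columns
(columns varying only in the outgroup are excluded). Summaries report
per-N label frequencies, variant distributions (type-7 quartiles, whiskers
at quartile ± 1.5·IQR), and bootstrap support grouped by (N, label) with
polytomies excluded.

"Consensus tree" here always means the single tree inferred from the
rep's concatenation; no separate consensus algorithm exists (the N = 1
case makes this reading unambiguous). Site-pattern counts and variant
counts are additive across loci, so the per-rep supermatrix is never
physically rebuilt — pattern tables are merged — which is an implementation
detail with bit-identical results, covered by the additivity tests.

Problem sizes: the packaged analyses run 200 repetitions per N over
N = 1…12 with two individuals per taxon, and disable bootstrap support in
the headline runs so that polytomy labels are driven by the data's actual
lack of topology-informative sites (likelihood ties and zero-length
internal branches) rather than by resampling noise; bootstrap-backed runs
are exercised at smaller scale. At these sizes the full suite and the
acceptance script each complete on a single CPU in well under half an
hour; 1,000 repetitions reproduce the same frequencies with tighter Monte
Carlo error and can be requested via `reps`.

## Introgression overlap

Segments are BED-like records (0-based half-open; 1-based input converted
on load with a flag). Any ≥1 bp overlap between a haplotype's introgressed
segment and the gene interval marks that chromosome as carrying the
archaic version — the natural reading of "gene within an introgressed
region"; frequencies divide distinct carrier `(individual, haplotype)`
pairs by the panel's chromosome count, with an individual-level option.
The global frequency pools carriers and chromosomes, i.e. it is the
chromosome-weighted mean of panel frequencies. The synthetic segment
generator plants carriers at exact rounded frequencies so recovery can be
asserted exactly.

## Numerical and degenerate-input choices

* Quantiles are type-7 (linear interpolation) everywhere.
* All-gap columns under the `exclude` gap policy have no defined entropy;
  they score 0 and are flagged.
* Entropy uses log base 2; only rankings matter for the comparisons, and
  bits are the conventional unit.
* Branch-length optimiser residues below 1e-9 are snapped to 0.
* Concatenation refuses missing taxa rather than padding with gaps: the
  analyses this package supports always have all four taxa per locus.
* One master seed drives every stage; per-locus/per-repetition substreams
  are derived deterministically, so panels are byte-identical across runs
  and parallel stages cannot interleave RNG draws.

## What passing tests do and do not show

The generator emulates the structure of real palaeoproteomic reference
panels — locus count and lengths, heterogeneous conservation, within-taxon
polymorphism, ILS, archaic admixture — but real data add alignment
uncertainty, peptide missingness and damage-induced ambiguity, none of
which are simulated (complete in-silico translated sequences are the
stated regime). Green tests therefore validate the statistical machinery
and the qualitative phenomena (information loss under translation,
resolution growth with N, introgression effects), not any quantitative
claim about particular fossil datasets. Known limitations: no intra-locus
recombination, a single pulse per admixture event, uniform codon
frequencies, no rate variation in *inference* (only in simulation), and
quartets only — more than four taxa is out of scope.
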