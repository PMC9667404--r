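---
title: "Demographic inference and gene-flow statistics for haploid SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference and gene-flow statistics for haploid SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mireflow)
```

mireflow analyses polarized haploid SNP matrices from short, effectively
unlinked loci — the data shape produced by RAD-seq assemblies of
gametophyte-dominant plants such as peatmosses, where each sample
contributes one haplotype and alignment to an outgroup reference genome
identifies the ancestral allele at every site. This vignette is the
package's account of its models and numerical choices; the README shows
the worked end-to-end example.

## Data model

A `haplo_matrix` stores one call per sample per site in `{0, 1, NA}`:
0 is the ancestral allele (the allele matching the outgroup-aligned
reference), 1 the derived allele, and `NA` a missing call. Sites whose
annotated ancestral state matches neither observed allele cannot be
polarized and are dropped rather than folded, so every retained site
supports an unfolded spectrum; multi-allelic sites are dropped likewise.
Missingness in RAD data is dominated by whole-locus allele dropout, which
is why the standard presence filter (`filter_locus_presence()`, default
80%) works on loci, not sites, and why the synthetic-data generator
models dropout per sample per locus.

## Site frequency spectra

`build_joint_sfs()` turns a matrix plus a population map into a
d-dimensional unfolded joint SFS over derived-allele counts. Missing data
are handled by hypergeometric projection: a site where population $k$ has
$n$ non-missing alleles, $d$ of them derived, contributes the
distribution of derived counts in a draw of $n'_k \le n$ alleles without
replacement. The default is the *expectation* projection (each usable
site adds its product-of-hypergeometrics mass, so the observed SFS holds
fractional counts); a seeded per-site random-draw mode
(`method = "sampled"`) exists for exact emulation of pipelines that
subsample individuals. Expectation projection is deterministic and uses
all data, which is why it is the default; the composite likelihood
accepts non-integer counts, so nothing downstream cares. Sites where any
population has fewer calls than its projection are skipped and counted.
The two monomorphic corner cells are tabulated but excluded from every
likelihood (the observed spectra are SNP-only).

## The coalescent simulator

Expected spectra come from a continuous-time structured coalescent
written in C++: within a deme of haploid size $N_e$, $k$ lineages
coalesce at rate $k(k-1)/(2N_e)$ per generation; divergence events move
all lineages of a deme into its parent backward in time; size changes
apply at epoch boundaries; migration is time-windowed. For every
simulated genealogy each branch's length is added to the SFS cell indexed
by its descendant counts per population; under infinite sites the
normalized branch-length table over polymorphic cells *is* the expected
SNP spectrum, independent of the mutation rate. Sampled spectra and
genotypes place Poisson($\mu L \times$ tree length) mutations on
branches, one genealogy per unlinked locus.

Two conventions are worth pinning. **Direction:** migration arrows in a
`model_spec` are forward in time (`source -> dest` means individuals move
source to dest); the simulator implements this as backward lineage
movement dest to source. A unit test freezes the convention with a
measurable asymmetry: under one-way forward flow A to B, lineages sampled
in B must wait to jump into A before coalescing, so B accumulates excess
private singletons. **Rates:** the `m` in a model is a per-generation
per-lineage probability; the simulator uses the exponential rate
$-\log(1-m)$, which equals $m$ to first order and makes a one-generation
window an exact admixture pulse of fraction $m$ — that is how the f4
calibration experiments inject a known admixed fraction.

The random-number generator is xoshiro256** seeded per replicate through
splitmix64, so runs are reproducible across platforms and replicate
substreams are independent of how many replicates precede them.
`mc_standard_error()` reports per-cell Monte-Carlo uncertainty from a
20-batch decomposition of the accumulated table.

The simulator is cross-checked in the test suite against an independent
backward simulator (msprime, branch-mode allele-frequency spectra) on a
two-population model with migration, against the $1/i$ law and the
$2N_e\sum 1/i$ total tree length for a single population, and against
the island-model equilibrium (below).

## Demographic models

All three-population analyses share one bifurcating history: a
recurvum-like species (REC) splits from the flexuosum-like lineage at
$T_{SP}$, and that lineage later splits into two allopatric populations
(ENA, EUR) at $T_{FLEX}$. Eight gene-flow events are enumerable: six
among the current populations and two between REC and the flexuosum
ancestor. `model_zoo()` builds every family the analysis design names —
strict isolation, full migration, current-populations-only, the eight
leave-one-out variants, and "model 10" (ENA to EUR, ENA to REC, REC into
the flexuosum ancestor) — with ancestral flow in three timing modes:
*continuous* over the whole ancestral epoch, *early* (window opening at
the species split, closing at a free stop time), and *secondary contact*
(window opening at a free contact time after an isolation period,
closing at the next divergence). The exact composition of all 29 base
models of the original 33-model comparison is not recoverable from the
published text (it sits in supplementary material); the zoo therefore
implements every named family plus `make_model()` for arbitrary subsets
of the eight events.

Nested times are parameterized as fractions ($T_{FLEX} = r \cdot T_{SP}$
with $r \in (0,1)$, contact times as fractions of the ancestral epoch),
so every point of the search space is a valid model by construction.
Time is in generations before present; sizes are haploid $N_e$; no
calendar calibration is attempted — with an assumed mutation rate
(default $2.8\times10^{-8}$ per site per generation, the standard moss
value) all estimates are relative quantities.

## Composite likelihood and the two-step fit

The multinomial composite log-likelihood of an observed SFS against
expected proportions is
$\sum_{\text{polymorphic cells}} o_i \log_{10} \max(e_i, \epsilon)$ with
the floor $\epsilon = 1/(10\,n_{sims})$ standing in for cells the finite
simulation left empty. Because both spectra are SNP-only, this term is
scale-free: a single-population spectrum has an $N_e$-independent shape,
and in general only parameter ratios are identified. `fit_model()`
therefore adds, when the locus count is known, a Poisson term on the
total polymorphic count with mean
$\mu L\, n_{loci}\, E[\text{polymorphic branch length}]$, which restores
absolute scale. This is the package's own resolution of a gap the
original method leaves open (its monomorphic-cell handling is not
described); it is exactly analogous to including the monomorphic cell
with a known sequence length.

Optimization mirrors the conditional-maximization ("ECM") scheme:
each cycle maximizes one parameter at a time by golden-section search on
the log scale, against a freshly simulated expected SFS. Two numerical
choices matter:

* **Common random numbers.** All objective evaluations within a cycle
  reuse one simulation substream, so each 1-D objective is deterministic
  and bracketing is not defeated by Monte-Carlo noise.
* **Shrinking brackets.** Cycle $c$ searches a log-scale window centred
  on the current value whose width shrinks by 0.6 per cycle (cycle 1
  spans the whole range). A fixed full-range bracket with a small
  evaluation budget quantizes estimates onto a coarse grid (~25%
  resolution over two decades), which is fatal for bootstrap coverage.

The two-step scheme follows the published procedure: parameters are
searched on the all-SNP spectrum (linked SNPs add information without
biasing estimates), then each model is re-scored against the
one-SNP-per-locus spectrum with a larger simulation, and
$AIC = 2k - 2\ln(10)\,\log_{10}CL$ ranks the models. The thinned
spectrum's total is not Poisson (at most one SNP per locus survives), so
the evaluation step uses the multinomial term only. Production-scale
defaults (100 runs, 50,000 simulations, 40 cycles, $10^7$ evaluation
simulations, 100 bootstrap replicates of 10 runs) are plain
configuration; the test suite runs desk-scale versions (3-10 runs,
1,500-5,000 simulations, 6-10 cycles, $10^4$-$10^5$ evaluation
simulations) chosen so the whole suite fits a single-CPU session.

`parametric_bootstrap()` re-simulates observed spectra at the fitted
values, refits each, and reports percentile intervals. Coverage is
approximate twice over — the likelihood is composite and the refits
carry Monte-Carlo noise — which in practice widens the intervals; the
recovery experiment in the test suite demands 80% empirical coverage of
a 95% interval for that reason.

## Diversity, differentiation and introgression statistics

$\pi$ and $D_{xy}$ are average pairwise differences (within and between
groups) with pairwise-complete normalization: a site enters a pair's
denominator only if both members are called there, so missingness biases
stay per-pair. When the total alignment length including invariant sites
is supplied, estimates are per alignment site; otherwise they are
per-variant-site and flagged. $F_{st}$ is Hudson's
$1 - \bar\pi_{within}/\pi_{between}$ with the unweighted two-group mean —
the conventional sequence-based estimator, monotone-compatible with the
island-model conversion — reported unclipped. Site classes
(monomorphic / fixed difference / shared polymorphic / private
polymorphic) partition the jointly-called sites exactly. Uncertainty
comes from the delete-one jackknife
($sd = \sqrt{\frac{n-1}{n}\sum(\hat\theta_{(i)}-\bar\theta)^2}$), and
group comparisons use one-way ANOVA plus pairwise Welch t-tests with
Bonferroni correction (matching the original analysis; Holm would be
less conservative).

ABBA/BABA statistics are frequency-weighted over all sites:
$D = (\text{ABBA}-\text{BABA})/(\text{ABBA}+\text{BABA})$ with
significance from a delete-one-block jackknife over contiguous
equal-size blocks (default 20 — conservative, since the loci are already
unlinked). The f4-ratio uses the P3-substituted denominator
$\sum(p_1-p_3)(p_3-p_4)$ because no donor subpopulation is available;
this "f-homozygosity" style estimator is deflated by drift on the donor
branch after the admixture event (the introgressed lineages track the
donor's frequencies at the pulse time, while the denominator tracks its
present frequencies), which is why the calibration experiment uses a
recent pulse and why results on old admixture should be read as lower
bounds. With polarized data the outgroup frequency may be taken as
identically zero (`outgroup = NA`), which equals using a
monomorphic-ancestral outgroup population.

Wright's island model for haploids gives $N_e m = \frac12(1/F_{st}-1)$
at equilibrium. The infinite-island assumption behind that formula
overstates differentiation for a finite deme count: exact coalescent
algebra for $d$ symmetric demes gives
$F_{st} = 1/(1 + 2dN m/(d-1))$. `island_model_spec()` therefore converts
a target $N_e m$ into the per-lineage rate $m = (N_{e}m/N_e)(d-1)/d$, so
a finite-deme simulation sits at the $F_{st}$ the formula predicts —
this is what ties the formula and the simulator together in the test
suite.

## The synthetic-data generator

`generate_dataset()` emulates the post-assembly product of a RAD
pipeline: ~10^3-10^4 loci of ~90 bp, one genealogy per locus, exact
polarization (the simulated ancestral state is 0), and whole-locus
dropout per sample. The default `paper_shape_spec()` encodes the
secondary-contact history described above with sizes and times scaled so
that at $\mu = 2.8\times10^{-8}$ roughly one SNP per locus segregates —
the density of a typical RAD assembly — and an outgroup deme deep enough
to serve as a genuine P4 for ABBA/BABA work. What the generator does
*not* emulate: sequencing error, paralog collapse, reference bias,
within-locus recombination, and finite-sites homoplasy. Tests passing on
synthetic data therefore validate the statistical machinery, not
robustness to assembly artefacts.

## Pipeline and reproducibility

`run_pipeline()` drives the stages (simulate or load data, diversity
tables, trio statistics, spectra, fits, ranking, bootstrap) from one
YAML config and writes tidy TSVs plus a JSON manifest. Every stochastic
stage consumes `derive_seed(master, stage_label)` — a pure hash — so
adding a stage never perturbs earlier ones and a rerun with the same
config is byte-identical.

## Known limitations

* Composite likelihood treats sites (and linked SNPs in the all-SNP
  spectrum) as independent; information is overstated and AIC
  differences near zero should not be over-read.
* The f4-ratio estimator is biased toward zero for old admixture (see
  above).
* No within-locus recombination; loci are exchangeable and unlinked.
* Timing variants of ancestral gene flow (continuous vs early vs
  secondary contact) are weakly separated at desk scale; reliable
  discrimination needs production-scale runs and full-size data.
* The bootstrap quantifies estimation noise given the model; it does not
  propagate model-selection uncertainty.
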