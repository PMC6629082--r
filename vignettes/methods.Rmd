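---
title: "Methods: diversity and structure analysis of inbred SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and structure analysis of inbred SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenpanel)
```

`popgenpanel` implements the statistical workflow used to characterise crop
germplasm collections genotyped with biallelic SNP chips: marker quality
control, Nei's gene-diversity partition with gene-flow estimates,
intra-chromosomal linkage-disequilibrium (LD) scans with LOESS decay
estimation, Bayesian admixture clustering with Evanno model choice, and
distance-based clustering and ordination.  The package targets inbred
(selfing) cereal panels — wheat being the motivating case, with 21
chromosomes in the A, B and D genomes — but nothing restricts it to wheat
beyond the default chromosome naming.

This vignette records the models, the tunable parameters and their defaults,
the numerical conventions, and the reasoning behind design choices where the
methodology literature leaves them open.

## Data model

Genotypes are stored as allele doses (0/1/2 copies of the locus' second
allele, `NA` missing) in a `geno_matrix`.  Alleles are kept in the order the
source file presents them; no minor-allele re-polarisation happens at read
time, so doses are stable across subsets.  A `genetic_map` places markers on
chromosomes at centimorgan positions; within a chromosome markers are sorted
by position with ties broken by locus id, which makes every scan
deterministic.

## Marker quality control

`filter_markers()` removes loci with missingness strictly above
`max_missing` (default 0.25) and then loci with minor allele frequency (MAF)
strictly below `min_maf` (default 0.05); a locus exactly at a boundary is
retained.  MAF is allele-count based — heterozygotes contribute one copy of
each allele — which for a highly homozygous panel is nearly identical to a
line-count definition.  The missingness-first precedence makes the report
additive: input = removed-by-missingness + removed-by-MAF + retained, the
arithmetic convention of germplasm-panel reports.

`partition_polymorphism()` classifies each locus as polymorphic within a
sample group iff at least two alleles are observed in that group's
non-missing calls.  A locus fixed for different alleles in two groups is
polymorphic in neither and is excluded from the union count.

`thin_by_decay()` implements LD-spacing marker selection: a greedy
left-to-right pass along each chromosome retaining a marker only when it
lies at least the chromosome's decay distance beyond the last retained one.
With spacing zero everything mapped is retained.  How many markers survive
is data dependent; the rule, not a target count, is the contract.

## Diversity statistics

For a biallelic locus with allele frequency $p$ ($q = 1-p$):

* gene diversity $H = 2pq$ (maximum 0.5 at $p = 0.5$),
* Botstein's polymorphic information content
  $\mathrm{PIC} = 1 - (p^2 + q^2) - 2p^2q^2$ (maximum 0.375).

PIC is deliberately the Botstein form even though its biallelic ceiling is
0.375; reports that quote a "maximum of 0.5" are describing gene diversity,
and the two statistics are kept distinct throughout.

`diversity_partition()` computes Nei's hierarchical partition for a
grouping: per locus, total diversity $H_T$ from the unweighted mean of the
subpopulation allele frequencies and $H_S$ as the unweighted mean of the
within-subpopulation diversities (a `weighted` option switches both to
sample-size weights).  $H_T$ and $H_S$ are averaged over loci *first*, and
only then are
$D_{ST} = H_T - H_S$, $G_{ST} = D_{ST}/H_T$ and the McDonald–McDermott
gene-flow estimate $Nm = 0.5\,(1 - G_{ST})/G_{ST}$ formed, so the printed
triple of any report row satisfies the closed forms exactly.  Averaging
per-locus $G_{ST}$ values instead would not have this property and is not
what panel reports tabulate.

**Small-sample bias.**  The plug-in $\hat H_S$ is biased downward by
$\approx H_S/\tilde n$ for groups of $\tilde n$ inbred lines, which biases
$G_{ST}$ upward — with 50 lines per group the bias is an order of magnitude
larger than the Monte-Carlo error of a 2000-locus panel.  The default
(`correct_bias = FALSE`) reproduces the plug-in convention of the classical
POPGENE-style reports; `correct_bias = TRUE` applies the Nei & Chesser
corrections (using per-group line counts and observed heterozygosity, so
selfing panels are handled without special casing), and is what the
package's own parameter-recovery tests use.  When the goal is comparing an
estimate against a simulation's truth, use the corrected estimator.

`gene_flow()` is strictly decreasing in $G_{ST}$ and undefined at
$G_{ST} \le 0$ (returned as `NA`, never a number).  `summarize_by_region()`
tabulates marker counts, mean $H_T$ and mean PIC per chromosome, per genome
and overall, with genome rows aggregating their chromosomes' loci exactly.

## Linkage disequilibrium

LD between two loci is $r^2 = D^2 / (p_A q_A p_B q_B)$ from two-locus
haplotype frequencies.  Genotypes are unphased, so
`haplotype_freqs_em()` resolves the double-heterozygote phase ambiguity by
EM (at most 100 iterations, tolerance $10^{-8}$); all other genotype
configurations determine their gametes, and a fully homozygous pair of loci
reduces to direct haplotype counting.

**Inbred panels and pseudo-replication.**  In a selfing panel the two
gametes of a line are near-identical copies.  Counting $2n$ gametes doubles
the apparent sample size and inflates the significance of every pair — at
$\alpha = 0.001$ the realised type-I error rises roughly twenty-fold.
`ld_scan()` therefore *haploidizes* by default whenever panel-wide
heterozygosity is below 5%: for each pair it uses the lines homozygous at
both loci, one haplotype per line.  For outbred data
(`haploidize = FALSE`, or automatically when heterozygosity is
appreciable) the EM path over all gametes is used.  Pairs whose $r^2$ is
undefined (a locus monomorphic among the complete cases) are excluded from
all summaries.

Significance comes from a two-sided Fisher exact test on the integer
haplotype count table (fractional EM expectations are rounded by largest
remainder); with `method = "auto"` a Pearson chi-square without continuity
correction substitutes when every cell is at least 5.  The scan evaluates
all intra-chromosomal pairs within `window_cM` (default 50 cM, read as a
genetic-distance window) and reports per-chromosome mean $r^2$ and the
percentage of pairs significant at `alpha` (default 0.001), averaged over
all evaluated pairs — averaging only significant pairs is a reporting
alternative some tools offer, and can be recovered from the returned table.

`fit_ld_decay()` fits a degree-1 LOESS (span 0.5, tricube weights; span
exposed) of $r^2$ on distance for one chromosome (at least 20 pairs) and
reports the smallest distance on a 0.1 cM grid at which the curve falls to
the critical $r^2$ — the mean $r^2$ of the chromosome's genome
(`critical_r2_per_genome()`).  The decay distance is reported in whole
centimorgans, matching how such tables are printed; a curve that starts
below the critical value gives 0, and one that never crosses is censored at
the maximum observed distance.

## Bayesian admixture model

`run_admixture_mcmc()` is a Gibbs-sampler implementation of the admixture
model with independent allele frequencies: each of a line's two allele
copies at a locus originates from one of $K$ latent subpopulations with
probabilities $q_i$, allele frequencies carry a $\mathrm{Beta}(1,1)$ prior
($\lambda = 1$), admixture vectors a symmetric Dirichlet$(\alpha)$ prior
with a single $\alpha$ shared across subpopulations, updated by a
Metropolis random walk (uniform prior on $(0, 10)$, proposal sd 0.025,
initial value 1).  The independent-frequencies prior is the simpler
documented model and is sufficient for $\Delta K$-style model choice; a
correlated-frequencies variant is deliberately out of scope.  Inbred
homozygosity needs no special casing: both copies simply tend to carry the
same allele.  Missing genotypes are skipped in every update.

The model-choice statistic is the harmonic-style estimator
$\ln P = \overline{L} - \mathrm{var}(L)/2$ over the post-burn-in trace of
the complete-data log-likelihood.  Defaults mirror the common run design —
burn-in 10000, 100000 recorded sweeps, $K = 1..10$, 7 replicates
(`structure_scan()`), with per-run seeds `seed + 1000 K + replicate` so a
scan is reproducible from one master seed.  The package's own validation
uses a scaled-down design (burn-in 2000, 5000 sweeps, $K = 1..5$, 3
replicates on 150 lines × 300 loci), which recovers a true $K = 3$ and
aligns admixture proportions to within a mean absolute error of 0.1.

`evanno_delta_k()` computes $\Delta K = |L''(K)| / \mathrm{sd}(L(K))$
across replicates; it is undefined at the endpoints of the $K$ range and
wherever the replicate sd is zero, and a linear $\ln P$ profile yields no
peak (`best_K` is `NA`, never silently 1).  `assign_membership()` applies
the strict printed conventions: strong membership $q > 0.7$, moderate
$0.5 < q \le 0.7$, admixed otherwise.  `aggregate_runs()` aligns replicate
Q matrices by greedy column correlation matching to the first run (ties by
column index) before averaging — full label-switching optimisation is out
of scope.

## Distances, trees, ordination

`simple_matching_distance()` compares genotype *states* (0/1/2), counting
matches over loci non-missing in both lines; this is the convention of
DARwin-style SNP analyses.  Pairs sharing fewer than 10 comparable loci are
flagged; a pair with none is an error.

`neighbor_joining()` is the Saitou–Nei algorithm with two determinism
conventions fixed: the joined pair minimises the Q-criterion with ties
broken by the smallest index pair, and a negative branch estimate is
clamped to zero with the deficit moved to its sister branch so path lengths
are preserved.  The result is an unrooted `ape::phylo` tree with a
trifurcating root and $2n - 3$ edges; on additive inputs the tree's path
lengths reproduce the input distances to $10^{-9}$.

`pcoa()` double-centres $-\tfrac12 D^2$ (Gower), eigendecomposes, and
scales eigenvectors by the square roots of the positive eigenvalues.
Variance proportions are taken over positive eigenvalues only; negative
eigenvalues — possible for non-Euclidean distances such as simple matching
with missing data — are reported separately rather than folded in.

## Synthetic panels

Because real chip genotypes of the motivating panels are not distributed,
`generate_panel()` provides fully specified ground truth under the
Balding–Nichols F-model: ancestral frequencies
$p_0 \sim U(0.05, 0.95)$, subpopulation frequencies
$p_k \sim \mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$, admixture rows
$Q_i \sim \mathrm{Dirichlet}(\alpha \mathbf 1_K)$, first allele copy from
the mixture $\sum_k q_{ik} p_k$, second copy duplicating the first with
probability `selfing_rate` (default 0.98) and i.i.d. missingness (default
3%, capped at 25%).  `generate_linked_panel()` adds along-chromosome LD by
drawing, per subpopulation, a pool of founder haplotypes (default 8) and
building each gamete as a founder mosaic with switch probability
$1 - e^{-c\,\Delta d}$ between adjacent markers ($c$ = `recomb_rate` per
cM).

Defaults mirror the motivating study conditions: 354 lines, 11196 mapped
SNPs on 21 chromosomes × 160 cM, six subpopulations at $F = 0.15$,
$\alpha = 0.2$.  Chromosome length and $F$, $\alpha$, founder and
recombination settings are the values a wheat diversity panel would make
plausible; they were chosen once from the panel descriptions, not tuned.
The generator reproduces the *statistics* the pipeline estimates — a MAF
spectrum with a sub-5% tail, realized $G_{ST}$ converging to the F-model
expectation $1 - (1-F)/(1-F/K)$, strong assignability at small $\alpha$,
and $r^2$ decaying in genetic distance.  It does not emulate wheat biology:
no coalescent ancestry, selection, mutation, genotyping-error structure, or
realistic marker-density variation along chromosomes.  Passing recovery
tests therefore demonstrate correctness of the estimators under the assumed
generative model, not robustness to everything real data can do.

Selfing is modelled as copy duplication rather than generational selfing;
for every statistic the package computes (dose frequencies, homozygosity,
haplotype counts) the two are equivalent parameterisations.

## Pipeline

`run_pipeline()` chains the stages in the order a panel study reports them:
per-era QC → polymorphism partition → per-era diversity and LD tables →
LD-decay thinning of the common polymorphic markers → a joint admixture
pre-pass on the thinned set, then per-era scans with Evanno choice and
membership classes → Nei partition over the assigned subpopulations
(structured lines only, admixed excluded; subpopulations with fewer than
two members are dropped) → simple-matching distances, neighbour-joining
tree and PCoA.  Configuration is a flat validated list (or YAML file);
unknown keys are rejected before any computation, every artifact lands in
`out_dir` as delimited text or Newick, and a YAML log echoes seeds and
thresholds so each number is traceable to a configuration.  Stages whose
outputs already exist are reused unless `overwrite = TRUE`.

## Numerical conventions and limitations

* Frequencies inside the Gibbs sampler are clamped to
  $[10^{-9}, 1-10^{-9}]$ and admixture entries to $\ge 10^{-12}$; Q rows
  are renormalised on output.
* `set.seed()` governs everything, including the C++ sampler (it uses R's
  RNG); identical seeds give byte-identical results.
* The LOESS decay grid step is 0.1 cM; reported decays are whole
  centimorgans, so decays below 0.5 cM round to 0.
* Validation problem sizes (150–354 lines, 300–5000 loci, scaled-down MCMC)
  were chosen as the smallest panels at which the recovery properties are
  statistically decisive.
* Known limitations: no correlated-allele-frequency or linkage model in the
  sampler, no D′ or haplotype blocks, no AMOVA or $F_{IS}$, no bootstrap
  support on trees, no imputation.
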