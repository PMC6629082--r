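# popgenpanel

Genetic diversity and population-structure analysis for SNP-genotyped crop
germplasm panels, tuned to inbred (selfing) cereal collections such as bread
wheat (21 chromosomes in the A, B and D genomes).

Breeders and genebank curators characterising a diversity panel — say, a few
hundred landraces and modern cultivars genotyped on a SNP chip — run the
same analysis chain over and over: filter markers, quantify diversity,
measure linkage disequilibrium and its decay, infer latent subpopulations,
and visualise relationships. `popgenpanel` packages that chain as tested,
reproducible R functions:

* **Marker QC** — missingness and MAF filters with additive accounting
  (`filter_markers`), polymorphism partition between germplasm groups
  (`partition_polymorphism`), LD-decay marker thinning (`thin_by_decay`).
* **Diversity statistics** — Botstein PIC and Nei gene diversity per locus;
  Nei's partition H_T, H_S, D_ST = H_T − H_S, G_ST = D_ST/H_T and the
  McDonald–McDermott gene-flow estimate Nm = 0.5(1 − G_ST)/G_ST for any
  grouping (`diversity_partition`); chromosome/genome summary tables
  (`summarize_by_region`).
* **Linkage disequilibrium** — intra-chromosomal r² with EM haplotype
  frequencies for unphased data (inbred-aware counting), Fisher-exact
  significance, per-genome critical r², and LOESS decay distance per
  chromosome (`ld_scan`, `fit_ld_decay`).
* **Population structure** — a Gibbs-sampler implementation of the Bayesian
  admixture model (independent allele frequencies, inferred Dirichlet
  concentration), replicate scans over K, Evanno ΔK model choice,
  q-threshold membership classes, label-aligned run averaging
  (`run_admixture_mcmc`, `structure_scan`, `evanno_delta_k`,
  `assign_membership`, `aggregate_runs`).
* **Distances and ordination** — simple-matching genetic distance,
  deterministic neighbour-joining trees (Newick output via `ape`), and
  principal coordinates analysis (`simple_matching_distance`,
  `neighbor_joining`, `pcoa`).
* **Synthetic panels** — a Balding–Nichols F-model generator with Dirichlet
  admixture, selfing, missingness and optional along-chromosome linkage,
  returning full ground truth for validation (`generate_panel`,
  `generate_linked_panel`, `simulate_panel`).
* **Pipeline** — `run_pipeline()` chains everything from a validated
  config list or YAML file into an output directory of delimited tables,
  Newick trees and a run log; `inst/cli/popgenpanel.R` is a thin
  command-line wrapper.

See `vignettes/methods.Rmd` for the models, parameter defaults and the
reasoning behind the numerical conventions.

## Worked example

Simulate a landrace-like panel (170 inbred lines, 3 latent subpopulations),
filter it, fit the admixture model at K = 3 and partition its diversity:

```r
library(popgenpanel)

panel <- simulate_panel("landrace-like", n_loci = 800, seed = 42)
fr <- filter_markers(panel$genotypes)
fr
#> Marker filter report
#>   input loci:           800
#>   removed, missing > 25%:      0
#>   removed, MAF < 5%:         57
#>   retained:             743

fit <- run_admixture_mcmc(fr$genotypes, K = 3,
                          burn_in = 1000, n_iter = 3000, seed = 1)
mem <- assign_membership(fit)
table(mem$class)
#>   strong moderate  admixed
#>      113       43       14

structured <- mem$class != "admixed"
diversity_partition(fr$genotypes[structured, ],
                    factor(mem$subpopulation[structured]))
#> Nei diversity partition
#>   samples: 156   loci: 743
#>   H_T = 0.3671   H_S = 0.3440   D_ST = 0.0231
#>   G_ST = 0.0630   Nm = 7.44
```

Reading the output: 57 of 800 simulated markers fall below 5% MAF and are
excluded, as expected from the generator's allele-frequency spectrum. At
K = 3, 113 lines are strong members of a subpopulation (q > 0.7) and 14
remain admixed (q ≤ 0.5). Among the 156 structured lines, 6.3% of the total
gene diversity lies between subpopulations (G_ST = 0.063), i.e. a high
gene-flow estimate (Nm ≈ 7.4) — the subpopulations are weakly
differentiated, consistent with the simulated divergence (F = 0.12) and
admixture.

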