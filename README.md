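# hicsubcomp

Probabilistic inference of nuclear **sub-compartments** from
inter-chromosomal (*trans*) Hi-C contacts.

## The problem

Chromatin is organized into a handful of nuclear neighborhoods —
speckle-associated active chromatin, polycomb-repressed domains,
lamina-associated domains (LADs), nucleolus-associated domains (NADs), and
so on. Population Hi-C mixes all cells' configurations together, and a given
genomic locus may sit in different neighborhoods in different cells. Hard
clustering of Hi-C profiles hides that heterogeneity. `hicsubcomp` instead
estimates, for every genomic bin *i*, the **probability** `P_ik` that the
bin resides in sub-compartment *k* across the cell population, together with
a per-bin technical **bias** `B_i`, from trans contacts only (cis contacts
are dominated by TADs and distance decay and carry little compartment
signal).

## The model

Each trans bin pair's observed read count is Poisson:

    N_ij ~ Poisson(F_ij),   F_ij = R_ij * sum_k C_ik C_jk,   C_ik = B_i P_ik >= 0

The factorized rate encodes three assumptions: loci on different chromosomes
localize independently; loci in different sub-compartments do not contact
each other; loci sharing a sub-compartment contact at a constant rate.
`R_ij = 1 + alpha*r_i*r_j + beta*(r_i + r_j)*r_i*r_j` corrects for the Rabl
configuration (centromere-with-centromere / telomere-with-telomere
clustering across chromosomes), with `r` the relative arm position running
from -0.5 at the centromere to +0.5 at the telomere.

The log-likelihood `sum_ij [N_ij ln F_ij - F_ij]` is maximized by block
coordinate ascent: every per-locus subproblem in `C_i` (all other rows
fixed) is convex and solved to its KKT conditions under nonnegativity by a
projected Newton method; `(alpha, beta)` get a damped Newton update each
outer iteration; the likelihood trace is provably non-decreasing. The
landscape is multi-modal, so the fitter runs multiple restarts (the first
seeded by spectral clustering of the contact matrix, the rest random) and
keeps the highest-likelihood one.

On top of the fit the package provides:

* **AIC model selection** for the number of sub-compartments,
  `AIC = 2(nM + 2) - 2 ln L` with `n` the number of non-empty windows;
* **Information content** per bin, `IC_i = sum_k p_ik log2(p_ik M)` (0 bits
  = maximally heterogeneous, `log2(M)` = deterministic localization);
* a **forward simulator** (Poisson sampling under the same generative
  model), binomial-thinning **down-sampling**, population **mixture**
  construction, and annotation-based truth randomization — the test bed for
  everything above;
* readers/writers for 4DN-style `.pairs`, chrom.sizes, BED blacklists and
  region groups, bedGraph tracks, TSV score tables and JSON run summaries;
* a CLI (`inst/cli/hicsubcomp`) with `infer`, `simulate`, `downsample`,
  `mix`, `ic`, `aic-sweep` and `assign` subcommands.

## Worked example

```r
library(hicsubcomp)

# synthetic genome: 4 chromosomes x 10 Mb, 100-kb bins, 3 sub-compartments
truth <- make_synthetic_genome(n_chroms = 4, chrom_length = 10e6,
                               bin_size = 1e5, M = 3, seed = 1)

# forward-simulate trans contacts under the generative model
contacts <- simulate_contacts(truth$binning, truth$C, alpha = 0.3, beta = 0.1,
                              depth_scale = 20, seed = 2)
contacts
#> contact_table: 49502 trans bin pairs, 439193 read pairs (400 bins)

# down-sample to 5% depth and fit 3 sub-compartments
low <- downsample_contacts(contacts, fraction = 0.05, seed = 3)
fit <- fit_compartments(low, fit_config(M = 3, seed = 4, n_restarts = 3))
fit
#> compartment_model: 400 bins x 3 sub-compartments; alpha=0.3644 beta=-0.01307; logL=-30845.3

# compare inferred probabilities with the generating ones
mc <- matched_correlation(decompose(fit)$P, truth$P)
round(mc$r, 3)
#> [1] 0.996 0.996 0.993

aic(fit)
#> [1] 64094.51
summary(information_content(decompose(fit)$P))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.1898  0.8703  1.0840  1.0861  1.3315  1.5850
```

Even at 5% of the simulated depth the inferred sub-compartment probabilities
correlate above 0.99 with the generating ones (columns matched by best
permutation, since compartment labels are arbitrary), the Rabl strength
`alpha` is recovered near its generating value 0.3, and the per-bin
information content spans heterogeneous (~0.2 bits) to well-localized
(~1.6 = log2(3)) bins.

The same pipeline from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hicsubcomp", package = "hicsubcomp"))')
Rscript "$CLI" infer --pairs reads.pairs --chrom-sizes genome.chrom.sizes \
    --bin-size 100000 --M 5 --restarts 5 --seed 7 --out run
# -> run_scores.tsv, run_comp1..5.bedGraph, run_summary.json
```

## Layout

* `R/`, `src/` — package code (R interface, RcppArmadillo optimizer core)
* `tests/testthat/` — unit, property and end-to-end suites with independent
  dense-enumeration and finite-difference oracles
* `vignettes/subcompartment-inference.Rmd` — the methods vignette: model
  assumptions, optimizer design, simulator scope, numerical choices
* `scripts/acceptance.R` — the reproduction script above
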