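---
title: "Sub-compartment inference from trans Hi-C contacts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-compartment inference from trans Hi-C contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicsubcomp)
```

## The generative model

`hicsubcomp` treats the nucleus as partitioned into `M` sub-compartments and
a cell population as heterogeneous: genomic bin `i` resides in
sub-compartment `k` with probability `P_ik`, `sum_k P_ik = 1`. Only
inter-chromosomal (trans) contacts are modeled. Cis contacts are shaped by
TADs, loops and genomic-distance decay, none of which reflect nuclear
neighborhood identity; trans contacts, by contrast, are dominated by
compartment co-location, which is why no distance-decay normalization is
needed anywhere in the package.

Three assumptions generate the rate model:

1. two loci on different chromosomes localize independently;
2. loci in different sub-compartments in a given cell do not contact;
3. loci sharing a sub-compartment contact at a constant rate.

With a per-bin technical bias `B_i` (mappability, accessibility, ligation
and PCR efficiency) absorbed into `C_ik = B_i P_ik`, the expected count for
a trans pair is

    F_ij = R_ij * sum_k C_ik C_jk,      N_ij ~ Poisson(F_ij),

and the log-likelihood is `sum_ij [N_ij ln F_ij - F_ij]` over all eligible
trans pairs (additive constants in `N_ij` dropped). A fitted model is
re-expressed through `B_i = sum_k C_ik` and `P_ik = C_ik / B_i`.

**The Rabl correction.** Assumption 1 is violated by the Rabl
configuration: centromeres cluster with centromeres and telomeres with
telomeres across chromosomes. The package models this with
`R_ij = 1 + alpha*r_i*r_j + beta*(r_i + r_j)*r_i*r_j`, where `r_i` in
[-0.5, 0.5] is the relative position of the bin along its chromosome arm
(-0.5 centromere, +0.5 telomere). This is the symmetric third-order power
series in `(r_i, r_j)` with all single-variable terms removed — those are
absorbed by the bias factors. `alpha` sets the strength of the effect,
`beta` its skew toward the centromeric or telomeric side; `alpha = beta = 0`
recovers plain bias factorization. `R_ij` must stay positive; the optimizer
enforces positivity over the whole square [-0.5, 0.5]^2 (a conservative
sufficient condition) rather than only at observed pairs.

**Relative arm positions.** When a centromere coordinate is supplied, `r`
is the bin midpoint's arm distance from the centromere divided by the arm
length, minus 0.5 — both arms run from -0.5 to +0.5 independently. Without
a centromere file the chromosome is treated as acrocentric (centromere at
coordinate 0), so `r` reduces to a monotone position proxy. The arm-wise
definition for metacentric chromosomes is this package's choice; it is the
natural extension of the centromere-to-telomere parameterization.

**Identifiability caveats, by design.** Two model violations leave the
likelihood's *form* intact and only change the reading of `C`:

* a mixture of two cell populations adds a second factorization term, so
  fitting `2*M0` compartments on a mixed population recovers both
  populations' score sets (the package's mixture tests exercise exactly
  this), but `B_i P_ik` no longer decomposes per population;
* a per-compartment interactivity modifier `S_k` (condensed heterochromatin
  contacting less than open chromatin, say) is absorbed as
  `C_ik = B_i P_ik S_k`, skewing that compartment's reported probabilities
  globally up or down while preserving between-bin ordering. No rescaling
  is attempted when reporting `P`; users should read `P` columns
  comparatively, not as calibrated occupancies.

For the same reason `beta` is only weakly identified at moderate depth —
part of an arm-position-dependent rate can also be absorbed by the biases —
so recovered `beta` values scatter around the generating value much more
than `alpha`. The package's parameter-recovery tests therefore check the
score (gradient) at the generating values and null-simulation coverage
rather than point equality of `beta`.

## Optimization

Minus the log-likelihood is convex in each score row `C_i` with everything
else fixed (the Hessian `-H_i` is a nonnegative weighted sum of outer
products), and convex in `(alpha, beta)` with all rows fixed. The fitter
exploits this block structure:

1. **Per-locus solves.** For each chromosome in input order, every
   non-blacklisted locus on it is solved to the KKT conditions of
   `max L_i` s.t. `C_i >= 0` by projected Newton with Armijo backtracking
   (gradient fallback if the Newton system is degenerate). Loci on one
   chromosome share no pair, so they are conditionally independent given
   the other chromosomes and the sweep's result does not depend on
   within-chromosome order. A locus with no trans reads is set to the exact
   optimum, the zero row.
2. **Rabl update.** One damped Newton step on `(alpha, beta)` per outer
   iteration, halving the step until the likelihood does not decrease and
   `R` stays positive on [-0.5, 0.5]^2. Updating the coefficients to full
   convergence each sweep is unnecessary: the outer loop revisits them.
3. **Convergence.** Outer iterations stop when the relative likelihood
   improvement falls below `rel_tol` (default 1e-6) or at
   `max_outer_iters` (default 400; ultralow-depth data genuinely needs
   100-200 sweeps). A final polish sweep at the terminal Rabl coefficients
   leaves every locus at its subproblem's KKT point; the run summary
   records the largest remaining KKT residual, normalized by each
   subproblem's gradient scale (`1 + max|w_i|`, with `w_i` the
   Rabl-weighted partner column sums) since absolute gradients scale with
   sequencing depth.

Every quantity involving *all* pairs — the `-sum F_ij` term, the Rabl
gradients' rate terms — is evaluated in closed form from cached per-column
moment sums (`sum_j C_jk`, `sum_j r_j C_jk`, `sum_j r_j^2 C_jk`, globally,
per chromosome and per region group), so an outer sweep costs
O((nnz + n) * M) rather than O(n^2 M). No epsilon is ever added to a rate:
a pair with `N_ij > 0` and `F_ij = 0` reports `-Inf` and the line searches
simply never accept such iterates.

**Ascent guarantee.** Each block update cannot decrease the likelihood, so
the per-outer-iteration trace is non-decreasing; the test suite asserts
this on every fit it runs (tolerance 1e-8 relative).

**Restarts and initialization.** The likelihood is multi-modal in the
joint variables, so the fitter runs `n_restarts` independent starts
(default 5) and keeps the best final likelihood, ties broken by lowest
restart index. Initial rows are scaled to
`sqrt(T_i / (M * mean rate per eligible pair))` (`T_i` = bin i's trans
read-ends), which puts initial rates at the observed magnitude. Two details
matter at low depth and were chosen after the uniform alternative failed:

* *row shapes are sharp, not uniform*: each row is a Dirichlet draw with a
  single dominant compartment (concentration 8 vs 0.3). Rows with
  near-equal entries start the ascent at a compartment-symmetric
  configuration from which escape is extremely slow at 1% depth — every
  such restart stalled far below the optimum reached from sharp starts;
* *the first restart is spectrally seeded*: dominant compartments come from
  k-means on the leading `M+1` eigenvectors of the symmetrically
  normalized trans-contact matrix (attempted only up to 6000 bins, where
  the dense decomposition is cheap; random seeding otherwise). Purely
  random sharp restarts reach the high-likelihood basin on most datasets
  but not all; the spectral start lands in a data-consistent basin
  reliably, while the remaining random restarts preserve the
  multiple-random-starts safety net. Selection between them stays purely
  by final likelihood.

All randomness flows from the mandatory `seed` in `fit_config()`, recorded
in the run summary; reruns are byte-identical.

## Excluded regions

Two exclusion mechanisms, both applied at load time and inside the
likelihood:

* **blacklisted bins** (assembly artifacts): score rows pinned at zero,
  pairs touching them dropped;
* **region groups** (e.g. translocation partners, whose "trans" contacts
  are really cis): all pairs *within* one group are excluded from the
  likelihood sum and from the closed-form rate totals, while each member
  still interacts normally with the rest of the genome.

`load_pairs()` returns exact filter accounting (cis / blacklisted /
grouped / unknown-chromosome read counts), so input reads are conserved —
a tested invariant.

## Model selection and heterogeneity

`aic()` implements `AIC = 2k - 2 ln L` with `k = n*M + 2`, `n` the number
of non-empty (>= 1 trans read, non-blacklisted) windows; the two extra
parameters are the Rabl coefficients and are counted whether or not the
Rabl term is enabled, matching the definition the rest of the package's
sweep logic assumes. A `k_formula = "nM"` variant is available.
`aic_sweep()` refits each candidate `M` with the same restart budget
(seeds offset per `M`) and selects the argmin.

`information_content()` measures per-bin localization certainty in bits,
`IC_i = sum_k p_ik log2(p_ik M)` with `0 log 0 = 0`: 0 for a uniform row,
`log2(M)` for a one-hot row. The uniform baseline `1/M` generalizes the
five-compartment definition (baseline 0.2); log base 2 is kept as is. IC is
permutation-invariant and strictly decreases along any mixing path toward
the uniform row — both tested properties.

`assign_compartments()` takes the per-row argmax, ties to the lowest
compartment index (a documented, deterministic convention), missing rows to
`NA`. `matched_correlation()` handles label arbitrariness by maximizing
summed Pearson correlation over column permutations — exhaustively for
`M <= 6`, by a Hungarian assignment solver above that (the two routes are
cross-checked in tests); a wider inferred matrix is matched to the best
subset of its columns, which is how mixture deconvolution is scored.

## The simulator, and what passing tests do and do not show

`simulate_contacts()` draws every eligible trans pair's count from
`Poisson(depth_scale * R_ij * C_i . C_j)` — the generative model itself.
`downsample_contacts()` implements sequencing-depth reduction as per-pair
binomial thinning, which is distributionally exact for Poisson tables
without materializing reads. `mix_contacts()` thins the deeper of two
tables to the shallower's total and sums — an equal-weight two-population
mixture. `randomize_from_annotation()` turns a discrete compartment
annotation into noisy truth scores: the annotated compartment draws from
`U(1-NL, 1)`, the others from `U(0, NL)`, rows then normalized to sum to 1
(row-sum normalization is this package's reading of "normalized"; it is
what makes the rows probabilities).

`make_synthetic_genome()` produces the standard test bed: equal-length
chromosomes, contiguous dominant-compartment domains of 5-20 bins
(0.5-2 Mb at 100-kb bins, the scale of real sub-compartment domains),
Dirichlet row perturbation with mean dominant probability ~0.8, and
log-normal bias with sdlog 0.25 (~25% coverage variation). These defaults
are the package's standard simulation conditions and are not tuned per
test.

Because simulated data satisfy the model assumptions *exactly*, passing
recovery tests demonstrate correctness and statistical efficiency of the
estimator — not robustness to everything real Hi-C contains. The simulator
deliberately omits cis contacts, TADs and loops (never modeled),
fragment-level bias (absorbed only as smooth per-bin bias),
compartment-specific interactivity (see the `S_k` caveat above), and
overdispersion beyond Poisson. Results on real data inherit the
corresponding caveats.

## Problem sizes and numerical conventions

The shipped test and reproduction scenarios use: 1600 bins (8 chromosomes
x 20 Mb at 100 kb) with ~48M simulated read pairs thinned to 1% for the
low-depth recovery scenario; 600 bins for mixture deconvolution (M = 10);
400 bins x 10 seeds x M in 1..6 for AIC consistency; 4-9 bins with dense
grid and finite-difference oracles for the optimizer's correctness checks.
These sizes were chosen so the full suite runs in about a minute while
keeping >= 300 observed pairs per locus in the low-depth scenario, the
regime the robustness claim is about.

Conventions worth knowing when interfacing:

* bins are 0-based half-open internally and in all written tables;
  `.pairs` positions are read as 1-based (4DN convention) and converted;
  strand columns are read and ignored;
* reads mapping beyond a chromosome's declared length are an error
  (assembly mismatch), not silently clamped;
* pairs on chromosomes absent from the chrom.sizes file are skipped with a
  counted warning;
* score tables are written at 6 decimals; round-tripping through
  `read_scores()` reproduces `P` to that precision;
* restart ties on final likelihood go to the lowest restart index; argmax
  assignment ties go to the lowest compartment index.

## Known limitations

* Only text `.pairs` input (no `.hic`/`.cool` readers) and no
  restriction-fragment-level processing.
* No global optimality guarantee — coordinate ascent on a non-convex
  landscape with restarts; the spectral seed mitigates but cannot remove
  this.
* The spectral seed builds a dense contact matrix, so it is skipped above
  6000 bins; genome-wide fine binning falls back to random restarts only.
* `P` columns are comparable between bins, not calibrated occupancies,
  whenever per-compartment interactivities differ (the `S_k` caveat).
* AIC counts parameters as `nM + 2` regardless of constraint activity;
  treat the selected `M` as a statistical reference point, not a
  biological truth — deeper data support more compartments.
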