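---
title: "Models and methods behind hybridzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in hybridzone,
the choices made where several defensible options existed, and what the
simulation-based validation does and does not establish.

## The scientific setting

Two related species meet in a contact zone. Individuals from reference
(allopatric) populations, sympatric pure populations and mixed populations
are scored at a small panel of codominant microsatellite loci. The analysis
asks, per mixed population: how many individuals are pure parentals, F1s,
F2s, backcrosses or later-generation hybrids, and is the distribution of
ancestry unimodal (a hybrid swarm) or bimodal (two parental clusters)?

hybridzone implements that chain end to end and, because such field data
sets are often unavailable for reanalysis, ships a simulator that emulates
the study design so every claim in the package is backed by a measurable
synthetic experiment.

## The synthetic-data generator

`simulate_parental_pools()` draws, per locus, an ancestral frequency vector
from a symmetric Dirichlet(1) and two descendant species pools from the
Balding–Nichols model, descendant ~ Dirichlet(p_anc (1−F)/F). The single
divergence knob F is calibrated to the between-species differentiation of
the motivating system: with F = 0.33, the realized Weir–Cockerham theta
between sampled founder panels of 44 and 43 individuals falls in roughly
0.2–0.45 across seeds, bracketing the observed between-species range of
0.29–0.37. Ten loci with 10 alleles each in the joint pool realize a mean
of about 4.7 observed alleles per locus inside one sampled pure population,
matching the allelic richness reported for allopatric populations
(4.5–6.0). These defaults are the package's study conditions; they were
fixed once from those published summary ranges.

Hybrid classes are generated at the gamete level under free recombination
and random mating: a species-A gamete draws each locus from pool A, an F1
gamete picks its origin A/B with probability 1/2 per locus, and classes are
composed as F1 = (A, B), F2 = (F1, F1), BC1 = (parent, F1). This is
distribution-equivalent to explicit mate-pairing simulators for these
classes, which is all the downstream models can see; the equivalence holds
only at the distribution level, not per-pedigree. "Fn" (advanced-generation
hybrid) has no generative definition in the classification scheme — it is
defined there only as a q1 interval — so the generator defaults to an
F2 × F2 offspring, which under free recombination shares the F2 gamete
marginal. Every simulated individual records its latent per-locus origin
pair, giving the tests an exact oracle for the genotype-frequency-class
expectations.

What the generator does **not** emulate: linkage and recombination maps,
mutation, selection, spatial structure, within-species population
substructure (all reference panels of one species draw from a single pool,
so within-species theta is ~0 by design, unlike the 0.05–0.25 observed
between real conspecific populations), allele-size homoplasy and
missing-data patterns. Passing tests therefore demonstrate correctness and
calibration of the estimators and samplers under idealized neutral
conditions, not robustness to those real-data features.

## Diversity statistics and F-statistics

H_E is the uncorrected 1 − Σp² (the common calculator default); an
unbiased 2n/(2n−1) variant sits behind a flag. Per-population values are
means over loci and the parenthetical spread is the across-locus standard
error (sd/√L), switchable to sd.

F_IS and F_ST are Weir–Cockerham variance-component estimators. For one
population, per allele, with n genotyped individuals, allele frequency p
and heterozygote proportion h:

* b = n/(n−1) · [p(1−p) − (2n−1)/(4n) · h]
* c = h/2, and f = 1 − Σc / Σ(b+c), components summed over alleles and loci.

The two-population theta uses the full r-population components (a, b, c)
with n_c, summed over alleles and loci: theta = Σa / Σ(a+b+c). Permutation
p-values shuffle whole multilocus individuals between the two populations
(the correct exchangeable unit for codominant genotype data) with the
+1/(n_perm+1) correction. Because the ambiguity "F_IS = Weir–Cockerham f
or (H_E−H_O)/H_E?" cannot be resolved from a table caption, both are
implemented; W&C is the default and `fis = "genalex"` selects the ratio
form. Loci with undefined components (monomorphic, or fewer than two
genotyped individuals) are skipped and reported, never silently zeroed.

## Distances and ordination

Nei's D_A between individuals treats each individual as a "population"
with allele frequencies 0, 1/2 or 1. Pairs are averaged over the loci
typed in both; a pair sharing no typed locus is flagged undefined rather
than imputed. PCoA is classical scaling via `stats::cmdscale` (Gower
double-centering of −D²/2); percent variance is reported over the positive
eigenvalues only and negative eigenvalues are counted and dropped, with
the Lingoes correction available behind a flag. This matches how ordination
percentages are conventionally reported for non-Euclidean genetic
distances.

## The admixture model

`run_admixture()` is a Gibbs sampler for the admixture model with
independent allele frequencies:

* each gene copy carries a latent cluster origin Z, updated from
  P(Z=k) ∝ q_ik · p_kla;
* cluster allele frequencies update from Dirichlet(λ + counts) with λ = 1,
  independently across clusters (the "independent frequencies" model; the
  correlated-frequencies model is deliberately not implemented);
* q_i updates from Dirichlet(α + origin counts);
* the scalar symmetric α is inferred by a random-walk Metropolis step
  (proposal sd 0.05) under a uniform prior on (0, 10] — the referenced
  assignment program's default admixture behavior. The prior bound is a
  configuration argument because the original analysis does not print it.

The recorded trace is the log-likelihood of the observed gene copies given
the current (Q, P) (up to the constant heterozygote multiplicity, which
cancels in all model comparisons). The per-chain evidence estimate is
lnP(D) = mean(lnL) − var(lnL)/2, the harmonic-style estimator the Evanno
procedure requires; ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd_K over replicate
chains, defined only for interior K, reported as +Inf with a warning when
replicate spread is zero. Replicate q matrices are aligned by exact search
over cluster-column permutations (K ≤ 6) maximizing the summed dot product
with the first replicate — exact label-switching resolution where
large-K heuristics are unnecessary — then averaged and row-renormalized.

Cluster labels are arbitrary in any mixture model; `orient_q()` relabels a
two-cluster solution so column 1 tracks the cluster favored by a declared
set of anchor individuals (for example the species-A reference panels).
Anchors affect labels only, never the fit.

## The six-category genealogical model

Each category is a genotype frequency class (GFC): the probability vector
φ = (φ_AA, φ_het, φ_BB) that a diploid locus carries 2, 1 or 0 gene copies
from pool A. The Mendelian values are P1 = (1,0,0), P2 = (0,0,1),
F1 = (0,1,0), F2 = (¼,½,¼), BC1 = (½,½,0), BC2 = (0,½,½). The genotype
probability at a locus is, for a homozygote {i,i},
φ_AA p_Ai² + φ_het p_Ai p_Bi + φ_BB p_Bi², and for a heterozygote {i,j},
φ_AA 2p_Ai p_Aj + φ_het (p_Ai p_Bj + p_Aj p_Bi) + φ_BB 2p_Bi p_Bj; missing
calls contribute 1. These probabilities sum to 1 over the genotype space
for every class and frequency pair, a property the test suite verifies by
brute-force enumeration.

`run_newhybrids()` Gibbs-samples latent categories z_i, per-gene-copy pool
origins (which let the two pool frequency vectors update from
Dirichlet(prior + origin-assigned counts)), and category mixing proportions
π ~ Dirichlet(1 + counts). The "Jeffreys-like" pool prior is interpreted as
the symmetric Dirichlet with parameter 1/A_l per allele at a locus with
A_l alleles — the referenced program's scale-type option — with uniform
Dirichlet(1) selectable; the exact parameterization is a documented choice,
not asserted as the original study's. Only the six standard categories are
modeled: later-generation hybrids are intentionally outside the sampler
(they are handled by the fallback rules below), matching the model's known
scope. Posterior probabilities are category visit frequencies after
burn-in. Study-scale MCMC defaults are 50,000 burn-in / 200,000 sweeps
(likewise 50,000/100,000 for the admixture model); the package's own tests
and analysis scripts use desk-scale profiles (1,000–5,000 burn-in,
4,000–20,000 sweeps on 30–300 individuals at 10 loci), which pilot checks
showed give reproducible posteriors at these sizes.

## The composite classification

`classify_individual()` makes the decision procedure total and explicit.
Rules fire in order:

1. q1 ≥ 0.9 → pure species A (LJ); q1 ≤ 0.1 → pure species B (LS). The
   pure thresholds are inclusive.
2. Otherwise the individual is of hybrid origin. If the maximum
   six-category posterior reaches Tq (default 0.5, ties excluded), that
   category is assigned; a P1/P2 winner contradicts the hybrid q1 signal
   and is recorded as LJ/LS **with a conflict flag** rather than silently
   accepted, preserving both signals for the analyst.
3. Otherwise the individual is treated as a later-generation hybrid binned
   by q1: (0.7, 0.9) → BCJ, (0.1, 0.3) → BCS, and the closed band
   [0.3, 0.7] → Fn.

The interval-edge conventions (inclusive pure thresholds, half-open
backcross bands, closed Fn band) resolve the overlapping prose definitions
of the source procedure into a total function; a property test sweeps the
(q1, posterior) domain to confirm exactly one category always results.
Exact posterior ties at Tq are conservative: unassigned, flagged, and left
to the fallback bands.

For population summaries, F1, F2 and Fn count as intermediate genotypes
while pure and all backcross categories (early and later generation) count
as parental genotypes; modality of each population's q1 is assessed by the
dip test at alpha = 0.05.

## The dip statistic

The dip is the minimal sup-norm distance between the empirical CDF and the
class of unimodal CDFs (convex up to the mode, concave after, with at most
an atom at the mode). It is computed from that definition: bisection on
the distance ε, with an exact feasibility test per candidate mode
placement. For a given ε the ECDF defines a tube at each unique value; a
convex nondecreasing selection through the left tubes exists iff the
greatest convex minorant of the upper bounds dominates the lower bounds,
and the linkage across the mode (the jump) is checked through two-point
slope certificates that give the exact extreme attainable values at the
junction. Mode placements between observations and at observations are
both enumerated. The statistic is floored at 1/(2n) — its value for a
constant sample — following the classical implementation's convention, and
never exceeds 1/4.

The implementation is validated against an independent exhaustive oracle
(closed-form case analysis over all mode placements, exact for samples
with up to three distinct values) on every multiset of size ≤ 6 over
two different 3-point supports, and against hand-derived exact values.

p-values are Monte Carlo: the sample's dip is ranked among the dips of
`n_boot` uniform(0,1) samples of the same n (the asymptotically least
favorable unimodal null), with the +1/(n_boot+1) correction. Because the
same statistic is used for the sample and the null reference, the test's
size is calibrated by construction; the suite confirms empirical size
0.05 ± 0.02 at n = 100. Null tables are cached per (n, n_boot, seed)
within a session, and the cache generation restores the caller's RNG
state. Note the p-values are not interchangeable with interpolated-table
p-values from other dip implementations, whose statistic conventions
differ; within this package all comparisons are internally consistent.

## The power study

`power_study()` runs the full workflow the way a marker-panel validation
would: simulate founder panels → admixture at K = 2 → retain individuals
with q > 0.90 in their own cluster as pure breeding pools (screening out
potential introgressants; the run errors if fewer than 2 survive per
species) → simulate 50 genotypes per genealogical class from the retained
pools → six-class assignment at Tq = 0.5 → per-class efficiency (recall),
accuracy (precision) and performance (their product; undefined accuracy is
reported NA rather than fabricated as 0). Under the study conditions the
qualitative ordering is stable across seeds: parental classes assign best,
F1 next, and F2 worst — the F2 genotype frequency class (¼, ½, ¼) overlaps
every other category, so with 10 loci its posterior mass frequently
spreads below threshold. Individual seeds can deviate (a low-divergence
pool draw weakens all classes); the package asserts the ordering under its
fixed study conditions and reports per-seed results honestly elsewhere.

## Numerical and degenerate-input choices

* Missing calls are whole-genotype (both slots NA); a sentinel of −9
  (two-row text format) or 000/00 (GenePop) decodes to missing.
  Individuals missing more than half their loci are flagged by validation,
  never auto-dropped; no missingness filter is imposed because the
  original procedure states none.
* Loci with no observed calls are excluded from the samplers with a
  warning; monomorphic loci contribute nothing and are warned about in the
  six-class model.
* All simulator and sampler randomness derives from explicit integer
  seeds; child seeds for composite operations are derived arithmetically
  (modulo 2³¹−19) so multi-stage runs are byte-reproducible.
* Dirichlet draws with very small shape parameters are floored at 10⁻³⁰⁰
  before normalization to avoid 0/0.
* Dip bisection runs 40 iterations (precision ~2×10⁻¹³ on D) with a
  10⁻¹² slack on feasibility comparisons.

## Known limitations

* The admixture and six-class samplers are single-chain Gibbs samplers;
  convergence at study-scale settings is asserted by replicate agreement
  (ΔK uses 5 replicates; the six-class model can be run across seeds),
  not by formal diagnostics.
* Within-sampler label switching is theoretically possible at very low
  divergence; at the study divergence the posterior modes are well
  separated and replicate alignment handles across-run switching. In the
  no-information limit (F → 0) posteriors concentrate toward symmetric
  q = 1/2, which the parameter-recovery tests exercise.
* The dip's O(K²) feasibility sweep per bisection step is sized for the
  sample sizes of population-level q1 vectors (tens to hundreds); it is
  not tuned for n in the millions.
* Efficiency/accuracy are evaluated against simulated truth; with real
  data the truth is unknown and the power study's percentages transfer
  only as far as the generator's idealizations hold (see above).
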