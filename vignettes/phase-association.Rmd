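---
title: "Testing cis and trans phase effects with phasereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing cis and trans phase effects with phasereg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasereg)
```

## The problem

Genome-wide association studies treat variants one at a time.  When two
associated variants sit at the same locus, the standard follow-up is
conditional analysis: re-test the secondary variant adjusting for the
primary one.  But two variants can influence a phenotype in two quite
different ways that conditional analysis cannot separate: independently
(allelic heterogeneity), or *coordinately through their phase* — the
arrangement of their alleles across the two homologous chromosomes.  Two
alternative alleles on the same chromosome are *in cis*; on opposite
chromosomes, *in trans*.  Long-read and linked-read sequencing make phase
directly observable across hundreds of kilobases, which creates the
opportunity — and the need — for association tests that use it.

## The phasetype coding

For two biallelic loci with alleles $\{A, a\}$ and $\{B, b\}$ there are
ten distinct diplotypes (unordered pairs of two-locus haplotypes).  By
analogy with the additive 0/1/2 genotype coding at a single locus, each
phase relationship is coded additively: the *phasetype* $Cis_{ij}$ counts
how many of an individual's two haplotypes carry allele $i$ at the first
locus together with $j$ at the second, and $Trans_{ij}$ counts how often
$i$ and $j$ fall on opposite haplotypes.  Each group of four counts sums
to 2 for every diplotype:

```{r}
phasetypes(all_diplotypes())
```

The coding satisfies exact linear identities, e.g.
$Cis_{AB} + Cis_{Ab} = Trans_{AB} + Trans_{Ab} = G_A$ and
$Cis_{ab} = 2 - G_A - G_B + Cis_{AB}$, where $G_A$, $G_B$ are the
additive genotypes.  `verify_identities()` checks them all.

## The model and the two phase tests

`rop()` fits the generalized linear model

$$g(E(Y)) = \beta_0 + \beta_{G_A} G_A + \beta_{D_A} D_A
  + \beta_{G_B} G_B + \beta_{D_B} D_B
  + \beta_{P_{cis}} P_{cis} + \beta_{P_{trans}} P_{trans}$$

with identity link for quantitative outcomes and logit link for binary
ones.  $D_A$, $D_B$ are heterozygosity indicators that absorb
non-additive marginal effects.  By default $P_{cis} = Cis_{AB}$ and
$P_{trans} = Trans_{AB}$ — the coding oriented on the alternative
alleles.  The cis and trans effects are tested separately, each on 1 df:
$H_0\!: \beta_{P_{cis}} = 0$ and $H_0\!: \beta_{P_{trans}} = 0$.

Because every alternative phasetype orientation is an affine combination
of the genotype columns and the default orientation, the test statistics
are *identical* under any reference-allele choice, for likelihood-ratio,
Wald and score tests alike; only the sign of the fitted phase coefficient
can flip (a misspecified reference yields the correct magnitude with
reversed direction).  Fitted values are invariant too.  The test suite
checks this to $10^{-8}$ across all $4 \times 4$ orientations.

```{r}
set.seed(1)
d <- sample_cohort(hap_freqs_from_ld(0.3, 0.3, 0), 500)
y <- 0.6 * phasetypes(d)[, "CisAB"] + rnorm(500)
fit <- rop(y, d)
fit
```

### Choice of test statistic

The default is the likelihood-ratio test.  The three classical tests are
equivalent under the null for this model family, and published power
results do not hinge on the choice; we prefer the LRT because it remains
well behaved near boundary aliasing, where Wald standard errors degrade
first.  `test = "Wald"` and `test = "score"` are available.  For the
Gaussian family, inference uses the $\chi^2$ reference with the
dispersion estimated from the full model (the GLM convention); an exact
F/t small-sample treatment is deliberately not the default so that the
two families behave identically, and the difference is negligible at the
cohort sizes where phase analysis is sensible.

### Estimability rather than silent dropping

A phase column can be linearly dependent on the genotype columns — for
example when one of the four haplotypes does not occur in the cohort
($D' = 1$ with a rare–common pair removes one haplotype, making
$Cis_{AB} \equiv G_A$).  Dropping the column and testing what remains
would silently change the hypothesis, so `rop()` instead reports the
affected test as `inestimable` and `estimability_report()` names the
columns that reproduce the phase term.

### Multi-allelic variants and haplotype blocks

With $m$ and $n$ alleles, `rop_multiallelic()` includes additive and
dominance genotypes for every non-reference allele and cis/trans counts
for every non-reference allele pair, testing all cis (or trans)
coefficients jointly on $(m-1)(n-1)$ df.  `block_to_marker()` collapses a
window of phased variants into one multi-allelic marker (each distinct
haplotype string is an allele), which is how LD blocks enter the model.
The reference allele is the most frequent one in the cohort — the
tabulations leave this open, and the modal choice keeps the remaining
terms maximally estimable — with frequency ties broken lexicographically
so results are deterministic.  Merging similar haplotypes within a block
to reduce df further is out of scope here.

Unphased or missing genotypes are handled by complete-case analysis with
a reported count; the model assumes phase is observed, and imputing phase
would change the meaning of the test.  Haploid samples (male X) have no
trans configuration; the VCF reader accepts haploid calls only in an
explicit opt-in mode, and the phase tests themselves are defined for
diploid data, matching the convention of testing trans effects in females
only.

## Benchmark tests

For comparison the package ships the standard indirect approaches, all
returning the same `phase_test` container:

* `interaction_test(df = 1)` — genotype product $G_A G_B$ over additive
  main effects.  Inflated type-I error when the loci are in LD and one
  carries a dominant or recessive marginal effect.
* `interaction_test(df = 4)` — all four additive/dominance products;
  calibrated, and the most powerful option against *recessive* cis
  effects, whose mean structure lies exactly in its design span.
* `saturated_test()` — adds the phase indicator $V = 1$ (both loci
  heterozygous, alternative alleles in cis); 5 df.  The additive cis and
  trans mean structures lie exactly in this span, so the test captures
  them, but the extra df cost power and the direction of $\beta_V$
  cannot separate cis from trans.
* `haplotype_or_test()` — case-control log cross-ratio of the four
  haplotype frequencies, $\chi^2 = \log(\widehat{OR})^2/(\hat v_1 + \hat
  v_0)$ on 1 df.  It approximates an additive cis effect under a rare
  outcome and is blind to trans effects.  `haplotype_or_cohort()` offers
  two frequency sources, and the choice is consequential.  With
  `freq_method = "observed"` (the default) the phased haplotype counts
  are used directly; this version matches the power of the RoP cis test
  under additive cis effects and, in our simulations, stays calibrated
  even when both loci carry marginal effects.  With
  `freq_method = "em"` the frequencies are EM-estimated per group from
  genotypes alone — the benchmark's historical unphased form — whose
  within-group random-pairing assumption is violated by case-control
  conditioning whenever both loci have marginal effects; that version
  inflates badly in exactly that situation (type-I error around 0.2 in
  the both-loci-additive null at $D' = 0$), which is the behaviour
  reported for this benchmark in the literature.  The variance
  $\hat v_g$ is the symmetric log-OR variance,
  $\frac{1}{2n_g}\sum_h 1/\hat f_h$ over all four haplotypes: the
  commonly printed version of this formula repeats the $AB$ term and
  omits $ab$, which we read as a typographical slip; the symmetric form
  is the standard delta-method variance.  Zero haplotype counts are an
  error by default — `continuity = 0.5` opts into the conventional
  correction, because a silent correction changes the statistic.
* `haplotype_regression()` — cis counts as alleles of one multi-allelic
  marker, 3 df, `ab` as reference, no main-effect adjustment; sensitive
  to marginal effects and unable to attribute a signal to phase.

### Recessive cis effects and an unavoidable rank deficiency

The additive phasetype has little power against recessive cis effects
(both haplotypes in the cis configuration).  `recessive_cis_test()`
jointly tests $P_{cis}$ and the dominance phasetype
$D_{cis} = 1(P_{cis} = 1)$ on 2 df.  Variant 1 keeps the trans phase
terms in the model; variant 2 omits them and is more powerful, at the
price of miscalibration if the truth is in trans.  One fact worth knowing
when interpreting variant 1: the identity
$P_{cis} - P_{trans} = D_{cis} - D_{trans}$ holds for *every* diplotype,
so the variant-1 design is always rank-deficient and one column
(conventionally $D_{trans}$) is aliased.  We follow the standard aliasing
treatment — the aliased column is excluded from both the full and the
reduced fit — which realizes the stated 2-df test; retaining the aliased
column in the reduced model would silently turn it into a 1-df test of a
different hypothesis.

## The simulation framework

`sim_scenario()` encodes the standard study designs.  Haplotypes are
drawn under Hardy–Weinberg equilibrium from frequencies parameterized by
allele frequencies and $D'$ (`hap_freqs_from_ld()`).  Phenotype models:

* Continuous (for the conditional-analysis experiment):
  $Y = -2 + 0.5\,G_A + 0.5\,G_B + \epsilon$ (allelic heterogeneity) or
  $Y = -2 + 1.5\,P + \epsilon$, $\epsilon \sim N(0, 1)$.
* Binary type-I-error models: $\mathrm{logit}(p) = -2 + 1 \cdot$
  (additive, dominant or recessive effect at one or both loci).  The
  intercept $-2$ corresponds to a baseline prevalence of 0.12.
* Binary power models: $\mathrm{logit}(p) = -2 + \beta_P \cdot$ (additive,
  dominant or recessive phase term), with $\beta_P = 0.5$ for additive
  and dominant and $1.5$ for recessive cis.

Binary outcomes are generated by rejection sampling of fresh individuals
until exactly the requested numbers of cases and controls are collected
(1,000 per group by default), with a cap of $10^7$ draws guarding
degenerate configurations.  `estimate_rates()` runs any registered set of
tests over `n_iter` fresh cohorts and reports rejection rates at
$\alpha = 0.05$ with Monte-Carlo standard errors $\sqrt{r(1-r)/n}$; a
failed or inestimable test is excluded from its denominator and counted.
Per-iteration seeds are derived arithmetically from the master seed and
the iteration index, so every scenario is reproducible in isolation and
independent of execution order.

`conditional_power_experiment()` contrasts testing SNP B with and without
adjustment for SNP A against the two phase tests; under allelic
heterogeneity without LD, conditioning raises power, while under phase
effects in LD it can mask the secondary signal — the phase tests separate
the two mechanisms, which single-variant conditioning cannot.

`power_ratio_surface()` maps how LD reshapes power over allele-frequency
grids (quantitative outcome, $n = 1000$, $\sigma = 2$, $\beta_P = 1$ by
default), either by simulation (default, 500 replicates per cell) or from
the noncentral-$\chi^2$ approximation with the noncentrality computed
exactly from population design moments — the analytic route exists
because the underlying numerical analysis method is not pinned down, and
the two agree to within Monte-Carlo error.  Rare–rare pairs in LD gain
cis power; similar allele frequencies in LD lose trans power, because the
diplotypes that distinguish trans from the main effects become rare.

`switch_error_experiment()` probes robustness to phasing errors: a switch
error flips a double heterozygote between `AB/ab` and `Ab/aB` and is
undetectable otherwise, so errors are injected only there, after the
phenotype has been generated from the true phase.  The cis effect size is
calibrated to a target heritability ($h^2 = 0.003$ by default, $n =
5000$, 2,000 iterations) via `h2_to_effect()`, which solves
$h^2 = \beta^2 V / (\beta^2 V + \sigma^2)$ with $V$ the exact population
variance of the phase term and $\sigma$ fixed at 1 — only the target
heritability is specified by the design, so fixing the residual scale and
solving for the coefficient is our calibration choice.  At a 10% switch
rate the cis test retains at least 95% of its error-free power and the
trans test stays calibrated; by 20% the trans type-I error inflates.
Modern phasing tools sit well below these rates.

### What the generator does and does not emulate

The generator reproduces the ingredients the method is about: HWE
diplotype sampling at chosen LD, the published effect models, exact
case/control sizes, and double-heterozygote switch errors.  It does not
emulate relatedness or population structure, genotyping error, covariate
confounding, X-inactivation, or locus-scale LD beyond the pair under
test — so passing simulations demonstrate calibration and power under
the stated sampling model, not robustness to those real-data
complications.

## Numerical choices

* IRLS convergence: deviance tolerance $10^{-12}$, at most 100
  iterations; non-convergence and separation are surfaced as statuses,
  never silently.
* Rank detection by pivoted QR before fitting; aliased columns are
  excluded from full and reduced designs alike and reported.
* Degenerate cohorts (fewer than three distinct diplotypes) are an
  error; an aliased *tested* term is `inestimable`.
* All simulation sizes quoted above are the package defaults and are what
  the acceptance checks use; the unit-test suite exercises the same code
  at the same or moderately reduced sizes chosen to keep the default test
  run brisk, with Monte-Carlo bands widened accordingly.

### Finite-sample behaviour worth knowing

Two corners of the design space deserve a caveat.  First, when the two
variants have similar allele frequencies and are in strong LD
($D' = 0.8$), only a handful of diplotypes identify the trans term, and
the 1-df LRT becomes mildly anti-conservative at case-control sizes of
1,000 per group (empirical level about 0.06–0.08 instead of 0.05 in our
null simulations; the Wald test errs conservative instead).  This is the
same weak-identification corner where power is lost, and it argues for
picking variant pairs outside strong LD when possible.  Second, under a
10% switch-error rate the flipped double heterozygotes carry an apparent
trans effect proportional to the cis coefficient, so the trans type-I
error drifts slightly above nominal (about 0.06–0.07 in the
heritability-0.003 design, largest when both alleles are rare and the
per-count effect is therefore largest) while cis power retains roughly
93–95% of its error-free value; by a 20% rate the trans inflation is
substantial.

## Limitations

Phasing itself is out of scope: the package consumes phase, it does not
infer it.  Mixed models, relatedness correction and genome-wide scanning
loops (with their multiple-testing machinery) are likewise out of scope;
the CLI tests one variant pair per invocation.  Recessive trans effects
have no dedicated test, mirroring the asymmetry of the underlying study
designs.
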