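---
title: "From life tables to genetic diversity: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From life tables to genetic diversity: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalNe)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they rest on, the parameters that matter, and the
conventions chosen where more than one defensible convention exists. Nothing
here reports an empirical number that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The question and the modelling chain

Across species, genome-wide heterozygosity at neutral sites should equal
$\theta = 4 N_e \mu$ at mutation-drift equilibrium. Differences in *census*
size and mutation rate are the obvious candidates for explaining diversity
differences, but age structure contributes a third, often dominant, lever: the
schedules of survival and fecundity over age determine the lifetime variance
in reproductive success $V_k$ among the members of a newborn cohort, and
through it the ratio $N_e/N$. The package quantifies this lever along a chain
with four links: life-table construction, an analytic $V_k \to N_e$ engine, an
individual-based forward simulator that measures diversity directly, and the
regression machinery connecting model output to observed trait tables.

## 2. Life tables

A life table (class `life_table`) is a vector of annual survival
probabilities $s_x$ and relative fecundities $f_x$ over contiguous integer
ages, with $s_\omega = 0$ at the maximum age $\omega$: nothing outlives its
lifespan. Only the *shape* of $f_x$ matters anywhere in the package; every
consumer rescales it.

**Empirical tables.** Direct survival estimates rarely exist for marine
fishes, so survival is derived from growth: length at age from the Von
Bertalanffy curve $L(a) = L_\infty(1 - e^{-K(a - t_0)})$, instantaneous
natural mortality from the length-based relation
$m_a = (L_a/L_\infty)^{-1.5} K$, and annual survival $s_a = e^{-m_a}$. The
$-1.5$ exponent makes mortality decrease monotonically with body size with
$m \ge K$ always, the canonical fisheries pattern; young (small) fish never
outlive old (large) fish in per-year survival under the same growth model.
Fecundity at age is a fecundity-length relation (power law
$F = \alpha L^\beta$ as the default family, exponential and linear as
alternatives; negative linear predictions clamp to zero with a warning)
evaluated at the age-specific length and zeroed below the age at first
maturity. Where sexes grow differently, per-sex tables are built from per-sex
growth models.

**Theoretical tables.** The survivorship-shape scans replace the growth chain
with a two-parameter Weibull survivorship $S(t) = e^{-(t/b)^c}$. The shape
$c$ sweeps the classical typology - $c < 1$ Type III (fish-like: high
juvenile, low adult mortality), $c = 1$ Type II (constant hazard), $c > 1$
Type I (mammal-like) - and the scale is pinned by the boundary condition that
1% of a newborn cohort remains alive at the maximum age:
$b = \omega \cdot (-\ln 0.01)^{-1/c}$, read with the natural logarithm, the
only reading that satisfies $S(\omega) = 0.01$. Annual mortality on
$[x, x+1)$ is $M_x = 1 - e^{(x/b)^c - ((x+1)/b)^c}$; the product of
$1 - M_x$ over $x = 0..\omega-1$ recovers the pinned 1% to $10^{-9}$, an
always-on invariant of the test suite. Age-fecundity schedules are
parametric: constant, exponential $F = e^{f\,\mathrm{age}}$ (the marine-fish
default; $f$ the package sweeps over $[-1, 1]$, with $f = 0.142$ as the
empirical median rate for the bundled species set), power-law, linear and
polynomial behind the same interface, all max-scaled to 1.

**Fractional ages.** Several bundled species mature at fractional ages (0.5,
1.5, 7.5 years). Annual projection needs integer ages, so the fecundity mask
uses $x < \lceil \mathrm{maturity} \rceil$ and the adult census counts ages
$\ge \lceil \mathrm{maturity} \rceil$. This is a placement convention, not
biology; it is applied consistently everywhere.

**Component toggles.** To attribute between-species variation in $N_e/N$ to
individual life-table components, 16 model variants per species switch the
four components (maturity, age-specific survival, age-specific fecundity,
sex differences) on and off independently (`toggle_set()`, ids 1..16 by
binary expansion). The null model keeps only lifespan: maturity 1, constant
fecundity, and a constant annual survival chosen per species so that a
fraction $10^{-4}$ of the cohort remains at the maximum age,
$s = (10^{-4})^{1/(\omega-1)}$. Whether that constant-survival rule was
originally meant per species or as a shared rate is ambiguous; the per-species
reading is implemented, and neither reading reproduces the published
null-model $N_e/N$ range (0.558-0.733) - computed here as roughly 0.62-0.99 -
so that range is treated as a documented soft check, not a target.

## 3. The analytic engine

Under constant population size and stable age structure, each newborn cohort
replaces itself: scaled per-year fecundities $b_x = C f_x$ satisfy
$\sum_x l_x b_x = 2$, where $l_x$ is cumulative survivorship. With
reproduction independent across years given survival (no persistent
individual quality) and a within-age variance-to-mean ratio $\phi$, the
lifetime offspring number $K$ of a cohort member decomposes over the age at
death $x$ (probability $d_x = l_x - l_{x+1}$):

$$V_k = \sum_x d_x \Big[ \sum_{j \le x} \phi_j b_j + (K_x - \bar k)^2 \Big],
\qquad \bar k = \sum_x d_x K_x = 2 .$$

The first term is reproductive noise accumulated over the years actually
lived; the second is the inequality generated purely by who dies when -
the component life tables control. Hill's overlapping-generations result then
gives $N_e = 4 N_1 T / (V_k + 2)$ per generation, with $T$ the mean parental
age and $N_1$ the (arbitrary, cancelling) number of newborns per year. A
Monte-Carlo cohort simulator (`monte_carlo_cohort_vk()`), sharing none of the
algebra, reproduces the analytic moments within 3 standard errors across 50
randomized Weibull-family tables in the always-on suite.

**Reading "equal contribution of individuals of the same age".** The package
reads this assumption as the Poisson default $\phi = 1$ - no sweepstakes
*overdispersion* within an age class - not as $\phi = 0$ (literally zero
within-age variance), which would force $N_e > N$ everywhere and is
inconsistent with any observed ratio below 1. $\phi$ is exposed as a
parameter; $\phi = 0$ yields the variance-minimised limit $N_e = 2 N_1$ for a
semelparous table, and a semelparous maturity-1 Poisson table yields
$N_e/N = 1$ exactly (the Wright-Fisher limit), both asserted in the tests.

**Census policies.** Which individuals count as $N$ is a reporting
convention, so `effective_size_ratio()` exposes three: `"adults"` (ages at
or above maturity; the default and the natural reading for comparisons with
mature census sizes), `"all"` (every age class from 1), and `"generation"`
(one generation's newborn cohort, $N = N_1 T$), under which the ratio
reduces to the classic Crow-Kimura variance form $N_e/N = 4/(V_k + 2)$.

**Two-sex combination.** Per-sex schedules are scaled separately (each sex's
cohort mean is 2), $V_k$ and $T$ are combined with sex-ratio weights, and one
Hill formula is applied to the combined quantities. At a 0.5 sex ratio there
is no between-sex mean component. The combination is a policy, not a theorem,
and is deliberately localised in one function.

## 4. The grid-scan convention (an open design, resolved)

For the survivorship-by-fecundity scans, three inter-locking conventions had
to be fixed: where the cohort starts, whether the parametric fecundity is
masked below maturity, and which census the ratio is reported against. The
package resolves them as: **the cohort starts at age 0** (the entire Weibull
curve, including first-year mortality, belongs to the cohort),
**fecundity applies from age 0 without maturity masking**, and **the ratio is
reported against the generation cohort**, $N_e/N = 4/(V_k + 2)$.

The reasoning is structural. Under an adult or all-ages census with maturity
masking, the ratio is provably flat in lifespan as $c \to 0$: within-table
survival becomes constant, every species' $V_k$ collapses to the Poisson
floor, and no lifespan dependence can emerge - contradicting the strong,
well-documented dependence of $N_e/N$ on adult lifespan under Type III
shapes that these scans exist to exhibit. The newborn-cohort,
generation-census convention is the unique member of the family that
produces that dependence across the whole Type III range, and it coincides
with the textbook Crow-Kimura form $N_e = 4N/(V_k+2)$ applied to a
generation of newborns. Its trade-off is documented honestly: the
constant-fecundity $R^2$ of the lifespan regression is then monotone in $c$
(maximal, about 0.97, at the most extreme Type III shapes) rather than
peaked near the Type II boundary; the `test-acceptance` suite records this
single known divergence from the published surface rather than masking it.

```{r grid, eval = FALSE}
surf <- scan_grid(grid_spec(fecundity_model = "constant"))
summarize_extremes(surf)
```

Default grids: 60 log-spaced shapes over $c \in [0.01, 30]$ plus the
landmark values 0.1 and 1.03 appended exactly, and 41 linear exponents over
$f \in [-1, 1]$ plus 0.142. The scan is fully deterministic; reruns are
bit-identical.

## 5. The forward simulator

The simulator measures what the analytic engine predicts. Each year, every
individual may parent this year's newborns with probability proportional to
its age- and sex-specific fecundity (reproduction precedes survival, so an
individual can reproduce in its death year, matching the analytic
decomposition); each individual then survives with probability $s_{x,\mathrm{sex}}$;
newborns replace the dead one-for-one, keeping census size constant by
construction. Offspring inherit one intact haplotype per parent - no
within-locus recombination, to which heterozygosity summaries are
insensitive under neutrality - plus Poisson($\mu L$) mutations as allele
flips at uniform finite sites. At the default $4N\mu \sim 10^{-3}$ the
finite-sites correction is negligible ($\theta/(1+2\theta)$ vs
$\theta/(1+\theta)$ differ in the fifth digit); the package compares against
$\theta/(1+\theta)$. Age at maturity is deliberately ignored (fecundity is
filled down from the first reproductive age), so a table acts through its
survival curve and fecundity *shape*; the analytic engine, which does use
maturity for the adult census, is compared to the simulator through $N_e$
rather than through any census ratio.

The core is compiled (bit-packed haplotypes, 64 sites per word), uses R's
RNG so `set.seed()` governs reproducibility exactly, and records mean
individual heterozygosity (fraction of heterozygous sites) on a configurable
stride. `equilibrium_summary()` averages a trailing window and flags
non-convergence via a t-test on the within-window linear trend; runs whose
burn-in is shorter than four drift time-scales ($4 N T$ years) are flagged
in the output metadata.

**What the simulator does and does not emulate.** It reproduces overlapping
generations, sex-specific schedules, and neutral diversity at a single
non-recombining locus in a closed, constant-size population. It does not
model selection, linked-selection erosion, recombination, migration,
demographic change, or heritable quality - so agreement between simulated
and analytic $N_e$ validates the variance bookkeeping, not the realism of
any of those excluded forces. Equally, parameter-recovery successes on the
synthetic trait generator (exact beta noise around an exactly logit-linear
mean) show estimator correctness, not that real interspecific data obey the
model.

## 6. Inference

Diversity is a proportion, so trait regressions use the beta distribution
parameterised by mean and a single constant precision $\phi$ with a logit
link - the convention under which the package's link-scale slopes (for
example, per year of adult lifespan) are comparable across fits. Estimation
is maximum likelihood: BFGS with analytic score over
$(\beta, \log\phi)$ from OLS-on-logit starting values, followed by damped
Newton polishing; every fit self-checks that the score norm is below
$10^{-6}$ (typically it reaches $10^{-11}$), and the optimiser is
deterministic. Pseudo-$R^2$ is the squared correlation between
$\mathrm{logit}(y)$ and the fitted linear predictor; Wald p-values come from
the observed information; nested models are compared by likelihood ratio.
Scaled analyses (variables divided by their maxima) always *refit* on the
scaled variables rather than rescaling coefficients. The exhaustive
leave-$k$-out scan enumerates all $\binom{n}{k}$ subsets - 4368 fits at
$n = 16, k = 11$, a few seconds of work - and summarises the slope and
pseudo-$R^2$ distributions by their empirical 2.5/97.5 percentiles.

One published regression is excluded from reproduction by design: the
fecundity-vs-propagule-size fit, whose variable roles and logarithm base are
not stated precisely enough to pin down.

## 7. Synthetic data

The generator exists so every stage is testable without downloads, and its
defaults are fixed study conditions, not tuning knobs. Trait tables draw
integer lifespans uniformly on $[3, 21]$ years (the bundled species' range),
derive maturity as $\max(0.5, 0.2\,\omega)$ (mimicking the empirical
maturity/lifespan ratios), and draw diversity from a beta distribution whose
logit mean is linear in adult lifespan - conjugate to the estimator, so
recovery tests are exact-model checks. Age-length data are Von Bertalanffy
means plus Gaussian noise; at zero noise a round trip through
`fit_von_bertalanffy()` recovers the generating parameters to optimizer
tolerance, and on noisy data the least-squares fit beats a brute-force
grid-search oracle. Where the empirical pipeline needs the per-species
growth and fecundity-length parameters (which live in species-specific
fisheries studies and are not bundled), `synthetic_growth_params()` provides
a clearly-labelled synthetic stand-in built from rules of thumb
($K = 3/\omega$, $L_\infty$ slightly above recorded body size, cubic
fecundity-length power law); results derived from it are structural, never
species-specific.

## 8. Numerical choices and degenerate inputs

* Ages are integers; tables start at 1 (recruit cohort) except the
  grid-scan's newborn tables, which start at 0.
* The beta likelihood requires responses strictly inside $(0,1)$; scaled
  responses touching 1 are nudged inside by $10^{-9}$ before refitting.
* `weibull_annual_mortality()` rejects ages at or beyond the lifespan;
  tables with all-zero fecundity are rejected at construction (a cohort
  that cannot replace itself has no stable schedule).
* The Monte-Carlo oracle refuses cohorts under 1000; its standard errors
  are moment-based (delta method), adequate at the $2\times10^4$ cohort
  sizes the tests use.
* A simulated population whose females or males all have zero fecundity
  aborts with a diagnostic rather than silently stalling.

## 9. Problem sizes used by the tests

The test suite and the acceptance script run desk-scale rescalings that
preserve the governing compound parameters. The Wright-Fisher control keeps
$4N\mu = 8\times10^{-4}$ at $N = 500, \mu = 4\times10^{-7}$ (script; 20
replicates) and $N = 250, \mu = 8\times10^{-7}$ (tests; 8 replicates), with
burn-in of $20 \times 4N$ generations before a 10,000-generation window.
The simulator-vs-analytic consistency checks use three contrasted tables at
$N = 150$ with 16 replicates and 12,000-year windows, comparing at 10%.
The Monte-Carlo-vs-analytic ensemble uses 50 tables at cohort size 20,000;
with 50 independent 3-SE bands an occasional marginal exceedance is expected
by chance, so at most two misses (none beyond 4 SE) are tolerated. The
growth-fit-vs-grid-oracle comparison uses 60 noise seeds. These sizes are
the package's choices for routine verification; all scale up linearly if
more precision is wanted.

## 10. Known limitations

* The analytic engine assumes stable age structure, constant size, and no
  heritable variation in quality; temporal fluctuation of vital rates and
  persistent individual effects are out of scope.
* The two-sex combination and the census definition are conventions;
  both are exposed as arguments and documented above rather than baked in.
* The grid-scan convention resolves an under-determined design as
  described in section 4; one published surface feature (the location and
  height of the constant-fecundity $R^2$ maximum) is not reproduced under
  any self-consistent convention the package explored, and the discrepancy
  is carried openly in the acceptance suite.
* Brooding species sit systematically off the diversity-lifespan trend;
  the package quantifies this (interaction tests, subset scans) but offers
  no mechanistic model of parental care.
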