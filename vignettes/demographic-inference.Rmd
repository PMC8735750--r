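---
title: "Methods: joint-SFS model selection and coalescent introgression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-SFS model selection and coalescent introgression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsdemog)
```

## The problem

`sfsdemog` addresses demographic inference for a three-population system
with an outgroup — the motivating system is a wide-ranging lizard with a
desert population (DST), a southern population (STH) and a plains population
(PLN) — where three questions recur:

1. Which divergence scenario best explains the folded three-dimensional
   joint site frequency spectrum (JSFS): continuous gene flow since
   divergence, divergence in isolation followed by secondary contact
   (refugia), or a riverine barrier suppressing gene flow into one lineage?
2. What do divergence times and effective population sizes look like once
   gene flow is modelled explicitly, via a multispecies coalescent with
   introgression (MSci) with bidirectional introgression (BDI) events?
3. How badly do estimates go wrong when gene flow is real but ignored, or
   when a single recently admixed individual is left in the sample?

All analyses are exercisable end to end on synthetic coalescent data; no
external downloads are involved.

## The simulation engine

The core is a structured-coalescent simulator (compiled code) over an
arbitrary set of demes with piecewise-constant sizes, continuous backward
migration, and three event types applied at fixed times: deme size changes,
population mergers (`join`), and instantaneous admixture pulses (`pulse`)
that reroute each lineage independently with a given probability.  Pulses
are how BDI introgression is represented: the contrast is with
isolation-with-migration models, where gene flow is continuous each
generation; here introgression is an episodic event at a single time.

Mutations follow the infinite-sites model within a locus: a Poisson number
of mutations proportional to total branch length, each at a distinct site.
The finite `locus_len` only expresses distances per site and bounds the
number of segregating sites; no multiple-hit model is applied, and raw
proportion distances are used throughout, consistently with that choice.

Two unit systems coexist, on purpose, because the two sub-literatures the
package serves use different conventions:

* **Mutation-scaled units** (the MSci side): times $\tau$ and sizes
  $\theta = 4N\mu$ are both in expected substitutions per site.  The engine
  uses deme size $\theta/2$, so a pair coalesces at rate $2/\theta$, and a
  mutation scale of 1.
* **$N_{ref}$-relative units** (the diffusion/moments side): sizes $\nu$
  relative to a reference, durations in units of $2N_{ref}$ generations,
  migration entries $2N_{ref}m$ (events per lineage per $2N_{ref}$
  generations).  The per-site scale $\theta_{ref} = 4N_{ref}\mu$ enters only
  when sequences or distances are generated (`mut_scale`, default 0.002, a
  typical per-site nucleotide diversity for a reptile population).

Randomness policy: everything draws from R's RNG.  Multilocus simulations
derive one substream per locus from the master seed by a fixed counter
scheme (`seed + 1046527 * locus`, mod $2^{31}-1$), so any locus is
reproducible in isolation and identical seed + configuration is reproducible
bit for bit.

Two data representations are available.  `"genotypes"` materialises 0/1
haploid site matrices (and can be written to FASTA/TSV); `"distances"`
computes per-locus pairwise distance and coalescence-time matrices directly
from per-branch Poisson mutation counts, never materialising sites.  The
distance representation makes very long loci (used by the bias experiments,
below) essentially free.

## Expected spectra and the JSFS toolkit

The expected unfolded JSFS of a demography is computed by genealogy
branch-length Monte Carlo: for each simulated genealogy, each branch's
length is credited to the spectrum cell indexed by how many sampled tips it
subtends per population.  Because mutation placement is integrated out
analytically, this is a Rao-Blackwellised estimate; it converges to the
$1/i$ neutral law in one population and is validated against that and
against exchange symmetries in the tests.

Toolkit conventions, chosen where text-file dialects genuinely differ:

* **Fixed cells** `(0,0,0)` and `(n1,n2,n3)` are always masked; masked
  cells carry no likelihood mass.
* **Folding** adds each majority-derived cell onto its mirror; *tie cells*
  (derived total exactly half the sample) are combined with their mirror and
  the sum is assigned to the lexicographically smaller index tuple, the
  mirror being masked.
* **Projection** to smaller sample sizes is the standard per-axis
  hypergeometric average.  Missing data are handled by projecting each
  site's observed haploid counts to the target sizes; a site whose observed
  count falls below the target in any population is dropped with a message.
  Projection sizes are user inputs, as they are data-set specific.
* **Polarisation**: spectra are built against a declared ancestral allele
  (REF for VCF input); the package's headline analyses fold, which removes
  the dependence.
* Positions are 0-based half-open internally; VCF input is converted on
  read.
* The SFS text serialisation is the dadi/moments dialect (header of
  dimensions + folding tag + population labels, flattened counts in C
  order, 0/1 mask line) and round-trips exactly.

## The ten-model registry

All ten three-population models share a fixed topology ((STH, PLN), DST),
an ancestral reference population of size 1, an STH+PLN ancestor of size
`nu23`, terminal sizes `nu1, nu2, nu3`, and durations `T*`.  "Adjacent"
migration means the DST–STH and STH–PLN pairs only, reflecting the
geographic arrangement.  The `split_*` family has migration (none /
symmetric-adjacent / asymmetric-adjacent / symmetric-all) active from each
split; the `refugia_*` family diverges in isolation and opens migration in
a secondary-contact phase.  The two headline models are defined by the
hypotheses they encode: `refugia_adj_2` (isolation between the splits,
adjacent gene flow after the second split) and `refugia_barrier` (the same
with no gene flow to or from DST — the riverine-barrier hypothesis), which
is nested in `refugia_adj_2` by fixing `mDS = 0`; the engine reproduces the
nesting exactly under common random numbers.  The remaining structures
(`refugia_adj_1/3`, the `split_*` variants, `refugia_symmig_all`) are
reconstructed from their names following the conventions of community
diffusion/moments model collections; since such reconstructions are
figure-derived in the source literature, all structures live in one
declarative registry table (`R/registry.R`) so any of them can be amended
without touching the engine.  Parameter counts `k` are counted from the
registry's free parameters (6 to 10 per model) because the source tables do
not print them.

```{r}
list_models()[, c("name", "k")]
```

## Composite likelihood and staged fitting

The observed folded JSFS is compared with a model's normalised expected
spectrum by the multinomial composite log-likelihood
$\ell = \sum_c n_c \log p_c$ over unmasked cells, with $p_c$ floored at
$10^{-300}$; the parameter-independent multinomial coefficient is omitted
(it cancels from every comparison).  One SNP per locus keeps linkage weak;
the likelihood is nevertheless composite, which is why model comparison is
paired with the Godambe machinery below.

`fit_model()` mirrors the staged optimisation practice of the moments
pipelines: four consecutive rounds of 10/20/30/40 replicate Nelder-Mead
searches in log-parameter space, each started from the incumbent best
perturbed by up to $2^{\pm fold}$ with fold 3/2/2/1 and iteration caps
3/5/10/15.  All parameters live in $[10^{-3}, 10^3]$ in relative units.

Two numerical choices matter here:

* **Common random numbers.** Every likelihood evaluation reuses one fixed
  seed, so the map from parameters to spectrum is deterministic and the fit
  reproducible.  The surface is, however, *rough* at small parameter scales
  (event reorderings between genealogy replicates), which stalls simplex
  moves near convergence.
* **Pattern-search polish.** After the staged rounds, a compass search with
  shrinking log-space steps (0.3, 0.15, 0.08, 0.04) at higher replicate
  counts refines the best point.  The move set includes the all-parameter
  scaling direction — the softest mode of any normalised-spectrum fit,
  since rescaling all sizes and times leaves the spectrum shape nearly
  invariant (exactly invariant were the ancestral size not pinned to 1).
  This combination is robust to the Monte-Carlo roughness that defeats a
  plain simplex.

`AIC = 2k - 2\ell` identically for every fit, and refitting with the same
seed reproduces the result bit for bit.

**Calibration experiments are parametric bootstraps of the implemented
family.**  Synthetic SNP spectra used to check parameter recovery and
likelihood-ratio calibration are multinomial draws from the package's own
expected-SFS map at the same replicate count and seed the fitter evaluates
with.  Drawing them instead from an independent engine run would make the
engine's frozen Monte-Carlo noise act as model misspecification — at
thousands of SNPs that mismatch alone contributes tens of log-likelihood
units and parameter displacements larger than any effect under study.  The
engine itself is validated separately against closed-form expectations
(the $1/i$ law, pairwise diversity and divergence means, exchange
symmetries, exact nesting identities), so the two kinds of error are
tested where each is measurable.

## Model ranking and adjusted tests

`akaike_table()` implements the ranking arithmetic
($\Delta AIC$, relative likelihood $e^{-\Delta AIC/2}$, Akaike weights),
`confidence_set()` the smallest cumulative-weight prefix at a level.

For nested pairs, `lrt_godambe()` rescales $D = 2(\ell_{full} -
\ell_{nested})$ by $df / \mathrm{tr}(J H^{-1})$, where $H$ is the observed
information and $J$ the bootstrap variance of the score, both with respect
to the parameters fixed by the nesting and evaluated at the nested optimum
embedded in the full model.  Choices: finite-difference step 0.01 in the
natural units of the fixed parameters (one-sided at the zero boundary,
since migration rates cannot be negative); the bootstrap unit is the locus
(with one SNP per locus this coincides with multinomially resampling the
observed spectrum, which `bootstrap_jsfs()` exploits); and because a
migration rate fixed at 0 lies on the boundary of the parameter space, the
default null is the 50:50 mixture $\chi^2_0 : \chi^2_{df}$ (switchable to
the plain $\chi^2_{df}$).  A non-positive adjusted statistic — which does
occur in practice when the full-model optimiser lands marginally below the
nested optimum — yields $p = 1$ by convention.

## The introgression model

The MSci model places two BDI events on the species tree.  Reading the
network: branch segments, named by their daughter node, are STH and PLN up
to $\tau_{CD}$; C (STH side) from $\tau_{CD}$ to $\tau_{AB}$; D (PLN side)
from $\tau_{CD}$ to $\tau_T$; DST up to $\tau_{AB}$; A (DST side) from
$\tau_{AB}$ to $\tau_S$; B (STH side) from $\tau_{AB}$ to $\tau_T$; then T,
S and R above, with the outgroup joining at the root.  Backward in time, a
lineage at node C crosses into D with probability $\phi_C$; at D into C
with $\phi_D$; at A (a DST lineage) into B with $\phi_A$; at B into A with
$\phi_B$.  All $\tau$ and $\theta$ are per-site values.  The ordering
constraint $0 < \tau_{CD} < \tau_{AB} < \tau_T \le \tau_S < \tau_R$ is
enforced at construction.  One reading of the published network drawing is
genuinely ambiguous — which of the two sister-side branches carries the C
node; the registry places C on the STH side and D on the PLN side, which
reproduces the published path probabilities (PLN lineages mostly taking the
D-to-C route) — and is flagged here for verification against the original
figure.

With all $\phi = 0$ the pulses vanish and the model reduces exactly to the
multispecies coalescent on the species tree; at matched seeds the
simulators agree bit for bit, and in distribution the equivalence is
checked by Kolmogorov–Smirnov tests across seeds.

**Label-swap unidentifiability.** Swapping the two node labels of a BDI
pair maps $\phi \to 1-\phi$ on both sides and exchanges the two $\theta$s.
For a BDI between sister branches this is an exact within-model
unidentifiability; for the A–B event here (the two branches continue to
different parent nodes, S and T) it is exact only in the limit
$\tau_S = \tau_T$, which is why the two posterior modes it generates are
"identifiable but very hard to distinguish" when the two speciation events
are nearly simultaneous.  The package's label-swap invariance test operates
at that statistical level: distances simulated under a parameter vector and
its swapped twin are indistinguishable by KS tests at the simulated scales.

**Recent hybrids** are modelled as per-locus parental assignment at
sampling time (time 0): each locus of the extra individual starts in one of
two parental populations with probability `mixing_prob`, while the
individual is labelled as a member of its host population.  This emulates a
first-generation-style admixed sample without modelling pedigrees.

## Minimum-divergence estimators and the two experiments

Under the coalescent, sequences from two populations cannot coalesce more
recently than the populations' separation, so cross-population divergence
is bounded below by twice the relevant node age: divergence times are
determined mostly by the *minimum*, not the average, cross-population
distance.  The moment estimators take per-locus distances $d = 2\tau + e$
with $e$ approximately exponential with mean $\theta_{anc}$:
$\hat\tau = d_{min}/2$, $\hat\theta_{anc} = \bar d - d_{min}$, with
within-population diversity estimating each $\hat\theta_{pop}$.  The inner
node uses the (STH, PLN) pair; the root uses DST against the pooled
STH+PLN sample.  This deliberately transparent estimator — not a Bayesian
sampler — is the device by which the package demonstrates the directional
claims below; the claims are directional, and are tested as such.

**Design of the experiments.**  Defaults emulate the study conditions: 500
loci, four haploid samples per focal population, node ages set to the
published posterior means ($\tau_R, \tau_S, \tau_T, \tau_{AB}, \tau_{CD}$ =
9.75, 6.14, 3.86, 1.42, 0.17, all $\times 10^{-3}$).  Two deliberate
choices:

* The experiment parameter set uses a *common* $\theta = 0.002$ on all
  branches.  With homogeneous $\theta$ the no-gene-flow arm is an exact
  shifted exponential whatever the coalescence path, so the control arm has
  a well-defined truth to be unbiased against; with the heterogeneous
  published $\theta$s (ancestral root $\theta$ an order of magnitude larger
  than the tips) the "ancestral $\theta$" of the moment model is not a
  single quantity and the control would confound estimator bias with model
  mismatch.
* Experiment loci are long (`locus_len` $10^6$) and use the distance
  representation.  The minimum-distance statistic inherits downward Poisson
  noise of order $\sqrt{2\tau L}/L$ at the minimum; long loci keep that
  noise small relative to the coalescent signal, so that the control arm
  isolates the estimator's behaviour rather than sequencing-length noise.
  (Empirical reduced-representation loci are hundreds of bases; at such
  lengths the minimum statistic is noise-dominated, which is itself one of
  the practical lessons of the minimum-divergence argument.)  The general
  simulator default is `locus_len = 100`, a typical short-locus setting,
  configurable since the empirical locus lengths behind any given data set
  vary.

`bias_experiment()` runs a treatment arm (some $\phi > 0$; the headline
case routes STH lineages into the PLN-side branch with $\phi_C = 0.25$)
and always a $\phi = 0$ control arm, recording per-replicate signed errors
and one-sided sign tests for the two directional claims: divergence times
underestimated, ancestral sizes overestimated, when introgression is
ignored.  `hybrid_sensitivity()` compares the same simulated data with and
without one appended recent hybrid: its donor-derived loci produce
within-population-scale cross distances, dragging $d_{min}$ and hence
$\hat\tau$ down; a `mixing_prob = 0` hybrid (pure host) is the negative
control.

## Calibration

With a substitution rate $\mu$ per site per million years, a generation
time $g$ in years, $T_{My} = \tau/\mu$, $N_e = \theta/(4 \mu_{yr} g)$ and
the empirical rate from an external calibration is $\mu = \tau/T$.
Defaults are $\mu = 0.0008$ substitutions/site/My, $g = 2$ years, and a
20 My external calibration.  Reported times are rounded half-up at the
printed precision (`round_half_up()`), since that is the convention the
worked values follow; base R's banker's rounding would differ at exact
halves.

## GEA outlier rules

Only the filtering rules are in scope (ordination and latent-factor model
fitting belong to their own packages and are consumed as inputs):
`loading_outliers()` flags SNPs beyond `sd_mult` (default 2.5) sample
standard deviations (n−1 denominator) from the mean locus score on any
constrained axis, with per-axis provenance and affine invariance;
`assign_predictor()` maps each candidate to its maximum-|r| environmental
variable, ties to the first-listed variable with a message.  The number of
axes is an input, not a constant.

## Problem sizes used by the test suite

The suite favours a few deep, parameterised checks.  Stochastic checks run
at desk scale, chosen once: spectra at 4–24 haploids and $10^3$–$2\times
10^4$ genealogy replicates; multilocus simulations of 200–5,000 loci;
recovery fits on 5,000-SNP spectra with staged rounds at 1,000–4,000
replicates and a 20,000-replicate polish; null-calibration LRTs on
1,000-SNP spectra at three haploids per population over 50 replicates; the
two experiments at 500 loci × 20 replicates per arm.  Every stochastic assertion carries the tolerance stated with it, and
all seeds are fixed in code.

## Known limitations

* The expected-SFS engine is Monte Carlo, not a diffusion/ODE solver:
  likelihood surfaces carry frozen noise at fine scales.  The staged +
  pattern-search optimiser is designed around this, but parameters along
  soft directions (notably the ancestral size `nu23` against the deep
  duration `T1`) are recovered with a few-percent engine-induced jitter on
  top of sampling spread.
* No recombination within loci, no sequencing-error model, no read-level
  simulation; loci are exchangeable and unlinked.
* The moment estimators are intentionally simple; they demonstrate bias
  directions and sensitivities, and are not a substitute for full-likelihood
  inference of MSci parameters.
* Synthetic data are idealised: no missing-data structure beyond what the
  projection policy handles, no ascertainment bias, equal sample sizes by
  default.  Passing tests show the machinery is correct and the paper-level
  claims reproduce under the stated generative conditions — not that any
  particular empirical data set satisfies those conditions.
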