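---
title: "Methods: INST-MFA of photosynthesizing leaves with leafMFA"
author: "leafMFA maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: INST-MFA of photosynthesizing leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During photosynthesis a leaf releases CO~2~ through two routes:
photorespiration (glycine decarboxylation downstream of rubisco oxygenation)
and *respiration in the light*, R~L~ — all other decarboxylations net of
non-rubisco carboxylation. R~L~ costs roughly a tenth of net carbon
fixation, yet its biochemical origin is contested: the classical candidates
are TCA-cycle-associated decarboxylations, pyruvate decarboxylation feeding
fatty-acid synthesis, and the G6P/OPP shunt (glucose 6-phosphate oxidized to
pentose phosphate via 6-phosphogluconate, releasing C1 of the hexose).

leafMFA implements isotopically nonstationary metabolic flux analysis
(INST-MFA) to partition R~L~ among these sources. A leaf photosynthesizing
at steady state is switched at t = 0 from ^12^CO~2~ to ^13^CO~2~; the mass
isotopologue distributions (MIDs) of central metabolites are measured over
0–60 min; fluxes, pool sizes and inactive-pool dilution fractions are then
estimated by fitting simulated labeling kinetics to these time courses under
measured boundary rates (net assimilation, starch and sucrose synthesis,
phloem export composition). Competing hypotheses about the source of R~L~
are compared by forcing each candidate to account for the independently
measured (gas-exchange) R~L~ and scoring the loss of goodness of fit.

# Model and simulation

## Atom-transition network

The network is a compartmentalized (plastid `.p`, cytosol `.c`,
mitochondrion `.m`) reaction list with per-carbon atom transitions in
letters notation, declared reversibility, and CO~2~ tags
(`release:shunt|tca|fa`, `fix`, `pr`, `none`). R~L~ is computed from a flux
vector as

> R~L~ = Σ(tagged releases, excluding photorespiratory) − Σ(fixations),

with the shunt, TCA and fatty-acid components read off the tags; PEP
carboxylase (the only `fix` reaction) offsets the TCA component, following
the biochemistry: OAA formed from PEP and CO~2~ re-captures carbon that TCA
decarboxylations release. Rubisco itself is tagged `none`: its carboxylation
is the reference input, not part of R~L~.

The shipped `camelinaLeafModel()` fixture reconstructs leaf central
metabolism — C3 cycle, photorespiration, starch and sucrose synthesis,
cytosolic glycolysis, PEP carboxylation, a noncyclic daytime TCA segment,
the G6P/OPP shunt and plastidic fatty-acid precursor synthesis, with
transport steps and a lumped phloem sink of fixed composition
(sucrose + 0.1618 Glu + 0.0425 Asp + 0.01137 Ala). Atom maps follow
standard carbon bookkeeping (e.g. rubisco `RuBP(abcde) + CO2(f) ->
PGA(cba) + PGA(fed)`; citrate synthase `OAA(abcd) + AcCoA(ef) ->
CIT(dcbfea)`). Succinate and fumarate are treated as rotationally symmetric
by 50/50 scrambling of the atom maps at their producing reactions.

Two small truth sinks close the steady state exactly: vacuolar malate
accumulation (0.117 µmol gFW^−1^ h^−1^) and glutamate accumulation (0.104),
both standard leaf behaviors. With the pinned published rates (starch 9.5,
sucrose export 4.3, shunt 4.6, cytosolic pyruvate decarboxylation 0.8 with
the stoichiometrically coupled isocitrate-dehydrogenase release 0.8, PEPC
1.1, v~o~/v~c~ = 0.2), carbon conservation then *implies* carboxylation
v~c~ ≈ 132 µmol gFW^−1^ h^−1^; we let the balance decide v~c~ rather than
pin it, so the truth satisfies N·v = 0 to machine precision.

## EMU decomposition

Only the carbon subsets needed to predict the measured fragments are
simulated. Backward traversal of the atom maps from each fragment's EMU
(elementary metabolite unit) collects the minimal closure; production terms
whose source atoms come from several molecules couple an EMU only to
strictly smaller EMUs through MID convolutions, so the system is a cascade
of linear blocks ordered by EMU size. Within a size class the coupling
graph is further split into connected components, which are decomposed
independently (eigendecomposition cost is cubic in block size). The full
camelina fixture with its 35 fragments needs 289 EMUs up to size 7.

## Integration

Within one block the balance equations are linear time-invariant once the
fluxes are fixed:

c~i~ dx~i~/dt = Σ~j~ v~ij~ x~j~ − out~i~ x~i~ + b~i~(t),

with x the MID vectors, c the pool sizes and b(t) the tracer input and
lower-block convolutions. Each block is propagated *exactly* through the
eigendecomposition of its coefficient matrix, with b(t) piecewise linear on
an internal log-dense grid (closed-form φ~1~/φ~2~ forcing integrals, series
fallback near λh → 0). This is unconditionally stable — necessary because
C3-cycle pools turn over in well under a second while the experiment runs
an hour — and exact for the linear dynamics; the only discretization error
is the forcing interpolation, controlled by the grid. The grid starts just
below the fastest pool turnover time (min c/v over simulated metabolites,
divided by 30), plus one point immediately after the tracer step so the
switch is effectively instantaneous. Halving/doubling the grid changes
target MIDs by < 10^−7^ at the reference resolution (`ngrid = 2000`);
fitting uses `ngrid = 100`, which reproduces the reference within a few
10^−4^ in mole fraction and adds ≈ 2 SSR units on a fixture dataset whose
SSR is ≈ 1400.

The production simulator is cross-checked in the test suite against a
brute-force positional-isotopomer ODE oracle (full 2^n^ state per
metabolite, integrated with `deSolve::lsoda`) on small networks exercising
reversibility, symmetry scrambling and convolutions; agreement is within
10^−6^ absolute at all time points.

## Tracer program

Data are assumed natural-abundance corrected, so the pre-switch MID is
[1, 0] and the post-switch CO~2~ MID is [1 − p, p] at tracer purity
p = 0.99. The default switch is a step at t = 0; an exponential washin with
τ = 5 s is available to quantify the finite atmosphere-exchange time of a
fast cuvette (it is negligible by the first 30 s sample).

# Measurement model

Fragments map EMU trajectories to observable ions: fixed mixtures over
moieties or co-measured compartment variants (e.g. the GC-MS sucrose ions
m/z 361 = 0.54 fructosyl + 0.46 glucosyl and m/z 451 = 0.92/0.08 — the
measured-standard values; the older literature pair 0.60/0.40, 0.95/0.05 is
available by argument), then affine mixing with the metabolite's inactive
(vacuolar) pool: observed = (1 − d)·active + d·unlabeled. Natural-abundance
correction matrices are built by convolving per-element isotope
distributions (^13^C abundance 0.0107; H, N, O, S, Si from IUPAC values,
configurable) for the derivatization/heteroatom formula of each fragment,
and corrected MIDs solve M·x = raw with small negatives clipped and
renormalized (components below −0.01 are flagged). A floor of 0.005 mole
fraction is applied to reported sds to avoid unbounded weights.

# Flux fitting

**Parameterization.** The steady-state space is coordinatized by pinned
reactions, one per free-flux dimension (8 for the camelina fixture:
oxygenation, shunt, starch, export, PEPC, cytosolic PDH, AKGDH, plastidic
PDH); every other net flux is the linear completion v = M~p~·p. The
rubisco ratio r = v~o~/v~c~ is fitted logit-bounded in [0.2, 0.25]
(physiological constraint; an unconstrained variant bounds r in (0, 0.5)),
solving the one linear equation that makes v~o~ = r·v~c~ consistent with
the completion. Exchange fluxes and pool sizes are fitted on log scale.
Dilution fractions enter the prediction affinely, so they are profiled out
by a single linear least-squares solve at every objective evaluation
(variable projection), clipped to [0, 0.995].

Exchange fluxes that the 12-point time course cannot resolve (the
phosphoglycerate-kinase and triose-isomerase equilibria, aldolases, the
mitochondrial fumarase segment) are fixed at the model's standing defaults;
the ten with direct leverage on the measured labeling are fitted: alanine
and aspartate transaminases, cytosolic malate dehydrogenase, both
phosphoglucose isomerases, triose-phosphate transport, and the four
pentose-phosphate interconversions (both transketolase reactions and the
two pentose isomerase/epimerase steps — leaving these free matters because
they set how strongly the G6P/OPP shunt's slower hexose label imprints on
the pentose MIDs). Pools of the 24 measured metabolites are fitted, the
rest stay at defaults. This is a deliberate identifiability/runtime
trade-off, standard in desk-scale MFA.

**Optimization.** Multi-start Levenberg–Marquardt (`minpack.lm::nls.lm`,
finite-difference Jacobian with `epsfcn = 10^−6^` to ride over
eigendecomposition jitter), staged: each start is first explored over the
flux coordinates only (pools/exchanges held), then the best candidates are
polished over the full vector. Starts are drawn log-uniformly around a
generic start point (boundary-rate pins start at the measured rates).
Negative irreversible fluxes are discouraged by a stiff one-sided penalty
block; forced scenarios are exact: the respective R~L~ component equation
(linear in p) eliminates one pinned flux, so the forcing holds identically
during optimization, never as a penalty.

**Pool-size measurements.** Absolute pool sizes of the quantified
metabolites enter as lognormal soft priors (log-scale sd 0.25, i.e. about
±30%). A chemical pool measurement sees the *total* pool — active plus
inactive — so the prior constrains active/(1 − d), coupling the fitted
pool to the dilution fraction. This matters for hypothesis testing: a free
pool and a free dilution fraction can jointly mimic any slowly-labeling
kinetics (only (1 − d)·v/c is identified from a near-linear ramp), and
even with a prior on the active pool alone, raising d hides label at no
cost. With the total-pool prior, hiding label by raising d shrinks the
implied active pool, speeds its turnover, and contradicts the measured
kinetics — restoring the discrimination the study relied on.

**Goodness of fit.** Residuals are (measured − predicted)/sd for every MID
entry plus the boundary rates with their own sds (both weighted 1/sd²);
SSR is assessed against the two-sided χ² interval at the dataset's degrees
of freedom (residual count minus fitted parameters including projected
dilutions). Scenario comparison reports SSR, ΔSSR, v~o~/v~c~ and the R~L~
partition per scenario, plus per-fragment squared residuals (SRES) to
localize which measurements reject a forced hypothesis.

# Confidence intervals

*Parameter continuation*: the quantity of interest (for example R~L~) is
stepped away from its optimum through a stiff penalty residual,
re-optimizing all other parameters at each step; the 95% bound is where the
penalty-free SSR crosses SSR~min~ + 3.84 (χ²~1~), located by interpolation
with adaptive steps. Profiles flat after the step budget return flagged
open intervals (structural non-identifiability). *Monte Carlo*: datasets
are resampled within the measurement sds (zero-truncated, renormalized;
boundary rates too, following the stated uncertainty of both measurement
classes), refitted warm-started from the unperturbed optimum, and the
2.5/97.5 percentiles reported. The full-scale analysis uses 3000 draws;
tests and examples use 60–200. The two methods agree on test problems
within the Monte-Carlo error of those sizes.

# Synthetic data generator

The generator emulates the study design: 12 sampling times (0, 0.5, 1, 2,
2.5, 3, 5, 7, 10, 15, 30, 60 min), three replicates averaged per point,
99 atom % tracer, ~35 fragment ions over C3-cycle, photorespiratory, sugar,
TCA and amino-acid metabolites, measured boundary rates jittered within
their sds (A~net~ sd 5, starch 0.1, sucrose 1.08 µmol gFW^−1^ h^−1^), and
measured pool sizes of the quantified metabolites (lognormal, 20%
measurement error, weighted in the fit with a conservative 0.35 log-sd).
Dilution fractions are set so that 60-min enrichments reproduce the
observed phenomenology: S7P the most-labeled C3 intermediate (~93%), hexose
phosphates 85–86%, sucrose with a 40% inactive pool, UDP-glucose ~78%,
alanine ~71%, aspartate ~22%, pyruvate ~76% (pyruvate carries no vacuolar
pool — it is not stored — but is measured as a 0.9/0.1
cytosolic/plastidic mixture, which is what gives the fatty-acid branch its
labeling footprint), citrate ~3% on two GC-MS fragments, and all TCA
intermediates < 5% (large vacuolar pools, dilution 0.86–0.95, with slow
active turnover). Noise is
Gaussian per replicate, truncated at zero and renormalized; its sd scales
with the signal (full fragment sd of 0.01–0.02 at mid-scale fractions,
much smaller near 0/1), emulating MS counting statistics — without this,
truncation at zero would bias every near-zero isotopologue upward by
~0.8 sd and distort both the SSR distribution and the fitted TCA fluxes.

What the generator does *not* emulate: chromatographic interferences and
co-elution (the reason the real study excluded G1P), drifting MS response
(scaling factors), diurnal non-steadiness, or biological replicate-level
flux variation. Passing recovery tests therefore demonstrates correctness
of the estimation machinery under the stated noise model, not robustness
to structural measurement artifacts.

The small `miniLeafModel()` (one carboxylation, a triose pool, a
one-carbon regeneration pool with shunt-like release, an export branch and
two pyruvate decarboxylations standing in for TCA and fatty-acid release)
carries the statistically replicated experiments — CI coverage across
seeds, continuation/Monte-Carlo agreement, scenario discrimination — at
seconds per fit; the full fixture is reserved for the single-seed
end-to-end experiments. Problem sizes used by the shipped tests: mini fits
with 2–12 starts, coverage over 8 seeds, Monte Carlo with 12–80 draws;
camelina fits with 20 multi-starts (6 warm-started per forced scenario) on the seed-1 dataset.

# Numerical choices and degenerate inputs

- Steady state is enforced by construction (linear completion); flux states
  reaching the simulator are checked to 10^−6^ relative mass balance.
- Metabolites with zero turnover (for example the plastidic pyruvate branch
  when its flux is 0) simply stay unlabeled; the propagator handles λ = 0
  through series expansions of the forcing integrals.
- Defective eigensystems are jittered (diagonal ridge 10^−9^·max|A|) and
  retried; this path is exercised only by pathological hand-built inputs.
- Sucrose deconvolution refuses mixing matrices with |det| < 10^−6^; the
  Laisk estimator refuses slope spreads < 10^−3^ (unstable intersection)
  and needs ≥ 3 light levels.
- Tiny negative MID undershoot (< 10^−9^) from forcing interpolation is
  clipped before renormalization.

# Known limitations

- The fitted exchange-flux subset is fixed by configuration; fully free
  exchange fitting would need regularization and longer time courses.
- The χ² verdict is conservative on generated data because the sd floor
  over-weights near-zero isotopologues (SSR at truth ≈ 0.6·dof).
- Continuation treats one quantity at a time; no simultaneous confidence
  regions.
- LM is local; the staged multi-start strategy is a heuristic and, like
  the original analysis, cannot guarantee the global optimum.
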