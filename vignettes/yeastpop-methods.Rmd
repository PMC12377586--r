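---
title: "A coarse-grained multiscale model of growing budding-yeast populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained multiscale model of growing budding-yeast populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastpop)
```

# Overview

`yeastpop` couples two models of the proliferating budding-yeast cell that
operate at different scales and exchange exactly two parameters:

1. **A proteome-allocation solver** (`solve_allocation`). Given a carbon
   source, its concentration, and the fermentative ratio *F* (the fraction
   of catabolized glucose routed to ethanol excretion rather than
   respiration), it distributes a bounded proteome budget across five
   protein classes — glucose carriers (HXT), glycolysis/gluconeogenesis,
   fermentation, respiration, and ribosome/translation — so as to maximize
   the balanced exponential growth rate λ. From the optimum it exports the
   growth interface: **K2**, the realized protein-synthesis rate per
   ribosome, and **ρ**, the target RNA/protein mass ratio.
2. **A single-cell growth and cycle simulator** driven only by (K2, ρ):
   protein and RNA dynamics, a Cln3/Far1 size trigger followed by cycle
   timers (or, alternatively, a molecular Whi5/SBF G1/S module), and an
   agent-based population engine that grows pedigree-structured populations
   to flow-cytometry scale (~50,000 cells) with division noise.

Population outputs — protein-content distributions on a 1024-channel axis,
mass duplication time, parent/daughter G1 lengths, budded fractions — are
directly comparable to flow-cytometry and bud-scar measurements of
exponentially growing cultures.

# The allocation model

## Structure

The metabolic network is a deliberately small self-replicator. Fluxes are
expressed in pyruvate-equivalent carbon units per minute per unit of total
protein; one glucose yields two pyruvate equivalents, and each excreted
ethanol carries one, so the stoichiometric maximum yield (two ethanol per
glucose, mass ratio 92/180 g/g) corresponds to *F* = 1 (`derive_F`).

On glucose, with fermentative ratio *F* and concentration *c*:

* transport: $v_{glc} \le k_{cat,hxt}\,\phi_{HXT}\,c/(K_M + c)$;
* glycolysis: $v_{glc} \le k_{cat,gly}\,\phi_{gly}$, producing
  $2 v_{glc}$ pyruvate and $y_{gly} = 2$ ATP per glucose;
* the catabolized pyruvate flux $v_{cat}$ splits $F : (1-F)$ between
  fermentation ($v \le k_{cat,ferm}\phi_{ferm}$, no further ATP) and
  respiration ($v \le k_{cat,resp}\phi_{resp}$, $y_{resp} = 13$
  ATP/pyruvate);
* biosynthesis drains one pyruvate equivalent and $e_{aa} = 5$ ATP per
  polymerized amino acid, plus a small growth-independent maintenance;
* translation: $\lambda \le k_{trans}\,a(q)\,\phi_{ribo}$ (below);
* budget: $\sum_i \phi_i + \phi_{other} \le \phi_{max}$.

On ethanol (*F* = 0 by definition) ethanol is either respired or converted
to precursors through the lumped gluconeogenic branch of the
glycolysis/gluconeogenesis class, at an extra ATP cost per precursor.

At a fixed *F* the program is linear in the class fractions, and at the
λ-optimum every capacity constraint and both balances bind: slack in any
constraint frees budget that could hold ribosomes and raise λ. The optimum
is therefore computed by propagating the carbon and ATP balances at a
candidate λ and locating, by a monotone one-dimensional root search, the
unique λ at which the proteome budget is exactly exhausted. Tests verify
the optimizer against an exhaustive grid oracle on a reduced instance.

## The overflow trade-off and the energy-coupled ribosome activity

Respiration extracts far more ATP per carbon but, in this calibration, far
less ATP per unit of proteome ($k_{cat,resp} \ll$ the effective fermentative
route), which is the resource-allocation reading of the Crabtree effect:
fast-growing cells ferment because fermentation is proteome-cheap. The
ribosome class additionally carries an activity factor

$$ a(q) = a_{min} + (1 - a_{min})\,\frac{q^{\,n}}{K_a^{\,n} + q^{\,n}}, $$

where $q$ is the specific substrate-level ATP flux produced by glucose
*catabolism* (fermentative/glycolytic overflow ATP; the biosynthetic carbon
drain does not signal). This encodes carbon-source signaling of the
translational program: a fully respiratory cell (ethanol; $q = 0$) runs its
ribosomes at the floor $a_{min}$, a strongly fermenting cell near capacity.
The exported interface is then

$$ K_2 = \lambda / \rho = k_{trans}\, a(q) / \chi_{RNA}, \qquad
   \rho = \chi_{RNA}\, \phi_{ribo}, $$

with $\chi_{RNA}$ the RNA mass per unit ribosomal-class protein. K2 — not
only λ — is therefore nutrient dependent, and it is the channel through
which the metabolic mode (rather than the growth rate per se) reaches the
cell-cycle machinery.

## The fermentative ratio

*F* is an input, as in the wet experiments it summarizes: for wild-type
glucose media it comes from a measured ethanol/glucose yield
(`derive_F`) or from the shipped saturating curve
$F(c) = F_0 + (F_{max}-F_0)\,c/(K_F + c)$ (`wildtype_fermentation_curve`,
fitted by `fit_fermentation_curve` when data are available). The shipped
constants ($F_0 = 0.02$, $F_{max} = 0.97$, $K_F = 0.35\%$) are a package
calibration reproducing respiro-fermentative physiology — nearly fully
respiratory at 0.05% glucose, nearly fully fermentative at 2% — not a
published dataset.

Metabolic mutants are expressed as multiplicative overlays on catalytic
coefficients (transporter ×1/5 for a transport-crippled strain, glycolysis
×1/2 for a hexokinase-crippled strain). Their measured fermentative ratios
are not package inputs; instead the package assumes such strains run the
catabolic split that maximizes their growth rate (`optimal_F`). With the
shipped calibration this reproduces their respiratory shift endogenously:
expensive transport or glycolysis makes the carbon-hungry fermentative
route unprofitable.

# The single-cell model

## Growth

Each cell carries protein content $P$ (amino acids; the cell-size proxy
throughout) and an RNA/ribosome pool $R$:

$$ \dot P = K_2 R - \delta_P P, \qquad
   \dot R = k_R(\rho P - R) - \delta_R R. $$

$k_R$ is fast by default (quasi-equilibrated ribosome fraction), so cells
grow balanced at $\lambda_{cell} \approx K_2 \rho - \delta_P$, matching the
allocation λ. Degradation rates default to zero and are exposed for
exploration. Integration is fixed-step RK4 (`step_growth`), dt = 0.1 min
for single cells and a shared dt = 0.5 min in the population engine; tests
check the integrator against the closed-form solution of the linear system
and a step-halving criterion.

## The G1 trigger and timers

The default controller is a size threshold followed by timers. Cln3 level
tracks protein content (a constitutive proteome share); it must overcome
the Far1 inhibitor threshold during the gated T1b period. The effective
threshold is

$$ \mathrm{Far1}_{eff} = \mathrm{Far1}_{ref}\,
   (K_2/K_{2,ref})^{\theta_{K2}}\,(\rho/\rho_{ref})^{\theta_\rho}, $$

i.e. the critical size at START scales with the nutrient-signaled
translational program, referenced to wild type in 2% glucose. This is the
coarse-grained encoding of the classical observation that the Cln3/Far1
size threshold is nutritionally modulated: cells in fermentative media set
a larger critical size, respiratory cells a smaller one, largely
independent of growth rate. The shipped exponents are calibrated (below):
$\theta_{K2} = 1.54$ carries the modulation; the small
$\theta_\rho = -0.03$ is a calibration residual that absorbs the remaining
difference between the K2 channel and the measured anchors.

After the trigger, T2 runs to budding; the budded timer T_B covers
S + G2 + M, its terminal T_G1* separating nuclear from cell division.
Newborns draw their timers from mean-preserving lognormal distributions
with CV `CV_timer` (default 0.15).

**Timer scale.** Timers are specified at the reference condition and
stretch with the condition's growth timescale,
$T \mapsto T\,(\lambda_{ref}/\lambda)^{\gamma_T}$ with $\gamma_T = 1$ by
default. This couples the cycle timescale to the growth interface — the
analogue of constraining the post-trigger timer jointly with (λ, ρ, K2) —
and makes the cycle geometry (budding index, phase fractions)
condition-invariant, consistent with the stability of budded fractions
across media. The reference set (T1a = 6, T2 = 9, T_B = 72, T_G1* = 13 min
at λ_ref ≈ 0.0066/min) reproduces a ~60% budding index, parent G1 ≈ 16 min
and daughter G1 ≈ 45 min in 2% glucose. With $\gamma_T = 0$ the timers are
absolute minutes instead; in that regime mean size tracks λ strongly and
nutritional size modulation is exaggerated, which is why the scaled regime
is the default.

## Division

The daughter receives the bud compartment — the protein accumulated since
budding — perturbed by a mean-preserving lognormal partition factor
(CV 0.10 by default); the parent keeps the remainder, so protein is
conserved exactly. The parent's genealogical age increments; daughters are
born at age 0. Both re-enter G1 with fresh timer draws. Parents are born
above the size threshold, so their G1 is short (T1a + T2); daughters must
grow to the threshold, which generates the mother–daughter G1 asymmetry
and, through it, the population's pedigree structure.

## The molecular G1/S plug-in

A mass-action Whi5/SBF module can replace the trigger and G1 timers
(`controller = "g1s_molecular"`): SBF is held by Whi5; Cln3 (proportional
to synthesis capacity $K_2 R$) drives sequential phosphorylation of the
four functional Whi5 sites on the complex; the fully phosphorylated complex
releases SBF, bound Whi5 is also slowly cleared ($\alpha_W$), and START —
budding — fires when the free-SBF fraction reaches a threshold (default
0.5). At cycle entry Whi5 rebinds SBF in a brief association burst, so the
association constant $k_{14}$ controls how completely SBF is re-inhibited
in newborns. Mutant presets: `whi5_delta` (total Whi5 = 0) and `whi5_4E`
($k_{14} \times 1/10$ and $\alpha_W \times 1/2$; the clearance factor is a
package choice, exposed as configuration). Both shift the population to
smaller cells, in the order whi5Δ ≤ whi5-4E ≤ wild type. The wild-type
module is calibrated so its noise-free G1 duration matches the timer
controller's T1a + T1b + T2 within 2% on a reference trace
(`controller_contract_check` validates any controller against the plug-in
contract: legal event order, determinism under a fixed seed).

# The population engine

Populations start from `n_lines` founder cells (default 10) drawn from an
approximate stationary age/size composition (spread genealogical ages on
the parent-size ladder), which desynchronizes the inoculum and fills the
old-parent tail quickly. The engine advances all cells on a shared dt,
handles divisions at the first step boundary after timer expiry, and stops
at `target_cells` (default 50,000) or at the horizon. Every run is exactly
reproducible from (seed, configuration).

`compute_stats` discards a burn-in (five population doublings by default),
fits the mass duplication time to the log cell-count trajectory — refitted
over the last three duplication times, where the age composition has
converged — and reports ⟨P⟩, SD(P), CV(P), the protein landmarks P0
(birth), Ps (trigger) and Pcd (division), G1 lengths and cycle times split
by newborn class, budded/genealogical fractions, and a stationarity drift
diagnostic (relative slope of division size per duplication time).

Two residual finite-size effects are documented deliberately. First,
successive parent generations are born slightly larger (growth during
T1a + T2 compounds on cells already above the threshold), so the
population mean converges from below as the genealogical-age tail fills
in; at 50,000 cells the residual drift is below ~1% per duplication time.
Second, timer expiry at step boundaries adds up to one dt per phase; with
dt = 0.5 min this biases absolute durations by well under 1% and cancels
almost exactly in cross-condition ratios, which are the quantities the
package is calibrated on.

# The population-kinetics calculator

The classical budded-fraction relations connect snapshot fractions to
phase durations: $T_B = \log_2(1+F_B)\,T$,
$T_{G1^*} = \log_2(1+F_{G1^*})\,T$, $T_P = \log_2(F_B/F_{PB})\,T$,
$T_D = \log_2(F_B/F_{DB})\,T$, with $\mu = \ln 2/T$, and the
asymmetric-division consistency $e^{-\mu T_D} + e^{-\mu T_P} = 1$
(`phase_durations`, `asymmetry_residual`, `solve_daughter_time` — monotone
bisection, checked against the closed form
$T_D = -\ln(1 - e^{-\mu T_P})/\mu$). The protein landmarks
$P_P = P/\mu\,(T_P - T_D + T_D e^{\mu T_P})$ and
$P_s = P_P\,e^{\mu(T_P - T_B)}$ are evaluated exactly as printed in the
source relations even though the dimensional bookkeeping of the first is
unusual (protein × time); a clearly labelled non-canonical alternative
reading ($P\mu(\cdot)$) is available behind a switch for exploration.
`crossvalidate_with_simulation` closes the loop: durations derived from
simulated fractions agree with the event log within a few percent under
default noise.

# Distribution comparison and synthetic experiments

Flow-cytometry protein distributions arrive as 1024-channel histograms in
arbitrary fluorescence units. `align_distributions` implements the
three-step comparison loop — candidate (origin, width) on the amino-acid
axis; subsample the simulation to the experimental sample size and bin it;
sum of squared residuals between count vectors — over an exhaustive 32×32
coarse grid with two local refinements, retaining the full SSR certificate.
The optimal scale found for the reference condition (wild type, 2%
glucose) is then frozen and reused unchanged for other conditions and
mutants (`reuse_alignment`). Bins are half-open $[low, high)$; out-of-range
values go to an overflow tally excluded from the SSR; subsampling is
seeded and recorded.

Because no external dataset ships with the package, `synthesize_experiment`
emulates an acquisition: sample `n_events` cells (default 30,000), apply
the affine instrument response $fu = g\,P\,(1+\varepsilon) + o$ with
multiplicative Gaussian noise (flow-cytometry CVs are approximately
scale-proportional), and bin into 1024 channels. Planted-transform
round-trips (gain and offset recovered within one grid step, 20/20 under
fixed seeds) validate the aligner. What passing these tests shows is that
the comparison machinery is faithful; they say nothing about
autofluorescence, debris, doublets, or gating in real cytometry data,
none of which are modelled.

# Calibration of the shipped defaults

The package ships one wild-type parameter set, fixed once by the following
procedure (the anchors are the headline experimental observations the
model family is built around):

* growth-rate anchors: λ(2% glucose) ≈ 0.0066/min (MDT ≈ 106 min),
  λ(0.05% glucose) ≈ 0.0056/min, λ(ethanol) ≈ 0.0026/min — the near
  halving of λ from 0.05% glucose to ethanol;
* size-modulation anchors: mean-protein ratios 2% glucose/ethanol ≈ 1.8
  (wild type), ≈ 1.33 under the transporter ×1/5 overlay, ≈ 1.15 under
  the glycolysis ×1/2 overlay, and ≈ 10% residual reduction from 0.05%
  glucose to ethanol;
* behavioural constraints: the growth-optimal F at 2% glucose is nearly
  fully fermentative for wild type and drops substantially for both
  overlays; the F-sweep and glucose-sweep monotonicities of the allocation
  hold.

The λ anchors pin the catalytic coefficients; the ratio anchors pin the
activity-curve shape ($a_{min}$, $K_a$, Hill exponent) and the single
threshold exponent $\theta_{K2}$. The absolute scale (Far1_ref =
2.6×10^10 aa) sets ⟨P⟩ ≈ 3.7×10^10 aa in 2% glucose, in the range of
measured per-cell protein content. After freezing, the acceptance script
recomputes the four ratio anchors from full 50,000-cell runs.

# Numerical choices and degenerate inputs

* dt: 0.1 min single-cell default, 0.5 min population default; timers
  expire at the first boundary past their duration (no interpolation).
* Root searches: allocation budget root by `uniroot` at 1e-12 tolerance;
  daughter-time inversion by bisection to 1e-9 min on [0, 10 T].
* Zero carbon, or a budget exhausted by maintenance, yields a flagged
  λ = 0 solution, never an error; F is forced to 0 on ethanol; a yield
  above 92/180 g/g is rejected by name.
* Lognormal noise is mean-preserving (meanlog = −σ²/2); partition draws
  implying an empty compartment are redrawn.
* Histogram ties: a value on a bin edge belongs to the upper bin; the
  mode of a tied histogram is the lowest maximal channel.
* The flat fermentation-curve degenerate case (constant F) returns
  F_0 = F_max with an arbitrary K_F rather than failing.

# Known limitations

* The metabolic network has no genome-scale structure, no individual
  enzymes, and no thermodynamic constraints; the five-class allocation is
  qualitative by construction.
* Balanced exponential growth only: no nutrient depletion, diauxie,
  stationary phase, or cell death; sensitivity scans that push parameters
  far from the calibration can leave the regime the defaults were built
  for.
* The parent-size ladder is unbounded (no replicative senescence), which
  is why population means converge from below at finite size (documented
  above).
* The molecular G1/S module is a minimal reconstruction — four sequential
  phosphorylation sites, one association constant, one clearance rate —
  suitable for mutant ordering and plug-in demonstrations, not for
  quantitative promoter-level predictions.
* Simulated populations used in the test suite are deliberately small
  (hundreds to a few thousand cells); the headline ratios are recomputed
  at the full 50,000-cell scale only in the acceptance script and the
  worked examples.

# A worked mini-example

```{r example, eval = FALSE}
# allocation for 2% glucose (F from the shipped wild-type curve)
alloc <- solve_allocation(nutrient_condition("glucose", 2))
alloc

# a 5,000-cell population (seconds); 50,000 for publication-scale runs
pop <- simulate_population(alloc, timer_settings(),
                           population_config(target_cells = 5000, seed = 1))
compute_stats(pop)

# wild-type size modulation at full scale
bundle <- run_scenario("wt_size_modulation")
size_modulation_ratio(bundle)
```
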