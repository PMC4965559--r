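---
title: "Methods: model-free relaxation analysis, titration mapping, and insertion modeling by gap growing"
author: "NMRDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NMRDynamics)
```

# Scope

NMRDynamics bundles the three bespoke computations behind a classic
solution-NMR characterisation of a two-lobed calcium-sensor protein and its
complex: (i) backbone dynamics from ¹⁵N relaxation via the Lipari–Szabo
model-free formalism, (ii) ligand-binding maps and affinities from HSQC
titrations, and (iii) a structural model of a homologous complex whose
sequence carries insertions too long for ordinary loop building, obtained by
an iterative gap-growing protocol monitored by solvent-accessible surface
area (SASA). This vignette records the models, the assumptions, every
tunable default and why it holds its value, and what the synthetic-data
tests do and do not demonstrate about real data.

# Model-free relaxation analysis

## Forward model

For an amide ¹⁵N–¹H spin pair tumbling isotropically with correlation time
$\tau_c$, internal motion is described by an order parameter $S^2$
(amplitude of the spatial restriction; 1 = rigid), an internal correlation
time $\tau_i$, and, where required, an exchange broadening $R_{ex}$ that
adds to $R_2$ only. The spectral density is

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2}
 + \frac{(S_f^2-S^2)\,\tau}{1+(\omega\tau)^2}\right],
 \qquad \tau^{-1} = \tau_c^{-1} + \tau_i^{-1},$$

with $S_f^2 = 1$ for the standard two-parameter form and
$S^2 = S_f^2 S_s^2$ for the extended (model 5) form. $R_1$, $R_2$ and the
heteronuclear NOE follow from the usual dipolar/CSA expressions; the
dipolar constant uses $r_{NH} = 1.02$ Å and the CSA constant
$\Delta\sigma = -160$ ppm, the conventional values for backbone ¹⁵N
analyses of this era, at a default proton frequency of 600.13 MHz (the
data this package was built around were recorded "at 600 MHz"; the exact
console frequency is configurable and every derived constant is recomputed
from it). The $\tau_i = 0$ limit is taken exactly: the internal term
vanishes, so model 1 is embedded in every richer model.

Five parameterisations are fit per residue: (1) $S^2$; (2) $S^2, \tau_i$;
(3) $S^2, R_{ex}$; (4) $S^2, \tau_i, R_{ex}$; (5) $S_f^2, S_s^2, \tau_i$.
Isotropic tumbling is assumed throughout; anisotropic diffusion is out of
scope.

## Fitting

Each model is fit to the residue's $(R_1, R_2, \mathrm{NOE})$ triple by
Levenberg–Marquardt least squares with residuals weighted by the
measurement uncertainties, projected onto box bounds
$S^2, S_f^2, S_s^2 \in [0,1]$, $\tau_i \in [0, \tau_c]$,
$R_{ex} \in [0, 20]\ \mathrm{s^{-1}}$. Zero is admitted for $\tau_i$
deliberately: the $\chi^2$ of the model ladder must nest
($\chi^2_4 \le \chi^2_2 \le \chi^2_1$, etc.), and that holds exactly only
if each richer model can represent its nested simpler ones. Nesting is
enforced constructively: every richer model is warm-started at the exact
embedding of its simpler fits (e.g. model 3 at $(\hat S^2_1, R_{ex}=0)$),
and LM never accepts a worse point.

Multiple starts guard against the multi-modality of the $\tau_i$ surface:
a deterministic grid of candidate starts (7–48 per model) is screened by
its initial $\chi^2$ — a cheap, fully reproducible stand-in for random
multi-starts — and the best three rows are polished. Noiseless data carry a
nominal relative weight of $10^{-6}$ so that "exact" recovery is meaningful
at machine precision.

## Model selection

The published protocols for this exact five-model ladder test the simplest
models for adequacy and escalate only on failure. With three observables,
models 4 and 5 are exactly determined (zero residual degrees of freedom),
so an F-test between them and their parents is undefined. The default
criterion therefore walks the ladder with a $\chi^2$ goodness-of-fit test
at $\alpha = 0.05$: accept model 1 if $\chi^2_1 < \chi^2_{0.95}(2)$;
otherwise accept the better of models 2/3 if adequate at one degree of
freedom; otherwise take the better of models 4/5 (preferring the
conventional model 4 on ties). An information-criterion alternative
(`selection = "aic"`, $\chi^2 + 2k$) is available.

## Global correlation time

An initial $\tau_c$ comes from residues whose relaxation is dominated by
overall tumbling: NOE strictly greater than 0.6 and no chemical-exchange
term. The 10%-trimmed mean of their $T_1/T_2$ ratios is root-solved
against the rigid-rotor ($S^2=1$) ratio curve, which is strictly
increasing in $\tau_c$; the trimmed mean buys robustness against residual
outliers. Exchange residues for the initial exclusion are found in a
pre-pass asking whether adding $R_{ex}$ to model 1 improves the fit at
$\alpha = 0.05$. Because the measurement variances are known, the correct
$\alpha$-level test is the likelihood-ratio form
$\Delta\chi^2 > \chi^2_{0.95}(1) = 3.84$; the F(1,1) form that the same
recipe would naively suggest has a critical value near 161 and no power at
all at this design size. The full analysis then alternates per-residue
fitting and $\tau_c$ re-estimation (refreshing the exchange exclusion from
the selected models) until $\tau_c$ moves by less than 0.5% between
iterations, capped at 20 iterations with a warning. The NOE > 0.6 filter
is applied inside the $\tau_c$ estimation as well as to the printed
averages; the averaging filter itself uses a strict inequality, so a
residue at exactly the cutoff is excluded.

## Uncertainties

Parameter uncertainties come from Monte-Carlo resampling of the
observables within their errors and refitting the selected model; 500
draws is the recommended protocol and `fitResidueModels(..., mcDraws =
500)` implements it. `runModelFree()` leaves draws off by default so a
150-residue analysis stays interactive; switch them on for final runs.

# Titration analysis

## Tracking and exchange regimes

Peak lists across a titration (molar ratios strictly increasing from 0,
default grid $\{0, 0.25, 0.5, 1, 2, 3, 4\}$ ending at the 1:4 saturating
endpoint typical of such peptide titrations) are linked by
nearest-neighbour matching in the weighted distance
$\sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2}$ with a per-step cap of
0.05 ppm. Two refinements matter in practice. First, on a coarse ratio
grid with protein far above $K_d$, the bound fraction can jump by ~0.4
between consecutive points, so a genuinely fast-exchange peak may move
farther than the cap; an unmatched trajectory may therefore take a farther
unclaimed peak, but only when the step continues the trajectory's
established drift direction — fast-exchange peaks move along the straight
line from free to bound position, so collinearity is the physically
correct disambiguator. Second, an appearing peak is interpreted as the
bound form of a doubling (slow-exchange) residue only if it lies
0.1–2 ppm from a trajectory whose original peak persists in place with
fading intensity; this is precisely the free/bound co-detection signature
and keeps migrating fast peaks from being misread as doublings. Matches
that remain genuinely confusable (two candidates within the cap of each
other, or two trajectories claiming one peak) are flagged ambiguous, never
guessed.

Classification thresholds: "unaffected" when the total composite motion
stays within 0.02 ppm (position jitter), "fast" when a single peak
migrates progressively by more than 0.05 ppm, "slow" when doubling with
intensity transfer and stationary peaks (drift ≤ jitter) is seen, and
"ambiguous" otherwise — a valid outcome, reported as such.

## CSP and binding maps

The composite chemical shift perturbation uses the conventional nitrogen
weight $w = 0.2$ (configurable); per-axis shifts are also reported so that
single-nucleus statements can be inspected. Binding maps split residues at
the lobe boundary, by default N lobe = 1–88 and C lobe = 89–158 (the
boundary is configurable; where a source gives both "1–88/89–158" and
"1–88/88–158", the one-residue overlap is treated as a typo and 88 closes
the N lobe).

## Dissociation constant

For fast-exchange residues, $\delta_{obs} = \delta_{free} +
(\delta_{bound}-\delta_{free})\,f_B(P, L, K_d)$ with the exact 1:1 binding
quadratic for $f_B$. $\delta_{free}$ is pinned to the measured ratio-0
position (so the fitted curve passes through it by construction),
per-residue bound shifts are profiled out linearly, and a single shared
$K_d$ is found by 1-D minimisation over $\log K_d$. Dilution during the
titration is ignored by default (concentrated ligand stocks); a correction
can be applied upstream by adjusting the concentrations in the series.

Identifiability is a first-class output: when $P \gg K_d$ the binding
curve collapses onto the stoichiometric limit $f_B = \min(L, P)/P$ and
contains no information about $K_d$. The fit compares its best curve with
that limit; if they differ by less than 0.01 in bound fraction everywhere
on the grid, the result is flagged unidentifiable and the confidence
interval is widened to the search floor. At 0.8 mM protein this correctly
flags a nanomolar site — such affinities are below what an NMR titration
at millimolar protein can resolve, and the tool reports that rather than a
number — while a 3 µM site remains identifiable through the curvature near
the equivalence point.

# Gap growing

## Protocol

The target sequence is aligned to the template (global, affine gaps,
BLOSUM62); runs of template gaps become insertions, numbered 1..k from the
N-terminus. The base model threads target residues onto the aligned
template backbone verbatim, leaves insertion sites empty with declared
chain breaks, and is briefly equilibrated; its SASA is the pre-insertion
reference. Insertions are then grown in descending index order (3 → 2 → 1
for three insertions; i.e. C- to N-terminal first), each in chunks of 3
residues by default — the middle of the customary 2–5 range; the final
remainder chunk may be smaller. Each chunk is built at ideal geometry with
the dihedrals of its secondary-structure annotation (helix (−60°, −45°),
coil (−120°, 130°)) and spliced at the growing end; an insertion flanked
by template helix on both sides is annotated helical, conserving the local
secondary structure through the growth. While the gap is open, a loose
tether guides the growing end toward the downstream anchor; numbering
becomes contiguous when the last residue is placed, which switches on the
peptide-geometry restraints across the junction and seals the break during
the final relaxation.

## Relaxation engine

The original protocol relaxed with 10–30 ns of explicit-solvent molecular
dynamics between additions. That engine is abstracted behind a pluggable
contract, and the built-in implementation is a desk-scale
simulated-annealing scheme over a coarse backbone potential assembled
entirely from pairwise terms: harmonic bond and 1–3 angle distances
(targets measured from ideal geometry), CA–CA peptide planarity, helix
$i/i{+}2$, $i/i{+}3$ CA and $i/i{+}4$ O···N restraints for annotated
helical runs, soft-sphere repulsion below 2.8 Å between non-bonded atoms,
weak positional restraints tethering conserved atoms to their template
coordinates, and a weak compaction term pulling atoms toward the centroid.
All terms have analytic gradients, so one annealing round is a
temperature-scaled random kick (0.5 → 0.05 Å across the schedule) followed
by L-BFGS minimisation. Rounds are accepted only when the total SASA
strictly decreases and the bonded geometry stays feasible, so the recorded
SASA sequence is monotone; relaxation stops when SASA falls to within 2%
of the reference (the published traces return to the reference line
without stating a tolerance; 2% is adopted and configurable) or the round
budget is exhausted, in which case the insertion is flagged and the
pipeline continues. A geometry-restoration phase (pure minimisation)
precedes the annealing rounds so that a freshly spliced or freshly sealed
junction is made chemically sound even when the SASA criterion is already
met. Energy rising monotonically over five accepted rounds aborts with a
divergence diagnostic. Force constants (reduced units per Å²): bonds 100,
angle-class 50, secondary structure 5, repulsion 20, positional 1,
compaction 0.02 — bonds must never yield, secondary structure should bend
before bonds do, and the compaction term must be the weakest force so it
shapes packing without distorting the fold. The configuration carries,
untouched, the metadata an external MD adapter would need (force field,
water model, electrostatics, thermostat/barostat, 10–30 ns relaxation runs
per addition); where sources disagree on the final annealing length (20 vs
50 ns), no canonical value is set — it is config-only.

## SASA

Shrake–Rupley with a deterministic golden-spiral point set: van der Waals
radii N 1.55, C 1.70, O 1.52 Å, probe 1.4 Å, 960 points per atom (about 1%
discretisation accuracy, confirmed against the analytic single-sphere area
and an independent random-dot Monte-Carlo oracle in the tests).
Determinism of the point set makes the whole gap-growing trace bitwise
reproducible for a fixed seed.

# Synthetic data and study conditions

The generators are pure functions of (truth, seed) and return their truth
record with the data.

* **Relaxation**: a 150-residue protein laid out like a two-lobed EF-hand
  dumbbell: helices rigid (model 1, $S^2 = 0.85$), ordinary loops mobile
  (model 2, $S^2 = 0.65$, $\tau_i = 50$ ps), two loops exchange-broadened
  (model 3, $S^2 = 0.80$, $R_{ex} = 4\ \mathrm{s^{-1}}$ — mirroring the
  non-binding EF-hand loops where exchange terms were needed), termini
  decaying to $S^2 = 0.3$ with $\tau_i = 300$ ps. Default $\tau_c$ 9.4 ns
  (the holo full-length value; the apo value was 8.4 ns), 2% multiplicative
  noise, error columns set to the noise level.
* **Titration**: 30 assigned residues — 10 fast-exchange binders in the N
  lobe, 8 slow in the C lobe, 12 unaffected — at 0.8 mM protein over the
  default ratio grid; fast peaks at population-weighted positions, slow
  peaks split with intensities $(1-f_B, f_B)$ and a 2% detection floor,
  0.005 ppm position jitter by default. A relative-jitter mode (noise
  proportional to each residue's own response amplitude) exists for
  recovery studies; 1% relative noise is the condition under which the
  package's median-$K_d$-error figure is computed.
* **Structures**: a two-helix hairpin from ideal dihedrals (14 residues
  per helix; the loop's turn dihedrals were chosen once, numerically, to
  give a near-antiparallel fold ~11 Å apart with no inter-helix clash),
  random hydrophobic-rich helix sequence, insertions drawn from G/S/T/N/D
  so alignment recovery is unambiguous.

What passing these tests shows: the estimators invert their own forward
models at the stated noise, the classifiers reproduce generated regimes,
the protocol's bookkeeping (orders, chunking, sealing, traces) is exact,
and the engine re-compacts toy folds. What they do not show: performance
on real spectra with peak overlap and missing assignments, anisotropic
tumbling, concerted loop motions, dilution effects, or the accuracy of
any particular homology model — the toy hairpin stands in for a real
template, and no claim is made about reproducing any published structure
or its force-field energies.

# Numerical choices and degenerate inputs

* LM damping starts at $10^{-3}$, grows ×6 on rejection, shrinks ×4 on
  acceptance; convergence when the best improvement falls below
  $10^{-10}$ of the worst $\chi^2$ for three sweeps.
* Zero measurement errors (noiseless inputs) are replaced by a $10^{-6}$
  relative weight floor; the all-parameters-zero corner where every $J$
  vanishes floors $R_1$ at $10^{-30}$ to keep the NOE defined.
* Exponential fits start from the log-linear solution; a non-decaying
  series is flagged (`ok = FALSE`) instead of fitted, and such residues
  are excluded downstream.
* $\tau_c$ root-solving brackets [0.3, 60] ns and doubles the upper bound
  as needed; fewer than five usable residues is an error, not a guess.
* Ties between models 4 and 5 prefer model 4; ambiguous peak matches are
  labelled, never resolved by coin flip.
* All generator and engine randomness is drawn from locally seeded RNG
  streams that restore the caller's RNG state.

# Known limitations

Single-field data only (no reduced spectral-density mapping, no
multi-field joint fits); isotropic tumbling only; backbone-only structural
representation with no side chains, so SASA trends — not absolute buried
areas — carry the convergence signal; the annealing engine is a surrogate
for MD and its reduced-unit energies have no thermodynamic meaning; the
$K_d$ fitter covers 1:1 binding in fast exchange and deliberately refuses
the slow-exchange (tight-binding) affinities, which need other experiments.
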