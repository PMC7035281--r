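---
title: "Models and methods: smFRET kinetics, gate geometry and binding for NSS transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: smFRET kinetics, gate geometry and binding for NSS transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretgate)
```

fretgate analyses the conformational dynamics of the cytoplasmic
(intracellular) gate of neurotransmitter:sodium symporters (NSS) such as
LeuT with three linked toolsets: single-molecule FRET trace idealization
and kinetics, geometric analysis of molecular coordinate frames, and
equilibrium-binding fits. Every input the pipeline consumes can also be
simulated with ground truth attached, so each stage is testable end to end.
This vignette records the models, the parameter choices that matter, and
the numerical decisions behind the implementation.

## The smFRET observation model

A labelled transporter molecule is modelled as a continuous-time Markov
chain over four emission states with fixed FRET means 0, 0.47, 0.63 and
0.79. The zero state is photophysical (donor dark); the three non-zero
states represent inward-open (low FRET), partially open intermediate, and
inward-occluded (high FRET) conformations of the intracellular gate. The
camera integrates over frames of 25 ms (40 fps), so the simulator:

1. samples an exact jump path from the generator matrix (Gillespie),
2. records per frame the *time average* of the state means over the frame
   — this deliberately reproduces the averaging artifact that makes
   sub-frame dwells unresolvable at high transition rates,
3. converts to channel intensities `I_D = T(1-E)`, `I_A = T·E`,
4. adds donor bleed-through to the raw acceptor channel
   (`I_A_raw = I_A + 0.165 I_D`),
5. adds Gaussian channel noise, and
6. zeroes the signal after an exponential photobleach time and during
   exponential blink intervals (frames keep being recorded, as in TIRF).

`noise_sd` (default 0.06) scales the per-channel Gaussian noise as a
fraction of the total intensity, which makes the FRET-efficiency noise SD
approximately `noise_sd`. The total-intensity scale (1000) and the noise SD
are realistic placeholders for typical TIRF recordings; neither quantity
is a measured instrument property, and nothing downstream depends on the
absolute intensity scale.

### Default conformational chain and ligand coupling

Substrate binding is modelled as modulating exactly one transition pair:
the low-to-intermediate forward rate becomes `k_on·[L]` and its reverse
`k_off` (defaults `k_on = 0.4 µM⁻¹s⁻¹`, `k_off = 2.04 s⁻¹`). The
default chain makes the high-FRET state a weakly populated satellite of
the intermediate (`0.1 s⁻¹` in, `2 s⁻¹` out). The reasoning: at
saturating aromatic substrate the intermediate dominates with minimal
excursions, while resolvable low/intermediate exchange happens near the
EC50. For any linear chain with this coupling, every state occupancy is
exactly of the form `base + amp·c/(c + K_app)` with a single shared

`K_app = (k_off/k_on) / (1 + k_i→h/k_h→i)`,

so with the default satellite branching (ratio 0.05) the apparent EC50 sits
about 5% below `k_off/k_on`. This is a property of the generating model,
worth keeping in mind when comparing recovered and nominal EC50 values.

The zero-FRET state is kinetically disconnected from the conformational
chain: zero-FRET frames arise from photophysics (blinks, bleaching), not
from a conformation, and are excluded from dwell statistics and occupancy
denominators throughout (an `include_zero_state` flag restores them).

## Trace correction, selection and idealization

Bleed-through correction subtracts a set fraction (0.165) of the donor
from the raw acceptor; FRET is `E = I_A/(I_A + I_D)` with dark frames
forced to exactly 0 (frames whose total intensity is non-positive are
treated as dark too — they contain only background noise and the ratio is
meaningless).

Selection applies five criteria: (i) single-step donor photobleaching,
(ii) `SNR_background ≥ 8`, (iii) `SNR_signal ≥ 5`, (iv) fewer than four
blink events, (v) FRET above 0.15 for at least 300 frames. The SNR
formulas are not uniquely fixed by common practice, so the package
declares its own: `SNR_background` is the mean pre-bleach total intensity
divided by the SD of the post-bleach background, and `SNR_signal` is the
bleach step amplitude divided by the SD of the pre-bleach total intensity.
Bleach detection finds the last sustained drop below a threshold placed
30% of the way from the terminal background level to the smoothed
maximum; a sustained (≥ 5 frame) intermediate level between 25% and 75%
of the step marks a multi-step trace.

Idealization is segmental K-means with the emission means held fixed at
the four model values: a hard nearest-mean assignment seeds the estimates,
then Viterbi decoding under the current transition matrix and shared
Gaussian emission SD alternates with re-estimation of both until the
assignment is unchanged (or 100 sweeps, flagged). Numerical choices:
the shared sigma is floored at 1e-4 so noiseless traces stay decodable;
transition counts get a pseudocount of `1/n` per cell so no move is ever
impossible; Viterbi ties break toward the lowest state index for
determinism. On noiseless traces at exact state means the procedure is
provably exact, and the suite asserts frame-for-frame equality.

## Kinetics: TDP, rates, occupancy, dose-response

Transitions are pairs of temporally adjacent non-dark dwells; pairs
separated by a dark dwell are dropped. The transition density plot bins
the mean *observed* FRET of the dwell before and after each transition
(0.05 bins) and reports transitions per second of non-dark observation
time.

Rates use the dwell-time maximum-likelihood estimator `k_ij = N_ij/T_i`
with `SE = √N_ij / T_i`, where `T_i` includes censored (trace-terminal)
dwell time. States never visited give flagged undefined entries; visited
states without exits give `k = 0` flagged as an upper bound. The
estimator applies no missed-event (dead-time) correction: at 25 ms frames,
rates approaching the frame rate are biased low because sub-frame dwells
are absorbed by their neighbours — the same regime the field flags as
unreliable for camera-based recordings. The estimator emits a caveat when
sub-2-frame dwells are present. Consequently the rate-consistency study in
the test suite samples at 5 ms frames (rates 0.5–4 s⁻¹, 10⁴ s of data),
where dwells are resolvable and all six pairwise rates land within 3 SE of
truth; the 25 ms dead-time bias (~5–10% at 4 s⁻¹) is a property of the
observation process, not of the estimator.

Ensemble occupancy is the fraction of non-dark frames per state, computed
per molecule and averaged across molecules (mean ± SE). The dose-response
fit is weighted least squares of `occ_s(c) = base_s + amp_s·c/(c + EC50)`
with one shared EC50 across the three states and the Hill coefficient
fixed at 1.0 (one binding event drives all occupancy changes). The EC50 is
estimated on the log scale; SE floors at 1e-4 keep noiseless data usable;
flat occupancy data raise an unidentifiability error, and an EC50 outside
the tested concentration range is flagged as extrapolation.

## Coordinate-frame geometry

Frames are atom tables (PDB or multi-model PDB via bio3d, categories
assigned from a residue-name map with an explicit "unknown" bucket).
All coordinates are in Å; residue numbering is taken as-is; a `chain`
argument selects one monomer of the dimer.

* **Gate distances.** The R5–D369 salt bridge is the minimum distance
  between {NE, NH1, NH2} of R5 and {OD1, OD2} of D369; the Y268–Q361
  hydrogen bond is the minimum between {OH} of Y268 and {OE1, NE2} of
  Q361. Minimum-over-set is robust to rotamer flips; the atom sets are
  this package's declared choice, since gate distances are convention.
* **χ1.** Signed N–CA–CB–CG dihedral in (−180°, 180°], IUPAC sign
  convention (cross-checked against an independent torsion
  implementation); |χ1| ≥ 120° classifies the "out" (trans-like) rotamer.
* **Substrate COM.** Mass-weighted over substrate atoms with standard
  atomic masses, hydrogens included when present.
* **Water counting.** A water oxygen is in the intracellular vestibule iff
  it is within 15 Å of the substrate COM, not within 5 Å of any lipid
  atom, has z between the z of F259 Cβ and G13 Cα (bounds ordered per
  frame), and is not within 8 Å of the L495 backbone, 5 Å of the L257
  backbone, or 13 Å of the V276/L280/L420 backbones ("backbone" = N, CA,
  C, O). The channel is the vestibule within 12 Å of the A198 backbone,
  so the channel count can never exceed the vestibule count (enforced).
  Only protein atoms qualify as reference atoms, so waters or ligands that
  reuse a residue number can never contaminate a backbone set.
* **Microstates.** 2D histogram of the two gate distances (0.25 Å bins
  anchored at the origin); microstates are the top-k strict
  8-neighbourhood maxima (k = 3 by default, labelled "a", "b", "c"), each
  with a representative frame nearest the peak bin center.
* **Ion coordination.** Polar O/N atoms within 3.0 Å, count-labelled:
  6 → octahedral-like, 5 → trigonal-bipyramidal-like.

A note on rigid-motion invariance: all distance-based quantities and |χ1|
are invariant under arbitrary rotations and translations (verified to
1e-9). The z-window of the hydration criterion, however, is anchored to
the membrane normal by definition (frames are assumed membrane-aligned,
no superposition is performed), so water counts are invariant under
membrane-preserving motions — any translation plus rotations about z —
but not under rotations that tilt the membrane normal. Testing full SO(3)
invariance for water counts would contradict the criterion's own
definition.

### Planted-water fixtures

The fixture generator builds a synthetic frame holding every reference
atom the criteria need (a 12-heavy-atom aromatic substrate centred at the
origin, z-bound atoms at ±12 Å, exclusion backbones placed inside or at
the edge of the vestibule sphere, single-atom lipids on a 16 Å ring) and
plants waters by rejection sampling so each water either satisfies every
criterion or violates exactly one named criterion. Waters are rigid
3-atom molecules but only the oxygen is tested, matching the criterion.
Labels record the boolean outcome of each criterion per water and are the
ground truth for the oracle-equivalence tests (the test suite re-evaluates
every criterion with an independent loop-based implementation).

## Equilibrium binding

Saturation data follow `S(L) = Bmax·L/(Kd+L) + m·L` with lognormal
mean-1 noise of chosen CV; paired nonspecific wells measure `m·L` under
the same noise model. The default fit is a *joint* nonlinear least squares
of total and nonspecific rows sharing the linear slope — statistically
safer than pre-subtraction because it propagates the background
uncertainty — while `subtract_paired = TRUE` reproduces the conventional
paired-background subtraction. Percent-of-max normalization divides by the
*fitted* Bmax, not the largest observed point, which is robust to noise at
the top concentration. SEs come from the fit covariance; a case-resampling
bootstrap is available behind a flag with a fixed seed. The fit is
scale-equivariant in signal and exactly equivariant under concentration
unit changes (both asserted in the suite). Affinity fold-changes are
ratios of fitted Kd values with first-order propagated SE.

## Problem sizes and what the tests show

The recovery studies run at desk scale, chosen to keep statistical power
high while the whole suite stays in the minutes range: the titration study
uses 150 molecules × 2000 frames at each of 8 concentrations
(0.1–300 µM); the emission-mean study 200 × 2000 frames; rate consistency
20 molecules × 10⁴ s at 5 ms sampling; binding recovery 12 log-spaced
concentrations in triplicate over 20 seeds; hydration oracle equivalence
1000 random fixtures. Recovered quantities under these conditions: EC50
within a few percent of `k_off/k_on` (the small negative offset is the
satellite-state algebra above), Kd medians within ~1% of the generating
1630 nM and 20.4 nM and their ~80-fold ratio, and a top-state mean
observed FRET within ±0.01 of 0.79.

What passing these tests does **not** show: the simulators emulate the
statistical structure of the real data (Markov dynamics with Gaussian
channel noise, bleaching, blinking, time averaging; planted waters with
exact criterion labels; lognormal assay noise), not the full physics.
There is no triplet photophysics or acceptor-specific bleaching, no real
solvent dynamics (reproducing the ~6-water channel or ~30 vs ~10-water
vestibule contrasts requires microsecond MD), no missed-event likelihood
(MIL) correction, and no crystallographic validation. Results on real
recordings additionally depend on instrument calibration that this
package deliberately leaves out of scope.
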