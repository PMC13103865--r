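---
title: "Methods: geometry, models and calibration choices in pistack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, models and calibration choices in pistack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pistack)
```

## The scientific question

Methylxanthines (caffeine, theophylline, theobromine) are flat bicyclic
alkaloids whose π-systems self-stack in water, limiting their solubility.
Aromatic anions such as ferulate, caffeate or salicylate can raise that
solubility dramatically. Two mechanisms are candidates:

* **Hydrotropy** — a collective effect that switches on above a minimum
  hydrotropic concentration (MHC), giving a flat-then-exponential
  solubility curve; diluting a saturated solution below the MHC
  precipitates the solute.
* **π-stacking complexation** — stoichiometric-like association of the
  agent with the xanthine (intercalation into its stacks), giving a
  linear solubility curve with no threshold; dilution is always safe.

`pistack` implements the quantitative toolchain that discriminates the
two: quantitative ¹H NMR concentration measurement, solubility-curve
model comparison, ROESY cross-peak classification, and geometric analysis
of molecular configurations. Because no public trajectories or spectra
accompany the underlying experiments, the package ships a
synthetic-configuration generator with exact ground truth; every analysis
stage is validated against it.

## qNMR molality

With the water resonance (4.80 ppm) as internal reference, the molality
of a solute follows from per-proton integral ratios:

$$ m = \frac{A_c / N_c}{A_w / 2} \cdot \frac{1}{M_W}, $$

where $A_c$ is the solute peak integral, $N_c$ the number of protons
behind that peak, $A_w$ the water integral (halved for water's two
protons) and $M_W = 0.0180153$ kg mol⁻¹. When a compound shows several
well-resolved peaks, per-proton integrals are averaged before the ratio.
The value of $M_W$ is fixed at four significant figures; the water
molality implied, $1/M_W = 55.508$ mol kg⁻¹, is exactly the value the
equimolal identity test asserts. The synthetic table generator is the
algebraic inverse of this formula (normalized so a designated one-proton
xanthine peak integrates to 1), which gives a machine-precision
round-trip test rather than a tolerance-based one.

## Solubility-curve models and selection

The two generating laws are

* linear: $s(c) = s_0 + k c$;
* MHC: $s(c) = s_0$ for $c < c_{\mathrm{MHC}}$ and
  $s_0 e^{b (c - c_{\mathrm{MHC}})}$ above.

The exponential-above-threshold form is one concrete realization of
"exponential increase beyond a critical concentration"; it is continuous
at the threshold and has the fewest parameters of the candidates we
considered. Fitting profiles the breakpoint over a 25-point grid spanning
the interior of the measured range; at each candidate the smooth
$(s_0, b)$ subproblem is solved by Nelder–Mead on log-transformed
parameters (positivity for free), initialized from the below-threshold
mean and a log-linear regression above the threshold. Models are compared
with the small-sample-corrected AIC (AICc); a difference below 2 — the
conventional weak-evidence boundary — yields `indeterminate` rather than
a forced verdict. Constant curves short-circuit to `indeterminate` with a
warning.

Breakpoint detection for inflections and plateaus uses the continuous
two-segment (hinge) parameterization with candidates restricted to data
abscissae, again demanding an AICc improvement of at least 2; a plateau
is declared when the post-break slope is at most one tenth of the
pre-break slope. Phase-diagram classification interpolates both binodal
polylines linearly and refuses to extrapolate, since measured binodals
are only trustworthy inside their span; the boundary tolerance defaults
to 0.01 mol kg⁻¹, the typical reproducibility of the underlying
solubility measurements.

## ROESY classification

Volumes are normalized to the intramolecular xanthine [A–B] cross-peak
(set to 1.0), making tables comparable across samples; normalization is
idempotent and scale-invariant, and symmetric duplicate entries are
averaged under unordered pair keys. The homo-association baseline is the
larger of the normalized [B–C] and [B–D] volumes (the only purely
intermolecular xanthine–xanthine signals). The default verdict rule is
purely volume-based: `hetero_preferred` needs at least half of the
xanthine–agent peaks, including the strongest, above the baseline;
`homo_preferred` needs the baseline to dominate every hetero peak;
anything else is `mixed`, with the full evidence reported. Because homo
pair formation scales with xanthine concentration, a concentration-aware
variant rescales the baseline by the agent:xanthine molality ratio before
comparison — a dilute xanthine showing a sizeable homo peak is strong
evidence of self-association. Systems near the rule boundary (in
practice, nicotinate-like tables where only a minority of hetero peaks
clear the baseline) flip from `mixed` to `homo_preferred` under the
concentration-aware rule; both readings are reported in the tests and the
rule choice is an explicit flag. No volume-to-distance conversion is
attempted: long-mixing-time ROESY volumes rank proximities, they do not
measure distances.

## Trajectory geometry

All geometry lives in a cubic periodic box (edge $L$, Å) under the
minimum-image convention, each displacement component folded into
$(-L/2, L/2]$. Molecule centres are unweighted means of atom positions
after unwrapping the molecule about its first atom (mass weighting is an
option, but the metrics are contact counts, for which geometric centres
suffice). Plane normals come from the SVD of the centred aromatic-plane
atoms; the sign is fixed deterministically, or by continuity against a
reference normal across frames — all downstream uses are sign-blind.

**Neighbor census.** A molecule "surrounds" a xanthine when its centre
(water: its single site) is within a cutoff of the xanthine's centre.
Defaults — 7.0 Å for xanthine/agent centres (about two stacking spacings
plus slack), 5.0 Å for water — are this package's calibration choices;
neither cutoff is stated in the experimental literature the package
accompanies, so both are parameters, and counts are monotone in them by
construction. The default search uses cell lists (grid cell ≥ the largest
cutoff, 27-cell neighborhoods); a brute-force $O(N^2)$ distance-matrix
path is retained and their exact equivalence is a test, not an
assumption.

**Axial classification.** Neighbor $j$ occupies an axial (stacking) site
of xanthine $i$ when the centre displacement projected on $i$'s plane
normal has magnitude in $[2.5, 5.0]$ Å, the residual lateral offset is at
most 2.5 Å, and the interplane tilt is at most 40°. The window brackets
the canonical 3.4 Å aromatic stacking distance; the lateral and tilt
limits admit the thermal wobble of a real stack while excluding
side-by-side pairs. Each side of the plane keeps one occupant — the
nearest qualifying neighbor, ties to the lower molecule index — so the
per-xanthine agent count from slots satisfies $k \le 2$. The reported
distribution $P(k)$, $k = 0\ldots3$, therefore has two readings, both
implemented: the default `count = "slots"` (at most one partner per
face, so $P(3) = 0$ identically), and `count = "all"`, which counts
every qualifying axial-window contact — the only geometry under which
three agents can crowd one planar molecule (two stacked, one off-axis
within the lateral allowance) — capping at 3 with a warning. We regard
the slot reading as the physically conservative default and retain the
permissive one for comparability with reports that show a $k = 3$ class.

**Efficiency.** The mean agent count per xanthine
$\bar k = \sum_k k P(k)$ is biased by composition: boxes with many
xanthines per agent mechanically depress it. The bias-corrected per-agent
efficiency $E = \bar k \, n_{\mathrm{xan}} / n_{\mathrm{agent}}$ — the
average number of xanthines engaged per agent — is invariant under
duplicating the box and is the cross-system comparison statistic.

**Aggregates.** Stacking contacts (slot occupancy, symmetrized) define a
graph; connected components are aggregates, and a component is a *fibril*
when its graph is a simple path of at least three molecules. Within a
fibril, agents of degree 2 are intercalated and agents of degree 1 at the
path ends are end-capping; the interior-agent fraction separates the two
morphologies.

## The synthetic generator and what it does (not) emulate

`generate_box()` plants rigid fibrils — ordered species sequences stacked
along a uniformly random axis at 3.4 Å spacing (the canonical aromatic
stacking distance), each molecule given a random in-plane spin — plus
free monomers, single-site water beads and counter-ions, all placed by
rejection sampling (bounded at 10,000 attempts, then an explicit packing
error naming the density) with a 2.0 Å heavy-atom clash floor under
minimum image. Noise enters as Gaussian in-plane jitter and Gaussian
plane tilt. Planar molecules of *different* placement units are kept at
least 6 Å apart (centre to centre, above the 5 Å axial-window maximum) so
the planted contacts are provably the only stacking contacts; without
this, a free agent can land by chance in a free xanthine's axial window
and the recorded ground truth would be incomplete. Species templates are
coarse flat skeletons with a representative heavy-atom footprint —
fused-bicyclic for xanthines, benzene-plus-substituent for aromatic
agents, a short aliphatic chain for levulinate-like agents — centred so
the body-frame centroid is the origin, making the nominal stack spacing
exact in centre-of-geometry terms. The analysis metrics are purely
geometric, so force-field geometry would add nothing the metrics can see.

What the generator deliberately does **not** emulate: thermal dynamics
(configurations are static, not Boltzmann-sampled), energetics and
H-bonding, realistic water structure (beads, optionally 3-site),
exchange between stacked and free states, and finite-time sampling noise
of real trajectory averages. Passing the planted-recovery tests therefore
shows that the geometric classifiers are *correct*, not that any real
system exhibits a particular $P(k)$; published all-atom trajectory
averages are out of reach at desk scale and are covered instead by the
formula-identity, oracle-equivalence and density-ordering properties.

## Problem sizes and numerical choices

The validation suites use boxes of 45–50 Å edge with roughly 80
molecules (three fibrils of mixed composition, free monomers, 60 waters):
large enough for wrap-around effects to be exercised, small enough that
50-box ensembles run in seconds. Model-discrimination power is measured
on 200 curves per class of 10 points each with noise at 5% of the clean
curve's range; recovery rates on 50 boxes per noise condition; oracle
equivalence on 100 random frames and $10^5$ random point pairs. The
census-ordering comparison uses 30 Å boxes with 450 waters, the densest
configurations in the suite. XYZ output carries six decimals
(round-trip tolerance $10^{-6}$ Å); PDB is fixed-format with three
decimals (tolerance $10^{-3}$ Å); only cubic cells are supported, and a
non-cubic CRYST1 is an explicit error.

## Known limitations

* The axial-window parameters are calibration choices; analyses of real
  trajectories should report sensitivity to them rather than treat the
  defaults as physical constants.
* Fibril detection requires a simple path; branched or cyclic stacks are
  reported as aggregates but never as fibrils.
* The MHC fit's breakpoint resolution is bounded by its profiling grid
  (about 1/25 of the data span by default).
* `count = "all"` can in principle over-count transient crowding in
  dense systems; the slot reading is preferred for quantitative use.
* Phase-diagram classification is strictly interpolatory; points outside
  the measured agent-molality span raise an error by design.
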