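---
title: "Free-energy surfaces for covalent inhibition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy surfaces for covalent inhibition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covfes)
```

## The problem

Covalent kinase inhibitors carry an electrophilic warhead (typically an
acrylamide) that alkylates an active-site cysteine by Michael addition.
Whether inhibition succeeds depends on free-energy quantities at several
scales: the ionization state of the nucleophilic cysteine, the activation
and reaction free energies of the addition step, the binding affinity of
the pre-reactive non-covalent complex, and the conformational
preference of the warhead for *reactive* arrangements in which the
nucleophile and electrophile are in van-der-Waals contact. `covfes`
implements the analysis layer of this protocol: umbrella-sampling
unbiasing into 1D/2D free-energy surfaces by WHAM, reaction-path and
barrier extraction, Boltzmann-inversion conformational surfaces from
unbiased trajectories, reactive-conformation statistics, and
thermodynamic-integration quadrature — together with synthetic
generators that stand in for the QM/MM and MD engines and supply exact
ground truth for every estimator.

Throughout, energies are in kcal mol⁻¹, distances in Å, angles in
degrees, and `kB = 0.0019872041` kcal mol⁻¹ K⁻¹ with a default
temperature of 300 K.

## Synthetic reaction surfaces

Because no trajectories can ship with an analysis package, the sampling
engines are emulated by an analytic two-well surface: a sum of negative
Gaussian wells on a quadratic confining background,

$$U(\xi) = k_c\,|\xi - \xi_c|^2 \;-\; \sum_w d_w \exp\!\Big(-\tfrac{(\xi_x-c_{x,w})^2}{2 w_{x,w}^2}
  -\tfrac{(\xi_y-c_{y,w})^2}{2 w_{y,w}^2}\Big).$$

This family was chosen because both calibration targets are cheap to
evaluate exactly: the basin free-energy difference by 2D quadrature of
$e^{-U/k_BT}$ over disjoint well regions, and the barrier as the
lowest-saddle (minimax) energy on a dense grid, found by union-find over
energy-sorted cells. `make_reaction_surface()` calibrates the two well
depths by nested 1D root-finding until both targets are met to
≤ 0.05 kcal mol⁻¹. The default geometry places the reactant well near
(3.4 Å, 2.0) and the product well near (1.9 Å, −1.5), so the
minimum free-energy path runs diagonally across the
(nucleophilic-attack, proton-transfer) coordinate plane, reproducing
the tight coupling of bond formation and protonation seen in
Michael-addition landscapes.

One subtlety: the quadrature ground truth is *basin-integrated* while
the surface read-out after WHAM is *minimum-to-minimum*. These agree
only when the two wells have equal curvature, so calibration iterates
the product-well width until $2k_c + d/w^2$ matches across wells. The
residual anharmonic mismatch is below 0.03 kcal mol⁻¹ for the default
geometry.

## Metropolis sampling of umbrella windows

Windows are sampled by Metropolis Monte Carlo targeting
$\exp[-(U+U_{bias})/k_BT]$ rather than by discretised dynamics: the
correctness contract (detailed balance) is exact, with no integrator
step-size to tune. The bias follows the AMBER restraint convention
$U_{bias} = k(\xi-\xi_0)^2$ **without** the ½ factor — a spring constant
of 100 kcal mol⁻¹ Å⁻² contributes 1 kcal mol⁻¹ at 0.1 Å displacement.
The proposal half-width starts at the random-walk-optimal scale
$2.4\sqrt{k_BT/2k}/\sqrt{d}$ and is tuned to a 30–60 % acceptance band
during burn-in (default 10 % of the retained samples), then frozen so
the chain stays reversible. Per-window seeds derive deterministically
from the master seed (two Lehmer steps, documented in `derive_seed()`),
so datasets replay identically, including on disk.

## WHAM

`wham()` histograms every window on a common grid and solves the
standard self-consistent equations

$$p_b = \frac{N_b}{\sum_i n_i e^{(f_i - U_i(b))/k_BT}},\qquad
  e^{-f_i/k_BT} = \sum_b p_b\, e^{-U_i(b)/k_BT},$$

reporting offsets relative to $f_1 = 0$, masking zero-count bins
(never pseudo-counting), and min-referencing the surface. Numerically,
the fixed point is first located by minimising the convex WHAM
likelihood with BFGS and its analytic gradient, then polished by the
plain self-consistent iteration until the largest per-sweep offset
change is ≤ 10⁻⁷ kcal mol⁻¹ (well below the 0.1 kcal mol⁻¹ scale of any
conclusion drawn here); if `max_iter` sweeps do not reach the tolerance
the result is flagged, never silently accepted.

Two numerical choices matter in practice:

* **Bin width.** WHAM evaluates each window's bias at bin centres. With
  k = 100 kcal mol⁻¹ Å⁻² the bias changes by up to ~1 kcal mol⁻¹ across
  a bin half a window-spacing wide, which left a ≈ −0.3 kcal mol⁻¹
  systematic on the recovered reaction free energy. The default grid is
  therefore the window grid refined **4×** per axis (extended one
  spacing beyond the outermost centres); `refine` and explicit `bins`
  remain configurable.
* **Uncertainty.** Statistical errors come from a Bayesian bootstrap
  with Dirichlet weights drawn per **block** of 50 consecutive samples
  (50 resamples). Per-sample weights underestimate the error of
  correlated Metropolis output several-fold; block weighting restores
  coverage. Time-block mean ± SD summaries in the convention of
  umbrella-sampling convergence reporting are available through
  `convergence_blocks()`.

Diagnostics mirror common umbrella-sampling practice: per-window
Shapiro–Wilk normality of the restrained coordinate (`normality_report()`;
windows larger than 5000 samples are tested on a fixed-seed subsample
because the statistic is undefined above that size) and pairwise
histogram-overlap coefficients with flags on weakly-overlapping adjacent
windows (`window_overlap()`).

## Basins, paths, barriers

`find_minima()` assigns every unmasked cell to a basin by
steepest-descent pointers under 8-connectivity (ties to the
lexicographically smallest index; equal-energy sink plateaus are merged
and flagged degenerate). `minimax_path()` finds the grid path that
minimises the maximum free energy — the discrete minimum free-energy
path whose highest cell is the transition state — by Dijkstra with the
lexicographic key (path max, path total, cell index). The tie-break
uses the path *total* above the grid minimum rather than the mean: the
total is monotone under path extension, so the label-setting argument
goes through, and it is verified against exhaustive enumeration on
small grids. `activation_reaction_energies()` then reads
ΔA_act = A(TS) − A(reactant minimum) and ΔA_reac = A(product minimum)
− A(reactant minimum).

## Conformational analysis of unbiased trajectories

Unbiased MD is emulated by a hidden two-state Markov chain with
Gaussian emissions: state *a* reactive (S–Cβ ≈ 3.5 ± 0.4 Å, dihedral
≈ −55° ± 20°), state *b* non-reactive (≈ 5.5 ± 0.5 Å, ≈ +110° ± 7°,
short Gln-side-chain hydrogen bond). Defaults are 4 replicas × 30 000
snapshots (pooled 120 000) with symmetric switch probabilities 0.002
per step, giving equally populated states and a handful of transitions
per replica — enough hops to estimate occupancies but visibly
metastable, as in the trajectories this emulates. The generator keeps
the hidden state as a ground-truth column, so occupancy, transition and
coupling estimators are tested against closed forms, not against other
estimates.

`boltzmann_fes()` inverts pooled (distance, dihedral) histograms with
A = −k_BT ln P. The conventional dihedral span −160°…+160° at 15° class
width is not an integer number of classes; the default keeps the stated
width using 21 bins centred on multiples of 15° (spanning −157.5° to
+157.5°, outside records counted out-of-range), with an exact-span
alternative behind `dihedral_mode = "exact"`. Reactive fractions use a
strict `<` at 3.9 Å (the AMBER99SB S⋯C van-der-Waals contact distance,
taken as a configuration constant); hydrogen-bond occupancy uses an
inclusive `≤` at 3.5 Å heavy-atom distance. "Highly correlated"
distance–dihedral coupling is quantified as the point-biserial
correlation between the distance and the binary dihedral state, with a
1000-shuffle permutation p-value under a fixed seed, plus the fraction
of state switches at which the distance crosses the 4.5 Å midline
within a ±5-record window. The boundary of the reactive region *a\**
of a mutant-like surface is not inferred — it is supplied by the user
as a `state_definition()`.

## Thermodynamic integration and replicate aggregation

`ti_integrate()` averages each λ-window's free-energy gradient after
discarding a burn-in fraction (default 1/3, e.g. 10 of 30 million Monte
Carlo moves) and applies the trapezoidal rule on the sampled range —
no extrapolation beyond [λ₁, λₙ] unless requested, in which case
end-point gradients are extended as constants. The canonical 16-window
schedule 0.005, 0.071, …, 0.995 ships as `lambda_schedule_16()`.
`aggregate_replicates()` provides the mean ± SD/SEM conventions used
for replicate binding free energies and per-snapshot pKa shifts.

## Geometry

PDB snapshots are parsed by fixed-column rules (insertion codes kept,
first model only, malformed coordinates reported with their line
number) and descriptors — distances, IUPAC-signed dihedrals in
(−180°, 180°] with the boundary mapped to +180°, and
difference-of-distances proton-transfer coordinates — are evaluated
over atom selectors of the form `"chain.resno.name"`. The dihedral is
verified against an independent torsion implementation and against
rigid-motion/reflection invariances at 10⁻⁹ Å / 10⁻⁶ ° tolerance. Toy
fixtures from `make_toy_snapshots()` use 40 Å arms so that 3-decimal
PDB coordinate precision keeps descriptor round-trips within 10⁻³.

## Study conditions, problem sizes, and what the tests show

The generator defaults *are* the study conditions: the 19 × 26 window
grid (x 3.6 → 1.8 Å step 0.1; y 2.8 → −2.2 step 0.2) with
k = 100 kcal mol⁻¹ Å⁻², 50 ps per window (24.7 ns total in the plan
summary), the 21-window 1D ladder 1 → −1 Å, 4 × 30 000 pooled
snapshots, the 3.9 Å reactive cutoff, and the 16-λ schedule. One stated
ladder is internally inconsistent — a 2.8 → −2.0 span at step 0.2
yields 25 centres, while the printed counts are 26 per column and 494
total — and the printed counts win: the default ladder ends at −2.2.

Calibrated-recovery tests run the full pipeline at 2 000 samples per
window over 5 seeds (≈ 10⁶ Metropolis samples per seed) against
quadrature/dense-grid ground truth of 7.8 / −10.3 kcal mol⁻¹, and the
1D oracle tests at 5 × 10⁴ samples per window; these sizes keep the
whole suite in the minutes range while leaving the statistical error of
the mean recovery a few times smaller than the 0.2 kcal mol⁻¹
acceptance band. What passing shows is that the estimators are correct
and well-calibrated *on data satisfying their assumptions* —
uncorrelated-replica Markov emissions, Gaussian window fluctuations, a
smooth two-well landscape. It does not show that 50 ps QM/MM windows
are converged for a real kinase, that real warhead dynamics are
two-state, or that the real landscape has no intermediate basin; those
are properties of the data, not of the estimators.

## Known limitations

* The minimax path is the lowest-saddle grid path, which is exactly
  what ΔA_act needs; it is not a steepest-descent or string-method
  path, and its geometry away from the saddle should not be
  over-interpreted.
* WHAM here is histogram-based; a binless estimator would avoid the
  bin-centre bias entirely at higher cost. The 4× refined default keeps
  that bias below ~0.05 kcal mol⁻¹ for k = 100.
* `run_pipeline()` orchestrates simulate → WHAM → analyse → conformational
  stages from one validated config with per-stage derived seeds; it is
  an R-level interface (no shell executable ships with the package).
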