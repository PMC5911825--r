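# covfes

Free-energy analysis for covalent-inhibition simulation protocols:
umbrella sampling + WHAM free-energy surfaces, reaction-path barriers,
and conformational statistics of warhead geometries.

## The problem

Covalent kinase inhibitors (e.g. third-generation EGFR inhibitors)
carry an acrylamide warhead that alkylates an active-site cysteine by
Michael addition. Explaining why a binding-site mutation defeats such
an inhibitor requires several free-energy quantities:

* the free-energy difference between nucleophile ionization states
  along a proton-transfer coordinate (1D umbrella sampling + WHAM);
* the activation and reaction free energies of the alkylation step on a
  2D surface spanned by the nucleophilic-attack distance
  (S–Cβ) and a proton-transfer difference-of-distances coordinate
  (2D umbrella sampling + WHAM + minimum free-energy path), with
  A = −k_BT ln P and the barrier read at the lowest saddle:
  ΔA_act = A(TS) − A(R), ΔA_reac = A(P) − A(R);
* the conformational preference of the warhead in the non-covalent
  complex: Boltzmann-inversion surfaces over (S–Cβ distance,
  amide-phenyl dihedral), basin free-energy gaps
  ΔA(a→b) = −k_BT ln(P_b/P_a), and the fraction of *reactive*
  conformations with S–Cβ < 3.9 Å (van-der-Waals contact);
* binding free energies by thermodynamic integration over a λ schedule
  (trapezoidal quadrature of mean gradients) with replicate mean ± SEM.

`covfes` implements all of these as composable, tibble-first R
functions, plus synthetic generators — an analytic two-well reaction
surface sampled by Metropolis Monte Carlo and a hidden two-state Markov
trajectory model — that stand in for the QM/MM and MD engines and carry
quadrature-verified ground truth, so every estimator in the pipeline is
testable against an exact reference. It is aimed at computational
chemists prototyping or validating free-energy workflows for covalent
inhibitors.

## Worked example

Calibrate a reaction surface whose exact barrier is 7.8 kcal/mol and
reaction free energy −10.3 kcal/mol, run the 19 × 26-window umbrella
grid (k = 100 kcal mol⁻¹ Å⁻², 2000 samples/window), and recover the
energetics by WHAM + minimax path:

```r
library(covfes)

surface <- make_reaction_surface(7.8, -10.3)
attr(surface, "ground_truth")
#> # A tibble: 1 × 2
#>   delta_A barrier
#>     <dbl>   <dbl>
#> 1   -10.3    7.80

windows <- generate_us_dataset(surface,
                               grid_spec(3.6, 1.8, -0.1),   # 19 windows
                               grid_spec(2.8, -2.2, -0.2),  # 26 windows
                               k = 100, n_per_window = 2000, seed = 1)
solution <- wham(windows)
minima   <- find_minima(solution$fes)
# reactant basin = minimum nearest (3.4, 2.0); product nearest (1.9, -1.5)
from <- minima$basin[which.min((minima$center_x - 3.4)^2 + (minima$center_y - 2.0)^2)]
to   <- minima$basin[which.min((minima$center_x - 1.9)^2 + (minima$center_y + 1.5)^2)]
path <- minimax_path(solution$fes, from, to, minima = minima)
activation_reaction_energies(path)
#> # A tibble: 1 × 5
#>   delta_A_act delta_A_reac  A_ts ts_position path_length
#>         <dbl>        <dbl> <dbl>       <int>       <int>
#> 1        7.72        -10.4  18.1          20          73
```

The recovered ΔA_act ≈ 7.7 and ΔA_reac ≈ −10.4 kcal/mol agree with the
surface's quadrature ground truth to well within the ±0.2 kcal/mol
band expected at this sampling size. `autoplot(solution$fes)` draws the
surface; `autoplot(path)` the path profile with its transition state.

Conformational statistics from a two-state trajectory:

```r
traj <- make_two_state_trajectory(two_state_model(), seed = 1)
reactive_fraction(traj, cutoff = 3.9)
#> <reactive_stats> cutoff 3.90 A: 52002 / 120000 snapshots (43.34%)
basin_delta(assign_states(traj))   # -kT ln(P_b / P_a), kcal/mol
#> [1] -0.06482894
```

See the methods vignette (`vignettes/free-energy-protocol.Rmd`) for the
model, numerical choices, and the limits of what the synthetic
generators emulate.

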