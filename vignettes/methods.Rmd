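---
title: "Methods: constant-pH Monte Carlo titration under transmembrane pH gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constant-pH Monte Carlo titration under transmembrane pH gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model, the algorithmic conventions, and the
design decisions behind `memtitra`. It is the reference for *why* the code
does what it does; the function documentation covers *what* each piece
does.

## The semi-grand canonical protonation ensemble

A titratable system is a set of sites, each with a discrete list of
tautomers. Tautomer $\tau_i$ of site $i$ carries an intrinsic free energy
$g_i(\tau_i)$ and a bound-proton count $n_i(\tau_i)$. All free energies in
the package are expressed in pK units (factors of $k_B T \ln 10$), so that
Boltzmann weights are powers of ten and pH enters linearly. The
semi-grand-canonical free energy of a microstate
$x = (\tau_1, \dots, \tau_M)$ is

$$
G(x) = \sum_i \left[ g_i(\tau_i) + n_i(\tau_i)\, \mathrm{pH}_{b(i)} \right]
     + \sum_{i<j} W_{ij}(\tau_i, \tau_j),
$$

with statistical weight $10^{-G(x)}$. The $n\,\mathrm{pH}$ term is the
chemical-potential cost of taking protons from the bath: binding becomes
unfavourable as the bath pH rises. For a single site with one protonated
and one deprotonated form this reduces exactly to Henderson–Hasselbalch,
$\langle \mathrm{prot} \rangle = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_{\mathrm{int}}})$
with $\mathrm{p}K_{\mathrm{int}} = g(\mathrm{deprot}) - g(\mathrm{prot})$;
the unit tests pin this closed form and several others.

### Proton baths and the gradient convention

Under a transmembrane pH gradient each site exchanges protons with exactly
one bath, interior (`in`) or exterior (`out`), with its own pH. The
package's sign convention is

$$ \Delta \mathrm{pH} := \mathrm{pH_{in}} - \mathrm{pH_{out}}, $$

and `gradient_endpoints(pH, delta_pH)` places the endpoints symmetrically
at $\mathrm{pH} \pm \Delta\mathrm{pH}/2$ with the $+$ toward the interior.
Bath membership defaults to the side of the membrane center the site's
reference `start_z` lies on (above the center is `out`); an explicit
`bath_override` always wins, and a site exactly at the center goes to
`out` with a warning rather than silently. These rules are deliberately
boring: bath assignment is a modelling decision and must never be decided
by floating-point noise without telling the user.

A structural invariant follows from the energy function: when
$\mathrm{pH_{in}} = \mathrm{pH_{out}}$ the bath labels are irrelevant, and
the package guarantees this *bitwise* — a zero-offset gradient run
consumes the identical random stream and produces identical output to a
single-bath run. The test suite enforces this reduction for the plain
sampler and for the replica-exchange driver.

## Monte Carlo sampling

`mc_titrate()` runs a Metropolis chain in the tautomer state space. Each
cycle performs one shuffled sweep of single-site moves (a uniformly drawn
alternative tautomer, accepted with probability $\min(1, 10^{-\Delta G})$)
followed by one sweep of coupled-pair moves, in which both tautomers of a
strongly coupled pair are re-drawn jointly. A pair counts as strongly
coupled when $\max |W_{ij}| > 2$ pK units — beyond that, single-site moves
alone can effectively freeze into one branch of the coupled landscape, and
the joint move restores mixing. The threshold is strict (`> 2`, not
`>= 2`).

The kernel is implemented in C++ (via Rcpp) but draws every random number
from R's own generator, so `set.seed()` governs the entire computation and
results are exactly reproducible across the R/C++ boundary. Uncertainties
are batch-means standard errors over 20 contiguous batches. For small
systems `enumerate_exact()` sums the ensemble exactly (up to $10^6$
microstates) and serves as the oracle throughout the test suite.

One sampling curiosity is worth recording: for an isolated site at
$\mathrm{pH} = \mathrm{p}K$, $\Delta G = 0$, every flip is accepted and
the chain alternates deterministically. The marginal is still exactly
correct (0.5), but the batch variance collapses to zero; tests that
compare against standard errors therefore floor the SE.

## pH replica exchange

`run_phre()` runs one replica per ladder pH. Each cycle advances every
replica (a few titration sweeps, then conformational propagation) and then
attempts exchanges between adjacent ladder neighbours, alternating
even/odd pairings cycle by cycle. A swap exchanges the pH labels and is
accepted with

$$ p = \min\!\left(1,\; 10^{(\mathrm{pH}_m - \mathrm{pH}_l)(N_i - N_j)} \right), $$

where $N$ counts the bound protons *of the sites whose bath pH depends on
the replica's ladder label*. That qualifier is the package's central
design rule, and it unifies the two gradient parameterizations:

* **Fixed interior** (`ph_in = 7.2`): the interior pH is the same in every
  replica and only the exterior pH exchanges, so in-bath protons
  contribute identical factors to both sides of the swap and cancel; $N$
  counts out-bath protons only.
* **Fixed offset** (`delta_ph`): both endpoint pH values shift with the
  ladder label, so every site's bath pH is label-dependent and $N$ counts
  all protons. Setting `delta_ph = 0` then makes the gradient run
  *bitwise* identical to a non-gradient run — the reduction invariant
  above — which would be violated if out-bath-only counting were applied
  unconditionally.

The driver takes a `propagator` object (`advance`, `summarize`, `init`)
for the conformational degrees of freedom, so molecular-dynamics
propagation, a surrogate Langevin walker, or a frozen conformation all
plug into the same exchange logic. Records keep the first half of each run
as burn-in by default.

## The analytic surrogate

Real constant-pH molecular dynamics is far outside an R package's scope,
so validation uses a surrogate with a closed-form answer. A single site
moves on a 1-D insertion coordinate $z$ with a harmonic background
potential and a depth-dependent intrinsic pK,

$$ \mathrm{p}K_{\mathrm{int}}(z) = \mathrm{p}K_{\mathrm{mod}} +
   \Delta\mathrm{p}K_{\mathrm{desolv}} \cdot
   \sigma\!\left((z_{\mathrm{mid}} - z)/z_{\mathrm{width}}\right), $$

a logistic switch from the solution value (default 5.5) to a
desolvation-shifted value (+2 pK) as the site buries below
$z_{\mathrm{mid}} = -3$ Å. The propagator is a Metropolis walker in $z$
whose stationary density factorizes against the protonation ensemble, so
`analytic_pka_profile()` is the exact ground truth for the full pipeline:
replica exchange → insertion series → binned Hill fits must reproduce the
logistic curve within tolerance, bin by bin. The defaults (harmonic well
at $z_0 = -2$, $k = 0.05$) were chosen so the walker straddles the
logistic switch and populates several bins on both sides of it.

## Membrane geometry

Insertion depth is measured against the *local* phosphate surface, not the
global average: the surface height at the probe's $(x, y)$ is the mean $z$
of phosphate-group atoms of the relevant monolayer within a 6 Å lateral
radius (periodic minimum-image in $x$ and $y$), falling back to the 10
nearest atoms when the annulus is sparse. Insertion is signed so that
negative means toward the membrane interior, in both monolayers.
Monolayer membership is assigned once from the first frame and held fixed,
so atoms near the midplane cannot flip leaflets frame to frame and corrupt
the thickness profile.

Membrane deformation is profiled as annulus half-thickness: per monolayer,
the mean $|z - z_{\mathrm{center}}|$ of phosphate atoms in 1 Å radial bins
around the peptide, with SEMs across frames (or replicate means).
Deformation subtracts the bulk value measured beyond a 15 Å radius. The
synthetic frame generator plants a Gaussian dimple of known amplitude, and
the tests require the profile machinery to recover it bin by bin.

## Profiles, criteria, and error bars

Observations (one row per frame: replicate, pH, insertion, protonation)
are binned into half-open 1 Å insertion windows after discarding the first
half of each (replicate, pH) stream. Three acceptance criteria gate the
fits:

1. every (bin, pH, replicate) cell must hold at least 10 protonated *and*
   10 deprotonated conformations;
2. at least 3 replicates must survive at a pH for that pH to count, and at
   least 2 surviving pH values are needed for a fit;
3. the pooled average protonation must not rise by more than 0.05 between
   consecutive surviving pH values (titration must go the right way).

Protonation profiles require only criteria 1–2; pKa fits require all
three. The boundaries are sharp (9 vs 10 conformations, 2 vs 3 replicates,
a 0.06 vs 0.04 rise) and tested exactly.

Per valid bin, the Hill equation
$\langle \mathrm{prot} \rangle = 1/(1 + 10^{\,n(\mathrm{pH} - \mathrm{p}K_a)})$
is fitted by weighted least squares with the Hill coefficient constrained
to $(0, 10]$, starting from the closed-form logit-linear solution and
refined with analytic gradients. Errors come from a Bayesian bootstrap:
each of $B$ passes draws flat-Dirichlet weights over the per-replicate
samples at each pH, recomputes the weighted averages, re-checks the
monotonicity criterion, and refits; the reported pKa and error are the
mean and standard deviation over passing passes. If more than half the
passes fail, the bin is declared unreliable and the computation stops with
an error instead of reporting a number. Bootstrap calibration (error vs
empirical scatter, two-sigma coverage) is validated on synthetic redraws
in the acceptance tests; with very few replicates any resampling scheme
understates the error, so calibration checks use 16 replicates.

## Scope and limitations

The package computes protonation thermodynamics for *given* energy terms;
it does not compute the electrostatic terms themselves (a Poisson–
Boltzmann solver's job) and does not propagate real molecular dynamics.
The surrogate validates the statistical machinery, not force-field
physics. Exchange statistics assume adjacent-neighbour swaps on a fixed
ladder; ladder spacing is the user's responsibility, and the exchange log
is exposed so acceptance rates can be checked. Coordinate handling
supports orthorhombic boxes with periodicity applied laterally ($x$, $y$)
only, which matches the planar-membrane geometry the analyses assume.
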