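---
title: "Methods: electron-transfer analysis for multi-domain P450s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electron-transfer analysis for multi-domain P450s}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etkit)
```

# Scope and scientific background

Self-sufficient cytochrome P450s fuse the heme monooxygenase domain with its
redox partner domains (an FMN-binding reductase and a [2Fe-2S] ferredoxin) in
one polypeptide. Their catalytic throughput is limited by intramolecular
electron transfer (ET): electrons must hop from FMN to the iron-sulfur
cluster and on to the heme iron, and the ferredoxin domain must swing from a
*distal* orientation (d[FeS-Heme] > 22 Å) to a *proximal* one
(< 20 Å) for the final transfer to be fast. `etkit` implements the
desk-scale computational layer of this analysis:

* a tunneling-graph model of ET routes and the exponential distance-decay
  rate law,
* MBAR estimation of umbrella-sampling free-energy profiles, projected onto
  arbitrary collective variables including the first principal component
  (PC1) of backbone dihedrals,
* per-frame ensemble observables (cofactor distances, Fe=O···substrate
  attack geometry, near-attack-conformation fractions, hydrogen-bond
  occupancy, RMSD, interdomain nonbonded energies),
* assay-derived efficiency statistics (conversion, total turnover number,
  coupling efficiency, Michaelis–Menten kinetics, Pearson correlation),
* synthetic-data generators that produce every input with exact ground
  truth.

Structure prediction, docking, force-field parametrization, and production
molecular dynamics are out of scope: the package analyses structures,
trajectories and sample tables, it does not create them. Where real
simulation data are unavailable, the synthetic module stands in with planted
truths, so what the test suite demonstrates is the correctness of the
*machinery*, not a reproduction of any particular protein's landscape.

# The tunneling-pathway model

ET routes are scored with the empirical Pathways decay model. Each step
between heavy atoms carries a multiplicative decay factor:

* covalent step: constant $\epsilon_C = 0.6$;
* hydrogen-bond step: $0.36\,e^{-1.7\,(d - 2.8)}$ with $d$ the
  donor–acceptor distance in Å;
* through-space jump: $0.6\,e^{-1.7\,(d - 1.4)}$.

Exponential decays are clamped to at most the covalent decay, and
through-space edges are only generated within 6.0 Å — beyond that a jump
decays below $2.4\times10^{-4}$ of a covalent step and can never compete
with a bonded detour. All eight constants are user-overridable through
`tunneling_params()`.

`best_pathway()` maximizes the product of step decays, equivalently a
shortest path under edge weights $-\log(\text{decay})$, via Dijkstra search
from the donor set. Ties in total coupling are broken by smaller total
length, then by lexicographic node sequence, so repeated runs are
bit-identical. The graph is atom-level; the reported `residue_trace`
collapses consecutive same-residue nodes because ET routes are conventionally
narrated at residue granularity, and `path_length(level = "residue")` sums
only the steps that cross residue boundaries. Donors and acceptors are
normally anchored at the metal atoms (the FES irons and the heme iron).
`exhaustive_pathway()` enumerates every simple path with identical
tie-breaking and serves as the independent oracle in the tests (graphs of
up to 12 nodes).

The ET rate uses the exponential distance-decay law
$k_{ET} = A_0\,e^{-\beta R}$ with the empirical biological-tunneling
calibration $A_0 = 2\times10^{12}\,\mathrm{s}^{-1}$ and
$\beta = 1.06\,\text{Å}^{-1}$ (`et_rate_params()`), where $R$ is the sum of
step distances along the best route:

```{r ket}
signif(compute_ket(c(32.36, 28.31)), 3)
```

A 4.05 Å shortening multiplies the rate by $e^{1.06 \times 4.05} \approx 73$.

# Structures, bonds, selections

PDB input is the fixed-column v3.3 dialect (parsed through `bio3d`), with
`MODEL`/`ENDMDL` delimiting trajectory frames; multi-frame XYZ is also
accepted. Alternate locations other than `' '`/`'A'` are skipped; insertion
codes are rejected loudly rather than silently renumbered. Residue ids keep
the author numbering because route descriptions cite author residue numbers.
Atom indices are 1-based throughout, the natural R convention.

Covalent bonds are inferred from consensus single-bond covalent radii
(H 0.31, C 0.76, N 0.71, O 0.66, S 1.05, Fe 1.32 Å, ...) with a 0.4 Å
tolerance; a hydrogen keeps only its nearest heavy-atom partner. Hydrogen
bonds use the common trajectory-analysis criterion of donor–acceptor
distance ≤ 3.5 Å and donor–H–acceptor angle ≥ 135°; both knobs sit in
`hbond_criterion()`.

`min_distance()` exposes three conventions, because published inter-cofactor
distances rarely state theirs: minimum heavy-atom pair, center of geometry,
and the iron–iron convention (`"fe-fe"`) that defines d[FeS–Heme] — the
FES iron minimizing the distance to the heme iron. No default claim is made
that any one convention reproduces a particular printed d[FMN–FeS] value.

# Umbrella sampling and MBAR

Windows carry a harmonic bias; the convention default is
$U_k(\xi) = k(\xi - \xi_0)^2$ (`k_full`, no ½), the convention under which a
stated force constant of 100 kcal mol⁻¹ Å⁻² is meaningful for the MD engine
family that produces such data; `k_half` is a switch away. Temperature
defaults to 300 K with $k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹.

`solve_mbar()` estimates the relative free energies $f_k$ of the biased
ensembles from the self-consistent MBAR identities

$$ e^{-\beta f_k} = \sum_n \frac{e^{-\beta U_k(x_n)}}
   {\sum_j N_j\, e^{-\beta (U_j(x_n) - f_j)}} , \qquad f_1 \equiv 0 . $$

Numerically the solver first minimizes the equivalent convex objective by
BFGS with an analytic gradient, then polishes by direct self-consistent
iteration (all in log-sum-exp arithmetic) until $\max_k |\Delta f_k| \le
10^{-8}$ kcal/mol, so the returned values satisfy the identities to the
stated tolerance rather than merely an optimizer's stopping rule. Unbiased
sample weights are $w_n \propto 1/\sum_j N_j e^{\beta f_j - \beta U_j(x_n)}$,
normalized to 1.

Burn-in (`apply_burn_in()`, default fraction 0.15, mirroring protocols that
keep the last 85 of 100 ns per window) is the only sample pruning applied by
default; statistical-inefficiency subsampling is deliberately not applied,
matching protocols that only discard equilibration. The projection
(`project_pmf()`) histograms the weighted samples — 50 equal-width bins over
the weighted 0.5–99.5 percentile range by default — and reports
$F(s) = -k_BT\ln P(s)$ min-shifted to zero, with empty bins masked as `NA`
and a width warning if everything lands in one bin.

Because d[FeS–Heme] can be a poor coordinate for a transition that involves
many degrees of freedom, the PMF can be re-projected on PC1 of the backbone
dihedrals: each dihedral is embedded as $(\cos\varphi, \sin\varphi)$ to
remove the $2\pi$ discontinuity, the embedded covariance is
eigendecomposed, and each component's sign is fixed so its
largest-magnitude loading is positive — the sign is physically arbitrary, so
it is pinned for reproducibility. Any dihedral selection may be supplied;
nothing restricts the analysis to a particular region.

`extract_barrier()` reads the transition barrier as the maximum of $F$ over
the span between the two basin minima minus the starting-basin minimum, and
`classify_conformation()` applies the 20/22 Å distal/proximal thresholds
with an explicit intermediate band.

# Ensemble observables

All summary spreads are population (divisor $n$) standard deviations, to
match "mean ± sd over frames" reporting. The attack angle is measured with
its vertex at the oxo oxygen (Fe–O···C), the convention of the near-attack
conformation literature, under which the favorable hydroxylation angle is
around 130°; the reactive-distance threshold defaults to 4 Å. The
d[Fe=O–H] distance is measured to the abstractable hydrogen when hydrogens
are present (MD models carry hydrogens; for hydrogen-free structures,
measure to the carbon and remember the ~1.09 Å C–H offset).

Interdomain nonbonded energies use plain pairwise Coulomb
($C = 332.0636$ kcal Å mol⁻¹ e⁻², dielectric 1) and 12-6 Lennard-Jones
terms with Lorentz–Berthelot combining, hard-truncated at a generous 99 Å
cutoff so long-range electrostatics are effectively complete; there is no
Ewald/PME and no solvation term, so these are gas-phase interaction
energies of the supplied point charges. Parameters come from a simple
per-atom CSV table — no force-field file parsing. RMSD uses Kabsch
superposition with the proper-rotation determinant guard.

# Assay statistics

The efficiency formulas are direct: conversion $= 100\,M_p/(M_p+M_s)$;
TTN $=$ product/enzyme (with the mM/µM factor); coupling $= 100 \times$
product/NADH consumed. Michaelis–Menten fitting is unweighted nonlinear
least squares (optional $1/v^2$ weighting) on log-parameterized
$(K_m, V_\mathrm{max})$, so neither parameter can escape to non-positive
values; initialization is $V^0 = \max(v)$, $K^0 = \mathrm{median}(S)$.
Saturated or purely linear designs drive $K_m$ into a flat valley below or
above the sampled range; the fit then reports a `boundary` flag instead of
pretending to a meaningful estimate. Catalytic efficiency is always computed
from the fitted values, never back-filled from rounded printed pairs.
Velocities are interpreted as turnovers (s⁻¹) by default since kcat is the
conventionally reported quantity; concentration rates are normalized when an
enzyme concentration is given. Pearson correlation reports the two-sided
p-value from the $t = r\sqrt{n-2}/\sqrt{1-r^2}$ statistic on $n-2$ degrees
of freedom; no multiple-testing correction is applied (single planned
comparisons, $\alpha = 0.05$).

# Synthetic data: what it emulates and what it does not

The generators produce inputs whose ground truth is known exactly:

* `sample_umbrella_windows()` draws Metropolis samples of
  $e^{-\beta(U + U_\mathrm{bias})}$ for analytic potentials. Metropolis (not
  Brownian dynamics) was chosen because it targets the exact distribution at
  any step size; the step is auto-tuned toward ~40% acceptance during
  burn-in and then frozen, and the acceptance rate is recorded with a
  warning flag outside [0.1, 0.9]. The default study design is the
  double-well $U = a(x^2-b^2)^2$ with $a = 1.5$, $b = 1$ — an exact
  $ab^4 = 1.5$ kcal/mol barrier, the shallowest (hardest-to-resolve) regime
  of interest; stiffer presets ($a = 6$, $17.5$) mirror the slower-switching
  regimes — sampled by 46 windows across $[-1.5, 1.5]$ with
  $k = 10$ kcal mol⁻¹ (chosen once so adjacent biased distributions overlap
  strongly), 5000 production samples per window.
* `make_planted_trajectory()` embeds drawn distance/angle/H-bond values
  *exactly* into coordinates of a minimal 7-atom system, rather than
  re-measuring noisy embeddings, so estimator tests are sharp: the measured
  series literally equal the draws. Default laws mirror a wild-type
  reactive-geometry ensemble (d ~ N(4.63, 1.01) Å, θ ~ N(157.3, 9.2)°,
  H-bond in 37.28% of frames, planted exactly).
* `make_toy_graph()` builds small random geometric graphs together with the
  exhaustively enumerated optimum; `make_two_domain_structure()` builds a
  ~54-atom fixture (FES cluster, heme iron, a covalent chain broken by one
  3.5 Å space jump, a planted hydrogen bond, a decorative helix kept > 6 Å
  away) whose best route and total length (13.75 Å) are known by
  construction.

What passing these tests shows: the estimators are unbiased on data whose
generating process is known, the solvers hit their stated tolerances, and
the graph search is exactly optimal. What they cannot show: force-field
accuracy, sampling convergence of real MD, or that any particular enzyme's
barrier/occupancy equals the synthetic values — real trajectories have
correlated, multi-modal noise these generators intentionally do not imitate.

# Numerical choices and problem sizes

* MBAR tolerance $10^{-8}$ kcal/mol on $\max|\Delta f|$; iteration cap
  $10^5$; non-convergence is flagged, never silent.
* Metropolis autocorrelation inflates statistical error relative to i.i.d.
  sampling by roughly $\sqrt{2\tau}$; tests therefore use batch-means
  standard errors or tolerances derived from a correlation time of tens of
  steps, not naive $\sigma/\sqrt{n}$.
* Floating-point ties in pathway search are resolved with a $10^{-9}$
  relative tolerance before the deterministic tie-break cascade.
* The suite sizes its simulations for a laptop-class single core: the
  largest run is the 46-window × 5000-sample double-well validation
  (~2–4 min); everything else is seconds.
* Degenerate inputs fail loudly by policy: empty selections, overlapping
  basins, zero-variance PCA input, windows emptied by burn-in, unknown
  elements, and non-disjoint atom sets are all errors, not warnings.

# Known limitations

* No mmCIF input, no hydrogen placement, no periodic-boundary imaging:
  trajectories are assumed imaged and hydrogen-complete where H-bond
  analysis is requested.
* Single-pathway coupling only — no multi-path interference, no full Marcus
  reorganization-energy treatment, no flavin redox-state modelling.
* 1-D PMFs only; no bootstrap error bars yet; no replica-exchange
  reweighting.
* Nonbonded energies are bare Coulomb + LJ with hard truncation; they are
  comparative statistics, not absolute binding energies.
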