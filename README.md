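# etkit — electron-transfer analysis for multi-domain P450s

Catalysis in self-sufficient cytochrome P450s (heme + FMN reductase +
[2Fe-2S] ferredoxin fused in one polypeptide) is throttled by intramolecular
electron transfer: the ferredoxin domain must swing from a *distal*
orientation (d[FeS–Heme] > 22 Å) to a *proximal* one (< 20 Å), and the
electron must then tunnel from the iron–sulfur cluster to the heme iron
along a chain of covalent, hydrogen-bond, and through-space steps. `etkit`
provides the desk-scale computational toolkit for quantifying each link in
that chain. It is aimed at enzyme engineers and computational biochemists
who already have structures, trajectories, umbrella-sampling tables, or
assay data, and want reproducible numbers out of them.

## What it computes

**Tunneling pathways and rates.** A tunneling graph over the heavy atoms
scores each step with the empirical Pathways decay model (covalent 0.6;
H-bond `0.36·exp(−1.7(d−2.8))`; through-space `0.6·exp(−1.7(d−1.4))`, all
overridable). `best_pathway()` finds the route maximizing the coupling
product (Dijkstra on `−log` decay, deterministic tie-breaks), and the ET
rate follows the distance-decay law

&nbsp;&nbsp;&nbsp;&nbsp;*k*<sub>ET</sub> = *A*₀ e<sup>−β R</sup>,&nbsp;&nbsp;
*A*₀ = 2×10¹² s⁻¹, β = 1.06 Å⁻¹,

with *R* the summed step distances of the best route.

**Umbrella-sampling free energies.** `solve_mbar()` implements the
multistate Bennett acceptance ratio (self-consistent reweighting with
log-sum-exp stabilization, tolerance 10⁻⁸ kcal/mol); `project_pmf()` turns
the unbiased weights into a free-energy profile *F*(s) = −k<sub>B</sub>T ln
P(s) over any collective variable, including PC1 of sin/cos-embedded
backbone dihedrals (`fit_dihedral_pca()`); `extract_barrier()` reads
transition barriers between basins.

**Ensemble observables.** Per-frame cofactor distances (min /
center-of-geometry / Fe–Fe conventions), Fe=O···substrate attack angles,
near-attack-conformation fractions, hydrogen-bond occupancy, Kabsch RMSD,
and interdomain electrostatic/van-der-Waals energy distributions.

**Assay statistics.** Conversion, total turnover number, coupling
efficiency, Michaelis–Menten fitting (log-parameterized nonlinear least
squares with degenerate-design flags), and Pearson correlation with
two-sided t significance.

**Synthetic data with exact truth.** Metropolis sampling of analytic
potentials (harmonic, double-well with exact barrier a·b⁴), toy tunneling
graphs with exhaustively enumerated optima, trajectories whose measured
series *equal* the planted draws, and a small two-domain structure fixture
with a known best route.

## Worked example

```r
library(etkit)

# a synthetic two-domain structure with a planted tunneling route
s <- make_two_domain_structure(seed = 1)
g <- build_tunneling_graph(s)
p <- best_pathway(g, attr(s, "truth")$donor, attr(s, "truth")$acceptor)
p
#> etk_pathway: 7 steps, total R = 13.75 A, coupling = 0.000788
#>   route: FES901 -> CYS347 -> LYS346 -> HEM902
#>   steps: covalent 6, space 1
compute_ket(p$total_R)        # 9.36e+05 /s
compute_ket(c(32.36, 28.31))  # 2.54e-03, 1.86e-01 /s

d <- min_distance(s, "group FES", "group HEME", mode = "fe-fe")
classify_conformation(d)      # "proximal" (13.75 A)

# umbrella sampling on a double well with a known 1.5 kcal/mol barrier
sp <- sampler_spec(centers = seq(-1.5, 1.5, length.out = 31),
                   n_samples = 2000, seed = 7)
mb <- solve_mbar(apply_burn_in(sample_umbrella_windows(sp), 0.15))
pr <- project_pmf(mb, cv_rc(), n_bins = 50)
extract_barrier(pr, c(-1.4, -0.6), c(0.6, 1.4))$barrier
#> 1.55   (planted: 1.5)

# efficiency metrics: TTN vs coupling efficiency across four enzymes
pearson_cor(c(25, 786, 1306, 2011), c(2.78, 23.19, 30.13, 38.03))
#> etk_cor: r = 0.9736, p = 0.02642 (two-sided, n = 4, df = 2)
```

Reading the output: the planted route runs from the FES iron through a
cysteine and a lysine into the heme, six covalent steps plus one 3.5 Å
through-space jump, total length 13.75 Å; at that distance the decay law
gives a fast ~10⁶ s⁻¹ rate, while at the 28–32 Å lengths typical of distal
interdomain arrangements the same law yields the 0.19–0.0025 s⁻¹ range —
which is why a few Å of pathway shortening matters. The MBAR profile
recovers the analytic double-well barrier to within sampling error, and the
strong TTN–coupling correlation (r = 0.97, p = 0.026) is the signature of
ET efficiency driving turnover.

## Layout

```
R/structure.R    PDB/XYZ I/O, bonds, selections, distances
R/selection.R    atom-selection mini-grammar
R/etnet.R        tunneling graph, best pathway, rate law
R/pmf.R          umbrella windows, MBAR, dihedral PCA, PMF, barriers
R/ensemble.R     per-frame geometry and nonbonded-energy series
R/assay.R        conversion, TTN, coupling, kinetics, correlation
R/synthetic.R    generators with exact ground truth
vignettes/       methods vignette (model, conventions, limitations)
```
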