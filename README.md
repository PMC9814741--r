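# defectometer

Data-driven detection of molecular motifs — ordered domains, stacking
defects, adsorbed monomers — in coarse-grained simulations of
self-assembled aggregates (supramolecular fibers, micelles, bilayers,
droplets), and quantitative classification of whole assemblies.

Defects in dynamical supramolecular structures cannot be defined by a
fixed geometric rule. `defectometer` instead describes the surroundings of
every monomer center with the SOAP (Smooth Overlap of Atomic Positions)
power spectrum — a rotation-, translation- and permutation-invariant
fingerprint of the local density,

$$\gamma_{nn'l} = \tfrac{1}{\sqrt{2l+1}}\textstyle\sum_{m=-l}^{l}
c^{*}_{nlm}\,c_{n'lm}, \qquad n' \ge n,$$

324-dimensional at the default `nmax = lmax = 8` — and lets an
unsupervised, density-based clustering (farthest-point-sampled grid,
anisotropic Gaussian KDE, quick-shift mode seeking, 73-fold bootstrap
stability, micro-to-macro dendrogram) decide which recurring environments
exist. Per-monomer state sequences then yield equilibrium populations and
transition matrices. Whole systems are compared through the metric
$d_\mathrm{SOAP} = \sqrt{2 - 2K}$ induced by the normalized linear kernel
$K$ on simulation-averaged fingerprints, with single-linkage
classification trees.

The package reads extended-XYZ and GRO trajectories (orthorhombic periodic
boxes, one SOAP center per monomer via bead-group centers of geometry) and
ships synthetic generators — 1-D stacks with planted defect/adsorbed
domains, gel/liquid planar lattices, micellar shells, filled droplets,
optionally driven by a planted Markov matrix — so the whole workflow is
testable against known ground truth without any external data.

## Worked example

A synthetic fiber of 200 monomers with 10 % planted stacking defects and
5 % adsorbed monomers; SOAP at 0.8 nm cutoff; PCA; clustering with
`K = 3`:

```r
library(defectometer)

fib <- gen_fiber(synthetic_spec("fiber", n_monomers = 200, n_frames = 60,
                                state_fractions = c(0.85, 0.10, 0.05),
                                seed = 7))
sr   <- soap_trajectory(fib$trajectory, soap_params(rcut = 0.8))
proj <- fit_projection(pool_balanced(list(sr$dataset), 5000, seed = 0), 3)
glance(proj)
#> # A tibble: 1 × 4
#>   n_components n_train cumulative_variance total_variance
#>          <int>   <int>               <dbl>          <dbl>
#> 1            3    5000               0.934           150.

fit <- pamm(proj$scores, n_grid = 300, K = 3, n_boot = 73, seed = 1)
fit
#> <pamm_fit> 5 microclusters -> 3 macroclusters (N = 5000, grid = 300)

macro <- fit$micro_to_macro[assign_microstates(project(proj, sr$dataset),
                                               fit$grid, fit$grid_labels)]
st <- state_trajectories(macro, M = 200, T = 60)
state_populations(st)
#> # A tibble: 3 × 2
#>   state population
#>   <int>      <dbl>
#> 1     1     0.0508
#> 2     2     0.103
#> 3     3     0.846

transition_matrix(st)
#> <transition_model> 3 states, lag = 1 frame(s) (1 ns)
#>       [,1]  [,2]  [,3]
#> [1,] 0.987 0.013 0.000
#> [2,] 0.007 0.949 0.044
#> [3,] 0.000 0.005 0.995
```

The three detected macrostates carry 84.6 %, 10.3 % and 5.1 % of the
monomer-frame observations — the planted 85/10/5 composition — and the
transition matrix shows the strong self-persistence planted in the static
labels (off-diagonal entries reflect monomers near state-domain
boundaries whose assignment flickers with the thermal jitter).

Multi-system comparison uses the same objects:

```r
dm   <- soap_distance_matrix(list(avgA, avgB, avgC))  # simulation averages
tree <- single_linkage(dm)
dendrogram_order(tree); rank_by_distance(dm, "A"); autoplot(proj)
```

`run_pipeline("cfg.yaml")` (or `inst/cli/defectometer.R run --config
cfg.yaml`) drives everything from one YAML file and writes plain-text
artifacts: spectra/scores/label CSVs, stability matrix, micro- and
system-level Newick trees, `d_SOAP` matrices, per-system transition JSON
and DOT interconversion diagrams, plus a manifest of every parameter and
seed.

See the methods vignette (`vignettes/defectometer-methods.Rmd`) for the
model, parameter meanings, numerical conventions and limitations.

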