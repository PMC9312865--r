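---
title: "Physics-guided binding free energy prediction: models and methods"
author: "PGBind authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided binding free energy prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PGBind)
```

## The problem

The binding free energy change $\Delta\Delta G$ of a receptor--ligand
association controls how strongly a small molecule binds its target, and
predicting it from structure is a central task of computational drug
discovery. Implicit-solvent MM/GBSA calculations are fast but carry errors
of several kcal/mol against experiment; purely data-driven graph networks
fit experimental affinities well but overfit easily on the small, noisy
datasets typical of the field and offer no physical interpretation. PGBind
implements a hybrid of the two: a generalized-Born energy engine supplies a
compact physics description of each complex, a graph convolutional network
supplies a learned structural summary, and the two are fused in a final
linear layer whose weights *are* the thermodynamic decomposition

$$\Delta\Delta G \;=\; \big[\Delta H_{\text{complex}} -
(\Delta H_{\text{receptor}} + \Delta H_{\text{ligand}})\big] - T\Delta S ,$$

so the trained model can be read back in physical terms.

## The physics engine

For each of the three structures of a complex (the bound complex, the
receptor alone, the ligand alone -- all in the bound conformation), the
engine computes five MM/GBSA energy terms, in kcal/mol:

* **EELEC** -- pairwise Coulomb energy $k_e q_i q_j / (\epsilon_{in}
  r_{ij})$ over atom pairs separated by more than three bonds (or
  unbonded), with $k_e = 332.0637$ kcal Å mol$^{-1}$ e$^{-2}$.
* **1-4-eel** -- the same Coulomb term restricted to pairs exactly three
  bonds apart, divided by 1.2 (the Amber 1--4 convention). Pairs one or two
  bonds apart are excluded entirely.
* **VDWAALS** -- a 12-6 Lennard-Jones sum
  $\epsilon[(r_{min}/r)^{12} - 2(r_{min}/r)^6]$ with Lorentz--Berthelot
  combining, the same exclusions, and 1--4 pairs divided by 2.0. No cutoff
  is applied: the structures this package targets (hosts under 100 atoms,
  single binding sites) make the full sum affordable and exact.
* **ESURF** -- nonpolar solvation, $\gamma \cdot \mathrm{SASA}$ with
  $\gamma = 0.0072$ kcal mol$^{-1}$ Å$^{-2}$ and zero offset. The
  solvent-accessible surface area uses Shrake--Rupley sphere sampling with
  a deterministic spherical Fibonacci point set (960 points per atom by
  default) and a 1.4 Å probe. The sampling directions are anchored in the
  molecule's principal-axes frame, which makes the sampled area exactly
  invariant under rigid motion whenever the principal axes are
  non-degenerate; for (near-)symmetric molecules whose in-plane axes are
  ill-conditioned, rotational invariance holds only to sampling
  resolution (about $10^{-4}$ relative at 960 points), which is an
  inherent property of any sampled surface area.
* **EGB** -- polar solvation in the ALPB (analytical linearized
  Poisson--Boltzmann) form
  $$\Delta G_{pol} \approx -\frac{1}{2}\Big(\frac{1}{\epsilon_{in}} -
  \frac{1}{\epsilon_{out}}\Big)\frac{1}{1+\beta\alpha}
  \sum_{ij} q_i q_j \Big[\frac{1}{f^{GB}_{ij}} +
  \frac{\alpha\beta}{A}\Big],$$
  with $\beta = \epsilon_{in}/\epsilon_{out}$, $\alpha = 0.571412$, the
  double sum running over ordered pairs including $i = j$ (self terms use
  $f = R_i$), and the canonical smoothing function
  $f^{GB}_{ij} = [r_{ij}^2 + R_i R_j \exp(-r_{ij}^2/4R_iR_j)]^{1/2}$.

Defaults are $\epsilon_{in} = 1$, $\epsilon_{out} = 78.5$, $T = 298.15$ K
(`gbParameters()`); all of them, the probe radius, $\gamma$, the 1--4
divisors and the Coulomb constant are configurable.

### Effective Born radii

The effective radius $R_i$ measures how deeply atom $i$ is buried in the
solute. PGBind uses the $r^{-6}$ volume-integral ("R6") definition,

$$R_i^{-3} = \rho_i^{-3} - \sum_{j \neq i}
\frac{3}{4\pi}\int_{V_j} \frac{dV}{|\mathbf r - \mathbf r_i|^6},$$

where $\rho_i$ is the intrinsic radius and the sum removes the descreening
contribution of each neighbor sphere. The integral has a closed form
obtained by decomposing neighbor $j$'s sphere into spherical shells
centered on atom $i$; when the neighbor sphere overlaps atom $i$'s own
intrinsic sphere, only the region outside $\rho_i$ is integrated (the
non-overlapping cap), and the fully-enclosed-shell regime that occurs when
the atom center lies inside a large neighbor is handled separately. This
analytic pairwise construction is validated in the test suite against
Monte-Carlo volume integration to within 1% on two- and three-atom
systems. It is a documented approximation to grid-based R6
implementations: pairwise descreening double-counts regions where
*neighbor* spheres overlap each other, so bit-agreement with grid codes is
not claimed, and each radii set carries the tag `R6-analytic-pairwise`.
Radii are clamped below at the intrinsic radius and the inverse cube is
floored so radii stay finite (30 Å ceiling) for pathologically buried
atoms.

### Electrostatic size

The ALPB correction needs the overall size $A$ of the molecule. PGBind
computes $A = \sqrt{5/3}\,R_g$ from the radius of gyration of the atom
centers, which is exact for a uniformly filled ball, with the intrinsic
radius as the single-atom fallback. This is a deliberate, documented
simplification of the full electrostatic-moment construction; for a single
ion it makes the ALPB self-energy reduce exactly to the classic Born
energy, which the tests exploit as a closed-form oracle.

### The entropy residual

No normal-mode or quasi-harmonic entropy is computed. Instead the entropic
component is treated as the residual between the computed enthalpy and the
experimental label: the stored feature is $T\Delta S = \Delta H -
\Delta\Delta G_{exp}$, so that the $-1$ weight the head places on it
reconstructs $\Delta\Delta G = \Delta H - T\Delta S$ exactly. (The two
natural sign conventions differ by which way the residual is taken; this
package fixes the one that makes the $-1$ initialization an identity.)
When no label is available the feature is 0 and a warning marks inference
mode.

### The 16-element physics vector

For each term in the fixed order (1-4-eel, VDWAALS, EELEC, ESURF, EGB) the
complex, receptor and ligand values, followed by the entropy residual:
$5 \times 3 + 1 = 16$ entries (`physicsFeatureNames()`). The
initialization pattern $(+1, -1, -1)$ per term, $-1$ for entropy
(`physicsInitPattern()`) makes the dot product with this vector equal
$\Delta\Delta G$ -- the central physics-consistency identity of the
package, asserted to $10^{-6}$ kcal/mol in the tests.

## The graph network

Each atom is encoded as a 75-wide feature row following the
Duvenaud/ConvMol convention: atom type (44 slots: 43 symbols + other),
degree 0--10 (11), implicit valence 0--6 (7), formal charge (1), radical
electrons (1), hybridization sp/sp²/sp³/sp³d/sp³d² (5), aromaticity (1),
total hydrogens 0--4 (5). For inputs without cheminformatic annotation
(bare PDB/PQR), hybridization and aromaticity are perceived from bond
counts and 5/6-ring detection by documented fallback rules, and formal
charges and radical electrons are 0.

Neighbor lists hold up to $k = 10$ atoms: bonded neighbors first, then the
nearest non-bonded atoms by 3D distance, ties broken toward the lower
index, sentinel-padded. Pure bond-graph and pure spatial modes are
available by configuration, since either reading of "neighborhood" is
defensible for this architecture.

The network is:

1. **GraphConv** ($\times 2$ by default, channel size fixed at 75): slot
   $s$ of the output is $\tanh(W_{self} h_i + W_{nbr} h_{n(i,s)} + b)$;
   sentinel slots use the self term only. The tanh keeps activations in
   $(-1, 1)$.
2. **Batch normalization** per channel over all (atom, slot) entries,
   followed by **max-pooling** over the 10 neighbor slots. Batch-norm uses
   batch statistics during training and running statistics (momentum 0.1)
   in eval mode, with no learnable affine; the statistics are treated as
   constants in the backward pass. Both simplifications are standard and
   are stated here because they slightly change the training-mode
   gradient; the eval-mode gradient is exact, and the full backward pass is
   verified against numerical differentiation in that mode.
3. **GraphGather**: per-graph sum of node states followed by tanh --
   permutation invariant.
4. **Model variable $M$**: two ReLU dense layers (75 → 32 → 1 by default)
   reduce the gathered vector to one scalar.
5. **Final dense layer** over $(M, P)$: 17 interpretable coefficients plus
   a bias.

### Physics-informed initialization

The final layer starts at the thermodynamic pattern (+1 complex, −1
receptor, −1 ligand per term, −1 entropy), 0.5 for the model variable, and
bias 0. The output layer of the $M$ head is **zero-initialized** so that
$M = 0$ exactly at initialization: a fresh model therefore reproduces
every label of a physics-consistent dataset with zero error before any
training. Because a zero-initialized ReLU output would otherwise block all
gradient, the ReLU subgradient at exactly 0 is taken as 1 -- a documented
tie-break that lets the $M$ head wake up during training.

Training minimizes the MSE with Adam at learning rate 0.001 for 100
epochs (batch size 32 by default), fully reproducible for a fixed seed on
one thread. The graph-only ablation (`usePhysics = FALSE`) zeroes the
physics vector and trains the same architecture, mirroring the pure
data-driven baseline the hybrid is compared against.

## Synthetic study system

Real benchmark inputs (crystal structures with curated force-field
parameters) require external downloads, so the package generates its own
study system with exact ground truth (`fixtureSpec()`,
`makeHostGuest()`): a ring-like host cage of 24--40 atoms (a two-level
carbon/nitrogen/oxygen macrocycle with ~1.5 Å bond lengths and hydrogen
decorations, mimicking the macrocyclic hosts of host--guest benchmarks,
always below 100 atoms) with a 4--8-atom helical heavy-atom rod threaded
through the cavity as the guest. All interatomic distances are at least
1.0 Å and non-bonded contacts sit at Lennard-Jones-compatible
separations; partial charges are uniform within ±0.3 e shifted to a
net-neutral complex, intrinsic radii lie in [1.2, 2.0] Å, and
Lennard-Jones parameters in physically plausible ranges (r_min/2 in
[0.8, 1.5] Å). Bond lengths are chosen so that distance-based bond
perception recovers the intended connectivity after a PDB/PQR
round-trip. Generation is bitwise deterministic per (seed, index).

Labels are built from the engine itself:
$$\Delta\Delta G = \Delta H - T\Delta S + s\,g(\text{structure}) +
\epsilon,$$
where $\Delta H$ is the computed enthalpy, $T\Delta S$ is a generated
entropic cost (a penalty growing with guest size, about
$-(0.5 + 0.25\,n_{guest})$ kcal/mol with 0.5 kcal/mol spread -- larger
guests lose more configurational freedom), $g$ is the tanh of a fixed
random projection of the complex's atom-type histogram (bounded in
$[-1,1]$ and learnable from the atom-type one-hots the network sees), $s$
is the nonlinearity amplitude and $\epsilon$ is Gaussian label noise. With
$s = \epsilon = 0$ the decomposition holds exactly and the initialized
network has zero error; with $s > 0$ part of the signal is invisible to
the physics head, so the hybrid-vs-ablation comparison is meaningful.

What the generator does *not* emulate: chemically realistic conformers or
force-field-quality geometries, conformational change on binding (the
bound-state single-conformation convention is used throughout),
protonation effects, and experimental noise structure beyond i.i.d.
Gaussian labels. Passing tests therefore demonstrate the correctness of
the machinery and the claimed structural/initialization properties, not
predictive accuracy on real protein--ligand data.

## Evaluation protocols

* **Split**: shuffled 3:1 train/test (368 items give 276/92),
  seed-reproducible. The held-out 25% serves as both validation and test
  set, and per-epoch validation loss is logged.
* **Cross-validation**: 4-fold by default; fold sizes differ by at most
  one, every item is validated exactly once, and the reported spread is
  the standard deviation across folds (labelled as such).
* **Robustness**: Gaussian noise $N(\mu, \sigma^2)$ is added to the
  entropy feature only, with $\mu$ and $\sigma$ the mean and standard
  deviation of that feature over the dataset -- the literal protocol, a
  deliberately biased noise -- and a conventional zero-mean mode by flag.
  Clean and noisy runs share seeds and partitions, so with $\sigma = \mu
  = 0$ the RMSE deltas are identically zero.
* **Feature correlations**: Pearson by default (Spearman by flag) across
  the 16 features or the complex-only subset; zero-variance features give
  flagged `NA` entries rather than propagating NaN.

## Numerical choices and edge cases

* Coincident atoms are a geometry error for Born radii; empty ligand or
  receptor selections are selection errors; an all-solvent structure
  strips to empty with a warning.
* Bond perception (for files lacking CONECT): distance below 1.3 times
  the covalent-radius sum; overridable.
* Distance ties in neighbor lists break toward the lower atom index, and
  max-pool gradient routes to the first maximal slot.
* Problem sizes in the shipped tests and the acceptance script -- 200
  complexes for the physics-consistency training run, 80 for the
  hybrid-vs-ablation and robustness experiments, 24 for cross-validation,
  $10^6$ Monte-Carlo points per radius check -- were chosen as the
  package's own study conditions: large enough for stable estimates on
  the synthetic system, small enough to run on a single CPU.

## Known limitations

* Pairwise R6 descreening ignores neighbor-neighbor overlap; radii for
  densely packed solutes are slightly overestimated relative to a grid
  treatment.
* The electrostatic size $A$ is the uniform-ball formula, not the full
  moment construction; for highly aspherical molecules the ALPB
  correction is approximate (the correction term is small at
  $\beta \approx 1/78.5$).
* Training-mode batch-norm gradients are approximate (statistics held
  constant), a standard simplification.
* The entropy residual requires an experimental label; at inference on
  unlabeled complexes the feature is 0 and predictions revert to
  enthalpy-plus-learned-correction.
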