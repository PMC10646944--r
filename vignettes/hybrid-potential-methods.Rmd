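---
title: "A hybrid equivariant-network / force-field potential: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid equivariant-network / force-field potential: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqnnp)
```

## The model

`eqnnp` implements a hybrid interatomic potential: a strictly local
equivariant neural network predicts, for every directed atom pair within a
cutoff `r_c`, a scalar feature vector and a set of spherical-tensor
features. Three output heads map the pair features to a local energy
contribution, an antisymmetrized charge exchange and an atomic volume, and
these atom-in-molecule quantities then parameterize two physically
motivated long-range terms:

$$V = \sum_i E^{\mathrm{NN}}_i \;+\; \sum_i E^{\mathrm{ref}}_{z_i} \;+\;
  \sum_{i<j} E^{\mathrm{C}}_{ij}(q, N, R) \;+\;
  \sum_{i<j} E^{\mathrm{D}}_{ij}(v/v^{\mathrm{free}}, R),$$

with charges in elementary-charge units, distances in Angstrom and
energies in kcal/mol throughout (Coulomb constant 332.0637 kcal A mol^-1
e^-2). The network is *local* — nothing beyond `r_c` = 5.2 A enters the
embedding — while electrostatics and dispersion genuinely extend beyond
the cutoff; that division of labor is the point of the architecture.

### Species encoding

Chemical species enter through a smooth positional encoding of their
periodic-table coordinates: the period and the 18-column group index are
each embedded with interleaved sine/cosine waves of geometrically spaced
frequencies (dimensions 5 and 10, frequency parameters 100 and 1000), and
the two blocks are concatenated. Elements sharing a period agree exactly
on the row block, elements sharing a group on the column block, and the
map is smooth in the (row, column) coordinates, so encodings can be
perturbed, interpolated or averaged — `average_encoding()` and the
`encodings` override of `dissociation_scan()` exercise exactly that. The
supported range is H through Xe; the row dimension is odd (5), so the last
sine/cosine pair is truncated, the natural extension of the interleaved
convention to odd dimensions.

### Pair embedding

Each directed pair (i, j) with distance below `r_c` is fingerprinted by
`n_basis` = 10 sinc-like Bessel functions multiplied by a polynomial
envelope (smoothness p = 3: value and first two derivatives vanish at the
cutoff) and by real spherical harmonics of the unit bond vector up to
`l_max` = 2. A two-body MLP of the two species encodings and the radial
basis produces the initial scalar features (256 for the production
configuration), multiplied by the envelope so they vanish smoothly at
`r_c`; a bias-free linear map spreads them over 10 tensor channels
attached to the harmonics.

Each of the 3 interaction layers then:

1. sums envelope-weighted, per-channel-weighted harmonics over every
   neighbor of the source atom into an environment tensor;
2. couples the environment tensor with the pair tensors channel by channel
   through every symmetry-allowed path (|l1 − l2| ≤ l ≤ l1 + l2, parity
   multiplicative, truncated at `l_max`), using real-basis coupling
   tensors derived from the closed-form complex coefficients and the
   standard complex-to-real unitary;
3. updates the scalars with a latent MLP of the previous scalars and the
   invariant part of the coupled features, mixed as
   `x' = a x + sqrt(1 - a^2) MLP(...)` with a trainable per-layer
   coefficient `a` (sigmoid-reparameterized to stay in [0, 1), initialized
   at 1/sqrt(2)); the square-root complement preserves feature
   normalization;
4. recombines the coupled features linearly over channels and paths (one
   weight matrix per output irrep, divided by the square root of its
   fan-in) back to the fixed channel count.

The set of (l, parity) blocks present is computed once at build time; it
grows from the two-body set {0+, 1-, 2+} to all six blocks over the first
two layers. With the production hyperparameters (256 scalar features,
10 channels, `l_max` 2, 3 layers, two-body MLP 64/128, latent MLPs
256/256, heads 256/128/64/32/16 on the concatenated two-body and final
scalars) the model holds about 1.22 million parameters.

### Heads, aggregation and constraints

The three heads act on the concatenation of the two-body and final scalar
embeddings, so simple pairwise information bypasses the deep pathway. At
aggregation, every per-pair output is weighted by the cutoff envelope —
this keeps all atomic properties C^1 as pairs cross `r_c`, which matters
for dynamics and for finite-difference force checks. Charges are
antisymmetrized over pair direction before summation, so global neutrality
is exact by construction (a telescoping sum), not imposed a posteriori.
Volume sums pass through a softplus; an isolated atom therefore carries a
volume ratio of softplus(0) ≈ 0.693 rather than the free-atom value 1 —
a deliberate interface choice (the constraint applies to the aggregated
atomic quantity), documented here because dispersion coefficients of
isolated fragments inherit it before training.

### Physics terms

**Electrostatics.** Network charges are scaled by a universal factor
`eps`, then passed through the valence correction: an atom may not lose
more than 95% of its valence electrons; the excess ("valence hole") is
computed with a smooth positive part of width 0.01 e (a scaled softplus,
so forces stay continuous) and returned from the neighbors that drained
charge in proportion to the amount each drained, in one pass that
conserves total charge exactly. When a hole exists but no neighbor
donated (possible only for inconsistent inputs), the transfer fades out
smoothly and a warning is emitted. The pair energy is the
charge-penetration form with valence populations N and electron
populations N − q: the core–core term is undamped, core–electron cross
terms damped by 1 − exp(−alpha R), the electron–electron term by
1 − exp(−beta R); it is symmetric and tends to the bare point-charge
energy at long range. Because the correction to the point-charge energy
is exponentially short-ranged, the package applies bare point-charge
Coulomb between all pairs (Ewald summation under periodic boundary
conditions) and adds the (CP − bare) correction only within `r_c`,
switched smoothly to zero over the last Angstrom. Beyond `r_c` charges
are exactly zero for isolated fragments, so dissociated systems see no
electrostatics at all.

**Dispersion.** Homonuclear C6 coefficients scale with the square of the
volume ratio and polarizabilities linearly; heteronuclear C6 follows the
standard combination rule; van der Waals radii scale with the cube root
of the volume ratio. The −C6/R^6 attraction is damped by a sigmoid in
R/(s (r_i + r_j)) with steepness `gamma` = 20 and `s` = 0.94 — the
literature values for this damping, kept as defaults because the trained
universal values are dataset-dependent; all five physics parameters
(`eps`, `alpha` = 3/A, `beta` = 2/A, `gamma`, `s`) are trainable in the
late schedule stages. Dispersion acts to a 12 A cutoff with a smooth
1 A switch; periodic systems add the standard continuum tail integral
beyond the cutoff (omitting it visibly distorts condensed-phase
structure). The exact dissociation asymptote — energy equal to the sum of
isolated-atom references with zero forces — therefore holds beyond the
dispersion cutoff; between 5.2 and 12 A only the (small) dispersion tail
survives.

**Free-atom table.** Valence counts are derived from the periodic table;
polarizabilities, free C6 coefficients and free vdW radii are the standard
free-atom reference values (converted from atomic units) for H, C, N, O,
F and S. The synthetic test suite does not depend on their precise
values.

### Forces and differentiation

`eqnnp` includes a small reverse-mode differentiation tape
(`R/autodiff.R`) over dense matrices, carrying exactly the primitives the
potential needs. Every primitive's vector-Jacobian product is itself
built from tape primitives, so gradients are differentiable again:
forces are exact reverse-mode gradients of the
implemented energy (through the network, the charge pipeline, Ewald and
the dispersion switches), and force-matching training differentiates
those forces with respect to the parameters by a second backward pass.
Force-versus-finite-difference agreement is part of the test suite at
1e-5 relative with step 1e-4 A.

## Training procedure

Training runs in stages over mini-batches that merge records into one
disconnected multi-molecule system (indices offset), so a single tape
evaluation yields per-molecule energies and per-atom quantities:

1. **Stage 1** trains the bare network on total energies, forces, charges
   and volume ratios with weights (E, F, q, v) = (0.001, 1, 1000, 1000) —
   strongly favoring forces early — then rebalances to (0.01, 0.1).
2. **Stage 2** activates the physics terms and retrains the energy head
   with the embedding and the charge/volume heads frozen (freezing is
   bitwise: values and optimizer state untouched), then unfreezes.
3. **Stage 3** adds dimer interaction-energy records — predicted as
   dimer minus monomers, all evaluated by the same model, so constant
   energy shifts cancel — with weights (E, DES) = (0.1, 5), and lets the
   physics parameters train.
4. **Stage 4** refines on system-specific records through the same
   machinery.

The optimizer is AdamW with weight decay 0.5 on the output heads and none
on the embedding; a plateau schedule multiplies the learning rate by 0.8
after 10 epochs without training-loss improvement, and stages stop when
the rate falls below their threshold (1e-4 early, 1e-5 late). A
covariance regularizer penalizes off-diagonal entries of the scalar
embedding's batch covariance (weight 1e-3 by default; the weight is not
prescribed anywhere, so it was chosen small relative to the main terms),
promoting statistically independent features for the multi-output heads.
Batch gradients are clipped at a global norm of 100 by default (50 in the
desk-scale experiments): records deep on a repulsive wall otherwise
produce occasional destabilizing steps. A random 10% of records, fixed by
the seed, serves as the validation set; one seed controls initialization,
splitting and shuffling.

## The synthetic-data generator

Desk-scale experiments need labeled records whose structure matches
coupled-cluster training sets: total energies referenced to isolated-atom
constants, per-atom forces, neutral-per-molecule charges, volume ratios,
and dimer interaction energies with monomer partitions. The generator
builds monomer/dimer geometries (diatomic and water templates, Gaussian
internal deformations, random rigid placement) and labels them with an
analytic surrogate: Morse bonds, damped point-charge Coulomb and
sigmoid-damped −C6/R^6 between nonbonded pairs — all pairwise-radial, so
its forces are exact in closed form (verified against finite differences
at 1e-6 relative). Charges follow a fixed electronegativity-balancing
rule; volume ratios are a smooth decreasing function of coordination
(1 at zero coordination); isolated-atom references sit at
coupled-cluster-like magnitudes so dissociation asymptotes are realistic.
Deformation defaults to 0.35 A (0.5 A in the recovery experiment, which
covers the well and the lower repulsive wall; compression is floored at
65% of the equilibrium bond length — harder compressions produce forces
of order 1e5 kcal/mol/A that no realistic dataset contains).

What the generator does *not* emulate: many-body polarization,
conformational diversity beyond small perturbations, real electronic
structure (its surrogate is pairwise by construction), or label noise.
Passing the desk-scale recovery test therefore demonstrates that the
architecture, losses, gradients and schedule can learn a smooth
dissociation curve and its asymptote from data of the right shape — not
that the model reaches coupled-cluster accuracy on real chemistry.

## Problem sizes used in the checks

The package's verification experiments are sized for a workstation: the
equivariance suite uses a 32-feature, 4-channel, 3-layer model on ten
6-atom clusters with 20 rotations/inversions; force consistency uses ten
5-atom clusters; charge conservation covers 1000 random systems with
charge scalings up to 50 to force valence holes; the recovery experiment
trains the reduced model (1 layer, 32 scalar features, `l_max` 1) on
2000 O–H diatomic records for up to 250 epochs (about ten minutes of CPU
time), targeting energy RMSE under 5% of the 118 kcal/mol well depth and
the dissociation asymptote at 15 A within 2%; the thermostat check runs
a million BAOAB steps on a 3-D harmonic oscillator. The production-size
architecture (1.22 M parameters) is built and evaluated, but not trained,
in the checks.

## Molecular dynamics

The integrator is the BAOAB splitting of Langevin dynamics: half kick,
half drift, exact Ornstein–Uhlenbeck velocity refresh
(c1 = exp(−gamma dt), noise amplitude sqrt(1 − c1²) sigma_v), half
drift, half kick. The thermostat interface is a plain closure over
energy/forces, so alternative thermostats can be plugged in without
touching the integrator; the default is classical Langevin (colored-noise
thermostats approximating nuclear quantum effects are out of scope).
Units: fs, amu, K, with kinetic energy converted through
1 kcal/mol/A / amu = 4.184e-4 A/fs². Radial distribution functions use
minimum-image distances normalized by the ideal-gas shell expectation
(the counting identity — the integral of rho g(r) 4 pi r² dr recovering
the mean neighbor count — is exact by construction and tested); dipole
spectra Fourier-transform the Hann-windowed autocorrelation of
M(t) = sum q_i(t) r_i(t), origin-independent for neutral systems, with
the axis in 1/cm.

## Numerical choices and degenerate inputs

* Neighbor search is a vectorized all-pairs scan with explicit
  lattice-image enumeration (exact for cells smaller than the cutoff);
  at the package's target sizes this outperforms cell lists in R and is
  trivially verifiable. Pairs are ordered deterministically, so
  locality tests can be bitwise.
* The boundary `R = r_c` is excluded (half-open interval); the envelope
  vanishes there anyway, so membership is energetically irrelevant but
  deterministic. Overlapping atoms (below 1e-6 A) raise an error naming
  the pair.
* Ewald parameters derive from the accuracy target: the splitting
  parameter defaults to 3/min(cell height), the real-space cutoff to
  erfc^{-1}(accuracy)/kappa (images enumerated if it exceeds the cell),
  the reciprocal cutoff to 2 kappa sqrt(−log accuracy). The energy is
  independent of the splitting parameter within the target, which is
  tested. Non-neutral cells are rejected.
* Empty neighbor graphs (isolated atoms) short-circuit to the exact
  asymptote; batches of size < 2 return a zero covariance regularizer;
  interaction records missing monomer partitions raise errors naming the
  field.
* Spherical harmonics use component normalization (mean square 1 per
  component over the sphere) in the standard real ordering; any
  self-consistent convention yields identical physics after training, so
  the convention is fixed and documented rather than configurable.

## Known limitations

* Tensorial outputs (multipoles from the equivariant features) are not
  implemented; the heads are scalar.
* The model is not designed for ionic total charges; the charge pipeline
  assumes neutral systems.
* Periodic evaluation assumes one system per call (no batched periodic
  training), and condensed-phase production runs are outside the
  package's desk-scale envelope.
* `l_max` is capped at 2 (the production setting); higher orders would
  need additional harmonic and coupling formulas.
* Training at the production architecture size is possible but slow in
  plain R; the package's training engine is sized for reduced models and
  methodological verification, not for training production potentials.
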