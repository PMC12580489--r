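---
title: "Quadrupole-based aromaticity descriptors: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrupole-based aromaticity descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmaq2)
```

## The problem and the model

Aromatic stabilization of ring molecules comes from π-electron density
delocalized above and below the ring plane. Because no operator measures
"aromaticity", descriptors probe correlates of it. The family implemented
here reads the out-of-plane electron density directly from the rank-2
(quadrupole) terms of a distributed multipole analysis (DMA): every atomic
site carries real spherical multipoles Q_lm (Stone ordering, atomic
units), and the out-of-plane Cartesian component

$$\Theta_{zz} = \int \rho(\mathbf r)\, r^2\,\tfrac{1}{2}(3\cos^2\theta - 1)\, d\mathbf r$$

weights density by the angular factor $(3\cos^2\theta-1)/2$: positive
inside the cone $\theta < 54.7^\circ$ about the ring normal, negative near
the ring plane, zero at $\theta = \arccos(1/\sqrt 3)$. π density therefore
*raises* $|\Theta_{zz}|$-type descriptors, while in-plane charge lowers or
raises them purely through the sign of the angular factor.

Six descriptors are computed per molecule in a canonical frame (ring
centroid at the origin, ring plane = xy): per-ring-atom sums of the site
Q2 magnitude and of the site Q20, and the magnitude and Q20 of the *total*
quadrupole translated to the ring center and to a point 1 Å above it.
Values are reported raw and normalized by a designated reference molecule
(benzene's role in the original protocol), which then scores exactly 1 in
each descriptor.

### Moment translation

The only nontrivial tensor operation is shifting site moments to a common
evaluation point. With $\mathbf a = \mathbf r_{\text{site}} - \mathbf p$,
site monopole $q$, Cartesian site dipole $\boldsymbol\mu$ and site
quadrupole $\Theta$ (all atomic units, positions in bohr):

$$\Theta_{\alpha\beta}(\mathbf p) = \Theta_{\alpha\beta}
 + \tfrac32 (a_\alpha \mu_\beta + a_\beta \mu_\alpha)
 - (\mathbf a\cdot\boldsymbol\mu)\,\delta_{\alpha\beta}
 + \tfrac{q}{2}\,(3 a_\alpha a_\beta - a^2 \delta_{\alpha\beta}).$$

This is exact, not asymptotic: whenever site ranks ≤ 2 fully describe the
underlying charge distribution, the translated tensor equals the
brute-force charge sum to rounding error, and site ranks ≥ 3 can never
leak into a translated rank-2 moment. The test suite enforces both facts
against independent oracles (direct $\Theta$ sums over random charges, and
real-solid-harmonic moment sums), plus the closed-form consequences:
linearity in sites, origin-independence for neutral dipole-free sets, and
the in-plane point-charge increment $-\tfrac12 q d^2$ that produces the
charged-substituent artifact.

### Conventions worth stating

* **Magnitude** is the Euclidean norm of the five real spherical
  components $(Q_{20}, Q_{21c}, Q_{21s}, Q_{22c}, Q_{22s})$ — Stone's
  convention. The Frobenius norm of the Cartesian tensor is larger by
  $\sqrt{3/2}$; pick one and stay with it.
* **Ring-atom sums** add per-site magnitudes (not the magnitude of the
  summed tensor), over the designated ring heavy atoms only; translated
  descriptors use *all* sites. This is the only reading under which "the
  magnitude computed at a point" is a single number per molecule; it is
  isolated in `compute_descriptors()` so the alternative reading is a
  one-function change.
* **Units**: all tensor math in atomic units; 1 Å = 1.8897261254578281
  bohr (CODATA 2018), 1 hartree = 27.211386245988 eV. The "1 Å above the
  plane" evaluation point is converted accordingly.
* **Canonical frame**: the ring plane is the smallest principal direction
  of the centered ring-atom coordinates. A plane fit cannot choose between
  the two faces, so the face sign is resolved from molecular content: the
  total out-of-plane dipole about the ring centroid is oriented along +z.
  Molecules with no such marker are z-mirror-symmetric in the moments used
  here, so either face yields identical descriptors. This makes all six
  descriptors invariant (≤ 1e-8) under arbitrary rigid motion of the
  input, which the acceptance tests assert.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| evaluation height | 1 Å | where `Q2_1`/`Q2_1zz` are defined; the z-scan (below) justifies it for benzene-like densities |
| z-scan grid | 0.1–3.0 Å, step 0.05 Å | dense enough to localize the out-of-plane maximum to the step the original analysis quotes; refinable |
| reference molecule | user-designated | the normalization denominator; every reference descriptor must be nonzero |
| k (clusters) | 4 | the partition depth used in the substituted-benzene analysis; configuration, not hard-coded |
| z-score sd | population (÷ n) | standard-scaler convention; the sample-sd alternative is a one-line change |
| Ward heights | ΔESS | objective increase per merge; `stats::hclust(ward.D)` on *squared* distances gives exactly 2× these heights |

The z-scan evaluates only the +z face: Q20 is even under the ring-plane
mirror for the mirrored site set, so the −z profile adds nothing. Grid
ties break toward smaller z.

## What the synthetic generators emulate — and what they do not

`make_ring_molecule()` builds planar n-fold rings whose sites carry a
monopole, an axial quadrupole (default Q20 = −0.4 e·a0², the sign π
density imposes on ring carbons), optional ± charge pairs above/below each
site emulating π density (offered both as explicit rank-0 sites and as the
exactly equivalent folded site dipole), and an optional in-plane charged
substituent — the configuration behind the angular-factor artifact. Ring
geometry defaults to the benzene C–C bond length (1.39 Å, which is also
the hexagon circumradius). `make_point_charge_molecule()` returns random
charge sets *with their own brute-force quadrupole oracle*, so the engine
is always tested against an independent formula.

`make_cluster_dataset()` draws Gaussian groups in six-descriptor space
with means mimicking the qualitative cluster structure of the substituted
benzenes — neutral near (1,…,1), quinoidal with depressed out-of-plane
entries, cationic below 1, anionic above 1 (group sizes 8/2/3/3 echo a
16-molecule study roster) — and σ = 0.01 by default, i.e. well-separated
groups. `make_energy_records()` draws IP ∈ [7, 11] eV and EA ∈ [−1, 3] eV
uniformly and independently, the range of small-aromatic energetics, with
IP > EA guaranteed.

What passing tests on these fixtures shows: the algebra, conventions,
determinism and recovery behavior of every stage. What they do **not**
show: anything about real DFT/GDMA multipoles — synthetic site moments are
not fitted to any molecule, the descriptor and energy generators are
mutually independent (so R² screens on synthetic data exercise machinery,
not chemistry), and cluster recovery at σ = 0.01 says nothing about
recovery on overlapping real-world groups (a documented simulation in the
test suite shows mean ARI < 1 at σ = 0.8).

## Numerical choices and degenerate inputs

* Spherical↔Cartesian conversion is closed by the zero-trace constraint;
  the inverse rejects tensors whose trace exceeds 1e-8 (relative).
* Canonicalization refuses collinear/degenerate ring atoms (no unique
  plane) and molecules only pass `compute_descriptors()` after the
  centroid (≤ 1e-8 Å) and plane checks.
* Normalization raises an explicit error naming the descriptor when a
  reference value is zero; IP = EA raises a degenerate-hardness error
  (zero denominator in the ω family). Negative EA is physical and allowed.
* Ward ties break toward the smallest lexicographic pair of cluster slots
  (leaves first, then merge order), making dendrograms fully
  deterministic; duplicate rows are legal and merge at height 0.
* PCA loading signs are fixed by making each column's largest-magnitude
  entry positive.
* The punch writer emits 17 significant digits so write→parse round-trips
  doubles exactly; ranks ≥ 3 are parsed, stored and rotated only as
  zero-flagged payload (they never affect descriptors).

## Problem sizes

The shipped analysis scripts and tests run at the scale of the original
study design: 16 molecules (1 reference + 15 derivatives), 6 descriptors,
4 clusters. Property tests use up to 20-charge random systems, 100 random
seeds for the translation and Ward oracles (Ward oracle instances at
n ≤ 7, where exhaustive greedy enumeration is cheap), 1000 random (IP, EA)
pairs for the identity checks, and a 10⁴-sample isotropic Gaussian for the
PCA sanity check.

## Known limitations

* Only rank-2 translation is implemented (ranks ≥ 3 are carried but
  ignored — exactly sufficient for these descriptors, useless for others).
* Rotation of ranks ≥ 3 is unimplemented; such components are zeroed with
  a flag during reorientation.
* The descriptors are frame-defined for a single ring; fused polycyclics
  would need one canonical frame per ring and are out of scope.
* Charged substituents inflate the translated descriptors through the
  angular-factor sign structure — the package reproduces this faithfully
  (it is the point of the artifact analysis), so interpretation for
  charged species needs care.
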