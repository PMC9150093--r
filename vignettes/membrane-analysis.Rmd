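---
title: "Elasticity, dynamics and surface defects of lipid bilayers: methods and validation"
author: "membraneTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elasticity, dynamics and surface defects of lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membraneTools)
```

# Scope

membraneTools post-processes molecular-dynamics trajectories of lipid
bilayers — here modelled on a five-component neuronal plasma membrane
(DPPC, POPC, palmitoyl-sphingomyelin, cholesterol and the ganglioside
GM1 at molar ratios 36.5:35.2:9.7:17.8:0.8, 484 lipids per leaflet) —
optionally carrying a protein aggregate near one surface. It computes:

* the **bending modulus** $K_C$ from the Boltzmann statistics of lipid
  splay angles,
* the **area compressibility modulus** $K_A$ from equilibrium
  area-per-lipid fluctuations,
* the **lateral diffusion coefficient** $D$ from mean-square
  displacements,
* the **acyl-chain order parameter** $S_{CD}$,
* lateral **density, thickness and radial-distribution maps**,
* **protein–membrane proximity, contact and nonbonded-energy**
  statistics, and
* **surface cracks**: connected empty-space regions between the bilayer
  surfaces on a van der Waals occupancy grid.

Every estimator is paired with a synthetic generator that plants a known
ground truth, so the whole pipeline is testable without running any
simulation. Running MD itself, system construction, Ewald
electrostatics, secondary-structure assignment and SASA are out of
scope.

# The membrane frame and data model

All coordinates are Angstrom internally (GRO input in nm is converted on
read). The membrane normal is taken to be the box $z$ axis and $z = 0$
is placed at the membrane centre; no normal re-fitting is attempted.
The centre defaults to the **unweighted mean $z$ of membrane atoms** —
mass weighting is available (`weighting = "mass"`) and differs
negligibly for compositionally symmetric bilayers. A lipid belongs to
the upper leaflet iff its head atom (P for phospholipids, O3 for
cholesterol) satisfies $z \ge z_0$; the tie goes to the upper leaflet,
an arbitrary but deterministic convention. Lateral $(x, y)$ distances
use the minimum-image convention throughout; $z$ is treated as
non-periodic within the analysis slab, with `unwrapLateral()` provided
for tracks that cross the boundary. Water and ions are dropped at load
time with a logged count.

Supported formats are GRO and PDB topologies and multi-frame GRO,
multi-model PDB and DCD trajectories (via bio3d). The GRO writer emits
four decimals in nm so that write/read round trips preserve coordinates
to better than $10^{-3}$ Å.

# Elastic moduli

## Splay statistics and the bending modulus

The lipid **director** is the unit vector from the midpoint of the P
and C2 atoms to the centre of mass of the last three carbon atoms of
the two acyl chains (PC/SM lipids; GM1 uses the same scheme on its
ceramide tails), or the C3$\to$C17 vector for cholesterol. The sign
convention is head$\to$tail; only same-leaflet pairs are compared, so a
global flip cancels.

For each unordered pair of lipid types $(i, j)$, splay angles $\alpha$
of **adjacent** same-leaflet pairs are pooled across frames. Adjacency
is not prescribed by the underlying experiment description, so the
package uses a lateral anchor-distance cutoff, default 10 Å, exposed as
a parameter. The splay potential of mean force is

$$F(\alpha)/k_BT = -\ln\!\frac{P(\alpha)}{\sin\alpha} + \text{const},$$

where the $\sin\alpha$ factor removes the geometric phase-space weight
of angles on the sphere. A quadratic $F = \tfrac{\chi}{2}\alpha^2 + c$
is fitted by unweighted least squares on the populated 1° bin centres
inside the window [10°, 30°] ($\alpha$ in radians in the fit), giving
the pair splay modulus $\chi_{12}^{ij}$ in $k_BT/\mathrm{rad}^2$. The
window and bin width follow the source analysis protocol; at least
three populated bins are required or the fit is refused.

Pair moduli combine into the bending modulus by the count-weighted
harmonic rule

$$\frac{1}{K_C} = \sum_{ij} \frac{\varphi_{ij}}{\varphi_{tot}}
  \frac{1}{\chi_{12}^{ij}},$$

with $\varphi_{ij}$ the number of adjacent $ij$ pairs. This combination
is bounded between the smallest and largest pair modulus and invariant
under common rescaling of the counts; an arithmetic weighting is
available as a one-argument switch. $K_C$ is converted from $k_BT$ to J
at the run temperature (default 323 K). Published tables sometimes
label this quantity in "$10^{-20}$ J/m"; dimensionally a bending
modulus is an energy, and the package reports J.

The generator `genSplaySample()` draws from
$p(\alpha) \propto \sin\alpha\, e^{-\chi\alpha^2/2}$ by inverse-CDF
lookup on a 20001-point quadrature grid, deliberately including the
$\sin\alpha$ factor the estimator divides out, so the pair is an exact
inverse: at $n = 10^6$ the fit recovers $\chi \in \{5, 15, 30\}$ within
5% (observed: well under 1%).

## Area compressibility

With $A$ the area per lipid (lateral box area over lipids per leaflet,
averaged over the two leaflets),

$$K_A = \frac{k_B T \langle A\rangle}{N\,\mathrm{Var}(A)},$$

converted to dyn/cm. The per-lipid form is used by default; passing the
total box area with $N = 1$ gives the box-area variant, and the two
agree exactly because $A_{box} = N A$. `genAreaSeries()` inverts the
same fluctuation law; at $10^5$ frames the recovery of
$K_A \in \{100, 236, 400\}$ dyn/cm is within 5% (observed ~1%), and
doubling the series variance at fixed mean halves $K_A$ exactly.

# Diffusion and chain order

The lateral MSD is averaged over particles and **all sliding time
origins**; `diffusionCoefficient()` fits a line over a window
defaulting to [10%, 50%] of the maximum lag — where the MSD of an
equilibrated lipid system is linear, while shorter lags are
ballistic/cage-dominated and longer lags are statistically starved —
and reports $D = \mathrm{slope}/(2d)$ with $d = 2$ (a $d = 3$ option
exists). Unit conversions ($\mathrm{cm^2/s} \leftrightarrow
\mathrm{Å^2/ps}$, dyn/cm, $k_B$ fixed at $1.380649\times10^{-23}$ J/K)
live in the single `mtConstants` table used by generators and
estimators alike. A step larger than half the box trips an error
directing the user to unwrap first. `genRandomWalk()` plants 2D
Brownian motion with per-axis step variance $2D\,\Delta t$; with
$10^3$ particles $\times$ $10^3$ steps the recovery is within 3%.

$S_{CD} = \langle (3\cos^2\theta - 1)/2 \rangle$ over C–H bond vectors,
with $\theta$ against the membrane normal; profiles report $-S_{CD}$
per carbon position, the plotting convention. Closed forms pin the
estimator: all-$z$ vectors give 1, in-plane vectors give $-1/2$, the
magic angle ($54.7356^\circ$) gives 0, and an isotropic $10^6$ sample
gives $|S_{CD}| < 0.01$. Reconstruction of missing hydrogens is *not*
performed; fixtures carry explicit C–H pairs.

# Spatial maps

Density maps are per-frame-normalised 2D histograms of lipid anchor
atoms (P for phospholipids, O3 for cholesterol — a per-type
configuration), so $\sum \rho \cdot \text{bin area}$ equals the anchor
count per frame exactly. Thickness maps take, per lateral cell, mean
upper-leaflet head $z$ minus mean lower-leaflet head $z$; cells never
populated by both leaflets are filled from the nearest populated cell
on the periodic lattice and flagged so downstream statistics can
exclude them. The lateral RDF normalises pair counts by the ideal-gas
annulus $2\pi r\,dr\,(N-1)/A$ (spherical shells in the 3D variant,
retained because a centre-of-mass reference can be read either way); a
homogeneous Poisson field of $10^4$ points reads $g(r) = 1 \pm 2\%$
over $[5\,\text{Å}, r_{max}]$.

# Proximity, contacts and energies

Per frame, the package records the minimum protein–membrane
interatomic distance and the minimum $|z - z_0|$ of the protein. The
minimum-distance search uses a uniform **cell list with expanding-shell
termination**: shells of cells are visited in increasing Chebyshev
distance and the search stops once the current best is provably
unbeatable by any unvisited shell, so results equal the $O(N^2)$ scan
exactly (tested bitwise on randomized fixtures). Contact population is
the percentage of window frames with minimum distance at or under the
cutoff; the inclusive comparator (≤) is the default and the strict
variant is a flag, both exposed because published definitions use both
("≤ 10 Å" population tables vs "< 6.5 Å" approach counts). The
membrane *surface* for inside/outside classification is half the
trajectory's own mean head-to-head thickness, recomputed per input
rather than hard-coded.

Side-chain contacts: two residues are in contact when their side-chain
centres of mass (backbone N, CA, C, O excluded; glycine falls back to
CA) are within 6.5 Å, boundary inclusive.

`nonbondedEnergy()` is a plain real-space re-scoring facility:
electrostatics $k_e q_i q_j / r$ with $k_e = 332.0636$
kcal·Å·mol$^{-1}$·e$^{-2}$ under a 12 Å cutoff, and Lennard-Jones
$4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with Lorentz–Berthelot
combination and a cubic switching function on [10, 12] Å (the standard
potential-switch form; the original simulations name no functional
form, so the choice is documented here). It does **not** reproduce
particle-mesh-Ewald electrostatics — a cutoff scheme systematically
misses the long-range tail — so its validation is by closed forms,
symmetry and additivity, not by published table values.
`interchainEnergy()` sums the cross terms over unordered chain pairs,
excluding intra-chain contributions.

# Surface cracks

A crack is a connected region of space between the two bilayer
surfaces containing no membrane atom, atoms being vdW spheres (element
radii H 1.2, C 1.7, N 1.55, O 1.52, P 1.8, S 1.8 Å by default,
overridable per atom). The slab between the leaflet head-atom mean
planes is voxelised (default 1.0 Å — for a ~165 Å box a
165×165×~41 grid, cheap in memory); a voxel is occupied iff its centre
lies within a sphere. Empty voxels are grouped into **6-connected**
components (periodic laterally); 6-connectivity avoids the
corner-leak artifacts of 26-connectivity and is a configuration knob.
A component is a *crack* if it owns a voxel in the top surface layer;
its depth is the distance from the top surface to the centre of its
lowest voxel (the unbiased position of the crack bottom within that
voxel), and components also touching the bottom layer are flagged as
channels/pores. Internal cavities not open to the top are ignored.
The "top lipid layer" reference is the mean $z$ of upper-leaflet head
atoms — an operational definition chosen because no more precise one is
available. Per-crack depth tables and per-frame maximum depth maps are
both emitted, since run-level statistics can be aggregated either way.

`genCrackedSlab()` plants cylindrical voids in a dense pseudo-atom
lattice by removing every atom whose sphere intersects the open
cylinder, so the void spans exactly $[\text{top} - \text{depth},
\text{top}]$ on the axis; a planted 17.0 Å crack in a 41.2 Å slab is
recovered within one voxel, and halving the voxel moves the estimate by
at most one coarse voxel.

# The synthetic bilayer

`genBilayer()` places pseudo-lipids on a jittered lattice at the target
area per lipid (default 52.7 Ų) with P sheets at $\pm$thickness/2
(default 41.2 Å), composition apportioned by **largest-remainder
rounding** so the leaflet total is exactly preserved (the source data
give ratios and a total, not counts). Each pseudo-lipid carries the
atoms the estimators need — P, C2, terminal tail carbons and C–H pairs;
O3/C3/C17 for cholesterol — with exactly straight tails, so directors
are $\pm z$ by construction, and the positional jitter (default
$\sigma = 0.3$ Å) is a rigid per-lipid displacement that perturbs
thickness and density but not orientations. GM1 pseudo-lipids differ
from PC only by label: sugar/neuraminic-acid geometry is not modelled,
since energy terms take per-atom charges from input tables.

What the generator does *not* emulate — thermal undulations, chain
disorder, asymmetric compositions, solvent — bounds what passing tests
prove: they certify the estimators against their defining statistical
laws, not the realism of any force field. The headline experimental
observables of the motivating study (e.g. $K_C \approx 10\times
10^{-20}$ J, $K_A \approx 236$ dyn/cm, $D \approx 2\times10^{-7}$
cm²/s, thickness ≈ 41 Å) come from ten 800 ns all-atom trajectories of
~440,000 atoms that are not publicly deposited; they cannot be
regenerated at desk scale, which is exactly why validation here is
property-based, anchored on the formulas with planted parameters at
those published magnitudes.

# Pipeline and reproducibility

`runPipeline()` drives the stages from one YAML config (paths or a
synthetic spec, stage list, per-stage parameter blocks, seed); stage
failures are recorded per trajectory without aborting independent
stages, and replicate results aggregate as mean ± sd with $n$. The
analysis window defaults to the final 3/8 of the frames, mirroring the
production convention of analysing the equilibrated tail of each run;
explicit first/last/stride override it. Every stochastic element takes
its seed from the config; a fixed config + seed reproduces the report
payload exactly (timestamps aside). A thin CLI
(`inst/scripts/membrane-tools`) exposes `analyze`, `synthesize`,
`validate` and `report`.

`validateSynthetic(seed)` runs every generator→estimator round trip at
the default ground-truth values and problem sizes ($10^6$ splay angles,
$10^5$ area frames, $10^3\times10^3$ walkers, $10^4$ RDF points, 100
contact frames of 500+500 atoms, ~24 Å crack slabs — sizes chosen so
the whole table completes in about a minute on one CPU while holding
the stated tolerances with wide margin):

```{r validate, eval = FALSE}
validateSynthetic(seed = 1)
```

# Numerical choices and known limitations

* Histogram bins are 1° (splay) and map grids default to 48×48; the
  splay fit refuses windows with fewer than 3 populated bins rather
  than extrapolating.
* `fitSplayModulus` uses unweighted least squares on bin centres;
  count-weighted fits were considered and rejected to follow the
  stated fitting protocol as literally as possible.
* Splay angles are pooled across frames within a trajectory and fitted
  once; per-frame fitting is statistically noisier and not offered.
* Whether published diffusion coefficients are pooled or per lipid
  type is ambiguous; the default pools all lipids, per-type extraction
  is a selection away.
* Degenerate inputs fail loudly: empty selections, zero-variance area
  series, wrapped MSD input, all-zero histograms and missing named
  atoms are errors, not silent NA propagation.
* The energy module is a cutoff re-scorer (see above); absolute
  electrostatic values will differ systematically from Ewald-based
  references.
* XTC trajectories are not read; convert to DCD or multi-model
  PDB/GRO. No trajectory alignment, SASA, secondary structure or
  force-field parsing is provided.
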