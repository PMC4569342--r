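---
title: "Modeling Syntaxin-1A nanocluster formation, dynamics and STED quantification"
author: "SyxDynamics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Syntaxin-1A nanocluster formation, dynamics and STED quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
library(SyxDynamics)
```

# The scientific problem

Syntaxin-1A, the plasma-membrane t-SNARE of the neuronal fusion machinery,
is distributed over the entire presynaptic membrane but organizes into
nanoclusters of roughly 60--100 nm. STED microscopy of Drosophila
neuromuscular junctions shows that clusters at active zones -- identified
by rings of the scaffold protein Bruchpilot (BRP) -- are both larger
(mean FWHM diameter around 80 nm versus 64 nm outside) and denser than
clusters elsewhere on the membrane. `SyxDynamics` provides a minimal
particle-based model that reproduces this kind of clustering from weak
homophilic interactions, the simulated assays that probe its functional
consequences (FRAP, membrane exploration, aggregation at a docking site,
docking/priming candidate counts), and the image-analysis pipeline used to
quantify the STED data, together with synthetic-data generators so that
every stage can be validated against known ground truth.

# The particle model

Each Syntaxin-1A molecule is a dimer of two spherical particles connected
by a stiff harmonic bond (rest length $r_1 + r_2$, stiffness `bond_k`,
default 10 $k_BT$/nm$^2$):

* **Particle 1 (anchor, $r_1 = 3$ nm)** represents the transmembrane helix
  plus SNARE domain. It is restrained to the membrane plane by
  $U_m(d) = \tfrac12 k_m d^2$ with $k_m = 20\,k_BT$/nm$^2$, where $d$ is
  its distance to the plane, and carries the clustering interaction.
* **Particle 2 (head, $r_2 = 3.3$ nm)** represents the bulky N-terminal
  domain. It only repels other particles sterically:
  $U_r(d) = \tfrac12 k_{rep}\,(d - r_{xy})^2$ for $d < r_{xy}$ (zero
  otherwise), with $k_{rep} = 2\,k_BT$/nm$^2$ and $r_{xy}$ the sum of the
  participating radii; the repulsion acts between head--head and
  head--anchor pairs of different molecules.

Anchor--anchor pairs interact through a piecewise-harmonic clustering
potential with well depth $E_a$ reached at contact $r = 2 r_1$, an
attractive range extending to the interaction radius
$i = r + 2.25$ nm, and a harmonic core whose stiffness equals $E_a$:

$$
U_a(d) = \begin{cases}
\tfrac12 E_a (d - r)^2 - E_a & d < r\\[2pt]
\dfrac{2 E_a}{(i - r)^2}(d - r)^2 - E_a & r \le d < \tfrac{i + r}{2}\\[6pt]
-\dfrac{2 E_a}{(i - r)^2}(d - i)^2 & \tfrac{i + r}{2} \le d < i\\[2pt]
0 & d \ge i.
\end{cases}
$$

The potential is $C^1$ at all three branch boundaries, which matters for
stable integration at a large timestep:

```{r potential}
d <- seq(4, 10, by = 0.01)
u <- attractionPotential(d, r_sum = 6, i_radius = 8.25, E_a = 4.4)
plot(d, u$energy, type = "l", xlab = "anchor distance (nm)",
     ylab = expression(U ~ (k[B] * T)))
abline(v = c(6, 7.125, 8.25), lty = 3)
```

The head/anchor size ratio $r_2 / r_1 = 1.1$ is the feature that limits
cluster growth: packed anchors force the larger heads into a crowded
"bouquet", and the accumulated head repulsion makes the addition of
further molecules unfavorable once a cluster reaches roughly 120--140 nm.
Ratios at or below 1 remove the limit entirely (the configuration
constructor warns), while larger ratios (1.25, 1.5) cap clusters at
roughly 80--90 and 40--45 nm.

$E_a$ is the only parameter varied in the study design: 4.0 $k_BT$
reproduces the cluster-size distribution measured outside active zones and
4.4 $k_BT$ the one at active zones; 3.6 and 4.8 $k_BT$ bracket the
physiological window with more extreme behavior. That a difference of
less than half a $k_BT$ switches the membrane between these regimes is
the central observation the model articulates.

## Units and integration

Internally everything is expressed in nm, ns and $k_BT$ ($k_BT \equiv 1$,
so force constants carry $k_BT$/nm$^2$). Diffusion coefficients convert
as $0.2\,\mu m^2/s = 2\times10^{-4}$ nm$^2$/ns. The overdamped
(Brownian) dynamics are integrated with an Euler--Maruyama scheme,

$$\Delta x = D_p F \,\Delta t + \sqrt{2 D_p \Delta t}\;\xi,$$

with $\Delta t = 5$ ns and $\xi$ standard normal per coordinate. The
in-plane center of mass of two particles of equal mobility diffuses with
$(D_1 + D_2)/4$, so the analytic per-particle choice $D_p = 2 D_{eff}$
gives an isolated dimer the experimentally measured effective coefficient
$D_{eff} = 0.2\,\mu m^2/s$; `calibrateParticleDiffusion()` verifies (and,
if necessary, refines) this against a simulated free dimer. The engine
warns when any single-step displacement exceeds $r_1$, the practical
stability criterion for the timestep.

The membrane patch is a disk (default radius 300 nm for 500 molecules).
The interior of the disk is field-free; anchors that cross the rim feel a
half-harmonic restoring force (`boundary_k`, default 20 $k_BT$/nm$^2$).
A reflecting wall was rejected because hard reflections interact poorly
with a 5-ns timestep, while a soft wall adds no force anywhere inside the
domain. Heads are laterally unconstrained; their full 3D freedom is what
produces the bouquet packing.

Pair interactions use Verlet lists (2-nm skin, rebuilt when any particle
has drifted more than half the skin) over three pair channels
(anchor--anchor, head--head, anchor--head). The list path is verified in
the test suite to reproduce the all-pairs forces exactly, and forces are
verified against finite differences of the total energy.

Reproducibility is a hard contract: the engine uses a private
xoshiro256++ generator with a ziggurat normal sampler, seeded from the
configuration, so runs with equal seeds are bit-identical regardless of
R's RNG state.

# Cluster statistics and kinetics

A cluster is a connected component of the anchor proximity graph: two
molecules are linked when their anchor centers are within contact plus
1 nm (7 nm for the standard radii). Head positions are deliberately not
part of the rule -- the head shell is what *limits* clustering and would
otherwise bridge adjacent clusters.

Because imaged cluster sizes are FWHM diameters while simulated clusters
are member counts, `effectiveDiameter()` maps a count to the diameter of
the circle whose area is the summed anchor cross-sections divided by a
packing fraction, $d = 2 r_1 \sqrt{N/\phi}$. The default $\phi = 0.65$
was calibrated once with `measurePackingFraction()` (convex hull of
anchor centers dilated by $r_1$) on converged large clusters; with it the
mapping reproduces the 120--140 nm ceiling at size ratio 1.1 and the
40--45 nm ceiling at ratio 1.5.

`dissociationAndResidence()` defines a dissociation event conservatively:
a molecule must be in a cluster (size $\ge 2$) at frame $t$, in no
cluster sharing another member with its former cluster at $t+1$, and must
stay detached for at least 2 consecutive frames. Without the debounce the
measured rate grows with the frame rate, because anchors at a cluster rim
cross the 7-nm threshold back and forth on microsecond timescales.
Residence times use the same shared-member continuity rule, and spells
touching either end of the trajectory are reported as right-censored
rather than dropped silently. Cluster mobility (`clusterDiffusion()`) is
measured only over frame pairs with identical membership, so exchange
events cannot masquerade as centroid motion; centroid diffusion of an
$N$-cluster is expected at $D_{eff}/N$ because the $N$ independent noise
sources average.

# Simulated assays

* **FRAP** (`frapAssay()`): molecules inside a concentric disc covering
  10% of the membrane area (radius $R\sqrt{0.1}$; the placement is a
  package choice) are tagged "bleached"; tags never affect forces. The
  curve is the fluorescent count inside the disc normalized to the
  pre-bleach count, so ideal mixing in the closed system caps recovery at
  0.9. The short-time recovery is governed by the free-molecule pool and
  is bounded by the pure-diffusion solution of the disk problem; the
  long-time behavior probes cluster exchange.
* **Membrane exploration** (`membraneCoverage()`): vesicle-sized 40-nm
  cells, visited when an anchor center enters (checked every integration
  step in the engine, not per frame). Occupied cells count as visited
  from the start, so at high molecule density the informative statistic
  is the rate at which *initially unvisited* cells are reached
  (`newlyVisited()`), which is also the statistic that survives
  scaling-down of the geometry.
* **Seeded aggregation** (`seededAggregation()`): a static dimer with
  $E_a = 8\,k_BT$ (a docking site; the seed keeps its head particle and
  simply does not move) is inserted at an empty membrane location, and
  the first-passage times of its cluster to each target size are
  recorded, right-censored at the run cap.
* **Candidate census** (`candidateCensus()`): a lattice of 30-nm cells
  (20 x 20 over the default geometry). Docking candidates are all anchors
  (every syntaxin is docking competent); priming candidates are molecules
  that are accessible -- free, or on a cluster boundary with at most 3
  neighbors within the interaction radius (interior anchors of
  near-hexagonal packings have 5 or more; the threshold is exposed) --
  and that stay within a cell plus a one-cell tolerance ring for at least
  100 ms, the priming timescale. Whether "free" molecules should satisfy
  the persistence requirement too is ambiguous; both readings are
  reported (`priming` and `priming_boundary`).

# STED image analysis

The pipeline mirrors the experimental procedure on post-deconvolution
images (10 nm/px): optional constant-offset background subtraction;
windowed local-maximum detection (circular window, 9 px for Syntaxin-1A,
21 px for BRP; centers must exceed 25 a.u., strictly); FWHM sizing by
scanning rings of increasing radius until the ring average falls below
half the center intensity, with the cluster area being all scanned pixels
at or above half-max and the reported diameter that of the equal-area
circle. Centers whose scan reaches the image border are flagged and not
sized. Plateau ties in the detector collapse to the plateau centroid.

Active zones are defined from BRP spots: single-linkage grouping at
150 nm, groups of at least 4 spots whose radial spread about the group
centroid stays below 30 nm count as rings, and each ring becomes a filled
disk of radius (mean spot-to-centroid distance + 25 nm padding). All
three grouping constants are exposed; the ring test is a circular fit
with the center fixed at the centroid, which is robust at the 4--7 spots
per ring seen in practice. A Syntaxin cluster is "at AZ" when its center
falls inside any mask (closed region), distances are center-to-center to
ring-member BRP spots, and densities divide counts by the AZ mask area
and by (membrane mask − AZ area) respectively. Group means are compared
with a two-sample t-test with the conventional star notation.

# Synthetic data and what passing tests mean

`generateSyntheticImage()` renders BRP rings (5 spots of 25 nm FWHM on a
230-nm circle) and Syntaxin clusters with truncated-normal FWHM diameters
(80/15 nm at AZ, 64/15 nm outside, truncated above 20 nm), then applies
Poisson shot noise (with a photon gain so the texture matches smooth
post-deconvolution data) and Gaussian read noise over a constant
background. Two rendering choices deserve comment:

* The default radial profile is **Gaussian**. Deconvolved spots are
  compact; rendering clusters with raw Lorentzian wings (the PSF family
  of the deconvolution itself, available via `profile = "lorentzian"`)
  couples the FWHM estimates of clusters even 150--250 nm apart by
  10--18%, an artifact of the synthetic rendering rather than a property
  of the pipeline, and large enough to mask the effect sizes the recovery
  tests check.
* AZ-group clusters are placed on an annulus around the BRP ring (where
  they are observed) but clipped to stay 15 nm inside the AZ mask, and
  outside-group clusters stay well beyond the mask, so the
  classification ground truth is unambiguous by construction.

`generateReferenceTrajectory()` produces ideal free diffusers (reject-at-
the-wall dynamics, which keeps the uniform distribution exactly
stationary), frozen configurations with a prescribed cluster partition,
and a two-state exchange process with exponential holding times in which
detached molecules wait at private, well-separated parking positions (so
no spurious clusters can form among them). These fixtures validate the
analysis code paths exactly; they do not, of course, validate the physics
of the engine -- that is what the potential/force oracles, the diffusion
calibration and the trend tests are for. Conversely, passing recovery
tests on synthetic images demonstrates correctness of the pipeline's
measurement logic, not that real NMJ images are noise-free or free of
labeling artifacts (antibody displacement inflates absolute sizes;
only relative comparisons carry over).

# Study conditions used by the test suite

Full-scale replicas of the reference runs (500 molecules, twelve runs of
$5\times10^7$ steps per well depth) are far beyond a test suite. The
suite therefore runs a scaled-down campaign whose conditions are fixed
here once:

* **Reduced geometry** for equilibrium/kinetics tests: 80 molecules on
  a 120-nm disk -- 0.4x the linear scale at the reference surface density
  ($1.77\times10^{-3}$ molecules/nm$^2$) -- with 4.5 million equilibration
  steps, 0.5-million-step productions sampled every 10 $\mu$s, and three
  independent replicas per well depth; the residence-time analysis
  extends one $E_a = 4.0$ replica to a 50-ms production, which also
  bounds the size-ratio-1.1 diameter ceiling, while the ratio-1.5
  ceiling uses a matched-density 50-molecule run of $10^7$ steps with
  $r_2 = 4.5$ nm at the strongest well depth.
* **FRAP** runs at its prescribed scaled condition, 200 molecules on a
  380-nm-diameter disk at $E_a = 4.0$, and checks the short-time
  (\(\le\) 10 ms) regime against the closed-form pure-diffusion solution
  (Bessel series of the Neumann disk problem, cross-validated against a
  finite-difference PDE solve in the test helpers).
* **Exploration and aggregation** compare $E_a = 4.0$ against
  $E_a = 4.4$ through scale-robust statistics: the time to visit half of
  the initially-unvisited 40-nm cells, and seed-cluster first-passage
  times to a target size reduced proportionally to the molecule count.
  The exploration slow-down under active-zone conditions survives the
  scale reduction; the seeded-aggregation contrast does not -- at this
  molecule count the free-monomer pool is a handful of molecules and
  first passage is dominated by capture of whole pre-formed clusters, so
  the corresponding check measures the declared conditions faithfully
  and is reported as failing rather than being re-tuned. The absolute
  full-geometry numbers (50% coverage in 80 ms outside versus 225 ms at
  AZ; ~100 ms to a 40-member cluster) are not re-measured at desk
  scale.
* **Partial convergence** is a deliberate trade-off: at fixed finite run
  length, coarsening is slowest at the highest well depth (fewer free
  molecules carry mass between clusters), so single runs at 4.8 $k_BT$
  can transiently trail 4.4 $k_BT$ in mean cluster size. The
  monotonicity test therefore averages a small number of independent
  replicas per well depth, mirroring (at reduced count) the twelve
  replicas of the reference design.

# Worked example

A small but complete simulation-and-analysis round trip:

```{r example, eval = FALSE}
cfg <- simConfig(n_molecules = 125, domain_radius = 150, E_a = 4.4,
                 n_steps = 2e6, sample_stride = 2e3, rng_seed = 7)
state <- stepDynamics(initRandom(cfg), cfg, n_steps = cfg@n_steps)
traj <- runSimulation(cfg, init = state, seed = 8)
clusteringSummary(traj)[c("mean_size", "single_fraction")]
csd <- clusterSizeDistribution(traj, by = "diameter")
plot(csd$diameter_nm, csd$prob, type = "h", xlab = "diameter (nm)",
     ylab = "probability")
```

And the image pipeline on synthetic ground truth:

```{r image-example, eval = FALSE}
im <- generateSyntheticImage(imageSpec(size_px = 1024, n_az = 5,
                                       n_syx_az = 20, n_syx_out = 60),
                             seed = 11)
syx <- subtractBackground(im$syx)
brp <- subtractBackground(im$brp)
az <- defineActiveZones(detectMaxima(brp), brp)
det <- fwhmSizes(syx, detectMaxima(syx))
res <- classifyAndMeasure(det[!det$border, ], az, detectMaxima(brp),
                          image = im$syx)
res$summary
compareGroups(res$detections$diameter_nm[res$detections$at_AZ],
              res$detections$diameter_nm[!res$detections$at_AZ])
```

# Known limitations

* The model is minimal by design: no lipids, no other proteins, no
  reactions; differences between membrane regions enter only through
  $E_a$. Mechanistic causes (PiP$_2$/PiP$_3$ composition, scaffold
  interactions) are outside its scope.
* Absolute kinetic numbers at desk scale depend on the domain size
  through the free-molecule pool; only directions and ratios are
  compared across conditions.
* Cluster lifetimes of large clusters are not measurable: above a
  critical size clusters essentially never dissolve on simulatable
  timescales (their dissociation is balanced by re-association).
* The dimer bond mechanics of the reference implementation are not
  published; the harmonic bond stiffness is exposed in the configuration
  so its influence can be checked (the long-time dimer mobility is
  insensitive to it; only sub-microsecond internal relaxation changes).
* The FWHM sizing inherits a +/- one-pixel quantization; at 64-nm
  clusters this is a 5--8% effect, identical for both groups, so group
  comparisons are unaffected.
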