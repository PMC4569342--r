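# SyxDynamics

Particle-based simulation and STED image analysis of Syntaxin-1A membrane
nanoclusters.

## The problem

Syntaxin-1A, the plasma-membrane t-SNARE required for synaptic vesicle
fusion, covers the entire presynaptic membrane but self-organizes into
nanoclusters of ~60–100 nm. STED microscopy of Drosophila neuromuscular
junctions shows these clusters are larger (~80 nm vs ~64 nm mean FWHM
diameter) and denser at active zones — the release sites marked by
Bruchpilot (BRP) rings — than elsewhere. `SyxDynamics` implements, as a
single tested R package:

- a Brownian-dynamics model of Syntaxin-1A clustering: each molecule is a
  dimer of a membrane anchor (radius r₁ = 3 nm, carrying a
  piecewise-harmonic attraction of well depth `E_a` with interaction
  radius 2r₁ + 2.25 nm) and a bulky head (r₂ = 3.3 nm, soft-core
  repulsion) whose size ratio r₂/r₁ = 1.1 caps cluster growth at
  120–140 nm. Dynamics are overdamped Euler–Maruyama steps
  Δx = D_p F Δt + √(2 D_p Δt) ξ with Δt = 5 ns, calibrated so a free
  dimer diffuses at D = 0.2 μm²/s. `E_a` = 4.0 k\_BT reproduces the
  cluster-size distribution outside active zones, 4.4 k\_BT the one at
  active zones;
- trajectory analyses: distance-cutoff cluster identification (anchors
  within 7 nm), size distributions, cluster diffusion (∝ 1/N),
  step-length distributions, dissociation rates and residence times;
- simulated assays: FRAP (10% bleach disc), membrane exploration on a
  40-nm vesicle-sized lattice, seeded aggregation at a static 8-k\_BT
  docking site, and a docking/priming candidate census on 30-nm cells;
- the STED quantification pipeline: windowed local-maximum detection
  (9 px / 21 px circular windows, > 25 a.u.), FWHM sizing by ring scans,
  BRP-ring active-zone definition (25 nm padding), AZ/outside
  classification, densities, and t-test group comparisons;
- synthetic two-channel image and trajectory generators with exact ground
  truth, so every stage is testable without any external data.

## Worked example

```r
library(SyxDynamics)

cfg <- simConfig(n_molecules = 125, domain_radius = 150, E_a = 4.4,
                 n_steps = 2e6, sample_stride = 2e3, rng_seed = 7)
state <- stepDynamics(initRandom(cfg), cfg, n_steps = cfg@n_steps)
traj  <- runSimulation(cfg, init = state, seed = 8)
cs <- clusteringSummary(traj)
cs$mean_size
#> [1] 6.093097
cs$single_fraction
#> [1] 0.05793875
```

After 20 ms at active-zone conditions the 125 molecules have condensed
into clusters of ~6.1 molecules on average, the largest holding 38
molecules (~46 nm effective diameter at this reduced scale), while only
~6% of molecules remain free — the balance between a large clustered
reserve and a small mobile pool that the model is built to expose.

The image pipeline, on a synthetic two-channel field with known ground
truth (5 BRP rings, 20 AZ-group and 60 outside-group clusters):

```r
im  <- generateSyntheticImage(imageSpec(size_px = 1024, n_az = 5,
                                        n_syx_az = 20, n_syx_out = 60),
                              seed = 11)
syx <- subtractBackground(im$syx)
brp <- subtractBackground(im$brp)
az  <- defineActiveZones(detectMaxima(brp), brp)
det <- fwhmSizes(syx, detectMaxima(syx))
res <- classifyAndMeasure(det[!det$border, ], az, detectMaxima(brp),
                          image = im$syx)
res$summary$mean_diameter_az
#> [1] 74.84308
res$summary$mean_diameter_out
#> [1] 64.7737
```

against generated group means of 75.7 nm (at AZ) and 65.5 nm (outside)
for this seed — recovery within ~1 nm, with all 5 rings found and every
cluster classified into its true group.

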