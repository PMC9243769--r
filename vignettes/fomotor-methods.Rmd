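---
title: "Model and methods: proton-transfer-coupled rotation of the Fo motor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: proton-transfer-coupled rotation of the Fo motor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fomotor)
```

## The model

The Fo motor of ATP synthase converts the proton motive force (pmf) across
the inner mitochondrial membrane into rotation of its c-ring. `fomotor`
implements a coarse-grained hybrid scheme in which proton chemistry and
ring mechanics alternate:

* an **MC phase** re-equilibrates the two half-channel glutamates (aE223 on
  the intermembrane-space side, aE162 on the matrix side) with their bulk
  reservoirs and then attempts geometry-gated proton transfers between the
  twelve carrier sites (ten c-ring glutamates cE59 plus the two channel
  glutamates);
* an **MD segment** propagates the ring angle by overdamped Langevin
  dynamics on the electrostatic energy surface of the current protonation
  state.

The protonation state is a binary vector $h$ over the carrier sites, with
$h_i = 0$ for a protonated (neutral) and $h_i = 1$ for a deprotonated
(charge $-1$) glutamate. The total energy, in units of $k_BT$, is

$$V_{total}(R, H^+) = V_{non\text{-}es}(R) + V_{es}(R, H^+) + V_{pKa}(H^+),$$

where $V_{non\text{-}es}$ maintains the structure (identically zero for the
default rigid rotor; an elastic network in bead mode), $V_{es}$ is a
Debye–Hückel-screened Coulomb sum over all charged sites plus a membrane
burial penalty for deprotonated carriers facing lipid, and
$V_{pKa} = -\ln(10)\,k_BT \sum_i pKa_i\,(1 - h_i)$ is the intrinsic
protonation preference.

Channel glutamates are assumed to stay at local equilibrium with their
reservoirs (water in the half-channels shuttles protons quickly), with
protonation energies

$$\epsilon_{aE223} = \ln(10)\,k_BT\,(pH_{IMS} - pKa_{aE223}) - \Delta\Psi/2,
\qquad
\epsilon_{aE162} = \ln(10)\,k_BT\,(pH_{matrix} - pKa_{aE162}) + \Delta\Psi/2,$$

the half-potential reflecting the mid-membrane position of the carrier
sites; each MC phase redraws the channel states with probability
$P(\epsilon) = e^{-\epsilon}/(1 + e^{-\epsilon})$ of being protonated.

A proton transfer from donor $i$ to acceptor $j$ requires that exactly one
of the pair is protonated, that they are close, that their side chains are
mutually oriented, and that the pair does not straddle the conserved
arginine aR176 separating the two half-channels. The last three criteria
form the kinetic weight $w_{j \leftarrow i} = f(r)\,g(\theta)\,h_{aR176}$,
and the move is accepted with probability

$$p = \left(1 - e^{-k\tau\,w_{j\leftarrow i}}\right)\,
      \min\!\left(1, e^{-\Delta E/k_BT}\right),
\qquad \Delta E = V_{total}(R, H^+_{after}) - V_{total}(R, H^+_{before}),$$

with $k\tau = 1$ by convention. The per-proton driving energy is
$\ln(10)\,\Delta pH + e\Delta\Psi/k_BT$; one pH unit contributes
$\ln 10 \approx 2.3\,k_BT$ and the default 150 mV a further
$\approx 5.8\,k_BT$ at 300 K.

## Standard conditions and key parameters

| parameter | default | units | role |
|---|---|---|---|
| `pH_ims`, `pH_matrix` | 7.0, 8.0 | pH | reservoir chemistry |
| `pKa` (aE223, cE59, aE162) | 6.0, 8.0, 9.0 | pH | intrinsic affinities; the rising ladder biases IMS-to-matrix transport |
| `delta_psi` | 150 | mV | membrane potential; enters the channel energies as $\pm\Delta\Psi/2$ only |
| `temperature` | 300 | K | fixes the mV-to-$k_BT$ conversion (25.85 mV per $k_BT$) |
| `debye_length`, `dielectric`, `coulomb_cutoff` | 10, 20, 30 | Å, –, Å | screened Coulomb model |
| `membrane_penalty` | 8 | $k_BT$ | burial cost of a lipid-facing deprotonated carrier; chosen to exceed the total pmf (~8 $k_BT$) so carriers are effectively proton-locked outside the a-subunit sector |
| `k_tau`, `r0`, `lambda`, `r_max` | 1, 4, 2.5, 15 | –, Å, Å, Å | transfer kinetics: $f(r)=1$ below `r0`, $e^{-(r-r_0)/\lambda}$ to `r_max`, 0 beyond |
| `theta_ref`, `sigma` | from geometry (~165°), 20° | deg | Gaussian side-chain angle factor $g(\theta)$ |

The electrostatic functional form and its constants are model choices: the
scheme requires a screened pair interaction and a burial penalty, not a
particular dielectric theory. A uniform relative dielectric of 20 is a
compromise for the membrane/protein interior; the prefactor reproduces the
unscreened Coulomb energy of two unit charges at 1 Å in that dielectric.

## The synthetic geometry

`build_synthetic_geometry()` is a first-class model component, not a test
fixture: it realizes the geometry the energy and kinetic models assume. Ten
carrier sites sit at 36° spacing on a 25 Å ring at mid-membrane; the
a-subunit contributes the two channel glutamates and the arginine inside a
±50° a-facing sector (outside it, the lipid weight rises smoothly over a
10° switch and the burial penalty applies). Side chains are radial unit
vectors — outward for c-sites, inward for a-sites — so the angle factor
peaks for carrier/channel pairs at small azimuthal separation and strongly
suppresses carrier-to-carrier hops (their side chains are near-parallel).

Three geometric choices deserve justification because the experimental
structure constrains them only loosely:

* **Channel azimuths ±25°.** Each half-channel must sit adjacent to the
  carrier track (3 Å radial gap: contact distance ~3 Å at matching
  azimuth), on opposite sides of the arginine, with a separation that is
  *not* a multiple of the 36° subunit spacing — at ±18° a stationary ring
  can bridge both channels with adjacent subunits and protons slip through
  without rotation (the measured coupling drops to ~22°/proton). ±25° keeps
  the channels adjacent to distinct subunits and additionally places
  straddling donor/acceptor pairs within (the tail of) transfer range, so
  the arginine gate is a live constraint rather than a vacuous one.
* **Arginine radial offset 6 Å.** The guanidinium sits farther from the
  carrier track than the channel carboxylates. Electrostatically this turns
  its attraction to a deprotonated carrier into a broad well of ~2.4
  $k_BT$ that localizes the charge between the two channels without
  freezing the ring; placed at the channels' 3 Å gap the well is ~7 $k_BT$
  deep and ~10° wide and the motor stalls.
* **Transfer decay length λ = 2.5 Å with a 15 Å hard cutoff.** The
  plateau below 4 Å reflects the hydrogen-bond contact distance the
  carboxylates can reach; the 2.5 Å tail lets transfers occur over the
  ~10–13 Å separations that arise while a carrier waits near the arginine,
  which is what gives the arginine-deleted mutant a leak pathway.

All of these remain arguments; the narrower values are one `mc_params()` or
`build_synthetic_geometry()` call away.

Experimental structures are supported through `load_ca_structure()`
(PDB/mmCIF via \pkg{bio3d}, model 1, Cα only): the ring axis and radius are
fit to the carrier positions by least squares, the frame is re-expressed
with the axis along +z and the arginine at azimuth 0, and side-chain
directions are synthesized radially, since a Cα model carries none.

## Dynamics, units and numerics

The default mechanical model is a rigid rotor: all in-scope observables are
functions of the ring angle and the protonation vector, so one Langevin
degree of freedom suffices. Time is reduced: one MD segment spans one
segment-time unit, split into 800 Euler–Maruyama steps of $dt = 1.25
\times 10^{-3}$ (the original protocol's $10^5$ steps per segment
correspond to $dt = 10^{-5}$ in these units; the package default preserves
the segment diffusion time while keeping the per-step drift well below the
width of the contact-scale Coulomb wells). The rotational friction
$\gamma = 1/648\ k_BT\,\mathrm{time/deg^2}$ makes a free ring diffuse 36°
RMS — one subunit spacing — per segment, keeping the MC and MD timescales
comparable. Velocities are therefore reported in degrees per MC phase;
no mapping to physical seconds is implied.

Within a segment the protonation state is fixed, so the angle-dependent
part of $V_{total}$ is a fixed smooth periodic function of one variable.
The integrator therefore works from a force table precomputed on a 0.25°
grid (`make_rotor_field()` tabulates per-carrier kernels once per run;
`rotor_force_grid()` assembles a state's table in a few vector additions),
with linear interpolation between nodes. A step exceeding 8° aborts with
advice to reduce `dt` — at the default settings the thermal step is 1.3°
RMS, so only a genuinely unstable configuration trips the guard. Setting
`kbt = 0` turns the integrator into gradient descent, which the test suite
uses to locate potential minima independently of the sampler.

Ties and degenerate inputs are resolved explicitly: eligible transfer
pairs are visited in a uniformly random permutation with sequential
$\Delta E$ updates and at most one accepted move per site per phase; the
modal deprotonation count reports the smallest mode with a tie flag;
antipodal site pairs (exactly 180° apart) count as straddling whenever the
arginine is not collinear with them; empty histogram bins are masked, not
interpolated, in free-energy curves.

## Mutant models

* `carrier_e_to_d`: aspartate's shorter side chain and lower intrinsic
  affinity enter as `delta_r = +1.5` Å of effective transfer distance and
  `delta_pka = -1.0` on the named subunits only. The slowed step for a
  mutated subunit is proton uptake, and adjacent double mutants can share a
  single waiting period while distant ones pay twice — the origin of the
  spacing-dependent velocity ordering probed by `mutant_scan()`.
* `arginine_to_ala`: the leakage gate $h_{aR176}$ is replaced by unity;
  the +1 charge is kept, which is the literal mutant model (pass
  `drop_charge = TRUE` for a full physical ablation). Straddling transfers
  then occur from the waiting position near the arginine, and
  `detect_leaks()` counts them together with carrier itineraries that move
  a proton between the channels with less ring rotation than the 10°
  window (configurable).

## Free energies

`sample_angles_fixed_h()` runs MC-free dynamics at a fixed protonation
vector; `fes_angle()` turns the sampled angles into
$F(\phi) = -\ln(\text{normalized histogram})$ (2° bins by default).
`bar_delta_f()` estimates the free-energy difference between two
protonation states from cross-evaluated energies by solving the Bennett
acceptance-ratio self-consistency equation (root-finding to $10^{-6}$
$k_BT$), with a block-bootstrap standard error (50-sample blocks) and an
overlap diagnostic that warns when the forward and reverse work
distributions barely share support. Curves for different states can be
aligned by adding the BAR offsets.

## What the tests do and do not show

The test suite exercises the model at desk scale: standard-condition runs
of 2,000 phases after 200 burn-in across 5 seeds (about 10 s per run), a
10-seed equilibrium null at zero pmf, 5 + 5 drive-reversal runs, an exactly
enumerable two-carrier toy for Monte-Carlo/Boltzmann consistency,
harmonic-well checks of the Langevin sampler and of BAR against closed
forms, and the mutant scans. Under those conditions the simulations
reproduce the signature behaviour of the motor: directed rotation in the
synthesis direction, close to 36° of rotation per proton delivered to the
matrix channel, a modal count of two simultaneously deprotonated carriers,
zero straddling transfers in the wild type, and leak events with degraded
coupling once the arginine gate is removed.

The generator emulates the layout and energetics the model assumes — it
does not emulate real data. Passing tests show internal consistency of the
scheme and agreement with its own closed-form limits, not quantitative
agreement with experimental rotation rates: there is no explicit lipid or
water, no conformation-dependent pKa, no elastic compliance in the default
rotor, and the simulated-time axis is arbitrary.

## Known limitations

* The reverse (hydrolysis-direction) flux under a reversed pmf is
  kinetically much weaker than the forward flux, because the rising pKa
  ladder (6 → 8 → 9) that speeds synthesis-direction hops Metropolis-
  penalizes every reverse hop; the sign still reverses, which is what the
  suite asserts.
* The arginine-deleted mutant leaks robustly, but its loss of coupling at
  desk scale is small (a ~1°/proton drop in the coupling ratio, comparable
  to seed-to-seed noise), with none of the strong suppression a
  structurally relaxing model would show: a rigid rotor cannot lose the
  structural organization of the a/c interface, only its gate.
* Configs serialize to YAML with ~15 significant digits; parameters exactly
  representable at that precision round-trip bit-exactly, others to ~1
  part in $10^{15}$.
* Bead mode supplies the elastic-network energetics and per-bead dynamics
  for structure-based work but is not wired into the full MC/MD engine;
  the rigid rotor is the production path.
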