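---
title: "Methods: mesoscale polymer transport in slit nanochannels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesoscale polymer transport in slit nanochannels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package simulates

`slitflow` couples a particle-based mesoscale solvent (multiparticle
collision dynamics, MPCD, in its stochastic-rotation form) to a single
coarse-grained bead-spring polymer confined between two parallel hard walls.
The solvent carries hydrodynamic interactions and thermal fluctuations; the
chain is a Kremer–Grest model (WCA excluded volume between all monomer
pairs, FENE bonds, optional harmonic bending). Flows are driven by body
forces: a constant force density for Poiseuille (pressure-like) flow, or an
implicit-ion electroosmotic (EO) force density $\rho_{el}(z)\,eE$ obtained
from the nonlinear Poisson–Boltzmann (PB) charge distribution between
charged plates. The observables are the quantities that diagnose
flow-induced lift and hydrodynamic focusing: the monomer density across the
channel, the gyration tensor and asphericity (overall and conditioned on
chain position), transport velocities of fluid and chain, persistence
length, and the Zimm time / Weissenberg number.

All quantities are in MPCD units: fluid particle mass $m_f$, collision cell
edge $a_0$, thermal energy $k_BT$, and the derived time
$t_0 = a_0\sqrt{m_f/k_BT}$. The physical scale enters only through one named
constant, $a_0 = 0.147$ nm, fixed by the correspondence
$L_z = 17\,a_0 \leftrightarrow 2.5$ nm of the reference geometry.

# The solvent and its boundary conditions

Each MPCD step streams point solvent particles ballistically for
$\delta t_c$ under the body force (velocity-Verlet half-kick / drift /
half-kick; the force acts along $x$ and depends at most on $z$, so the
kick–drift split is exact), then sorts all particles — solvent and monomers —
into cubic cells of edge $a_0$ on a randomly shifted grid and rotates the
velocities relative to each cell's mass-weighted center-of-mass velocity by
$\alpha$ about a per-cell random axis. Momentum is conserved cell-wise to
machine precision; the random grid shift restores Galilean invariance.
Default fluid parameters: $\rho = 5\,a_0^{-3}$, $\alpha = 130^\circ$,
$\delta t_c = 0.1\,t_0$, for which the measured kinematic viscosity is
$\nu = 0.81\,a_0^2/t_0$ (dynamic $\eta = \rho\,\nu = 4.05$). The
kinetic-theory estimate for these parameters, available as
`srd_viscosity_theory()`, is $0.792$ and serves as an independent
cross-check of the transport measurement, never as its source.

**Thermostat.** Nonequilibrium runs need a thermostat. We use cell-level
Maxwell–Boltzmann *scaling*: after each collision the relative kinetic
energy of every cell is rescaled to a draw from
$\Gamma\!\left(\tfrac{3}{2}(N_c-1), k_BT\right)$, which preserves the cell
momentum exactly, realizes the correct Maxwellian relative-velocity
statistics, and—unlike a full velocity resampling—does not disturb the SRD
transport coefficients (a resampling thermostat would act as a strong
additional collision and lower the viscosity). The choice is isolated in one
function.

**Walls.** No-slip walls at $z = \pm L_z/2$ are realized by the stochastic
reflection rule (SRR): a particle whose trajectory segment crosses a wall
plane is restored to the impact point and re-emitted with tangential
velocities Maxwellian at the wall temperature and the normal component
flux-weighted (Rayleigh) into the fluid; the remaining flight time is then
spent. Streaming needs no subdivision into smaller steps. On its own,
however, the SRR leaves a slip layer of the order of the cell size: the
wall-truncated collision cells created by the grid shift transmit almost no
collisional stress to the wall. Clamping the grid shift along $z$ would
remove the truncated cells but destroys collisional momentum transport
across $z$ (most of the viscosity), so the engine instead uses virtual
wall particles: every wall-cut cell's center-of-mass reference includes a
virtual member of mass $\rho \times$ (cut volume) with Maxwellian momentum
at the resting wall temperature. The residual slip is then below 5% of
$v_{max}$ and is measured and reported by `measure_viscosity()`, not
silently corrected. Momentum absorbed by the walls — during streaming and
through the virtual members — is tallied, and the package's tests verify the
global ledger (body-force input = fluid momentum change + wall absorption)
to $10^{-8}$ relative.

The thermostat target for a wall-cut cell uses
$\tfrac{3}{2}\,(N_c - 1 + m_{virt}/m_{sum})$ degrees of freedom: the virtual
member ties the reference frame only partially, and the corrected count
keeps the fluid temperature flat (to $\sim$0.1%) across the whole channel.

# Electrostatics and flow drivers

The EO driver needs the equilibrium mobile-charge profile between the
charged plates. `solve_pb_no_salt()` and `solve_pb_with_salt()` solve the
nonlinear PB boundary-value problem in reduced units
($\phi'' = -4\pi l_B \rho_{el}(\phi)$, Gauss's law
$\phi'(\pm L_z/2) = \mp 4\pi l_B \Sigma$) by RK4 shooting from the midplane
with a `uniroot` match at the wall; both regimes share this one code path,
and the counterion-only closed form ($\rho_{el} \propto \sec^2 Kz$ with
$K\tan(KL_z/2) = 2\pi l_B\Sigma$) is reserved for validation. Defaults:
$\Sigma = 0.5\,e/\mathrm{nm}^2$, Bjerrum length $l_B = 0.718$ nm. The two
screening constants used by the channel studies, $\kappa = 0.23\,a_0^{-1}$
(no added salt) and $\kappa = 0.47\,a_0^{-1}$ (2 mol/L 1:1 salt), are pinned
as named run constants: no textbook bookkeeping of the Debye sum reproduces
them exactly from $a_0 = 0.147$ nm (2 mol/L gives $0.685\,a_0^{-1}$), so the
`debye_kappa()` utility that evaluates
$\kappa = \sqrt{4\pi l_B \sum_\alpha Z_\alpha^2 c_\alpha}$ is exposed
separately from the pinned values, and the added-salt solver accepts either
a concentration or a $\kappa$ override (which fixes
$c_s = \kappa^2/8\pi l_B$).

Stationary reference profiles come from the 1D Stokes balance: the parabola
$v_{max} = fL_z^2/8\eta$ for a constant force *density* $f$, and a double
cumulative trapezoid of $-\rho_{el}(z)\,eE/\eta$ for EO flow. Flow types are
compared at equal average shear
$\dot\Gamma = \langle|\partial v/\partial z|\rangle$, which for any no-slip
single-maximum profile telescopes to $2v_{max}/L_z$ — fixing $\dot\Gamma$ is
therefore the same as fixing $v_{max}$, and `match_amplitude()` exploits the
linearity of Stokes flow to calibrate any driver to a target $v_{max}$ with
a single solve. Inside the simulator the force density is shared among the
$\rho$ solvent particles per unit volume ($f/\rho$, or
$\rho_{el}(z)eE/\rho$, per particle), so the momentum input per volume
equals the Stokes force density; monomers receive no direct body force and
are driven purely through collisions with the solvent.

# The chain and its wall interactions

Kremer–Grest defaults: $N = 40$, $\sigma = a_0$, $\epsilon = k_BT$,
$k = 30\,\epsilon/\sigma^2$, $R_0 = 1.5\,\sigma$, monomer mass $M = 5 m_f$
(the mean solvent mass per cell). The combined FENE+WCA bond minimum sits at
$0.9609\,\sigma$. Monomers are integrated by velocity Verlet with
$\delta t_{MD} = 0.01\,\delta t_c$ between collisions; a trajectory that
destabilizes at the configured substep is retried once with the substep
halved, and bond overstretch otherwise aborts the affected seed with a
diagnostic rather than being silently clamped. Monomer–wall excluded volume is the SRR
rule itself, exactly as for the solvent.

**Semiflexible chains.** Bending is harmonic in the bond angles,
$U = \tfrac{\epsilon_{bend}}{2}\sum_i \theta_i^2$, and the persistence
length is defined through the bond-angle fluctuations,
$L_p = 2\sigma/\langle\theta^2\rangle$. Small-angle equipartition gives
$\epsilon_{bend} \approx L_p k_BT/\sigma$; `calibrate_bending()` refines
this by secant iteration against Monte Carlo estimates (the spherical
$\sin\theta$ measure shifts the realized $\langle\theta^2\rangle$ by a few
percent, landing near $\epsilon_{bend} = 9.3\,k_BT$ for $L_p = 10\sigma$).
A caveat worth stating: for this discrete model the Benoit–Doty worm-like
chain prediction at $L_p = 10\sigma$, $N = 40$ is $R_g \approx 8.0\,a_0$
(excluded volume adds $\sim$1%), and our sampler reproduces that; a bulk
stiff-chain $R_g$ of $10.5\,a_0$ would require $L_p \approx 60\sigma$, so
the two reference numbers sometimes quoted together for this system are
mutually inconsistent, and the package follows the calibration contract
($L_p$), reporting the $R_g$ it actually computes.

**Screened wall attraction.** Monomers may feel a van der Waals attraction
to induced dipoles localized at the two fluid–solid boundaries, screened by
the implicit ions: the pair kernel $-w\sigma^6 e^{-\kappa r}/r^6$ integrated
over a wall plane gives, per wall,
$$U_{w}(d) = -2\pi\, n_s\sigma^2\, w\,\sigma^6\, \frac{E_5(\kappa d)}{d^4},$$
with $E_5$ the order-5 exponential integral and $d$ the distance to the
wall plane. Two regularizations are unavoidable and documented:

* the plane integral diverges at contact while the only wall repulsion is
  the SRR plane, so the energy is held constant (zero force) inside one
  monomer size $d < \sigma$ — the exact closed form applies everywhere
  $d \ge \sigma$, and each wall's contribution is cut off at $8/\kappa$ with
  an energy shift to zero;
* the dimensionless site density $n_s\sigma^2$ of the boundary dipoles is a
  model parameter. Its default, $1/2\pi$ (contact well $\approx -0.19\,k_BT$
  per monomer at $\kappa = 0.23$), is calibrated on equilibrium behavior:
  with it, $w = k_BT$ leaves the flexible chain's conformation statistics
  ($R_g$, asphericity) unchanged and shifts the equilibrium monomer
  distribution only mildly toward the walls (about +9% in mean $|z|$ in the
  wide channel — thermal occupation of the shallow contact well, not
  adsorption), which is the defining phenomenology of the "weak vdW" regime
  this model targets; the bare plane integral ($n_s\sigma^2 = 1$) instead
  makes even flexible chains adsorb.

With added salt ($\kappa = 0.47$) the same $w$ is more strongly screened —
the contact well shrinks by about a quarter — reproducing the intended
salt-dependence of the wall attraction.

# Equilibrium sampling: the chain Monte Carlo

`chain_mc()` samples the exact chain Hamiltonian without solvent: per sweep,
$N$ single-bead Metropolis displacements, one rigid $z$-translation of the
whole chain (wall energies only — this equilibrates the slow center-of-mass
coordinate across the channel), and two pivot rotations of the chain tail
about a random interior vertex (these decorrelate $R_g$ within a few
sweeps). Collisional-coupling MPCD conserves the equilibrium ensemble, so
the Monte Carlo sampler doubles as the independent statics oracle for the
dynamics engine: the tests compare $R_g$ and the confined monomer density
between the two routes. Bulk flexible-chain sampling gives
$R_g = \sqrt{\langle \hat R_g^2\rangle} = 4.19\,a_0$ at $N = 40$, the
reference length scale $R_{g,b}$ used to express channel widths
($L_z = 17 a_0 \approx 4.1 R_{g,b}$, $34 a_0 \approx 8.2 R_{g,b}$).

# Observables

For each stored conformation the gyration tensor
$G_{\alpha\beta} = \frac{1}{N}\sum_i (r_{i\alpha}-r_{cm,\alpha})
(r_{i\beta}-r_{cm,\beta})$ yields $\hat R_g^2 = \mathrm{tr}\,G$ and, from
the ordered eigenvalues $\lambda_1\le\lambda_2\le\lambda_3$, the
asphericity
$b = [(\lambda_3-\lambda_2)^2 + (\lambda_3-\lambda_1)^2 +
(\lambda_2-\lambda_1)^2] / [2(\lambda_1+\lambda_2+\lambda_3)^2] \in [0,1]$
(0 = sphere, 1 = rod). Reported $R_g$ values are root-mean-square over the
ensemble. Monomer density profiles are probability densities (unit integral
over the channel) in bins of $0.25\,a_0$; asphericity profiles condition on
the chain center-of-mass bin (width of order $R_{g,b}/2$) and flag bins
with fewer than 100 pooled samples, because near-wall bins are rarely
visited and noisy. Error bars come from independent trajectories (the
reference protocol uses at least four seeds); the Monte Carlo routines also
correct their standard errors by an integrated-autocorrelation factor.

Time scales: the Zimm (slowest internal) relaxation time is evaluated in
closed form,
$$\tau_Z = \frac{\eta\,\sigma^3 N^{3\nu_F}}{\sqrt{6}\,\pi\,k_BT},
\qquad \nu_F \simeq 0.588,$$
and the Weissenberg number compares it with the flow time $L_z/v_{max}$
(the inverse average shear rate): $Wi = \tau_Z v_{max}/L_z$. For the
strongest flow ($v_{max} = 1.644\,a_0/t_0$ at $L_z = 34\,a_0$, and equally
$0.822$ at $17\,a_0$), $\tau_Z \approx 353\,t_0$ and $Wi \approx 17$: the
chain cannot relax between shear events, the regime where lift forces and
hydrodynamic focusing are strong.

# What the initial-state generator does and does not emulate

`build_initial_state()` places the solvent uniformly at the target density
with Maxwellian velocities, grows the chain as a self-avoiding walk with
bonds near the FENE+WCA minimum, and removes the composite net momentum
exactly. The chain's initial center-of-mass height is a configuration
parameter: equilibrium and transport runs start mid-channel (focusing then
only has to hold, not develop), while the flow-type comparisons start
off-center ($z_0 = 2.5\,a_0 \approx 0.6\,R_{g,b}$) so that differences in
lift strength show up as differences in the sampled monomer distribution
within the production window. This emulates the *steady-state* conditions
of channel transport but not: startup transients of real devices, multiple
chains (no chain–chain hydrodynamics), charged monomers, or chemical detail
of real biopolymers. Passing tests therefore demonstrate the mesoscale
mechanism — shear-induced lift, its dependence on the shear localization,
and its coupling to wall attraction — not quantitative predictions for a
specific polymer.

# Numerical choices and degenerate inputs

* PB shooting uses RK4 with $n_{grid}/2$ half-channel intervals (default
  $n_{grid} = 512$) and `uniroot` tolerance $10^{-14}$; electroneutrality
  holds to $10^{-8}$ relative and doubling the grid moves the integrated
  charge by less than $10^{-6}$ relative. $\Sigma = 0$ short-circuits to a
  zero profile.
* Stokes double quadrature enforces both no-slip boundaries exactly by
  removing the (quadrature-level) linear residual.
* SRD rotation uses one uniform random axis per occupied cell per collision
  step; cells with a single member (and no virtual mass) are untouched —
  their relative velocity is zero.
* Degenerate gyration input (all monomers coincident) reports $R_g = 0$
  with `NaN` asphericity and a `degenerate` flag.
* Perfectly straight chains report infinite persistence length.
* Bond angles at $\theta \to 0$ use the series limit $\theta/\sin\theta
  \to 1$ in the bending force.
* The MD wall-crossing search is linear in the substep (position updates in
  velocity Verlet are linear given the half-kicked velocity), with a
  64-reflection guard per segment and a hard consistency trap if a particle
  ends beyond a wall.
* Run manifests record a config hash, completed seeds, and the package
  version; a seed whose trajectory destabilizes (overstretch) is reported
  and skipped while other seeds continue.

Run configurations are YAML files mirroring the `run_config()` structure;
trajectories are extended XYZ; profiles are TSV with `#` metadata headers;
checkpoints are single RDS containers holding positions, velocities, step
counter and RNG state, giving bit-exact restarts.

# Problem sizes used by the test and acceptance runs

The validation suite is sized for a single desktop core: viscosity from a
$10\times10\times20$-cell channel (10,000 solvent particles, 4 seeds); bulk
chain statistics from $2\times10^5$ Monte Carlo sweeps ($10^5$ samples);
transport and focusing from the reduced channel $30\times22\times17$ cells
($\approx$ 56,000 solvent particles) at the strongest-flow Weissenberg
number ($Wi \approx 17$), with warmup 4,000 and production 6,000 collision
steps over 2–4 seeds; the wall-attraction synergy additionally uses the
wide channel $30\times22\times34$ (112,000 particles), where the effect
lives, at single-seed resolution. Full-size production geometries
($60\times45\times34$, $\approx$ 459,000 solvent particles, multi-$\tau_Z$
sampling) use the same code paths unchanged; only wall-clock time separates
them from the reduced runs.

# Known limitations

* Angular momentum is not conserved by the SRD collision (the standard
  trade-off of this solvent); no Andersen or angular-momentum-conserving
  variants are provided.
* The implicit-ion EO driver assumes the charge distribution is unperturbed
  by the flow and by the (neutral) chain.
* The wall-attraction site density is a calibrated model constant, not a
  derived quantity; its value sets the absolute scale of the vdW effects.
* The reduced channel inverts one qualitative result of the wide channel:
  at $L_z = 4.1\,R_{g,b}$ a strongly driven EO chain is already fully
  focused, so adding wall attraction can only compete with (not amplify)
  the lift; the focusing–synergy effect requires the $8.2\,R_{g,b}$
  geometry where the unattracted EO chain is unfocused. The package's
  checks run the synergy comparison in the wide channel for this reason.
* Single chain only; no electrophoretic forces on monomers; no explicit
  ions; no slip boundary conditions; no time-dependent startup flows.
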