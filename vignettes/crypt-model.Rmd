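---
title: "An individual-cell-based model of the intestinal crypt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-cell-based model of the intestinal crypt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsim)
```

# The model

`cryptsim` simulates a murine small-intestinal crypt as a population of
individual cells on a fixed basal membrane (BM). Three ingredients drive
everything else:

1. **Biomechanics.** Cells are adhesive elastic spheres moving with
   overdamped dynamics on the inside of a test-tube-shaped surface.
2. **Signalling.** Wnt activity is a decreasing function of the axial
   position, through the local curvature of the BM; Notch activity is the sum
   of ligand contributions of directly contacting neighbours (lateral
   inhibition).
3. **A reversible lineage state machine.** Threshold crossings of the two
   activities switch cells between an undifferentiated state, reversible
   primed states for the Paneth, Goblet and enterocyte lineages, and
   irreversible terminal fates.

Steady-state cell turnover, the spatial distribution of the lineages, clonal
(monoclonal-conversion) dynamics, the response to Wnt/Notch gain- and
loss-of-function and the recovery from subpopulation ablation are all
*emergent*: none of them is prescribed directly by the rules.

## Geometry and the basal membrane

The crypt surface is a surface of revolution $r(z)$ over the axial
coordinate $z \in [-z_0, 0]$ (base at $-z_0$, crypt--villus junction at 0).
The profile family

$$ r(s) = r_b\sqrt{1 - e^{-2s/r_b}} + a\,(1 - e^{-s/L_1})
        + b\,(e^{-(z_0 - s)/L_2} - e^{-z_0/L_2}), \qquad s = z + z_0 $$

consists of a spherical-like bottom cap of radius $r_b = \lambda_1 r_0$, a
gentle mid-crypt widening ($a = r_0/4$, $L_1 = 0.15\,z_0$) and an
exponential flare ($L_2 = 2\lambda_2 z_0$) that reaches the junction radius
$r_0$; $b$ is fixed by $r(0) = r_0$. With the reference parameters
($z_0 = 150\,\mu m$, $r_0 = 60\,\mu m$, $\lambda_1 = 0.25$,
$\lambda_2 = 0.1$) the Gaussian curvature is maximal at the crypt bottom,
is about $5\times10^{-4}\,\mu m^{-2}$ at the priming threshold position,
and crosses zero just above the differentiation threshold position — the
geometric facts the fitted model is described to have.

The BM itself is a triangulated fibre network built deterministically from
rings of knots spaced by the mesh size $\lambda_{MAX}$ along the meridian
arc, with per-ring knot counts proportional to the local circumference and
zig-zag stitching between rings. At $\lambda_{MAX} = 1.25\,\mu m$ the
reference surface carries about 25,000 knots; the triangle inradius is
bounded by $\lambda_{MAX}/(2\sqrt3)$, far below any cell radius, so the
network is watertight for cells. A structured ring mesh was chosen over
blue-noise sampling because it gives a lower coordination-number variance,
an exact inradius bound and bit-reproducible meshes at a fraction of the
cost.

## Cell--cell mechanics

For two cells with radii $R_i, R_j$ at centre distance $d$:

* **Adhesion** $W = -\varepsilon_c A$, with $A$ the flattened contact facet.
  We use the Hertz-theory facet $A = c\,\pi R^* \delta$
  ($1/R^* = 1/R_i + 1/R_j$, overlap $\delta = R_i + R_j - d$) with facet
  factor $c = 1.5$, which lies between the bare Hertz circle ($c = 1$) and
  the geometric sphere--sphere intersection disc ($c \approx 2$). The factor
  was calibrated once against the stated relation between the growth time
  (14 h) and the effective cell-cycle time (about 24 h): larger facets make
  resting packings so adhesive that cells sit permanently below the
  contact-inhibition threshold, smaller ones leave the niche too loosely
  cohesive. The exported `contact_area()` reports the exact intersection
  disc for geometric use.
* **Hertz deformation** $W = \tfrac{8}{15} E^* \sqrt{R^*}\,\delta^{5/2}$
  with $1/E^* = 2(1-\nu^2)/E$.
* **Compression** $W = \tfrac{K}{2}(V_t - V_a)^2/V_t$, where the actual
  volume $V_a$ is the sphere volume minus the spherical caps cut off by the
  contact plane with every neighbour. $K$ defaults to the isotropic
  relation $E/(3(1-2\nu)) = 1\,kPa$.

Forces on positions and radii are the exact negative gradients of these
energies (verified against finite differences in the test suite).

## Cell--BM interaction

A cell interacts with every knot closer than its radius $R$. The energy per
knot is scaled by $1/n_K$ (the number of interacting knots), so the total
interaction is insensitive to the mesh density. The potential has two
branches meeting with zero slope at the threshold distance $\Omega R$
($\Omega = 0.95$):

* a **repulsive barrier** rising as a convex cubic to the maximum
  interaction energy $\varepsilon_K$ at $d = 0$ — this is what makes the
  network impenetrable (5.5 and 35 $\times 10^{-12}$ N·m for ordinary and
  Paneth cells; the Paneth value anchors them at the crypt base), and
* a **weakly adhesive skin** of depth $0.005\,\varepsilon_K$ with its
  minimum at $\Omega R$ and zero energy and force at $d = R$.

The barrier is summed over the discrete knots. The adhesive skin is
evaluated in its continuum limit as a function of the analytic surface
distance: summing a 0.25-µm-wide well over knots spaced 1.25 µm leaves a
lattice corrugation of several nN that pins cells and would make the
nominal migration velocity $F/\eta_{BM} \approx 5\,\mu m/h$ unattainable.
The continuum form has the identical well shape, depth and normal force and
zero artificial tangential force; the single-cell migration test reproduces
$F/\eta_{BM}$ to 0.1%.

A cell whose centre moves farther than $R$ from the surface has lost its
membrane contact and is removed (anoikis). Cells crossing $z = 0$ leave
through the crypt mouth; terminal Paneth cells die at age
$t_P = 57$ days.

## Signalling and fate

Wnt activity is the normalised analytic Gaussian curvature at the cell's
axial position, clamped to its running minimum above the curvature minimum
so the link is monotone. The thresholds are $TP_{Wnt} = f(z_p)$
($z_p = -125\,\mu m$) and $TD_{Wnt} = f(z_d)$ ($z_d = -87.5\,\mu m$); fate
changes therefore occur where cells cross those positions. Notch activity
is $\sum_j LP_j$ over direct contacts, with $LP = 0.35$ for Paneth and
Paneth-primed cells and $LP = 1$ for Goblet cells and Goblet progenitors
(primed cells must present ligand: without it, lateral inhibition cannot
operate in the progenitor zone and the absorptive lineage collapses).
A single Notch threshold of 1 serves priming and differentiation; both are
exposed separately for sweeps.

The truth table (activities at a threshold count as "high"):

```{r}
fate_truth_table()
```

Transitions among the non-terminal states are fully reversible. Terminal
enterocyte/Goblet differentiation is deferred until a running cell cycle
completes. Terminal *Paneth* differentiation happens at cycle completion
for mothers that were primed *continuously for at least one mean growth
time* (14 h): because the Notch sum is quantised in steps of 0.35 against a
threshold of 1, niche stem cells flicker in and out of the primed state on
contact noise, and sampling the flag at the division instant would convert
stem cells into Paneth pairs faster than Paneth cells die, draining the stem
pool. The commitment window is the package's resolution of what "finishing
its current cell cycle" means for a flickering cell; it was set against the
described steady-state composition (stem cells persistently intermingled
with Paneth cells) and not adjusted afterwards.

## Growth, division, removal

Proliferative cells (undifferentiated cells and enterocyte progenitors)
grow their target volume from $V_0$ to $2V_0$ in 50 stochastic increments
with exponential waiting times, so unconstrained doubling times are
$\Gamma(50, \tau/50)$ with mean $\tau = 14$ h. Growth pauses while the cell
is compressed below the contact-inhibition threshold
$V_p = 0.88\,V_0$ — the threshold refers to the *minimal* volume (it is
printed in units of $V_0$), which is also the only reading that produces
the stated gap between the 14 h growth time and the ~24 h effective cycle:
fresh daughters wait for space, cells past the early cycle complete it.
Secretory-primed cells finish a running cycle but start no new one. At
$2V_0$ the cell divides into two daughters of target volume $V_0$, placed
symmetrically along a random tangent direction and snapped to their own
equilibrium height above the membrane. Labels (clone, BrdU) are inherited.

## Migration

Paneth and Paneth-primed cells are pulled toward the crypt base with
$F_A = 7.5$ nN along the meridian tangent; primed and terminal cells of the
other lineages are pushed toward the junction with 4.5 nN.
*Undifferentiated cells move only passively.* Applying the upward force to
them as well empties the stem compartment within a day (transit time
shorter than the doubling time) and the crypt dies — this resolves the
ambiguity between the parameter table's row label ("all other cells") and
the text ("all other primed cells") in favour of the text.

# Numerics

* **Time stepping.** Overdamped dynamics: the friction system couples cells
  through pairwise friction proportional to the contact facet
  ($\eta_c A$); positions are updated in parallel by conjugate gradients on
  the $3N$ system. The time step adapts so no cell moves farther than
  $0.1\,R_0$ per step, capped at $dt_{max} = 0.05$ h; steps that would push
  two centres below $0.2(R_i+R_j)$ are rejected and retried at $dt/2$
  (pre-existing violations, e.g. fresh daughters, are tolerated while the
  step relieves them).
* **Stiff BM modes.** With the printed $\varepsilon_K$ values the knot
  potential has a stiffness of order $10^4$ nN/µm, far beyond explicit
  stability at any usable step. The friction operator therefore gains a
  per-cell Gauss--Newton term $dt\sum_k |W''_k|\, n_k n_k^T$ (backward Euler
  on the linearised stiff modes), and the radius equation an analogous
  scalar term. Equilibria and tangential mobilities are untouched; only the
  sub-step transient of membrane attachment is over-damped.
* **Fate updates.** After motion, growth, division and removal, cells are
  re-classified in a random sequential order, each seeing its neighbours'
  already-updated states. A synchronous update lets the lateral-inhibition
  rule flip whole contact clusters in lockstep (a period-2 artefact); the
  asynchronous sweep settles into stable checkerboard-like patterns.
* **Determinism.** All stochastic elements draw from R's global RNG in a
  fixed order; identical seeds give identical event logs, and a run
  resumed from a checkpoint replays the uninterrupted run exactly (the
  warm-started surface coordinate is part of the state for this reason).

# Initial condition

`initialize_crypt()` places a single layer of cells on the membrane at
near-equilibrium spacing, assigns states by position — Paneth and
undifferentiated cells strictly interleaved below $z_p$ (every stem cell
starts with enough ligand contacts), progenitors above, a progenitor/
terminal mix near the mouth — staggers cell-cycle progress, draws Paneth
ages uniformly over the life span (so replacement demand is steady from the
start) and relaxes the packing mechanically. The generator's randomness is
fully seed-controlled. A 10-day warm-up is discarded before measurements.

# What the simulations show — and what they do not

After warm-up the reference crypt settles into a self-organised steady
state: a ~40-cell bottom compartment of Paneth cells with stem cells
intermingled singly between them, a thin stream of transiting, amplifying
progenitors, and terminal cells leaving through the mouth. Turnover is
about 2 days, spontaneous apoptosis is rare, nearly all stem divisions
complete within 48 h, clonal labelling converges to monoclonality within
weeks, each single lineage recovers after ablation, and the four
constitutive signalling perturbations reproduce the described lineage
shifts.

Known limitations, measured and documented rather than hidden:

* The steady crypt is *lean* (~70 cells) compared to the densely packed
  appearance of real crypts: at the free migration speed
  $F/\eta_{BM} \approx 5\,\mu m/h$ the transit zone empties in about a day,
  so only the flux the niche produces populates it. Consequences: ablated
  pools of 5--15 cells replenish within ~0.5--1.5 days (faster than the
  multi-day recovery reported for a full crypt), and the
  de-differentiation rate per (small) progenitor pool exceeds the reported
  per-progenitor bound even though the absolute event rate (~0.3/day per
  crypt) is "occasional".
* Terminal Paneth cells persist through Wnt/Notch loss-of-function for
  their full 57-day life span; the model contains no mechanism that could
  deplete them within days.
* The BM is rigid: crypt fission, budding and membrane remodelling are out
  of scope, as are Wnt--Notch crosstalk, BMP signalling and the villus.

Problem sizes used throughout the package's own tests: the reference crypt
(~25,000 knots, ~70--400 cells, 10-day warm-up + 10-day windows) for the
steady-state, ablation and perturbation measurements, and a reduced crypt
(`make_fixture("mini_crypt")`: $z_0 = 75\,\mu m$, $r_0 = 30\,\mu m$,
$\lambda_{MAX} = 2.5\,\mu m$, migration forces scaled with the length, a
viable ~18-cell niche) for property-style and clonal tests.

# A short session

```{r, eval = FALSE}
p <- model_params()                      # the reference parameter set
st <- initialize_crypt(p, seed = 1)
warm <- simulate_crypt(st, 240, obs_dt = 24, seed = 1)$state
res <- simulate_crypt(warm, 240, obs_dt = 12)
steady_state_metrics(res$trajectory, res$events, res$state)

br <- brdu_assay(res$state, sample_times = c(2, 24), seed = 1)
cl <- clonal_conversion(res$state, duration = 21 * 24, seed = 1)
```
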