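---
title: "Shadow-aware intercostal ultrasound scan planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shadow-aware intercostal ultrasound scan planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuplan)
```

## The planning problem

Ultrasound imaging of organs beneath the rib cage — most prominently the
right liver lobe — is limited by acoustic shadows: bone blocks the beam,
so a target can only be insonified through the intercostal gaps. Planning
a probe trajectory that covers a target volume completely, keeps the
probe close (attenuation grows with path length), and avoids shadowed
acquisitions is a sequential decision problem. `icuplan` casts it as a
fully observable Markov decision process over a voxelized 3D scene and
trains a dueling double deep Q-network on it. The package provides the
scene model (synthetic phantoms or segmented anatomy), the simulator, the
agent, and the evaluation protocols.

## Scene model and state

A scene consists of a closed skin surface, a set of bone solids, and one
to three target volumes, all in millimetres. The state is a
$120\,\mathrm{mm}$ cube around the target centroid voxelized at
$4\,\mathrm{mm}$ ($30^3$ cells, half-open, inclusion by voxel-center
test) with three binary channels per voxel: target, bone, insonified.
The three most recent grids are stacked, giving a $9 \times 30^3$ binary
observation; at reset all three time slots hold the initial grid, whose
insonified channel already shows the imaging plane of the starting pose.
With multiple targets, the target channel holds their union and coverage
is assessed on the union.

## Probe kinematics

A bounding cylinder is fitted to the rib cage: the axis is fixed to the
longitudinal body axis (patients lie supine, so the free 5-DoF cylinder
fit would add instability without adding realism), the radius $R_c$ is
the minimal enclosing circle of the bone points projected along the
axis, and the height range spans their extent. The probe lives on the
skin in cylinder surface coordinates $(h, \theta)$ — $\theta = 0$ at the
anterior midline, increasing to the patient's left; $h$ from the caudal
end — and is projected onto the skin along the inward radial ray. Two
rotations complete the pose: $\phi$ about the skin normal (applied to
the long axis, which starts along the circumferential tangent) and then
$\psi$, the tilt, about the rotated long axis. The composition order is
a convention the package fixes and documents, not a physical claim.

To remove inter-patient size differences the frame carries an
anisotropic affine onto a generic cylinder (radius 100 mm, height
200 mm — an adult-thorax scale chosen once). Step sizes are defined in
generic scale — 4 mm in $h$, $3^\circ$ in $\theta$, $2^\circ$ in $\phi$
and $\psi$ — and mapped back through the exact inverse, so one action
means the same fraction of a rib cage on every patient. Angles are not
affine-invariant, so the $20^\circ$ tilt termination is evaluated in
patient space, where the constraint is physical.

## Ray casting and shadows

The virtual linear transducer emits parallel rays along the probe
centerline from elements spaced along the long axis (defaults: 40 mm
footprint, 2 mm spacing — at most half a voxel, so no traversed column
is skipped — and 120 mm imaging depth). The transducer geometry is not
anatomy-derived; all three values are configuration keys. Each ray is
traversed with exact voxel stepping: cells before the first bone cell
are insonified, the first bone cell and everything behind it are
shadowed. A cell reached unblocked by any ray counts as insonified;
each cell counts once per step. The shadow fraction is
$p_t = n^t_{shadow} / N_t$ where $N_t$ is the total scanned volume
(insonified plus shadowed cells), so $p_t \in [0, 1]$; when the plane
misses the grid entirely ($N_t = 0$) the package defines $p_t = 1$,
which routes the step into the penalty branch — an uninformative pose
should not look shadow-free.

## Reward

The per-step reward decomposes into coverage, attenuation and shadow
terms:

$$r_t = r_c + \alpha_1 r_a + \alpha_2 r_s, \qquad
  r_c = \frac{n_t}{N},\quad
  r_a = e^{-d_t / R_c},\quad
  r_s = 1 - p_t,$$

with $n_t$ the target voxels covered for the first time this step, $N$
the total target voxels, and $d_t$ the probe-face-to-target-centroid
distance in generic scale. The coverage coefficient is fixed at 1;
$\alpha_1 = 1$ and $\alpha_2 = 0.5$ by default. Coverage only accrues in
examining mode and only when $p_t$ stays below the tolerance
$T_{th} = 0.20$; at or above it the step earns $-0.1$ and its coverage
is discarded. The switch action toggles between examining and
readjusting modes at a fixed $-1$; readjusting-mode steps earn exactly
0 and contribute nothing to coverage or to the episode averages. An
episode succeeds when cumulative coverage reaches 95% of $N$ and then
pays

$$r_{end} = k_{end}\left(1 + \alpha_1 \frac{1}{D} + \alpha_2 P\right),
  \qquad D = \frac{1}{T}\sum_t \frac{d_t}{R_c},\quad
  P = \frac{1}{T}\sum_t (1 - p_t),$$

where the averages run over the $T$ examining-mode steps — acquisitions
in readjusting mode are excluded from reconstruction, so they are
excluded from the episode quality summaries too (shadow-penalized
examining steps are included; they are part of the scanning process).
$k_{end}$ defaults to 10 and is a configuration key. Episodes truncate
at 80 steps. Tilting beyond $20^\circ$ terminates the episode with the
ordinary step reward and no bonus: the pose is infeasible, and the
package logs it as a failure. An off-surface move (the radial ray misses
the cropped skin) leaves the pose unchanged and the step is rewarded on
the unchanged state — the probe neither teleports nor crashes.

## Agent

Action values follow the dueling decomposition
$Q(s, a) = V(s) + (A(s, a) - \tfrac{1}{N_a}\sum_{a'} A(s, a'))$ over the
9 discrete actions, with double-Q targets: the online network selects
the next action, the target network evaluates it. Exploration is
$\varepsilon$-greedy with a linear decay (1 to 0.05 over the first
3/5 of the default budget), ties broken by lowest action index.
Prioritized replay samples transitions with probability
$\propto p^{0.6}$, importance weights $(n P(i))^{-\beta}$ max-normalized
with $\beta$ annealed 0.4 to 1, and priorities refreshed to the absolute
TD error plus a floor of $10^{-6}$. States are binary, so the buffer
stores them bit-packed.

The network front end is a 3D max-pool over each channel (binary max =
any) followed by a fully connected rectifier trunk and the two dueling
heads. The pooling factor (default 3, i.e. $10^3$ cells per channel) and
trunk widths (default one layer of 128) are configuration keys; this
architecture was chosen so that training runs entirely on one CPU core
at useful speed — at the $30^3$ scale the pooled occupancy retains the
gap/target geometry that drives the policy. Remaining optimizer choices
are standard deep-Q practice and are declared defaults, not claims:
discount 0.99, batch 32, Huber loss on importance-weighted TD errors,
adaptive-moment optimizer at learning rate $7 \times 10^{-5}$, global
gradient-norm clip 10, warm-up of 1000 transitions, target-network copy
every $5 \times 10^3$ steps. Training is single-process (the original
16-node distributed setup is replaced by one process with a single
$5 \times 10^4$ buffer), fully seeded, and resumable from checkpoints
that carry weights, optimizer moments, buffer, environment state and
RNG state.

## Synthetic phantoms

The generator emulates the geometry that matters for intercostal
planning: a partial rib cage of capsule arcs around a cylindrical torso
(so the intercostal gap — the bone-free distance between adjacent rib
surfaces — is exact and configurable down to 10 mm), a closed
cylindrical skin offset above the ribs, and ellipsoidal targets
rejection-sampled beneath the ribs so they intersect no bone (budget
1000 attempts per target, then an error). Ellipsoids give closed-form
volumes and inside tests; target volumes are drawn per size class —
small below 4 cm$^3$, medium 4 to 13.5 cm$^3$, large above — with random
orientation and mild axis anisotropy. Segmented anatomy enters through
watertight STL/PLY meshes or NIfTI label maps (millimetres enforced);
arbitrary mesh targets remain fully supported.

What the phantoms do **not** emulate: anatomically curved, oblique ribs;
cartilage; soft-tissue deformation and breathing; irregular tumor
shapes; vertebral anatomy (real scenes crop to a thoraco-lumbar band;
the generator emits an analogous band with no claim of vertebral
correspondence). Tests passing on phantoms therefore demonstrate the
mechanics of the simulator, reward and learner — not clinical coverage
performance on patient anatomy.

## Numerical choices and degenerate inputs

* Voxels are half-open 4 mm cells, 0-based in the lattice convention;
  a ray running exactly on a boundary plane belongs to the upper cell.
* The minimal enclosing circle uses Welzl's algorithm with a
  deterministic shuffle; degenerate on-axis bone points are an error.
* $p_t = 1$ when $N_t = 0$; coverage rewards error on $N = 0$ (a target
  entirely outside the state cube is a mis-configured reset, and a
  target partially outside is a recorded warning).
* Success requires cumulative coverage $\ge 0.95 N$; the final step's
  own shadow fraction is not additionally constrained.
* Greedy ties take the lowest action index; the argmax inside the
  double-Q target does the same.
* All randomness flows from one master seed through named substreams
  (placement, initial pose, exploration, replay); generation, resets,
  evaluation and training are bit-reproducible under a fixed seed.

## Scaled-down protocols

The full-scale protocol ($5 \times 10^6$ steps) is a GPU-month-class
computation; the package's own checks run a scaled protocol chosen as a
coherent unit: a single-gap phantom (two ribs, 30 mm gap, one small
target), $2 \times 10^4$ training steps, pooling factor 5 with a
32-unit trunk, learning rate $10^{-3}$, exploration annealed over
$1.2 \times 10^4$ steps, the importance-weight exponent annealed to 1
over the full scaled budget (standard prioritized-replay practice),
buffer $10^4$, target copy every 500 steps.
The larger learning rate and shorter schedules scale with the budget;
the full-scale values remain the package defaults. At this scale the
greedy policy reliably improves over the uniform-random baseline in
success rate and mean episode return; it does not approach the
full-scale success rates, and nothing in the package should be read as
reproducing them. Test problem sizes elsewhere follow the same logic:
oracle comparisons run over 10 random phantoms times 20 random poses,
statistical checks of sampling frequencies use $10^5$ draws.

## Known limitations

Beyond the phantom simplifications above: the acoustic model is purely
geometric (no refraction, speckle, frequency-dependent attenuation, or
B-mode image formation — attenuation enters only through the distance
proxy $r_a$); probe-tissue force and deformation are not modelled;
registration of planned trajectories onto real patients is out of
scope. The ray caster treats any bone voxel as fully blocking, which
overestimates shadows from thin or partially calcified structures at
the 4 mm resolution.
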