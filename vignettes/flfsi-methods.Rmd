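---
title: "Tri-channel 2DPCA with swarm-selected components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-channel 2DPCA with swarm-selected components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flfsi)
```

## The problem

Conventional B-mode sonography and contrast-enhanced ultrasound (CEUS) view
the same anatomy through different physics: B-mode renders tissue texture,
CEUS renders blood-pool perfusion. Downstream region-detection models
benefit from a single image that carries both kinds of evidence. This
package builds such images by (i) decomposing each modality's image stack
with two-dimensional PCA applied per colour channel, (ii) selecting a
compact set of projected feature vectors with a binary particle swarm
optimiser, and (iii) blending the two modality reconstructions at a tunable
CEUS proportion.

## Per-channel 2DPCA

2DPCA works on image matrices directly rather than on flattened pixel
vectors. For a stack of $N$ images $O_i \in \mathbb{R}^{H \times W}$ (one
colour channel $c \in \{R, G, B\}$ at a time), the column-scatter matrix is

$$
S_t^c = \frac{1}{N} \sum_{i=1}^{N}
  \left(O_i^c - \bar O^c\right)^{\!\top} \left(O_i^c - \bar O^c\right),
$$

a $W \times W$ symmetric positive semi-definite matrix ($1/N$
normalisation, deliberately not $1/(N-1)$). Its eigenvectors $W_j^c$,
ordered by non-increasing eigenvalue, are the projection axes; the
coefficient columns

$$
Y_j^c = O^c\, W_j^c
$$

are the *projected feature vectors*. Given a binary selection $S \in
\{0,1\}^{d \times 3}$ over the $d = W$ components of the three channels, a
channel is reconstructed by the partial expansion

$$
\tilde O^c = \sum_{j :\, S_{jc} = 1} Y_j^c \,(W_j^c)^{\top}.
$$

Two conventions deserve attention:

* **Raw projection.** The *raw* image is projected, and the mean is not
  re-added at reconstruction — the expansion is complete regardless
  (the basis is a full orthonormal set), and the dataset mean then lives
  mostly in the leading components rather than being removed. The
  conventional centred variant is available through
  `projection_basis(stack, centered = TRUE)`, which centres at projection
  and re-adds the mean at reconstruction; it is off by default.
* **Sign convention.** Each eigenvector is flipped so its first nonzero
  entry is non-negative. Eigenvectors are only defined up to sign, and
  fixing it makes bases, masks and manifests bit-reproducible across
  platforms and LAPACK builds.

Reconstruction quality is measured per channel by the Frobenius distortion
$\lVert O^c - \tilde O^c \rVert_F$, summed over channels.

## Swarm selection of components

The selection mask is optimised by minimising

$$
\mathrm{Fitness}(S) \;=\;
\frac{1}{N}\sum_{i=1}^N \sum_{c}
\bigl\lVert O_i^c - \tilde O_i^c(S) \bigr\rVert_F \;+\; \lambda\, k,
$$

where $k$ is the total number of selected components across the three
channels and $\lambda \ge 0$ charges for density. The error term is
averaged over the whole training stack (a single reference image would make
the selection image-specific); `fitness_subset` restricts the average to a
leading subset when stacks are large.

Both swarm variants share the velocity recursion

$$
v \leftarrow \omega v + \alpha r_1 (p - x) + \beta r_2 (g - x),
$$

with $p$ the particle's best-seen mask, $g$ the swarm's, and differ in the
transfer to bits:

* **Traditional (sigmoid).** $r_1, r_2 \sim U[0,1]$ per dimension; each bit
  is resampled as $x = \mathbf{1}[u < 1/(1+e^{-v})]$ with a fresh uniform
  $u$. Positions are probabilistic at every step.
* **Improved (sign-quantised).** $r_1, r_2$ are uniform draws from
  $\{0, 1\}$ per dimension; the velocity is quantised to
  $\mathrm{sgn}(v) \in \{-1, 0, 1\}$ and the position moves additively,
  $x \leftarrow \mathrm{clamp}_{[0,1]}(x + v)$. The clamp is the only
  reading of the additive update that keeps positions binary, since
  $x + v$ can reach $-1$ or $2$.

Defaults follow the settings the method was developed with: 50 particles,
100 iterations, $\omega = 1.5$, $\alpha = 2$, $\beta = 1$,
$\lambda = 0.001$. One iteration evaluates every particle, updates personal
and global bests on *strict* improvement (stable under ties), and then
moves the swarm; a run of $T$ iterations therefore costs exactly
$N \cdot T$ fitness evaluations, and the best-so-far trace is
non-increasing by construction. Each run draws from a private stream seeded
by its configuration, so results are pure functions of the config.

Velocity initialisation is configurable (`random_pm1`, the default, or
`zero`) because both conventions are defensible for the sign-quantised
variant and they behave differently; the choice is recorded in run
manifests.

### Fast fitness evaluation

With a full orthonormal basis the residual of a masked expansion is carried
entirely by the unselected columns:
$\lVert O^c - \tilde O^c \rVert_F = \bigl(\sum_{j \notin S_c} \lVert Y_j^c
\rVert^2\bigr)^{1/2}$. The optimiser therefore precomputes the column
energies once per stack and evaluates a mask in $O(d)$ per channel instead
of reconstructing images (`make_fitness_fn()`). The explicit
reconstruction route (`mask_fitness()`) is retained and the two are tested
against each other; they agree to roughly the square root of machine
epsilon, because a near-complete mask leaves a residual that is the square
root of a cancelled difference.

### Assembling the final set

After the swarm run, the final component set is assembled in three steps:

* $B_1$: components the swarm kept in **all three channels** — the
  parameter-free reading of cross-channel consensus;
* $B_2$: the top-$m$ components by $\ell_2$ energy of their coefficient
  columns, with the energy pooled as a mean over channels and over stack
  images (so the ranking is modality-level, not per-image); ties break to
  the lower index; $m$ defaults to 100, capped at $d$;
* $B = B_1 \cup B_2$, applied to all three channels at reconstruction.

Because reconstruction is a partial orthonormal expansion, enlarging the
set can never increase the error, so $B$ reconstructs at least as well as
either part — a property the tests assert. The `baseline_topk()` rule
(keep the $k$ leading eigen-components, customarily $k = 160$ on 640-wide
images) provides the conventional comparison path. Component indices are
1-based throughout, in eigenvalue order.

## Fusion

The fusion parameter $x \in [0,1]$ is the CEUS proportion:

$$
F = x \cdot \tilde O_{\mathrm{ceus}} + (1 - x) \cdot \tilde O_{\mathrm{conv}}.
$$

The blend is applied to the *reconstructions*. Reconstruction is linear in
the projected feature vectors, so under a shared basis this equals blending
the features themselves; blending reconstructions additionally allows each
modality its own basis and selection, which is what the pipeline does
(selection runs once per modality and is applied to every image of that
modality). Endpoints are exact, the output lies pixelwise between the
inputs, and the operation is linear in $x$. Grayscale baselines convert via
Rec. 601 luma weights (0.299, 0.587, 0.114) and replicate the result across
channels.

Values are clipped to $[0,1]$ only when writing 8-bit PNG output; all
in-memory operations and the 32-bit float TIFF writer keep unclipped
values so the algebraic identities hold exactly.

## The synthetic generator

Clinical paired CEUS data cannot ship with a package, so every stage is
exercised against a seeded generator (`generate_dataset()`) that emulates
the statistical structure the pipeline assumes:

* one elliptical region of interest per pair, sampled uniformly from
  configurable ranges and shared by both modalities, with the ground-truth
  binary mask returned;
* multiplicative mean-one gamma speckle (shape 25 by default, i.e. 20%
  noise — a standard first-order surrogate for ultrasound speckle),
  independent between modalities unless `shared_speckle = TRUE`;
* modality structure: background level 0.15, region gain 0.35
  (conventional) versus 0.55 (CEUS, emulating perfusion enhancement), and
  a fixed amber per-channel tint (1, 0.82, 0.55) applied after clipping so
  cross-channel ratios are exact.

The default frame is 64 × 64 with 16 pairs: large enough that bases,
swarm runs and fused sweeps have realistic structure, small enough that
eigendecompositions and 5000-evaluation swarm runs complete in seconds —
the tests and the acceptance script use 8–10 pairs at this size, plus a
width-4 stack for the exhaustive testbed. What the generator does *not*
model: wave propagation and attenuation, perfusion time dynamics, probe
and depth-dependent resolution, patient heterogeneity. Passing tests
therefore demonstrate the algebra and the optimiser contracts under
controlled conditions, not clinical detection performance.

## Numerical choices

* Covariance matrices are symmetrised (`(S + t(S)) / 2`) before
  eigendecomposition, and inputs asymmetric beyond `1e-9` are rejected.
* Degenerate inputs: an all-zero mask reconstructs the zero image (or the
  mean, for a centred basis); `m = 0` gives an empty $B_2$; `m >= d`
  returns every component.
* The fast fitness clips tiny negative energy differences at zero before
  the square root.
* Ties: eigenvalues are sorted non-increasing as returned by LAPACK;
  energy ranking breaks ties toward the lower index; best-mask updates
  require strict improvement.
* Per-pair generator streams are derived as
  `(seed * 10007 + index * 7919) mod (2^31 - 1)` so pairs are
  reproducible individually, not only as a sequence.

## Known limitations

* **Desk-scale behaviour of the sign-quantised variant.** Once a bit's
  position, personal best and global best agree and its velocity is zero,
  no term of the update can change it again: with $\omega = 1.5$ the
  quantised inertia preserves any nonzero velocity's sign, and a zero
  velocity stays zero unless the (then-vanished) pull terms act. The
  swarm therefore loses upward exploration within a few iterations of
  consensus and can stall short of the optimum of small exhaustive
  testbeds, where the sigmoid variant's perpetual resampling searches the
  4096-mask space more reliably. The package's exhaustive-testbed checks
  measure exactly this, and the acceptance script reports both variants'
  success rates side by side. The variant's design intent — cheap discrete
  jumps in very high-dimensional sparse spaces under a detection-quality
  objective — is not what a width-4 testbed measures.
* Selection is dataset-level: one mask per modality per run, applied to
  every image. There is no per-image adaptive selection, and $B$ is not
  re-optimised after the union.
* The stack must fit in memory; covariance accumulation is not streamed.
* Fusion is a pixelwise convex blend of reconstructions; no registration
  is attempted, so the two modality stacks are assumed aligned pair by
  pair.

## A small worked run

```{r example, eval = FALSE}
ds <- generate_dataset(synthetic_params(height = 32, width = 32,
                                        n_pairs = 8, seed = 7))
basis <- projection_basis(ds$conv)
sel <- select_components(ds$conv, basis,
                         bpso_config(swarm_size = 20, iterations = 40,
                                     seed = 7), m = 10)
sel$b
fused <- build_fused_dataset(ds$conv, ds$ceus,
                             fusion_spec(x = 0.2, m = 10),
                             bpso_config(swarm_size = 20, iterations = 40,
                                         seed = 7))
fused
```

The same flow, with artifacts written to disk (fused PNGs, selection JSON,
swarm trace CSV and a manifest holding the config echo, seeds and input
content hashes), is `run_pipeline(run_config(...))`, and
`inst/cli/flfsi.R` exposes it from the shell.
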