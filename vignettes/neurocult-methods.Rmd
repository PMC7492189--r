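---
title: "Methods: reconstructing and analysing growing neuronal culture networks"
author: "neurocult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and analysing growing neuronal culture networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neurocult` studies how cultured neurons wire up. A culture imaged by
label-free quantitative phase microscopy shows bright round somas connected
by thin curvilinear neurites; reading each snapshot as a spatial graph —
somas as nodes, soma-to-soma neurites as edges — turns the growth recording
into a time series of networks whose organisation can be quantified. The
package covers the full chain: a synthetic-culture generator (ground truth
plus rendered snapshots), image-to-network reconstruction, the network
statistics used to characterise growth (three centralities, node-to-node
degree mixing and assortativity, transitivity/local/square clustering,
edge-length exceedance), comparison against six null-model families, and
multifractal spectrum estimation by finite box covering.

# The synthetic culture generator

Real culture recordings are rarely redistributable, so the generator is a
first-class module: it defines a known ground truth against which every
downstream stage is validated.

**Model.** Somas are placed by rejection sampling with a minimum centroid
separation. Each unordered pair is connected independently with probability
$\exp(-d/\lambda)$, the simplest kernel that reproduces the empirical
observation that physically close neurons carry most connections; the decay
length `connectScalePx` ($\lambda$) is the package's one structural
connectivity parameter. Each edge carries a quadratic arc with bounded
random curvature (control-point offset up to $0.2\,d$ perpendicular to the
chord). Arcs are routed to keep clear of third-party somas: a neurite that
ran through another cell body would constitute a genuine contact with that
cell, which the pairwise edge list deliberately does not model. Edges are
assigned birth snapshots shortest-first in batches of
$\lceil \text{fraction} \times |E| \rceil$, so connections are only ever
added — short neurites complete first in a growth process.

**Corruption model.** Rendering stamps soma disks and neurite arcs onto a
flat background (background < neurite < soma intensity), then erases one
gap per selected neurite (same stamp geometry as the drawing pass, so
exactly the drawn pixels of the gap stretch are removed), overlays
sub-threshold debris blobs, and adds Gaussian pixel noise.

**Defaults as study conditions.** The defaults emulate a low-density
culture: a $1024 \times 1024$ px field at 0.65 µm/px holds 30 somas,
about 65 cells/mm²; 15 snapshots span 14 h. Soma radii 14–17 px give areas
of roughly 620–910 px², above the 600 px segmentation threshold, while
debris (50–300 px²) sits well below it. $\lambda = 150$ px yields a mean
degree near 4. Gap rate 0.15 with 3–10 px gaps, 30 debris blobs and noise
$\sigma = 0.02$ are plumbing values chosen once to exercise every code
path without overwhelming the imaging contrast (the binarization rule
needs ink to clear the background by about $6\,\mathrm{MAD}$).

**What the generator does not emulate:** phase-imaging optics (halo,
shot-noise structure, defocus), soma shape variability, branched or fasciculated
neurites, cluster migration and merging, or neurite growth dynamics within a
snapshot interval. Passing reconstruction tests on these images therefore
demonstrates algorithmic correctness on idealised geometry, not performance
on real phase images.

# Reconstruction

The four stages mirror how a practitioner reads these images.

1. **Clarity triage.** A deterministic focus score — mean local variance in
   a 15 px window, normalised by the squared half-range — replaces manual or
   learned screening of dim, out-of-focus frames. Constant images score 0;
   blur strictly lowers the score. The pipeline compares it to a
   configurable threshold (default 0: accept everything, since synthetic
   frames are in focus by construction).

2. **Soma/debris segmentation.** Bright structure is separated from
   background by robust statistics: ink must exceed the image median by
   $\max(6\,\mathrm{MAD},\ 5\%\ \text{of the dynamic range})$. A global
   two-class threshold (e.g. Otsu) is unreliable here because the histogram
   has three modes (background, neurite, soma) and the split tends to land
   between neurite and soma, discarding all neurites. A morphological
   opening with a disc larger than the neurite half-width then isolates
   compact blobs; 8-connected components with area of at least 600 px
   (neuron mode) or 800 px (cluster mode) become somas, smaller bright
   shapes are debris and are dropped. Cluster mode differs from neuron mode
   only by this threshold.

3. **Skeleton, terminals, gap filling.** The foreground is thinned
   (Zhang–Suen) to a 1 px, 8-connected skeleton. Terminals are skeleton
   pixels with exactly one neighbour (isolated pixels are reported
   separately). Each terminal searches within a radius (default 12 px) for
   the nearest skeleton pixel outside its own local branch — pixels within
   geodesic distance $2.5 r$ along the skeleton are excluded, otherwise a
   terminal would trivially "bridge" to its own neighbours — preferring
   candidates within 60° of the broken neurite's outgoing direction, since
   the lost continuation lies ahead of the break while unrelated neurites
   pass laterally. Each terminal bridges at most once; the result is
   re-thinned. Bridging is monotone: it only ever adds ink, so enabling it
   never removes edges.

4. **Tracing.** Soma masks are removed from the skeleton. Candidate
   connections are the soma pairs joined by the skeleton at all (shared
   8-connected component). Each candidate is confirmed by a parametric
   trace: a family of bounded-curvature quadratic arcs between the two
   centroids (control offsets up to $0.25\,d$ in steps of $0.005\,d$) is
   scanned, and the pair becomes an edge only when some arc lies on the
   (2 px dilated) skeleton for at least 92% of its samples, without passing
   through a third soma's mask. Because neurites are smooth, gently curved
   processes, a genuine connection always carries such an arc, whereas the
   dog-legged route along two neurites that merely cross in the image does
   not — crossings are traced through rather than fused, which is the main
   failure mode of naive skeleton-component linking. The steerable filter
   bank (second derivative of a Gaussian at 8 orientations, scale
   defaulting to half the neurite width) confirms that traced ink is
   ridge-like; on images without contrast plain skeleton following is the
   fallback. The 92% coverage tolerance sits in the middle of the wide
   empirical separation between genuine connections (coverage ≈ 1) and
   crossing artefacts (coverage ≤ 0.83 in our diagnostics), and is strict
   enough that an unbridged gap fails confirmation.

**Known limitations.** Two near-parallel neurites that merge into one
thinned corridor for a long stretch are genuinely ambiguous and can still
swap partners; neurites that are not well approximated by a single
low-curvature arc (strongly S-shaped or branched processes) would fail arc
confirmation; and a neurite that touches a third soma is attributed to that
soma, as a walk that stops at cell bodies should.

# Network statistics

The literal, unnormalized forms are the defaults; normalized variants
(degree and closeness scaled by $n-1$) are available by flag, and the
package takes no position on which a published figure used.

- Degree: $\deg(v)$. Closeness: $1/\sum_u d(u,v)$ with unweighted
  shortest paths; on disconnected graphs the sum runs over reachable nodes
  only, and nodes with no reachable partner get 0 by the empty-sum
  convention. Betweenness: $\sum_{s\ne v\ne t} \sigma_{st}(v)/\sigma_{st}$
  over unordered pairs, with disconnected pairs contributing 0.
- The node-to-node degree mixing matrix counts both orientations of every
  edge, so it is symmetric with total mass $2|E|$; peak coordinates are
  reported with ties in ascending lexicographic order. The assortativity
  coefficient is the Pearson correlation of end degrees over both
  orientations; degree-regular graphs have zero end-degree variance and
  return NA rather than erroring.
- Transitivity $T = 3 \times \text{triangles}/\text{triplets}$ (0 when no
  triplet exists); average clustering $C$ averages
  $\delta(v)/\tau(v)$ over nodes of degree ≥ 2; square clustering $C_4$
  uses the Lind–González–Herrmann per-pair form
  $q_{imn} / ((k_m-\eta)(k_n-\eta) + q_{imn})$ with
  $\eta = 1 + q_{imn} + \theta_{mn}$, accumulated per node as a ratio of
  sums over neighbour pairs — the convention of the standard NetworkX
  implementation — then averaged over nodes of degree ≥ 2. A pair with no
  possible square contributes nothing (no cliquishness evidence); a node
  whose pairs all degenerate scores 0.
- The edge-length exceedance curve is the strict-inequality ECCDF
  $P(L > \ell)$ at every distinct observed length (lengths deduplicated at
  10 significant digits to absorb floating-point noise).

# Null models

Six families are size-matched to an observed network with $n$ nodes and
$E$ edges: random regular ($d = \mathrm{round}(2E/n)$, parity adjusted),
Erdős–Rényi ($p = 2E/(n(n-1))$), Watts–Strogatz (even ring degree
$k = \mathrm{round}(2E/n)$, rewiring $\beta = 0.05$ by default),
Barabási–Albert ($m = \mathrm{round}(E/n)$), a spatial scale-free growth
model, and a weighted multifractal graph model. The first four delegate to
igraph's generators.

**SSF.** Nodes arrive one at a time on fixed planar positions (the observed
layout when available, uniform otherwise) and connect to $m$ distinct
existing nodes with probability $\propto k_j \exp(-d_{ij}/r_c)$, seeded by
an $(m{+}1)$-clique. The distance shift inside the exponential is
normalised by the minimum distance, which preserves the proportionality
exactly while avoiding underflow at small $r_c$. When matched to an
observed network, $r_c$ defaults to the observed mean edge length.

**WMG.** Node positions are uniform on $[0,1]$; a pair whose positions have
digit sequences $(i_1..i_K)$, $(j_1..j_K)$ under the recursive interval
partition links with probability $\prod_t P[i_t, j_t]$, times a global
scale calibrated so the expected edge count matches the target (an error
names the feasible range when no scale in $(0,1]$ suffices). The
comparison harness fits WMG by a coarse grid over partition size
$m \in \{2,3\}$, depth $K \in \{2,3\}$ and diagonal dominance
$\{1,4,16\}$, scoring each candidate on a 20-realization pilot before the
full run; likelihood-based estimation is out of scope.

**Comparison.** For each family, `compareModels` draws the requested
number of realizations (1000 for headline use), computes $T$, $C$ and
$C_4$ on each, and reports the realization mean, the empirical 2.5/97.5
percentile interval (robust to the skewed distributions these metrics
have on sparse graphs), the realization standard deviation, and the error
$|\text{observed} - \text{mean}|$. Both the spread interval and the sd are
emitted so either error-bar convention can be drawn. A family whose
generator fails is dropped with a warning rather than aborting the rest.

# Multifractal analysis

**Covering.** A box of size $r$ is a set of nodes with pairwise
shortest-path distance at most $r$. Random-sequential covering grows balls
of radius $\lfloor r/2 \rfloor$ around uniformly drawn uncovered seeds;
each cover is then compacted by greedily merging boxes (smallest first)
whenever the union still satisfies the diameter bound. Compaction strictly
reduces the box count and removes the 1–2 node fragments the sequential
pass leaves between earlier boxes — fragments that otherwise dominate the
partition sum at strongly negative $q$ and are the classic failure mode of
box-covering multifractal estimates. `boxCover` keeps the best of
`nCovers` restarts; an exhaustive minimum-cover oracle on small cycles
pins its correctness in the tests.

**Mass exponents.** For each $r$ in the grid, `nCovers` compacted covers
are drawn; normalised masses $\mu_i = M_i(r)/N$ give
$Z(q,r) = \sum_i \mu_i^q$ (evaluated in log space), and $\ln Z$ is
averaged over the covers. The scale variable is $\ell = r + 1$: a box of
diameter $r$ spans $r+1$ nodes along a path, and fitting against $r$
itself biases the slope strongly at small scales. $\tau(q)$ is the slope
of $\overline{\ln Z}$ against $\ln(\ell/(d+1))$ over the grid,
$D(q) = \tau(q)/(q-1)$, and $D(1)$ uses the limit form (slope of
$\overline{\sum_i \mu_i \ln \mu_i}$). The default grid is 8 log-spaced
sizes from 4 to $\lceil d/2 \rceil$: scales below 4 are dominated by the
discreteness correction, scales above half the diameter leave too few
boxes. Fits with $R^2 < 0.8$ are flagged per $q$; a graph without at
least 4 usable scales (e.g. a star) is marked degenerate rather than
erroring. Disconnected inputs are reduced to their largest component. The
default of 40 covers per scale suits interactive use; the validation runs
use 100, where the ring and flower estimates are stable to about ±0.05
across seeds.

**Spectrum.** $\alpha(q) = \frac{d}{dq}[(q-1)D(q)]$ by central differences
(one-sided at the ends) and $f(\alpha) = q\alpha - (q-1)D(q)$; the summary
parameters are the spectrum height $f_{\max}$, the width
$\alpha_{\max} - \alpha_{\min}$, and the height range. A non-monotone
$\alpha(q)$ beyond tolerance attaches a warning (noisy estimate). The
Legendre identity is exact by construction and asserted to $10^{-12}$.

**Validation fixtures.** The $C_{200}$ ring (box dimension 1, monofractal,
spectrum width near 0), the generation-5 $(2,2)$-flower (box dimension
$\ln(u+v)/\ln u = 2$; at 684 nodes the finite-size estimate sits near 1.82,
within the validation band), and an exact binomial cascade with masses
$p, 1-p$ whose spectrum endpoints are
$-\log_2 \max(p,1-p)$ and $-\log_2 \min(p,1-p)$ in closed form. The
cascade's partition sums are computed exactly at dyadic levels 4–10 and
fitted with the same machinery, isolating the Legendre step from covering
noise.

# Pipeline and reproducibility

`runPipeline` executes simulate (or load) → reconstruct → metrics →
null-model comparison → multifractal analysis from one YAML config, writing
every artifact (GraphML, tidy CSVs, JSON summaries) before the next stage
starts, plus a manifest naming all files, the config fingerprint and the
seeds. One global seed is expanded into per-stage seeds by a fixed counter
scheme so stages can be re-run in isolation; re-running with the same
config and seed reproduces byte-identical CSV content. Node coordinates are
rounded to $10^{-6}$ px when networks are built, so GraphML round trips are
exact. The demo configuration simulates 3 snapshots of a 1024² culture; the
statistical defaults (600/800 px thresholds, 1000 realizations, 95% CIs)
follow the experimental design the package emulates, while test
configurations scale the field, the realization counts and the cover counts
down to keep the suite interactive.

# Design decisions on genuinely open points

- **Centrality normalization** is a flag (default off, the literal forms);
  published centrality CDFs rarely state which variant was plotted.
- **Edge birth ordering** is shortest-first; any growth schedule consistent
  with "edges are only added" would do, but shortest-first matches the
  physical picture of short neurites completing first.
- **Gap-fill search radius** (12 px), **binarization rule** and
  **steerable-filter scale** are exposed in the config with the defaults
  above; none has a canonical published value.
- **Cluster mode** differs from neuron mode only by the 800 px area
  threshold; distinguishing intra- from inter-cluster neurites is out of
  scope.
- **Box-covering variant**: random-sequential ball growth with compaction
  and restart minimisation; the exhaustive oracle on small cycles is the
  correctness anchor. $r$ is interpreted as box diameter throughout.
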