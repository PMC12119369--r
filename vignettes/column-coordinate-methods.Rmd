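---
title: "Methods: column coordinates, pins, layers and type inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: column coordinates, pins, layers and type inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexpin)
```

This vignette is the package's own account of the methods it implements:
the models and procedures, their assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, and the numerical
choices made where a published description left the design open.

## The coordinate model

The optic lobe is retinotopic: each neuropil repeats a columnar unit in
one-to-one correspondence with the lenses of the eye, and the lenses form
a hexagonal grid. We address columns with axial coordinates $(p, q)$; a
lattice of `n_rings` rings holds $1 + 3n(n+1)$ columns, and rows with
$q = 0$ are flagged as the equator by convention. The orientation of the
$(p, q)$ axes relative to the eye's anatomical axes is a configuration
convention, not something the data determine.

Within a neuropil, a column is modelled as a **pin**: an ordered polyline
of $N_{\mathrm{samp}}$ 3D points from the top surface to the bottom. Depth
is the pin-point index normalized to $[0, 1]$ — we fix the normalization
as $\mathrm{index}/(N_{\mathrm{samp}}-1)$ so that the first point has
depth exactly 0 and the last exactly 1. Any 3D point is assigned to the
pin containing its globally nearest pin point, which simultaneously gives
its column and depth; this assignment is total and single-valued, so it
partitions any synapse set.

## Assigning neurons to columns

A column's **proto-axis** is the first principal component of the synapse
cloud of the neurons currently assigned to it, anchored at the centroid
and oriented top-to-bottom. Synapses are assigned to the nearest axis,
with point-to-polyline distance defined as the minimum distance to any
sampled axis point (the same rule as pin-point assignment, so the two
stages are consistent). A neuron's coordinate is the mode of its synapse
assignments.

Two deterministic conventions replace what was originally manual review:
equidistant synapses and modal ties resolve to the lowest $(p, q)$
lexicographically, and the result carries an `ambiguous` flag so
downstream code can treat tied cells separately. The original multi-stage
bootstrap (manually seeded types, then proto-axes, then prototype pins) is
folded into one loop — assign, rebuild axes from the new assignment,
reassign — with a configurable iteration count (default 3). On synthetic
volumes the loop converges in one round from the planted axes and in two
to three from laterally perturbed axes.

## Building pins

Per column the eight steps are:

1. collect the synapse positions $r_i$ of the assigned neurons;
2. PCA; orient PC1 from the top of the neuropil to the bottom;
3. drop lateral outliers: with $l_i$ the distance from the centroid in
   the PC2–PC3 plane and $\sigma_{\mathrm{lat}}$ the root-mean-square of
   the $l_i$, drop points with $l_i > f_{\mathrm{lat}}\sigma_{\mathrm{lat}}$
   (they belong to neighbouring columns);
4. define $t_i$, the projection on the step-2 PC1 normalized so the top
   surface is $-1$ and the bottom $+1$;
5. estimate the endpoints: separate PCAs of the top fraction
   ($t_i < 0.1$, falling back to the $N_{PC}$ smallest $t_i$ when the
   fraction is small) and bottom fraction ($t_i > 0.2$, or $N_{PC}$
   largest), each intersected with its surface;
6. smooth: order the retained points by $t_i$, prepend/append the
   endpoints, and replace each interior element by the mean of itself and
   its $N_{\mathrm{avg}}$ nearest list neighbours (window truncated at the
   ends; endpoints preserved exactly);
7. extract the shortest sublist from $r_{\mathrm{top}}$ to
   $r_{\mathrm{bottom}}$ whose consecutive gaps are at most
   $d_{\max} = \lVert r_{\mathrm{top}} - r_{\mathrm{bottom}}\rVert /
   N_{\mathrm{tang}}$;
8. resample with a piecewise cubic Hermite interpolant (PCHIP) against
   cumulative arc length at $N_{\mathrm{samp}}$ uniform stations.

The presets are the published values — medulla
$f_{\mathrm{lat}}=2$, $N_{PC}=800$, $N_{\mathrm{avg}}=260$,
$N_{\mathrm{tang}}=7$, $N_{\mathrm{samp}}=121$; lobula
$1.5/37/2/76$; lobula plate $1/56/2/51$ — exposed through
`pin_params()` and carried in the default configuration.

Numerical choices worth recording:

- **Step 3 inequality direction.** The source description of the trim
  step prints the inequality in a direction that contradicts its own
  rationale; we drop the *far* points ($l_i > f_{\mathrm{lat}}
  \sigma_{\mathrm{lat}}$), the only direction that yields usable pins. A
  cloud with zero lateral spread is retained in full. We likewise read
  $\sigma_{\mathrm{lat}}$ as the root-*mean*-square (with the $1/n$).
- **"Shortest sublist" is solved exactly.** We interpret sublist as an
  order-preserving subsequence and find a minimum-length one by dynamic
  programming ($O(n^2)$), ties resolved toward the earliest indices. A
  greedy scan can miss the optimum; the test suite checks the DP against
  an independent shortest-path search and, on small instances, against
  full enumeration. The minimum feasible length is
  $N_{\mathrm{tang}} + 1$, reached when $d_{\max}$ is a whole number of
  point spacings.
- **Arc-length resampling.** "Uniformly sample" is ambiguous on unevenly
  spaced points; we resample uniformly in cumulative chord length, which
  makes the stations of a straight pin exactly equidistant and is
  well-defined for any input. PCHIP is shape-preserving, so the resampled
  pin never overshoots the data range in any coordinate.
- **Surfaces.** Neuropil top/bottom are analytic planes in the synthetic
  slab (triangulated surfaces would drop in unchanged: only the
  line–surface intersection differs). A principal axis parallel to a
  surface raises a no-intersection error rather than extrapolating.

### Thin-neuropil variants

The lobula and lobula plate use one PCA of all points for both endpoints
(variant A); the lobula top endpoint is the axis projection of the median
of the $N_{\mathrm{avg}}$ shallowest points, avoiding surface ridges; and
in the lobula plate the PCA runs on per-neuron mean positions (variant B)
because the slab is thin enough that within-column depth variation rivals
the lateral spread. Three acceptance criteria apply there: at least
$N_{\mathrm{avg}}$ points after the trim, and the centroids of the 5%
shallowest and 5% deepest points within $d_{\max}$ of the respective
endpoints. We pair the shallow centroid with $r_{\mathrm{top}}$ and the
deep centroid with $r_{\mathrm{bottom}}$ — the printed pairing is
inverted, which would reject every well-formed column since the
top-to-bottom distance always exceeds $d_{\max}$ by construction.

### Regularization and filling-in

Existing pins are replaced by the componentwise median, over all pins
within lattice distance 2 (read as $\max(|\Delta p|, |\Delta q|) \le 2$,
the pin itself included), of their offset-from-first-point lists,
re-anchored at the pin's own first point. Missing coordinates are filled
as the median of their four axial $\pm 1$ neighbours when all exist, else
of a complete one-axis pair; rim coordinates with neither stay missing
and are recorded. Iteration stops when nothing is filled; on synthetic
lattices this takes one to three rounds.

## Layers

A layer scheme is a strictly increasing list of depth thresholds
partitioning $[0, 1]$ into named layers. Each threshold is a peak cut-off
of a marker type's synapse depth distribution: `syn_thre` is the largest
observed bin level with at least `frac_peaks` of the distribution mass
strictly above it (the published fractions are 0.85 medulla, 0.8 lobula,
0.75 lobula plate); runs of above-threshold stations are peaks; runs
closer than three stations merge, and a peak's upper cut-off sits at
least three stations past its lower one. We measure the three-station
separation in the stations of the distribution as given (subsampled
stations when the distribution was subsampled by 2). Cut-offs are
invariant to uniform rescaling of the counts. In the lobula plate each
boundary is the mean of two marker thresholds, reflecting the depth gaps
between the four T4 populations. Interval membership is half-open,
deeper-layer-inclusive — a depth equal to a boundary belongs to the
deeper layer, and depth 1 to the last layer — a convention the source
leaves unstated.

Which type, polarity, peak and side define each boundary is biological
knowledge, not derivable from the data, so marker specs are configuration
data.

## Typing

Connectivity features sum a neuron's connection weights per named partner
type, split into inputs and outputs, restricted to the optic-lobe
regions; `_unclear` partners are excluded and fragment bodies fold into
their parent types. Clustering is agglomerative with Ward linkage on
cosine distances, cut into a preset number of flat clusters; cosine's
built-in normalization is what makes raw count vectors comparable, and an
L2-normalize-then-Euclidean path is provided and must co-cluster with it
(the suite asserts identical partitions on the synthetic volume).
Zero-weight neurons are excluded with a warning because cosine distance
is undefined for them.

Morphology features are 244-vectors: presynapse counts per depth bin
(121 stations subsampled by 2 into 61), rescaled by
$N_{\mathrm{pre,size}}/N_{\mathrm{pre,syn}}$ so the block sums to the
presynaptic innervated-column count; the same for postsynapses; then the
raw per-depth column-innervation counts for both polarities. Only
synapses with confidence at least 0.9 enter. These cluster under
Euclidean distance.

Cluster-versus-annotation agreement uses the five-category confusion
matrix (red 1-to-1, blue many-to-1, green 1-to-many, yellow mixed, grey
outliers, by the 80%/10% rules; the categories are exhaustive and
exclusive over nonzero cells) with the greedy column ordering and its 5%
stopping rule, plus entropy-based completeness and homogeneity.
Fingerprint uniqueness uses the *ranked* top-$n$ connection list per type
(ties broken by partner name); ranked prefixes make the uniqueness
proportion provably non-decreasing in $n$, which an unordered-set reading
does not.

## Anchor matching

Connectivity matrices are row-normalized
($\tilde{C}_{ij} = C_{ij} / \sum_k C_{ik}$; all-zero rows stay zero and
are flagged), assigned by maximum-weight bipartite matching (exact;
verified against permutation brute force), and vetoed by the distance
between the anchor's class-directed mean presynapse position and the
candidate's mean postsynapse position, threshold 8 µm by default.
Internally all geometry is nm; thresholds are configured in µm because
that is how they are quoted. The group rule — all candidate classes
assigned, at least three surviving the veto — resolves a grammatically
ambiguous description in the direction consistent with the reported
group counts. The threshold is configuration, not re-estimated from the
distance histogram.

## Coverage and trimming

Per neuron, columns are ranked by synapse count and the cumulative
synapse fraction accumulated over ranks; the type-level curve is the
element-wise median, shorter curves padded with 1. The knee finder is a
from-scratch kneedle implementation (normalize both axes, difference
curve $y - x$, local maxima thresholded at $S \cdot \overline{\Delta x}$
with $S = 1$, concave increasing, the point $(0,0)$ prepended); remaining
options are pinned to the algorithm's published defaults. If the median
cumulative fraction at the knee is below 0.775 the rank falls back to the
first rank reaching 0.995, or the curve maximum. Trimming then discards,
per neuron, synapses in columns with fewer synapses than that neuron's
own rank-$\mathrm{rank}^*$ column — phrased as a count cutoff so tied
columns are kept together.

Cell size is the median trimmed column count; the coverage factor is the
mean number of cells contributing trimmed synapses per occupied column,
which satisfies the exact double-counting identity (mean cells per
occupied column × occupied columns = summed per-cell trimmed counts);
columnar completeness uses untrimmed occupancy; column area is the convex
hull of occupied coordinates in the unit-spacing planar embedding,
reported in column-area units, with an occupied-column-count fallback for
flagged types and for degenerate (collinear) hulls.

## Neurotransmitters

Calls aggregate per-synapse probability vectors over the seven classes.
Confidence is the modal fraction of per-synapse argmax classes; the
cited confidence formula is not restated in the source, so this choice is
isolated behind one function with a `mean_prob` variant (argmax and value
of the mean probability vector) behind a switch. A two-way modal tie
cannot be "most frequent" uniquely and yields unclear. Cells call at
≥50 presynapses and confidence ≥0.5, types at ≥100 and ≥0.5 on the
pooled synapses, and consensus resets aminergic calls (Dop, OA, 5HT)
without experimental support to unclear — never upgrading an unclear
call. Co-transmission is represented by letting the support table carry
several transmitters while the call logic stays single-label. Fan-out is
the per-cell output-connections-to-presynapses ratio averaged over the
type, excluding zero-presynapse cells with a warning.

## Inter-region connectivity

A neuron's contribution to region pair $A \to C$ is its output count in
$C$ times its input fraction in $A$; contributions sum over a group. A
connection's region is the region of its postsynaptic site, on both
sides of the scheme, following the database convention. The column sums
of a group matrix equal the output totals of the group's neurons that
receive at least one input — a neuron with no inputs contributes nothing
under the rule, which is the one caveat to the conservation identity.
Display ranking keeps the leading 93.75% of cumulative mass, binned at
the halving bands 50/75/87.5/93.75%.

## The synthetic generator

`generate_grid()` plants a hex lattice with per-column centre axes in a
slab (top at $z = 0$); curvature bends axes as circular arcs with sagitta
`curvature × depth`, endpoints staying on the surfaces.
`generate_neurons()` places each type as a mosaic (a permutation of
columns when counts match the lattice), samples synapse depths from the
type's profile control points with a Gaussian smear, and applies
isotropic Gaussian lateral jitter in the plane orthogonal to the local
axis tangent — default $\mathrm{spacing}/6$, chosen so nearest-axis
assignment is almost always correct, matching the premise that columnar
synapses cluster around one column. `generate_connectivity()` draws
Poisson counts per partner rule, split over the spatially nearest
partners so planted wiring respects retinotopy. Transmitter probability
vectors are Dirichlet draws peaked at the true class; confidences are
Beta(8, 2), so a realistic minority falls below the 0.5 load filter.
Seeds are explicit arguments everywhere, generation is bit-reproducible,
and the global RNG state is restored after every call.

The default study conditions (`default_type_specs()`) are three columnar
mosaics with distinct depth profiles and disjoint partner rules, one
five-column type and one sparse wide-field type; the columnar profiles
were chosen to jointly tile depth, as the pooled synapses of the real
columnar seed types do across the medulla layers — pins are built from
columnar neurons only, as in the original coordinate bootstrap. Test
problem sizes are a 19-column (two-ring) lattice with 16,000 synapses for
the recovery suites and 7-column lattices for the per-preset pin checks;
these sizes were chosen as the smallest lattices that exercise rim
effects, filling-in and mosaic structure.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: reconstruction errors and split/merge
artefacts, incomplete proofreading, non-Gaussian arbor shapes and true
neurite geometry, curved (shell-like) neuropil surfaces, biological
covariation between connectivity and morphology beyond the planted rules,
and class imbalance in transmitter predictions. Recovery at 100% on
planted mosaics bounds algorithmic correctness, not expected performance
on real reconstructions.

## Known limitations

- Pin quality degrades when a column's synapse cloud does not span the
  slab; rim columns can legitimately fail the bounded-gap step and, when
  they also lack a complete axial neighbour pair, stay missing (recorded,
  not fatal).
- The hex-distance reading of "differed by at most 2"
  ($\max(|\Delta p|, |\Delta q|) \le 2$) is one of two defensible
  conventions; it affects only which neighbours enter the regularization
  median.
- `syn_thre` selection scans observed bin heights; distributions with no
  level satisfying the mass fraction return no peaks, and an explicit
  `syn_thre` override is available for externally supplied thresholds.
- The smoothing window splits $N_{\mathrm{avg}}$ neighbours evenly around
  each element and truncates at the list ends; the source does not state
  the window's centring or end behaviour.
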