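---
title: "Models and measures of retinotopic map formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measures of retinotopic map formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinosim)
```

# The system being modelled

During development, axons of retinal ganglion cells (RGCs) grow into the
superior colliculus (SC) and refine into a topographic map: neighbouring
RGCs terminate on neighbouring SC neurons, with the temporal retina mapping
to the anterior SC and the ventral retina to the medial SC. Two orthogonal
receptor/ligand systems instruct this map. EphA receptors rise
nasal-to-temporal across the retina while their repulsive ephrin-A ligands
rise anterior-to-posterior across the SC (high-EphA axons are pushed away
from high-ephrin territory); EphB and ephrin-B form the orthogonal,
attractive pair for the dorsoventral-to-mediolateral axis. On top of the
molecular labels, correlated spontaneous activity (retinal waves) and
competition among axons for target space shape the final pattern.

`retinosim` simulates this process under four classical computational models
sharing one substrate and one evaluation suite, for five genotypes:
wild type, the `Isl2-EphA3` knock-ins (homozygous and heterozygous, which
raise EphA in a scattered ~40% subpopulation of RGCs), the ephrin-A2/A3/A5
triple knock-out (TKO, optionally with a weak residual AP gradient of
strength $K < 1$), and the `Math5` null (a retina with only 10% of the RGC
population, probing competition).

# Substrate

`build_substrate()` places $N_R$ RGCs in a unit-diameter disc and $N_{SC}$
SC neurons in a fixed SC-like outline, by uniform rejection sampling with a
minimum spacing ($d_R = 0.0139$, $d_{SC} = 0.0119$ at the reference size of
2,000 neurons per structure). Sampling extends into a margin of three
exclusion distances around the outline so that boundary neurons are not
artificially dense; margin points are discarded afterwards. Placement
aborts after $1000 \cdot N$ rejected candidates (infeasible packing).

Each Eph/ephrin subtype is an exponential profile along one normalized axis
coordinate,
$$G(x) = \max\!\big(0,\; G_0 + G_1 e^{-G_2 |x - G_3|}\big), \qquad x \in [0,1],$$
with per-subtype parameters (EphA4/A5/A6, EphB, ephrin-A2/A3/A5, ephrin-B)
taken from quantitative in-situ measurements where available and estimated
profiles otherwise. Subtype profiles are summed per system and scaled once
so that each summed wild-type gradient peaks at exactly 1; the same scale
constants are reused for every genotype, so the EphA3 knock-ins peak above 1
(the knock-in adds a flat EphA3 profile, $G_0 = 1.86$ homozygous, $0.93$
heterozygous, to Isl2-positive RGCs only) and knock-outs peak below 1. The
Isl2 label is an independent Bernoulli(0.4) draw per RGC ("salt and
pepper"); no spatial correlation is imposed because none is reported.

The exact traced SC outline used historically is not recoverable; the
package ships a smooth convex blob, longer anteroposteriorly than
mediolaterally and normalized to unit AP extent, with a circle available as
an alternative. All analyses are outline-agnostic. Gradient coordinates are
the AP position directly and the ML position divided by the outline's ML
extent.

One master seed drives every run; `seed_streams()` splits it
deterministically into placement, labelling and model streams, so a whole
experiment is reproducible bit for bit.

# The four models

All models consume the same substrate and emit an RGC-by-SC weight matrix
(`connection_state`).

## Gierer (potential descent with bounded competition)

Each RGC owns 16 terminals on SC neurons (initially uniform random). A
terminal of RGC $i$ sitting on SC neuron $j$ evaluates the potential
$$p(i,j) = R_A(i) L_A(j) - R_B(i) L_B(j) + c(j)$$
over the Delaunay neighbours of $j$ and hops to the lowest-potential
neighbour if strictly lower than at $j$ (ties broken uniformly at random).
The competition level obeys $\dot c = \epsilon \rho - \eta c$ with $\rho$
the terminal count per SC neuron ($\epsilon = 0.005$, $\eta = 0.1$; one
epoch of visiting every terminal once advances time by 1).

*Numerical choice.* Advancing $c$ by a single epoch-synchronous Euler step
is dynamically unstable at these parameter values: during a sweep every
terminal sees the same stale competition field, and since the gradient term
differs between neighbours by far less than the competition spikes that
build up, all terminals make identical decisions and aggregate into a single
travelling blob (the wild-type map never forms). Because $\rho$ is piecewise
constant between terminal moves, the ODE has an exact piecewise-exponential
solution; the default (`c_update = "continuous"`) integrates it lazily per
SC neuron between terminal examinations, which lets the competition field
respond within a sweep and yields stable, strongly topographic maps. The
epoch-synchronous variant is retained for comparison. Convergence is
monitored by the mean of $|c_j - (\epsilon/\eta)\rho_j|$ over SC neurons.

## Koulakov (stochastic energy minimization)

Connections are discrete synapses; the state energy is
$E = E_{chem} + E_{act} + E_{comp}$ with
$$E_{chem} = \sum_{syn} \big(\alpha R_A L_A - \beta R_B L_B\big), \quad
E_{act} = -\frac{\gamma}{2} \sum_{syn\ pairs} C(r, r')\, U(s, s'),$$
$$C = e^{-|r - r'|/b}, \quad U = e^{-(s - s')^2 / 2a^2}, \quad
E_{comp} = \sum_{RGC} \big({-500}\, n^{1/2} + n^2\big) + \sum_{SC} n^2,$$
with $\alpha = 90$, $\beta = 135$, $\gamma = 5/16$, $b = 0.11$, $a = 0.03$
at the reference scale. Starting from no synapses, each iteration attempts
to add a synapse on a uniformly random RGC-SC pair and then to remove a
uniformly random existing synapse, each accepted with probability
$p = 1/(1 + e^{4\Delta E})$. An epoch is $\max(N_R, N_{SC})$ iterations.

The activity sum runs over ordered synapse pairs including self-pairs; the
incremental $\Delta E$ therefore carries a $\mp\gamma/2$ self term and is
asserted (in the tests) to equal the brute-force energy difference to
$10^{-8}$. Increments truncate the $U$ kernel at $8a$
($e^{-32} \approx 10^{-14}$), far below that tolerance; `cutoff = Inf`
disables the truncation and smaller cutoffs (down to $4a$, truncation
$\sim 10^{-2}$ on $\Delta E$ of scale 1-10) are available for long
production runs.

*Duplicate synapses.* Whether one (RGC, SC) pair may hold several synapses
is not determined by the update rule alone, and the choice is not neutral:
duplicates have retinal correlation and SC interaction exactly 1, so a
clump of $k$ duplicates gains about $-\gamma k$ from each further addition.
With duplicates allowed the synapse count runs away (~70 per RGC at
reference scale) and the activity energy drowns the chemical labels — the
knock-in genotypes then show no map duplication at all. The default is
therefore no duplicates (an add attempt on an existing pair is a no-op),
under which counts equilibrate at ~25-30 per RGC; `allow_duplicates = TRUE`
restores the other convention.

*Activity strength.* The reference $\gamma = 5/16$ embeds a factor-5
pair-count compensation for running 2,000 rather than 10,000 neurons (the
number of synapse pairs within the interaction range scales with the
population, so $\gamma \propto 1/N$). Under this implementation's
conventions that value still leaves the chemistry too weak relative to the
activity glue: the homozygous knock-in duplicates only in its nasal
quarter instead of along the whole axis. The activity strength was
therefore calibrated once against phenotypes that are not quantitative
readouts: the homozygous knock-in's full-axis duplication brackets the
admissible strength (duplication reaches the temporal end only for
$\gamma \lesssim 0.08$ at 800 neurons), stability of the duplicated
pattern over the reference-length schedule selects the interior of that
bracket (at its upper edge the separation keeps annealing away instead of
settling), and the triple knock-out's local-order pattern is insensitive
across the bracket. The result is `koulakov_gamma(N) = 40/N`, with the
pair-count rule carrying it across sizes. With that single parameter set
for all genotypes, the heterozygous knock-in's collapse point — measured
afterwards — settles at ~60% of the NT axis under the reference-length
schedule. `run_koulakov()` keeps the reference table's $5/16$ as its
default. Convergence gauges: the rejected-action fraction and the mean
per-RGC projection spread; the collapse position and the `Math5` map's
internal order anneal slowly, so those runs need near-reference
schedules.

## Whitelaw (Hebbian waves with dual normalization)

The system starts fully connected with weight 1. Chemospecificity enters as
a nonnegative adhesion
$M_{ij} = R_A(i)[\max_k L_A(k) - L_A(j)] + R_B(i) L_B(j)$. One epoch sweeps
every RGC $q$ as the centre of a circular retinal wave (radius
$r_R = 0.07$; member activity $2/|neigh|$, total exactly 2), computes the
induced SC activity $y^I = W^\top x$, smooths it laterally over SC
neighbourhoods of radius $r_{SC} = 0.0289$ scaled by $k$, and accumulates
$\Delta W_{ij} = \Delta t[(M_{ij} + 1) x_i y_j - \mu y_j]$. The update is
applied once per epoch, entries below $w_{min} = 10^{-5}$ are zeroed, and
$W$ is normalized per SC neuron (totals $N_R$) and then per RGC (totals
$N_{SC}$) — in that order; normalizing the other way round erases the
knock-in double map, because it is the SC-side normalization that preserves
the growth advantage of high-EphA inputs.

Two constants are not documented anywhere in the lineage of this model:
the lateral proportionality $k$ and the epoch count. The package defaults
to $k = 0.5$ (the induced SC activity stays below the retinal input level,
as the original formulation intends) and exposes the epoch count with the
per-epoch total weight change $\sum |\Delta W|$ as the convergence gauge;
at the reference scale the map is stable well before 500 epochs.
The epoch reduces to three sparse-dense matrix products, so this model is
implemented directly in R on top of `Matrix`.

## Willshaw (marker induction)

SC ligand fields are plastic. Weights start as independent uniform draws
from $[0, 10^{-4}]$; the plastic markers start at the standard gradients
($T^A = L_A$, $T^B = L_B$), which is also the weak bias that sets map
polarity (for TKO the $K$-scaled gradient is the bias; with $K = 0$ there is
none, and global polarity varies across runs). Each step, in order:

1. induced markers $I^X_j = \sum_k W_{kj} R_X(k) / \sum_k W_{kj}$
   (zero-afferent SC neurons carry their previous value forward);
2. marker production and diffusion
   $\Delta T^A = (\sigma(1 - \zeta I^A T^A) + \delta \nabla^2 T^A)\Delta t$,
   $\Delta T^B = (\sigma(I^B - T^B) + \delta \nabla^2 T^B)\Delta t$, with the
   graph Laplacian on a Delaunay triangulation of the SC neurons whose
   sliver edges have been pruned;
3. weight growth by similarity
   $\Phi_{ij} = \exp(-[(\zeta R_A T^A_j - 1)^2 + (R_B - T^B_j)^2]/2\kappa^2)$
   followed by presynaptic normalization, leaving each RGC's weights
   summing to exactly 1.

Parameters: $\sigma = 0.05$, $\delta = 0.01$, $\theta = 0.1$, $\zeta = 1$,
$\kappa = 0.0504$, $\Delta t = 0.1$, 48,000 steps at the reference scale
(the parameter table's $\Delta t = 1$ is also accepted as an argument, but
the runs described in the source text used 0.1, which is the default).
$w_{min} = 0.001$ thresholds weights for analysis only. The compiled core
maintains $W$ as a scaled row representation so each step costs one pass
over the matrix; similarity terms with exponent below $-45$
($\Phi < 3\times10^{-20}$, forty orders below any weight that influences
the map) are dropped. The R step functions (`induced_markers()`,
`marker_step()`, `weight_step()`) define the reference semantics and the
compiled path is tested against them step for step.

*Sliver pruning.* The rule "edges making angles smaller than 10 degrees are
removed" is interpreted as: for any Delaunay triangle containing an angle
below 10 degrees, drop its longest edge. Such triangles are hull slivers;
their long edge is a nonlocal shortcut that would let markers diffuse
across the boundary chord (and, in the lattice analysis below, produces
spurious edge crossings). Dropping the edge *subtending* the small angle —
the other natural reading — removes exactly the wrong (short, local) edges
and keeps the artifact.

# Map evaluation

All measures operate on the strongest-connection mapping: each RGC with a
nonzero weight row is paired with its argmax SC neuron (continuous-weight
models are first thresholded at their $w_{min}$).

**Lattice analysis.** 100 centre nodes are spread approximately
equidistantly over the mapped retinal extent by farthest-point sampling
(seed-free: the first centre is the point nearest the centroid). Each
centre's SC node is the centroid of the strongest targets of the RGCs
within a retinal circle of radius 7% of the retinal diameter. The Delaunay
lattice on the centres (sliver-pruned, as above) is projected into the SC;
crossing edge pairs mark local distortions. Nodes are removed greedily —
the node involved in the most crossings first, ties by larger summed
crossing-edge length, then lower index — until the submap is crossing-free,
which a pairwise audit in the test suite re-verifies. Reported: the
percentage of nodes that kept all their edges, the percentage of edges
kept, AP and ML polarity (the percentage of lattice edges whose SC order
matches the canonical orientation — temporal to anterior, ventral to
medial), and the mean absolute orientation difference between SC edges and
canonically transferred retinal edges. A random map scores ~50% polarity
and retains almost no ordered submap; a perfect map scores 100/100 with
polarity near 100 (a few tenths below, because edges nearly perpendicular
to an axis resolve that axis at the scale of one SC neuron spacing).

**Virtual injections.** A retrograde injection at an SC point labels the
RGCs whose strongest target lies within the injection radius (default
0.05). The segregation of two injections is the fraction of labelled RGCs
whose nearest labelled retinal neighbour carries the same label: 1 when
fully segregated, 0.5 when overlapping. RGCs captured by both injections
are assigned to the nearer centre (exact ties: a seeded fair coin), so two
coincident injections segregate at chance.

**Contour analysis.** Labelled retinal points get a Gaussian kernel density
estimate on a 100x100 grid, bandwidth chosen by maximizing the leave-one-out
log-likelihood (scalar optimization over $[5\times10^{-4}, 0.5]$, with a
$10^{-3}$ floor flagged for degenerate point sets). The readout is the
percentage of retinal area inside the contour enclosing the top $p$% of
total labelling. `sc_coverage()` gives the percentage of SC area holding
99% of the synaptic weight — the measure that separates the `Math5`
phenotypes (anteromedial confinement vs full-SC innervation). Because the
SC neurons are themselves a uniform spatial sample of the SC, this is
measured directly as the fraction of SC neurons (in decreasing order of
afferent weight) needed to hold the mass; a weighted-KDE contour variant
is available, but its cross-validated bandwidth smooths the support
outward and inflates the area by roughly a bandwidth-times-perimeter
term.

**Collapse points.** Restricted to the central third of the DV axis, the NT
axis is divided into 50 equal bins and AP termination coordinates are
clustered with 2-means (each bin pooled with one neighbouring bin per
side, since a lone bin holds only ~10-20 RGCs; labels belong to the
central bin). The stated distinctness gates — cluster mean separation
above 1.5 pooled within-cluster standard deviations, minor cluster at
least 5% of the bin — are kept but cannot by themselves decide
bimodality: a 2-means split of *unimodal* data always separates its
cluster means by ~2.2-4 pooled SDs, and at these bin sizes the 5% rule
never binds. A bin is therefore called double only if, in addition, the
split shows a genuine density valley (at most `max(1, 0.10 n)` points in
the middle half of the inter-mean interval; unimodal data put 25-30% of
their mass there) *or* the separation exceeds 4.5 pooled SDs (measured
unimodal maps stay below 4.0; genuinely separated bands run 5-10). The
collapse point is the nasal/temporal boundary between double and single
bins minimizing label misclassification, shifted back by the pooling
window; maps >90% single report "no split", maps double everywhere except
at most one bin "no merge". On constructed fixtures the detector recovers
a merge built at 70% of the NT axis to within one bin, reads the identity
and noisy maps as no-split, and the fully duplicated map as no-merge.
One bias is intrinsic and worth knowing about: when two bands approach
each other gradually, there is a zone (separation between roughly 2 and
4.3 within-band SDs) in which no statistic of the sample distinguishes
"two overlapping bands" from the flat-topped unimodal spread of a clean
map bin; this detector reads that zone as single, so gradually merging
maps report the nasal edge of the ambiguity zone rather than the point
where the band means finally coincide.

# Fixtures

`make_mapping()` builds mappings with known ground truth on any substrate:
identity (canonical orientation), noisy, AP-mirrored, duplicated (two
interleaved populations offset along AP), merged-at-$x$ (two separated AP
bands nasal of $x$, one band temporal — the heterozygous knock-in
geometry), random permutation, and half-coverage. These drive the analysis
oracle tests without any model run. The constructions are pure functions of
(substrate, seed).

# What the synthetic conditions do and do not show

The generator reproduces the *structure* of the modelled system — point
densities, gradient shapes, genotype manipulations — but real maps develop
from growth cones with arborization dynamics, non-exponential gradients and
measured (not constructed) retinal waves. Passing the oracle and phenotype
tests shows the models and measures are implemented faithfully at the
stated parameter values, not that any model is a complete account of the
biology.

# Problem sizes

The reference configuration is 2,000 neurons per structure with 10,000
epochs (Gierer, Koulakov), ~500 epochs (Whitelaw) and 48,000 steps
(Willshaw). The test suite and the acceptance script run the same code at
reduced sizes chosen by the models' own convergence gauges
(terminal-move and rejection-fraction plateaus, weight-change decay):
Koulakov at 800 neurons per structure with `koulakov_gamma()` and the $4a$
activity cutoff (the knock-in runs keep a near-reference epoch count,
since their collapse position anneals slowly); Gierer at 800-1,000
neurons; Whitelaw and Willshaw at 450-500 neurons with schedules past the
point where their separation profiles stop changing. Desk-scale maps are
noisier than reference-scale maps — lattice circles capture fewer RGCs
and termination zones are grainier — so percentage measures carry several
points more spread across seeds, and lattice node retention in particular
sits a few points below its reference-scale value.

# Known limitations

* The SC outline is a stand-in shape; absolute area-based numbers (SC
  coverage) depend mildly on it.
* The collapse detector's valley condition is a regularization the source
  text does not specify; it is required for the detector to accept any
  unimodal bin at finite sample size.
* The Willshaw model's very long runs rotate the map slowly (the plastic
  gradients are not locked to the anatomical axes); orientation-sensitive
  measures are meaningful only at the documented run lengths.
* No countergradients, no activity-perturbed genotypes, no optic-tract
  fiber ordering: these are outside the scope of all four models as
  implemented here.
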