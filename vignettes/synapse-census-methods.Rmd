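---
title: "Methods: synapse quantification in FIB/SEM neuropil stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synapse quantification in FIB/SEM neuropil stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices
behind `synapseCensus` in the way a maintainer or reviewer would want
them stated: what each stage assumes, which knobs matter, what the
synthetic data do and do not emulate, and where the genuinely open design
decisions were made.

## 1. The quantification problem

Focused ion beam / scanning electron microscopy (FIB/SEM) produces
aligned stacks of backscattered-electron images of tissue, a few
nanometres per pixel in the imaging plane and tens of nanometres of
milling depth per section. In cortical neuropil, chemical synapses are
visible as apposed electron-dense plates — the presynaptic density and
the postsynaptic density (PSD) separated by the synaptic cleft. Two
morphological classes matter: asymmetric junctions (AS, prominent PSD,
overwhelmingly excitatory) and symmetric junctions (SS, thin PSD similar
to the presynaptic density, overwhelmingly inhibitory). A census asks:
how many junctions per unit volume, of which type, on which postsynaptic
target (spine head, spine neck, dendritic shaft), and on which kind of
dendrite (spiny versus not determinable).

The package implements that census as a pipeline of five stages —
synthetic-stack generation, junction segmentation, counting-frame
stereology, target annotation, statistics — each exposed as ordinary
functions over S4 containers (`VoxelVolume`, `GroundTruth`,
`JunctionSet`, `CountingFrame`, `LayerCountTable`). `runPipeline()`
orchestrates them with a seed, a configuration list (or YAML file) and a
JSON manifest. The package's interface is these functions; there is no
shell executable, by design.

## 2. The synthetic neuropil generator

Real censuses rest on manually proof-read annotations, and no imaging
data are bundled here. Instead the generator produces stacks whose every
object is known, so each downstream stage can be scored exactly.

**Scene model.** Dendritic shafts are smooth random-walk tubes
(default diameter 0.3–1.5 µm, step 150 nm, direction jitter 0.08 per
step). Spines are a cylindrical neck (radius 70 nm, length 250–500 nm)
plus a prolate ellipsoidal head (transverse semi-axis 180–260 nm,
elongation 1.2) attached to a shaft. Every synapse is two apposed plates:
a presynaptic density 20 nm thick and a postsynaptic density drawn from
40–60 nm (AS) or 15–25 nm (SS), discs of radius 130–180 nm separated by a
bright cleft of at least one voxel. An unlabeled presynaptic bouton
sphere sits behind the presynaptic plate. Glia and mitochondria are
omitted: nothing downstream consumes them. Background is bright (gray
200), cytoplasm barely darker (190), densities dark (40), matching
backscattered contrast; Gaussian noise (sd 12) plus a small Poisson dark
current are added last. The AS/SS PSD-thickness ranges are a modeling
choice — the field's "prominent versus thin PSD" criterion carries no
published numeric boundary — and they are what makes automatic
classification at a 32 nm boundary operational.

**Population model.** The number of synapses is Poisson with mean
`synapseIntensity x nominal volume`. Types and targets follow the
configured mixture: AS fraction 0.9028; spine-target fractions 0.8361
(AS) and 0.2547 (SS); head fraction 0.9702 among axospinous synapses;
5.57% of innervated spines carry 2–3 synapses, mixed over the observed
combination categories; 58.98% of shaft targets lie on spiny dendrites.
These defaults are the layer-averaged values of the bundled census and
are not tuned per experiment. The parameterisation is overdetermined:
single/multiple spine-profile mixtures fix the AS share among
spine-targeting synapses at 0.9646, so the AS share of shaft synapses is
derived in the constructor such that the overall AS fraction equals
`asFraction` exactly in expectation (the implied conditional
P(spine | AS) is then 0.833 rather than the configured 0.8361 — the
mixture components cannot all hold simultaneously, and we chose to honor
the overall AS fraction and the profile table exactly).

**Truncation is emergent.** Objects are laid in a domain extending
1 µm beyond the stack and clipped at the faces. A spine attached to a
dendrite segment outside the stack enters through a face; its in-volume
part cannot be traced to a parent, which is exactly the truncation
mechanism of real annotation work. No truncation flag is ever sampled.

**Non-interpenetration.** Structures never overlap: dendrite walks
steer around existing tubes; spines must clear every foreign tube and
every earlier spine along their whole neck and head; junction plates
must not stamp into structures other than their own postsynaptic
element. Placements that cannot be achieved within the retry budget are
dropped, so the ledger always describes the realized population (at the
default intensity the realized count is within ~2% of the Poisson
plan; in deliberately crowded test volumes the shortfall is larger).
A repair pass guarantees that every non-border spine is 26-adjacent to
its parent dendrite in the label volume, and the neck root claims a plug
inside the parent so the true parent always carries the dominant contact
surface.

**What the generator does not emulate.** Membrane texture, vesicle
clouds, mitochondria, milling artifacts (curtaining, charging) and
section-to-section misalignment are absent; gray levels are bimodal by
construction. Passing segmentation tests on this material therefore
demonstrates the correctness of the operator chain and its geometry
handling, not robustness to the full appearance of real tissue — on real
stacks the threshold and the minimum-volume floor would need operator
attention, exactly as in interactive practice.

**Known spatial bias.** The constructive placement process leaves the
synapse population slightly non-uniform: truncated-spine synapses
concentrate within ~0.5 µm of the faces, so the interior runs ~5–8%
below the nominal intensity while the whole-volume realized count honors
it. Every scheme we tried that removes the excess (dropping out-of-volume
head synapses rather than redrawing them) trades it for a count deficit,
so the bias is documented rather than hidden: density-recovery
experiments quote both the interior counting-frame estimate and the
realized whole-volume density.

## 3. Segmentation

The chain is blur – threshold – components – classify, each with a
logged parameter:

* `sigmaNm = 8` — smoothing bandwidth in nm, converted per axis to
  voxels so anisotropic stacks smooth isotropically in tissue space.
  Mirror boundary, kernel truncated at 4 sigma.
* `level = "otsu"` — one global threshold from the gray histogram
  (recorded on the mask); any fixed level can be supplied instead.
* `connectivity = 26` — junctions are thin oblique plates;
  6-connectivity fragments them.
* `closingVoxels = 2` — a binary closing bridges the bright cleft when
  the threshold leaves the two densities disconnected; component
  membership is decided on the closed mask but each junction keeps only
  its true dark voxels.
* `minVolumeNm3 = 5000` — floor below which components are dropped (and
  counted in the run log); one noise voxel at 4 x 4 x 20 nm is 320 nm³.
* `thicknessBoundary = 32` — AS/SS boundary on the PSD thickness,
  centred between the generator's SS (15–25 nm) and AS (40–60 nm)
  ranges.

Classification estimates the cleft plane as the minor principal axis of
the junction's voxel cloud in physical coordinates (darkness-weighted
when gray values are available), splits the projections into the two
densities with a deterministic 1D two-means partition, and estimates
each density's thickness as `sqrt(12 var - footprint)` where the
footprint term removes the voxel extent along the normal — a uniform
slab of thickness h has variance h²/12, and the deconvolution makes the
estimate resolution-independent. Two numerical guards matter: the
measurement uses only the half-amplitude core of the junction (voxels
darker than midway between the density gray and the image background),
because a generous threshold admits a partial-volume halo that would
inflate both densities; and junctions with fewer than 10 voxels or a
degenerate (coplanar) cloud are reported `unclassified`, never silently
typed. Oblique and en-face junctions can also be inspected through
`reslice()`, which permutes the stack axes and their voxel metadata; all
physical measurements are invariant under it.

## 4. Counting-frame stereology

The unbiased brick has inclusion faces at the low x, y, z ends and
exclusion faces with extended forbidden planes at the high ends; a
junction counts iff its voxel set intersects the brick and touches no
exclusion surface. The rule is applied to the whole voxel set, never the
centroid: junctions are extended plates, and centroid rules undercount
obliquely cut ones. The plane at `x = hi_x` extends over `y >= lo_y`,
`z >= lo_z` (and cyclically), which makes the rule exact under tiling —
the suite verifies that translating random voxel-set objects across a
lattice of frames counts each exactly once, and that the estimator's
mean over 200 Poisson-seeded frames matches the generative intensity
within Monte-Carlo error. Densities divide by shrinkage-corrected volume
`nominal / (1 - s)^3`; the default `s = 0` because the factor used in
any given study is a property of its fixation protocol (the source
protocols cite but do not print theirs), so any nonzero default would be
an invented number. Synapses on truncated targets count toward density
and are excluded only from target-proportion tables.

## 5. Target annotation

Annotation is deterministic bookkeeping over object-level labels, not
image-based inference: the census workflow this package follows
identified targets by human navigation, and inventing a recognizer would
exceed it. The postsynaptic object of each junction comes from the
ledger (or an external annotation volume in the same shape); the spine
is then traced through the label volume. `traceToParent()` verifies
26-adjacency to the designated parent when one is given — a spine
clipped at the border can incidentally brush a passing dendrite, and
contact size alone cannot always distinguish that brush from a true
attachment — and falls back to largest-contact discovery when no parent
is designated. A spine that reaches no parent and touches a stack face
is `truncated`; reaching neither a parent nor a face is an
annotation-integrity error. Dendrites are `spiny` iff at least one
in-volume spine traces to them; spine-free segments are
`not_determined`, since absence of spines in the sampled volume proves
nothing. Spines straddling the head/neck boundary are assigned by
majority voxel overlap with ties going to the head (heads dominate the
head/neck split roughly 97:3).

## 6. Statistics

Percentage tables are rebuilt from counts at full precision and rounded
only at render time. The layer-averaged column is the **unweighted mean
of per-layer percentages**, not the pooled-count percentage: sampling
effort differs per layer, the reference census reports unweighted means,
and only this choice reproduces its printed averages; pooled percentages
are attached as an attribute for comparison. The published
"heads among axospinous" average follows the same convention — it is the
ratio of the layer-averaged head percentage to the layer-averaged
axospinous percentage. Expected contingency counts use
`E_ij = T_i T_j / T`; the chi-squared test applies no Yates correction
by default (the plain formula is what reproduces the printed expected
counts; the correction is available by flag). Kruskal–Wallis and
Mann–Whitney use tie-corrected rank statistics, exhaustive enumeration
for total n ≤ 8 and the classic approximations above, two-sided; raw
p-values are reported without multiplicity correction, matching how
pairwise layer comparisons are conventionally quoted in this literature.
Per-stack values behind published layer comparisons live in records not
bundled here, so the rank tests are exercised on synthetic per-stack
proportions and against enumeration oracles rather than on reproduced
significance patterns.

## 7. Problem sizes used by the suite

The suite runs entirely on synthetic material sized for a desk machine:
fixtures are 96 x 96 x 32 voxels at 8 x 8 x 20 nm; parameter-recovery
volumes are ~42 µm³ at 8 x 8 x 20 nm with the synapse intensity raised
to 8 /µm³ (several seeds pooled to exceed 500 synapses) — a compact
volume at elevated intensity preserves the per-synapse segmentation task
(same plate geometry, same mixtures) while a full-scale stack at the
census density would need hundreds of µm³; density recovery runs at the
census mean density 0.89 /µm³ in ~100 µm³ cubes at 10 x 10 x 25 nm.
Acquisition-scale stacks (2048 x 1536 x 255 voxels at 4 nm xy) remain
the generator's default geometry and work through the same code path.

## 8. Known limitations

* The generator's gray model is bimodal; Otsu thresholds real stacks
  less gracefully than it thresholds these.
* The interior synapse intensity runs a few percent below nominal (see
  section 2); counting-frame recoveries are quoted with this in mind.
* PSD thickness classification assumes the two densities are resolvable
  across the cleft; at voxel sizes much coarser than ~15 nm xy the
  two-means split degrades before the thickness estimator does.
* Aggressively crowded volumes thin the realized population through
  rejection; the ledger is always the source of truth for what exists.
* HDF5 containers are not written; stacks travel as multipage TIFF with
  a JSON sidecar, ledgers as JSON, tables as CSV.
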