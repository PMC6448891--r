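---
title: "Catalytic-geometry constraints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic-geometry constraints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catgeo)
```

## The conservation model

Enzymes that catalyze the same reaction hold their catalytic residues in a
tight, family-wide spatial arrangement: the side chains must meet the
substrate with the right geometry or the chemistry does not happen. `catgeo`
operationalizes this as a set of scalar distances. For a target sequence with
catalytic residues $A$ and $B$, the Euclidean distance $d = m(A, B)$ is
measured between a chosen atom of each residue; the equivalent distance
$d' = m(A', B')$ on an aligned homolog uses the residues identified through
the sequence alignment; and

$$\Delta = d - d'$$

is the homolog's deviation from the catalytically viable arrangement. Only
the C$\alpha$ and C$\beta$ atoms are used: they are present in (almost) every
residue, insensitive to side-chain rotamers, and between them they capture
both backbone placement (C$\alpha$) and the direction the side chain points
(C$\beta$). For every unordered residue pair all four cross-residue
combinations are enumerated — C$\alpha$–C$\alpha$, C$\alpha$–C$\beta$,
C$\beta$–C$\alpha$, C$\beta$–C$\beta$ — as distinct measurements, because the
two mixed pairs carry independent information about which of the two side
chains is misdirected.

Two assumptions matter. First, distances are compared, not coordinates, so
$\Delta$ needs no superposition and is exactly invariant under rigid motion
of either structure — the measurement cannot be contaminated by a poor
overlay. Second, the alignment is trusted to identify the equivalent
residues; a misaligned catalytic residue produces a nonsense $\Delta$, which
is why records carry the template's percent identity so low-homology strata
can be inspected separately.

Pooled over homolog ensembles, the $\Delta$ distribution is approximately
Gaussian, centered at zero, with a standard deviation of about 0.5 Å. That
number is the empirical license for the constraint tolerance below.

## From distances to restraints

A reference structure in a catalytically viable arrangement (for
benchmarking, the target crystal itself; in production, any solved homolog
with a mechanistically bound ligand) yields one reference distance per
enumerated atom pair. Each becomes a harmonic AtomPair restraint line:

```
AtomPair CB 73 CB 217 SCALARWEIGHTEDFUNC 1000 HARMONIC 8.23 0.5
```

* **tolerance** (0.5 Å default): the standard deviation of the harmonic
  well, set to the observed family-wide conservation level — the restraint
  tolerates exactly the deviation real homologs exhibit, no more.
* **weight** (1000 default): a scalar up-weighting that makes these few
  restraints dominate any other term acting on the same atoms; the intent is
  a hard prior, not a soft suggestion.
* **numbering** (`author` default): the example above uses the crystal's
  author numbering. `pose` mode renumbers 1..n over the modeled region
  (after terminal trimming) and emits the author-to-pose mapping as a
  sidecar table, since modeling engines consume pose numbers.

Rendering prints distances to 2 decimals and the tolerance to 1 decimal,
single-space separated, in a deterministic canonical order (residue number,
then CA before CB), so identical inputs give byte-identical files. The
parser inverts the renderer at those precisions; round-tripping is tested on
randomized reference sets.

Glycine has no C$\beta$: affected pairs are dropped with a message rather
than fabricating a pseudo-atom — a measurement tool should never invent
coordinates. A $k$-residue site therefore yields $4\binom{k}{2}$ lines minus
$2(k-1)$ per glycine.

## Template handling

Template selection consumes precomputed pairwise alignments (aligned FASTA
or Clustal). Percent identity is computed over doubly-ungapped columns by
default; candidates above the 80 % ceiling are removed (strictly "over":
exactly 80.0 survives), and up to 10 of the remainder are kept, ranked by
descending identity with lexicographic tie-breaks. Keeping the *closest*
eligible homologs is a deliberate choice the selection rule leaves open:
they carry the most structural signal per template. The modeled region is
trimmed only at the termini — positions before the first or after the last
position covered by any template — never at internal gaps.

## Superposition and accuracy metrics

Rigid superposition uses the SVD (Kabsch) solution with reflections
forbidden; collinear inputs raise a conditioning error rather than returning
an arbitrary rotation. The test suite checks the fitted RMSD against an
independently implemented quaternion characteristic-matrix oracle to 1e-8 on
random clouds.

Subset C$\alpha$ RMSDs default to the **global frame**: the model is
superposed on all mapped C$\alpha$ atoms, then the RMSD is read out over the
subset (catalytic residues, 8 Å shell, or everything) without refitting.
This matches the "overlay the homolog onto the query, then measure the site"
procedure and makes the three metrics nested in interpretation: a local
refit (`mode = "local"`), which can only be tighter, is available when the
question is intrinsic subset geometry rather than placement in context.

The 8 Å active-site shell contains every residue with at least one heavy
atom within 8 Å (inclusive) of the reference center. Whether the center is
the ligand or the catalytic residues is genuinely ambiguous in practice;
both are supported, ligand-centered being the default when a ligand is
present since bound ligands define the functional site most directly.

Ligand accuracy is heavy-atom RMSD after superposing the protein frames,
atoms paired by name within the het group. No graph-automorphism symmetry
correction is applied — a known limitation: for internally symmetric ligands
the name-based pairing can overstate the RMSD.

Success counting is strict: a target counts only when its best model is
*below* the threshold (default 1.0 Å), with best-of-$n$ semantics (the
minimum over the $n$ top-ranked models; $n = 5$ mirrors multi-submission
assessment, $n = 1$ scores only the energy winner).

## The filter cascade

Docked-model selection works on score tables alone (energies are produced by
external samplers; `catgeo` never computes them):

1. per starting model, keep the lowest 10 % by total score
   (count = ⌈fraction × group size⌉, so small groups keep at least one
   model), then pool;
2. drop any model whose **largest single** mechanism-constraint penalty
   exceeds 1.0 energy units — "single" read as max, not sum, since one badly
   violated interaction already falsifies the mechanism;
3. keep the lowest 50 % by active-site energy (ceiling count again);
4. sort by ligand interface score.

Ties break on (score, model id) everywhere, and the table is canonically
sorted internally, so the cascade is invariant to input row order; the
tests verify equivalence against a brute-force $O(N^2)$ re-implementation.
An empty post-filter table is a legitimate outcome (it is how targets with
no mechanism-consistent models manifest) and is reported with a full count
trace rather than an error.

Scorefiles are the whitespace-delimited `SCORE:`-tagged dialect; the
penalty, interface and grouping column names are configurable because
different pipelines label them differently.

## The synthetic generator

The generator exists so every operation is testable against known ground
truth with no downloads. It emulates the *statistical* situation of a
conservation benchmark, not protein physics:

* **toy fold**: catalytic C$\alpha$ atoms sit on a 4 Å circle around the
  origin (a convergent active site by construction, guaranteeing every
  catalytic residue lies inside the default 8 Å shell around the ligand
  placed at their centroid); connecting loops are circular arcs bulging away
  from the site in tilted planes; terminal tails run straight. Consecutive
  C$\alpha$–C$\alpha$ spacing is exactly 3.8 Å by chord construction and
  C$\beta$ atoms sit at an idealized 1.53 Å offset. The walk is smooth and
  non-self-intersecting for well-separated catalytic indices but makes no
  claim of Ramachandran realism — the metrics under test care about
  distances and frames, not dihedrals.
* **homologs**: independent per-coordinate Gaussian noise, with separate
  scales for catalytic residues (`sigma_cat`) and everything else
  (`sigma_global`), then a random proper rotation and translation, then
  sequence mutations at non-catalytic positions to hit a percent identity
  drawn from `pid_range`. For a target distance measured against a template
  whose two endpoint atoms each carry isotropic noise $\sigma$, $\Delta$ has
  standard deviation $\sigma\sqrt{2}$ (to first order in $\sigma/d$); the
  default `sigma_cat` $= 0.5/\sqrt{2} \approx 0.354$ Å therefore plants the
  0.5 Å conservation level, and `sigma_global` = 1.0 Å gives the larger
  whole-chain divergence typical of 20–80 % identity pairs. These defaults
  were fixed from that closed-form relation, once.
* **score tables**: 5 groups × 100 rows of correlated Gaussians with a
  configurable interface-score/ligand-RMSD correlation, plus optional
  planted mechanism violations placed on guaranteed stage-1 survivors so
  filter arithmetic is checkable by construction.

Everything is deterministic given the seed (the RNG state is scoped and
restored). What passing tests on this generator do **not** show: behavior on
real crystallographic pathologies (alternate conformations beyond simple
altloc picks, missing density, multiple chains), on genuinely non-Gaussian
structural divergence (hinge motions, loop remodeling), or on real energy
landscapes — the score generator's correlation structure is an assumption,
not an emulation of any force field.

## Numerical and degenerate-input choices

* Altloc resolution: highest occupancy wins, ties to the label that sorts
  first; first MODEL only; waters always excluded from ligand groups.
* Multi-chain files: the first polymer chain is used unless a chain is
  requested explicitly (the intended benchmark inputs are monomeric).
* Missing atoms raise a distinguishable missing-atom condition (glycine
  C$\beta$ being the common case), distinct from absent-residue key errors;
  all errors are classed conditions (`catgeo_*_error`) so callers can
  dispatch on them.
* Zero-length reference distances render as `0.00` rather than erroring:
  pathological, but a formatting question, not a measurement one.
* Sample statistics use the $n-1$ denominator; histograms default to 0.1 Å
  bins aligned to bin-width multiples.
* Percent identity of an alignment with no doubly-ungapped columns is 0,
  not NaN.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances: toy enzymes of 25–100 residues with 2–6 catalytic residues,
homolog ensembles of 10–200 templates, score tables of up to 1000 rows, and
Monte-Carlo oracles of $10^4$–$10^5$ draws. These sizes make every
distributional check stable to within the asserted tolerances while keeping
the full suite fast; they are package defaults, and all of them scale up by
argument.

## Known limitations

* No symmetry-aware ligand atom pairing (see above).
* Alignments are consumed, never computed; alignment error is invisible to
  the deviation machinery beyond the carried identity value.
* Only AtomPair/HARMONIC constraints are authored; angle or dihedral
  restraints on catalytic geometry, and the authoring of enzyme-mechanism
  ("enzdes") constraint blocks, are out of scope (mechanism files are
  consumed only as per-model penalty scores).
* The toolkit measures and filters; it does not build models or sample
  docking poses.
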