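# catgeo

Catalytic-geometry constraints for enzyme active-site modeling.

## The problem

Comparative (homology) modeling usually gets an enzyme's global fold right
while missing the atomic detail of the active site — exactly the part that
matters for docking inhibitors or engineering catalysts. But the chemistry an
enzyme family performs pins its catalytic residues into a nearly invariant
spatial arrangement: across homologous structures, the distances between the
Cα and Cβ atoms of catalytic residues deviate from a catalytically viable
reference by only about half an Ångström, even at 20–30 % sequence identity.
That conservation is cheap, reusable prior information: measured once on a
solved structure, these distances can restrain the modeling of any number of
related sequences.

`catgeo` is a toolkit for working with this signal. It is aimed at structural
bioinformaticians who build enzyme models with Rosetta-style pipelines and
want to (a) quantify the conservation on their own homolog sets, (b) emit it
as constraint files, and (c) filter and score the resulting models.

## What it computes

**Deviation analysis.** For a target *S* with catalytic residues *A*, *B* the
Euclidean distance *d* = m(*A*, *B*) is measured between specific atoms
(Cα/Cβ), the equivalent distance *d′* = m(*A′*, *B′*) on an aligned homolog
*T*, and the deviation Δ = *d* − *d′* summarizes how far the template strays
from the catalytically viable arrangement. All Cα/Cβ combinations over all
catalytic residue pairs are enumerated; the pooled Δ distribution (mean, sd,
histogram) is the conservation estimate.

**Constraint emission.** Reference distances become weighted harmonic
AtomPair restraints in the Rosetta constraint-file dialect, e.g.

```
AtomPair CB 73 CB 217 SCALARWEIGHTEDFUNC 1000 HARMONIC 8.23 0.5
```

— "keep this Cβ–Cβ distance at 8.23 ± 0.5 Å, up-weighted by 1000 so it
dominates other restraints". Author or pose numbering is supported, with an
emitted mapping table for trimmed modeling sequences.

**Model selection.** A four-stage cascade over Rosetta-style score tables:
per starting model keep the lowest 10 % by total score and pool; drop models
with any single mechanism-constraint penalty above 1 energy unit; keep the
lowest 50 % by active-site energy (residues within 8 Å of the site); sort by
ligand interface score. The final pick is the lowest-interface model or the
lowest-ligand-RMSD model among the five lowest-interface ones.

**Evaluation.** Site-specific accuracy metrics in one global frame: Cα RMSD
over the catalytic residues, the 8 Å active-site shell and the whole chain,
ligand heavy-atom RMSD after protein superposition, and strict sub-1 Å
success counting with best-of-*n* semantics.

**Synthetic fixtures.** A deterministic toy-enzyme generator (ideal 3.8 Å
backbone, planted convergent active site, tunable catalytic vs global noise,
homolog ensembles at 20–80 % identity, planted score tables) so the whole
pipeline runs and tests with no structure download.

## Worked example

```r
library(catgeo)

spec <- synthetic_spec(seed = 42)      # 50 residues, catalytic site 10,25,40
toy  <- make_toy_enzyme(spec)
toy$structure
#> <cg_structure 'toy042': 50 polymer residues (100 atoms), 1 ligand group(s)>

refs <- measure_reference_distances(toy$structure, toy$site)
cat(render_cst(refs))
#> AtomPair CA 10 CA 25 SCALARWEIGHTEDFUNC 1000 HARMONIC 6.93 0.5
#> AtomPair CA 10 CB 25 SCALARWEIGHTEDFUNC 1000 HARMONIC 5.73 0.5
#> ... (12 lines: 3 residue pairs x 4 atom pairs)

# conservation across 10 noisy homologs
recs <- do.call(rbind, lapply(1:10, function(k) {
  h <- perturb_homolog(toy$structure, spec, k)
  deviation_records(toy$structure, toy$site, h$structure,
                    residue_correspondence(h$alignment), pid = h$pid)
}))
summarize_deviations(recs)
#> <cg_deviation_summary [all]: n = 120, mean = 0.049 A, sd = 0.454 A>

# four-stage selection over a 5 x 100 docking score table
res <- apply_filter_cascade(make_score_table(seed = 42), filter_config())
res$trace
#> input  after_pool  after_mechanism  after_active_site  final
#>   500          50               50                 25     25
select_final(res$table, filter_config())
#> [1] "g5_m0017"
```

The deviation sd of ≈ 0.45–0.5 Å is the generator's planted conservation
level being recovered; the trace shows the 10 %-per-group pooling
(500 → 50), no mechanism violators in this table (50 → 50), and the 50 %
active-site cut (50 → 25).

A command-line wrapper over the same functions is installed as `exec/catgeo`
(subcommands `simulate`, `cst`, `measure`, `filter`, `eval`; see
`catgeo --help`).

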