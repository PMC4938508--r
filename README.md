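# memidr — intrinsic disorder in transmembrane proteomes

`memidr` is an R package for proteome-scale analysis of intrinsically
disordered regions (IDRs) in membrane proteins, for structural
bioinformaticians who have sequences and UniProt-style topology
annotations and want to ask: where does disorder sit relative to the
membrane, and what is it doing there?

An IDR is a run of **≥ 30 consecutive residues** called disordered by a
per-residue predictor; a protein with at least one IDR is an IDP, one
with none an FOP. The package provides:

* **Disorder scoring** — a charge/hydropathy score
  (`foldindex_score()`, per-window
  `s = 2.785·⟨H⟩ − |⟨R⟩| − 1.151` with Kyte–Doolittle hydropathy scaled
  by `(H+4.5)/9`; `s < 0` ⇒ disordered), the TOP-IDP propensity scale
  (`topidp_score()`), ingestion of external predictor tracks
  (`ingest_scores()`), and a [0,1] consensus (`consensus_track()`).
* **IDR calling** (`call_idrs()`, 30-residue rule), IDP/FOP
  classification, and pairwise predictor-overlap tables
  (`inclusion_table()`, `100·|A∩B|/min(|A|,|B|)`).
* **Topology** — models built from TRANSMEM/TOPO_DOM features with
  alternation inference (`build_topology()`), majority-vote side
  localization of IDRs/MoRFs/PTM sites (`localize()`), side percentages,
  per-side IDR occupancy and length statistics.
* **Orientation prediction** (`predict_orientation()`) — resolves the
  two-fold in/out ambiguity of a multi-pass protein by preferring the
  labeling that places IDRs (and boundary K/R, the positive-inside rule)
  cytoplasmic.
* **Composition/PTM/PPI** — amino-acid enrichment, phosphosite density
  and IDR co-localization, unique-partner degree statistics.
* **Synthetic proteomes** (`generate_proteome()`) with planted TM
  architecture, side-biased IDRs, PTM sites and interaction degrees, so
  the whole pipeline is testable offline with known ground truth.

## Worked example

```r
library(memidr)

# a 300-protein synthetic membrane proteome with known truth
sim    <- generate_proteome(sim_spec(n_proteins = 300, seed = 42))
tracks <- lapply(sim$records, foldindex_score, window = 21)
idrs   <- idr_table(tracks)
labels <- idp_labels(idrs, names(sim$records))
mean(labels == "IDP") * 100
#> 66

models <- lapply(sim$records, build_topology)
asg    <- localize_intervals(models, idrs)
side_statistics(asg, pass_types(sim$records))
#>     pass_type n_cyto n_extra n_ambiguous pct_cyto pct_extra
#> 1  multi-pass    235      52           0     81.9      18.1
#> 2 single-pass     45      14           0     76.3      23.7
#> 3         all    280      66           0     80.9      19.1
```

81.9% of multi-pass IDR calls localize cytoplasmic, recovering the
planted 79.6% side bias within sampling error — the cytoplasmic
preference that motivates using disorder for topology prediction.
Running that idea on the packaged 8-TM fixture with a disordered
C-terminal tail:

```r
fx <- tmem117_like_fixture()
v  <- predict_orientation(fx$record,
                          idrs_from_track(foldindex_score(fx$record, 21)))
c(v$verdict, round(v$margin, 2), v$n_term_side)
#> "A" "0.64" "Cytoplasmic"
```

Candidate A places the disordered tail (and, with eight TM segments, the
N-terminus) inside the cell, with a decisive 0.64 margin over the
mirror-image orientation.

A one-shot pipeline over files is available via `run_all(run_config(...))`
(TSV bundle + hashed manifest + markdown report) or the CLI in
`inst/cli/memidr.R`.

## Documentation

The methods vignette (`vignettes/memidr-methods.Rmd`) documents the
scoring formulas, the topology and orientation conventions, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and known limitations.
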