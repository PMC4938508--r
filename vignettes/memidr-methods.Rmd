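---
title: "Methods: disorder analysis of membrane proteomes with memidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder analysis of membrane proteomes with memidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memidr)
```

## The problem

Roughly a quarter of the human proteome is membrane-embedded, yet membrane
proteins are routinely under-represented in studies of intrinsic disorder.
An intrinsically disordered region (IDR) is operationally defined here, as
is standard in the field, as a stretch of **at least 30 consecutive
residues** called disordered by a per-residue predictor; a protein with at
least one IDR is a disorder-containing protein (IDP), and one with none is
a fully ordered protein (FOP). For membrane proteins the interesting
questions are topological: do IDRs prefer the cytoplasmic face, how much
of each topological domain do they occupy, and can their placement be
turned around to *predict* the orientation of a multi-pass protein whose
membrane topology is known only up to the two-fold in/out ambiguity?

`memidr` implements this analysis end to end on standard inputs (FASTA
sequences; UniProt-style TRANSMEM/TOPO_DOM feature tables with 1-based
inclusive coordinates; optional external score tracks, MoRF intervals,
PTM site tables and bait/prey interaction edges), plus a synthetic
membrane-proteome generator with planted ground truth so that every stage
is testable without any external database.

## Disorder scoring

Two scale-based predictors are implemented natively; everything heavier
(pairwise-energy, SVM or neural-network predictors) is consumed as an
externally computed score track via `ingest_scores()`, never
reimplemented.

**Charge/hydropathy score** (`foldindex_score()`). For each residue, over
a window centred there, the mean Kyte–Doolittle hydropathy rescaled to
[0,1] via $(H + 4.5)/9$, $\langle H\rangle$, and the mean net charge
$\langle R\rangle$ (fraction of K/R minus fraction of D/E) give

$$s = 2.785\,\langle H\rangle - |\langle R\rangle| - 1.151,$$

with $s < 0$ a disorder call. The constants and scale come from the
published fold-propensity method and are shipped as a plain-text resource
(`inst/extdata/disorder_scales.tsv`); they are inputs, not fitted values.

**TOP-IDP score** (`topidp_score()`). The windowed mean of the published
TOP-IDP per-residue disorder propensity scale; positive means
disorder-prone, threshold 0.

Numerical choices:

* **Windows.** Defaults are 51 for the charge/hydropathy score (the
  convention of the original tool) and 21 for TOP-IDP. The source study
  does not state window sizes; both are exposed as parameters.
* **Termini.** Windows shrink *symmetrically* at the termini (radius
  $\min(h, i-1, L-i)$), so every residue receives a score and terminal
  windows stay centred. Terminal IDRs are central results in this domain
  (disordered C-terminal tails decide orientation calls), so producing
  no-calls at the ends was not an option.
* **Ambiguity code X** contributes neutrally: scaled hydropathy 0.5,
  charge 0, TOP-IDP 0.
* Both predictors are verified against a brute-force loop-written
  windower to 1e-9 on random sequences.

**Consensus** (`consensus_track()`). Probability-like tracks —
higher-is-disordered with a threshold inside (0,1), the convention of
ingested external predictors — must already lie in [0,1] and pass
through unchanged. Raw-scale tracks (the charge/hydropathy score, or the
TOP-IDP score whose threshold 0 is outside the unit interval) are mapped
through the logistic $1/(1+e^{\pm(s-t)/\tau})$ with $\tau = 0.5$, signed
by orientation, which sends the decision threshold $t$ to 0.5 and
preserves the decision boundary. The
consensus is the per-position arithmetic mean with threshold 0.5. No
fusion rule is published for this analysis; the mean is the simplest
choice that reproduces the "meta-predictor in [0,1]" behaviour and is
idempotent on identical inputs.

## IDR calling

`binarize()` applies each track's threshold (boundary values count as
disorder calls on higher-is-disordered tracks; strictly below threshold
on lower-is-disordered ones). `call_idrs()` extracts maximal runs of
length ≥ 30. No smoothing or merging of nearby runs is applied: the
source analysis describes none, so the rule operates on raw calls, and a
single ordered residue splits a run. IDR calling deliberately ignores
feature annotations — a run may span a TM segment (in practice
hydrophobic TM stretches suppress calls by construction).

`inclusion_table()` quantifies predictor overlap as
$100\,|A\cap B|/\min(|A|,|B|)$, rounded **half-up** to two decimals to
match published table formatting (base R's round-half-even differs on
exact ties). Pairs whose smaller set is empty are flagged and excluded
from summaries rather than reported as 0 or 100.

## Topology models and side statistics

`build_topology()` partitions $[1, L]$ into Cytoplasmic / TM /
Extracellular / Unknown segments. TOPO_DOM annotations label the loop
containing them; loops alternate sides across each TM segment, so labels
propagate along the TM chain to unannotated loops (a fixpoint
iteration). Conflicts — two labels in one loop, same-side labels across
one TM, a TOPO_DOM overlapping a TRANSMEM — are hard errors. "Lumenal"
labels collapse to Extracellular: all reported statistics use a binary
cytoplasmic/extracellular split.

`localize()` assigns an interval (IDR, MoRF, or single PTM site — one
code path) to the strict majority side among its non-TM, non-Unknown
residues; exact ties and zero sided overlap are Ambiguous and excluded
from two-way percentages. Boundary-spanning behaviour is not described in
the source analysis; majority voting is the neutral choice and the
Ambiguous class keeps it honest.

`occupancy()` reports, per protein and side, the percentage of that
side's residues covered by IDRs, pooling all same-side loops of a
multi-pass protein before dividing. Whether published occupancy averages
are per-protein means (as implemented, with standard errors over
proteins) or pooled residue ratios is not stated; per-protein means match
the "mean percentage of topological domain occupied" reading and the
histogram-of-proteins presentation.

`filter_undeterminable()` removes multi-pass proteins all of whose loops
are shorter than 30 residues — such proteins can never be classified IDP
by the length rule and would dilute side statistics. Single-pass and
unannotated proteins are always retained, per the stated rule.

## Orientation prediction

For a protein with known TM segments but unknown in/out orientation,
`enumerate_orientations()` builds the only two alternating labelings
(candidate A: N-terminal side cytoplasmic; B: its complement).
`score_orientation()` scores each by

* `disorder_score`: fraction of IDR residues on loops the candidate
  labels cytoplasmic — the observation that membrane-protein IDRs are
  strongly cytoplasmic, used in reverse;
* `charge_score`: fraction of loop K/R residues within 15 residues of a
  TM boundary placed cytoplasmic — the positive-inside rule.

`combined = w_d * disorder + w_c * charge` with equal default weights
0.5/0.5; a component with no evidence (no IDRs on loops, or no boundary
K/R) contributes a neutral 0.5. The verdict is the higher-scoring
candidate unless the margin is below 0.05, in which case `ambiguous` is
returned rather than overclaiming. The 15-residue boundary window, the
equal weights and the 0.05 margin are package choices: the source
validates the idea qualitatively on a single protein (an 8-TM protein
with a disordered C-terminal tail, decided by disorder alone) and gives
no quantitative combination; all three are configurable. The packaged
deterministic fixture `tmem117_like_fixture()` reproduces that scenario:
eight TM segments, two C-terminal disordered stretches of 50 and 34
residues, and an expected C-terminus-inside verdict.

## Composition, PTM and interaction statistics

`composition()` reports percentages over the 20 standard residues, X
excluded from numerator and denominator, pooled across sequences.
`enrichment()` reports $(\text{subset}/\text{background} - 1)\times 100$,
so over-representation is positive (+66 for a residue at 1.66× its
background). A published figure legend prints the algebraically inverted
form $100 - \text{subset}\cdot 100/\text{background}$, which yields
negative values for enriched residues and contradicts that figure's own
bars and the accompanying text; the positive-is-enriched convention is
the default and the printed form is available via `convention =
"printed"`.

`ptm_stats()` reports, per IDP/FOP class and modification type, the
percentage of proteins with ≥ 1 site, mean sites per protein, mean
percentage of residues modified, the in/out-of-IDR split, and the S/T/Y
breakdown of phospho sites inside IDRs. Sites are validated against the
sequences at load; phospho sites on non-S/T/Y residues are chemically
implausible and dropped with a warning by default (`strict = FALSE`
keeps them). No reproducibility threshold is applied to sites, matching
the source's stated practice.

`degree_stats()` counts unique interaction partners with bait/prey
direction collapsed, duplicates removed and self-loops excluded, so the
statistics are invariant under edge duplication and reversal.

## The synthetic proteome: what it is and is not

`generate_proteome()` builds each protein as alternating loop/TM/loop…
architecture: pass type (45% single / 55% multi by default, close to the
observed membrane-proteome split), 2–10 TM segments of 19–23 residues
(typical helix spans) for multi-pass proteins, log-normal loop lengths
(meanlog log 40, sdlog 0.8), and a random N-terminal side. Each loop is
independently planted disordered with probability 0.40 (cytoplasmic) or
0.10 (extracellular) — an 80/20 planted side bias of the magnitude seen
in real multi-pass proteins. Disordered loops are drawn from the loop
distribution truncated at 30 residues so every planted IDR satisfies the
length rule, and their residues come from a disorder-biased composition
(P/E/S/Q/D/K/R up; F/L/I/V/W/Y/C down) stored as a versioned resource,
calibrated once so the charge/hydropathy predictor separates planted
ordered and disordered segments with margin; it was not adjusted after
observing test outcomes. Phosphosites are Poisson at 1.6 (IDP) vs 0.8
(FOP) sites per 100 residues — a 2:1 density ratio at realistic absolute
levels — with 58% of sites on serine; interaction degrees are Poisson at
means 9.5 vs 6, the magnitude of database-derived degree differences.
Seeds are mandatory; nothing is wall-clock seeded.

What a green test on this generator establishes: that the pipeline
recovers planted side bias (±5 points at ≥ 500 planted IDRs), planted
rate/degree ratios (±15%), planted IDRs (≥ 90% detected at ≥ 50% residue
overlap for planted IDRs of ≥ 40 residues), and enrichment signs. What it
does **not** establish: performance on real sequences, whose composition
is not an i.i.d. draw from a class-specific multinomial; no evolutionary
correlation, no signal peptides, no re-entrant loops, no partial or wrong
annotations, and no predictor disagreement structure are modelled. One
deliberate consequence: because IDP status is planted via extra loops and
length-truncated disordered loops, IDP proteins are systematically longer
than FOP proteins — as in real proteomes — so sites-per-protein ratios
confound rate with length; the rate-recovery test therefore uses a
length-matched configuration (near-constant loop lengths) to isolate the
planted ratio.

## Numerical and formatting conventions

* Coordinates are 1-based inclusive everywhere (UniProt convention).
* Reported percentages use half-up rounding (1 decimal for side and
  pass-type percentages, 2 for inclusion percentages) to reproduce
  printed tables; internal arithmetic is unrounded.
* One published inclusion value (2938/3123 = 94.0762…) appears truncated
  to 94.07 in print where half-up arithmetic gives 94.08; the package
  reproduces the arithmetic, and the discrepancy is covered explicitly in
  the acceptance tests.
* `run_all()` writes every stage table as TSV plus a manifest with MD5
  content hashes; identical configurations reproduce identical bytes.

## Known limitations

* The implemented predictors are scale-based; claims about
  energy/SVM/neural predictors rest entirely on ingested tracks.
* The orientation heuristic is validated by construction and by
  property tests (accuracy rising with planted bias), not against an
  experimental benchmark — none exists in the source analysis beyond a
  single protein.
* MoRF intervals are consumed, not predicted.
* UniProt flat files/XML are not parsed; annotations enter through the
  package's flat TSV formats.
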