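---
title: "Methods: stage-specific miRNA prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific miRNA prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagemiR)
```

## The model

A miRNA represses its target mRNAs by seed-complementary binding in their
3'UTRs, so the abundance of a regulatory miRNA and the expression of its
targets are expected to anti-correlate ("reverse interplay"). `stagemiR`
exploits this twice:

1. **Coverage.** Given a directional gene panel — the genes characteristically
   up- (or down-) regulated in one early histological stage of oral
   oncogenesis — a miRNA that *simultaneously* targets most of the panel is a
   plausible shared regulator of that stage's signature. The target score of
   miRNA $m$ against panel $P$ ($|P| = n$) is
   $\mathrm{score}(m, P) = |T(m) \cap P| / n$, where $T(m)$ is the miRNA's
   target set in a bipartite interaction table.
2. **Direction.** The candidate must itself be dysregulated in OSCC tissue or
   saliva in the direction *opposite* to the panel: downregulated miRNAs for
   upregulated panels, upregulated miRNAs for downregulated panels.

The panels are direction-homogeneous by construction, so "reverse with
respect to the targets" is implemented as panel-level opposition
(`required_direction()` is the involution UP↔DOWN).

## Parameters that matter

* **`threshold_rule(min_fraction = 0.75, strict = TRUE)`** — the coverage
  threshold (dimensionless fraction of panel genes). Strictness is
  load-bearing: on an 8-gene panel, 6/8 is exactly 75% and must be excluded,
  which forces `min_required_count(8) == 7`. The derived counts for panel
  sizes 8, 9, 5, 3, 2 are 7, 7, 4, 3, 2. With `strict = TRUE` and
  `min_fraction = 1` no count can qualify (`n + 1` is returned); that is the
  faithful reading of a strict threshold, and the constructor for simulation
  configs refuses such rules. Floating-point boundaries are handled with a
  `1e-9` slack so that `0.75 * 8 = 6` is treated as the exact integer it is.
* **`allowed_sources` (default tissue + saliva)** — the specimen restriction
  for direction evidence. Blood and cell-line records are retained in the
  database and reported in verdicts, but excluded from the pass decision by
  default, because tumor-adjacent specimens give the most disease-reflective
  signal for a salivary biomarker program.
* **Evidence conflict policy** — a miRNA qualifies if *any* allowed-source
  record supports the required direction. The verdict qualifier carries the
  majority structure: `CONSISTENT` (no opposing record), `MOSTLY`
  (supporting records outnumber opposing), `RARELY` (opposing outnumber
  supporting), `NONE`. Counting is per evidence record, not per study, since
  study tallies are generally unavailable. An exact tie is labelled `MOSTLY`
  (the tie-break favors the queried direction); no shipped data exercises a
  tie. This existential policy is the only one consistent with a conflicted
  miRNA (the miR-34a-5p pattern) legitimately appearing in the down-candidate
  lists of all stages *and* in the early-invasion up-candidates.

## The synthetic world

`simulate_truth()` generates a stated world for validation, not a tunable
benchmark:

* one stage panel; planted true candidates receive exactly the threshold
  count `k` of panel genes (sampled without replacement) plus a
  reverse-direction tissue/saliva record;
* `decoy_score` miRNAs receive the same coverage but alternate between a
  wrong-direction record and no record at all;
* `decoy_direction` miRNAs receive the correct record but coverage `k - 1`;
* background miRNAs draw independent Bernoulli(`edge_probability`) edges to
  each panel gene (and to `n_background_genes` noise genes) and carry no
  dysregulation records, so their panel coverage is Binomial(`n`, `p`) with a
  closed-form tail — the check used by the calibration test.

Defaults (`edge_probability = 0.05`, class sizes 5/5/5, 20 background genes)
mirror a sparse validated-interaction network in which true regulators are
rare; the separation construction makes precision = recall = 1 the designed
outcome, so a green recovery test establishes that the filter chain is wired
correctly — not that the method would be error-free on real data, where
coverage and direction evidence are noisy and correlated. Degree structure,
realistic miRNA degree distributions, and sequence-level simulation are
deliberately out of scope. The generator restores the caller's RNG state, so
simulation never perturbs an enclosing analysis's random stream.

## Numerical and representational choices

* Scores are kept as exact rationals (`count`, `panel_size`, `fraction`)
  with a display `percent` rounded to one decimal (87.5, 77.8, 80), matching
  the conventional rendering. Acceptance comparisons use the display value.
* Ranking is by descending count, then lexicographic miRNA id — a
  deterministic tie-break.
* miRNA identifiers are normalized to canonical `hsa-`prefixed miRBase-style
  names; a missing hyphen after `miR` is repaired, the `let-7` family keeps
  its stem, arm suffixes are preserved verbatim, and non-miRNA tokens are
  rejected rather than coerced. Normalization is idempotent.
* Exosomal-saliva records are stored as source `SALIVA` with an `exosome`
  flag, so they count toward the saliva restriction while remaining
  distinguishable.
* Source-database tags on edges are free-text set members, unioned on
  deduplication and serialized in C-locale order so outputs are byte-stable
  across locales.
* Empty cases are well-defined everywhere: a panel disjoint from the table
  gives an empty network, an absent miRNA scores 0 and gets verdict `NONE`,
  and a stage may end with zero candidates (the dysplasia down-panel does).

## Design decisions taken where the design was open

* **Edge tables, not a live web query.** The interaction network consumed is
  a TSV edge table; public network services are version-dependent snapshots,
  so whole-network sizes are logged but never asserted. The packaged fixture
  encodes exactly the per-miRNA target lists enumerated in the study's
  result tables (42 unique pairs over 7 miRNAs).
* **Panel configs are JSON.** No YAML parser is available in the supported
  dependency set; `jsonlite` is, and the shipped default config round-trips
  `builtin_panels()` exactly.
* **`simulate_truth()` naming** avoids masking the `stats::simulate` S3
  generic.
* **Comparison decomposition.** The first stage's `added_down` is taken
  relative to the shared core, later stages relative to the union of earlier
  same-direction candidate sets; `dropped_*` audit fields record
  non-nestedness. When candidate sets are nested (as in the shipped data),
  shared core + cumulative additions reconstruct each stage losslessly.
* **Seed-site grammar.** The optional scanner implements the canonical site
  classes (8mer, 7mer-m8, 7mer-A1, 6mer; seed = miRNA nt 2–8) with strict
  Watson–Crick pairing, no G:U wobble, 0-based half-open UTR coordinates,
  sense strand only, overlapping matches collapsed to the most specific
  class. The default `min_type = "SITE_7MER_A1"` for edge emission is a
  configuration choice, not a biological claim; upstream target databases do
  not publish a uniform site-class requirement.

## Known limitations

* The curated evidence database is a fixture-scale stand-in; the package
  validates and queries whatever table it is given but ships only the
  literature-update records and the directions needed by the worked example.
* `MOSTLY`/`RARELY` qualifiers depend on record counts in the supplied
  table, not on any weighting by study size or quality.
* The pipeline is presence/absence throughout: no interaction strength,
  binding energy, conservation, or expression magnitude enters the score.
* Stage panels reduce an animal model's expression signature to directions
  over human symbols; no ortholog mapping machinery is included, and panels
  encode the printed directions without reinterpretation (including a
  tumor-suppressor gene listed as upregulated in the precancerous stages).
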