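# stagemiR

Stage-specific miRNA prioritization for the early, asymptomatic stages of
oral squamous cell carcinoma (OSCC): hyperplasia, dysplasia, and early
invasion.

## The problem and the method

OSCC is usually diagnosed late; the early histological stages are
asymptomatic and mixed together inside excised tumor tissue, so their
stage-specific regulators are nearly impossible to isolate experimentally.
`stagemiR` implements an in-silico prioritization that combines two kinds of
evidence:

1. **Stage gene panels.** Each early stage carries a directional
   expression signature — a set of genes up- or downregulated at that stage
   (derived from a hamster model of sequential oral oncogenesis, expressed
   as human gene symbols). The built-in panels are: hyperplasia up
   (8 genes), dysplasia up (9) and down (3), early invasion up (5) and
   down (2).
2. **miRNA dysregulation evidence.** A curated table of miRNAs reported
   significantly up- or downregulated in OSCC tissue and/or saliva
   specimens.

For a panel `P` of `n` genes and a miRNA `m` with target set `T(m)` in a
bipartite miRNA–gene interaction network, the **target score** is the
simultaneous coverage

```
score(m, P) = |T(m) ∩ P| / n
```

A candidate must satisfy two filters:

* **coverage:** `score(m, P) > 0.75` (strict: on an 8-gene panel 6/8 = 75%
  is excluded, so the minimal passing count is 7);
* **reverse interplay:** since miRNAs repress their targets, `m` must be
  reported dysregulated in the direction *opposite* to the panel
  (downregulated miRNAs against upregulated gene panels, and vice versa),
  in tissue or saliva.

Cross-stage set algebra then yields the shared downregulated core, the
per-stage distinguishing additions, and the overlap with a disease-level
(whole-OSCC) miRNA list.

## Worked example

Running the pipeline on the packaged fixtures (the edge set and evidence
directions of the study's result tables):

```r
library(stagemiR)
run <- run_pipeline()
#> hyperplasia_up            network    7 -> score   3 -> direction   3
#> dysplasia_up              network    5 -> score   4 -> direction   4
#> dysplasia_down            network    5 -> score   0 -> direction   0
#> early_invasion_up         network    5 -> score   5 -> direction   5
#> early_invasion_down       network    5 -> score   3 -> direction   3

run$stages$HYPERPLASIA$candidates[, c("mirna_id", "count", "panel_size",
                                      "percent", "qualifier")]
#>          mirna_id count panel_size percent  qualifier
#> 1  hsa-miR-34a-5p     8          8   100.0     MOSTLY
#> 2  hsa-miR-124-3p     7          8    87.5 CONSISTENT
#> 3 hsa-miR-125b-5p     7          8    87.5 CONSISTENT

run$comparison
#> <comparison_report>
#>   stages: HYPERPLASIA -> DYSPLASIA -> EARLY_INVASION
#>   shared downregulated core: hsa-miR-124-3p, hsa-miR-125b-5p, hsa-miR-34a-5p
#>   HYPERPLASIA adds: down {} up {}
#>   DYSPLASIA adds: down {hsa-miR-1-3p} up {}
#>   EARLY_INVASION adds: down {hsa-miR-147a} up {hsa-miR-155-5p, hsa-miR-34a-5p, hsa-miR-423-3p}
```

Reading the log: each row is one panel's filter chain — miRNAs in the
panel subnetwork, then those clearing the strict >75% coverage threshold,
then those also showing reverse dysregulation. The `dysplasia_down` row
shows the characteristic empty result: no miRNA fully covers that 3-gene
panel in this edge set. The hyperplasia candidates are the three miRNAs
downregulated in OSCC that cover 8/8 (100%) or 7/8 (87.5%) of the
upregulated panel; `MOSTLY` flags a miRNA whose downregulation is the
majority but not unanimous report (miR-34a-5p also has minority
upregulation evidence, which is exactly why it reappears — upregulated —
among the early-invasion candidates).

Every stage shares the downregulated core {miR-34a-5p, miR-124-3p,
miR-125b-5p}; dysplasia is distinguished by adding miR-1-3p (down); early
invasion by miR-147a (down) plus miR-155-5p, miR-423-3p and miR-34a-5p
(up).

Other entry points: `run_stage()` (one stage), `filter_by_score()` /
`compute_target_score()` (scoring only), `simulate_truth()` (synthetic
worlds with planted candidates and decoys), `find_seed_sites()` /
`scan_fasta_seed_sites()` (canonical 8mer/7mer/6mer seed-site detection in
3'UTRs), and `inst/scripts/stagemir-cli.R` (command-line front end with
`run`, `simulate` and `export-fixtures` commands).

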