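# mtscreen

Multi-target virtual screening hit triage in R.

## The problem

Multi-target-directed ligands (MTDLs) — single small molecules intended to
modulate several disease-relevant proteins at once — are an increasingly
common design goal in neurodegeneration, where combinations such as
acetylcholinesterase (AChE), histone deacetylase 2 (HDAC2) and monoamine
oxidase B (MAO-B) pair symptomatic with potentially disease-modifying
activity. A structure-based campaign for such ligands docks a large
library into each target separately and must then *triage*: reduce
hundreds of thousands of per-target score rows to a short, defensible,
ranked list of compounds predicted active against **all** targets, free of
assay-interference chemistry, and plausible as CNS drugs.

`mtscreen` implements that triage cascade as a tested, reusable pipeline.
Docking itself is out of scope — scores and predicted affinity ranges
arrive from tables (or from the built-in synthetic generator) — but
everything downstream of the docking engines is here:

1. **Reference-derived score gates.** For each target the selection
   threshold is the best re-docking score *s\*ₜ* of the co-crystallized
   reference ligand; a compound survives iff its score *sₜ < s\*ₜ*
   (strictly) for **every** target, under the rigid protocol and then the
   flexible one. Binding-site compatibility between targets is assessed by
   closed-interval overlap of cross-docking vs re-docking score ranges.
2. **Substructure alerts.** PAINS (pan-assay interference) families and a
   Schiff-base (hydrolytically labile acyclic imine) pattern, as SMARTS
   catalogs; unparseable structures are removed conservatively.
3. **Affinity gate and rank fusion.** Per-target predicted Ki is the
   geometric mean of a predicted affinity range, *Ki = √(lo·hi)* (nM). A
   hit needs *Kiₜ < 5000 nM* for every target and a multiplication product
   *∏ₜ Kiₜ < 10⁸ nM³*; survivors are ranked ascending by that product.
   Products, unlike sums, are invariant to per-target rescaling of the
   scoring functions, which is why the product is the fusion statistic.
4. **Consensus pharmacophores.** Typed features (aromatic/hydrophobic,
   H-bond donor/acceptor, positive ionizable) perceived from docked poses
   are clustered across ligands per target (tolerance 1.45 Å, ligand
   support ≥ 50 %); a compound survives only if it matches *every*
   consensus feature of *every* target.
5. **BBB and toxicity gating.** The strict passive-permeation rule
   (tPSA < 79 Å² and 0.4 < logP < 6.0), consensus over external BBB model
   labels (penetrant iff *any* model says penetrant, weak penetrants
   demoted to non-penetrant), and ingestion of structural-alert toxicity
   predictions on the ordered likelihood scale (flagging at `plausible`,
   annotate-only by default).

Every removal is attributed to exactly one stage with a reason, so stage
counts + final hits always reconstruct the input library.

## Worked example

```r
library(mtscreen)

# a 600-compound synthetic library with 2% planted triple-actives
lib <- generate_library(sim_params(n_compounds = 600, seed = 29, q_pains = 0.1))
rep <- run_cascade(cascade_config(lib$library, lib$scores,
  stages = c("score_gate_rigid", "score_gate_flexible",
             "substructure", "affinity_gate")))
rep
#> Multi-target hit-triage cascade report
#>   ...
#>                stage n_in n_out
#>     score_gate_rigid  600    22
#>  score_gate_flexible   22    22
#>         substructure   22    22
#>        affinity_gate   22    22
#>
#> Final hits: 22
setequal(rep$hits$compound_id, lib$planted)
#> [1] TRUE
```

Only the planted actives survive: the background is drawn so that beating
all three re-docking thresholds *and* both affinity constraints by chance
is vanishingly rare. On the bundled 16-hit reference set:

```r
fx <- hit_fixture()
head(rank_by_product(fx$affinities)[, c("rank", "compound_id", "product_4sf")], 3)
#>   rank           compound_id product_4sf
#> 1    1 Specs AH-487/42478269         499
#> 2    2     Tripos 1503-03309       10970
#> 3    3    Chembridge 7905648       13610
```

The `product_4sf` column is the Ki multiplication product in nM³ at 4
significant figures — e.g. rank 2 is 3.808 × 1615 × 1.784 ≈ 10 970 nM³.
Lower products mean better simultaneous affinity across the three enzymes.

A command-line wrapper over the same functions, with one subcommand per
stage (`simulate`, `score-gate`, `substructure`, `rank`, `bbb`,
`report`), is installed at
`system.file("scripts", "mtscreen-cli.R", package = "mtscreen")`; stages
composed through files reproduce `run_cascade()` byte-for-byte.

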