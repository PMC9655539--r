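---
title: "Methods: the multi-target hit-triage cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-target hit-triage cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtscreen)
```

## Scope and model of the data

`mtscreen` triages the output of a multi-target docking campaign. The
unit of data is a (compound, target) pair carrying up to four numbers:
a rigid-protocol docking score, a flexible-protocol docking score (both
kcal/mol, more negative is better) and a predicted-affinity range
`(ki_lower_nM, ki_upper_nM)`. The package never computes docking scores
or affinity predictions; it assumes they were produced upstream by
docking engines and makes the downstream selection logic explicit,
deterministic and attributable. The default target panel is the
three-enzyme neurodegeneration panel AChE / HDAC2 / MAO-B, but nothing in
the code fixes the number or names of targets except the bundled
reference thresholds.

## Stage semantics

**Score gates.** The selection threshold for a target is the *best*
(minimum) re-docking pose score of its co-crystallized reference ligand
(`derive_threshold()`); the bundled values come from re-docking ranges
spanning the best 10 poses (donepezil in AChE, a benzamide derivative in
HDAC2, safinamide in MAO-B; rigid thresholds −14.71 / −13.01 / −13.56,
flexible −8.52 / −7.68 / −8.34 kcal/mol). A compound passes only with a
score *strictly* below the threshold on *every* target
(`triple_activity_filter()`). "Better than the best" is read as strictly
more negative than the minimum: a compound exactly at the reference
score has not beaten the reference. The rigid gate runs before the
flexible gate as configuration, not as hard-coded order — each is an
independent stage.

Binding-site compatibility between targets is a separate question,
answered by `ranges_overlap()`: closed-interval overlap of a ligand's
cross-docking score range with the receptor's own re-docking range.
Closed intervals (touching endpoints overlap) were chosen because the
published ranges are rounded to two decimals; an open-interval rule
would let rounding decide borderline calls. Under the flexible protocol
every bundled cross-docking range overlaps the target's re-docking
range, which is the observation that motivates a triple-active search in
the first place. Under rigid docking the bundled ranges also produce
some overlaps beyond the one compatibility call usually quoted for
HDAC2; the exact historical criterion for that narrower statement is not
recorded, so the package simply exposes the arithmetic and leaves the
interpretation to the analyst.

**Substructure alerts.** `filter_clean()` removes any compound matched
by a SMARTS pattern in the active catalogs. Two catalogs ship with the
package. `pains` is a hand-curated set of about twenty SMARTS covering
the major published PAINS families (rhodanines and ene-rhodanines,
para- and ortho-quinones, catechols and hydroquinones, hydroxyphenyl
hydrazones, aryl azo dyes, phenolic Mannich bases, alkylidene
barbiturates, maleimides and other conjugated Michael acceptors,
C-nitroso, enolized 1,3-dicarbonyls). It is a representative
realization, not the full several-hundred-pattern published list; the
catalog format is a plain TSV and `compile_catalog()` accepts any
external file, so the full set can be dropped in without code changes.
`schiff_base` is a single pattern for acyclic imines,
`[CX3;!R;!$([CX3](=[NX2])[#7,#8,#16])](=[NX2;!R][#6])`: the alert
targets hydrolytically unstable C=N, so amidines, guanidines, imidates
and ring-embedded (including aromatic) C=N are deliberately excluded.
Which PAINS subfamilies and which exact imine pattern the original
KNIME-based workflow applied is not recorded; both are configuration
here, and the defaults are documented as this package's choices.
Structures that fail to parse are *removed*, not passed: the stage
exists to protect downstream assays, so unevaluable compounds are
treated conservatively.

**Affinity gate and ranking.** The point affinity is the geometric mean
of the predicted range, `ki_from_range(lo, hi) = sqrt(lo * hi)`, in nM.
The gate (`affinity_gate()`) requires every per-target Ki strictly below
5000 nM (the hit-level micromolar expectation) and the product of the
three Ki strictly below 1e8 nM³; both inequalities are strict because
both ceilings are phrased as "less than". Units are fixed to nM at
ingest — the 1e8 nM³ ceiling is only meaningful on that scale. Ranking
(`rank_by_product()`) is ascending by the *full-precision* product; the
presentation layer rounds to 4 significant figures afterwards. Because
a few reported products were evidently computed from unrounded upstream
affinities, recomputing from the rounded reported Ki reproduces most but not
all reported products at 4 s.f.; the recomputed values agree to better
than 1 % everywhere and the induced order is identical, which is what
the test suite asserts. Ties are broken by compound id, making the
ranking stable and input-order independent. The product (not the sum)
is the fusion statistic because it is equivariant under per-target
rescaling: multiplying any target's affinities by *c* multiplies every
product by *c* and moves no compound past another.

**Consensus pharmacophores.** `perceive_features()` maps a docked pose
to typed points: aromatic rings (and all-carbon aliphatic rings) give
one `aromatic_hydrophobic` feature at the ring centroid; N/O with an
explicit attached hydrogen give `hbond_donor` at the heteroatom; N/O
with a free lone pair give `hbond_acceptor` (excluding amide-type
nitrogens, aromatic N–H and cations); formally positive atoms give
`positive_ionizable`. Hydrophobic and aromatic points share one merged
type, matching the feature vocabulary in which consensus models are
usually reported. Protonated amines are represented by their
`positive_ionizable` feature only (not additionally as donors): the
cationic interaction is the dominant, defining one. Donor perception
requires explicit hydrogens in the pose file; `read_poses()` records
whether a file carries them, since libraries differ on this and a pose
set without explicit hydrogens silently has no donors.

`build_consensus()` clusters same-type features across ligands with a
neighborhood distance tolerance (default 1.45 Å) and retains clusters
supported by at least a fraction of the ligands (default 50 %, compared
with `>=` so a feature in exactly half the ligands survives). The
clustering is greedy centroid-linkage: seed at the feature with the
densest neighborhood, admit at most one feature per ligand within
tolerance, recompute the centroid, drop members that fall outside
tolerance of it (so the final model always satisfies the invariant that
every member lies within tolerance of its cluster centroid), remove the
cluster, repeat. Ties are broken by ligand order then coordinate
lexicographic order, so the procedure is deterministic. Whether the
historical 50 % threshold counted ligands or poses is not recorded; the
package counts ligands. Poses are assumed pre-aligned in the target's
binding-site frame — they come from docking into one fixed site — and no
superposition is attempted. `match_all_features()` implements the
match-all selection rule: a compound is a pharmacophore hit for a target
only if, for every consensus feature, it has a compatible-typed feature
within tolerance; `hbond_either` accepts a donor or an acceptor.
`multi_target_pharmacophore_filter()` requires this for all targets
simultaneously.

**BBB and toxicity.** `passive_bbb_rule()` is the strict two-descriptor
rule: penetrant iff tPSA < 79 Å² and 0.4 < logP < 6.0. tPSA is the Ertl
fragment-contribution value and logP an atom-contribution estimate, both
computed with OpenBabel from the connection table. The external tools
that produced published per-compound BBB labels use their own
(consensus or transport-based) descriptor models, so those labels are
shipped as data (`bbb_fixture()`) and *ingested*, never recomputed;
agreement with them per compound is not asserted anywhere — only the
rule arithmetic and the combiner are testable. `consensus_bbb()`
implements the combination rule: demote `weak_penetrant` to
`non_penetrant`, then call the compound penetrant iff any model does.
`toxicity_gate()` ingests structural-alert predictions on the ordered
likelihood scale (certain > probable > plausible > equivocal > doubted >
improbable > impossible), flags at `plausible` or stronger, and by
default only annotates — the reference campaign retained its flagged
compound through the subsequent analysis, so removal is opt-in.

## The synthetic-data generator

`generate_library()` emulates what the cascade consumes, not what
docking physics produces. Background docking scores are multivariate
normal across targets with common correlation `rho` (default 0.3 —
docking scores of the same compound against related binding sites are
positively but not strongly correlated), means −9 (rigid) and −5.5
(flexible) with sds 1.5 and 1.0: comfortably worse than the reference
thresholds, so a background compound beats all three thresholds
essentially never. Background affinities are lognormal with median
50 µM and log-sd 1.2 — an inactive screening library. Affinity ranges
are `(Ki/φ, Ki·φ)` with spread factor φ = 3 (HYDE-style ranges span
roughly an order of magnitude), so the geometric mean recovers the
generating Ki exactly and parameter recovery is assertable to machine
precision. A Bernoulli fraction `p_active` (default 0.02) of compounds
is planted as triple-actives: scores strictly below every threshold by a
positive margin, per-target Ki log-uniform in 5–2000 nM, rescaled
multiplicatively when needed so the product constraint holds by
construction. A fraction `q_pains` (default 0.05) of *background*
compounds carries a PAINS-matching substructure; contaminants never
overlap planted actives, so planted actives are clean by construction
and zero false negatives is a provable property, not a statistical one.
SMILES come from a small bundled fragment grammar (aromatic cores ×
linkers × tails) that is guaranteed clean against the bundled catalogs.

What this does and does not show: passing tests on generated data
validate the *selection logic* — thresholds, strictness, bookkeeping,
invariances, planted-active retrieval at the binomial rate — under the
stated statistical structure. They say nothing about docking-score
realism, pose geometry, conformational strain or the chemistry of real
vendor libraries, and no such claim is made anywhere in the package.

## Numerical and design choices

- All gate comparisons are strict (`<`); boundary compounds are removed.
  Rationale: every published ceiling is phrased as "less than", and the
  threshold itself is the reference ligand's own score.
- Products are computed in double precision and only *presented* at 4
  significant figures; ranking never uses rounded values.
- Charged SMILES are taken as given (screening libraries arrive
  protonated at physiological pH); no neutralization, so canonical keys
  distinguish protonation states.
- Duplicate structures collapse at ingest (first id wins, with a
  warning) because the cascade's accounting is per unique compound.
- `M  CHG` property lines supersede atom-block charge codes when both
  are present in an SDF record, following the V2000 convention.
- Degenerate inputs: empty libraries and empty catalogs are identities
  with warnings, an empty reference profile or empty consensus input is
  an error, single-compound ranking yields rank 1.
- The consensus-clustering centroid iteration is capped at 10 rounds;
  with tolerance 1.45 Å and the feature densities involved it converges
  in 1–2.

## Problem sizes

The test suite exercises the exhaustive-oracle comparisons at 10 000
compounds, the planted-recovery condition at n = 5000 with p = 0.02
(survivor count checked against the exact 99 % binomial interval), and
the remaining property suites at 60–800 compounds; substructure scans
run on a few hundred molecules because each SMARTS pattern is matched
against every structure. These sizes were chosen as the smallest that
make the distributional assertions sharp.

## Known limitations

- The PAINS catalog is a curated subset; coverage-sensitive work should
  load the full published pattern file via `compile_catalog()`.
- Feature perception is structural and minimal: no tautomer awareness,
  no directionality on donors/acceptors, no projected points, and
  chain (non-ring) hydrophobes are not perceived.
- logP is a single atom-contribution model; published per-compound BBB
  labels from consensus logP models will not be reproduced exactly, and
  the package does not attempt to.
- The cascade is desk-scale by design: single process, in-memory tables.
  The stage logic is O(n·targets) and handles 1e5-row score tables
  comfortably, but there is no parallel or out-of-core path.
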