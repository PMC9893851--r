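---
title: "Methods: multilevel MHC-I epitope identification by pool-matrix screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel MHC-I epitope identification by pool-matrix screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The problem and the model

Replicating viral vectors raise anti-viral CD8⁺ T cells alongside any
intended anti-tumor response, and telling the two apart requires knowing
which viral peptides the host's MHC class I alleles actually present. The
package implements the screening chain used for that purpose in mouse
models: *in silico* prioritization of candidate peptides, a combinatorial
two-pool ELISpot screen over the prioritized set, deconvolution of the
positive pools to individual candidates, individual confirmation, ICS
validation and descriptive characterization.

The statistical model underneath the wet-lab stages is deliberately the one
practitioners apply in graphing software: animal-level technical-replicate
means are analyzed with a two-factor linear model
`response ~ group * stimulus`, and each stimulus's mock-vs-immunized
difference in cell means is tested against the model's pooled error term,

$$ t_s = \frac{\bar y_{s,\mathrm{imm}} - \bar y_{s,\mathrm{mock}}}
{\sqrt{\mathrm{MSE}\,(1/n_\mathrm{imm} + 1/n_\mathrm{mock})}}, $$

with the residual degrees of freedom of the full interaction model and a
Šidák adjustment $p' = 1 - (1-p)^m$ over the $m$ stimuli of the family.
This presumes homoscedastic, roughly Gaussian animal-level means — an
approximation for overdispersed spot counts that we keep because it is the
field's convention for these assays, not because counts are Gaussian (see
*Limitations*). The contrast arithmetic is cross-checked in the test suite
against `emmeans` pairwise comparisons on the same fitted model, and
against a group-label permutation oracle on planted-effect data.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| binder tier cutoffs | 0.5 / 2 / 3 | percentile rank (%) | standard strong/weak/marginal tiers for MHC-I predictors |
| quota | N 15, P 15, M 10, GP 5, L 5 | peptides/allele | decreasing along the 3'→5' transcription gradient; totals 50 |
| pool grid | 7 × 7 | pools | 14 pools/allele; smallest square grid holding 50 with one doubled cell |
| α | 0.05 | — | family-wise, after Šidák |
| group sizes | pools 4/6, individual 5/4, ICS 6/6 | animals (mock/immunized) | the assay design the simulator emulates |
| replicates | 2 | technical wells | averaged before testing |
| background mean | 5 | spots/well | unstimulated splenocyte background |
| responder mean | 60 | spots/well | a clearly positive ELISpot response |
| dispersion (NB size) | 8 | — | overdispersed counts, CV ≈ 36% at 60 spots/well |
| planted binder ranks | Uniform(0, 0.5) | % | below the strong cutoff by construction |
| ICS slope / noise | 0.02 %/spot, sd 0.1 pp | — | %IFN-γ⁺ CD8⁺ linearly linked to spots, truncated at 0 |

## Design choices where the design was open

**Tier boundaries.** Published tier definitions give ranges without
boundary semantics. We declare half-open intervals assigning boundary
values to the weaker tier (0.5 is weak, 2 is marginal, 3 is non-binder),
so every rank belongs to exactly one tier; this is a convention, not an
inference.

**Ranking combination rule.** Three ranking criteria (consensus tier,
stability, dissimilarity) do not define a total order by themselves. We use
strict lexicographic priority in that listed order, with `peptide_id` as
the final tie-break so the order is total and reproducible. Worsening a
candidate's stability rank can never improve its position (tested by
perturbation).

**Self-filter placement.** Whether host-identical peptides are removed
before or after ranking is not prescribed; we filter before ranking so that
quotas are always filled with eligible peptides.

**Dissimilarity score.** TCR-recognition-based foreignness models need
external alignment resources; we use a transparent best-window identity
complement (0 for a verbatim self match, 1 for no shared residue at any
offset), which has the same exclusion behaviour for self peptides and is
oracle-checkable by brute force. The foreignness and hydrophobicity
annotations are never ranking keys.

**Grid split and overflow.** 14 pools admit several r + c splits and 50
peptides cannot fill any of their grids exactly (max r·c = 49). We fix
7 × 7 with row-major gene-order filling and deterministic co-placement of
overflow into the first cell; the split is configurable. Pool labels are
1–7 horizontal, 8–14 vertical.

**Šidák family size.** m equals the number of stimuli tested together in a
panel: 14 for a pool screen, and for individual testing the deconvolved
candidates plus their vertical pools (which are re-assayed alongside, as in
the bench workflow). NC/PC wells are metadata, excluded from the family;
PC only backs a plate-validity warning (PC mean must exceed NC mean).

**Coverage convention.** "Residues covered" is ambiguous when epitopes
overlap. The headline fraction uses the interval union (idempotent,
order-invariant, bounded by 1); the literal summed variant is reported
alongside because overlapping epitopes double-count there.

**candidate_id numbering.** Labels N1…L50 are assigned after selection,
in gene order within protein blocks and by position within each protein.
They are internally consistent; no claim is made that they coincide with
any externally published numbering of the same form.

## What the synthetic-data generator emulates

The generator stands in for the two expensive parts of the real study: the
external predictors and the animal assays.

* **Predictions.** Planted binders draw percentile ranks from
  Uniform(0, 0.5) independently per tool (consensus key 3-3-3 by
  construction); all other peptides draw from Uniform(0, 100), so ≈ 0.5%
  of background peptides are spurious strong binders per tool, as the rank
  definition implies.
* **ELISpot.** Replicate spot counts are negative binomial (size 8): mock
  animals, non-responder stimuli and NC wells at mean 5 spots/well,
  immunized animals on responder stimuli at mean 60, PC wells at mean 500
  in both groups. A pool well responds iff the pool contains at least one
  planted responder.
* **ICS.** Per animal, %IFN-γ⁺ CD8⁺ = max(0, 0.02 × mean spots +
  N(0, 0.1)).
* **Proteome.** Five random proteins (N 130, P 130, M 100, GP 140, L 90
  residues — scaled down from the real proteins so a full run takes
  seconds) with background amino-acid composition, and the four
  literature-described C57BL/6 epitope sequences planted at their
  published coordinates where they fit. Everything else about the proteome
  is synthetic.

Everything is deterministic given a seed: two runs with the same seed give
identical tables.

What the generator does **not** emulate — and therefore what green tests do
not certify about real data: predictor errors are not structured (real
predictors err systematically by motif, not uniformly); spot counts have no
plate, batch or edge effects (the two-experiment structure of real designs
is modelled as no-effect by default); responder magnitudes are homogeneous
(all planted responders share the 60 spots/well mean), so the
across-epitope ICS–ELISpot correlation is not identified in a default
pipeline run — the linked-ICS property is instead tested by feeding
heterogeneous ELISpot summaries to the ICS simulator directly; and real
immunodominance hierarchies, precursor frequencies and peptide purity are
out of scope.

## Numerical and degenerate-input behaviour

Ambiguity codes (X, B, Z) are rejected at parse time rather than skipped —
every downstream score assumes the 20-letter alphabet. Requested peptide
lengths longer than a protein contribute zero candidates without error; an
empty length set yields an empty table. A candidate absent from one
predictor's table is scored non-binder for that slot (and counted), not
dropped. A stimulus present in only one group is excluded with a warning;
zero residual variance aborts the test as degenerate rather than returning
p = 0. The Šidák transform is clipped to [0, 1]; correlation requires at
least three pairs and positive variance in both variables. Matrix
deconvolution with an empty significant set returns an empty candidate set.

## Problem sizes used in the shipped experiments

The packaged experiments run on the scaled-down proteome above: 2190
candidate peptides per allele, 50 selected, 14 pools, and assay tables of a
few hundred wells. The plant-and-recover experiment (also run by
`scripts/acceptance.R`) uses one simulated proteome pair shared across 20
seeded replicate runs, re-simulating predictions and assays each time; the
null-calibration check uses 1000 simulated null pool screens. These sizes
were chosen so the full suite runs in about a minute while keeping every
count (candidates per protein, pools, animals) at the study's own scale
from the selection stage onward.

## Known limitations

* The pooled-error ANOVA on untransformed counts is anti-conservative
  under strong mean-variance coupling; the null-calibration test bounds the
  family-wise false-positive rate empirically under the generator's null,
  not under arbitrary real-data noise.
* The dissimilarity score is an identity heuristic, not a TCR-recognition
  model; it is meant for self-exclusion and coarse deprioritization.
* With the default homogeneous responder magnitude the pipeline's internal
  ICS–ELISpot correlation estimate is noise around a weak true value;
  treat it as a plumbing demonstration, not a power claim.
* Pool-level counts (how many pools reach significance, how many
  candidates survive deconvolution) depend on the exact matrix layout; with
  a different grid split or fill order they legitimately differ even for
  the same planted truth.
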