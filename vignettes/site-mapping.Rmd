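---
title: "Site mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitemapr)
```

## The model

Site mapping treats a ranked ensemble of docked ligand poses as a sample
from the recognition landscape of a binding site. The quantity of
interest is not any single pose but the per-residue frequency of
interactions across the ensemble. The procedure is:

1. **Detect** hydrogen bonds and van der Waals contacts between each of
   the top-ranked poses (100 by default) and the receptor.
2. **Tally** interactions per protein residue and interaction family.
   The counting unit is the atom pair per pose: a residue making three
   hydrogen bonds to one pose contributes three counts. A per-pose-unique
   mode (`count_mode = "residue_per_pose"`) is available because the
   multiplicity convention of earlier implementations is not fully
   determined; the atom-pair convention is the default since the tally
   is explicitly of *interactions*, not of residues.
3. **Normalize** each family separately: a residue's contribution is its
   count divided by the family total, so contributions sum to 1.
4. **Select** important residues per family by cumulative sum: sort
   contributions in decreasing order and accumulate until the cutoff is
   reached.

The underlying assumptions are that the docking program samples binding
modes broadly enough for frequency to be meaningful, and that residues
contacted consistently across high-ranked poses are the residues that
actually drive recognition. Nothing in the mapping math depends on the
ligand class; the defaults are tuned for antibody recognition of acidic
sugars.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_n` | 100 | poses tallied per ensemble (rank order = file order) |
| `hb_cutoff` | 0.90 | cumulative-sum cutoff, hydrogen bonds |
| `vdw_cutoff` | 0.40 | cumulative-sum cutoff, van der Waals |
| `hb_da_max` | 3.5 Å | donor–acceptor distance |
| `hb_angle_min` | 120° | D–H···A angle at the hydrogen |
| `vdw_max` | 4.0 Å | heavy-atom contact distance |
| `a`, `b` | 0.9, 0.4 | similarity weights (= the two cutoffs) |
| `min_poses` | 10 | minimum ensemble size per conformer |
| `d_threshold` | 3.00 pp | mimicry significance threshold |

The asymmetric cutoff pair (90%/40%) encodes the empirical finding that
hydrogen bonding carries most of the specific signal for acidic sugars
while a shallow van der Waals cutoff suffices to pick up non-polar
side-chain packing; using one identical cutoff for both families (the
legacy 80%/80% scheme, available by passing equal cutoffs) admits many
erroneous van der Waals contacts. The geometric criteria are deliberately
config-exposed: they are conventional values, not part of the mapping
method's contribution, and reproducing another tool's contact definition
(or bypassing geometry entirely via `tally_from_table()`) must be
possible.

## Numerical choices

* **Cumulative-cutoff boundary.** The residue at which the running sum
  first reaches the cutoff is *included*, and residues tied with it in
  contribution are included as a group. This guarantees the captured
  mass is at least the cutoff and makes selection deterministic under
  ties; sort ties are broken by residue label.
* **Hydrogen handling.** When the system carries explicit hydrogens, only
  atoms with an attached hydrogen can donate and the angle criterion
  applies; a hydrogen-free system falls back to distance-only detection
  with a notice. Hydrogens are attached to their nearest heavy atom
  within 1.3 Å. Histidine and similar ambiguous cases need no special
  treatment because any N/O with an explicit H can donate and every N/O
  can accept.
* **HB/vdW partition.** An atom pair recorded as a hydrogen bond is not
  re-counted as a van der Waals contact (configurable), so the two maps
  describe disjoint interaction sets.
* **Correlation.** `map_r2()` computes squared Pearson correlation over
  the union of residue supports with zero fill. A constant vector makes
  Pearson undefined; the result is then `NA` with a warning rather than a
  silent 0, and such conformers are simply never selected. A
  regression-through-the-origin variant is available
  (`method = "origin"`) because the published tables cannot discriminate
  between the two conventions; both agree on the fixtures used here.
* **Similarity form.** The conformer similarity is the cutoff-weighted
  arithmetic mean `(a·r²_HB + b·r²_vdW)/(a+b)`. This functional form
  reproduces the published per-conformer similarity column from its r²
  inputs (8/10 rows exact at two decimals, all within the 0.01 envelope
  that input rounding allows), which is the strongest available evidence
  for the exact expression; it is kept pluggable.
* **d-statistic.** The default is the signed perpendicular distance
  `(y−x)/√2` from the equivalence line, in percentage points, matching
  the geometric definition of a point-to-line distance; a vertical mode
  (`y−x`) is provided since the defining convention is not restated in
  every account. The 3.00 threshold applies to whichever mode is active.
  Because both maps are normalized, Σd = 0 over the union support — the
  statistic measures redistribution of interactions, not their amount.
* **Aggregation.** Docking summaries use the sample standard deviation
  (n−1) by default, which matches the published aggregate rows at their
  printed precision; the population variant is available.
* **Degenerate inputs.** Empty interaction families normalize to empty
  maps with a warning; an empty reference set is an error (quality is
  undefined); single-observation standard deviations are reported as 0
  with an explicit flag.

## The synthetic-fixture generator

`make_binding_site()` builds a ring of pocket residues, each with one
donor nitrogen (explicit hydrogen pointing outward) and one apolar
carbon displaced below the ring plane. The spacing is chosen so a probe
placed against one residue can contact no other; each generated pose is
a two-atom rigid probe producing exactly one hydrogen bond (2.9 Å,
linear) and one van der Waals contact (3.6 Å). Target residues are drawn
per pose from programmed frequency profiles — multinomially, or by
largest-remainder quota when exact realized frequencies are wanted.
`make_conformer_series()` perturbs a base profile with double-centered
perturbations (zero-sum across residues and across conformers), so the
ensemble-average profile equals the base and the planted centroid
conformer is the unique similarity maximizer whenever divergence is
positive.

What this emulates: ranked ensembles with known per-residue contact
frequencies, i.e. exactly the statistical object site mapping consumes.
What it does not emulate: real ligand chemistry and geometry —
competing contacts, correlated residues, pose-score correlation, solvent,
or realistic binding-site topography. Passing the recovery tests
therefore validates the tally/normalize/select/compare machinery, not
the docking realism of any particular input ensemble.

Test problem sizes: most suites use 3–6 residues and 2–200 poses; the
end-to-end recovery property uses 10 000 poses (recovering profiles
within ±0.02, which is about three binomial standard errors at that
depth) and the conformer-recovery fixtures use 4–6 conformers of 30–120
poses.

## Open design decisions

* Residue identity is (chain, author number, insertion code);
  IMGT-style display labels are cosmetic metadata applied from a mapping
  file, never computed — there is no renumbering algorithm in scope.
* Pose rank is file order; re-ranking by a score field is opt-in
  (`rank_by_score`), because docking programs emit ranked files and the
  ensemble is defined by rank.
* Fragment pooling sums raw counts before normalizing
  (pool-then-normalize), so fragments with more interactions weigh more;
  per-fragment weighting to equalize pose counts is deliberately not the
  default.
* The hexapeptide window slides with step 1 (maximally overlapping);
  both window and step are exposed.
* Conformers with fewer than 10 poses are excluded from dynamic mapping
  rather than silently retained: a map built from a handful of poses is
  noise. Substituting a replacement conformer is a user decision, not an
  automatic one.

## Limitations

* Contact detection is geometric and criteria-based; it does not model
  CH–π or cation–π interactions, salt-bridge energetics, or
  protonation-state assignment. Structures are consumed as prepared.
* Reproduction/correctness scoring is residue-level (the union of the
  two important sets), which matches how published aggregate values are
  defined but discards per-family detail at the scoring stage.
* The published per-complex map values for real antibody systems depend
  on running external docking programs and are therefore out of reach of
  this package's own computations; only the metric, aggregation, and
  regression layers are reproduced here, plus full synthetic end-to-end
  validation.
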