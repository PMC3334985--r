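# sitemapr

Site mapping of protein–ligand recognition from docking pose ensembles.

## The problem

Docking a flexible ligand — a carbohydrate epitope, a peptide mimotope —
into an antibody combining site rarely yields one trustworthy pose: the
top-ranked pose is often wrong, while the ensemble of plausible poses as a
whole carries a robust signal about *which protein residues* do the
recognizing. Site mapping extracts that signal. Instead of trusting a
single pose, it tallies every hydrogen bond and van der Waals contact made
by the top-ranked poses (100 by default), aggregates them per protein
residue, and asks which residues dominate recognition.

The package is aimed at structural immunologists and molecular modellers
studying antibody–carbohydrate recognition, paratope mapping, mimotope
design, and related problems where ligand flexibility defeats
single-pose docking analysis.

## The method

For each interaction family *f* ∈ {HB, vdW} and residue *i*, the
normalized contribution is

    c_i = n_i / Σ_j n_j

where `n_i` is the number of interactions of family *f* observed with
residue *i* across the pose ensemble; normalization is separate per
family. Contributions are sorted in decreasing order and the residues
accumulating up to a **cumulative-sum cutoff** are deemed important —
90% for hydrogen bonds and 40% for van der Waals contacts by default,
the optimum for antibody recognition of acidic sugars.

Maps are scored against crystallographic contact residues by

    reproduction = |mapped ∩ reference| / |reference|
    correctness  = |mapped ∩ reference| / |mapped|

and the product of the two; cutoffs can be optimized by grid scan of the
mean product over a validation set (`scan_cutoffs()`).

**Dynamic site mapping** handles receptors with uncertain loop
conformations (e.g. an incomplete HCDR3): each conformer is mapped
separately, conformers with fewer than 10 poses are excluded, maps are
averaged residue-wise, and each conformer is scored against the average by

    similarity = (a · r²_HB + b · r²_vdW) / (a + b)

with `a`, `b` the two cutoffs and `r²` the squared Pearson correlation of
the per-residue contributions. The conformer with the highest similarity
is the most representative of the ensemble-average recognition state.

**Peptide mimicry** of a carbohydrate epitope is quantified by docking the
peptide as overlapping hexapeptide fragments (`fragment_peptide()`),
pooling the fragment tallies into one map (`pool_fragment_tallies()`),
and comparing carbohydrate and mimic maps residue-by-residue through the
signed distance of each point (carb %, mimic %) from the equivalence
line y = x:

    d = (y − x) / √2      (percentage points)

Residues with |d| > 3.00 differ significantly; positive d means more
interactions with the mimic, negative more with the carbohydrate.

## Worked example

A synthetic pocket with programmed contact frequencies, mapped end to end:

```r
library(sitemapr)

spec <- fixture_spec(5, hb_profile  = c(.40, .25, .20, .10, .05),
                        vdw_profile = c(.10, .15, .25, .25, .25),
                        n_poses = 100, seed = 42)
ens <- make_pose_ensemble(spec)
map <- map_ensemble(ens, top_n = 100, hb_cutoff = 0.90, vdw_cutoff = 0.40)
map
#> site_map: 5 HB residues, 5 VDW residues (cutoffs 90%/40%)
#>   important HB: 1A, 2A, 3A, 4A
#>   important VDW: 4A, 5A

round(100 * map$hb, 2)   # recovered HB contributions (%)
#> 1A 2A 3A 4A 5A
#> 38 22 23 11  6

map_quality(map, reference = c("1A", "2A", "3A", "4A"))
#> quality_report: reproduction 1.00, correctness 0.80, product 0.80 (5 mapped / 4 reference)
```

The recovered hydrogen-bond percentages track the programmed profile
(40/25/20/10/5) within sampling noise; the 90% cumulative cutoff selects
the top four residues, which reproduce the full reference set at
correctness 0.80 (one extra van der Waals residue mapped).

Conformer selection from a published correlation table bundled with the
package:

```r
tab <- benchmark_table("chp3_conformers")
sim <- similarity_score(tab$r2_hb, tab$r2_vdw, a = 0.9, b = 0.4)
tab$conformer[which.max(sim)]
#> [1] 10
```

A shell entry point wrapping the same functions ships in
`inst/cli/sitemapper` (subcommands `map`, `score`, `scan`, `dockeval`,
`dynamic`, `mimic`, `fragment`, `synth`).

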