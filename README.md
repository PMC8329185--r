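# halotrace

Quantitation of nucleocytoplasmic transport receptor (NTR) cargo binding
from bead halo assay images, and evolutionary trace analysis of NTR
paralog pairs.

## The problem

Importin-β family NTRs carry specific sets of cargo proteins through
nuclear pores, but many experimentally identified cargoes lack any known
consensus localization signal. One way to map where cargoes contact a
receptor is to mutate candidate surface positions and measure how each
mutation changes binding across a cargo panel. That program needs four
computational pieces, which this package provides for anyone running a
similar receptor–cargo dissection:

1. **Evolutionary trace analysis (ETA)** — given a joint alignment of two
   paralogs' ortholog groups (e.g. transportin-SR vs importin-13),
   find columns conserved within each group but differing between groups:
   candidate specificity determinants worth mutating.
2. **Bead halo assay (BHA) quantitation** — receptor is immobilized on
   beads as a GST-mCherry fusion and mixed with GFP-cargo; bound cargo
   forms a fluorescent halo. From two-channel confocal images, segment
   beads, build ring ROIs, and measure the binding index.
3. **Binding-profile clustering** — normalize mutant binding to wild
   type, discretize into three ranks, and Ward-cluster cargoes by their
   mutant-response profiles.
4. **RSY-rich segment scanning** — flag arginine/serine/tyrosine-rich
   candidate signal segments in cargo sequences.

A fifth module generates seeded synthetic data (bead images, grouped
alignments, RSY-bearing sequences) with ground truth, so every stage is
verifiable end-to-end.

## The statistics at the core

**ETA score.** At each alignment column, amino-acid profiles `p` (group A)
and `q` (group B) are estimated from Gerstein–Sonnhammer–Chothia weighted
counts smoothed by a Dirichlet prior, and scored with the symmetric
Kullback–Leibler divergence

    KL = Σᵢ pᵢ log(pᵢ/qᵢ) + Σᵢ qᵢ log(qᵢ/pᵢ)        (natural log default)

Columns with pooled weighted gap fraction > 0.5 are skipped; the top 10%
of retained columns (ties included) are candidate sites.

**Binding index.** Per image, with ring ROIs just inside bead outlines
and background rings just outside,

    GFP/mCherry = (ROI_GFP − BG_GFP) / (ROI_mCherry − BG_mCherry)

averaged over three replicate images, thresholded for negative binding
(0.1 TrnSR-like, 0.05 Imp13-like), normalized by the wild-type value, and
discretized (> 0.6 → 1; (0.2, 0.6] → 0.5; ≤ 0.2 → 0). Wild-type/mutant
differences are tested with a permutation-exact Mann–Whitney U test
(minimum one-sided p = 0.05 for triplicates).

## Worked example

Simulate a small assay panel (two cargoes, wild type plus two mutants,
three replicate images each) and run the full pipeline:

```r
library(halotrace)

cfg <- image_sim_config(pixels = 512L)        # 317 µm field, 12-bit
truth <- rbind(WT    = c(SRSF1 = 1.2, RBM12 = 0.8),
               D750R = c(0.10, 0.60),
               R671E = c(1.15, 0.25))
panel <- simulate_assay_panel(truth, reps = 3, cfg = cfg,
                              beads_per_image = 2, seed = 42)
run <- run_pipeline(panel$sample_sheet, images = panel$images,
                    ntr_class = "TrnSR-like")
run$profile_table
#>   cargo mutant normalized discrete mwu_p
#> 1 SRSF1  D750R 0.06309334      0.0  0.05
#> 2 SRSF1  R671E 0.99122905      1.0  0.80
#> 3 RBM12  D750R 0.70444609      1.0  0.05
#> 4 RBM12  R671E 0.33791907      0.5  0.05
run$profile_matrix
#>       D750R R671E
#> SRSF1     0   1.0
#> RBM12     1   0.5
```

The planted effects are recovered: the D750R-style mutant abolishes
SRSF1-style binding (normalized 0.06 → rank 0, exact MWU p = 0.05, the
triplicate floor), while R671E leaves it untouched (0.99 → rank 1) and
reduces the second cargo (0.34 → rank 0.5). Ward clustering of the
discrete profiles (`run$linkage`, `run$clusters`) groups cargoes by
mutant response.

ETA on a simulated 78 + 72 ortholog alignment with two planted
differentiated columns:

```r
cfg <- alignment_sim_config(n_per_group = c(A = 78L, B = 72L),
    column_classes = c(rep("shared-conserved", 16),
                       rep("differentiated", 2), rep("variable", 12)))
sim <- simulate_grouped_alignment(cfg, seed = 1)
scores <- score_all_sites(sim$alignment)
head(top_sites(scores, 0.10)[, c("column", "consensus_A", "consensus_B",
                                 "kl", "rank")], 3)
#>    column consensus_A consensus_B         kl rank
#> 18     18           I           S 13.6987452    1
#> 17     17           Y           G  9.8820962    2
#> 19     19           D           A  0.9585997    3
```

Both planted columns (17, 18) top the ranking with scores an order of
magnitude above every background column. And the RSY scanner on the
classic qualifying repeat:

```r
window_compositions("RSYSRSYSRSYSRSY", 1, 15)
#>   start end length rsy_comp dipep_rsy_comp dipep_sy_comp qualifies
#> 1     1  15     15        1              1           0.5      TRUE
```

A thin command-line wrapper over these functions ships in
`inst/scripts/halotrace.R` (subcommands `eta`, `rsy`, `cluster`).

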