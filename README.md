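# alascan

Quantitative pharmacology for receptor alanine-scanning mutagenesis.

Alanine scans of G protein-coupled receptors — the motivating system is
the extracellular surface of the GLP-1 receptor probed with GLP-1,
oxyntomodulin and exendin-4 across cAMP, pERK1/2 and intracellular Ca²⁺
signaling — produce, per point mutant, concentration-response curves for
several ligand × pathway combinations, competition radioligand-binding
curves, and a cell-surface expression measurement. `alascan` turns those
raw tables into per-residue pharmacology for the people who generate
them: it

* fits three-parameter logistic curves (pEC50, Emax) and one-site
  competition binding with Cheng–Prusoff conversion to pKi;
* estimates operational efficacy with the Black–Leff model
  `Y = Bottom + (Em − Bottom) / (1 + (10^logKA + 10^log[A]) / 10^(logτ + log[A]))`
  and corrects τ for cell-surface expression
  (`log τc = log τ − log10(f_mut/f_wt)`) with full error propagation;
* compares every mutant to wild-type with one-way ANOVA plus Dunnett's
  post-test and classifies significant effects into the fold-change heat
  classes 3–5, 5–10, 10–30 and >30-fold;
* quantifies biased agonism as ΔΔlog(τ/K_A) — transduction coefficients
  normalized to a reference ligand within pathway, then to a reference
  pathway within ligand — with "web of bias" radar-plot export;
* projects per-residue heat categories onto a 3D structure through the
  PDB B-factor column, plus per-residue summary classes (global /
  selective / shared / enhanced / mixed) across ligands;
* ships a synthetic-data generator with known ground truth emulating the
  study design (4–6 independent experiments in duplicate, 5% CV), so the
  entire pipeline is testable end to end without any external data.

See `vignettes/alanine-scan-pharmacology.Rmd` for the models, the
operational-model identifiability discussion, and all numerical choices.

## Worked example

Simulate a mutant panel with known truth — 4-, 7-, 18- and 50-fold
losses in either binding affinity (L201A, K202A, M204A, V206A) or
signaling efficacy (G285A, T286A, Y291A, E294A) — and analyze it:

```r
library(alascan)
library(dplyr)

lib   <- scenario_library()
panel <- generate_panel(lib$mutant_classes, seed = 42)
res   <- analyze_panel(panel, run_config())

res$deltas |>
  filter(ligand_id == "GLP-1", measure == "pKi" | pathway_id == "cAMP") |>
  select(construct_id, measure, delta, p_adj, fold_change, category) |>
  arrange(measure, construct_id)
```

```
   construct_id   measure    delta    p_adj fold_change   category
1         E294A log_tau_c -1.68033 0.00e+00       47.90 fold_gt_30
2         G285A log_tau_c -0.55514 0.00e+00        3.59   fold_3_5
3         K202A log_tau_c -0.00496 1.00e+00        1.01  no_effect
4         L201A log_tau_c -0.13154 7.08e-03        1.35  no_effect
5         M204A log_tau_c -0.01875 9.97e-01        1.04  no_effect
6         T286A log_tau_c -0.85412 0.00e+00        7.15  fold_5_10
7         V206A log_tau_c -0.03934 8.47e-01        1.09  no_effect
8         Y291A log_tau_c -1.23210 0.00e+00       17.06 fold_10_30
9         E294A       pKi -0.01529 1.00e+00        1.04  no_effect
10        G285A       pKi -0.09271 4.12e-01        1.24  no_effect
11        K202A       pKi -0.90239 0.00e+00        7.99  fold_5_10
12        L201A       pKi -0.64244 1.44e-15        4.39   fold_3_5
13        M204A       pKi -1.27073 0.00e+00       18.65 fold_10_30
14        V206A       pKi -1.69931 0.00e+00       50.04 fold_gt_30
...
```

Each of the eight mutants is recovered in its true heat bin on the
measure its truth perturbs (e.g. V206A: 50-fold affinity loss, measured
50.04-fold, `fold_gt_30`), while the untouched measure stays below the
3-fold reporting threshold — note L201A's 1.35-fold τc change is
statistically significant (p = 0.007) but renders `no_effect`, mirroring
the heatmap convention that sub-3-fold effects are not colored. The same
run yields wild-type bias factors:

```r
res$bias |> select(ligand_id, pathway_id, log_tka, ddelta_log_tka)
```

```
      ligand_id pathway_id log_tka ddelta_log_tka
1     exendin-4       cAMP    9.39         0.0000
2         GLP-1       cAMP    8.87         0.0000
3 oxyntomodulin       cAMP    6.75         0.0000
4     exendin-4       pERK    9.07         0.0455
5         GLP-1       pERK    8.50         0.0000
6 oxyntomodulin       pERK    7.37         0.9787
7     exendin-4        iCa    8.63        -0.2271
8         GLP-1        iCa    8.33         0.0000
9 oxyntomodulin        iCa    6.32         0.1012
```

The oxyntomodulin-like ligand's generative truth is a +1.0 log-unit bias
toward pERK relative to GLP-1 and cAMP; the pipeline recovers
ΔΔlog(τ/K_A) = 0.98 (a ~10-fold bias factor). Reference rows are exactly
0 by construction. The full example takes about two minutes.

Structure heatmaps are written with
`write_structure_annotation(annotations, "model.pdb", "heatmap.pdb",
"heatmap.tsv")`, which encodes category codes (0 no-effect … 4 >30-fold,
5 enhanced, −1 not determined, −9 unannotated) in the B-factor column of
every atom; the color legend ships in
`inst/extdata/heat_legend.json`. A thin command-line wrapper with
`simulate` / `analyze` / `bias` / `map-structure` verbs is installed at
`system.file("cli/alascan", package = "alascan")`.

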