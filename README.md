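# patchbind

Predicting which residues of a protein bind RNA, from structure alone
plus sequence profiles. `patchbind` is an R implementation of a
surface-patch shape-descriptor method for RNA-binding residue
prediction, aimed at structural bioinformaticians who have protein–RNA
complexes (PDB) and PSI-BLAST PSSMs and want leakage-free, protein-level
cross-validated predictions — or who want to study the method itself on
fully synthetic, self-contained benchmarks.

## The method in brief

A residue is **RNA-binding** when any of its atoms lies within 5 Å of
any nucleotide atom, and a **surface residue** when its
solvent-accessible area (Shrake–Rupley, probe 1.4 Å) is strictly
positive. Each residue is reduced to five points — backbone N, CA, C, O
and the side-chain center — and two or three neighboring surface
residues (minimum heavy-atom distance ≤ d\_N = 3 Å) form a rigid
*patch*. Patches are compared by the permutation-minimized least-squares
distance

d\_SS(X, Y) = min over residue orders of
&radic;( min\_{R,t} &Sigma;\_{ij} ‖x\_{ij} − (R y\_{ij} + t)‖² ),

with the rotation from the SVD of the centered cross-covariance
(determinant-corrected; scale fixed to 1). Patches around known binding
residues of a training set are the *template patches*; complete-linkage
clustering under d\_SS groups them into 40 three-residue and 20
two-residue clusters whose medoids are the *representative patches*
Y\_1 … Y\_60. A residue's structural features are its accumulated
distances f\_j = &Sigma;\_i d\_SS(X\_i, Y\_j) of its surrounding patches
to each representative (the size-mismatched block set to zero), giving
60 values; 20 PSSM scores and one interface propensity complete an
81-dimensional vector. An ensemble of ridge regression, perceptron and
a small MLP — inner 5-fold tuned, outputs clipped to [−1, 1] and
averaged — scores each residue, evaluated by protein-level 4-fold
cross-validation with the full confusion-metric suite and ROC/AUC.

## Worked example

Everything below is self-contained: the fixture generator writes toy
protein–RNA complexes (planted binding-site geometry, known labels) and
pseudo-PSSMs, and the pipeline consumes them through the same PDB/PSSM
readers used for real data.

```r
library(patchbind)

# generate a small benchmark of toy protein-RNA complexes
spec <- fixture_spec(n_proteins = 8, residues_per_protein = 30, seed = 7)
dir <- file.path(tempdir(), "demo-bench")
make_benchmark(spec, dir)
bench <- load_benchmark(dir)

# annotate: solvent accessibility, surface and 5 A binding labels
complexes <- lapply(bench$complexes, annotate_complex)
head(annotation_table(complexes[[1]]), 3)
#>   source_id chain_id seq_index aa_type     sasa is_surface is_binding
#> 1     toy01        A         1       R 251.9793       TRUE       TRUE
#> 2     toy01        A         2       A 119.5255       TRUE      FALSE
#> 3     toy01        A         3       R 122.6365       TRUE      FALSE

# protein-level 4-fold cross-validation of the full pipeline
cfg <- default_run_config(n3 = 10, n2 = 4)   # small template library
cv <- crossvalidate(complexes, bench$pssms, n_folds = 4, seed = 1,
                    config = cfg)
cv
#> <cv_result: 4 folds, pooled AUC 0.998 MCC 0.959>
round(unlist(cv$pooled[c("auc", "mcc", "precision", "sensitivity",
                         "specificity", "f_score")]), 3)
#>         auc         mcc   precision sensitivity specificity     f_score
#>       0.998       0.959       0.941       1.000       0.977       0.970
```

The annotation table shows each residue's accessible area and the two
labels every later stage depends on; residue 1 is a designated contact
(an RNA pseudo-nucleotide sits 3 Å away), so it is binding. The pooled
cross-validated AUC near 1 says the planted structural motif at binding
sites is recovered almost perfectly by the accumulated-distance
features — on real complexes the signal is, of course, far weaker.

Templates, representatives and features are also available directly:
`extract_templates()`, `build_representative_set()`,
`assemble_features()`, `train_ensemble()`, `predict_scores()`,
`compute_metrics()`; `run_pipeline()` persists every intermediate of a
run, and `ablation_study()` re-runs the same folds under the four
feature designs (structural / PSSM / structural+PSSM / all). A thin
command-line front-end is installed as `exec/patchbind`
(`patchbind make-fixtures`, `patchbind run`).

## Documentation

The methods vignette (`vignettes/structural-features.Rmd`) describes
the model, its parameters and defaults, the numerical choices, what the
synthetic benchmark does and does not emulate, and known limitations.
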