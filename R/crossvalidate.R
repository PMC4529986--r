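#' Protein-level cross-validation of the full pipeline
#'
#' Proteins (never residues) are partitioned into `n_folds` groups at
#' random under `seed`. In each fold, template patches, representative
#' patches and the interface propensity table are derived from the
#' training proteins only; both sides are then featurized against those
#' fold-specific representatives, the ensemble is trained on the training
#' residues and scores the test residues. No information from a test
#' protein enters templates, propensity or training.
#'
#' @param complexes list of annotated `complex_model`s (surface and
#'   binding labels assigned).
#' @param pssms named list of PSSM matrices keyed `"<source_id>|<chain>"`.
#' @param n_folds number of folds (default 4).
#' @param seed integer seed driving fold assignment, subsampling and
#'   member fitting.
#' @param config pipeline parameters; see [default_run_config()].
#' @param categories optional named character vector (by source_id) for a
#'   per-category metrics breakdown.
#' @return an object of class `cv_result`: `pooled` metrics over the
#'   concatenated test scores, `per_fold` metrics, `fold_assignment`,
#'   `predictions`, and a provenance `audit` of template origins.
#' @export
crossvalidate <- function(complexes, pssms, n_folds = 4, seed = 1,
                          config = default_run_config(),
                          categories = NULL) {
  n <- length(complexes)
  if (n < n_folds) {
    stop("need at least ", n_folds, " proteins for ", n_folds,
         "-fold cross-validation")
  }
  ids <- vapply(complexes, function(cx) cx$source_id, character(1L))
  folds <- with_seed(child_seed(seed, "folds"),
                     sample(rep_len(seq_len(n_folds), n)))
  names(folds) <- ids

  preds <- list()
  per_fold <- list()
  audit <- list()
  for (f in seq_len(n_folds)) {
    tr <- complexes[folds != f]
    te <- complexes[folds == f]
    templ <- extract_templates(tr, d_N = config$d_N,
                               same_chain_only = config$same_chain_only)
    reps <- build_representative_set(
      templ$templates_3aa, templ$templates_2aa,
      n3 = config$n3, n2 = config$n2, n_max = config$n_max,
      seed = child_seed(seed, paste0("subsample", f)))
    prop <- compute_propensity(tr, alpha = config$propensity_alpha)
    feats_tr <- assemble_features(tr, reps, pssms, prop, d_N = config$d_N,
                                  same_chain_only = config$same_chain_only)
    feats_te <- assemble_features(te, reps, pssms, prop, d_N = config$d_N,
                                  same_chain_only = config$same_chain_only)
    model <- train_ensemble(feats_tr, seed = child_seed(seed, paste0("fit", f)),
                            config = config$ensemble,
                            blocks = config$feature_blocks)
    pred <- predict_scores(model, feats_te, theta = config$theta)
    pred$fold <- f
    preds[[f]] <- pred
    per_fold[[f]] <- compute_metrics(pred)
    audit[[f]] <- list(
      test_ids = vapply(te, function(cx) cx$source_id, character(1L)),
      template_sources = unique(c(
        vapply(templ$templates_3aa, function(p) p$origin$source_id,
               character(1L)),
        vapply(templ$templates_2aa, function(p) p$origin$source_id,
               character(1L)))),
      train_sources = unique(feats_tr$source_id))
  }
  predictions <- do.call(rbind, preds)
  out <- list(pooled = compute_metrics(predictions),
              per_fold = per_fold,
              fold_assignment = folds,
              predictions = predictions,
              audit = audit)
  if (!is.null(categories)) {
    out$per_category <- lapply(split(
      predictions, categories[predictions$source_id]), compute_metrics)
  }
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, pooled AUC %.3f MCC %.3f>\n",
              length(x$per_fold), x$pooled$auc, x$pooled$mcc))
  invisible(x)
}

#' Feature-ablation experiment
#'
#' Runs the same cross-validation folds under four feature
#' configurations -- structural only, PSSM only, structural + PSSM, and
#' all features (adding the interface propensity) -- mirroring the
#' standard ablation design for this method.
#'
#' @inheritParams crossvalidate
#' @return named list of `cv_result`s: `structural`, `pssm`,
#'   `structural_pssm`, `all`.
#' @export
ablation_study <- function(complexes, pssms, n_folds = 4, seed = 1,
                           config = default_run_config()) {
  designs <- list(structural = "structural",
                  pssm = "pssm",
                  structural_pssm = c("structural", "pssm"),
                  all = c("structural", "pssm", "propensity"))
  lapply(designs, function(blocks) {
    cfg <- config
    cfg$feature_blocks <- blocks
    crossvalidate(complexes, pssms, n_folds = n_folds, seed = seed,
                  config = cfg)
  })
}
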