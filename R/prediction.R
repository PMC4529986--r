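# Ensemble of ridge regression, perceptron and multilayer perceptron on
# z-scored features with +/-1 targets. Member outputs are clipped to
# [-1, 1] and averaged; hyperparameters are chosen by inner 5-fold
# cross-validation maximizing AUC.

clip1 <- function(x) pmin(1, pmax(-1, x))

default_ensemble_config <- function() {
  list(ridge_lambdas = c(0.01, 0.1, 1, 10, 100),
       perceptron_epochs = c(5L, 20L, 50L),
       mlp_sizes = c(5L, 10L, 20L),
       mlp_decay = 0.01,
       mlp_maxit = 150L,
       inner_folds = 5L)
}

# --- members ---------------------------------------------------------------

fit_ridge <- function(X, y, lambda) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- diag(lambda, p); pen[1, 1] <- 0  # intercept unpenalized
  w <- solve(crossprod(Xi) + pen, crossprod(Xi, y))
  list(kind = "ridge", w = as.numeric(w), lambda = lambda)
}

# Classic Rosenblatt perceptron: online updates on misclassified points,
# fixed shuffled order per epoch; score is the clipped linear activation.
fit_perceptron <- function(X, y, epochs, seed) {
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        if (y[i] * (sum(w * X[i, ]) + b) <= 0) {
          w <- w + y[i] * X[i, ]
          b <- b + y[i]
        }
      }
    }
  })
  scale <- sqrt(sum(w^2))
  list(kind = "perceptron", w = w, b = b,
       scale = if (scale > 0) scale else 1, epochs = epochs)
}

fit_mlp <- function(X, y, size, decay, maxit, seed) {
  fit <- with_seed(seed, nnet::nnet(
    x = X, y = y, size = size, decay = decay, maxit = maxit,
    linout = TRUE, trace = FALSE, MaxNWts = 10000))
  list(kind = "mlp", fit = fit, size = size)
}

member_scores <- function(member, X) {
  raw <- switch(member$kind,
    ridge = as.numeric(cbind(1, X) %*% member$w),
    perceptron = (as.numeric(X %*% member$w) + member$b) / member$scale,
    mlp = as.numeric(predict(member$fit, X)),
    stop("unknown member kind"))
  clip1(raw)
}

# --- tuning ----------------------------------------------------------------

inner_cv_auc <- function(fit_fun, X, y, n_folds, seed) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  scores <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    member <- fit_fun(X[tr, , drop = FALSE], y[tr])
    scores[!tr] <- member_scores(member, X[!tr, , drop = FALSE])
  }
  roc_auc(scores, y > 0)$auc
}

tune_member <- function(grid, make_fit, X, y, n_folds, seed) {
  aucs <- vapply(seq_along(grid), function(g) {
    inner_cv_auc(function(Xt, yt) make_fit(Xt, yt, grid[[g]], g),
                 X, y, n_folds, seed)
  }, numeric(1L))
  if (all(is.na(aucs))) return(list(choice = grid[[1L]], aucs = aucs))
  list(choice = grid[[which.max(aucs)]], aucs = aucs)
}

# --- ensemble --------------------------------------------------------------

#' Train the ensemble classifier
#'
#' Fits ridge regression, a perceptron and a single-hidden-layer
#' multilayer perceptron on z-scored features with targets encoded as
#' -1/+1. Each member's hyperparameter (ridge penalty, perceptron epochs,
#' hidden width) is chosen by inner 5-fold cross-validation maximizing
#' AUC; the fitted ensemble averages the members' clipped outputs.
#' Deterministic for a fixed seed.
#'
#' @param features data.frame from [assemble_features()], or a numeric
#'   matrix; must carry a logical `label` column (or supply `labels`).
#' @param labels optional logical/±1 labels when `features` is a matrix.
#' @param seed integer seed.
#' @param config member grids (see package vignette); defaults cover a
#'   small desk-scale grid.
#' @param blocks feature blocks to use ("structural", "pssm",
#'   "propensity").
#' @return an object of class `ensemble_model`.
#' @export
train_ensemble <- function(features, labels = NULL, seed = 1,
                           config = default_ensemble_config(),
                           blocks = c("structural", "pssm", "propensity")) {
  if (is.data.frame(features)) {
    cols <- feature_columns(features, blocks)
    X <- as.matrix(features[, cols, drop = FALSE])
    if (is.null(labels)) labels <- features$label
  } else {
    X <- as.matrix(features)
    cols <- colnames(X)
  }
  y <- ifelse(as.logical(labels), 1, -1)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes")
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  Z <- scale(X, center = mu, scale = sdev)

  cfg <- config
  nf <- min(cfg$inner_folds, nrow(Z))
  tune_seed <- child_seed(seed, "tune")
  ridge_t <- tune_member(as.list(cfg$ridge_lambdas),
                         function(Xt, yt, v, g) fit_ridge(Xt, yt, v),
                         Z, y, nf, tune_seed)
  perc_t <- tune_member(as.list(cfg$perceptron_epochs),
                        function(Xt, yt, v, g) {
                          fit_perceptron(Xt, yt, v,
                                         child_seed(seed, paste0("perc", g)))
                        }, Z, y, nf, tune_seed)
  mlp_t <- tune_member(as.list(cfg$mlp_sizes),
                       function(Xt, yt, v, g) {
                         fit_mlp(Xt, yt, v, cfg$mlp_decay, cfg$mlp_maxit,
                                 child_seed(seed, paste0("mlp", g)))
                       }, Z, y, nf, tune_seed)

  members <- list(
    fit_ridge(Z, y, ridge_t$choice),
    fit_perceptron(Z, y, perc_t$choice, child_seed(seed, "percfinal")),
    fit_mlp(Z, y, mlp_t$choice, cfg$mlp_decay, cfg$mlp_maxit,
            child_seed(seed, "mlpfinal")))

  structure(list(members = members, center = mu, scale = sdev,
                 feature_names = cols, seed = seed,
                 tuning_record = list(ridge = ridge_t, perceptron = perc_t,
                                      mlp = mlp_t)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model: %d members, %d features>\n",
              length(x$members), length(x$feature_names)))
  invisible(x)
}

#' Score residues with a trained ensemble
#'
#' Member outputs are clipped to [-1, 1] and averaged; the predicted
#' label is `score >= theta`.
#'
#' @param model an `ensemble_model`.
#' @param features data.frame or matrix with the training feature
#'   columns.
#' @param theta decision threshold (default 0, the midpoint of the score
#'   range).
#' @return a `prediction_set` data.frame: provenance columns when
#'   available, `score` in [-1, 1], `pred_label`, `true_label` (NA when
#'   unknown).
#' @export
predict_scores <- function(model, features, theta = 0) {
  stopifnot(inherits(model, "ensemble_model"))
  prov <- NULL
  truth <- NA
  if (is.data.frame(features)) {
    missing <- setdiff(model$feature_names, names(features))
    if (length(missing) > 0L) {
      stop("feature columns missing from input: ",
           paste(head(missing, 5), collapse = ", "))
    }
    X <- as.matrix(features[, model$feature_names, drop = FALSE])
    prov_cols <- intersect(c("source_id", "chain_id", "seq_index", "aa"),
                           names(features))
    if (length(prov_cols) > 0L) prov <- features[, prov_cols, drop = FALSE]
    if ("label" %in% names(features)) truth <- features$label
  } else {
    X <- as.matrix(features)
    if (ncol(X) != length(model$feature_names)) {
      stop("feature dimension mismatch: got ", ncol(X), ", expected ",
           length(model$feature_names))
    }
  }
  Z <- scale(X, center = model$center, scale = model$scale)
  S <- vapply(model$members, function(mb) member_scores(mb, Z),
              numeric(nrow(Z)))
  if (nrow(Z) == 1L) S <- matrix(S, nrow = 1L)
  score <- clip1(rowMeans(S))
  out <- data.frame(score = score, pred_label = score >= theta,
                    true_label = truth)
  if (!is.null(prov)) out <- cbind(prov, out)
  class(out) <- c("prediction_set", class(out))
  out
}
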