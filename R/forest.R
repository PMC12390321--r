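# The immunogenicity classifier: a random forest over the 118-dimensional
# peptide encoding. 1000 Gini trees, minimum split size 3, no bootstrap
# (every tree sees the full training set; diversity comes from per-split
# feature subsampling), scores = mean leaf class-1 fraction across trees.

#' Random-forest configuration
#'
#' @param n_trees number of trees (default 1000).
#' @param min_samples_split smallest node that may still be split (default 3).
#' @param bootstrap if `FALSE` (default) every tree is fit on the full
#'   training set.
#' @param features_per_split candidate features per split; defaults to
#'   `floor(sqrt(p))` at fit time when `NULL`.
#' @param seed integer seed controlling all tree randomness.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 1000L, min_samples_split = 3L,
                          bootstrap = FALSE, features_per_split = NULL,
                          seed = 1L) {
  stopifnot(n_trees >= 1, min_samples_split >= 2)
  if (!is.null(features_per_split)) {
    stopifnot(features_per_split >= 1, features_per_split <= FEATURE_DIM)
  }
  structure(
    list(
      n_trees = as.integer(n_trees),
      min_samples_split = as.integer(min_samples_split),
      split_criterion = "gini",
      bootstrap = isTRUE(bootstrap),
      features_per_split = features_per_split,
      seed = as.integer(seed)
    ),
    class = "forest_config"
  )
}

#' Train the immunogenicity random forest
#'
#' @param features numeric matrix (n x 118), e.g. from [encode_peptides()].
#' @param labels binary vector (1 = immunogenic).
#' @param config a [forest_config()].
#' @return an object of class `immuno_forest` with the fitted ensemble,
#'   normalized per-feature importances, and a training fingerprint.
#' @export
train_forest <- function(features, labels, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  features <- as.matrix(features)
  if (anyNA(features)) stop("NaN/NA feature values", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels/features length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2) stop("training data contains a single class", call. = FALSE)
  if (min(table(labels)) < 2) stop("need at least 2 instances per class", call. = FALSE)
  mtry <- config$features_per_split %||% floor(sqrt(ncol(features)))
  df <- data.frame(.label = factor(labels, levels = c(0, 1)), features,
    check.names = FALSE
  )
  fit <- ranger::ranger(
    dependent.variable.name = ".label",
    data = df,
    num.trees = config$n_trees,
    mtry = mtry,
    min.node.size = config$min_samples_split,
    splitrule = "gini",
    replace = config$bootstrap,
    sample.fraction = 1,
    probability = TRUE,
    importance = "impurity",
    seed = config$seed,
    num.threads = 1L,
    respect.unordered.factors = FALSE
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  structure(
    list(
      config = config,
      fit = fit,
      feature_importances = imp,
      feature_names = colnames(features),
      training_fingerprint = rlang::hash(list(dim(features), labels, config))
    ),
    class = "immuno_forest"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.immuno_forest <- function(x, ...) {
  cat(sprintf(
    "<immuno_forest> %d trees, mtry %s, %d features (fingerprint %s)\n",
    x$config$n_trees, x$config$features_per_split %||% "sqrt", length(x$feature_names),
    substr(x$training_fingerprint, 1, 8)
  ))
  invisible(x)
}

#' Score peptide feature vectors with a trained forest
#'
#' @param model an `immuno_forest`.
#' @param features numeric matrix with the same columns as at training.
#' @return numeric vector of immunogenicity scores in \[0, 1\] (mean leaf
#'   class-1 fraction across trees); higher means more likely immunogenic.
#' @export
score_forest <- function(model, features) {
  stopifnot(inherits(model, "immuno_forest"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$feature_names)) {
    stop(sprintf(
      "feature dimension mismatch: %d columns, model expects %d",
      ncol(features), length(model$feature_names)
    ), call. = FALSE)
  }
  colnames(features) <- model$feature_names
  unname(stats::predict(model$fit,
    data = as.data.frame(features, check.names = FALSE),
    num.threads = 1L
  )$predictions[, "1"])
}

#' Build a peptide scorer closure from a model and encoder
#'
#' @param model an `immuno_forest`.
#' @param encoder the [fit_residue_encoder()] used at training time.
#' @return a function mapping a character vector of peptides to scores.
#' @export
forest_scorer <- function(model, encoder) {
  force(model)
  force(encoder)
  function(peptides) score_forest(model, encode_peptides(peptides, encoder))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class under a fixed seed; every instance is scored
#' by a model whose training folds excluded it. ROC AUC and average precision
#' are computed on the pooled out-of-fold scores.
#'
#' @inheritParams train_forest
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @return a `cv_result` list: `fold_assignments`, `scores` (out-of-fold,
#'   in input order), `roc_auc`, `pr_auc`.
#' @export
cross_validate <- function(features, labels, config = forest_config(),
                           k = 10L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > min(table(labels))) {
    stop("k exceeds the minority class count", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    test <- fold == f
    m <- train_forest(features[!test, , drop = FALSE], labels[!test], config)
    scores[test] <- score_forest(m, features[test, , drop = FALSE])
  }
  structure(
    list(
      fold_assignments = fold,
      scores = scores,
      roc_auc = roc_curve_auc(scores, labels)$auc,
      pr_auc = pr_curve_ap(scores, labels)$average_precision
    ),
    class = "cv_result"
  )
}

#' Aggregate feature importances by positional slot and global descriptor
#'
#' @param model an `immuno_forest` trained on the 118-feature encoding.
#' @return data.frame with columns `group` (`pos1`..`pos11`, then the 8
#'   descriptor names), `kind` (`positional`/`global`), `importance`;
#'   importances sum to 1.
#' @export
feature_importance_report <- function(model) {
  stopifnot(inherits(model, "immuno_forest"))
  imp <- model$feature_importances
  nm <- model$feature_names
  pos <- sub("_pc[0-9]+$", "", nm)
  is_pos <- grepl("^pos[0-9]+$", pos)
  groups <- c(paste0("pos", seq_len(N_SLOTS)), GLOBAL_DESCRIPTOR_NAMES)
  agg <- vapply(groups, function(g) {
    sum(imp[pos == g | (!is_pos & nm == g)])
  }, numeric(1))
  data.frame(
    group = groups,
    kind = rep(c("positional", "global"), c(N_SLOTS, 8L)),
    importance = unname(agg),
    stringsAsFactors = FALSE
  )
}
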