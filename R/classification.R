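## Subtype classification by k-nearest neighbors.
##
## The discovery cohort is split 4:1 (stratified by event status so the
## test fifth keeps events for the log-rank evaluation); a KNN classifier
## with the fixed hyperparameters n_neighbors = 5, leaf_size = 30 and
## Minkowski power 2 (Euclidean) is trained on the PAS panel features
## against the G1/G2 cluster labels, validated by stratified 10-fold CV,
## and applied to held-out and external cohorts. The leaf size is a
## neighbor-search index parameter with no effect on predictions; it is
## recorded for fidelity and otherwise inert. The classifier's continuous
## risk score is the fraction of neighbors voting G2.

#' Split samples into training and test sets at a 4:1 ratio
#'
#' Random split stratified by event indicator; the training set receives
#' `floor(ratio * n)` samples overall (per-stratum floors, remainder
#' assigned to the strata with the largest fractional parts).
#'
#' @param sample_ids character vector of sample ids.
#' @param surv survival data.frame covering the ids (for stratification).
#' @param ratio training fraction (default 0.8, the 4:1 split).
#' @param seed integer seed; same seed, same split.
#' @param stratify_event stratify by the event indicator (default TRUE).
#' @return list(train_ids, test_ids, ratio, seed, stratified_by_event).
#' @export
split_train_test <- function(sample_ids, surv, ratio = 0.8, seed = 1L,
                             stratify_event = TRUE) {
  n <- length(sample_ids)
  stopifnot(n >= 2, ratio > 0, ratio < 1)
  strata <- if (stratify_event) {
    ev <- surv$event[match(sample_ids, surv$sample_id)]
    if (anyNA(ev)) stop("survival table missing sample(s) for the split")
    split(sample_ids, ev)
  } else {
    list(all = sample_ids)
  }
  n_train_total <- floor(ratio * n)
  floors <- vapply(strata, function(s) floor(ratio * length(s)), numeric(1))
  frac <- vapply(strata, function(s) ratio * length(s), numeric(1)) - floors
  deficit <- n_train_total - sum(floors)
  if (deficit > 0) {
    bump <- order(-frac, names(strata))[seq_len(deficit)]
    floors[bump] <- floors[bump] + 1
  }
  strata_seeds <- spawn_seeds(seed, length(strata))
  train_ids <- unlist(lapply(seq_along(strata), function(i) {
    with_seed(strata_seeds[i],
              sample(strata[[i]], size = min(floors[i], length(strata[[i]]))))
  }), use.names = FALSE)
  list(train_ids = sort(train_ids),
       test_ids = sort(setdiff(sample_ids, train_ids)),
       ratio = ratio, seed = as.integer(seed),
       stratified_by_event = stratify_event)
}

#' Train the KNN subtype classifier
#'
#' KNN stores its training set; training is index construction only. The
#' defaults are the pipeline's fixed hyperparameters: 5 neighbors, leaf
#' size 30, Minkowski power 2.
#'
#' @param features training PAS matrix, features (panel) x samples.
#' @param labels named subtype labels for the training samples.
#' @param n_neighbors,leaf_size,minkowski_power KNN hyperparameters.
#' @return a `knn_model` list.
#' @export
train_knn <- function(features, labels, n_neighbors = 5, leaf_size = 30,
                      minkowski_power = 2) {
  x <- t(features)
  labels <- labels[rownames(x)]
  if (anyNA(labels)) stop("labels missing for some training samples")
  if (nrow(x) < n_neighbors) {
    stop(sprintf("need at least %d training samples for %d-NN",
                 n_neighbors, n_neighbors))
  }
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class")
  }
  structure(list(x = x, labels = labels, panel = colnames(x),
                 n_neighbors = as.integer(n_neighbors),
                 leaf_size = as.integer(leaf_size),
                 minkowski_power = minkowski_power,
                 risk_levels = sort(unique(as.character(labels)))),
            class = "knn_model")
}

#' Predict subtypes and risk scores for new samples
#'
#' Majority vote among the `n_neighbors` nearest training samples under
#' the Minkowski metric (power 2 = Euclidean); distance ties are resolved
#' by training-sample order. The score is the fraction of neighbors voting
#' G2 and serves downstream as the continuous risk score; vote ties break
#' toward the lower-risk label (G1 before G2 in the survival ordering), to
#' avoid over-calling the aggressive class.
#'
#' @param model a `knn_model`.
#' @param features PAS matrix of new samples (features x samples) covering
#'   the model's panel.
#' @return data.frame (sample_id, label, score).
#' @export
predict_knn <- function(model, features) {
  stopifnot(inherits(model, "knn_model"))
  miss <- setdiff(model$panel, rownames(features))
  if (length(miss) > 0) {
    stop("features missing panel entries: ", paste(head(miss, 5), collapse = ", "))
  }
  xnew <- t(features[model$panel, , drop = FALSE])
  p <- model$minkowski_power
  k <- model$n_neighbors
  lvl <- model$risk_levels  # survival-ordered: G1 < ... < G2
  out <- lapply(seq_len(nrow(xnew)), function(i) {
    d <- (rowSums(abs(model$x - matrix(xnew[i, ], nrow(model$x),
                                       ncol(model$x), byrow = TRUE))^p))^(1 / p)
    nb <- order(d, seq_along(d))[seq_len(k)]  # stable under distance ties
    votes <- as.character(model$labels[nb])
    counts <- vapply(lvl, function(l) sum(votes == l), numeric(1))
    label <- lvl[which.max(counts)]  # ties -> first = lower-risk label
    data.frame(sample_id = rownames(xnew)[i], label = label,
               score = mean(votes == "G2"), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratified k-fold cross-validation of the KNN classifier
#'
#' Folds are stratified by class; when the minority class has fewer members
#' than `folds`, the fold count is reduced to that size with a warning.
#' Returns per-fold accuracy and ROC-AUC of the G2-fraction score against
#' the held-out labels, with their mean and SD.
#'
#' @param features PAS matrix, features x samples.
#' @param labels named subtype labels.
#' @param folds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param ... hyperparameters passed to [train_knn()].
#' @return list(per_fold, mean_accuracy, sd_accuracy, mean_auc, sd_auc, folds).
#' @export
cross_validate <- function(features, labels, folds = 10, seed = 1L, ...) {
  labels <- labels[colnames(features)]
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to minority class size %d",
                    folds, min_class), call. = FALSE)
    folds <- min_class
  }
  stopifnot(folds >= 2)
  fold_of <- with_seed(seed, {
    f <- integer(length(labels))
    names(f) <- colnames(features)
    for (cls in unique(labels)) {
      ids <- names(labels)[labels == cls]
      f[ids] <- sample(rep_len(seq_len(folds), length(ids)))
    }
    f
  })
  per_fold <- lapply(seq_len(folds), function(fd) {
    test_ids <- names(fold_of)[fold_of == fd]
    train_ids <- setdiff(colnames(features), test_ids)
    model <- train_knn(features[, train_ids, drop = FALSE],
                       labels[train_ids], ...)
    pred <- predict_knn(model, features[, test_ids, drop = FALSE])
    truth <- labels[pred$sample_id]
    auc <- if (length(unique(truth)) == 2) {
      roc_auc(pred$score, truth == "G2")
    } else NA_real_
    data.frame(fold = fd, n_test = length(test_ids),
               accuracy = mean(pred$label == truth), auc = auc)
  })
  tab <- do.call(rbind, per_fold)
  list(per_fold = tab,
       mean_accuracy = mean(tab$accuracy), sd_accuracy = sd(tab$accuracy),
       mean_auc = mean(tab$auc, na.rm = TRUE),
       sd_auc = sd(tab$auc, na.rm = TRUE),
       folds = folds)
}
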