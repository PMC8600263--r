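## End-to-end discovery and prediction.
##
## Discovery, per cohort: PAS on the original gene sets -> univariate Cox
## ranking -> SIS screen (top 100) -> crosstalk decomposition of the
## screened pathways -> PAS on originals + sub-pathways -> Cox + BH FDR
## filter. The per-cohort selections are intersected into the final panel;
## panel PAS is then recomputed within each cohort (scores are always
## cohort-relative), the primary cohort is split 4:1, subtypes are
## discovered by K-means on the training fifth's complement, a KNN
## classifier is trained and cross-validated, and every cohort is
## evaluated (C-index, Brier, log-rank, AUC). One master seed drives the
## per-stage seeds so a single integer reproduces a full run.

#' Run the discovery pipeline on a multi-cohort study
#'
#' @param cohorts list of cohorts; each a list with `expr` (genes x samples
#'   matrix) and `surv` (sample_id/time/event data.frame) — synthetic
#'   cohorts from [generate_cohort()] qualify directly.
#' @param gene_sets named list of gene id vectors (original pathways).
#' @param primary index of the discovery cohort to split and cluster.
#' @param intersect_idx cohorts whose FDR-passing features are intersected
#'   into the panel. The default (`NULL`) takes the three cohorts with the
#'   most observed events (the primary always among them): FDR screening at
#'   `alpha = 0.01` needs event counts that very small cohorts cannot
#'   supply. A chosen cohort whose screen selects nothing is dropped from
#'   the intersection with a warning as long as two cohorts remain; small
#'   cohorts outside the intersection still serve as external validation.
#' @param sis_d SIS screening threshold (default 100).
#' @param min_overlap minimum pair intersection for crosstalk (default 3).
#' @param fdr_alpha FDR threshold for sub-pathway selection (default 0.01).
#' @param k_range candidate cluster counts (default 2:6).
#' @param split_ratio training fraction of the primary cohort (default 0.8).
#' @param n_neighbors,leaf_size,minkowski_power KNN hyperparameters
#'   (defaults 5, 30, 2).
#' @param cv_folds cross-validation folds (default 10).
#' @param seed master integer seed.
#' @return list: `panel`, `panel_collection`, `subtype_model`, `classifier`,
#'   `split`, `cv`, `per_cohort` (stats/selections), `reports`
#'   (evaluation per cohort), `manifest`.
#' @export
run_discovery <- function(cohorts, gene_sets, primary = 1,
                          intersect_idx = NULL,
                          sis_d = 100, min_overlap = 3, fdr_alpha = 0.01,
                          k_range = 2:6, split_ratio = 0.8,
                          n_neighbors = 5, leaf_size = 30, minkowski_power = 2,
                          cv_folds = 10, seed = 1L) {
  stopifnot(length(cohorts) >= 2, primary %in% seq_along(cohorts))
  if (is.null(names(cohorts))) {
    names(cohorts) <- sprintf("cohort%02d", seq_along(cohorts))
  }
  if (is.null(intersect_idx)) {
    # cohorts with enough events to power the q < 0.01 screen (~80 events
    # for a hazard ratio of 3; see the methods vignette), primary always
    # included, at most the three best-powered; fall back to the two
    # largest event counts when fewer than two qualify
    n_events <- vapply(cohorts, function(co) sum(co$surv$event == 1), numeric(1))
    by_events <- order(-n_events, seq_along(cohorts))
    powered <- by_events[n_events[by_events] >= 80]
    if (length(setdiff(powered, primary)) < 1) powered <- by_events[1:2]
    intersect_idx <- sort(unique(c(primary, powered))[
      seq_len(min(3, length(unique(c(primary, powered)))))])
  }
  stopifnot(primary %in% intersect_idx)
  seeds <- spawn_seeds(seed, 3)  # split, clustering, CV

  per_cohort <- lapply(seq_along(cohorts), function(ci) {
    co <- cohorts[[ci]]
    al <- align_cohort(co$expr, co$surv)
    pct_log("pas", names(cohorts)[ci], ": scoring ", length(gene_sets),
            " pathways over ", ncol(al$expr), " samples")
    pas_orig <- compute_pas_matrix(al$expr, gene_sets)
    ranked <- rank_by_survival(pas_orig, al$surv)
    screened <- sis_screen(ranked, d = sis_d)
    subfeats <- build_crosstalk_features(gene_sets[screened],
                                         min_overlap = min_overlap)
    subcoll <- subpathways_to_collection(subfeats)
    pas_sub <- compute_pas_matrix(al$expr, subcoll)
    substats <- add_fdr(rank_by_survival(pas_sub, al$surv))
    selected <- fdr_filter(substats, alpha = fdr_alpha)
    list(cohort_id = names(cohorts)[ci], expr = al$expr, surv = al$surv,
         screened = screened, subfeatures = subfeats,
         subcollection = subcoll, stats = substats, selected = selected)
  })
  names(per_cohort) <- names(cohorts)

  selections <- lapply(per_cohort[intersect_idx], `[[`, "selected")
  empty_sel <- vapply(selections, length, integer(1)) == 0
  if (any(empty_sel)) {
    warning(sprintf(
      "cohort(s) %s selected no feature at FDR < %g and leave the intersection",
      paste(names(selections)[empty_sel], collapse = ", "), fdr_alpha),
      call. = FALSE)
    if (per_cohort[[primary]]$cohort_id %in% names(selections)[empty_sel]) {
      stop("the primary cohort selected no feature at the FDR threshold")
    }
    intersect_idx <- intersect_idx[!empty_sel]
    selections <- selections[!empty_sel]
  }
  if (length(selections) < 2) {
    stop("fewer than 2 cohorts with FDR-selected features; ",
         "cannot form a cross-cohort panel (consider a larger alpha)")
  }
  panel <- intersect_cohorts(selections)
  # gene sets behind the panel ids (identical wherever defined across cohorts)
  panel_collection <- list()
  for (pc in per_cohort) {
    hit <- intersect(panel, names(pc$subcollection))
    panel_collection[hit] <- pc$subcollection[hit]
  }
  panel_collection <- panel_collection[panel]
  if (anyNA(names(panel_collection))) stop("panel feature without a gene set")

  # panel PAS recomputed within each cohort (cohort-relative medians)
  panel_pas <- lapply(per_cohort, function(pc) {
    compute_pas_matrix(pc$expr, panel_collection)
  })

  prim <- per_cohort[[primary]]
  split <- split_train_test(colnames(prim$expr), prim$surv,
                            ratio = split_ratio, seed = seeds[1])
  train_feat <- panel_pas[[primary]][, split$train_ids, drop = FALSE]
  test_feat <- panel_pas[[primary]][, split$test_ids, drop = FALSE]
  train_surv <- prim$surv[prim$surv$sample_id %in% split$train_ids, ]

  subtype_model <- fit_subtypes(train_feat, train_surv, k_range = k_range,
                                seed = seeds[2])
  classifier <- train_knn(train_feat, subtype_model$labels,
                          n_neighbors = n_neighbors, leaf_size = leaf_size,
                          minkowski_power = minkowski_power)
  cv <- cross_validate(train_feat, subtype_model$labels, folds = cv_folds,
                       seed = seeds[3], n_neighbors = n_neighbors,
                       leaf_size = leaf_size, minkowski_power = minkowski_power)

  # training-cohort KM per subtype, the survival-probability model for Brier
  surv_prob_of <- make_group_surv_prob(train_surv, subtype_model$labels)

  reports <- list()
  reports[["training"]] <- evaluate_cohort(
    labels = subtype_model$labels, surv = train_surv,
    pred_surv_prob = surv_prob_of(subtype_model$labels,
                                  median(train_surv$time)),
    cohort_id = paste0(names(cohorts)[primary], "_training"))
  reports[["training"]]$auc <- cv$mean_auc  # CV score vs cluster labels

  eval_predicted <- function(feat, surv, cohort_id) {
    pred <- predict_knn(classifier, feat)
    labels <- setNames(pred$label, pred$sample_id)
    truth <- assign_subtype(subtype_model, feat)  # centroid reference labels
    t_star <- median(surv$time)
    rep_ <- evaluate_cohort(
      labels = labels, surv = surv, score = setNames(pred$score, pred$sample_id),
      pred_surv_prob = surv_prob_of(labels, t_star), t_star = t_star,
      truth = truth, cohort_id = cohort_id)
    rep_$predictions <- pred
    rep_
  }
  reports[["test"]] <- eval_predicted(
    test_feat, prim$surv[prim$surv$sample_id %in% split$test_ids, ],
    paste0(names(cohorts)[primary], "_test"))
  for (ci in setdiff(seq_along(cohorts), primary)) {
    reports[[names(cohorts)[ci]]] <- eval_predicted(
      panel_pas[[ci]], per_cohort[[ci]]$surv, names(cohorts)[ci])
  }

  manifest <- build_manifest(per_cohort, panel, subtype_model, split, cv,
                             reports, seed,
                             params = list(sis_d = sis_d,
                                           min_overlap = min_overlap,
                                           fdr_alpha = fdr_alpha,
                                           k_range = range(k_range),
                                           split_ratio = split_ratio,
                                           n_neighbors = n_neighbors,
                                           leaf_size = leaf_size,
                                           minkowski_power = minkowski_power,
                                           cv_folds = cv_folds,
                                           primary = primary,
                                           intersect_idx = intersect_idx))
  list(panel = panel, panel_collection = panel_collection,
       subtype_model = subtype_model, classifier = classifier,
       split = split, cv = cv, per_cohort = per_cohort,
       panel_pas = panel_pas, reports = reports, manifest = manifest)
}

## Per-subtype KM survival probability lookup on the training cohort.
## Returns f(labels, t_star) -> per-sample predicted survival probability.
make_group_surv_prob <- function(train_surv, train_labels) {
  idx <- match(names(train_labels), train_surv$sample_id)
  curves <- lapply(split(idx, unname(train_labels)), function(i) {
    cv <- km_curve(train_surv$time[i], train_surv$event[i])
    stepfun(cv$time[-1], cv$surv)
  })
  function(labels, t_star) {
    vapply(as.character(labels), function(l) {
      if (!l %in% names(curves)) return(NA_real_)
      curves[[l]](t_star)
    }, numeric(1))
  }
}

build_manifest <- function(per_cohort, panel, subtype_model, split, cv,
                           reports, seed, params) {
  cohort_counts <- lapply(per_cohort, function(pc) {
    list(n_samples = ncol(pc$expr), n_genes = nrow(pc$expr),
         n_screened = length(pc$screened),
         n_crosstalk_features = length(pc$subfeatures),
         n_fdr_selected = length(pc$selected))
  })
  metric_summary <- lapply(reports, function(r) {
    list(c_index = r$c_index, brier = r$brier, logrank_p = r$logrank$p,
         auc = r$auc, t_star = r$t_star,
         group_sizes = r$group_sizes)
  })
  list(seed = as.integer(seed), params = params,
       package_version = as.character(packageVersion("pascrosstalk")),
       cohorts = cohort_counts,
       panel = as.list(panel), panel_size = length(panel),
       selected_k = subtype_model$k,
       k_diagnostics = subtype_model$diagnostics,
       split = list(n_train = length(split$train_ids),
                    n_test = length(split$test_ids)),
       cv = list(folds = cv$folds, mean_accuracy = cv$mean_accuracy,
                 mean_auc = cv$mean_auc),
       evaluation = metric_summary)
}

#' Write a run manifest as JSON
#' @param manifest manifest list from [run_discovery()].
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Predict subtypes in a new cohort with a fitted discovery result
#'
#' PAS is computed within the new cohort (its own medians) on the panel's
#' gene sets; any panel feature with zero present genes aborts with a
#' per-feature coverage listing, partial coverage is reported. The stored
#' KNN classifier assigns labels and risk scores; when survival data are
#' supplied the cohort is evaluated as in discovery.
#'
#' @param result output of [run_discovery()].
#' @param expr expression matrix of the new cohort.
#' @param surv optional survival data.frame for evaluation.
#' @return list(predictions, coverage, report or NULL).
#' @export
run_predict <- function(result, expr, surv = NULL) {
  coll <- result$panel_collection
  present <- vapply(coll, function(g) sum(g %in% rownames(expr)), integer(1))
  coverage <- data.frame(feature_id = names(coll),
                         n_genes = lengths(coll), n_present = present,
                         row.names = NULL)
  if (any(present == 0)) {
    stop("panel feature(s) with no genes in the new cohort:\n",
         paste(sprintf("  %s: %d/%d genes present", coverage$feature_id,
                       coverage$n_present, coverage$n_genes), collapse = "\n"))
  }
  pas <- compute_pas_matrix(expr, coll)
  pred <- predict_knn(result$classifier, pas)
  out <- list(predictions = pred, coverage = coverage, report = NULL)
  if (!is.null(surv)) {
    keep <- pred$sample_id %in% surv$sample_id
    labels <- setNames(pred$label, pred$sample_id)[keep]
    train_surv <- result$per_cohort[[result$manifest$params$primary]]$surv
    surv_prob_of <- make_group_surv_prob(
      train_surv[train_surv$sample_id %in% result$split$train_ids, ],
      result$subtype_model$labels)
    t_star <- median(surv$time[surv$sample_id %in% names(labels)])
    out$report <- evaluate_cohort(
      labels = labels, surv = surv,
      score = setNames(pred$score, pred$sample_id)[keep],
      pred_surv_prob = surv_prob_of(labels, t_star), t_star = t_star,
      cohort_id = "new_cohort")
  } else {
    pct_log("predict", "no survival data supplied; labels only")
  }
  out
}
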