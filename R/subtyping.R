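## Subtype discovery by K-means.
##
## Training samples are clustered in the final PAS feature space for each
## candidate k in 2..6; three indices — mean silhouette width, the
## Calinski-Harabasz criterion, and the concordance index of a
## cluster-survival-rank risk score — each rank the candidate k values, and
## the k with the best mean rank wins (ties toward smaller k). Clusters are
## then named by survival: the best-surviving cluster is G1 (moderate), the
## worst is G2 (aggressive); intermediates, only possible for k > 2, are
## G1a, G1b, ... ordered by survival. PAS values are already bounded in
## [-1, 1], so clustering runs on raw (unstandardized) features with
## squared-Euclidean distance and 10 restarts.

## Calinski-Harabasz criterion: between-cluster over within-cluster
## dispersion, scaled by their degrees of freedom.
calinski_harabasz <- function(x, cl) {
  n <- nrow(x)
  k <- length(unique(cl))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(cl)) {
    xg <- x[cl == g, , drop = FALSE]
    cg <- colMeans(xg)
    w <- w + sum(sweep(xg, 2, cg)^2)
    b <- b + nrow(xg) * sum((cg - grand)^2)
  }
  if (w == 0) return(NA_real_)
  (b / (k - 1)) / (w / (n - k))
}

## Best-of-restarts K-means with explicit per-restart seeds so the
## best-objective contract is observable and the whole fit deterministic.
kmeans_restarts <- function(x, k, seed, nstart = 10) {
  seeds <- spawn_seeds(seed, nstart)
  best <- NULL
  objectives <- rep(NA_real_, nstart)
  for (r in seq_len(nstart)) {
    fit <- with_seed(seeds[r], tryCatch(
      kmeans(x, centers = k, nstart = 1, iter.max = 50),
      error = function(e) NULL))
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    objectives[r] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (!is.null(best)) attr(best, "restart_objectives") <- objectives
  best
}

## Risk score from cluster membership: clusters ranked by KM median
## survival, shorter median = higher risk (ties by cluster index).
cluster_risk_rank <- function(cl, time, event) {
  cl_ids <- sort(unique(cl))
  med <- vapply(cl_ids, function(g) km_median(time[cl == g], event[cl == g]),
                numeric(1))
  # rank 1 = best survival (lowest risk); larger rank = higher risk
  risk_of_cluster <- rank(-med, ties.method = "first")
  setNames(risk_of_cluster, cl_ids)[as.character(cl)]
}

#' Per-k clustering diagnostics
#'
#' For each candidate k, runs best-of-restarts K-means and computes the
#' mean silhouette width, the Calinski-Harabasz criterion and the
#' concordance index of the cluster-survival-rank risk score. A k whose
#' clustering degenerates (empty cluster in every restart, or undefined
#' silhouette on identical points) is flagged invalid.
#'
#' @param features PAS matrix restricted to the panel, features x samples.
#' @param surv survival data.frame covering the samples.
#' @param k_range candidate cluster counts (default 2:6).
#' @param seed integer seed.
#' @param nstart K-means restarts per k.
#' @return list: `table` (data.frame k/silhouette/ch/c_index/valid) and
#'   `fits` (the per-k kmeans objects).
#' @export
evaluate_k <- function(features, surv, k_range = 2:6, seed = 1L, nstart = 10) {
  x <- t(features)  # samples x features
  stopifnot(nrow(x) > max(k_range))
  idx <- match(rownames(x), surv$sample_id)
  if (anyNA(idx)) stop("survival table missing sample(s) present in features")
  surv <- surv[idx, , drop = FALSE]
  k_seeds <- spawn_seeds(seed, length(k_range))
  fits <- vector("list", length(k_range))
  tab <- data.frame(k = k_range, silhouette = NA_real_, ch = NA_real_,
                    c_index = NA_real_, valid = FALSE)
  d <- stats::dist(x)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmeans_restarts(x, k, seed = k_seeds[i], nstart = nstart)
    if (is.null(fit)) next
    sil <- tryCatch(
      mean(cluster::silhouette(fit$cluster, d)[, "sil_width"]),
      error = function(e) NA_real_)
    ch <- calinski_harabasz(x, fit$cluster)
    ci <- tryCatch(
      concordance_index(cluster_risk_rank(fit$cluster, surv$time, surv$event),
                        surv$time, surv$event),
      error = function(e) NA_real_)
    if (is.na(sil) || is.na(ch) || is.na(ci)) next
    fits[[i]] <- fit
    tab[i, c("silhouette", "ch", "c_index")] <- c(sil, ch, ci)
    tab$valid[i] <- TRUE
  }
  list(table = tab, fits = setNames(fits, paste0("k", k_range)))
}

#' Select the number of clusters from the diagnostics
#'
#' Each index (silhouette, Calinski-Harabasz, prognostic C-index; higher is
#' better for all three) ranks the valid k values; the k with the best
#' (smallest) mean rank wins, ties broken toward smaller k.
#'
#' @param diagnostics output of [evaluate_k()] (or its `table`).
#' @return the selected k (integer).
#' @export
select_k <- function(diagnostics) {
  tab <- if (is.data.frame(diagnostics)) diagnostics else diagnostics$table
  tab <- tab[tab$valid, , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid clustering for any candidate k")
  ranks <- cbind(rank(-tab$silhouette, ties.method = "average"),
                 rank(-tab$ch, ties.method = "average"),
                 rank(-tab$c_index, ties.method = "average"))
  mean_rank <- rowMeans(ranks)
  tab$k[order(mean_rank, tab$k)][1]
}

## Survival-ordered label set: best cluster G1, worst G2, intermediates G1a...
risk_label_names <- function(k) {
  if (k == 2) c("G1", "G2") else c("G1", paste0("G1", letters[seq_len(k - 2)]), "G2")
}

#' Fit the subtype model: choose k, cluster, and name clusters by survival
#'
#' Runs [evaluate_k()] and [select_k()], keeps the best-of-restarts
#' clustering at the chosen k, and maps cluster indices to risk labels by
#' Kaplan-Meier median survival: the best-surviving cluster is G1, the
#' worst is G2 (survival ties broken toward the smaller cluster index,
#' which then receives the better label).
#'
#' @inheritParams evaluate_k
#' @return a `subtype_model` list: k, centroids, panel (feature ids, in
#'   order), risk_label_map, labels (training samples), diagnostics, seed.
#' @export
fit_subtypes <- function(features, surv, k_range = 2:6, seed = 1L, nstart = 10) {
  diag_ <- evaluate_k(features, surv, k_range = k_range, seed = seed,
                      nstart = nstart)
  k <- select_k(diag_)
  fit <- diag_$fits[[paste0("k", k)]]
  idx <- match(colnames(features), surv$sample_id)
  surv_o <- surv[idx, , drop = FALSE]
  cl_ids <- sort(unique(fit$cluster))
  med <- vapply(cl_ids, function(g) {
    km_median(surv_o$time[fit$cluster == g], surv_o$event[fit$cluster == g])
  }, numeric(1))
  ord <- order(-med, cl_ids)  # best survival first; ties -> smaller index
  label_map <- setNames(risk_label_names(k)[match(cl_ids, cl_ids[ord])],
                        as.character(cl_ids))
  labels <- setNames(label_map[as.character(fit$cluster)], colnames(features))
  # contract: the aggressive cluster survives no longer than the moderate one
  stopifnot(med[ord][1] >= med[ord][k])
  model <- list(k = k, centroids = fit$centers,
                panel = rownames(features), risk_label_map = label_map,
                labels = labels, diagnostics = diag_$table, seed = seed)
  class(model) <- "subtype_model"
  model
}

#' Assign subtypes to new samples by nearest centroid
#'
#' @param model a `subtype_model`.
#' @param features PAS matrix of the new samples (features x samples) over
#'   the model's panel.
#' @return named character vector of risk labels.
#' @export
assign_subtype <- function(model, features) {
  stopifnot(inherits(model, "subtype_model"))
  miss <- setdiff(model$panel, rownames(features))
  if (length(miss) > 0) {
    stop("features missing panel entries: ", paste(head(miss, 5), collapse = ", "))
  }
  x <- t(features[model$panel, , drop = FALSE])
  d2 <- outer(rowSums(x^2), rep(1, nrow(model$centroids))) -
    2 * x %*% t(model$centroids) +
    outer(rep(1, nrow(x)), rowSums(model$centroids^2))
  nearest <- apply(d2, 1, which.min)  # ties -> lower cluster index
  setNames(unname(model$risk_label_map[as.character(nearest)]), rownames(x))
}
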