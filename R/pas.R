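## Pathway activity score (PAS).
##
## Each gene is dichotomized across the cohort at its median: samples
## strictly above the split score +1, all others (including ties at the
## split) score -1. A pathway's activity in a sample is the mean of that
## sample's gene scores over the pathway's genes present in the matrix, so
## every PAS lies in [-1, +1] with denominator equal to the gene count.
## Because only within-gene ranks enter, PAS is invariant under any
## strictly increasing per-gene transform — the property that lets RNA-seq
## and microarray cohorts be scored on a common footing (each cohort scored
## against its own medians, never merged).

#' Dichotomize one gene's expression across samples
#'
#' Samples with expression strictly greater than the split quantile
#' (default: median) score +1; all others, including ties at the split,
#' score -1. A constant row scores -1 everywhere (tie rule) with a warning.
#'
#' @param x numeric vector of one gene's expression over >= 2 samples.
#' @param split_quantile quantile defining the split point (default 0.5).
#' @return numeric vector of +1/-1 scores, same length and names as `x`.
#' @export
dichotomize_gene <- function(x, split_quantile = 0.5) {
  if (length(x) < 2) stop("dichotomization needs at least 2 samples")
  if (anyNA(x)) stop("dichotomization is undefined on missing values")
  cut <- if (split_quantile == 0.5) median(x) else
    stats::quantile(x, probs = split_quantile, names = FALSE)
  s <- ifelse(x > cut, 1, -1)
  if (all(s == -1) && length(unique(x)) == 1) {
    warning("constant expression row: all samples scored -1", call. = FALSE)
  }
  names(s) <- names(x)
  s
}

## All genes at once; rows of `expr` dichotomized independently.
dichotomize_matrix <- function(expr, split_quantile = 0.5) {
  cuts <- if (split_quantile == 0.5) apply(expr, 1, median) else
    apply(expr, 1, stats::quantile, probs = split_quantile, names = FALSE)
  s <- ifelse(expr > cuts, 1, -1)  # cuts recycles down columns (row-wise)
  dimnames(s) <- dimnames(expr)
  s
}

#' Pathway activity score of one gene set
#'
#' Per sample, the mean of its +1/-1 dichotomized scores over the set's
#' genes present in the matrix; genes absent from the matrix are dropped
#' and counted.
#'
#' @param expr expression matrix (genes x samples).
#' @param genes character vector of gene ids.
#' @param split_quantile split point passed to [dichotomize_gene()].
#' @return numeric vector over samples in [-1, +1], with attributes
#'   `n_present` and `n_absent`.
#' @export
compute_pas <- function(expr, genes, split_quantile = 0.5) {
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stop("no genes of the set are present in the expression matrix")
  }
  scores <- dichotomize_matrix(expr[present, , drop = FALSE], split_quantile)
  pas <- colMeans(scores)
  attr(pas, "n_present") <- length(present)
  attr(pas, "n_absent") <- length(setdiff(genes, present))
  pas
}

#' Pathway activity score matrix for a gene-set collection
#'
#' One row per gene set with at least one gene present in the matrix; sets
#' with zero present genes are dropped (counted in the `dropped_features`
#' attribute). Dichotomization is computed once per gene and reused across
#' all sets.
#'
#' @param expr expression matrix (genes x samples).
#' @param collection named list of gene id vectors.
#' @param split_quantile split point passed to [dichotomize_gene()].
#' @return numeric matrix (features x samples) in [-1, +1] with attributes
#'   `dropped_features` (character vector of dropped set ids) and
#'   `n_present` (named integer vector of per-feature present-gene counts).
#' @export
compute_pas_matrix <- function(expr, collection, split_quantile = 0.5) {
  stopifnot(length(collection) >= 1, !is.null(names(collection)))
  scores <- dichotomize_matrix(expr, split_quantile)
  present_list <- lapply(collection, intersect, y = rownames(expr))
  n_present <- vapply(present_list, length, integer(1))
  keep <- n_present > 0
  if (!any(keep)) {
    stop("no gene set has any gene present in the expression matrix")
  }
  dropped <- names(collection)[!keep]
  if (length(dropped) > 0) {
    pct_log("pas", sprintf("dropped %d gene set(s) with no present genes",
                           length(dropped)))
  }
  pas <- do.call(rbind, lapply(present_list[keep], function(g) {
    colMeans(scores[g, , drop = FALSE])
  }))
  rownames(pas) <- names(collection)[keep]
  colnames(pas) <- colnames(expr)
  attr(pas, "dropped_features") <- dropped
  attr(pas, "n_present") <- n_present[keep]
  pas
}

#' Write a PAS matrix as TSV with a JSON sidecar
#'
#' The sidecar records, per feature, the gene list scored and the count of
#' genes that were absent from the expression matrix.
#'
#' @param pas matrix from [compute_pas_matrix()].
#' @param collection the gene-set collection it was computed from.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @export
write_pas_matrix <- function(pas, collection, path) {
  df <- data.frame(feature_id = rownames(pas), pas, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- lapply(rownames(pas), function(f) {
    list(genes = as.list(collection[[f]]),
         n_present = unname(attr(pas, "n_present")[f]))
  })
  names(side) <- rownames(pas)
  jsonlite::write_json(list(features = side,
                            dropped = as.list(attr(pas, "dropped_features"))),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
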