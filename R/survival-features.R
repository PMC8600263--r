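## Survival-supervised feature screening.
##
## Each PAS feature is tested for marginal association with overall
## survival by a univariate Cox proportional-hazards fit with the feature
## as the single continuous covariate; the reported p-value is the fit's
## score (log-rank) test. Features are ranked, the top d = 100 are kept per
## cohort (sure independence screening), crosstalk sub-pathway features are
## re-tested and filtered at Benjamini-Hochberg FDR < 0.01, and the final
## panel is the intersection of the selections across training cohorts.

#' Rank PAS features by univariate Cox survival association
#'
#' Fits one proportional-hazards model per feature and sorts ascending by
#' the score-test p-value (ties broken by feature id for determinism).
#' Zero-variance features carry no information and are assigned p = 1;
#' non-convergent fits likewise get p = 1 with a flag, never an error.
#'
#' @param pas PAS matrix, features x samples.
#' @param surv survival data.frame with sample_id/time/event covering the
#'   PAS samples (matched by id, so row order is irrelevant).
#' @return data.frame (feature_id, coef, p_value, flag, rank) sorted by p.
#' @export
rank_by_survival <- function(pas, surv) {
  validate_survival(surv)
  idx <- match(colnames(pas), surv$sample_id)
  if (anyNA(idx)) {
    stop("survival table is missing sample(s): ",
         paste(head(colnames(pas)[is.na(idx)], 5), collapse = ", "))
  }
  surv <- surv[idx, , drop = FALSE]
  y <- survival::Surv(surv$time, surv$event)
  stats_list <- lapply(rownames(pas), function(f) {
    x <- pas[f, ]
    if (var(x) == 0) {
      return(data.frame(feature_id = f, coef = NA_real_, p_value = 1,
                        flag = "zero_variance", stringsAsFactors = FALSE))
    }
    fit <- tryCatch(survival::coxph(y ~ x),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || anyNA(coef(fit))) {
      return(data.frame(feature_id = f, coef = NA_real_, p_value = 1,
                        flag = "non_convergent", stringsAsFactors = FALSE))
    }
    sc <- summary(fit)$sctest
    data.frame(feature_id = f, coef = unname(coef(fit)[1]),
               p_value = unname(sc["pvalue"]), flag = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_list)
  out <- out[order(out$p_value, out$feature_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Sure independence screening: keep the top d features
#'
#' @param ranked data.frame from [rank_by_survival()] (sorted ascending by
#'   p, ties already broken lexicographically).
#' @param d screening threshold (default 100, the usual value for cohorts
#'   of a few hundred samples, well above n/log(n)).
#' @return character vector of the first `min(d, nrow)` feature ids.
#' @export
sis_screen <- function(ranked, d = 100) {
  stopifnot(is.data.frame(ranked), "feature_id" %in% colnames(ranked))
  head(ranked$feature_id, min(d, nrow(ranked)))
}

#' Attach Benjamini-Hochberg q-values to a Cox stats table
#'
#' @param stats data.frame with a `p_value` column (one cohort's features).
#' @return the data.frame with a `q_value` column added.
#' @export
add_fdr <- function(stats) {
  stats$q_value <- p.adjust(stats$p_value, method = "BH")
  stats
}

#' Filter features at an FDR threshold
#'
#' Benjamini-Hochberg step-up over the supplied p-values; features with
#' q < alpha pass, ordered by p-value (ties by id).
#'
#' @param stats data.frame with feature_id and p_value (e.g. from
#'   [rank_by_survival()]).
#' @param alpha FDR threshold (default 0.01).
#' @return character vector of passing feature ids (possibly empty).
#' @export
fdr_filter <- function(stats, alpha = 0.01) {
  if (nrow(stats) == 0) return(character(0))
  stats <- add_fdr(stats)
  pass <- stats[stats$q_value < alpha, , drop = FALSE]
  pass <- pass[order(pass$p_value, pass$feature_id), , drop = FALSE]
  pass$feature_id
}

#' Intersect per-cohort selections into the final feature panel
#'
#' @param per_cohort_selected list (>= 2) of feature-id vectors, each
#'   ordered by within-cohort significance.
#' @return character vector: the common features, ordered by mean rank
#'   across cohorts (ties by id).
#' @export
intersect_cohorts <- function(per_cohort_selected) {
  stopifnot(length(per_cohort_selected) >= 2)
  common <- Reduce(intersect, per_cohort_selected)
  if (length(common) == 0) {
    stop("no feature is selected in every cohort; consider a larger FDR alpha")
  }
  mean_rank <- vapply(common, function(f) {
    mean(vapply(per_cohort_selected, function(v) match(f, v), numeric(1)))
  }, numeric(1))
  common[order(mean_rank, common)]
}
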