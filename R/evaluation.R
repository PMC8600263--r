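## Prognostic evaluation metrics.
##
## Harrell's concordance index and the rank ROC-AUC are implemented
## directly with explicit tie rules (risk ties credited 0.5; pairs with
## tied follow-up times are not orderable and are excluded); Kaplan-Meier
## curves and the log-rank test are delegated to the survival package; the
## Brier score uses inverse-probability-of-censoring weighting with the
## censoring distribution estimated by Kaplan-Meier.

#' Harrell's concordance index
#'
#' Over all sample pairs whose survival ordering is determinable under
#' censoring (the shorter observed time carries an event; tied times are
#' excluded), the fraction in which the earlier-failing sample has the
#' higher risk, with risk ties counted 0.5.
#'
#' @param risk numeric risk score per sample (higher = worse prognosis).
#' @param time follow-up time per sample.
#' @param event event indicator (1 = death observed, 0 = censored).
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n, n >= 2)
  ti <- matrix(time, n, n)
  ei <- matrix(event, n, n)
  ri <- matrix(risk, n, n)
  usable <- ti < t(ti) & ei == 1  # sample i fails before sample j
  n_usable <- sum(usable)
  if (n_usable == 0) stop("no usable (orderable) pair for the concordance index")
  conc <- sum(usable & ri > t(ri)) + 0.5 * sum(usable & ri == t(ri))
  conc / n_usable
}

#' IPCW Brier score at a time horizon
#'
#' Mean squared difference between the predicted survival probability at
#' `t_star` and the observed survival status, weighted by the inverse
#' Kaplan-Meier estimate of the censoring distribution: samples dead by
#' `t_star` contribute `pred^2 / G(T-)`, samples still under observation
#' contribute `(1 - pred)^2 / G(t_star)`, samples censored before `t_star`
#' contribute through the weights only.
#'
#' @param pred predicted probability of surviving beyond `t_star`, per sample.
#' @param time,event observed follow-up and event indicator.
#' @param t_star evaluation horizon, within the follow-up range.
#' @return Brier score in [0, 1] (under correct weights).
#' @export
brier_score <- function(pred, time, event, t_star) {
  n <- length(pred)
  stopifnot(length(time) == n, length(event) == n)
  if (t_star <= 0 || t_star > max(time)) {
    stop("t_star must lie within the follow-up range (0, max(time)]")
  }
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G_right <- stepfun(cfit$time, c(1, cfit$surv))              # G(t)
  G_left <- stepfun(cfit$time, c(1, cfit$surv), right = TRUE) # G(t-)
  contrib <- numeric(n)
  dead_by <- time <= t_star & event == 1
  alive_at <- time > t_star
  if (any(dead_by)) {
    g <- G_left(time[dead_by])
    if (any(g <= 0)) stop("censoring survival estimate is zero at a required event time")
    contrib[dead_by] <- pred[dead_by]^2 / g
  }
  if (any(alive_at)) {
    g <- G_right(t_star)
    if (g <= 0) stop("censoring survival estimate is zero at t_star")
    contrib[alive_at] <- (1 - pred[alive_at])^2 / g
  }
  sum(contrib) / n
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for one group; starts at 1 and is non-increasing
#' and right-continuous.
#'
#' @param time,event follow-up and event indicator for the group.
#' @return data.frame (time, n_risk, n_event, surv) including the origin
#'   row (time 0, surv 1).
#' @export
km_curve <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             surv = c(1, fit$surv))
}

## Kaplan-Meier median survival; +Inf when the curve never reaches 0.5.
km_median <- function(time, event) {
  curve <- km_curve(time, event)
  below <- which(curve$surv <= 0.5)
  if (length(below) == 0) Inf else curve$time[below[1]]
}

#' Log-rank test between two or more groups
#'
#' @param groups per-sample group label (>= 2 non-empty groups).
#' @param time,event follow-up and event indicator.
#' @return list(chi2, p, df); p from the chi-square reference with
#'   `groups - 1` degrees of freedom.
#' @export
logrank_test <- function(groups, time, event) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("log-rank test needs at least 2 groups")
  if (any(tab == 0)) stop("log-rank test: empty group")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(tab) - 1
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = df, lower.tail = FALSE), df = df)
}

#' Rank-based ROC-AUC
#'
#' Probability that a positive sample's score outranks a negative's, with
#' ties credited 0.5 (the Mann-Whitney statistic).
#'
#' @param scores numeric score per sample (higher = more positive-like).
#' @param truth binary truth per sample (1/TRUE = positive).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, truth) {
  pos <- as.logical(truth == 1 | truth == TRUE)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("ROC-AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predicted subtype labels and risk scores on one cohort
#'
#' Bundles the prognostic metrics for a cohort: Harrell's C of the risk
#' score, IPCW Brier score at `t_star` (default: the cohort's median
#' follow-up) of the supplied survival-probability predictions, log-rank
#' test between the predicted groups, per-group Kaplan-Meier curves, and —
#' when reference labels are available — the ROC-AUC of the score against
#' them.
#'
#' @param labels per-sample predicted subtype (G1/G2, named by sample).
#' @param score per-sample continuous risk score (e.g. the classifier's
#'   G2-neighbor fraction); defaults to the binary G2 indicator.
#' @param surv survival data.frame aligned to the labels by sample_id.
#' @param pred_surv_prob optional predicted probability of surviving beyond
#'   `t_star` per sample; when NULL the Brier score is skipped.
#' @param t_star Brier horizon; default median follow-up time.
#' @param truth optional reference labels for the AUC (G2 = positive).
#' @param cohort_id identifier carried into the report.
#' @return an `evaluation_report` list.
#' @export
evaluate_cohort <- function(labels, surv, score = NULL,
                            pred_surv_prob = NULL, t_star = NULL,
                            truth = NULL, cohort_id = "cohort") {
  idx <- match(names(labels), surv$sample_id)
  if (anyNA(idx)) stop("survival table missing labelled sample(s)")
  surv <- surv[idx, , drop = FALSE]
  if (is.null(score)) score <- as.numeric(labels == "G2")
  if (is.null(t_star)) t_star <- median(surv$time)
  rep_ <- list(cohort_id = cohort_id,
               group_sizes = as.list(table(labels)),
               t_star = t_star)
  rep_$c_index <- concordance_index(score, surv$time, surv$event)
  rep_$logrank <- if (length(unique(labels)) >= 2) {
    logrank_test(labels, surv$time, surv$event)
  } else {
    list(chi2 = NA_real_, p = NA_real_, df = NA_integer_)
  }
  rep_$brier <- if (!is.null(pred_surv_prob)) {
    brier_score(pred_surv_prob, surv$time, surv$event, t_star)
  } else NA_real_
  rep_$auc <- if (!is.null(truth)) {
    roc_auc(score, truth[names(labels)] == "G2")
  } else NA_real_
  rep_$km_curves <- lapply(split(seq_along(labels), labels), function(i) {
    km_curve(surv$time[i], surv$event[i])
  })
  class(rep_) <- "evaluation_report"
  rep_
}
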