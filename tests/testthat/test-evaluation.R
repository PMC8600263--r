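test_that("concordance index handles the canonical extremes", {
  time <- c(10, 20, 30, 40)
  event <- rep(1, 4)
  expect_equal(concordance_index(c(4, 3, 2, 1), time, event), 1.0)
  expect_equal(concordance_index(c(1, 2, 3, 4), time, event), 0.0)
  expect_error(concordance_index(c(1, 2), c(5, 9), c(0, 1)), "usable")
})

test_that("concordance of the worked censored example equals pair enumeration", {
  time <- c(2, 4, 6, 8); event <- c(1, 1, 0, 1); risk <- c(4, 3, 2, 1)
  expect_equal(concordance_index(risk, time, event),
               oracle_cindex(risk, time, event))
  expect_equal(oracle_cindex(risk, time, event), 1.0)  # all 5 usable pairs agree
})

test_that("concordance matches the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    inst <- random_surv_instance(n)
    risk <- if (rep %% 3 == 0) sample(1:4, n, replace = TRUE) else inst$risk
    if (sum(inst$event[inst$time < max(inst$time)]) == 0) next
    expect_equal(concordance_index(risk, inst$time, inst$event),
                 oracle_cindex(risk, inst$time, inst$event))
  }
})

test_that("negating an untied risk score flips concordance to its complement", {
  set.seed(17)
  for (rep in 1:20) {
    inst <- random_surv_instance(15)
    c1 <- concordance_index(inst$risk, inst$time, inst$event)
    c2 <- concordance_index(-inst$risk, inst$time, inst$event)
    expect_equal(c1 + c2, 1)
  }
  # agreement with the survival package on continuous untied data
  inst <- random_surv_instance(40)
  ref <- survival::concordance(survival::Surv(inst$time, inst$event) ~ inst$risk,
                               reverse = TRUE)$concordance
  expect_equal(concordance_index(inst$risk, inst$time, inst$event), ref)
})

test_that("Brier score has its closed-form values without censoring", {
  time <- c(10, 20, 30, 40, 50, 60)
  event <- rep(1, 6)
  t_star <- 35
  perfect <- as.numeric(time > t_star)
  expect_equal(brier_score(perfect, time, event, t_star), 0)
  expect_equal(brier_score(rep(0.5, 6), time, event, t_star), 0.25)
  expect_error(brier_score(rep(0.5, 6), time, event, 1000), "follow-up")
})

test_that("IPCW Brier matches a hand-computed weighted sum with censoring", {
  time <- c(2, 3, 4, 5, 6, 7)
  event <- c(1, 1, 0, 1, 1, 1)
  pred <- c(0.2, 0.3, 0.6, 0.4, 0.8, 0.9)
  t_star <- 5
  # censoring KM: one censoring at t=4 with 4 at risk -> G = 0.75 from t=4 on
  hand <- (pred[1]^2 / 1 + pred[2]^2 / 1 + 0 +       # deaths at 2, 3; censored at 4
             pred[4]^2 / 0.75 +                      # death at 5, G(5-) = 0.75
             (1 - pred[5])^2 / 0.75 +                # alive past 5, G(5) = 0.75
             (1 - pred[6])^2 / 0.75) / 6
  expect_equal(brier_score(pred, time, event, t_star), hand)
})

test_that("the KM prediction never does worse than the coin-flip predictor", {
  set.seed(303)
  for (rep in 1:5) {
    n <- 500
    time <- rexp(n, 1 / 300)
    cens <- runif(n, 0, 900)
    obs <- pmin(time, cens)
    event <- as.integer(time <= cens)
    t_star <- median(obs)
    km <- km_curve(obs, event)
    s_hat <- km$surv[max(which(km$time <= t_star))]
    b_km <- brier_score(rep(s_hat, n), obs, event, t_star)
    b_half <- brier_score(rep(0.5, n), obs, event, t_star)
    expect_lte(b_km, b_half + 0.01)
  }
})

test_that("Kaplan-Meier curves follow the product-limit form", {
  flat <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(flat$surv == 1))

  steps <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(steps$surv, c(1, 2/3, 1/3, 0))

  # censoring after the last event adds no further drop
  b <- km_curve(c(1, 2, 3, 9), c(1, 1, 1, 0))
  expect_equal(b$surv[b$time == 9], b$surv[b$time == 3])

  # non-increasing, starts at 1, total drop <= 1
  set.seed(12)
  inst <- random_surv_instance(30)
  cv <- km_curve(inst$time, inst$event)
  expect_equal(cv$surv[1], 1)
  expect_true(all(diff(cv$surv) <= 1e-12))
  expect_lte(cv$surv[1] - min(cv$surv), 1)
})

test_that("log-rank handles the null identity and label symmetry", {
  time <- rep(c(5, 10, 15, 20), 2)
  event <- rep(c(1, 0, 1, 1), 2)
  groups <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(groups, time, event)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(8)
  inst <- random_surv_instance(16)
  g <- rep(c("A", "B"), 8)
  lr1 <- logrank_test(g, inst$time, inst$event)
  lr2 <- logrank_test(ifelse(g == "A", "B", "A"), inst$time, inst$event)
  expect_equal(lr1$chi2, lr2$chi2)

  expect_error(logrank_test(rep("A", 4), 1:4, rep(1, 4)), "2 groups")
})

test_that("log-rank chi-square equals the hand tabulation on small cases", {
  cases <- list(
    list(g = c("A", "A", "A", "B", "B", "B"),
         time = c(2, 5, 9, 3, 7, 11), event = c(1, 1, 0, 1, 1, 1)),
    list(g = c("A", "A", "B", "B", "A", "B", "A", "B"),
         time = c(1, 4, 2, 6, 8, 3, 9, 12), event = c(1, 0, 1, 1, 1, 1, 0, 1)))
  for (cs in cases) {
    expect_equal(logrank_test(cs$g, cs$time, cs$event)$chi2,
                 oracle_logrank_chi2(cs$g, cs$time, cs$event),
                 tolerance = 1e-10)
  }
})

test_that("log-rank p agrees with a permutation p within Monte-Carlo error", {
  set.seed(44)
  n <- 18
  time <- rexp(n, 1 / 50)
  event <- rbinom(n, 1, 0.8)
  g <- rep(c("A", "B"), each = n / 2)
  obs <- logrank_test(g, time, event)$chi2
  B <- 2000
  perm <- vapply(seq_len(B), function(b) {
    logrank_test(sample(g), time, event)$chi2
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  p_asym <- logrank_test(g, time, event)$p
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_perm - p_asym), mc_err + 0.05)
})

test_that("rank AUC matches exhaustive pair enumeration, ties at half credit", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  scores <- c(0.9, 0.8, 0.4, 0.4, 0.2)
  truth <- c(1, 1, 0, 1, 0)
  expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth))
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
  }
  # near-chance for independent scores at large n
  set.seed(5)
  s <- rnorm(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.05)
})

test_that("cohort evaluation bundles the metrics coherently", {
  set.seed(61)
  n <- 80
  truth <- sample(c("G1", "G2"), n, replace = TRUE, prob = c(0.6, 0.4))
  time <- rexp(n, ifelse(truth == "G2", 3, 1) / 500)
  surv <- data.frame(sample_id = paste0("s", 1:n), time = time,
                     event = rbinom(n, 1, 0.8))
  labels <- setNames(truth, surv$sample_id)
  rep_ <- evaluate_cohort(labels, surv, truth = labels, cohort_id = "demo")
  expect_s3_class(rep_, "evaluation_report")
  expect_gt(rep_$c_index, 0.5)
  expect_lt(rep_$logrank$p, 0.05)
  expect_equal(rep_$auc, 1)  # score is the G2 indicator, truth the labels
  expect_named(rep_$km_curves, c("G1", "G2"))
  expect_equal(rep_$t_star, median(surv$time))
})
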