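# Two well-separated PAS-like blobs with distinct hazards.
blob_features <- function(n1 = 60, n2 = 40, p = 6, sep = 1.2, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(p * n1, -sep / 2, 0.15), p),
             matrix(rnorm(p * n2, sep / 2, 0.15), p))
  x <- pmax(pmin(x, 1), -1)
  dimnames(x) <- list(paste0("f", 1:p), paste0("s", seq_len(n1 + n2)))
  truth <- rep(c("low", "high"), c(n1, n2))
  time <- rexp(n1 + n2, rate = ifelse(truth == "high", 3, 1) / 1000)
  surv <- data.frame(sample_id = colnames(x), time = time,
                     event = rbinom(n1 + n2, 1, 0.8))
  list(x = x, surv = surv, truth = setNames(truth, colnames(x)))
}

test_that("diagnostics favor k = 2 on two separated prognostic blobs", {
  bl <- blob_features(seed = 10)
  diag_ <- evaluate_k(bl$x, bl$surv, seed = 42)
  tab <- diag_$table
  expect_true(all(tab$valid))
  expect_equal(tab$k[which.max(tab$silhouette)], 2)
  expect_equal(select_k(diag_), 2)
  # same seed twice: identical diagnostics
  diag2 <- evaluate_k(bl$x, bl$surv, seed = 42)
  expect_identical(diag_$table, diag2$table)
})

test_that("degenerate identical points invalidate every k", {
  x <- matrix(0.5, 4, 30, dimnames = list(paste0("f", 1:4), paste0("s", 1:30)))
  surv <- data.frame(sample_id = colnames(x), time = 1:30,
                     event = rep(1, 30))
  diag_ <- evaluate_k(x, surv, k_range = 2:4, seed = 1)
  expect_false(any(diag_$table$valid))
  expect_error(select_k(diag_), "no valid clustering")
})

test_that("k selection aggregates the three indices by mean rank", {
  # unanimity
  d1 <- data.frame(k = 2:4, silhouette = c(0.8, 0.5, 0.3), ch = c(90, 60, 40),
                   c_index = c(0.7, 0.6, 0.55), valid = TRUE)
  expect_equal(select_k(d1), 2)
  # k=2 wins two indices, k=3 wins one -> mean ranks 1.33 vs 1.67
  d2 <- data.frame(k = 2:3, silhouette = c(0.8, 0.5), ch = c(90, 60),
                   c_index = c(0.55, 0.7), valid = TRUE)
  expect_equal(select_k(d2), 2)
  # exact rank tie -> smaller k
  d3 <- data.frame(k = 2:3, silhouette = c(0.8, 0.5), ch = c(60, 90),
                   c_index = c(0.6, 0.6), valid = TRUE)
  expect_equal(select_k(d3), 2)
  # invalid k is never selected even if its indices look best
  d4 <- data.frame(k = 2:3, silhouette = c(0.5, 0.9), ch = c(50, 99),
                   c_index = c(0.6, 0.9), valid = c(TRUE, FALSE))
  expect_equal(select_k(d4), 2)
})

test_that("the Calinski-Harabasz criterion agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(11)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
  km <- kmeans(x, 2, nstart = 5)
  ours <- pascrosstalk:::calinski_harabasz(x, km$cluster)
  ref <- vegan::cascadeKM(x, 2, 2)$results["calinski", 1]
  expect_equal(ours, unname(ref), tolerance = 1e-6)
})

test_that("the kept clustering is the best of its restarts", {
  bl <- blob_features(seed = 3)
  fit <- pascrosstalk:::kmeans_restarts(t(bl$x), 3, seed = 9, nstart = 10)
  objs <- attr(fit, "restart_objectives")
  expect_true(all(fit$tot.withinss <= objs[!is.na(objs)] + 1e-9))
})

test_that("clusters are named by survival: worst becomes G2", {
  bl <- blob_features(seed = 21)
  model <- fit_subtypes(bl$x, bl$surv, seed = 5)
  expect_equal(model$k, 2)
  expect_setequal(unique(model$labels), c("G1", "G2"))
  # the planted high-hazard blob is the aggressive subtype
  expect_gt(mean(model$labels[bl$truth == "high"] == "G2"), 0.9)
  # KM median survival of G2 never exceeds G1's (fit contract)
  idx <- match(names(model$labels), bl$surv$sample_id)
  med <- vapply(split(idx, unname(model$labels)), function(i) {
    pascrosstalk:::km_median(bl$surv$time[i], bl$surv$event[i])
  }, numeric(1))
  expect_lte(med[["G2"]], med[["G1"]])
  # full determinism
  model2 <- fit_subtypes(bl$x, bl$surv, seed = 5)
  expect_identical(model$centroids, model2$centroids)
  expect_identical(model$labels, model2$labels)
})

test_that("risk labels depend only on survival, not on cluster indexing", {
  # relabeling clusters must not change G1/G2: rerun with permuted features
  # (k-means may index clusters differently) and compare sample labels
  bl <- blob_features(seed = 31)
  m1 <- fit_subtypes(bl$x, bl$surv, seed = 2)
  m2 <- fit_subtypes(bl$x[rev(seq_len(nrow(bl$x))), ], bl$surv, seed = 8)
  expect_gt(mean(m1$labels[names(m2$labels)] == m2$labels), 0.95)
})

test_that("subtype recovery holds across seeded replicates", {
  skip_if_not_installed("mclust")
  ok <- vapply(1:10, function(r) {
    bl <- blob_features(seed = 100 + r)
    model <- fit_subtypes(bl$x, bl$surv, seed = r)
    ari <- mclust::adjustedRandIndex(model$labels[names(bl$truth)], bl$truth)
    g2_is_high <- mean(model$labels[bl$truth == "high"] == "G2") > 0.5
    ari >= 0.8 && g2_is_high
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("nearest-centroid assignment is consistent and breaks ties low", {
  centroids <- rbind(c(-0.5, -0.5), c(0.5, 0.5))
  model <- structure(list(k = 2, centroids = centroids,
                          panel = c("f1", "f2"),
                          risk_label_map = c(`1` = "G1", `2` = "G2")),
                     class = "subtype_model")
  feats <- matrix(c(-0.4, -0.6, 0.45, 0.5, 0, 0, -0.5, -0.5),
                  nrow = 2, dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  lab <- assign_subtype(model, feats)
  expect_equal(unname(lab), c("G1", "G2", "G1", "G1"))
  # s3 is equidistant -> lower cluster index wins; s4 sits on centroid 1
})
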