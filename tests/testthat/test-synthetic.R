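test_that("gene-set generator places exact overlaps between designated pairs", {
  cfg <- simulation_config(n_genes = 40, n_pathways = 2, genes_per_pathway = 10,
                           overlap_genes = 4, n_prognostic_pathways = 0)
  gs <- generate_gene_sets(cfg)
  expect_length(intersect(gs[[1]], gs[[2]]), 4)
  expect_length(union(gs[[1]], gs[[2]]), 16)

  cfg0 <- simulation_config(n_genes = 60, n_pathways = 4, genes_per_pathway = 10,
                            overlap_genes = 0, n_prognostic_pathways = 0)
  gs0 <- generate_gene_sets(cfg0)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_length(intersect(gs0[[i]], gs0[[j]]), 0)
  }

  cfg_full <- simulation_config(n_genes = 20, n_pathways = 2,
                                genes_per_pathway = 10, overlap_genes = 10,
                                n_prognostic_pathways = 0)
  gs_full <- generate_gene_sets(cfg_full)
  expect_setequal(gs_full[[1]], gs_full[[2]])

  expect_error(generate_gene_sets(
    simulation_config(n_genes = 10, n_pathways = 3, genes_per_pathway = 10,
                      overlap_genes = 0, n_prognostic_pathways = 0)), "budget")
})

test_that("non-designated pairs stay disjoint under the default layout", {
  cfg <- simulation_config(seed = 3)
  gs <- generate_gene_sets(cfg)
  for (i in seq_len(length(gs) - 1)) {
    for (j in seq(i + 1, length(gs))) {
      designated <- (j == i + 1) && (i %% 2 == 1)
      expected <- if (designated) cfg$overlap_genes else 0
      expect_length(intersect(gs[[i]], gs[[j]]), expected)
    }
  }
})

test_that("the same seed reproduces a cohort bit for bit", {
  cfg <- simulation_config(n_samples = 50, seed = 11, platform = "microarray_like")
  gs <- generate_gene_sets(cfg)
  a <- generate_cohort(cfg, gs)
  b <- generate_cohort(cfg, gs)
  expect_identical(a$expr, b$expr)
  expect_identical(a$surv, b$surv)
  expect_identical(a$true_labels, b$true_labels)
})

test_that("realized censoring tracks the target within 5 points for n >= 300", {
  for (target in c(0.2, 0.3, 0.5)) {
    realized <- vapply(1:5, function(r) {
      cfg <- simulation_config(n_samples = 400, censoring_rate = target,
                               seed = 5 + r)
      co <- generate_cohort(cfg, generate_gene_sets(cfg))
      mean(co$surv$event == 0)
    }, numeric(1))
    # each cohort within the documented +-5 point band up to binomial noise;
    # the replicate mean pins the calibration itself well inside it
    expect_lt(abs(mean(realized) - target), 0.05)
    expect_lt(max(abs(realized - target)), 0.05 + 2 * sqrt(target * (1 - target) / 400))
  }
})

test_that("subtype prevalence and survival contrast match the planted model", {
  cfg <- simulation_config(n_samples = 400, hazard_ratio = 3,
                           censoring_rate = 0.3, seed = 21)
  co <- generate_cohort(cfg, generate_gene_sets(cfg))
  prev <- mean(co$true_labels == "G2")
  # binomial sampling error around the target prevalence
  expect_lt(abs(prev - cfg$subtype_prevalence), 4 * sqrt(0.4 * 0.6 / 400))

  # closed-form exponential medians: baseline_scale*log(2) for G1, /3 for G2
  g1 <- co$true_labels == "G1"
  km_med <- function(keep) {
    fit <- survival::survfit(survival::Surv(co$surv$time[keep],
                                            co$surv$event[keep]) ~ 1)
    unname(summary(fit)$table["median"])
  }
  m1 <- km_med(g1); m2 <- km_med(!g1)
  expect_lt(m2, m1)
  expect_lt(abs(m1 - cfg$baseline_scale * log(2)) / (cfg$baseline_scale * log(2)), 0.25)
  expect_lt(abs(m2 - cfg$baseline_scale * log(2) / 3) / (cfg$baseline_scale * log(2) / 3), 0.25)
})

test_that("with no planted effect the true labels carry no survival signal", {
  ps <- vapply(1:20, function(r) {
    cfg <- simulation_config(n_samples = 120, hazard_ratio = 1, effect_size = 0,
                             n_genes = 60, n_pathways = 2, genes_per_pathway = 10,
                             overlap_genes = 0, n_prognostic_pathways = 0,
                             seed = 100 + r)
    co <- generate_cohort(cfg, generate_gene_sets(cfg))
    logrank_test(co$true_labels, co$surv$time, co$surv$event)$p
  }, numeric(1))
  # p-values behave like a uniform sample, not like a signal
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("multi-cohort studies share the gene universe with per-cohort samples", {
  study <- small_study(seed = 9, n_samples = c(120, 50, 50, 80))
  expect_length(study$cohorts, 4)
  expect_equal(vapply(study$cohorts, function(co) ncol(co$expr), numeric(1)),
               c(cohort01 = 120, cohort02 = 50, cohort03 = 50, cohort04 = 80))
  genes <- rownames(study$cohorts[[1]]$expr)
  for (co in study$cohorts[-1]) expect_identical(rownames(co$expr), genes)
})

test_that("survival p-value rankings of pathway scores agree across platforms", {
  # same latent prognostic structure, different platforms -> positively
  # correlated feature rankings (checked over 20 replicates)
  rhos <- vapply(1:20, function(r) {
    study <- small_study(seed = 500 + r, n_samples = c(150, 150))
    ps <- lapply(study$cohorts, function(co) {
      pas <- compute_pas_matrix(co$expr, study$gene_sets)
      st <- rank_by_survival(pas, co$surv)
      st$p_value[match(names(study$gene_sets), st$feature_id)]
    })
    cor(ps[[1]], ps[[2]], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.8)
})
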