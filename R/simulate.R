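## Multi-cohort synthetic study generator.
##
## Emulates the structure of a multi-platform colorectal-cancer study: one
## large RNA-seq-like discovery cohort plus several smaller microarray-like
## validation cohorts, all sharing a gene universe and a gene-set collection
## with controlled pairwise overlap. Two prognostic subtypes (G1 moderate,
## G2 aggressive) are planted: genes of designated "prognostic" pathways are
## mean-shifted in G2, and G2 carries a proportional excess hazard. Every
## stage of the pipeline can therefore be scored against known truth.

#' Build a validated simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' tests and analyses: cohorts of a few hundred samples, 20 gene sets of 20
#' genes with designated consecutive pairs sharing 8 genes, 4 prognostic
#' pathways (two overlapping pairs), a 1.5 SD expression shift and a hazard
#' ratio of 3 for the aggressive subtype, exponential event times on a
#' 1000-day scale and 30% uniform administrative censoring.
#'
#' @param n_samples samples in the cohort.
#' @param n_genes genes in the shared universe (pathway members plus
#'   background noise genes).
#' @param n_pathways number of gene sets.
#' @param genes_per_pathway genes per set.
#' @param overlap_genes genes shared by each designated consecutive pair
#'   (1,2), (3,4), ...; other pairs are disjoint.
#' @param n_prognostic_pathways leading pathways whose genes are shifted in G2.
#' @param effect_size G2 mean shift of prognostic-pathway genes, in
#'   within-gene SD units.
#' @param hazard_ratio G2 vs G1 proportional hazard (> 0).
#' @param baseline_scale mean G1 event time, days (exponential scale).
#' @param censoring_rate target censored fraction in [0, 1).
#' @param subtype_prevalence fraction of G2 samples in (0, 1).
#' @param platform "rnaseq_like" (latent Gaussian log-scale values emitted
#'   directly) or "microarray_like" (gene-specific strictly increasing
#'   nonlinear transform of the same latent values).
#' @param seed integer seed; same seed, same cohort, bit for bit.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_samples = 500, n_genes = 500, n_pathways = 20,
                              genes_per_pathway = 20, overlap_genes = 8,
                              n_prognostic_pathways = 4, effect_size = 1.5,
                              hazard_ratio = 3, baseline_scale = 1000,
                              censoring_rate = 0.3, subtype_prevalence = 0.4,
                              platform = c("rnaseq_like", "microarray_like"),
                              seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(n_samples >= 2, n_genes >= 1, n_pathways >= 1,
            genes_per_pathway >= 1, overlap_genes >= 0,
            n_prognostic_pathways >= 0, n_prognostic_pathways <= n_pathways,
            hazard_ratio > 0, baseline_scale > 0,
            censoring_rate >= 0, censoring_rate < 1)
  if (overlap_genes > genes_per_pathway) {
    stop("overlap_genes must not exceed genes_per_pathway")
  }
  if (subtype_prevalence <= 0 || subtype_prevalence >= 1) {
    stop("subtype_prevalence must lie strictly between 0 and 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 overlap_genes = as.integer(overlap_genes),
                 n_prognostic_pathways = as.integer(n_prognostic_pathways),
                 effect_size = effect_size, hazard_ratio = hazard_ratio,
                 baseline_scale = baseline_scale,
                 censoring_rate = censoring_rate,
                 subtype_prevalence = subtype_prevalence,
                 platform = platform, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a gene-set collection with controlled pairwise overlap
#'
#' Pathways are laid out over the gene universe so that each designated
#' consecutive pair (1,2), (3,4), ... shares exactly `overlap_genes` genes
#' while every other pair is disjoint — exercising the crosstalk
#' decomposition with known ground truth.
#'
#' @param config a [simulation_config()].
#' @return named list of gene id vectors (GMT-compatible collection).
#' @export
generate_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$n_pathways
  gpp <- config$genes_per_pathway
  ov <- config$overlap_genes
  n_pairs <- np %/% 2L
  needed <- np * gpp - n_pairs * ov
  if (needed > config$n_genes) {
    stop(sprintf("gene budget insufficient: %d pathway genes needed, %d available",
                 needed, config$n_genes))
  }
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  sets <- vector("list", np)
  cursor <- 0L
  for (i in seq_len(np)) {
    paired_second <- (i %% 2L == 0L)  # second member of a designated pair
    if (paired_second && ov > 0) {
      shared <- sets[[i - 1L]][seq_len(ov)]
      fresh_n <- gpp - ov
      fresh <- if (fresh_n > 0) genes[cursor + seq_len(fresh_n)] else character(0)
      cursor <- cursor + fresh_n
      sets[[i]] <- c(shared, fresh)
    } else {
      sets[[i]] <- genes[cursor + seq_len(gpp)]
      cursor <- cursor + gpp
    }
  }
  names(sets) <- sprintf("PW%03d", seq_len(np))
  attr(sets, "description") <- setNames(
    ifelse(seq_len(np) <= config$n_prognostic_pathways,
           "synthetic prognostic pathway", "synthetic background pathway"),
    names(sets))
  sets
}

## Solve the uniform-censoring horizon c so that P(C < T) hits the target,
## where T is the prevalence mixture of Exponential(rate) event times and
## C ~ Uniform(0, c):  P(C < T | rate) = (1 - exp(-rate * c)) / (rate * c).
censoring_horizon <- function(rates, weights, target) {
  p_cens <- function(cmax) {
    sum(weights * (1 - exp(-rates * cmax)) / (rates * cmax))
  }
  lo <- 1e-6; hi <- 1
  while (p_cens(hi) > target && hi < 1e12) hi <- hi * 10
  uniroot(function(c) p_cens(c) - target, c(lo, hi), tol = 1e-10)$root
}

#' Generate one synthetic cohort with planted prognostic subtypes
#'
#' Subtype labels are Bernoulli(`subtype_prevalence`); genes of the first
#' `n_prognostic_pathways` gene sets are shifted by `effect_size` SD units
#' in G2, all other genes are i.i.d. standard normal; event times are
#' exponential with the G2 hazard multiplied by `hazard_ratio`; censoring is
#' uniform administrative censoring with its horizon solved numerically to
#' hit `censoring_rate`. Microarray-like cohorts pass every gene through a
#' gene-specific strictly increasing map `a*sinh(b*x) + c` (a, b > 0), under
#' which rank-based pathway scores are provably invariant.
#'
#' @param config a [simulation_config()].
#' @param gene_sets collection from [generate_gene_sets()] (or a compatible
#'   named list over the same gene universe).
#' @return a `synthetic_cohort` list: `expr` (genes x samples matrix),
#'   `surv` (data.frame sample_id/time/event), `true_labels` (named G1/G2
#'   vector), `config`.
#' @export
generate_cohort <- function(config, gene_sets) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    samples <- sprintf("S%04d", seq_len(n))

    labels <- ifelse(rbinom(n, 1, config$subtype_prevalence) == 1, "G2", "G1")
    names(labels) <- samples

    latent <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes,
                     dimnames = list(genes, samples))
    prog_idx <- seq_len(min(config$n_prognostic_pathways, length(gene_sets)))
    prog_genes <- unique(unlist(gene_sets[prog_idx], use.names = FALSE))
    prog_genes <- intersect(prog_genes, genes)
    if (length(prog_genes) > 0 && config$effect_size != 0) {
      latent[prog_genes, labels == "G2"] <-
        latent[prog_genes, labels == "G2"] + config$effect_size
    }

    rate <- (1 / config$baseline_scale) *
      ifelse(labels == "G2", config$hazard_ratio, 1)
    event_time <- rexp(n, rate = rate)
    if (config$censoring_rate > 0) {
      pi2 <- config$subtype_prevalence
      cmax <- censoring_horizon(
        rates = c(1, config$hazard_ratio) / config$baseline_scale,
        weights = c(1 - pi2, pi2), target = config$censoring_rate)
      cens_time <- runif(n, 0, cmax)
    } else {
      cens_time <- rep(Inf, n)
    }
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)

    expr <- latent
    if (config$platform == "microarray_like") {
      a <- rlnorm(config$n_genes, meanlog = 0, sdlog = 0.3)
      b <- rlnorm(config$n_genes, meanlog = 0, sdlog = 0.3)
      cc <- rnorm(config$n_genes, mean = 8, sd = 1)
      expr <- a * sinh(b * latent) + cc  # strictly increasing per gene
      dimnames(expr) <- dimnames(latent)
    }

    structure(list(
      expr = expr,
      surv = data.frame(sample_id = samples, time = time, event = event,
                        stringsAsFactors = FALSE),
      true_labels = labels,
      config = config), class = "synthetic_cohort")
  })
}

#' Generate a shared-gene-space multi-cohort study
#'
#' All cohorts share the gene universe and gene-set collection of the first
#' configuration (pathway layout parameters must agree) but draw independent
#' samples and, for microarray-like cohorts, independent per-gene platform
#' transforms.
#'
#' @param config_list list of [simulation_config()] objects, one per cohort.
#' @return list with `cohorts` (list of `synthetic_cohort`) and `gene_sets`.
#' @export
generate_multi_cohort_study <- function(config_list) {
  stopifnot(length(config_list) >= 1,
            all(vapply(config_list, inherits, logical(1), "sim_config")))
  ref <- config_list[[1]]
  for (cfg in config_list[-1]) {
    same <- cfg$n_genes == ref$n_genes && cfg$n_pathways == ref$n_pathways &&
      cfg$genes_per_pathway == ref$genes_per_pathway &&
      cfg$overlap_genes == ref$overlap_genes &&
      cfg$n_prognostic_pathways == ref$n_prognostic_pathways
    if (!same) stop("all cohorts must share the same pathway layout parameters")
  }
  gene_sets <- generate_gene_sets(ref)
  cohorts <- lapply(config_list, generate_cohort, gene_sets = gene_sets)
  names(cohorts) <- sprintf("cohort%02d", seq_along(cohorts))
  list(cohorts = cohorts, gene_sets = gene_sets)
}

#' Configurations for the default four-cohort study
#'
#' One RNA-seq-like discovery cohort of 500 samples plus three
#' microarray-like validation cohorts of 60, 60 and 200 samples, emulating
#' a large sequencing cohort validated in small array cohorts.
#'
#' @param seed master seed; per-cohort seeds are spawned from it.
#' @param n_samples per-cohort sample counts.
#' @param hazard_ratio,effect_size,censoring_rate planted-signal parameters
#'   shared by all cohorts.
#' @param ... further arguments passed to every [simulation_config()].
#' @return list of `sim_config`, ready for [generate_multi_cohort_study()].
#' @export
default_study_configs <- function(seed, n_samples = c(500, 60, 60, 200),
                                  hazard_ratio = 3, effect_size = 1.5,
                                  censoring_rate = 0.3, ...) {
  seeds <- spawn_seeds(seed, length(n_samples))
  platforms <- c("rnaseq_like", rep("microarray_like", length(n_samples) - 1))
  lapply(seq_along(n_samples), function(i) {
    simulation_config(n_samples = n_samples[i], platform = platforms[i],
                      hazard_ratio = hazard_ratio, effect_size = effect_size,
                      censoring_rate = censoring_rate, seed = seeds[i], ...)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits expression TSV, survival TSV and truth-label TSV under `dir` with
#' the given prefix; gene sets are written separately with [write_gmt()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_expression.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_survival.tsv"))
  p3 <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_expression(cohort$expr, p1)
  write_survival(cohort$surv, p2)
  write.table(data.frame(sample_id = names(cohort$true_labels),
                         true_label = unname(cohort$true_labels)),
              p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
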