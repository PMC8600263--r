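# Independent brute-force oracles and tiny fixture builders.
# These re-derive expected values from first principles (explicit loops,
# hand tabulation) and deliberately share no code with the package.

# Harrell's C by exhaustive pair enumeration: a pair is usable when the
# shorter observed time carries an event and the times differ; concordant
# when the earlier-failing sample has the higher risk; risk ties 0.5.
oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (time[i] == time[j]) next
      first <- if (time[i] < time[j]) i else j
      other <- if (first == i) j else i
      if (event[first] != 1) next
      den <- den + 1
      if (risk[first] > risk[other]) num <- num + 1
      else if (risk[first] == risk[other]) num <- num + 0.5
    }
  }
  num / den
}

# Mann-Whitney AUC by exhaustive pair enumeration (ties 0.5).
oracle_auc <- function(scores, truth) {
  pos <- which(truth == 1)
  neg <- which(truth != 1)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Two-group log-rank chi-square by hand tabulation of observed-minus-
# expected events over the distinct event times.
oracle_logrank_chi2 <- function(group, time, event) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  ev_times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d_t * n1 / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  (O1 - E1)^2 / V
}

# 3-gene x 4-sample fixture from the worked PAS example:
# per-gene scores (-1,-1,+1,+1), (+1,+1,-1,-1), (-1,-1,+1,+1).
pas_fixture_expr <- function() {
  m <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(4, 3, 2, 1),
             g3 = c(1, 1, 4, 4))
  colnames(m) <- paste0("s", 1:4)
  m
}

# Random strictly increasing per-gene map of the microarray kind.
random_monotone_transform <- function(expr) {
  a <- exp(rnorm(nrow(expr), 0, 0.4))
  b <- exp(rnorm(nrow(expr), 0, 0.4))
  cc <- rnorm(nrow(expr), 5, 2)
  out <- a * sinh(b * expr) + cc
  dimnames(out) <- dimnames(expr)
  out
}

# Strip non-structural attributes so matrices compare on values alone.
bare_matrix <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# Small random survival data with controllable censoring.
random_surv_instance <- function(n, cens_frac = 0.3) {
  time <- round(rexp(n, 1 / 100), 3)
  event <- as.integer(runif(n) > cens_frac)
  list(time = time, event = event, risk = rnorm(n))
}

# Small two-cohort study for fast pipeline tests.
small_study <- function(seed, n_samples = c(200, 60, 60), ...) {
  cfgs <- default_study_configs(seed = seed, n_samples = n_samples, ...)
  generate_multi_cohort_study(cfgs)
}
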