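# Shared fixtures: the five-category ovarian tumour type example
# (1 benign, 2 borderline, 3 stage I invasive, 4 stage II-IV invasive,
# 5 metastatic) with its reported pairwise evidence.

iota_counts <- c(2557, 186, 176, 467, 120)

iota_r2 <- c("2,1" = 0.116, "3,1" = 0.179, "4,1" = 0.497, "5,1" = 0.170,
             "3,2" = 0.185, "4,2" = 0.499, "5,2" = 0.374, "4,3" = 0.328,
             "5,3" = 0.129, "5,4" = 0.210)

iota_cstat <- c("2,1" = 0.85, "3,1" = 0.92, "4,1" = 0.99, "5,1" = 0.95,
                "3,2" = 0.75, "4,2" = 0.95, "5,2" = 0.87, "4,3" = 0.87,
                "5,3" = 0.71, "5,4" = 0.82)

# published whole-cohort pairwise sizes (computed from unrounded simulated
# R-squared values, so only reproducible to ~1% from the 3-d.p. inputs)
iota_published_grid <- data.frame(
  k = c(2L, 3L, 4L, 5L, 3L, 4L, 5L, 4L, 5L, 5L),
  r = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
  n_published = c(1574, 982, 246, 1067, 7147, 1128, 3629, 2045, 13063, 3813)
)

iota_dist <- function() outcome_distribution(iota_counts)

iota_resolved <- function() {
  resolve_evidence(pairwise_evidence(5, r2 = iota_r2), iota_dist())
}

# random outcome distribution generator for property-style tests
random_dist <- function(K = sample(2:6, 1), max_count = 500) {
  outcome_distribution(sample(seq_len(max_count), K, replace = TRUE))
}

# numeric-integration oracle for the true per-individual Cox-Snell R2 of a
# single-covariate logistic model whose linear predictor is normal within
# groups (unit variance, mean separation sqrt(2) * qnorm(C)); the Bayes
# posterior log-odds is then exactly linear in the predictor, so the
# logistic model is correctly specified and the large-sample R2 follows
# from the expected log-likelihoods.
true_r2_for_cstat <- function(c_statistic, phi) {
  mu <- sqrt(2) * qnorm(c_statistic)
  logit0 <- log(phi / (1 - phi))
  p1 <- function(x) plogis(logit0 + mu * x - mu^2 / 2)
  e_model <- phi * integrate(function(x) dnorm(x, mu) * log(p1(x)),
                             -10, 10 + mu)$value +
    (1 - phi) * integrate(function(x) dnorm(x, 0) * log(1 - p1(x)),
                          -10, 10 + mu)$value
  e_null <- phi * log(phi) + (1 - phi) * log(1 - phi)
  1 - exp(-2 * (e_model - e_null))
}

# small, quick-to-calibrate simulation design used across tests
toy_design <- function(K = 3, Q = 2) {
  beta <- matrix(c(0.6, 0.4, -0.5, 0.5), 2, 2)[seq_len(Q), seq_len(K - 1),
                                               drop = FALSE]
  simulation_design(K, Q, beta, target_proportions = c(0.5, 0.3, 0.2)[seq_len(K)] /
                      sum(c(0.5, 0.3, 0.2)[seq_len(K)]))
}
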