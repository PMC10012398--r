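#' Convert a pairwise C-statistic to an anticipated Cox-Snell R-squared
#'
#' Simulation-based conversion of a C-statistic (AUC) plus the pairwise
#' outcome fraction into the Cox-Snell R-squared of the corresponding
#' one-vs-one logistic model. The construction assumes the model's linear
#' predictor is normally distributed within each outcome group with common
#' unit variance; a C-statistic `C` then corresponds to a mean separation
#' of `sqrt(2) * qnorm(C)` between the event and non-event groups (the
#' location and common scale are immaterial to the R-squared). Each
#' replicate simulates `sim_size` individuals, refits a single-covariate
#' logistic regression of outcome on the linear predictor by maximum
#' likelihood, and computes `R2_CS = 1 - exp(-LR / sim_size)` from its
#' likelihood-ratio statistic. The reported estimate is the mean over
#' replicates, with the Monte-Carlo standard error retained.
#'
#' @param c_statistic C-statistic in \[0.5, 1). Exactly 0.5 (no
#'   discrimination) is allowed but warns: the conversion returns a value
#'   near zero.
#' @param phi pairwise outcome fraction (proportion of the pair subset with
#'   the 'event' category), in (0, 1).
#' @param sim_size simulated individuals per replicate. Values below 1e5
#'   warn, as the Monte-Carlo error becomes visible at the third decimal.
#' @param n_replicates number of replicates averaged.
#' @param seed integer seed; the result is reproducible bit-identically for
#'   a fixed seed, `sim_size` and `n_replicates`. `NULL` uses the current
#'   RNG state.
#' @param sampling `"fixed"` (default) allocates exactly
#'   `round(phi * sim_size)` events per replicate, which removes the
#'   binomial variation in the group sizes; `"bernoulli"` draws each
#'   individual's group independently.
#' @param max_retries retries (with fresh draws) should the logistic fit
#'   fail to converge before erroring.
#'
#' @return An object of class `cstat_r2`: a list with `estimate` (mean
#'   R-squared over replicates), `se` (Monte-Carlo standard error of the
#'   mean), `replicates`, and the echoed inputs.
#' @examples
#' r2_from_cstat(0.85, 0.068, sim_size = 1e4, n_replicates = 2, seed = 1)
#' @seealso [resolve_evidence()] for the batch route used during sizing.
#' @export
r2_from_cstat <- function(c_statistic, phi, sim_size = 1e6, n_replicates = 10,
                          seed = NULL, sampling = c("fixed", "bernoulli"),
                          max_retries = 5) {
  sampling <- match.arg(sampling)
  if (!is.numeric(c_statistic) || length(c_statistic) != 1L ||
      c_statistic < 0.5 || c_statistic >= 1)
    stop("`c_statistic` must be a single value in [0.5, 1)")
  if (c_statistic == 0.5)
    warning("`c_statistic` = 0.5 implies no discrimination; the converted ",
            "R-squared is approximately 0")
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1)
    stop("`phi` must be a single value in (0, 1)")
  if (!is.numeric(sim_size) || length(sim_size) != 1L || sim_size < 100)
    stop("`sim_size` must be at least 100")
  sim_size <- as.integer(round(sim_size))
  if (sim_size < 1e5)
    warning("`sim_size` below 1e5: the Monte-Carlo error may be visible at ",
            "the third decimal of the converted R-squared")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L || n_replicates < 1)
    stop("`n_replicates` must be a positive integer")
  n_replicates <- as.integer(n_replicates)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)

  mu <- sqrt(2) * stats::qnorm(c_statistic)
  reps <- numeric(n_replicates)
  for (rep in seq_len(n_replicates)) {
    value <- NA_real_
    for (attempt in seq_len(max_retries)) {
      if (sampling == "fixed") {
        n1 <- max(1L, min(sim_size - 1L, as.integer(round(phi * sim_size))))
      } else {
        n1 <- sum(stats::rbinom(sim_size, 1L, phi))
        if (n1 == 0L || n1 == sim_size) next
      }
      n0 <- sim_size - n1
      y <- rep(c(1, 0), c(n1, n0))
      lp <- c(stats::rnorm(n1, mean = mu), stats::rnorm(n0, mean = 0))
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, lp), y, family = stats::binomial(),
                       control = stats::glm.control(maxit = 50))
      )
      if (!fit$converged) next
      ll_model <- -fit$deviance / 2
      ll_null <- n1 * log(n1 / sim_size) + n0 * log(n0 / sim_size)
      lr <- 2 * (ll_model - ll_null)
      value <- 1 - exp(-lr / sim_size)
      break
    }
    if (is.na(value))
      stop(sprintf("logistic refit failed to converge after %d attempts (replicate %d)",
                   max_retries, rep))
    reps[rep] <- value
  }
  structure(
    list(estimate = mean(reps),
         se = if (n_replicates > 1) stats::sd(reps) / sqrt(n_replicates) else NA_real_,
         replicates = reps,
         c_statistic = c_statistic, phi = phi, sim_size = sim_size,
         n_replicates = n_replicates, sampling = sampling),
    class = "cstat_r2"
  )
}

#' @export
print.cstat_r2 <- function(x, ...) {
  cat(sprintf("C-statistic %.3f with outcome fraction %.3f -> Cox-Snell R2 = %.4f",
              x$c_statistic, x$phi, x$estimate))
  if (!is.na(x$se))
    cat(sprintf(" (MC se %.2g over %d replicates of %s)",
                x$se, x$n_replicates, format(x$sim_size, big.mark = ",")))
  cat("\n")
  invisible(x)
}

#' Batch C-statistic to R-squared conversion
#'
#' Applies [r2_from_cstat()] to a table of pairs, deriving per-pair
#' sub-seeds from a single seed.
#'
#' @param pairs data frame with columns `k`, `r`, `c_statistic` and `phi`.
#' @inheritParams r2_from_cstat
#' @return the input with columns `r2` and `r2_se` appended.
#' @export
r2_from_cstat_grid <- function(pairs, sim_size = 1e6, n_replicates = 10,
                               seed = NULL, sampling = c("fixed", "bernoulli")) {
  sampling <- match.arg(sampling)
  if (!is.data.frame(pairs) ||
      !all(c("k", "r", "c_statistic", "phi") %in% names(pairs)))
    stop("`pairs` needs columns k, r, c_statistic, phi")
  if (!is.null(seed)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(pairs))
  } else {
    sub_seeds <- rep(NA_integer_, nrow(pairs))
  }
  pairs$r2 <- NA_real_
  pairs$r2_se <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    conv <- r2_from_cstat(pairs$c_statistic[i], pairs$phi[i],
                          sim_size = sim_size, n_replicates = n_replicates,
                          seed = if (is.na(sub_seeds[i])) NULL else sub_seeds[i],
                          sampling = sampling)
    pairs$r2[i] <- conv$estimate
    pairs$r2_se[i] <- conv$se
  }
  pairs
}
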