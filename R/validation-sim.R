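#' Data-generating design for the shrinkage validation experiment
#'
#' Specifies a multinomial logistic data-generating process with `Q`
#' independent standard-normal covariates and sub-model coefficient
#' columns `beta[, k - 1]` for categories `k = 2..K` against reference
#' category 1. Intercepts are calibrated (see [calibrate_intercepts()]) so
#' the marginal category proportions match `target_proportions`.
#'
#' @param K number of outcome categories (>= 2).
#' @param Q number of covariates (each enters one coefficient per
#'   sub-model).
#' @param beta `Q x (K - 1)` coefficient matrix (sub-models 2..K vs
#'   reference 1).
#' @param target_proportions length-`K` positive vector of marginal
#'   category probabilities (normalised to sum to 1).
#' @param n_val_mult validation-set size as a multiple of the development
#'   size in [run_shrinkage_experiment()].
#' @return an object of class `simulation_design` (uncalibrated:
#'   `intercepts` is `NULL` until [calibrate_intercepts()] is run).
#' @examples
#' simulation_design(3, 2, matrix(c(0.5, 0.3, -0.4, 0.2), 2, 2),
#'                   c(0.5, 0.3, 0.2))
#' @export
simulation_design <- function(K, Q, beta, target_proportions,
                              n_val_mult = 100) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K))
    stop("`K` must be a single integer >= 2")
  if (!is.numeric(Q) || length(Q) != 1L || Q < 1 || Q != round(Q))
    stop("`Q` must be a single positive integer")
  beta <- as.matrix(beta)
  if (nrow(beta) != Q || ncol(beta) != K - 1)
    stop(sprintf("`beta` must be a %d x %d matrix (covariates x sub-models)",
                 Q, K - 1))
  tp <- as.numeric(target_proportions)
  if (length(tp) != K || any(tp <= 0))
    stop("`target_proportions` must be a positive vector of length K")
  tp <- tp / sum(tp)
  structure(list(K = as.integer(K), Q = as.integer(Q), beta = beta,
                 targets = tp, n_val_mult = n_val_mult,
                 intercepts = NULL, calibration = NULL),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("Multinomial simulation design: K = %d, Q = %d\n", x$K, x$Q))
  cat("  target proportions:", paste(round(x$targets, 3), collapse = " "), "\n")
  if (is.null(x$intercepts)) cat("  intercepts: not yet calibrated\n")
  else cat("  intercepts:", paste(round(x$intercepts, 4), collapse = " "), "\n")
  invisible(x)
}

softmax_probs <- function(x, intercepts, beta) {
  eta <- cbind(0, sweep(x %*% beta, 2, intercepts, "+"))
  p <- exp(eta - apply(eta, 1, max))
  p / rowSums(p)
}

#' Calibrate design intercepts to the target proportions
#'
#' Solves for the sub-model intercepts so that the marginal category
#' probabilities of the design match its targets. With all coefficients
#' zero the solution is closed-form, `log(p_k / p_1)`. Otherwise the
#' expected marginal probabilities are evaluated on a fixed calibration
#' sample of covariates and the intercepts iterated by the standard
#' marginal-matching update `a_k <- a_k + log(target_k / current_k)`,
#' which is deterministic given the seed.
#'
#' @param design a [simulation_design()].
#' @param n_cal calibration sample size.
#' @param tol required maximum absolute deviation of the achieved marginal
#'   proportions from the targets.
#' @param max_iter iteration cap (error on non-convergence).
#' @param seed seed for the calibration covariate sample.
#' @return the design with `intercepts` and a `calibration` record filled
#'   in.
#' @export
calibrate_intercepts <- function(design, n_cal = 1e6, tol = 0.002,
                                 max_iter = 100, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  targets <- design$targets
  if (all(design$beta == 0)) {
    design$intercepts <- log(targets[-1] / targets[1])
    design$calibration <- list(method = "closed_form", achieved = targets,
                               n_cal = NA_integer_, seed = NA_integer_)
    return(design)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  x <- matrix(stats::rnorm(n_cal * design$Q), n_cal, design$Q)
  a <- log(targets[-1] / targets[1])
  achieved <- NULL
  for (it in seq_len(max_iter)) {
    achieved <- colMeans(softmax_probs(x, a, design$beta))
    if (max(abs(achieved - targets)) < tol / 5) break
    a <- a + log(targets[-1] / achieved[-1])
  }
  if (max(abs(achieved - targets)) >= tol)
    stop(sprintf("intercept calibration did not reach tolerance %.3g in %d iterations",
                 tol, max_iter))
  design$intercepts <- a
  design$calibration <- list(method = "marginal_matching", achieved = achieved,
                             n_cal = n_cal, seed = seed, iterations = it)
  design
}

#' Simulate a dataset from a calibrated design
#'
#' Draws `n` independent standard-normal covariate vectors and samples
#' each outcome category from the multinomial model probabilities (which
#' sum to one for every individual by construction). Reproducible for a
#' fixed seed.
#'
#' @param design a calibrated [simulation_design()].
#' @param n number of individuals.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a list with `x` (`n x Q` covariate matrix) and `y` (integer
#'   outcome categories in `1..K`).
#' @export
simulate_multinomial_data <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(design$intercepts))
    stop("calibrate the design first with calibrate_intercepts()")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  x <- matrix(stats::rnorm(n * design$Q), n, design$Q)
  p <- softmax_probs(x, design$intercepts, design$beta)
  cp <- p
  for (k in seq_len(design$K - 1) + 1L) cp[, k] <- cp[, k - 1L] + p[, k]
  y <- 1L + rowSums(stats::runif(n) > cp[, -design$K, drop = FALSE])
  list(x = x, y = as.integer(y))
}

# log-likelihood of a multinomial model with full coefficient matrix
# b_full: (Q + 1) x K, first row intercepts, reference column all zero.
mnl_loglik <- function(b_full, x, y) {
  eta <- cbind(1, x) %*% b_full
  sum(eta[cbind(seq_along(y), y)]) - sum(log(rowSums(exp(eta))))
}

#' Fit a multinomial logistic regression by maximum likelihood
#'
#' Thin wrapper around [nnet::multinom()] with tight convergence settings,
#' returning the full coefficient matrix (reference category 1 as a zero
#' column), the model and null log-likelihoods and the likelihood-ratio
#' statistic, plus flags for non-convergence and (quasi-)separation
#' detected via diverging coefficients.
#'
#' @param x `n x Q` covariate matrix.
#' @param y integer outcome categories; all `K` categories must be
#'   present.
#' @param K number of categories (defaults to `max(y)`).
#' @param maxit optimiser iteration cap.
#' @param coef_limit absolute slope size beyond which the fit is flagged
#'   as separated.
#' @return an object of class `mnl_fit`: list with `coef`
#'   (`(Q + 1) x K` full matrix, row 1 = intercepts), `lnL_model`,
#'   `lnL_null`, `LR`, `converged`, `flagged`, `reason`, `counts`, `n`,
#'   `K`, `Q`.
#' @export
fit_multinomial <- function(x, y, K = max(y), maxit = 500, coef_limit = 15) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("`x` and `y` lengths differ")
  counts <- tabulate(y, nbins = K)
  if (any(counts == 0))
    stop("all K categories must be present in the data (missing: ",
         paste(which(counts == 0), collapse = ", "), ")")
  n <- length(y)
  df <- data.frame(.y = factor(y, levels = seq_len(K)), x)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = maxit,
                        reltol = 1e-12, MaxNWts = 10000)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(NULL, names(cf)))
  b_full <- cbind(0, t(cf))  # (Q + 1) x K
  lnl_model <- as.numeric(stats::logLik(fit))
  lnl_null <- sum(counts * log(counts / n))
  lr <- 2 * (lnl_model - lnl_null)
  converged <- isTRUE(fit$convergence == 0)
  separated <- max(abs(b_full[-1, ])) > coef_limit
  reason <- if (!converged) "non-convergence"
            else if (separated) "separation (diverging coefficients)"
            else NA_character_
  structure(
    list(coef = b_full, lnL_model = lnl_model, lnL_null = lnl_null,
         LR = lr, converged = converged,
         flagged = !converged || separated, reason = reason,
         counts = counts, n = n, K = K, Q = ncol(x)),
    class = "mnl_fit"
  )
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat(sprintf("Multinomial fit: K = %d, Q = %d, n = %d | lnL = %.2f, LR = %.2f%s\n",
              x$K, x$Q, x$n, x$lnL_model, x$LR,
              if (x$flagged) paste0(" [flagged: ", x$reason, "]") else ""))
  invisible(x)
}

#' Heuristic shrinkage factor of a multinomial model
#'
#' The van Houwelingen--Le Cessie heuristic applied to the whole
#' multinomial model: `1 - (K - 1) * Q / LR`, where `LR` is the model's
#' likelihood-ratio statistic and `(K - 1) * Q` its total slope parameter
#' count. May be negative for very weak fits (returned as-is with a
#' warning); undefined at `LR = 0`.
#'
#' @param LR likelihood-ratio statistic (> 0).
#' @param K number of outcome categories.
#' @param Q candidate predictor parameters per sub-model.
#' @return the heuristic shrinkage factor (<= 1).
#' @export
heuristic_shrinkage <- function(LR, K, Q) {
  if (!is.numeric(LR) || length(LR) != 1L || LR < 0)
    stop("`LR` must be a single non-negative number")
  if (LR == 0) stop("heuristic shrinkage is undefined at LR = 0")
  s <- 1 - (K - 1) * Q / LR
  if (s < 0)
    warning(sprintf("heuristic shrinkage is negative (%.3f): LR is smaller than the parameter count", s))
  s
}

# linear predictor of sub-model k vs reference r (slopes only, no intercept)
pair_lp <- function(b_full, x, k, r) {
  as.vector(x %*% (b_full[-1, k] - b_full[-1, r]))
}

#' Sub-model shrinkage factors by multinomial recalibration
#'
#' Estimates the Van Hoorde-style sub-model shrinkage factors of a
#' developed multinomial model on validation data: with reference category
#' `r`, the `2(K - 1)`-parameter recalibration model
#' `ln P(Y = k) / P(Y = r) = a_k + s_k * LP_k` (one free intercept and one
#' slope per sub-model, each slope multiplying only its own developed
#' linear predictor) is fitted by maximum likelihood, and the fitted
#' slopes `s_k` are the shrinkage estimates. The recalibration likelihood
#' is concave; it is maximised by BFGS with an analytic gradient.
#'
#' @param fit an [fit_multinomial()] object from the development data (or
#'   a bare `(Q + 1) x K` full coefficient matrix).
#' @param x_val,y_val validation covariates and outcomes (all categories
#'   present).
#' @param reference reference category `r`.
#' @param reltol convergence tolerance of the optimiser.
#' @return an object of class `recalibration_fit`: named slope vector
#'   `slopes` (names = sub-model categories `k != r`), `intercepts`,
#'   `reference`, `logLik` and `converged`.
#' @export
submodel_shrinkage <- function(fit, x_val, y_val, reference = 1,
                               reltol = 1e-10) {
  b_full <- if (inherits(fit, "mnl_fit")) fit$coef else as.matrix(fit)
  K <- ncol(b_full)
  x_val <- as.matrix(x_val)
  y_val <- as.integer(y_val)
  if (any(tabulate(y_val, nbins = K) == 0))
    stop("all K categories must be present in the validation data")
  r <- as.integer(reference)
  if (r < 1 || r > K) stop("invalid reference category")
  ks <- setdiff(seq_len(K), r)
  lp <- vapply(ks, function(k) pair_lp(b_full, x_val, k, r),
               numeric(nrow(x_val)))
  yi <- match(y_val, c(r, ks))  # 1 = reference
  m <- K - 1L
  yind <- cbind(seq_along(yi), yi)
  nll <- function(par) {
    eta <- cbind(0, sweep(lp %*% diag(par[(m + 1):(2 * m)], m), 2,
                          par[1:m], "+"))
    -(sum(eta[yind]) - sum(log(rowSums(exp(eta)))))
  }
  gr <- function(par) {
    eta <- cbind(0, sweep(lp %*% diag(par[(m + 1):(2 * m)], m), 2,
                          par[1:m], "+"))
    p <- exp(eta - apply(eta, 1, max))
    p <- p / rowSums(p)
    d <- p[, -1, drop = FALSE] - outer(yi, seq_len(m) + 1L, "==")
    c(colSums(d), colSums(d * lp))
  }
  opt <- stats::optim(c(rep(0, m), rep(1, m)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = reltol))
  structure(
    list(slopes = stats::setNames(opt$par[(m + 1):(2 * m)], ks),
         intercepts = stats::setNames(opt$par[1:m], ks),
         reference = r, logLik = -opt$value,
         converged = opt$convergence == 0),
    class = "recalibration_fit"
  )
}

#' @export
print.recalibration_fit <- function(x, ...) {
  cat(sprintf("Multinomial recalibration (reference %d)%s\n", x$reference,
              if (!x$converged) " [did not converge]" else ""))
  print(round(rbind(intercept = x$intercepts, slope = x$slopes), 4))
  invisible(x)
}

#' Distinct-logistic (one-vs-one) calibration slope
#'
#' Calibration slope of a developed pair linear predictor on the
#' validation subset with outcomes in `{k, r}`: a two-parameter logistic
#' regression (intercept + slope) of `I(Y = k)` on
#' `LP = x (beta_k - beta_r)`.
#'
#' @inheritParams submodel_shrinkage
#' @param k,r the outcome pair.
#' @return the fitted slope (scalar), or `NA` with a warning if the subset
#'   is one-sided or the fit fails.
#' @export
distinct_logistic_shrinkage <- function(fit, x_val, y_val, k, r) {
  b_full <- if (inherits(fit, "mnl_fit")) fit$coef else as.matrix(fit)
  x_val <- as.matrix(x_val)
  y_val <- as.integer(y_val)
  idx <- y_val %in% c(k, r)
  yy <- y_val[idx] == k
  if (!any(yy) || all(yy)) {
    warning(sprintf("validation subset for pair {%d,%d} is one-sided", k, r))
    return(NA_real_)
  }
  lp <- pair_lp(b_full, x_val[idx, , drop = FALSE], k, r)
  g <- suppressWarnings(
    stats::glm.fit(cbind(1, lp), as.numeric(yy), family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
  if (!g$converged) {
    warning(sprintf("calibration-slope fit for pair {%d,%d} did not converge", k, r))
    return(NA_real_)
  }
  unname(g$coefficients[2])
}

#' Shrinkage validation experiment
#'
#' Empirical check that the pairwise shrinkage criterion delivers the
#' targeted sub-model calibration slopes. The experiment:
#' \enumerate{
#'   \item calibrates the design intercepts;
#'   \item estimates the 'true' pairwise Cox-Snell R-squared values from a
#'     single large pilot sample (one-vs-one logistic fits on the pair
#'     subsets);
#'   \item sizes the development set with [criterion_shrinkage()] at
#'     `S_target`;
#'   \item over `n_sims` replicates, fits the multinomial model on a fresh
#'     development sample of that size, and estimates on an independent
#'     large validation sample the recalibration sub-model slopes
#'     `S_MN[k, r]` (every reference category), the distinct-logistic
#'     slopes `S_DL[k, r]` (pairs `k > r`) and the heuristic factor
#'     `S_VH_MN`.
#' }
#' Replicates flagged for separation or non-convergence are excluded and
#' counted, never retried with new data (retrying would bias the shrinkage
#' summaries). All randomness derives from the single `seed`.
#'
#' @param design a [simulation_design()] (calibrated or not).
#' @param S_target targeted shrinkage, default 0.9.
#' @param n_sims number of replicates.
#' @param pilot_n pilot sample size for the true pairwise R-squared.
#' @param n_val_mult validation size multiplier (times the development
#'   size); defaults to the design's.
#' @param seed master seed; replicate sub-seeds are derived
#'   deterministically.
#' @param rounding rounding policy passed to the sizing step.
#' @param tolerance half-width of the acceptance band around `S_target`
#'   for the headline median check.
#' @return An object of class `shrinkage_experiment`: the sizing result
#'   (`criterion`, `n_dev`), `pilot_r2`, per-replicate long table
#'   `shrinkage` (columns `replicate`, `quantity` in
#'   `{"S_MN", "S_DL"}`, `k`, `r`, `value`), heuristic factors `s_vh`,
#'   the per-pair `summary` and `agreement` tables, the exclusion count
#'   and the headline flag `target_met`.
#' @examples
#' \donttest{
#' des <- simulation_design(3, 2, matrix(c(0.6, 0.4, -0.5, 0.5), 2, 2),
#'                          c(0.5, 0.3, 0.2))
#' ex <- run_shrinkage_experiment(des, n_sims = 10, pilot_n = 5e4, seed = 7)
#' ex$summary
#' }
#' @export
run_shrinkage_experiment <- function(design, S_target = 0.9, n_sims = 200,
                                     pilot_n = 1e6,
                                     n_val_mult = design$n_val_mult,
                                     seed = 1,
                                     rounding = c("ceiling", "nearest"),
                                     tolerance = 0.05) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(design, "simulation_design"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_sims + 2L),
                  ncol = 2L + 2L * n_sims)
  cal_seed <- seeds[1]; pilot_seed <- seeds[2]
  dev_seeds <- seeds[2L + seq_len(n_sims)]
  val_seeds <- seeds[2L + n_sims + seq_len(n_sims)]
  K <- design$K; Q <- design$Q

  if (is.null(design$intercepts))
    design <- calibrate_intercepts(design, seed = cal_seed)

  # pilot: 'true' pairwise R2 from one-vs-one fits at large n
  pilot <- simulate_multinomial_data(design, pilot_n, seed = pilot_seed)
  grid <- pair_grid(K)
  pilot_r2 <- data.frame(grid, r2 = NA_real_, provenance = "pilot_simulation")
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; r <- grid$r[i]
    idx <- pilot$y %in% c(k, r)
    yy <- as.numeric(pilot$y[idx] == k)
    g <- suppressWarnings(
      stats::glm.fit(cbind(1, pilot$x[idx, , drop = FALSE]), yy,
                     family = stats::binomial()))
    m_pair <- sum(idx)
    ll0 <- sum(yy) * log(mean(yy)) + sum(1 - yy) * log(1 - mean(yy))
    lr <- 2 * (-g$deviance / 2 - ll0)
    pilot_r2$r2[i] <- 1 - exp(-lr / m_pair)
  }

  weak <- pilot_r2$r2 < 1e-4
  if (any(weak))
    stop("pilot pairwise R-squared is approximately zero for pairs ",
         paste(sprintf("{%d,%d}", pilot_r2$k[weak], pilot_r2$r[weak]),
               collapse = ", "),
         ": a no-effect design cannot be sized for shrinkage")

  dist <- suppressWarnings(
    outcome_distribution(proportions = design$targets, n = pilot_n))
  crit <- criterion_shrinkage(dist, pilot_r2, Q = Q, S_target = S_target,
                              rounding = rounding)
  n_dev <- crit$n
  n_val <- n_val_mult * n_dev

  rows <- list()
  s_vh <- rep(NA_real_, n_sims)
  excluded <- character()
  for (s in seq_len(n_sims)) {
    dev <- simulate_multinomial_data(design, n_dev, seed = dev_seeds[s])
    if (any(tabulate(dev$y, nbins = K) == 0)) {
      excluded <- c(excluded, sprintf("replicate %d: empty category", s))
      next
    }
    fit <- fit_multinomial(dev$x, dev$y, K = K)
    if (fit$flagged) {
      excluded <- c(excluded, sprintf("replicate %d: %s", s, fit$reason))
      next
    }
    val <- simulate_multinomial_data(design, n_val, seed = val_seeds[s])
    bad <- FALSE
    for (r in seq_len(K)) {
      recal <- submodel_shrinkage(fit, val$x, val$y, reference = r)
      if (!recal$converged) { bad <- TRUE; break }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = s, quantity = "S_MN",
        k = as.integer(names(recal$slopes)), r = r,
        value = unname(recal$slopes))
    }
    if (bad) {
      excluded <- c(excluded, sprintf("replicate %d: recalibration non-convergence", s))
      next
    }
    for (i in seq_len(nrow(grid))) {
      sdl <- distinct_logistic_shrinkage(fit, val$x, val$y,
                                         grid$k[i], grid$r[i])
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = s, quantity = "S_DL", k = grid$k[i], r = grid$r[i],
        value = sdl)
    }
    s_vh[s] <- heuristic_shrinkage(fit$LR, K, Q)
  }
  shrinkage <- do.call(rbind, rows)

  qsum <- function(sub) {
    data.frame(n = nrow(sub), mean = mean(sub$value),
               median = stats::median(sub$value),
               q25 = unname(stats::quantile(sub$value, 0.25)),
               q75 = unname(stats::quantile(sub$value, 0.75)))
  }
  summ <- do.call(rbind, lapply(split(
    shrinkage[shrinkage$quantity == "S_MN", ],
    interaction(shrinkage$k[shrinkage$quantity == "S_MN"],
                shrinkage$r[shrinkage$quantity == "S_MN"], drop = TRUE)),
    function(sub) cbind(sub[1, c("k", "r")], qsum(sub))))
  rownames(summ) <- NULL
  summ <- summ[order(summ$r, summ$k), , drop = FALSE]

  agree <- NULL
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; r <- grid$r[i]
    smn <- shrinkage[shrinkage$quantity == "S_MN" & shrinkage$k == k &
                       shrinkage$r == r, c("replicate", "value")]
    sdl <- shrinkage[shrinkage$quantity == "S_DL" & shrinkage$k == k &
                       shrinkage$r == r, c("replicate", "value")]
    mg <- merge(smn, sdl, by = "replicate", suffixes = c("_mn", "_dl"))
    mg <- mg[stats::complete.cases(mg), , drop = FALSE]
    agree <- rbind(agree, data.frame(
      k = k, r = r,
      median_S_DL = stats::median(mg$value_dl),
      median_S_MN = stats::median(mg$value_mn),
      median_abs_diff = stats::median(abs(mg$value_dl - mg$value_mn))))
  }

  target_met <- all(summ$median >= S_target - tolerance &
                      summ$median <= S_target + tolerance)

  structure(
    list(design = design, S_target = S_target, n_sims = n_sims,
         n_dev = n_dev, n_val = n_val, pilot_n = pilot_n,
         pilot_r2 = pilot_r2, criterion = crit,
         shrinkage = shrinkage, s_vh = s_vh,
         summary = summ, agreement = agree,
         n_excluded = length(excluded), exclusions = excluded,
         target_met = target_met, tolerance = tolerance, seed = seed),
    class = "shrinkage_experiment"
  )
}

#' @export
print.shrinkage_experiment <- function(x, ...) {
  cat(sprintf("Shrinkage validation experiment: K = %d, Q = %d, S_target = %.2f\n",
              x$design$K, x$design$Q, x$S_target))
  cat(sprintf("  development n = %s (criterion (i), pilot R2 at n = %s), validation n = %s\n",
              format(x$n_dev, big.mark = ","),
              format(x$pilot_n, big.mark = ","),
              format(x$n_val, big.mark = ",")))
  cat(sprintf("  %d replicates, %d excluded\n\n",
              x$n_sims, x$n_excluded))
  cat("Sub-model recalibration slopes S_MN[k, reference r]:\n")
  print(transform(x$summary, mean = round(mean, 3), median = round(median, 3),
                  q25 = round(q25, 3), q75 = round(q75, 3)),
        row.names = FALSE)
  cat("\nDistinct-logistic vs sub-model slope agreement (pairs k > r):\n")
  print(transform(x$agreement, median_S_DL = round(median_S_DL, 3),
                  median_S_MN = round(median_S_MN, 3),
                  median_abs_diff = round(median_abs_diff, 3)),
        row.names = FALSE)
  cat(sprintf("\nHeuristic S_VH_MN: median %.3f\n",
              stats::median(x$s_vh, na.rm = TRUE)))
  cat(sprintf("Headline check (all median S_MN within %.2f +/- %.2f): %s\n",
              x$S_target, x$tolerance, if (x$target_met) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
plot.shrinkage_experiment <- function(x, ...) {
  smn <- x$shrinkage[x$shrinkage$quantity == "S_MN", ]
  lab <- sprintf("S[%d|ref %d]", smn$k, smn$r)
  graphics::boxplot(smn$value ~ lab, xlab = "sub-model (k | reference r)",
                    ylab = "recalibration slope",
                    main = sprintf("Sub-model shrinkage at criterion-(i) n = %d",
                                   x$n_dev), ...)
  graphics::abline(h = x$S_target, lty = 2)
  invisible(x)
}
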