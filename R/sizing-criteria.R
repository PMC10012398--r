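#' Sample size to target a given shrinkage factor in a logistic model
#'
#' Number of individuals required so that the expected heuristic
#' (van Houwelingen--Le Cessie) shrinkage factor of a logistic regression
#' with `Q` candidate predictor parameters and anticipated adjusted
#' Cox-Snell R-squared `r2_adj` equals the target `S`:
#' `m = Q / ((S - 1) * log(1 - r2_adj / S))`.
#'
#' Returned unrounded; callers apply the rounding policy at the final step.
#' Strictly increasing in `Q` and in `S`, strictly decreasing in `r2_adj`.
#'
#' @param Q number of candidate predictor parameters (>= 1).
#' @param S targeted shrinkage factor in (0, 1), commonly 0.9.
#' @param r2_adj anticipated optimism-adjusted Cox-Snell R-squared in
#'   (0, 1); must satisfy `r2_adj < S`, otherwise the target is
#'   unattainable at any sample size.
#' @return required number of individuals (unrounded).
#' @examples
#' binary_shrinkage_size(17, 0.9, 0.497)  # about 211.6
#' @export
binary_shrinkage_size <- function(Q, S, r2_adj) {
  if (!is.numeric(Q) || any(Q < 1)) stop("`Q` must be >= 1")
  if (!is.numeric(S) || any(S <= 0) || any(S >= 1))
    stop("`S` must lie in (0, 1)")
  if (!is.numeric(r2_adj) || any(r2_adj <= 0) || any(r2_adj >= 1))
    stop("`r2_adj` must lie in (0, 1)")
  if (any(r2_adj >= S))
    stop(sprintf("targeted shrinkage S = %s is unattainable: the anticipated R-squared (%s) must be below S",
                 paste(format(S[r2_adj >= S]), collapse = ", "),
                 paste(format(r2_adj[r2_adj >= S]), collapse = ", ")))
  Q / ((S - 1) * log(1 - r2_adj / S))
}

round_size <- function(x, rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  if (rounding == "ceiling") ceiling(x) else round(x)
}

criterion_result <- function(criterion, label, n, binding, ...) {
  structure(list(criterion = criterion, label = label, n = n,
                 binding = binding, ...),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("%s\n  required n = %s (binding: %s)\n",
              x$label, format(x$n, big.mark = ","), x$binding_text))
  invisible(x)
}

#' Criterion (i): pairwise shrinkage of every sub-model
#'
#' For every pair of outcome categories `{k, r}` with `k > r`, computes the
#' number of pair-subset individuals `m_{k,r}` needed to target the
#' shrinkage factor of the distinct one-vs-one logistic model (see
#' [binary_shrinkage_size()]), converts it to a whole-cohort size
#' `n_{k,r} = m_{k,r} / p_{k,r}` using the pairwise cohort proportion, and
#' takes the maximum over pairs. Because the one-vs-one models are
#' parametrically equivalent to the multinomial sub-models under every
#' choice of reference category, this targets all sub-model shrinkage
#' factors simultaneously.
#'
#' @param dist an [outcome_distribution()].
#' @param evidence either the resolved per-pair R-squared table from
#'   [resolve_evidence()] (columns `k`, `r`, `r2`) or a
#'   [pairwise_evidence()] object (resolved here with defaults).
#' @param Q candidate predictor parameters per sub-model.
#' @param S_target targeted shrinkage factor, default 0.9.
#' @param S_overrides optional per-pair relaxation of the shrinkage target
#'   (e.g. `c("5,3" = 0.8)`), as a named vector or a data frame with
#'   columns `k`, `r` and the target; a mitigation for infeasible sizes.
#' @param rounding `"ceiling"` (default, conservative) or `"nearest"`,
#'   applied only to the final per-pair whole-cohort sizes.
#' @return A `criterion_result` with the per-pair table (`pairs`: columns
#'   `k`, `r`, `r2`, `S_target`, `m` unrounded, `p_pair`, `n_pair`), the
#'   criterion sample size `n` and the binding pair.
#' @examples
#' dist <- outcome_distribution(c(2557, 186, 176, 467, 120))
#' ev <- pairwise_evidence(5, r2 = c(
#'   "2,1" = 0.116, "3,1" = 0.179, "4,1" = 0.497, "5,1" = 0.170,
#'   "3,2" = 0.185, "4,2" = 0.499, "5,2" = 0.374, "4,3" = 0.328,
#'   "5,3" = 0.129, "5,4" = 0.210))
#' criterion_shrinkage(dist, resolve_evidence(ev, dist), Q = 17)
#' @export
criterion_shrinkage <- function(dist, evidence, Q, S_target = 0.9,
                                S_overrides = NULL,
                                rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(dist, "outcome_distribution"))
  if (inherits(evidence, "pairwise_evidence"))
    evidence <- resolve_evidence(evidence, dist)
  if (!is.data.frame(evidence) || !all(c("k", "r", "r2") %in% names(evidence)))
    stop("`evidence` must be a resolved pair table with columns k, r, r2")
  if (!is.numeric(S_target) || length(S_target) != 1L ||
      S_target <= 0 || S_target >= 1)
    stop("`S_target` must be a single value in (0, 1)")
  overrides <- normalize_pair_table(S_overrides, dist$K, "S",
                                    lower = 0, upper = 1)
  grid <- pair_grid(dist$K)
  tab <- merge(grid, evidence, by = c("k", "r"), all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$r, tab$k), , drop = FALSE]
  if (anyNA(tab$r2))
    stop("missing pairwise R-squared for pairs: ",
         paste(sprintf("{%d,%d}", tab$k[is.na(tab$r2)], tab$r[is.na(tab$r2)]),
               collapse = ", "))
  tab$S_target <- S_target
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      hit <- tab$k == overrides$k[i] & tab$r == overrides$r[i]
      tab$S_target[hit] <- overrides$S[i]
    }
  }
  tab$m <- NA_real_
  tab$p_pair <- NA_real_
  for (i in seq_len(nrow(tab))) {
    tab$m[i] <- tryCatch(
      binary_shrinkage_size(Q, tab$S_target[i], tab$r2[i]),
      error = function(e)
        stop(sprintf("pair {%d,%d}: %s", tab$k[i], tab$r[i], conditionMessage(e)),
             call. = FALSE))
    tab$p_pair[i] <- p_pair(dist, tab$k[i], tab$r[i])
  }
  tab$n_pair <- round_size(tab$m / tab$p_pair, rounding)
  rownames(tab) <- NULL
  ibind <- which.max(tab$n_pair)
  criterion_result(
    criterion = "i",
    label = "Criterion (i): pairwise sub-model shrinkage",
    n = tab$n_pair[ibind],
    binding = c(k = tab$k[ibind], r = tab$r[ibind]),
    binding_text = sprintf("pair {%d,%d}", tab$k[ibind], tab$r[ibind]),
    pairs = tab, Q = Q, S_target = S_target, rounding = rounding
  )
}

#' Heuristic multinomial shrinkage size (diagnostic only)
#'
#' The rejected 'direct' extension of the shrinkage criterion: plugging the
#' total parameter count `(K - 1) * Q` and the overall multinomial adjusted
#' Cox-Snell R-squared into the binary shrinkage formula, thereby targeting
#' only the single heuristic shrinkage factor of the whole multinomial
#' model. This would not necessarily result in the required level of
#' shrinkage in each sub-model, so some sub-models could remain overfit;
#' it is exposed purely for comparison with [criterion_shrinkage()] and a
#' warning to that effect is always emitted.
#'
#' @param K number of outcome categories.
#' @param Q candidate predictor parameters per sub-model.
#' @param r2_adj overall adjusted Cox-Snell R-squared of the multinomial
#'   model.
#' @param S_target targeted heuristic shrinkage factor.
#' @param rounding rounding policy for the returned size.
#' @return required sample size (rounded per policy).
#' @export
heuristic_shrinkage_size <- function(K, Q, r2_adj, S_target = 0.9,
                                     rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K))
    stop("`K` must be a single integer >= 2")
  warning("the heuristic multinomial shrinkage target does not guarantee the ",
          "required shrinkage in each sub-model; some sub-models may remain ",
          "overfit. Diagnostic only - use criterion_shrinkage() for sizing.")
  round_size(binary_shrinkage_size((K - 1) * Q, S_target, r2_adj), rounding)
}

#' Criterion (ii): bounded optimism in the overall Nagelkerke R-squared
#'
#' Smallest sample size ensuring the difference between the apparent and
#' optimism-adjusted Nagelkerke R-squared of the overall multinomial model
#' is at most `delta`. The implied lower bound on the heuristic shrinkage
#' factor is `S = r2_adj / (r2_adj + delta * max_r2)`; substituting it into
#' the shrinkage formula with `(K - 1) * Q` parameters gives
#' `n >= (K - 1) * Q / ((S - 1) * log(1 - r2_adj - delta * max_r2))`.
#'
#' @param K number of outcome categories.
#' @param Q candidate predictor parameters per sub-model.
#' @param r2_adj anticipated overall adjusted Cox-Snell R-squared.
#' @param max_r2 maximum attainable Cox-Snell R-squared (see
#'   [max_r2_multinomial()]).
#' @param delta tolerated difference between apparent and adjusted
#'   Nagelkerke R-squared, default 0.05.
#' @param rounding rounding policy; the default ceiling returns the
#'   smallest integer satisfying the bound.
#' @return A `criterion_result` with the size `n`, the unrounded bound
#'   `n_raw` and the implied shrinkage bound `S_bound`.
#' @examples
#' criterion_r2_difference(5, 17, r2_adj = 0.126, max_r2 = 0.841)
#' @export
criterion_r2_difference <- function(K, Q, r2_adj, max_r2, delta = 0.05,
                                    rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K))
    stop("`K` must be a single integer >= 2")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    stop("`delta` must lie in (0, 1)")
  if (!is.numeric(r2_adj) || r2_adj <= 0 || r2_adj >= 1)
    stop("`r2_adj` must lie in (0, 1)")
  if (!is.numeric(max_r2) || max_r2 <= 0 || max_r2 >= 1)
    stop("`max_r2` must lie in (0, 1)")
  dm <- delta * max_r2
  if (r2_adj + dm >= 1)
    stop("r2_adj + delta * max_r2 >= 1: the tolerated optimism is not ",
         "attainable at any sample size")
  s_bound <- r2_adj / (r2_adj + dm)
  n_raw <- (K - 1) * Q / ((s_bound - 1) * log(1 - r2_adj - dm))
  criterion_result(
    criterion = "ii",
    label = "Criterion (ii): bounded Nagelkerke R-squared optimism",
    n = round_size(n_raw, rounding),
    binding = NA,
    binding_text = sprintf("overall model, implied shrinkage bound %.4f", s_bound),
    n_raw = n_raw, S_bound = s_bound, delta = delta,
    r2_adj = r2_adj, max_r2 = max_r2, K = K, Q = Q, rounding = rounding
  )
}

#' Criterion (iii): simultaneous precision of the category proportions
#'
#' Sample size ensuring the simultaneous `(1 - alpha)` confidence intervals
#' for all `K` outcome category proportions have absolute margin of error
#' at most `delta`. The simultaneous (Bonferroni/Goodman-type) construction
#' uses the chi-squared(1 df) upper-tail quantile at `alpha / K`, giving
#' per-category requirements
#' `n_k = qchisq(1 - alpha/K, 1) * p_k * (1 - p_k) / delta^2`
#' and overall `n = max_k n_k`.
#'
#' @param dist an [outcome_distribution()].
#' @param delta absolute margin of error for each proportion, default 0.05.
#' @param alpha significance level, default 0.05.
#' @param pointwise if `TRUE`, uses the pointwise normal-approximation
#'   quantile `qnorm(1 - alpha/2)^2` per category instead of the
#'   simultaneous quantile (the binary-outcome convention; less
#'   conservative).
#' @param rounding rounding policy for the per-category sizes.
#' @return A `criterion_result` with the per-category table
#'   (`per_category`: columns `k`, `p`, `n_k`), the criterion size `n`
#'   and the binding category. Degenerate proportions (0 or 1) contribute
#'   0 with a warning.
#' @examples
#' criterion_precision(outcome_distribution(c(2557, 186, 176, 467, 120)))
#' @export
criterion_precision <- function(dist, delta = 0.05, alpha = 0.05,
                                pointwise = FALSE,
                                rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(dist, "outcome_distribution"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    stop("`delta` must lie in (0, 1)")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  quant <- if (pointwise) stats::qnorm(1 - alpha / 2)^2
           else stats::qchisq(1 - alpha / dist$K, df = 1)
  p <- dist$p
  degenerate <- p %in% c(0, 1)
  if (any(degenerate))
    warning("categories with proportion 0 or 1 contribute no precision ",
            "requirement: ", paste(which(degenerate), collapse = ", "))
  n_k <- ifelse(degenerate, 0, round_size(quant * p * (1 - p) / delta^2, rounding))
  tab <- data.frame(k = seq_len(dist$K), p = p, n_k = n_k)
  ibind <- which.max(n_k)
  criterion_result(
    criterion = "iii",
    label = "Criterion (iii): simultaneous precision of category proportions",
    n = n_k[ibind],
    binding = ibind,
    binding_text = sprintf("category %d (p = %.3f)", ibind, p[ibind]),
    per_category = tab, delta = delta, alpha = alpha,
    quantile = quant, pointwise = pointwise, rounding = rounding
  )
}

#' Events-per-variable comparator sample size
#'
#' Legacy rule-of-thumb offered only for comparison with the criteria-based
#' sizes, never as a recommendation: the smallest `n` such that the rarest
#' outcome category is expected to contribute at least `epv * Q` events,
#' i.e. `ceiling(epv * Q / min_k p_k)`.
#'
#' @param epv events per candidate predictor parameter (vectorised).
#' @param Q candidate predictor parameters per sub-model.
#' @param dist an [outcome_distribution()].
#' @return required sample size(s).
#' @examples
#' epv_size(c(10, 20), 17, outcome_distribution(c(2557, 186, 176, 467, 120)))
#' @export
epv_size <- function(epv, Q, dist) {
  stopifnot(inherits(dist, "outcome_distribution"))
  if (!is.numeric(epv) || any(epv <= 0)) stop("`epv` must be positive")
  if (!is.numeric(Q) || length(Q) != 1L || Q < 1) stop("`Q` must be >= 1")
  p_min <- min(dist$p[dist$p > 0])
  ceiling(epv * Q / p_min)
}
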