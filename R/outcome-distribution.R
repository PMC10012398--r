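#' Outcome distribution of a polytomous endpoint
#'
#' Container for the category structure of a nominal outcome with `K >= 2`
#' categories: per-category event counts `E_k`, total cohort size `n`, and
#' the derived proportions used throughout the sample-size criteria.
#'
#' Supply either integer `counts` (one per category; `n` is their sum) or
#' `proportions` together with a nominal cohort size `n`. In the latter case
#' the likelihood-based quantities that genuinely need counts
#' ([lnl_null()], pairwise maxima from counts) use `round(p_k * n)`, and a
#' warning is issued once at construction, because published models often
#' report only rounded prevalences.
#'
#' Zero-count categories are permitted in the container itself (criterion
#' (iii) handles them gracefully) but are a hard error in every
#' likelihood-based operation: the sizing question is ill-posed for an
#' outcome category that is never observed.
#'
#' @param counts non-negative integer vector of per-category event counts.
#' @param proportions numeric vector of category proportions (must sum to 1
#'   up to rounding error of at most 0.005); requires `n`.
#' @param n total cohort size; only used (and required) with `proportions`.
#'
#' @return An object of class `outcome_distribution`: a list with elements
#'   `K`, `counts`, `n`, `p` (category proportions) and `from_proportions`.
#'
#' @examples
#' iota <- outcome_distribution(c(2557, 186, 176, 467, 120))
#' iota$p
#' max_r2_multinomial(iota)
#' @seealso [max_r2_multinomial()], [lnl_null()], [p_pair()], [phi_pair()]
#' @export
outcome_distribution <- function(counts = NULL, proportions = NULL, n = NULL) {
  if (!is.null(counts) && !is.null(proportions))
    stop("supply either `counts` or `proportions`, not both")
  if (!is.null(counts)) {
    counts <- as.numeric(counts)
    if (length(counts) < 2L)
      stop("at least two outcome categories are required")
    if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
      stop("`counts` must be non-negative integers")
    if (sum(counts) <= 0) stop("`counts` must contain at least one event")
    n <- sum(counts)
    p <- counts / n
    from_proportions <- FALSE
  } else if (!is.null(proportions)) {
    if (is.null(n)) stop("`n` must be supplied together with `proportions`")
    if (!is.numeric(n) || length(n) != 1L || n <= 0)
      stop("`n` must be a single positive number")
    p <- as.numeric(proportions)
    if (length(p) < 2L)
      stop("at least two outcome categories are required")
    if (anyNA(p) || any(p < 0) || any(p > 1))
      stop("`proportions` must lie in [0, 1]")
    if (abs(sum(p) - 1) > 0.005)
      stop(sprintf("`proportions` sum to %.4f; must equal 1 up to rounding error of 0.005",
                   sum(p)))
    counts <- round(p * n)
    warning("counts derived from `proportions` as round(p_k * n); ",
            "likelihood-based quantities will use these rounded counts")
    from_proportions <- TRUE
  } else {
    stop("supply `counts`, or `proportions` together with `n`")
  }
  structure(
    list(K = length(p), counts = counts, n = n, p = p,
         from_proportions = from_proportions),
    class = "outcome_distribution"
  )
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat(sprintf("Outcome distribution: K = %d categories, n = %s\n",
              x$K, format(x$n, big.mark = ",")))
  df <- data.frame(category = seq_len(x$K), events = x$counts,
                   proportion = round(x$p, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

check_category <- function(dist, k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > dist$K)
    stop(sprintf("category index must be an integer in 1..%d", dist$K))
  as.integer(k)
}

#' Pairwise cohort proportion
#'
#' Proportion of the whole cohort whose outcome lies in the pair `{k, r}`,
#' `p_{k,r} = (E_k + E_r) / n`. Symmetric in its arguments.
#'
#' @param dist an [outcome_distribution()].
#' @param k,r distinct category indices.
#' @return numeric in \[0, 1\].
#' @export
p_pair <- function(dist, k, r) {
  stopifnot(inherits(dist, "outcome_distribution"))
  k <- check_category(dist, k); r <- check_category(dist, r)
  if (k == r) stop("`k` and `r` must be distinct categories")
  dist$p[k] + dist$p[r]
}

#' Pairwise outcome fraction
#'
#' Fraction of the pair subset with outcome `k` rather than `r`,
#' `phi_{k,r} = E_k / (E_k + E_r)`; satisfies `phi_{r,k} = 1 - phi_{k,r}`.
#'
#' @inheritParams p_pair
#' @return numeric in \[0, 1\].
#' @export
phi_pair <- function(dist, k, r) {
  stopifnot(inherits(dist, "outcome_distribution"))
  k <- check_category(dist, k); r <- check_category(dist, r)
  if (k == r) stop("`k` and `r` must be distinct categories")
  if (dist$p[k] + dist$p[r] == 0)
    stop(sprintf("categories %d and %d both have zero events", k, r))
  dist$p[k] / (dist$p[k] + dist$p[r])
}

check_positive_counts <- function(dist, what) {
  zero <- which(dist$counts < 1)
  if (length(zero))
    stop(sprintf("%s is undefined with empty outcome categories (category %s has zero events)",
                 what, paste(zero, collapse = ", ")))
}

#' Null-model log-likelihood of a multinomial outcome
#'
#' Log-likelihood of the intercept-only multinomial model,
#' `sum_k E_k * log(E_k / n)`, in nats. Always non-positive.
#'
#' @param dist an [outcome_distribution()] with all counts >= 1.
#' @return numeric scalar <= 0.
#' @examples
#' lnl_null(outcome_distribution(c(50, 50)))  # 100 * log(0.5)
#' @export
lnl_null <- function(dist) {
  stopifnot(inherits(dist, "outcome_distribution"))
  check_positive_counts(dist, "the null log-likelihood")
  n <- sum(dist$counts)
  sum(dist$counts * log(dist$counts / n))
}

#' Maximum attainable Cox-Snell R-squared of a multinomial model
#'
#' The upper bound of the Cox-Snell R-squared given the outcome category
#' proportions, `1 - (prod_k p_k^{p_k})^2`. Equals
#' `1 - exp(2 * lnl_null / n)` evaluated on the same counts, and is used to
#' rescale a Nagelkerke R-squared back to the Cox-Snell scale.
#'
#' @inheritParams lnl_null
#' @return numeric in (0, 1).
#' @examples
#' max_r2_multinomial(outcome_distribution(c(2557, 186, 176, 467, 120)))
#' @export
max_r2_multinomial <- function(dist) {
  stopifnot(inherits(dist, "outcome_distribution"))
  check_positive_counts(dist, "the maximum Cox-Snell R-squared")
  p <- if (dist$from_proportions) dist$p else dist$counts / sum(dist$counts)
  1 - prod(p ^ p)^2
}

#' Maximum attainable Cox-Snell R-squared of a pairwise logistic model
#'
#' For the distinct ('one-vs-one') logistic model of categories `k` vs `r`,
#' the maximum Cox-Snell R-squared depends only on the pairwise outcome
#' fraction `phi = E_k / (E_k + E_r)`:
#' `1 - (phi^phi * (1 - phi)^(1 - phi))^2`. Symmetric in `(e_k, e_r)`.
#'
#' @param e_k,e_r positive event counts (or positive weights) of the two
#'   categories; vectorised.
#' @return numeric in (0, 0.75\].
#' @examples
#' max_r2_pair(50, 50)         # 0.75, the balanced maximum
#' max_r2_pair(186, 2557)
#' @export
max_r2_pair <- function(e_k, e_r) {
  if (anyNA(e_k) || anyNA(e_r) || any(e_k <= 0) || any(e_r <= 0))
    stop("both event counts must be strictly positive: the pairwise maximum ",
         "R-squared is undefined for an empty category")
  phi <- e_k / (e_k + e_r)
  1 - (phi ^ phi * (1 - phi) ^ (1 - phi))^2
}

#' Convert a Nagelkerke R-squared to the Cox-Snell scale
#'
#' The Nagelkerke R-squared is the Cox-Snell R-squared rescaled by its
#' maximum attainable value, so the inverse map is a product:
#' `R2_CS = R2_Nagelkerke * max(R2_CS)`. Used for the conservative default
#' assumption of an optimism-adjusted Nagelkerke R-squared of 0.15 when no
#' prior evidence is available.
#'
#' @param r2_nagelkerke Nagelkerke R-squared, in \[0, 1).
#' @param max_r2 maximum attainable Cox-Snell R-squared, in \[0, 1).
#' @return Cox-Snell R-squared.
#' @examples
#' r2_from_nagelkerke(0.15, 0.841)
#' @export
r2_from_nagelkerke <- function(r2_nagelkerke, max_r2) {
  if (anyNA(r2_nagelkerke) || any(r2_nagelkerke < 0) || any(r2_nagelkerke >= 1))
    stop("`r2_nagelkerke` must lie in [0, 1)")
  if (anyNA(max_r2) || any(max_r2 < 0) || any(max_r2 >= 1))
    stop("`max_r2` must lie in [0, 1)")
  r2_nagelkerke * max_r2
}

#' Merge outcome categories
#'
#' Collapses the given sets of categories into single categories, as a
#' mitigation when the required sample size is infeasible. Category counts
#' are summed; the merged category takes the position of its smallest
#' member, and remaining categories keep their relative order.
#'
#' Merging changes the distinct one-vs-one logistic models, so any pairwise
#' evidence (R-squared or C-statistic) touching a merged category is
#' invalidated and must be re-supplied; evidence between untouched
#' categories is carried over with re-mapped indices.
#'
#' @param dist an [outcome_distribution()].
#' @param merge a list of integer vectors, each the set of (disjoint)
#'   categories to collapse into one. Singleton sets are allowed (identity).
#' @param evidence optional [pairwise_evidence()] to carry over.
#' @return A list with elements `dist` (the merged distribution), `mapping`
#'   (old category -> new category), `evidence` (re-mapped evidence or
#'   `NULL`) and `dropped_pairs` (character description of invalidated
#'   evidence entries).
#' @examples
#' iota <- outcome_distribution(c(2557, 186, 176, 467, 120))
#' merge_categories(iota, list(c(3, 4)))$dist$counts  # 2557 186 643 120
#' @export
merge_categories <- function(dist, merge, evidence = NULL) {
  stopifnot(inherits(dist, "outcome_distribution"))
  if (!is.list(merge) || length(merge) == 0)
    stop("`merge` must be a non-empty list of category index vectors")
  flat <- unlist(merge)
  if (anyNA(flat) || any(flat != round(flat)) || any(flat < 1) || any(flat > dist$K))
    stop(sprintf("merge sets must contain integer categories in 1..%d", dist$K))
  if (anyDuplicated(flat))
    stop("merge sets must be disjoint")
  # groups: merged sets plus untouched singletons, ordered by smallest member
  groups <- c(lapply(merge, as.integer),
              as.list(setdiff(seq_len(dist$K), flat)))
  groups <- groups[order(vapply(groups, min, 1L))]
  if (length(groups) < 2L)
    stop("merging all categories into one is not allowed: K must stay >= 2")
  mapping <- integer(dist$K)
  for (g in seq_along(groups)) mapping[groups[[g]]] <- g
  new_counts <- vapply(groups, function(g) sum(dist$counts[g]), 1)
  new_dist <- outcome_distribution(counts = new_counts)
  touched <- unlist(merge[lengths(merge) > 1L])
  new_evidence <- NULL
  dropped <- character()
  if (!is.null(evidence)) {
    stopifnot(inherits(evidence, "pairwise_evidence"))
    remap <- function(tab, what) {
      if (is.null(tab)) return(NULL)
      keep <- !(tab$k %in% touched) & !(tab$r %in% touched)
      if (any(!keep))
        dropped <<- c(dropped, sprintf("%s {%d,%d}", what, tab$k[!keep], tab$r[!keep]))
      out <- tab[keep, , drop = FALSE]
      if (nrow(out) == 0) return(NULL)
      kk <- mapping[out$k]; rr <- mapping[out$r]
      out$k <- pmax(kk, rr); out$r <- pmin(kk, rr)
      rownames(out) <- NULL
      out
    }
    new_evidence <- pairwise_evidence(K = new_dist$K)
    new_evidence$r2 <- remap(evidence$r2, "R2")
    new_evidence$cstat <- remap(evidence$cstat, "C-statistic")
    new_evidence$nagelkerke <- evidence$nagelkerke
    if (length(dropped))
      warning("pairwise evidence invalidated by merging (re-supply it): ",
              paste(dropped, collapse = "; "))
  }
  list(dist = new_dist, mapping = mapping, evidence = new_evidence,
       dropped_pairs = dropped)
}
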