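#' Pairwise evidence for the shrinkage criterion
#'
#' Bundle of the prior evidence available for each distinct one-vs-one
#' logistic model `{k, r}` (with `k > r`): directly reported optimism-adjusted
#' Cox-Snell R-squared values, pairwise C-statistics (converted to R-squared
#' by simulation at resolution time), and/or a fallback Nagelkerke
#' R-squared assumption applied to every pair without other evidence.
#'
#' Pair tables can be given either as a data frame with columns `k`, `r`
#' and a value column, or as a named vector/list with names like `"4,1"`.
#' Pairs given with `k < r` are stored as `(r, k)`; both the R-squared and
#' the C-statistic of a one-vs-one model are invariant to swapping the
#' event and reference labels.
#'
#' @param K number of outcome categories.
#' @param r2 optional pair table of adjusted Cox-Snell R-squared values,
#'   each in (0, 1).
#' @param cstat optional pair table of C-statistics, each in \[0.5, 1).
#' @param nagelkerke optional fallback Nagelkerke R-squared in (0, 1)
#'   (commonly the conservative 0.15) applied to pairs lacking other
#'   evidence.
#' @return An object of class `pairwise_evidence`.
#' @seealso [resolve_evidence()], [r2_from_cstat()]
#' @examples
#' pairwise_evidence(3, r2 = c("2,1" = 0.2, "3,1" = 0.25, "3,2" = 0.3))
#' @export
pairwise_evidence <- function(K, r2 = NULL, cstat = NULL, nagelkerke = NULL) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K))
    stop("`K` must be a single integer >= 2")
  K <- as.integer(K)
  r2 <- normalize_pair_table(r2, K, "r2", lower = 0, upper = 1,
                             open_lower = TRUE, open_upper = TRUE)
  cstat <- normalize_pair_table(cstat, K, "c_statistic", lower = 0.5, upper = 1,
                                open_lower = FALSE, open_upper = TRUE)
  if (!is.null(nagelkerke)) {
    if (!is.numeric(nagelkerke) || length(nagelkerke) != 1L ||
        nagelkerke <= 0 || nagelkerke >= 1)
      stop("`nagelkerke` must be a single value in (0, 1)")
  }
  structure(list(K = K, r2 = r2, cstat = cstat, nagelkerke = nagelkerke),
            class = "pairwise_evidence")
}

# Accepts data.frame(k, r, <value>) or named vector/list ("k,r" = value);
# returns data.frame(k, r, value) with k > r, or NULL.
normalize_pair_table <- function(x, K, what, lower, upper,
                                 open_lower = TRUE, open_upper = TRUE) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    if (!all(c("k", "r") %in% names(x)))
      stop(sprintf("pair table for `%s` needs columns `k` and `r`", what))
    valcol <- setdiff(names(x), c("k", "r"))
    if (what %in% valcol) valcol <- what
    else if ("value" %in% valcol) valcol <- "value"
    else if (length(valcol) == 1L) valcol <- valcol
    else stop(sprintf("pair table for `%s` needs a single value column", what))
    out <- data.frame(k = as.integer(x$k), r = as.integer(x$r),
                      value = as.numeric(x[[valcol]]))
  } else {
    x <- unlist(x)
    nm <- names(x)
    if (is.null(nm) || any(nm == ""))
      stop(sprintf("`%s` pairs must be named like \"k,r\" (e.g. \"4,1\")", what))
    idx <- strsplit(gsub("[^0-9]+", ",", nm), ",")
    if (any(lengths(idx) != 2L))
      stop(sprintf("could not parse `%s` pair names; use \"k,r\"", what))
    idx <- do.call(rbind, lapply(idx, as.integer))
    out <- data.frame(k = idx[, 1], r = idx[, 2], value = as.numeric(x))
  }
  if (anyNA(out))
    stop(sprintf("missing values in `%s` pair table", what))
  if (any(out$k < 1 | out$k > K | out$r < 1 | out$r > K))
    stop(sprintf("`%s` pair indices must lie in 1..%d", what, K))
  if (any(out$k == out$r))
    stop(sprintf("`%s` pairs must involve two distinct categories", what))
  kk <- pmax(out$k, out$r); rr <- pmin(out$k, out$r)
  out$k <- kk; out$r <- rr
  if (anyDuplicated(out[c("k", "r")]))
    stop(sprintf("duplicate pairs in `%s` table", what))
  bad <- (out$value < lower) | (out$value > upper) |
    (open_lower & out$value == lower) | (open_upper & out$value == upper)
  if (any(bad))
    stop(sprintf("`%s` values out of range for pairs: %s", what,
                 paste(sprintf("{%d,%d}", out$k[bad], out$r[bad]), collapse = ", ")))
  names(out)[3] <- what
  rownames(out) <- NULL
  out
}

#' All category pairs `k > r`
#'
#' @param K number of categories.
#' @return data frame with columns `k`, `r`, one row per unordered pair,
#'   listed with `k > r`.
#' @export
pair_grid <- function(K) {
  idx <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
  out <- data.frame(k = as.integer(idx[, "row"]), r = as.integer(idx[, "col"]))
  out <- out[order(out$r, out$k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve pairwise evidence into one R-squared per pair
#'
#' Produces the per-pair adjusted Cox-Snell R-squared feeding the shrinkage
#' criterion, applying a fixed precedence for every pair `k > r`:
#' a directly reported R-squared beats a C-statistic (converted via
#' [r2_from_cstat()] using the pair's outcome fraction from `dist`), which
#' beats the fallback Nagelkerke assumption
#' (`R2 = nagelkerke * max_r2_pair`). The provenance of each value is
#' recorded. Pairs with no route at all are an error listing the gaps.
#'
#' @param evidence a [pairwise_evidence()].
#' @param dist an [outcome_distribution()] with `K` matching `evidence`.
#' @param sim_size,n_replicates simulation size and replicates for the
#'   C-statistic conversion (see [r2_from_cstat()]).
#' @param seed integer seed governing all C-statistic conversions
#'   (per-pair sub-seeds are derived deterministically); `NULL` leaves the
#'   RNG state untouched.
#' @return data frame with one row per pair `k > r`: columns `k`, `r`,
#'   `r2`, `provenance` (`reported`, `from_cstat_simulation` or
#'   `from_nagelkerke_assumption`), `c_statistic`, `phi`, `max_r2` and
#'   `r2_se` (Monte-Carlo standard error, `NA` for non-simulated values).
#' @examples
#' dist <- outcome_distribution(c(120, 60, 40))
#' ev <- pairwise_evidence(3, r2 = c("2,1" = 0.2), nagelkerke = 0.15)
#' resolve_evidence(ev, dist)
#' @export
resolve_evidence <- function(evidence, dist, sim_size = 1e6,
                             n_replicates = 10, seed = NULL) {
  stopifnot(inherits(evidence, "pairwise_evidence"),
            inherits(dist, "outcome_distribution"))
  if (evidence$K != dist$K)
    stop(sprintf("evidence is for K = %d but the outcome distribution has K = %d",
                 evidence$K, dist$K))
  check_positive_counts(dist, "pairwise evidence resolution")
  grid <- pair_grid(dist$K)
  npair <- nrow(grid)
  if (!is.null(seed)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    pair_seeds <- sample.int(.Machine$integer.max - 1L, npair)
  } else {
    pair_seeds <- rep(NA_integer_, npair)
  }
  out <- data.frame(grid, r2 = NA_real_, provenance = NA_character_,
                    c_statistic = NA_real_, phi = NA_real_,
                    max_r2 = NA_real_, r2_se = NA_real_)
  gaps <- character()
  for (i in seq_len(npair)) {
    k <- grid$k[i]; r <- grid$r[i]
    out$phi[i] <- phi_pair(dist, k, r)
    out$max_r2[i] <- max_r2_pair(dist$counts[k], dist$counts[r])
    direct <- match_pair(evidence$r2, k, r)
    cs <- match_pair(evidence$cstat, k, r)
    if (!is.na(direct)) {
      out$r2[i] <- direct
      out$provenance[i] <- "reported"
    } else if (!is.na(cs)) {
      conv <- r2_from_cstat(cs, out$phi[i], sim_size = sim_size,
                            n_replicates = n_replicates,
                            seed = if (is.na(pair_seeds[i])) NULL else pair_seeds[i])
      out$r2[i] <- conv$estimate
      out$r2_se[i] <- conv$se
      out$c_statistic[i] <- cs
      out$provenance[i] <- "from_cstat_simulation"
    } else if (!is.null(evidence$nagelkerke)) {
      out$r2[i] <- r2_from_nagelkerke(evidence$nagelkerke, out$max_r2[i])
      out$provenance[i] <- "from_nagelkerke_assumption"
    } else {
      gaps <- c(gaps, sprintf("{%d,%d}", k, r))
    }
  }
  if (length(gaps))
    stop("no evidence (R-squared, C-statistic or Nagelkerke fallback) for pairs: ",
         paste(gaps, collapse = ", "))
  bad <- out$r2 <= 0 | out$r2 >= out$max_r2
  if (any(bad))
    stop("resolved R-squared outside (0, max_r2_pair) for pairs: ",
         paste(sprintf("{%d,%d} (r2 = %.4f, max = %.4f)",
                       out$k[bad], out$r[bad], out$r2[bad], out$max_r2[bad]),
               collapse = ", "))
  out
}

match_pair <- function(tab, k, r) {
  if (is.null(tab)) return(NA_real_)
  hit <- which(tab$k == k & tab$r == r)
  if (length(hit)) tab[[3]][hit[1]] else NA_real_
}

#' @export
print.pairwise_evidence <- function(x, ...) {
  cat(sprintf("Pairwise evidence for K = %d categories\n", x$K))
  if (!is.null(x$r2)) {
    cat("  reported Cox-Snell R-squared:\n")
    print(x$r2, row.names = FALSE)
  }
  if (!is.null(x$cstat)) {
    cat("  pairwise C-statistics (converted by simulation at resolution):\n")
    print(x$cstat, row.names = FALSE)
  }
  if (!is.null(x$nagelkerke))
    cat(sprintf("  fallback Nagelkerke R-squared: %.3f\n", x$nagelkerke))
  invisible(x)
}
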