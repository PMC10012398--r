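#' Minimum sample size for a multinomial prediction model
#'
#' End-to-end sample-size calculation for developing a multinomial logistic
#' regression prediction model: resolves the per-pair evidence, evaluates
#' the three criteria -- (i) pairwise sub-model shrinkage
#' ([criterion_shrinkage()]), (ii) bounded optimism in the overall
#' Nagelkerke R-squared ([criterion_r2_difference()]), (iii) simultaneous
#' precision of the category proportions ([criterion_precision()]) -- and
#' reports the maximum together with the expected per-category event
#' counts at that size.
#'
#' Evidence for each pair `{k, r}` is resolved with a fixed precedence:
#' a directly reported Cox-Snell R-squared beats a pairwise C-statistic
#' (converted by simulation), which beats the conservative fallback of a
#' Nagelkerke R-squared of `nagelkerke` applied to the pair's maximum
#' attainable R-squared. The overall adjusted R-squared for criterion (ii)
#' is `overall_r2_adj` when given, otherwise
#' `nagelkerke * max_r2_multinomial(dist)`.
#'
#' All warnings raised during the computation (e.g. the rounding note for
#' criterion (ii), or proportion-derived counts) are collected into the
#' report rather than printed mid-computation.
#'
#' @param counts,proportions,n the outcome distribution, as in
#'   [outcome_distribution()]; alternatively pass a ready-made `dist`.
#' @param Q candidate predictor parameters per sub-model.
#' @param pairwise_r2 reported per-pair adjusted Cox-Snell R-squared values
#'   (named vector `c("2,1" = ..., ...)` or data frame; see
#'   [pairwise_evidence()]).
#' @param pairwise_cstat per-pair C-statistics, same formats.
#' @param nagelkerke fallback Nagelkerke R-squared for pairs (and the
#'   overall model) without direct evidence; default 0.15. Set `NULL` to
#'   disable the fallback (missing pairs then error).
#' @param overall_r2_adj optional reported overall adjusted Cox-Snell
#'   R-squared for criterion (ii).
#' @param S_target,S_overrides shrinkage target and optional per-pair
#'   relaxations (see [criterion_shrinkage()]).
#' @param delta_r2 tolerated Nagelkerke optimism for criterion (ii).
#' @param delta_precision absolute margin of error for criterion (iii).
#' @param alpha significance level for criterion (iii).
#' @param rounding `"ceiling"` (default) or `"nearest"`.
#' @param pointwise use pointwise rather than simultaneous intervals in
#'   criterion (iii).
#' @param epv optional events-per-variable value(s) for the comparator
#'   ([epv_size()]); reported alongside, never used for the recommendation.
#' @param sim_size,n_replicates Monte-Carlo settings for any C-statistic
#'   conversion.
#' @param seed integer seed governing all simulation-based conversions.
#' @param dist optionally, an [outcome_distribution()] instead of
#'   `counts`/`proportions`.
#'
#' @return An object of class `mnl_size_report`: final size `n`, binding
#'   criterion, the three `criterion_result`s, the heuristic diagnostic
#'   size, resolved evidence with provenance, expected per-category counts
#'   at the final `n`, the EPV comparator table (if requested), echoed
#'   inputs and collected warnings.
#' @examples
#' rep <- mnl_sample_size(
#'   counts = c(2557, 186, 176, 467, 120), Q = 17,
#'   pairwise_r2 = c("2,1" = 0.116, "3,1" = 0.179, "4,1" = 0.497,
#'                   "5,1" = 0.170, "3,2" = 0.185, "4,2" = 0.499,
#'                   "5,2" = 0.374, "4,3" = 0.328, "5,3" = 0.129,
#'                   "5,4" = 0.210),
#'   epv = c(10, 20))
#' rep$n
#' @seealso [run_sizing()] for the config-file driven route.
#' @export
mnl_sample_size <- function(counts = NULL, proportions = NULL, n = NULL, Q,
                            pairwise_r2 = NULL, pairwise_cstat = NULL,
                            nagelkerke = 0.15, overall_r2_adj = NULL,
                            S_target = 0.9, S_overrides = NULL,
                            delta_r2 = 0.05, delta_precision = 0.05,
                            alpha = 0.05,
                            rounding = c("ceiling", "nearest"),
                            pointwise = FALSE, epv = NULL,
                            sim_size = 1e6, n_replicates = 10, seed = NULL,
                            dist = NULL) {
  rounding <- match.arg(rounding)
  if (missing(Q)) stop("`Q` (candidate predictor parameters) is required")
  warn_log <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  collect({
    if (is.null(dist))
      dist <- outcome_distribution(counts = counts, proportions = proportions,
                                   n = n)
    stopifnot(inherits(dist, "outcome_distribution"))

    max_r2 <- max_r2_multinomial(dist)
    if (!is.null(overall_r2_adj)) {
      r2_overall <- overall_r2_adj
      overall_provenance <- "reported"
    } else {
      if (is.null(nagelkerke))
        stop("no overall R-squared: supply `overall_r2_adj` or `nagelkerke`")
      r2_overall <- r2_from_nagelkerke(nagelkerke, max_r2)
      overall_provenance <- "from_nagelkerke_assumption"
    }

    evidence <- pairwise_evidence(dist$K, r2 = pairwise_r2,
                                  cstat = pairwise_cstat,
                                  nagelkerke = nagelkerke)
    resolved <- resolve_evidence(evidence, dist, sim_size = sim_size,
                                 n_replicates = n_replicates, seed = seed)

    crit_i <- criterion_shrinkage(dist, resolved, Q = Q, S_target = S_target,
                                  S_overrides = S_overrides,
                                  rounding = rounding)
    crit_ii <- criterion_r2_difference(dist$K, Q, r2_adj = r2_overall,
                                       max_r2 = max_r2, delta = delta_r2,
                                       rounding = rounding)
    crit_iii <- criterion_precision(dist, delta = delta_precision,
                                    alpha = alpha, pointwise = pointwise,
                                    rounding = rounding)
    heuristic <- heuristic_shrinkage_size(dist$K, Q, r2_adj = r2_overall,
                                          S_target = S_target,
                                          rounding = rounding)
  })
  if (crit_ii$n > crit_ii$n_raw && crit_ii$n - crit_ii$n_raw < 1)
    warn_log <- c(warn_log, sprintf(
      "criterion (ii): unrounded bound %.2f reported as the ceiling %d",
      crit_ii$n_raw, crit_ii$n))

  n_final <- max(crit_i$n, crit_ii$n, crit_iii$n)
  binding_criterion <- c("i", "ii", "iii")[
    which.max(c(crit_i$n, crit_ii$n, crit_iii$n))]

  expected <- round(n_final * dist$p)
  resid <- n_final - sum(expected)
  if (resid != 0) expected[which.max(dist$p)] <- expected[which.max(dist$p)] + resid

  epv_tab <- NULL
  if (!is.null(epv))
    epv_tab <- data.frame(epv = epv, n = epv_size(epv, Q, dist))

  structure(
    list(n = n_final, binding_criterion = binding_criterion,
         criteria = list(i = crit_i, ii = crit_ii, iii = crit_iii),
         heuristic_diagnostic = heuristic,
         evidence = resolved,
         overall = list(r2_adj = r2_overall, max_r2 = max_r2,
                        provenance = overall_provenance),
         expected_counts = expected,
         epv = epv_tab,
         inputs = list(dist = dist, Q = Q, S_target = S_target,
                       S_overrides = S_overrides, delta_r2 = delta_r2,
                       delta_precision = delta_precision, alpha = alpha,
                       rounding = rounding, pointwise = pointwise,
                       nagelkerke = nagelkerke, sim_size = sim_size,
                       n_replicates = n_replicates, seed = seed),
         warnings = warn_log),
    class = "mnl_size_report"
  )
}

#' @export
print.mnl_size_report <- function(x, digits = 3, ...) {
  dist <- x$inputs$dist
  cat("Minimum sample size for a multinomial logistic regression prediction model\n")
  cat(sprintf("  K = %d outcome categories, Q = %d candidate predictor parameters per sub-model\n",
              dist$K, x$inputs$Q))
  cat(sprintf("  shrinkage target %.2f | Nagelkerke optimism delta %.3g | precision delta %.3g at alpha %.3g\n\n",
              x$inputs$S_target, x$inputs$delta_r2, x$inputs$delta_precision,
              x$inputs$alpha))
  cat(sprintf("Overall: max R2_CS = %.*f, adjusted R2_CS = %.*f (%s)\n\n",
              digits, x$overall$max_r2, digits, x$overall$r2_adj,
              x$overall$provenance))

  cat("Criterion (i): pairwise sub-model shrinkage\n")
  tab <- x$criteria$i$pairs
  shown <- data.frame(pair = sprintf("{%d,%d}", tab$k, tab$r),
                      R2 = round(tab$r2, digits),
                      provenance = tab$provenance,
                      S = tab$S_target,
                      m = round(tab$m, 1),
                      n = tab$n_pair)
  print(shown, row.names = FALSE)
  cat(sprintf("  criterion (i) n = %s (binding %s)\n\n",
              format(x$criteria$i$n, big.mark = ","),
              x$criteria$i$binding_text))

  cat(sprintf("Criterion (ii): n = %s (unrounded bound %.2f, implied shrinkage bound %.3f)\n\n",
              format(x$criteria$ii$n, big.mark = ","), x$criteria$ii$n_raw,
              x$criteria$ii$S_bound))

  cat("Criterion (iii): simultaneous precision of category proportions\n")
  pc <- x$criteria$iii$per_category
  print(data.frame(category = pc$k, p = round(pc$p, digits), n = pc$n_k),
        row.names = FALSE)
  cat(sprintf("  criterion (iii) n = %s (binding %s)\n\n",
              format(x$criteria$iii$n, big.mark = ","),
              x$criteria$iii$binding_text))

  cat(sprintf("FINAL minimum sample size: n = %s (binding criterion (%s))\n",
              format(x$n, big.mark = ","), x$binding_criterion))
  cat("Expected events per category at the final n:\n  ")
  cat(paste(sprintf("%d: %s", seq_along(x$expected_counts),
                    format(x$expected_counts, big.mark = ",")),
            collapse = "  "), "\n")
  cat(sprintf("\n[diagnostic] heuristic overall-shrinkage size: %s (does not guarantee per-sub-model shrinkage)\n",
              format(x$heuristic_diagnostic, big.mark = ",")))
  if (!is.null(x$epv)) {
    cat("\nEvents-per-variable comparator (not a recommendation):\n")
    print(x$epv, row.names = FALSE)
  }
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Plain-list view of a sample-size report
#'
#' Lossless conversion of an `mnl_size_report` to base lists and data
#' frames, suitable for JSON serialisation.
#'
#' @param report an [mnl_sample_size()] report.
#' @return a nested list mirroring the report field-for-field.
#' @export
as_report_list <- function(report) {
  stopifnot(inherits(report, "mnl_size_report"))
  dist <- report$inputs$dist
  list(
    n = report$n,
    binding_criterion = report$binding_criterion,
    criteria = list(
      i = list(n = report$criteria$i$n,
               binding_pair = as.list(report$criteria$i$binding),
               pairs = report$criteria$i$pairs),
      ii = list(n = report$criteria$ii$n,
                n_unrounded = report$criteria$ii$n_raw,
                shrinkage_bound = report$criteria$ii$S_bound,
                delta = report$criteria$ii$delta),
      iii = list(n = report$criteria$iii$n,
                 binding_category = report$criteria$iii$binding,
                 quantile = report$criteria$iii$quantile,
                 per_category = report$criteria$iii$per_category)
    ),
    heuristic_diagnostic = report$heuristic_diagnostic,
    overall = report$overall,
    evidence = report$evidence,
    expected_counts = report$expected_counts,
    epv = report$epv,
    inputs = list(
      K = dist$K, counts = dist$counts, n_cohort = dist$n,
      proportions = dist$p, Q = report$inputs$Q,
      S_target = report$inputs$S_target,
      delta_r2 = report$inputs$delta_r2,
      delta_precision = report$inputs$delta_precision,
      alpha = report$inputs$alpha, rounding = report$inputs$rounding,
      pointwise = report$inputs$pointwise,
      nagelkerke = report$inputs$nagelkerke,
      seed = report$inputs$seed
    ),
    warnings = report$warnings
  )
}

#' Serialise a sample-size report to JSON
#'
#' @param report an [mnl_sample_size()] report.
#' @param pretty pretty-print the JSON.
#' @return a JSON string (class `json`).
#' @export
report_json <- function(report, pretty = TRUE) {
  jsonlite::toJSON(as_report_list(report), auto_unbox = TRUE, digits = NA,
                   pretty = pretty, null = "null", dataframe = "columns")
}
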