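#' Read and validate a sizing configuration
#'
#' Configurations are YAML or JSON with the blocks:
#' \preformatted{
#' outcome:    {counts: [2557, 186, 176, 467, 120]}   # or {proportions: [...], n: N}
#' predictors: {Q: 17}
#' criteria:   {S_target: 0.9, delta_r2: 0.05, delta_precision: 0.05,
#'              alpha: 0.05, rounding: ceiling, pointwise: false,
#'              S_overrides: {"5,3": 0.8}}
#' evidence:   {pairwise_r2: {"2,1": 0.116, ...}}     # and/or pairwise_cstat,
#'                                                    # nagelkerke_fallback,
#'                                                    # overall_r2_adj,
#'                                                    # sim_size, n_replicates
#' seed: 1
#' epv: [10, 20]
#' }
#' Unknown keys at any level are rejected before any computation.
#'
#' @param config a file path (`.yaml`/`.yml`/`.json`) or an equivalent
#'   nested list.
#' @return the validated configuration list.
#' @export
read_sizing_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop(sprintf("unknown key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")))
  }
  check_keys(config, c("outcome", "predictors", "criteria", "evidence",
                       "seed", "epv"), "config")
  if (is.null(config$outcome)) stop("config needs an `outcome` block")
  check_keys(config$outcome, c("counts", "proportions", "n"), "outcome")
  if (is.null(config$predictors) || is.null(config$predictors$Q))
    stop("config needs `predictors: {Q: ...}`")
  check_keys(config$predictors, "Q", "predictors")
  check_keys(config$criteria,
             c("S_target", "S_overrides", "delta_r2", "delta_precision",
               "alpha", "rounding", "pointwise"), "criteria")
  check_keys(config$evidence,
             c("pairwise_r2", "pairwise_cstat", "nagelkerke_fallback",
               "overall_r2_adj", "sim_size", "n_replicates"), "evidence")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full sizing workflow from a configuration
#'
#' Executes the six-step workflow -- choose `Q`; assemble the outcome
#' proportions and R-squared evidence; evaluate criteria (i)-(iii); take
#' the maximum -- from a validated configuration, resolving per-pair
#' evidence with the documented precedence (reported R-squared, then
#' C-statistic conversion, then Nagelkerke fallback).
#'
#' @inheritParams read_sizing_config
#' @return an [mnl_sample_size()] report (`mnl_size_report`).
#' @examples
#' cfg <- system.file("extdata", "iota_ovarian_r2.yaml",
#'                    package = "mnlsampsize")
#' report <- run_sizing(cfg)
#' report$n
#' @export
run_sizing <- function(config) {
  config <- read_sizing_config(config)
  crit <- config$criteria
  ev <- config$evidence
  mnl_sample_size(
    counts = config$outcome$counts,
    proportions = config$outcome$proportions,
    n = config$outcome$n,
    Q = config$predictors$Q,
    pairwise_r2 = ev$pairwise_r2,
    pairwise_cstat = ev$pairwise_cstat,
    nagelkerke = ev$nagelkerke_fallback %||% 0.15,
    overall_r2_adj = ev$overall_r2_adj,
    S_target = crit$S_target %||% 0.9,
    S_overrides = crit$S_overrides,
    delta_r2 = crit$delta_r2 %||% 0.05,
    delta_precision = crit$delta_precision %||% 0.05,
    alpha = crit$alpha %||% 0.05,
    rounding = crit$rounding %||% "ceiling",
    pointwise = isTRUE(crit$pointwise),
    epv = config$epv,
    sim_size = ev$sim_size %||% 1e6,
    n_replicates = ev$n_replicates %||% 10,
    seed = config$seed
  )
}

#' Render a sizing report
#'
#' @param report an `mnl_size_report`.
#' @param format `"text"` for the human-readable table view, `"json"` for
#'   the lossless JSON serialisation.
#' @return a character scalar (text) or a `json` string.
#' @export
render_report <- function(report, format = c("text", "json")) {
  stopifnot(inherits(report, "mnl_size_report"))
  if (length(format) > 1L) format <- format[1L]
  if (identical(format, "text"))
    paste(utils::capture.output(print(report)), collapse = "\n")
  else if (identical(format, "json"))
    report_json(report)
  else stop("unknown format: ", format)
}
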