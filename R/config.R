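#' De-identification configuration
#'
#' Central bundle of the tunable release parameters with the defaults used
#' throughout: per-record probability threshold `theta = .05` (implying a
#' population class-size floor of 20), Safe Harbor uniqueness rate
#' `u = 0.0004` (implying a 0.8% high-risk budget), top-coding at the 99th
#' percentile, claim truncation at the 95th percentile of per-patient
#' counts, provider-pattern suppression below 20 estimated population
#' providers, and an adversary power cap of 5.
#'
#' @param alpha sampling fraction of the release.
#' @param theta,u,F_min,maxsup,p_m see [risk_params()].
#' @param topcode_percentile percentile for [top_code_dataset()].
#' @param truncate_percentile percentile for [truncate_claims()].
#' @param provider_min_count threshold for [suppress_provider_ids()].
#' @param estimator population class-size estimator name.
#' @param secret pseudonymization secret (keep out of configs committed to
#'   version control; `NULL` means pseudonymization is skipped).
#' @param pseudonym_fields identifier fields to pseudonymize.
#' @param grouping_paths named list of grouping-table CSV paths (see
#'   [build_default_hierarchies()]).
#' @param code_list_path path of a high-risk code list CSV; `NULL` uses the
#'   packaged demonstration list.
#' @return An object of class `deid_config`.
#' @export
deid_config <- function(alpha = 1, theta = 0.05, u = 0.0004,
                        F_min = NULL, maxsup = NULL, p_m = 5L,
                        topcode_percentile = 0.99,
                        truncate_percentile = 0.95,
                        provider_min_count = 20L,
                        estimator = "large_sample",
                        secret = NULL,
                        pseudonym_fields = c("member_id", "provider_id",
                                             "vendor", "pcp"),
                        grouping_paths = list(),
                        code_list_path = NULL) {
  params <- risk_params(theta = theta, alpha = alpha, u = u,
                        F_min = F_min, maxsup = maxsup, p_m = p_m)
  structure(
    list(params = params,
         topcode_percentile = topcode_percentile,
         truncate_percentile = truncate_percentile,
         provider_min_count = provider_min_count,
         estimator = estimator,
         secret = secret,
         pseudonym_fields = pseudonym_fields,
         grouping_paths = grouping_paths,
         code_list_path = code_list_path),
    class = "deid_config"
  )
}

#' Read a de-identification config from YAML or JSON
#'
#' Keys mirror the arguments of [deid_config()]; missing keys fall back to
#' the defaults.
#'
#' @param path file path (`.yaml`/`.yml`/`.json` — YAML is a JSON
#'   superset, so both parse with the same reader).
#' @return A [deid_config()].
#' @export
read_deid_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(deid_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(deid_config, raw)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: pseudonymization (when a secret is configured),
#' top-coding, high-risk patient removal, claim truncation, and
#' provider/vendor/PCP suppression. Returns both the processed dataset and
#' the intermediate products downstream stages need (the untruncated
#' dataset is the adversary's reference for the simulated attack).
#'
#' @param ds a `claims_dataset`.
#' @param config a [deid_config()].
#' @param codes optional [high_risk_code_list()]; defaults to the packaged
#'   demonstration list (or `config$code_list_path`).
#' @return List with `dataset` (fully preprocessed), `untruncated` (same
#'   pipeline minus truncation), `caps`, `truncation_plan`.
#' @export
preprocess_dataset <- function(ds, config = deid_config(), codes = NULL) {
  validate_dataset(ds)
  if (is.null(codes)) {
    path <- config$code_list_path
    if (is.null(path)) {
      path <- system.file("extdata", "high_risk_codes_synthetic.csv",
                          package = "longdeid", mustWork = TRUE)
    }
    codes <- read_code_list(path)
  }
  if (!is.null(config$secret)) {
    ds <- pseudonymize(ds, config$pseudonym_fields, config$secret)
  }
  tc <- top_code_dataset(ds, config$topcode_percentile)
  ds <- tc$dataset
  ds <- remove_high_risk_patients(ds, codes)
  ds$alpha <- config$params$alpha
  tr <- truncate_claims(ds, config$truncate_percentile)
  d2 <- suppress_provider_ids(tr$dataset, config$provider_min_count,
                              config$estimator)
  d1 <- suppress_provider_ids(ds, config$provider_min_count,
                              config$estimator)
  list(dataset = d2, untruncated = d1, caps = tc$caps,
       truncation_plan = tr$plan)
}
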