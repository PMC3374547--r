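#' Nearest-rank percentile
#'
#' The order statistic at `ceiling(p * n)` of the sorted vector. Used for
#' every percentile rule in preprocessing so the cut-offs are well defined on
#' small samples (no interpolation).
#'
#' @param values non-empty numeric vector.
#' @param percentile fraction in (0, 1].
#' @return The nearest-rank percentile value.
#' @keywords internal
nearest_rank <- function(values, percentile) {
  if (length(values) == 0) stop("values must be non-empty")
  if (percentile <= 0 || percentile > 1) {
    stop("percentile must be in (0, 1]")
  }
  sort(values)[ceiling(percentile * length(values))]
}

#' Top-code a numeric vector at a percentile cap
#'
#' Extreme values make records stand out, so values above the nearest-rank
#' percentile cap are replaced by the cap. Applied in a release to `PayDelay`
#' and the `DaysInHospital` columns at the 99th percentile.
#'
#' @param values non-empty numeric vector.
#' @param percentile cap percentile, default `0.99`.
#' @return List with `values` (capped vector) and `cap` (the cap value).
#' @export
#' @examples
#' top_code(1:100, 0.99) # cap 99; the value 100 becomes 99
top_code <- function(values, percentile = 0.99) {
  cap <- nearest_rank(values, percentile)
  values[values > cap] <- cap
  list(values = values, cap = cap)
}

#' Apply default top-coding to a dataset
#'
#' Top-codes `pay_delay` and both `DaysInHospital` columns in place (numeric
#' columns only; generalized label columns are left untouched).
#'
#' @param ds a `claims_dataset`.
#' @param percentile cap percentile, default `0.99`.
#' @return List with the top-coded `dataset` and the named `caps` used.
#' @export
top_code_dataset <- function(ds, percentile = 0.99) {
  validate_dataset(ds)
  caps <- c(dih_y2 = NA_real_, dih_y3 = NA_real_, pay_delay = NA_real_)
  for (col in c("dih_y2", "dih_y3")) {
    if (is.numeric(ds$patients[[col]])) {
      tc <- top_code(ds$patients[[col]], percentile)
      ds$patients[[col]] <- tc$values
      caps[col] <- tc$cap
    }
  }
  if (is.numeric(ds$claims$pay_delay)) {
    tc <- top_code(ds$claims$pay_delay, percentile)
    ds$claims$pay_delay <- tc$values
    caps["pay_delay"] <- tc$cap
  }
  list(dataset = ds, caps = caps)
}

#' Rarity score per claim
#'
#' Each claim gets the sum, over the level-2 quasi-identifiers, of
#' `-log2(relative frequency of its value in the full claims table)`: a claim
#' made entirely of ubiquitous values scores 0, and rarer value combinations
#' score higher. Truncation deletes the highest-scoring (most re-identifying)
#' claims first.
#'
#' @param ds a `claims_dataset` with a non-empty claims table.
#' @return Numeric vector of scores, one per claims-table row.
#' @export
score_claims <- function(ds) {
  validate_dataset(ds)
  claims <- ds$claims
  if (nrow(claims) == 0) stop("claims table is empty")
  n <- nrow(claims)
  score <- numeric(n)
  for (qi in level2_qis()) {
    v <- as.character(claims[[qi]])
    freq <- table(v, useNA = "ifany")
    rel <- as.numeric(freq[match(v, names(freq))]) / n
    score <- score - log2(rel)
  }
  score
}

#' Truncate each patient's claims at a percentile cut-off
#'
#' The cut-off is the nearest-rank percentile (default 95th) of per-patient
#' claim counts. For every patient above the cut-off, the highest-scoring
#' claims (see [score_claims()]) are removed until the count equals the
#' cut-off. Ties are broken deterministically: larger `dsfc` first, then
#' larger input row index (preserving the earliest clinical history).
#'
#' The untruncated input plays the role of the adversary's reference ("D1");
#' the returned truncated dataset is the releasable version ("D2").
#'
#' @param ds a `claims_dataset`.
#' @param percentile claim-count percentile, default `0.95`.
#' @return List with `dataset` (truncated) and `plan` (a `truncation_plan`:
#'   `cutoff`, per-claim `scores`, integer row indices `removed`).
#' @export
truncate_claims <- function(ds, percentile = 0.95) {
  validate_dataset(ds)
  counts <- table(factor(ds$claims$member_id,
                         levels = ds$patients$member_id))
  cutoff <- nearest_rank(as.numeric(counts), percentile)
  scores <- score_claims(ds)
  dsfc_num <- if (is.numeric(ds$claims$dsfc)) {
    ds$claims$dsfc
  } else {
    rep(0, nrow(ds$claims))
  }
  removed <- integer(0)
  over <- names(counts)[counts > cutoff]
  for (m in over) {
    rows <- which(ds$claims$member_id == m)
    # highest score first; ties: larger dsfc, then larger row index
    ord <- rows[order(-scores[rows], -dsfc_num[rows], -rows)]
    removed <- c(removed, ord[seq_len(length(rows) - cutoff)])
  }
  out <- ds
  if (length(removed) > 0) {
    out$claims <- ds$claims[-removed, , drop = FALSE]
    rownames(out$claims) <- NULL
  }
  plan <- structure(
    list(cutoff = cutoff, scores = scores, removed = sort(removed)),
    class = "truncation_plan"
  )
  list(dataset = out, plan = plan)
}

#' High-risk code list
#'
#' Code patterns (exact codes or prefixes) for conditions whose bearers must
#' not appear in a release at all: highly stigmatized diagnoses and
#' procedures. A prefix such as `"042"` matches the whole ICD-9 family
#' `042.x`. The list shipped with the package is a small synthetic
#' demonstration list, not an authoritative clinical standard.
#'
#' @param icd9_codes character vector of ICD-9 patterns.
#' @param cpt_codes character vector of CPT patterns.
#' @return An object of class `high_risk_code_list`.
#' @export
high_risk_code_list <- function(icd9_codes = character(0),
                                cpt_codes = character(0)) {
  chk <- function(x, what) {
    x <- as.character(x)
    if (any(is.na(x) | !nzchar(x))) {
      stop("empty or NA pattern in ", what, " code list")
    }
    x
  }
  structure(
    list(icd9_codes = chk(icd9_codes, "ICD-9"),
         cpt_codes = chk(cpt_codes, "CPT")),
    class = "high_risk_code_list"
  )
}

#' Read a high-risk code list from a two-column CSV
#'
#' Expected columns: `code_system` (`icd9` or `cpt`) and `pattern`.
#'
#' @param path CSV path.
#' @return A [high_risk_code_list()].
#' @export
read_code_list <- function(path) {
  tab <- read.csv(path, colClasses = "character")
  names(tab) <- .norm_header(names(tab))
  if (!all(c("codesystem", "pattern") %in% names(tab))) {
    stop("code list must have columns code_system and pattern")
  }
  sys <- tolower(tab$codesystem)
  bad <- setdiff(unique(sys), c("icd9", "cpt"))
  if (length(bad) > 0) {
    stop("unknown code_system value(s): ", paste(bad, collapse = ", "))
  }
  high_risk_code_list(
    icd9_codes = tab$pattern[sys == "icd9"],
    cpt_codes = tab$pattern[sys == "cpt"]
  )
}

.matches_pattern <- function(values, patterns) {
  hit <- rep(FALSE, length(values))
  for (p in patterns) {
    hit <- hit | startsWith(as.character(values), p)
  }
  hit
}

#' Remove patients carrying high-risk codes
#'
#' Any patient with at least one claim whose diagnosis (ICD-9) or procedure
#' (CPT) code matches the list — exact or prefix match — is removed together
#' with all of their claims. For these patients the only acceptable residual
#' risk is zero, so they are excluded rather than generalized.
#'
#' @param ds a `claims_dataset`.
#' @param codes a [high_risk_code_list()].
#' @return The filtered `claims_dataset`.
#' @export
remove_high_risk_patients <- function(ds, codes) {
  validate_dataset(ds)
  stopifnot(inherits(codes, "high_risk_code_list"))
  hit <- .matches_pattern(ds$claims$diagnosis, codes$icd9_codes) |
    .matches_pattern(ds$claims$cpt_code, codes$cpt_codes)
  flagged <- unique(ds$claims$member_id[hit])
  out <- ds
  out$patients <- ds$patients[!ds$patients$member_id %in% flagged, ,
                              drop = FALSE]
  out$claims <- ds$claims[!ds$claims$member_id %in% flagged, , drop = FALSE]
  rownames(out$patients) <- NULL
  rownames(out$claims) <- NULL
  validate_dataset(out)
  out
}

#' Suppress provider-type identifiers with rare treatment patterns
#'
#' A treatment pattern is the 4-tuple (specialty, place of service, CPT code,
#' diagnosis). For each pattern the number of distinct providers having at
#' least one claim with that pattern is counted in the sample and scaled to a
#' population estimate (sample count / `alpha` under the default large-sample
#' estimator). Where the estimated population count falls below `min_count`
#' (default 20, matching the population class-size floor), the provider ID is
#' blanked on those claims. The same rule is applied independently to the
#' vendor and primary-care-provider columns. Already-suppressed (`NA`) IDs do
#' not contribute to pattern counts.
#'
#' @param ds a `claims_dataset` (its `alpha` is used).
#' @param min_count minimum estimated population count, default 20.
#' @param estimator `"large_sample"` (count / alpha) or `"truncated_poisson"`
#'   (see [estimate_population_class_size()]).
#' @return The `claims_dataset` with rare-pattern IDs suppressed.
#' @export
suppress_provider_ids <- function(ds, min_count = 20,
                                  estimator = c("large_sample",
                                                "truncated_poisson")) {
  validate_dataset(ds)
  estimator <- match.arg(estimator)
  if (min_count < 1) stop("min_count must be >= 1")
  pattern <- paste(
    ds$claims$specialty, ds$claims$place_of_service,
    ds$claims$cpt_code, ds$claims$diagnosis,
    sep = "\x1f"
  )
  out <- ds
  for (field in c("provider_id", "vendor", "pcp")) {
    ids <- ds$claims[[field]]
    ok <- !is.na(ids)
    n_distinct <- tapply(ids[ok], pattern[ok],
                         function(x) length(unique(x)))
    if (length(n_distinct) == 0) next
    est <- vapply(
      as.numeric(n_distinct),
      function(f) estimate_population_class_size(f, ds$alpha, estimator),
      numeric(1)
    )
    rare <- names(n_distinct)[est < min_count]
    out$claims[[field]][ok & pattern %in% rare] <- NA_character_
  }
  out
}
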