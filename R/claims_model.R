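#' @useDynLib longdeid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnbinom runif setNames uniroot quantile rpois
#' @importFrom utils read.csv write.csv head
NULL

# Canonical column layouts (release layout of the two linked tables).
.patient_cols <- c(
  member_id = "MemberID", age = "Age", sex = "Sex",
  dih_y2 = "DaysInHospital Y2", dih_y3 = "DaysInHospital Y3"
)
.claim_cols <- c(
  member_id = "MemberID", provider_id = "ProviderID", vendor = "Vendor",
  pcp = "PCP", year = "Year", specialty = "Specialty",
  place_of_service = "PlaceOfService", cpt_code = "CPTCode", los = "LOS",
  dsfc = "DSFC", pay_delay = "PayDelay", diagnosis = "Diagnosis"
)

#' Names of the quasi-identifier columns
#'
#' Level-1 quasi-identifiers live in the patients table (demographics and
#' hospital-day outcomes); level-2 quasi-identifiers live in the claims table
#' (per-claim attributes an adversary could learn piecemeal).
#'
#' @return Character vector of internal column names.
#' @export
level1_qis <- function() c("age", "sex", "dih_y2", "dih_y3")

#' @rdname level1_qis
#' @export
level2_qis <- function() {
  c("specialty", "place_of_service", "cpt_code", "los", "dsfc", "diagnosis")
}

.id_fields <- function() c("member_id", "provider_id", "vendor", "pcp")

#' Construct a longitudinal claims dataset
#'
#' Bundles the two linked tables — one row per patient, many rows per patient
#' in the claims table — together with the sampling fraction `alpha` relating
#' the dataset to the patient population it was drawn from. `alpha` travels
#' with the data because every population-level risk estimate divides by it.
#'
#' @param patients data.frame with columns `member_id`, `age`, `sex`,
#'   `dih_y2`, `dih_y3`. Numeric columns may instead hold generalized interval
#'   labels after de-identification.
#' @param claims data.frame with columns `member_id`, `provider_id`, `vendor`,
#'   `pcp`, `year`, `specialty`, `place_of_service`, `cpt_code`, `los`,
#'   `dsfc`, `pay_delay`, `diagnosis`. `NA` in the three optional ID columns
#'   means suppressed.
#' @param alpha sampling fraction in (0, 1]: the fraction of the source
#'   population present in this dataset.
#' @return An object of class `claims_dataset`.
#' @export
claims_dataset <- function(patients, claims, alpha = 1) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  claims <- as.data.frame(claims, stringsAsFactors = FALSE)
  rownames(patients) <- NULL
  rownames(claims) <- NULL
  ds <- structure(
    list(patients = patients, claims = claims, alpha = alpha),
    class = "claims_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a claims dataset
#'
#' Checks the structural invariants: required columns present, unique patient
#' IDs, referential integrity from claims to patients, non-negative day
#' counts on numeric columns, and `alpha` in (0, 1].
#'
#' @param ds a `claims_dataset`.
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "claims_dataset"))
  miss_p <- setdiff(names(.patient_cols), names(ds$patients))
  if (length(miss_p) > 0) {
    stop("patients table missing column(s): ", paste(miss_p, collapse = ", "))
  }
  miss_c <- setdiff(names(.claim_cols), names(ds$claims))
  if (length(miss_c) > 0) {
    stop("claims table missing column(s): ", paste(miss_c, collapse = ", "))
  }
  if (anyDuplicated(ds$patients$member_id)) {
    stop("duplicate member_id in patients table")
  }
  unknown <- setdiff(ds$claims$member_id, ds$patients$member_id)
  if (length(unknown) > 0) {
    stop(
      "claims reference member_id value(s) absent from patients table: ",
      paste(head(unknown, 5L), collapse = ", ")
    )
  }
  for (col in c("dih_y2", "dih_y3")) {
    v <- ds$patients[[col]]
    if (is.numeric(v) && any(v < 0, na.rm = TRUE)) {
      stop("negative values in ", col)
    }
  }
  if (is.numeric(ds$claims$dsfc) && any(ds$claims$dsfc < 0, na.rm = TRUE)) {
    stop("negative values in dsfc")
  }
  if (!is.numeric(ds$alpha) || length(ds$alpha) != 1 ||
      ds$alpha <= 0 || ds$alpha > 1) {
    stop("alpha must be a single number in (0, 1]")
  }
  invisible(ds)
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat(
    "<claims_dataset> ", nrow(x$patients), " patients, ",
    nrow(x$claims), " claims, alpha = ", format(x$alpha), "\n",
    sep = ""
  )
  invisible(x)
}

# Normalize a header name: case and punctuation insensitive.
.norm_header <- function(x) tolower(gsub("[^a-z0-9]", "", tolower(x)))

# Map raw CSV headers onto internal names; error on missing required columns.
.match_headers <- function(raw, canonical, table_name) {
  want <- .norm_header(unname(canonical))
  got <- .norm_header(raw)
  idx <- match(want, got)
  if (anyNA(idx)) {
    stop(
      table_name, " file missing required column(s): ",
      paste(unname(canonical)[is.na(idx)], collapse = ", ")
    )
  }
  idx
}

.parse_int_or_label <- function(x) {
  x <- as.character(x)
  suppress <- is.na(x) | x == ""
  num <- suppressWarnings(as.integer(x))
  if (all(!is.na(num) | suppress)) {
    num
  } else {
    x[suppress] <- NA_character_
    x
  }
}

.parse_id <- function(x) {
  x <- as.character(x)
  x[x == ""] <- NA_character_
  x
}

#' Read a claims dataset from the two-table CSV layout
#'
#' Header matching is case- and punctuation-insensitive and column order is
#' free. Numeric quasi-identifier columns that contain generalized interval
#' labels are read back as character, so a de-identified release round-trips.
#' Empty strings in `ProviderID`/`Vendor`/`PCP` are read as suppressed (`NA`).
#'
#' @param patients_path path to the patients CSV.
#' @param claims_path path to the claims CSV.
#' @param alpha sampling fraction recorded on the returned dataset.
#' @return A validated [claims_dataset()].
#' @export
read_dataset <- function(patients_path, claims_path, alpha = 1) {
  praw <- read.csv(patients_path, check.names = FALSE,
                   colClasses = "character")
  craw <- read.csv(claims_path, check.names = FALSE,
                   colClasses = "character")
  pidx <- .match_headers(names(praw), .patient_cols, "patients")
  cidx <- .match_headers(names(craw), .claim_cols, "claims")
  patients <- setNames(praw[pidx], names(.patient_cols))
  claims <- setNames(craw[cidx], names(.claim_cols))
  patients$member_id <- .parse_id(patients$member_id)
  for (col in c("age", "dih_y2", "dih_y3")) {
    patients[[col]] <- .parse_int_or_label(patients[[col]])
  }
  for (col in c("member_id", "provider_id", "vendor", "pcp")) {
    claims[[col]] <- .parse_id(claims[[col]])
  }
  for (col in c("year", "specialty", "place_of_service", "cpt_code",
                "diagnosis")) {
    claims[[col]] <- as.character(claims[[col]])
  }
  for (col in c("los", "dsfc", "pay_delay")) {
    claims[[col]] <- .parse_int_or_label(claims[[col]])
  }
  claims_dataset(patients, claims, alpha = alpha)
}

#' Write a claims dataset as two CSV files
#'
#' Inverse of [read_dataset()]: columns are emitted under the release layout
#' headers, suppressed IDs as empty fields, and generalized labels verbatim,
#' so `read_dataset(write_dataset(ds))` reproduces `ds` field-for-field.
#'
#' @param ds a `claims_dataset`.
#' @param out_dir output directory (created if absent).
#' @param basenames names for the two files.
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(ds, out_dir,
                          basenames = c("patients.csv", "claims.csv")) {
  validate_dataset(ds)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  ppath <- file.path(out_dir, basenames[1])
  cpath <- file.path(out_dir, basenames[2])
  pat <- setNames(ds$patients[names(.patient_cols)], unname(.patient_cols))
  cla <- setNames(ds$claims[names(.claim_cols)], unname(.claim_cols))
  for (col in c("ProviderID", "Vendor", "PCP")) {
    cla[[col]][is.na(cla[[col]])] <- ""
  }
  write.csv(pat, ppath, row.names = FALSE, na = "")
  write.csv(cla, cpath, row.names = FALSE, na = "")
  invisible(c(patients = ppath, claims = cpath))
}

#' Replace identifier fields by irreversible keyed pseudonyms
#'
#' Each identifier value is mapped to a fixed-width hex token by HMAC-SHA256
#' under a caller-supplied secret, with the field name bound into the message
#' so the same raw value in different fields yields unrelated tokens. The
#' mapping is deterministic for a fixed secret (preserving the patient-claims
#' linkage across both tables), injective in practice (64-bit tokens), and
#' cannot be inverted or replayed without the secret. Suppressed (`NA`) values
#' stay suppressed.
#'
#' @param ds a `claims_dataset`.
#' @param fields which identifier fields to pseudonymize; subset of
#'   `member_id`, `provider_id`, `vendor`, `pcp`.
#' @param secret non-empty character scalar; the release key. An empty secret
#'   is refused: unkeyed hashes of low-entropy IDs fall to dictionary attack.
#' @param nchar_token token width in hex characters (default 16 = 64 bits).
#' @return A new `claims_dataset` with pseudonymized fields.
#' @export
pseudonymize <- function(ds, fields = .id_fields(), secret,
                         nchar_token = 16L) {
  validate_dataset(ds)
  if (!is.character(secret) || length(secret) != 1 || !nzchar(secret)) {
    stop("secret must be a non-empty character scalar")
  }
  bad <- setdiff(fields, .id_fields())
  if (length(bad) > 0) {
    stop("not an identifier field: ", paste(bad, collapse = ", "))
  }
  token <- function(field, values) {
    out <- values
    ok <- !is.na(values)
    # field label separated by a byte that cannot occur in the values
    out[ok] <- .hmac_sha256_hex(
      secret, paste0(field, "\x1f", values[ok]), nchar_token
    )
    out
  }
  for (f in intersect(fields, "member_id")) {
    new_p <- token("member_id", ds$patients$member_id)
    ds$claims$member_id <- token("member_id", ds$claims$member_id)
    ds$patients$member_id <- new_p
  }
  for (f in setdiff(fields, "member_id")) {
    ds$claims[[f]] <- token(f, ds$claims[[f]])
  }
  validate_dataset(ds)
  ds
}
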